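meth_fixture <- function(n_per_group = 3, cpgs) {
  # cpgs: list of list(chrom, pos, m1, t1, m2, t2) with per-sample vectors
  samples <- sample_table(
    c(paste0("F1F", seq_len(n_per_group)), paste0("F1M", seq_len(n_per_group))),
    rep(c("F1F", "F1M"), each = n_per_group)
  )
  mt <- tibble::tibble(
    chrom = vapply(cpgs, `[[`, "", "chrom"),
    pos = vapply(cpgs, `[[`, 0, "pos"),
    strand = "+"
  )
  for (j in seq_len(n_per_group)) {
    mt[[paste0("F1F", j, "_meth")]] <- vapply(cpgs, function(x) x$m1[j], 0)
    mt[[paste0("F1F", j, "_total")]] <- vapply(cpgs, function(x) x$t1[j], 0)
    mt[[paste0("F1M", j, "_meth")]] <- vapply(cpgs, function(x) x$m2[j], 0)
    mt[[paste0("F1M", j, "_total")]] <- vapply(cpgs, function(x) x$t2[j], 0)
  }
  list(mt = mt, samples = samples)
}

test_that("coverage filter is strict and drops invariant CpGs", {
  fx <- meth_fixture(cpgs = list(
    list(chrom = "chr1", pos = 100, m1 = c(5, 5, 5), t1 = c(10, 10, 10),
         m2 = c(2, 2, 2), t2 = c(10, 10, 10)),           # kept
    list(chrom = "chr1", pos = 200, m1 = c(5, 5, 5), t1 = c(10, 8, 10),
         m2 = c(2, 2, 2), t2 = c(10, 10, 10)),           # one sample at 8 -> out
    list(chrom = "chr1", pos = 300, m1 = c(10, 10, 10), t1 = c(10, 10, 10),
         m2 = c(10, 10, 10), t2 = c(10, 10, 10)),        # all methylated -> out
    list(chrom = "chr1", pos = 400, m1 = c(0, 0, 0), t1 = c(10, 10, 10),
         m2 = c(0, 0, 0), t2 = c(10, 10, 10))            # all unmethylated -> out
  ))
  kept <- filter_cpgs(fx$mt, fx$samples, "F1F_vs_F1M")
  expect_equal(kept$pos, 100)
})

test_that("a planted-coverage fixture retains exactly the hand count", {
  set.seed(113)
  n <- 100
  covered <- rep(c(TRUE, FALSE), length.out = n)
  cpgs <- lapply(seq_len(n), function(i) {
    t <- if (covered[i]) rep(20, 3) else c(20, 6, 20)
    list(chrom = "chr1", pos = i * 10,
         m1 = pmin(rbinom(3, t, 0.5), t), t1 = t,
         m2 = pmin(rbinom(3, t, 0.5), t), t2 = t)
  })
  fx <- meth_fixture(cpgs = cpgs)
  kept <- filter_cpgs(fx$mt, fx$samples, "F1F_vs_F1M")
  pooled <- (rowSums(as.matrix(fx$mt[, grep("_meth$", names(fx$mt))])) /
               rowSums(as.matrix(fx$mt[, grep("_total$", names(fx$mt))])))
  expect_equal(nrow(kept), sum(covered & pooled > 0 & pooled < 1))
})

test_that("identical pooled proportions give a null test result", {
  fx <- meth_fixture(cpgs = list(
    list(chrom = "chr1", pos = 100, m1 = c(6, 6, 6), t1 = c(12, 12, 12),
         m2 = c(9, 3, 6), t2 = c(18, 6, 12))
  ))
  res <- dm_test(fx$mt, fx$samples, "F1F_vs_F1M")
  expect_equal(res$pvalue, 1)
  expect_equal(res$delta, 0)
  expect_false(res$is_dm)
})

test_that("Fisher p-values equal the enumeration oracle", {
  # the strongly unbalanced worked example
  expect_equal(omicsconcord:::fisher_exact_p(90, 10, 10, 90),
               fisher_oracle(90, 10, 10, 90), tolerance = 1e-12)
  expect_equal(omicsconcord:::fisher_exact_p(90, 10, 10, 90),
               stats::fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value,
               tolerance = 1e-9)
  # exhaustive small-margin agreement, pooled totals <= 60
  set.seed(127)
  for (i in 1:200) {
    tot <- sample(4:60, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    expect_equal(omicsconcord:::fisher_exact_p(a, b, c, d),
                 fisher_oracle(a, b, c, d), tolerance = 1e-12)
    expect_equal(omicsconcord:::fisher_exact_p(a, b, c, d),
                 stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the DM caller is calibrated on a null simulation", {
  cfg <- sim_config(n_genes = 100, n_mapped_proteins = 50, n_cpgs = 5000,
                    frac_meth_sex = 0, frac_meth_origin = 0,
                    female_meth_offset = 0, rng_seed = 131)
  sim <- simulate_methylation(cfg)
  mf <- filter_cpgs(sim$methylation, sim$samples, "F1F_vs_F1M")
  dm <- dm_test(mf, sim$samples, "F1F_vs_F1M")
  expect_lte(mean(dm$is_dm), 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(dm)))
})

test_that("degenerate pooled tables yield p = 1", {
  expect_equal(omicsconcord:::fisher_exact_p(0, 10, 0, 12), 1)
  expect_equal(omicsconcord:::fisher_exact_p(10, 0, 12, 0), 1)
})

test_that("feature-context annotation respects definitions and precedence", {
  # + strand transcript txA: exons [3000,3200] and [4000,4200]; TSS = 3000,
  # promoter [1000,3500]. - strand txB: exons [5000,5200], [6000,6200],
  # [7000,7300]; TSS = 7300, promoter [6800,9300]; its 5'-first intron is the
  # genomically-last one
  gm <- tibble::tibble(
    transcript_id = c("txA", "txA", "txB", "txB", "txB"),
    chrom = "chr1",
    start = c(3000, 4000, 5000, 6000, 7000),
    end = c(3200, 4200, 5200, 6200, 7300),
    strand = c("+", "+", "-", "-", "-")
  )
  dm <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(3000,   # TSS -> promoter
            3700,   # unique intron of txA, past the promoter window -> first_intron
            4100,   # inside exon 2 of txA -> exon
            6500,   # genomically-second intron of txB = 5' first on minus strand
            5500,   # genomically-first intron of txB = other_intron (minus strand)
            7400,   # just upstream of the minus-strand TSS -> promoter
            100),   # unannotated chromosome
    strand = "+", delta = 0, log2_ratio = 0, pvalue = 1, fdr = 1,
    is_dm = FALSE
  )
  ann <- annotate_context(dm, gm)
  expect_equal(ann$feature_context,
               c("promoter", "first_intron", "exon", "first_intron",
                 "other_intron", "promoter", "intergenic"))
  expect_true(ann$unannotated_chrom[7])
  # every CpG gets exactly one label
  expect_true(all(ann$feature_context %in%
                    c("promoter", "exon", "first_intron", "other_intron",
                      "intergenic")))
})

test_that("promoter precedence wins over exon across overlapping transcripts", {
  gm <- tibble::tibble(
    transcript_id = c("tx1", "tx2"), chrom = "chr1",
    start = c(1000, 3500), end = c(5000, 4000), strand = "+"
  )
  dm <- tibble::tibble(chrom = "chr1", pos = 3600, strand = "+",
                       delta = 0, log2_ratio = 0, pvalue = 1, fdr = 1,
                       is_dm = FALSE)
  # 3600 is inside tx1's exon but within tx2's promoter window
  ann <- annotate_context(dm, gm)
  expect_equal(ann$feature_context, "promoter")
})

test_that("methylation tables round-trip and validate", {
  fx <- meth_fixture(cpgs = list(
    list(chrom = "chr1", pos = 10, m1 = c(1, 2, 3), t1 = c(4, 5, 6),
         m2 = c(0, 0, 1), t2 = c(3, 3, 3))
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fx$mt, path)
  back <- read_methylation(path)
  expect_equal(back, fx$mt)

  bad <- fx$mt
  bad$F1F1_meth <- bad$F1F1_total + 1
  expect_error(omicsconcord:::validate_methylation(bad), "m <= total")
})
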