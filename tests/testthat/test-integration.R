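fake_result <- function(ids, lfc, p, status, contrast, layer) {
  res <- tibble::tibble(feature_id = ids, log2fc = lfc, pvalue = p,
                        fdr = p, status = status)
  attr(res, "contrast") <- omicsconcord::contrast(
    strsplit(contrast, "_vs_")[[1]][1], strsplit(contrast, "_vs_")[[1]][2])
  attr(res, "layer") <- layer
  class(res) <- c("contrast_result", class(res))
  res
}

test_that("the classifier maps every status combination correctly", {
  expect_equal(classify_pair("UP", 2.0, "UP", 1.0), "CONCORDANT_UP")
  expect_equal(classify_pair("DOWN", -1.2, "DOWN", -0.6), "CONCORDANT_DOWN")
  expect_equal(classify_pair("UP", 2.0, "DOWN", -0.8), "DISCORDANT")
  expect_equal(classify_pair("DOWN", -2.0, "UP", 0.8), "DISCORDANT")
  expect_equal(classify_pair("UP", 1.5, "NS", 0.1), "RNA_EXCLUSIVE")
  expect_equal(classify_pair("DOWN", -1.5, "NS", 0.1), "RNA_EXCLUSIVE")
  expect_equal(classify_pair("NS", 0.2, "UP", 0.7), "PROTEIN_EXCLUSIVE")
  expect_equal(classify_pair("NS", 0.2, "DOWN", -0.7), "PROTEIN_EXCLUSIVE")
  expect_equal(classify_pair("NS", 0.3, "NS", -0.1), "NS")
  # a status contradicting its fold-change sign is an upstream bug
  expect_error(classify_pair("UP", -2.0, "NS", 0), "contradicts")
})

test_that("pair construction follows the map and per-contrast testability", {
  deg <- fake_result(c("g1", "g2", "g3"), c(2, -1.5, 0.1),
                     c(0.001, 0.01, 0.8), c("UP", "DOWN", "NS"),
                     "F1F_vs_F1M", "RNA")
  dep <- fake_result(c("p1", "p2", "p3"), c(1, 0.7, -0.2),
                     c(0.001, 0.02, 0.9), c("UP", "UP", "NS"),
                     "F1F_vs_F1M", "PROT")
  map <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                        gene_id = c("g1", "g1", "g2"))
  pairs <- build_pairs(deg, dep, map)
  # two proteins of g1 give two pairs; no collapsing by default
  expect_equal(nrow(pairs), 3L)
  expect_equal(sum(pairs$gene_id == "g1"), 2L)
  expect_setequal(
    pairs$pair_class[pairs$gene_id == "g1"], "CONCORDANT_UP")
  expect_equal(pairs$pair_class[pairs$protein_id == "p3"], "RNA_EXCLUSIVE")

  # a protein whose gene was untested at RNA contributes no pair
  deg_na <- deg
  deg_na$pvalue[2] <- NA
  pairs2 <- build_pairs(deg_na, dep, map)
  expect_false("g2" %in% pairs2$gene_id)

  # mismatched contrasts are rejected
  dep_wrong <- dep
  attr(dep_wrong, "contrast") <- contrast("wtF", "wtM")
  expect_error(build_pairs(deg, dep_wrong, map), "different contrasts")

  expect_warning(
    empty <- build_pairs(deg, dep,
                         tibble::tibble(protein_id = "px", gene_id = "gx")),
    "no mapped"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("collapse mode keeps the highest-intensity representative", {
  deg <- fake_result("g1", 2, 0.001, "UP", "F1F_vs_F1M", "RNA")
  dep <- fake_result(c("p1", "p2"), c(1, -0.9), c(0.01, 0.01),
                     c("UP", "DOWN"), "F1F_vs_F1M", "PROT")
  map <- tibble::tibble(protein_id = c("p1", "p2"), gene_id = c("g1", "g1"))
  intens <- make_counts(rbind(c(10, 10), c(1000, 1000)),
                        genes = c("p1", "p2"), samples = c("s1", "s2"))
  pairs <- build_pairs(deg, dep, map, collapse = TRUE, intensities = intens)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$protein_id, "p2")
})

test_that("concordance summaries reproduce the reporting arithmetic", {
  # printed-count arithmetic, including the sub-0.1% two-decimal rule
  expect_equal(concordance_pct(161, 867), 18.6)
  expect_equal(concordance_pct(5, 835), 0.6)
  expect_equal(concordance_pct(1, 1228), 0.08)
  expect_equal(concordance_pct(102, 798), 12.8)

  set.seed(89)
  lfc <- rnorm(20)
  deg <- fake_result(paste0("g", 1:20), lfc, rep(0.001, 20),
                     ifelse(lfc > 0, "UP", "DOWN"), "F1F_vs_F1M", "RNA")
  dep <- fake_result(paste0("p", 1:20), lfc, rep(0.001, 20),
                     ifelse(lfc > 0, "UP", "DOWN"), "F1F_vs_F1M", "PROT")
  map <- tibble::tibble(protein_id = paste0("p", 1:20),
                        gene_id = paste0("g", 1:20))
  pairs <- build_pairs(deg, dep, map)
  s <- summarize_concordance(pairs)
  # identical fold changes at both layers: all concordant, perfect correlation
  expect_equal(s$n_concordant, 20L)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$spearman_rho, 1)
  expect_identical(glance(pairs), s)
})

test_that("correlations match rank-based oracles", {
  expect_equal(correlate(1:5, 5:1),
               tibble::tibble(pearson_r = -1, spearman_rho = -1))
  # hand-derived Spearman for a single swap: 1 - 6*2/(4*15) = 0.8
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))$spearman_rho, 0.8)
  # mid-rank handling of ties against the direct rank formula
  x <- c(1, 1, 2, 5, 5, 9)
  y <- c(2, 3, 3, 7, 1, 8)
  expect_equal(correlate(x, y)$spearman_rho,
               cor(rank(x), rank(y)))
  expect_true(is.na(correlate(c(1, 1, 1), c(1, 2, 3))$pearson_r))
  expect_error(correlate(1:3, 1:4), "equal length")
  expect_error(correlate(c(1, NA), c(1, 2)), "missing")
})

test_that("pair classes partition and are orientation-symmetric", {
  sim <- simulate_multiomics(sim_config(n_genes = 800,
                                        n_mapped_proteins = 400,
                                        n_cpgs = 50, rng_seed = 97))
  deg <- nb_wald_contrast(sim$counts, sim$samples_rna, "F1F_vs_F1M")
  norm <- normalize_intensities(filter_proteins(sim$intensities)$intensities)
  dep <- moderated_t_contrast(norm, sim$samples_protein, "F1F_vs_F1M")
  pairs <- build_pairs(deg, dep, sim$map)
  s <- summarize_concordance(pairs)
  # the six class counts partition n_pairs
  expect_equal(
    s$CONCORDANT_UP + s$CONCORDANT_DOWN + s$DISCORDANT + s$RNA_EXCLUSIVE +
      s$PROTEIN_EXCLUSIVE + s$NS,
    s$n_pairs
  )

  # flip the contrast orientation: negate both layers and swap UP/DOWN
  flip <- function(st) ifelse(st == "UP", "DOWN", ifelse(st == "DOWN", "UP", "NS"))
  flipped <- pairs
  flipped$rna_log2fc <- -flipped$rna_log2fc
  flipped$prot_log2fc <- -flipped$prot_log2fc
  flipped$rna_status <- flip(flipped$rna_status)
  flipped$prot_status <- flip(flipped$prot_status)
  flipped$pair_class <- classify_pair(flipped$rna_status, flipped$rna_log2fc,
                                      flipped$prot_status, flipped$prot_log2fc)
  sf <- summarize_concordance(flipped)
  expect_equal(sf$CONCORDANT_UP, s$CONCORDANT_DOWN)
  expect_equal(sf$CONCORDANT_DOWN, s$CONCORDANT_UP)
  expect_equal(sf$DISCORDANT, s$DISCORDANT)
  expect_equal(sf$RNA_EXCLUSIVE, s$RNA_EXCLUSIVE)
  expect_equal(sf$PROTEIN_EXCLUSIVE, s$PROTEIN_EXCLUSIVE)
  expect_equal(sf$concordance_pct, s$concordance_pct)
  expect_equal(abs(sf$pearson_r), abs(s$pearson_r))
  expect_equal(abs(sf$spearman_rho), abs(s$spearman_rho))
})

test_that("estimated pair classes track planted truth under strong coupling", {
  cfg <- sim_config(n_genes = 1500, n_mapped_proteins = 800,
                    frac_sex_de = 0.15, sex_lfc_scale = 3,
                    coupling = c(F1F_vs_F1M = 0.9, F1F_vs_wtF = 0.9,
                                 F1M_vs_wtM = 0.9, wtF_vs_wtM = 0.9),
                    rng_seed = 101)
  sim <- simulate_multiomics(cfg)
  deg <- nb_wald_contrast(sim$counts, sim$samples_rna, "wtF_vs_wtM")
  norm <- normalize_intensities(filter_proteins(sim$intensities)$intensities)
  dep <- moderated_t_contrast(norm, sim$samples_protein, "wtF_vs_wtM")
  pairs <- build_pairs(deg, dep, sim$map)
  truth <- subset(sim$truth$pairs, contrast == "wtF_vs_wtM")
  truth <- truth[match(pairs$gene_id, truth$gene_id), ]
  # condition on pairs whose estimated statuses match the planted truth:
  # for those, any class mismatch is a classifier bug, not estimation noise
  status_match <- pairs$rna_status == truth$rna_status &
    pairs$prot_status == truth$prot_status
  expect_gt(sum(status_match), 100)
  agree <- pairs$pair_class == truth$true_pair_class
  expect_gte(mean(agree[status_match]), 0.9)
})
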