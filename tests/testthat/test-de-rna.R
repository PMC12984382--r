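test_that("median-of-ratios size factors match hand computations", {
  # two identical samples: symmetry forces (1, 1)
  sf <- estimate_size_factors(make_counts(cbind(c(3, 5, 8), c(3, 5, 8))))
  expect_equal(sf$size_factor, c(1, 1))

  # exact doubling with the geomean-1 convention forces (1/sqrt2, sqrt2)
  sf2 <- estimate_size_factors(make_counts(cbind(c(4, 6), c(8, 12))))
  expect_equal(sf2$size_factor, c(1 / sqrt(2), sqrt(2)))

  # 4 genes x 3 samples: medians of ratios give s prop (1, 2, 1), normalised
  # to geometric mean one: (2^(-1/3), 2^(2/3), 2^(-1/3))
  counts <- make_counts(rbind(c(10, 20, 10), c(4, 8, 4),
                              c(6, 12, 6), c(8, 16, 8)))
  sf3 <- estimate_size_factors(counts)
  expect_equal(sf3$size_factor, c(2^(-1 / 3), 2^(2 / 3), 2^(-1 / 3)))

  expect_error(
    estimate_size_factors(make_counts(cbind(c(0, 5), c(3, 0)))),
    "no gene has positive counts"
  )
})

test_that("dispersion estimation recovers known truth", {
  st <- sample_table(c(paste0("F1F", 1:10), paste0("F1M", 1:10)),
                     rep(c("F1F", "F1M"), each = 10))
  # Poisson data: true dispersion 0, median final estimate must be small
  set.seed(101)
  mu <- 2^runif(2000, 3, 10)
  pois <- matrix(rpois(2000 * 20, rep(mu, 20)), nrow = 2000)
  cp <- make_counts(pois, samples = st$sample_id)
  dp <- estimate_dispersions(cp, st)
  expect_lte(median(dp$disp_final), 0.05)

  # NB data with alpha = 0.4: median recovered dispersion in [0.3, 0.5]
  set.seed(102)
  nb <- matrix(rnbinom(2000 * 20, mu = rep(mu, 20), size = 1 / 0.4),
               nrow = 2000)
  cn <- make_counts(nb, samples = st$sample_id)
  dn <- estimate_dispersions(cn, st)
  expect_gte(median(dn$disp_final), 0.3)
  expect_lte(median(dn$disp_final), 0.5)

  # constant counts: zero variance, moment estimate 0, pulled to the trend
  cc <- make_counts(matrix(7, 5, 20), samples = st$sample_id)
  dc <- estimate_dispersions(cc, st)
  expect_true(all(dc$on_trend))
  expect_equal(dc$disp_final, dc$disp_trend)
})

test_that("NB Wald log2FC converges to the definition on a forced doubling", {
  st <- sample_table(c(paste0("F1F", 1:5), paste0("F1M", 1:5)),
                     rep(c("F1F", "F1M"), each = 5))
  base <- c(400, 1000, 250, 4000)
  counts <- make_counts(cbind(matrix(rep(2 * base, 5), ncol = 5),
                              matrix(rep(base, 5), ncol = 5)),
                        samples = st$sample_id)
  sf <- tibble::tibble(sample_id = st$sample_id, size_factor = rep(1, 10))
  disp <- tibble::tibble(feature_id = paste0("g", 1:4), base_mean = base,
                         disp_mom = 0.1, disp_trend = 0.1, disp_final = 0.1,
                         on_trend = FALSE)
  res <- nb_wald_contrast(counts, st, "F1F_vs_F1M", sf, disp)
  expect_equal(res$log2fc, rep(1, 4), tolerance = 1e-6)
  expect_true(all(res$converged))
})

test_that("the Wald statistic is calibrated given the generating dispersion", {
  cfg <- sim_config(n_genes = 2000, n_mapped_proteins = 100,
                    frac_sex_de = 0, frac_origin_de_per_sex = 0,
                    rng_seed = 23)
  sim <- simulate_rna(cfg)
  # supply the true dispersion to isolate the test statistic itself from
  # dispersion-estimation noise (the full plug-in null is checked end to end
  # in the calibration suite)
  truth_disp <- tibble::tibble(
    feature_id = sim$counts$feature_id, base_mean = 1, disp_mom = 0.2,
    disp_trend = 0.2, disp_final = cfg$nb_dispersion, on_trend = FALSE)
  res <- nb_wald_contrast(sim$counts, sim$samples, "F1F_vs_F1M",
                          dispersions = truth_disp)
  frac <- mean(res$pvalue < 0.05, na.rm = TRUE)
  mc <- 3 * sqrt(0.05 * 0.95 / sum(!is.na(res$pvalue)))
  expect_lt(abs(frac - 0.05), mc)
})

test_that("planted strong effects are recovered with controlled error", {
  cfg <- sim_config(n_genes = 2000, n_mapped_proteins = 100,
                    frac_sex_de = 0.1, sex_lfc_scale = 3,
                    frac_origin_de_per_sex = 0, nb_dispersion = 0.2,
                    rng_seed = 29)
  sim <- simulate_rna(cfg)
  res <- nb_wald_contrast(sim$counts, sim$samples, "wtF_vs_wtM")
  truth <- subset(sim$truth, contrast == "wtF_vs_wtM")
  truth <- truth[match(res$feature_id, truth$gene_id), ]
  called <- res$status != "NS"
  strong <- truth$rna_de & abs(truth$rna_log2fc) >= 1.5
  expect_gte(sum(called & strong) / sum(strong), 0.7)          # sensitivity
  expect_lte(sum(called & !truth$rna_de) / max(sum(called), 1), 0.10)  # FDR
})

test_that("scaling one sample's counts only moves its size factor", {
  st <- sample_table(c(paste0("F1F", 1:3), paste0("F1M", 1:3)),
                     rep(c("F1F", "F1M"), each = 3))
  set.seed(31)
  base <- matrix(2 * rnbinom(300 * 6, mu = 50, size = 5), ncol = 6)  # even
  c1 <- make_counts(base, samples = st$sample_id)
  scaled <- base; scaled[, 1] <- 2 * scaled[, 1]
  c2 <- make_counts(scaled, samples = st$sample_id)
  r1 <- nb_wald_contrast(c1, st, "F1F_vs_F1M")
  r2 <- nb_wald_contrast(c2, st, "F1F_vs_F1M")
  keep <- r1$converged & r2$converged
  expect_lt(max(abs(r1$log2fc[keep] - r2$log2fc[keep])), 1e-6)
})

test_that("all-zero genes are excluded and statuses obey the thresholds", {
  st <- sample_table(c(paste0("F1F", 1:3), paste0("F1M", 1:3)),
                     rep(c("F1F", "F1M"), each = 3))
  set.seed(37)
  m <- matrix(rnbinom(100 * 6, mu = 30, size = 5), ncol = 6)
  m[1, ] <- 0
  res <- nb_wald_contrast(make_counts(m, samples = st$sample_id), st,
                          "F1F_vs_F1M")
  expect_false("g1" %in% res$feature_id)
  expect_equal(attr(res, "n_excluded"), 1L)
  up <- res$status == "UP"; down <- res$status == "DOWN"
  expect_true(all(res$fdr[up] < 0.05 & res$log2fc[up] >= 1))
  expect_true(all(res$fdr[down] < 0.05 & res$log2fc[down] <= -1))
})

test_that("BH equals the definition and handles edge cases", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, NA)), "missing")

  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p))
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
  }
})
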