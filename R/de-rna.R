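# Negative-binomial differential expression for RNA-seq counts.
#
# Deliberately simplified relative to full production NB pipelines: a plain
# per-gene NB GLM Wald test with method-of-moments dispersion shrunk halfway
# (in log space) toward a 1/mean parametric trend. No Cox-Reid adjustment, no
# fold-change shrinkage, no independent filtering, no outlier refitting.

#' Median-of-ratios size factors
#'
#' For each sample, the median across reference genes of the ratio of its
#' count to the gene's geometric mean; reference genes are those with a
#' positive count in every sample. Factors are then divided by their own
#' geometric mean so that `geomean(size_factor) == 1`.
#'
#' @param counts count matrix tibble (`feature_id` + sample columns).
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- as_feature_matrix(counts)
  if (ncol(m) < 2L) stop_input("need at least 2 samples for size factors")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop_input("no gene has positive counts in every sample; ",
               "median-of-ratios is undefined (pseudo-reference fallback ",
               "is not provided)")
  }
  logg <- rowMeans(log(m[ref, , drop = FALSE]))
  s <- apply(log(m[ref, , drop = FALSE]) - logg, 2L, median)
  s <- exp(s - mean(s))
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Per-gene dispersion estimates with trend shrinkage
#'
#' Method-of-moments gene-wise estimates on size-factor-normalised counts
#' (variances pooled within groups), a robust parametric mean-dispersion trend
#' `a0 + a1/mean`, and a final value combining gene-wise and trend estimates
#' with equal weight in log space. Genes whose moment estimate is zero or
#' whose mean is zero fall back to the trend and are flagged.
#'
#' @param counts count matrix tibble.
#' @param samples sample table covering all count columns.
#' @param size_factors result of [estimate_size_factors()]; computed when
#'   `NULL`.
#' @return A tibble with columns `feature_id`, `base_mean`, `disp_mom`,
#'   `disp_trend`, `disp_final`, `on_trend` (logical flag).
#' @export
estimate_dispersions <- function(counts, samples, size_factors = NULL) {
  assert_samples_in_table(counts, samples)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  m <- as_feature_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  q <- sweep(m, 2L, sf, "/")
  grp <- samples$group[match(colnames(m), samples$sample_id)]

  base_mean <- rowMeans(q)
  # pooled within-group variance (df-weighted)
  ssq <- numeric(nrow(q))
  df_tot <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) >= 2L) {
      gm <- rowMeans(q[, idx, drop = FALSE])
      ssq <- ssq + rowSums((q[, idx, drop = FALSE] - gm)^2)
      df_tot <- df_tot + length(idx) - 1L
    }
  }
  if (df_tot == 0L) stop_input("need >=2 replicates in at least one group")
  s2 <- ssq / df_tot
  disp_mom <- ifelse(base_mean > 0, pmax(0, (s2 - base_mean) / base_mean^2), NA_real_)

  trend <- fit_dispersion_trend(base_mean, disp_mom)
  disp_trend <- pmax(1e-8, trend$a0 + trend$a1 / pmax(base_mean, 1e-8))

  on_trend <- is.na(disp_mom) | disp_mom <= 0
  disp_final <- ifelse(
    on_trend,
    disp_trend,
    exp(0.5 * log(pmax(disp_mom, 1e-8)) + 0.5 * log(disp_trend))
  )
  tibble(
    feature_id = rownames(m),
    base_mean = unname(base_mean),
    disp_mom = unname(disp_mom),
    disp_trend = unname(disp_trend),
    disp_final = unname(pmax(disp_final, 1e-8)),
    on_trend = unname(on_trend)
  )
}

# robust fit of disp ~ a0 + a1/mean on genes with positive moment estimates,
# by iterated outlier trimming of extreme ratio residuals
fit_dispersion_trend <- function(base_mean, disp_mom) {
  use <- which(!is.na(disp_mom) & disp_mom > 0 & base_mean > 0)
  if (length(use) < 10L) {
    med <- if (length(use) > 0L) median(disp_mom[use]) else 0.1
    return(list(a0 = max(med, 1e-8), a1 = 0))
  }
  x <- 1 / base_mean[use]
  y <- disp_mom[use]
  keep <- rep(TRUE, length(y))
  a0 <- median(y); a1 <- 0
  for (it in 1:7) {
    fit <- lm(y[keep] ~ x[keep])
    a0 <- max(coef(fit)[[1]], 1e-8)
    a1 <- max(coef(fit)[[2]], 0)
    pred <- a0 + a1 * x
    ratio <- y / pred
    keep_new <- ratio > 1e-4 & ratio < 15
    if (identical(keep_new, keep)) break
    keep <- keep_new
    if (sum(keep) < 10L) break
  }
  list(a0 = a0, a1 = a1)
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits, per gene, an NB GLM with log link and design `~ group` on the two
#' contrast groups (size factors as offsets, dispersion fixed at the supplied
#' final estimate), by iteratively reweighted least squares. The group
#' coefficient divided by `ln 2` is the log2 fold change (numerator group on
#' top); a Wald p-value comes from its asymptotic normal, and BH adjustment is
#' applied across all tested genes of the contrast. Genes with all-zero counts
#' across the two groups are excluded from testing and from the BH family.
#' Genes whose IRLS does not converge within `max_iter` get a missing p-value
#' and status `NS`, flagged in the `converged` column.
#'
#' @param counts count matrix tibble.
#' @param samples sample table.
#' @param contrast a [contrast()] (or `"A_vs_B"` string).
#' @param size_factors,dispersions optional precomputed results; estimated
#'   from all samples when `NULL`.
#' @param lfc_threshold,fdr_threshold significance rules: status `UP` when
#'   `log2fc >= lfc_threshold` and `fdr < fdr_threshold`, `DOWN` when
#'   `log2fc <= -lfc_threshold` and `fdr < fdr_threshold`, else `NS`.
#'   Defaults are the gene-level rules (|log2FC| >= 1, FDR < 0.05).
#' @param max_iter IRLS iteration cap.
#' @return A `contrast_result` tibble with columns `feature_id`, `log2fc`,
#'   `se`, `pvalue`, `fdr`, `status`, `converged`, and attributes `contrast`,
#'   `layer = "RNA"`, `n_excluded` (all-zero genes).
#' @export
nb_wald_contrast <- function(counts, samples, contrast,
                             size_factors = NULL, dispersions = NULL,
                             lfc_threshold = 1, fdr_threshold = 0.05,
                             max_iter = 100L) {
  contrast <- as_contrast(contrast)
  assert_samples_in_table(counts, samples)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, samples, size_factors)
  }
  m <- as_feature_matrix(counts)
  num_ids <- group_samples(samples, contrast$numerator, colnames(m))
  den_ids <- group_samples(samples, contrast$denominator, colnames(m))
  if (length(num_ids) < 2L || length(den_ids) < 2L) {
    stop_input("both contrast groups need >=2 samples")
  }
  cols <- c(den_ids, num_ids)
  y <- m[, cols, drop = FALSE]
  tested <- rowSums(y) > 0
  n_excluded <- sum(!tested)
  y <- y[tested, , drop = FALSE]
  alpha <- dispersions$disp_final[match(rownames(y), dispersions$feature_id)]
  sf <- size_factors$size_factor[match(cols, size_factors$sample_id)]
  x <- c(rep(0, length(den_ids)), rep(1, length(num_ids)))

  fit <- nb_irls_two_group(y, sf, x, alpha, max_iter = max_iter)
  log2fc <- fit$b1 / log(2)
  se <- fit$se / log(2)
  z <- fit$b1 / fit$se
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[!fit$converged] <- NA_real_

  res <- tibble(
    feature_id = rownames(y),
    log2fc = log2fc,
    se = se,
    pvalue = pvalue,
    fdr = NA_real_,
    converged = fit$converged
  )
  ok <- !is.na(res$pvalue)
  res$fdr[ok] <- benjamini_hochberg(res$pvalue[ok])
  res$status <- assign_status(res$log2fc, res$fdr, lfc_threshold, fdr_threshold)
  res <- res[, c("feature_id", "log2fc", "se", "pvalue", "fdr", "status",
                 "converged")]
  new_contrast_result(res, contrast, layer = "RNA",
                      lfc_threshold = lfc_threshold,
                      fdr_threshold = fdr_threshold,
                      n_excluded = n_excluded)
}

assign_status <- function(log2fc, fdr, lfc_threshold, fdr_threshold) {
  status <- rep("NS", length(log2fc))
  sig <- !is.na(fdr) & fdr < fdr_threshold
  status[sig & log2fc >= lfc_threshold] <- "UP"
  status[sig & log2fc <= -lfc_threshold] <- "DOWN"
  status
}

new_contrast_result <- function(df, contrast, layer, lfc_threshold,
                                fdr_threshold, ...) {
  out <- as_tibble(df)
  attr(out, "contrast") <- contrast
  attr(out, "layer") <- layer
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("contrast_result", class(out))
  out
}

# Vectorised two-group NB IRLS across genes, fitted on size-factor-normalised
# counts q = y/s (so every estimate is a pure function of q, making log2FC
# exactly invariant to rescaling any one sample's counts). x: 0/1 group
# indicator per sample; alpha: per-gene dispersion. With the saturated
# two-group design the IRLS fixed point is the normalised group mean; the SE
# of the group coefficient comes from the weighted information with NB
# weights w = mu / (1 + alpha * mu). Returns intercept/coefficient, SE and a
# convergence flag; genes empty in one group drift without converging and
# are flagged.
nb_irls_two_group <- function(y, sf, x, alpha, max_iter = 100L, tol = 1e-8) {
  G <- nrow(y); n <- ncol(y)
  q <- sweep(y, 2L, sf, "/")
  den <- x == 0; num <- x == 1
  mu_den <- rowMeans(q[, den, drop = FALSE])
  mu_num <- rowMeans(q[, num, drop = FALSE])
  b0 <- log(pmax(mu_den, 1e-8))
  b1 <- log(pmax(mu_num, 1e-8)) - b0
  active <- rep(TRUE, G)
  converged <- rep(FALSE, G)
  xmat <- matrix(x, G, n, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(b0 + b1 * xmat, -50), 50)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    zz <- eta + (q - mu) / mu
    sw <- rowSums(w); swx <- rowSums(w * xmat)
    swz <- rowSums(w * zz); swxz <- rowSums(w * xmat * zz)
    det <- sw * swx - swx^2
    det[det <= 0] <- NA_real_
    b0_new <- (swx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    bad <- is.na(b0_new) | is.na(b1_new)
    b0_new[bad] <- b0[bad]; b1_new[bad] <- b1[bad]
    delta <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    b0[active] <- b0_new[active]
    b1[active] <- b1_new[active]
    newly <- active & !bad & delta < tol
    converged[newly] <- TRUE
    active <- active & !newly
    if (!any(active)) break
  }
  eta <- pmin(pmax(b0 + b1 * xmat, -50), 50)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  sw <- rowSums(w); swx <- rowSums(w * xmat)
  det <- pmax(sw * swx - swx^2, 1e-300)
  se <- sqrt(sw / det)
  list(b0 = unname(b0), b1 = unname(b1), se = unname(se),
       converged = unname(converged))
}
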