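# Exploratory views: sample-space PCA and z-score hierarchical clustering
# orderings for heatmaps.

#' Principal component analysis of a feature-by-sample matrix
#'
#' Samples are the observations. Features are centred; by default they are
#' not unit-scaled, because on log-transformed abundance data the per-feature
#' variance is itself meaningful (scaling can be switched on). Constant
#' features are dropped with a warning. With `log_mode = TRUE` the matrix is
#' transformed as `log2(x + 1)` first (for counts).
#'
#' @param x matrix tibble (`feature_id` + sample columns).
#' @param log_mode apply `log2(x + 1)` before centring.
#' @param scale. unit-scale features.
#' @return An object of class `omics_pca`: a list with `scores` (tibble,
#'   one row per sample), `loadings`, `variance_explained_pct`, `n_features`.
#' @export
run_pca <- function(x, log_mode = FALSE, scale. = FALSE) {
  m <- as_feature_matrix(x)
  if (ncol(m) < 2L) stop_input("PCA needs at least 2 samples")
  if (log_mode) m <- log2(m + 1)
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " constant feature(s) before PCA"))
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop_input("no non-constant features left for PCA")
  pc <- prcomp(t(m), center = TRUE, scale. = scale.)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(
    tibble(sample_id = colnames(m)),
    as_tibble(pc$x, .name_repair = "minimal")
  )
  structure(
    list(
      scores = scores,
      loadings = pc$rotation,
      variance_explained_pct = ve,
      n_features = nrow(m)
    ),
    class = "omics_pca"
  )
}

#' @export
print.omics_pca <- function(x, ...) {
  ve <- x$variance_explained_pct
  cat("<omics_pca> ", nrow(x$scores), " samples, ", x$n_features,
      " features\n", sep = "")
  cat("  PC1 = ", round(ve[1], 1), "%",
      if (length(ve) > 1) paste0(", PC2 = ", round(ve[2], 1), "%"),
      ", PC1+PC2 = ",
      round(sum(ve[seq_len(min(2, length(ve)))]), 1), "%\n", sep = "")
  invisible(x)
}

#' Z-score the rows of a matrix tibble
#'
#' Per feature: subtract the mean and divide by the standard deviation over
#' samples. Zero-variance features become rows of zeros (flagged with a
#' warning), matching the convention used for heatmap display.
#'
#' @param x matrix tibble.
#' @return A tibble of the same shape with standardised values.
#' @export
zscore_rows <- function(x) {
  m <- as_feature_matrix(x)
  mu <- rowMeans(m)
  sds <- apply(m, 1L, sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(paste0(sum(flat), " zero-variance feature(s) z-scored to 0"))
  }
  sds[flat] <- 1
  z <- (m - mu) / sds
  out <- as_matrix_tibble(z)
  names(out)[1] <- "feature_id"
  out
}

#' Row and column orderings for a clustered heatmap
#'
#' Rows are z-scored, then rows and columns are clustered agglomeratively on
#' Euclidean distance with the chosen linkage; leaf orders are returned for
#' heatmap display. `stats::hclust` resolves ties deterministically by input
#' order, so the result is reproducible.
#'
#' @param x matrix tibble.
#' @param linkage `"average"` or `"complete"`.
#' @return A list with `row_order` and `col_order` (integer index vectors),
#'   plus the two `hclust` objects.
#' @export
cluster_heatmap_order <- function(x, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  z <- as_feature_matrix(suppressWarnings(zscore_rows(x)))
  if (nrow(z) < 2L || ncol(z) < 2L) stop_input("need >=2 rows and columns")
  hr <- hclust(dist(z), method = linkage)
  hc <- hclust(dist(t(z)), method = linkage)
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}

#' PCA of methylation proportions on the logit scale
#'
#' Convenience wrapper: per-CpG methylation proportions (pooled per sample
#' from a methylation tibble) are logit-transformed with a 0.01 squeeze and
#' passed to [run_pca()].
#'
#' @param mt methylation tibble.
#' @return An `omics_pca` object.
#' @export
pca_methylation <- function(mt) {
  ids <- meth_sample_ids(mt)
  m <- meth_counts(mt, ids, "meth")
  t <- meth_counts(mt, ids, "total")
  p <- (m + 0.01) / (t + 0.02)
  lo <- log(p / (1 - p))
  colnames(lo) <- ids
  df <- as_matrix_tibble(lo)
  df$feature_id <- paste(mt$chrom, mt$pos, sep = ":")
  run_pca(df)
}
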