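# broom-style accessors for the package's result objects.

#' Tidy a contrast result
#'
#' Returns the per-feature table as a plain tibble (drops the result class
#' and attributes).
#'
#' @param x a `contrast_result`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.contrast_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "contrast_result")
  attr(out, "contrast") <- NULL
  as_tibble(out)
}

#' One-row summary of a contrast result
#'
#' @param x a `contrast_result`.
#' @param ... unused.
#' @return A tibble with the contrast name, layer, feature counts and the
#'   number of significant features in each direction.
#' @export
glance.contrast_result <- function(x, ...) {
  ctr <- attr(x, "contrast")
  tibble(
    contrast = if (!is.null(ctr)) ctr$name else NA_character_,
    layer = attr(x, "layer") %||% NA_character_,
    n_tested = sum(!is.na(x$pvalue)),
    n_up = sum(x$status == "UP"),
    n_down = sum(x$status == "DOWN"),
    lfc_threshold = attr(x, "lfc_threshold") %||% NA_real_,
    fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_
  )
}

#' @rdname tidy.contrast_result
#' @export
tidy.paired_contrast <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "paired_contrast")
  attr(out, "contrast") <- NULL
  as_tibble(out)
}

#' One-row concordance summary of a paired contrast
#'
#' Equivalent to [summarize_concordance()].
#'
#' @param x a `paired_contrast`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.paired_contrast <- function(x, ...) {
  summarize_concordance(x)
}

#' Tidy PCA scores
#'
#' @param x an `omics_pca`.
#' @param ... unused.
#' @return The score tibble, one row per sample.
#' @export
tidy.omics_pca <- function(x, ...) {
  x$scores
}

#' Per-component variance summary of a PCA
#'
#' @param x an `omics_pca`.
#' @param ... unused.
#' @return A tibble with `component` and `variance_explained_pct`.
#' @export
glance.omics_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$variance_explained_pct),
    variance_explained_pct = x$variance_explained_pct
  )
}
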