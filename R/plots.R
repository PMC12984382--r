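# ggplot2 views of the result objects. Aesthetic parity with any particular
# publication figure is out of scope; these are working plots.

PAIR_CLASS_COLOURS <- c(
  CONCORDANT_UP = "#c0392b", CONCORDANT_DOWN = "#2e6da4",
  DISCORDANT = "#27ae60", RNA_EXCLUSIVE = "#8e44ad",
  PROTEIN_EXCLUSIVE = "#e67e22", NS = "grey70"
)

#' Volcano plot of a contrast result
#'
#' @param object a `contrast_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.contrast_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$pvalue), ]
  ctr <- attr(object, "contrast")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$pvalue),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(UP = "#c0392b", DOWN = "#2e6da4", NS = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = if (!is.null(ctr)) ctr$name,
                  subtitle = attr(object, "layer")) +
    ggplot2::theme_minimal()
}

#' RNA-protein fold-change scatter of a paired contrast
#'
#' One point per mapped gene-protein pair, coloured by regulatory-pattern
#' class.
#'
#' @param object a `paired_contrast`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.paired_contrast <- function(object, ...) {
  ctr <- attr(object, "contrast")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rna_log2fc, y = .data$prot_log2fc,
                               colour = .data$pair_class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = PAIR_CLASS_COLOURS) +
    ggplot2::labs(x = "RNA log2 fold change", y = "protein log2 fold change",
                  title = if (!is.null(ctr)) ctr$name) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object an `omics_pca`.
#' @param samples optional sample table used to colour points by group.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.omics_pca <- function(object, samples = NULL, ...) {
  df <- object$scores
  if (!is.null(samples)) {
    df <- dplyr::left_join(df, samples, by = "sample_id")
  }
  ve <- object$variance_explained_pct
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(samples)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Terms against rich factor, sized by count and coloured by -log10 adjusted
#' p, faceted by direction (and layer when present).
#'
#' @param enr enrichment tibble from [ordered_query_enrichment()] or
#'   [hypergeometric_ora()].
#' @param top show at most this many terms per facet (by p-value).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enr, top = 15L) {
  group_cols <- intersect(c("direction", "layer"), names(enr))
  df <- enr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::slice_min(.data$pvalue, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rich_factor,
    y = stats::reorder(.data$term_name, .data$rich_factor),
    size = .data$count, colour = -log10(.data$adjusted_p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rich factor", y = NULL,
                  colour = "-log10 adj. p", size = "count") +
    ggplot2::theme_minimal()
  if (length(group_cols) > 0L) {
    p <- p + ggplot2::facet_wrap(group_cols, scales = "free_y")
  }
  p
}
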