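# RNA-protein integration: mapped gene-protein pairs per contrast, the
# six-category regulatory-pattern classification, and concordance /
# correlation summaries. This is the analytical core of the package.

PAIR_CLASSES <- c("CONCORDANT_UP", "CONCORDANT_DOWN", "DISCORDANT",
                  "RNA_EXCLUSIVE", "PROTEIN_EXCLUSIVE", "NS")

#' Build mapped gene-protein pairs for one contrast
#'
#' One row per protein that was tested at the protein level in this contrast
#' and whose mapped gene was tested at the RNA level. Genes carrying several
#' proteins contribute one row per protein (no collapsing by default): the
#' pair universe is contrast-specific because testability differs between
#' contrasts. With `collapse = TRUE` each gene keeps a single representative
#' protein, the one with the largest mean log2 intensity (requires the
#' normalised intensity tibble in `intensities`).
#'
#' @param deg RNA `contrast_result` (from [nb_wald_contrast()]).
#' @param dep protein `contrast_result` (from [moderated_t_contrast()]).
#' @param map gene-protein map tibble (`protein_id`, `gene_id`).
#' @param collapse collapse many-to-one proteins to one representative per
#'   gene.
#' @param intensities normalised intensity tibble, needed when
#'   `collapse = TRUE`.
#' @return A `paired_contrast` tibble with columns `gene_id`, `protein_id`,
#'   `rna_log2fc`, `rna_pvalue`, `rna_fdr`, `rna_status`, `prot_log2fc`,
#'   `prot_pvalue`, `prot_fdr`, `prot_status`, `pair_class`; attribute
#'   `contrast`.
#' @export
build_pairs <- function(deg, dep, map, collapse = FALSE, intensities = NULL) {
  ctr_rna <- attr(deg, "contrast"); ctr_prot <- attr(dep, "contrast")
  if (!is.null(ctr_rna) && !is.null(ctr_prot) &&
      !identical(ctr_rna$name, ctr_prot$name)) {
    stop_input("RNA and protein results come from different contrasts: ",
               ctr_rna$name, " vs ", ctr_prot$name)
  }
  rna <- tibble(
    gene_id = deg$feature_id,
    rna_log2fc = deg$log2fc, rna_pvalue = deg$pvalue,
    rna_fdr = deg$fdr, rna_status = deg$status
  ) |>
    dplyr::filter(!is.na(.data$rna_pvalue))
  prot <- tibble(
    protein_id = dep$feature_id,
    prot_log2fc = dep$log2fc, prot_pvalue = dep$pvalue,
    prot_fdr = dep$fdr, prot_status = dep$status
  )
  pairs <- map |>
    dplyr::inner_join(prot, by = "protein_id") |>
    dplyr::inner_join(rna, by = "gene_id")
  if (collapse && nrow(pairs) > 0L) {
    if (is.null(intensities)) {
      stop_input("collapse = TRUE needs the intensity tibble to pick a representative")
    }
    im <- as_feature_matrix(intensities)
    mean_int <- rowMeans(im, na.rm = TRUE)
    pairs$mean_intensity <- mean_int[match(pairs$protein_id, rownames(im))]
    pairs <- pairs |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::arrange(dplyr::desc(.data$mean_intensity), .data$protein_id,
                     .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::select(-"mean_intensity")
  }
  if (nrow(pairs) == 0L) {
    warn("no mapped gene-protein pairs for this contrast")
  }
  pairs$pair_class <- classify_pair(pairs$rna_status, pairs$rna_log2fc,
                                    pairs$prot_status, pairs$prot_log2fc)
  pairs <- pairs[, c("gene_id", "protein_id",
                     "rna_log2fc", "rna_pvalue", "rna_fdr", "rna_status",
                     "prot_log2fc", "prot_pvalue", "prot_fdr", "prot_status",
                     "pair_class")]
  out <- as_tibble(pairs)
  attr(out, "contrast") <- ctr_rna %||% ctr_prot
  class(out) <- c("paired_contrast", class(out))
  out
}

#' Classify a gene-protein pair into its regulatory pattern
#'
#' Six mutually exclusive classes: pairs significant at both layers with
#' matching fold-change sign are `CONCORDANT_UP`/`CONCORDANT_DOWN`; both
#' significant with opposite signs is `DISCORDANT`; significance at exactly
#' one layer gives `RNA_EXCLUSIVE` or `PROTEIN_EXCLUSIVE`; neither significant
#' is `NS`. Concordance requires significance at both layers, the strict
#' reading of the scatter-plot legend convention.
#'
#' @param rna_status,prot_status status vectors (`"UP"`, `"DOWN"`, `"NS"`).
#' @param rna_log2fc,prot_log2fc fold-change vectors; a status whose sign
#'   contradicts its fold change is an upstream bug and raises an error.
#' @return Character vector of pair classes.
#' @examples
#' classify_pair("UP", 2, "UP", 1)     # CONCORDANT_UP
#' classify_pair("UP", 2, "DOWN", -1)  # DISCORDANT
#' @export
classify_pair <- function(rna_status, rna_log2fc, prot_status, prot_log2fc) {
  check_status_sign <- function(status, lfc, layer) {
    bad <- (status == "UP" & lfc < 0) | (status == "DOWN" & lfc > 0)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      stop_input(layer, " status contradicts the sign of log2fc at index ",
                 which(bad)[1])
    }
  }
  check_status_sign(rna_status, rna_log2fc, "RNA")
  check_status_sign(prot_status, prot_log2fc, "protein")
  rna_sig <- rna_status != "NS"
  prot_sig <- prot_status != "NS"
  dplyr::case_when(
    !rna_sig & !prot_sig ~ "NS",
    rna_sig & !prot_sig ~ "RNA_EXCLUSIVE",
    !rna_sig & prot_sig ~ "PROTEIN_EXCLUSIVE",
    rna_status == prot_status & rna_status == "UP" ~ "CONCORDANT_UP",
    rna_status == prot_status & rna_status == "DOWN" ~ "CONCORDANT_DOWN",
    TRUE ~ "DISCORDANT"
  )
}

#' Round a concordance percentage for reporting
#'
#' One decimal place, except two decimals below 0.1% so that very small but
#' nonzero fractions do not round to zero (e.g. 1 of 1228 pairs prints as
#' 0.08, not 0.1 or 0.0).
#'
#' @param n_concordant,n_pairs counts.
#' @return The rounded percentage (numeric).
#' @examples
#' concordance_pct(161, 867)  # 18.6
#' concordance_pct(1, 1228)   # 0.08
#' @export
concordance_pct <- function(n_concordant, n_pairs) {
  pct <- 100 * n_concordant / n_pairs
  ifelse(pct < 0.1, round(pct, 2), round(pct, 1))
}

#' Pearson and Spearman correlation of two fold-change vectors
#'
#' Product-moment correlation plus Spearman's rho computed as Pearson on
#' mid-ranks (average ranks on ties). Either coefficient is `NA` when its
#' input has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2, no missing values.
#' @return A one-row tibble with `pearson_r` and `spearman_rho`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_input("missing values are not allowed")
  if (length(x) < 2L) {
    return(tibble(pearson_r = NA_real_, spearman_rho = NA_real_))
  }
  safe_cor <- function(a, b, method) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = method)
  }
  tibble(
    pearson_r = safe_cor(x, y, "pearson"),
    spearman_rho = safe_cor(x, y, "spearman")
  )
}

#' Summarise concordance for a paired contrast
#'
#' Counts concordant pairs (both directions), the concordance percentage
#' (see [concordance_pct()] for the reporting rounding; the unrounded value
#' is also returned), and Pearson/Spearman correlations of the RNA and
#' protein log2 fold changes over all pairs, significant or not.
#'
#' @param pairs a `paired_contrast` tibble from [build_pairs()].
#' @return A one-row tibble with `contrast`, `n_pairs`, `n_concordant`,
#'   `concordance_pct` (reporting-rounded), `concordance_pct_raw`,
#'   `pearson_r`, `spearman_rho`, plus the six per-class counts.
#' @export
summarize_concordance <- function(pairs) {
  ctr <- attr(pairs, "contrast")
  n_pairs <- nrow(pairs)
  counts <- vapply(PAIR_CLASSES, function(cl) sum(pairs$pair_class == cl), 0L)
  n_conc <- counts[["CONCORDANT_UP"]] + counts[["CONCORDANT_DOWN"]]
  if (n_pairs >= 2L) {
    cc <- correlate(pairs$rna_log2fc, pairs$prot_log2fc)
  } else {
    cc <- tibble(pearson_r = NA_real_, spearman_rho = NA_real_)
  }
  out <- tibble(
    contrast = if (!is.null(ctr)) ctr$name else NA_character_,
    n_pairs = n_pairs,
    n_concordant = n_conc,
    concordance_pct = if (n_pairs > 0) concordance_pct(n_conc, n_pairs) else NA_real_,
    concordance_pct_raw = if (n_pairs > 0) 100 * n_conc / n_pairs else NA_real_,
    pearson_r = cc$pearson_r,
    spearman_rho = cc$spearman_rho
  )
  dplyr::bind_cols(out, as_tibble(as.list(counts)))
}
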