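# Functional enrichment on gene/protein lists: classical over-representation
# and a ranked-list scheme that scans nested prefixes of a fold-change
# ordering, with a Bonferroni correction over prefixes and BH over terms.

# upper-tail hypergeometric: P(X >= k) drawing n from universe N with K
# successes
hypergeom_upper_p <- function(k, n, K, N) {
  ifelse(k <= 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

prepare_terms <- function(terms, universe) {
  terms |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::group_by(.data$term_id) |>
    dplyr::mutate(term_size = dplyr::n()) |>
    dplyr::ungroup()
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, an upper-tail hypergeometric p-value for the
#' overlap between the query set and the term's members, both intersected
#' with the analysis universe (all features tested in the relevant layer and
#' contrast, not the genome — using the tested universe avoids spurious
#' enrichment from detection bias). BH adjustment runs within each namespace.
#' The rich factor is the fraction of the term's (universe-restricted)
#' members found in the query.
#'
#' @param query character vector of feature ids; must be a subset of
#'   `universe`.
#' @param universe character vector of all tested feature ids.
#' @param terms annotation tibble from [read_annotations()].
#' @return A tibble with `term_id`, `term_name`, `namespace`, `count`,
#'   `term_size`, `rich_factor`, `pvalue`, `adjusted_p`, sorted by p-value.
#' @export
hypergeometric_ora <- function(query, universe, terms) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe)) > 0L) {
    stop_input("query contains features outside the universe")
  }
  if (length(query) == 0L) {
    return(tibble(term_id = character(), term_name = character(),
                  namespace = character(), count = integer(),
                  term_size = integer(), rich_factor = numeric(),
                  pvalue = numeric(), adjusted_p = numeric()))
  }
  tt <- prepare_terms(terms, universe)
  res <- tt |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$namespace,
                    .data$term_size) |>
    dplyr::summarise(count = sum(.data$gene_id %in% query), .groups = "drop") |>
    dplyr::mutate(
      rich_factor = .data$count / .data$term_size,
      pvalue = hypergeom_upper_p(.data$count, length(query),
                                 .data$term_size, length(universe))
    ) |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(adjusted_p = benjamini_hochberg(.data$pvalue)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$pvalue) |>
    dplyr::select("term_id", "term_name", "namespace", "count", "term_size",
                  "rich_factor", "pvalue", "adjusted_p")
  res
}

#' Ranked-list (ordered-query) enrichment
#'
#' Features are ordered by log2 fold change (descending for `direction =
#' "up"`, ascending for `"down"`); each term's hypergeometric p-value is
#' evaluated at nested prefix cutoffs (10, 20, ... up to
#' `min(length, max_prefix)`, plus the significance-threshold prefix when
#' `de_cutoff` is given), and the minimum over prefixes is Bonferroni-scaled
#' by the number of prefixes evaluated, clipped at 1. BH then runs across
#' terms. `count` and `rich_factor` are reported at the best prefix.
#'
#' @param ranked tibble with columns `feature_id` and `log2fc` (a
#'   `contrast_result` works directly), or a pre-ordered character vector.
#' @param universe all tested feature ids.
#' @param terms annotation tibble.
#' @param direction `"up"` or `"down"`.
#' @param prefix_step,max_prefix the prefix grid (defaults 10 and 1000).
#' @param de_cutoff optional extra prefix length, e.g. the number of
#'   threshold-significant features.
#' @return A tibble like [hypergeometric_ora()], plus `direction` and
#'   `best_prefix` columns.
#' @export
ordered_query_enrichment <- function(ranked, universe, terms,
                                     direction = c("up", "down"),
                                     prefix_step = 10L, max_prefix = 1000L,
                                     de_cutoff = NULL) {
  direction <- match.arg(direction)
  if (is.data.frame(ranked)) {
    ord <- order(ranked$log2fc, decreasing = (direction == "up"))
    ranked_ids <- ranked$feature_id[ord]
  } else {
    ranked_ids <- as.character(ranked)
    if (direction == "down") ranked_ids <- rev(ranked_ids)
  }
  ranked_ids <- ranked_ids[!duplicated(ranked_ids)]
  universe <- unique(universe)
  if (length(setdiff(ranked_ids, universe)) > 0L) {
    stop_input("ranked list contains features outside the universe")
  }
  L <- length(ranked_ids)
  top <- min(L, max_prefix)
  prefixes <- if (top >= prefix_step) {
    seq.int(prefix_step, top, by = prefix_step)
  } else {
    L
  }
  if (!is.null(de_cutoff) && de_cutoff >= 1L && de_cutoff <= L) {
    prefixes <- sort(unique(c(prefixes, as.integer(de_cutoff))))
  }
  n_prefix <- length(prefixes)
  N <- length(universe)

  tt <- prepare_terms(terms, universe)
  term_members <- split(tt$gene_id, tt$term_id)
  term_info <- tt |> dplyr::distinct(.data$term_id, .data$term_name,
                                     .data$namespace, .data$term_size)
  rank_of <- setNames(seq_len(L), ranked_ids)

  res <- purrr::map_dfr(term_info$term_id, function(tid) {
    members <- term_members[[tid]]
    K <- length(members)
    r <- sort(rank_of[members[members %in% ranked_ids]])
    k_at <- vapply(prefixes, function(p) sum(r <= p), 0L)
    p_at <- hypergeom_upper_p(k_at, prefixes, K, N)
    best <- which.min(p_at)
    tibble(term_id = tid, count = k_at[best],
           best_prefix = prefixes[best],
           pvalue = min(1, p_at[best] * n_prefix))
  })
  res <- res |>
    dplyr::left_join(term_info, by = "term_id") |>
    dplyr::mutate(rich_factor = .data$count / .data$term_size,
                  direction = direction,
                  adjusted_p = benjamini_hochberg(.data$pvalue)) |>
    dplyr::arrange(.data$pvalue) |>
    dplyr::select("term_id", "term_name", "namespace", "direction", "count",
                  "term_size", "best_prefix", "rich_factor", "pvalue",
                  "adjusted_p")
  res
}

#' Terms enriched in the same direction at both omic layers
#'
#' Intersects RNA-level and protein-level enrichment results from the same
#' contrast: a term is concordant when its adjusted p-value is below `alpha`
#' at both layers with equal direction.
#'
#' @param rna,prot enrichment tibbles carrying a `direction` column (combine
#'   up and down runs with `dplyr::bind_rows()` first).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return A tibble of concordant terms with per-layer statistics and a
#'   `direction` column.
#' @export
concordant_terms <- function(rna, prot, alpha = 0.05) {
  sig_rna <- rna |> dplyr::filter(.data$adjusted_p < alpha)
  sig_prot <- prot |> dplyr::filter(.data$adjusted_p < alpha)
  dplyr::inner_join(
    sig_rna |> dplyr::select("term_id", "term_name", "namespace", "direction",
                             rna_pvalue = "pvalue", rna_adjusted_p = "adjusted_p"),
    sig_prot |> dplyr::select("term_id", "direction",
                              prot_pvalue = "pvalue",
                              prot_adjusted_p = "adjusted_p"),
    by = c("term_id", "direction")
  )
}
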