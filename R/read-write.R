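# Readers and writers for the plain-text formats the pipeline touches:
# TSV feature-by-sample matrices, the gene-protein correspondence file, and
# GMT annotation collections. All validation is done here so downstream code
# can assume clean inputs.

MISSING_TOKENS <- c("", "na")

#' Read a feature-by-sample matrix from TSV
#'
#' The file must have a header row naming the samples, with the first column
#' holding feature identifiers. For `kind = "intensities"` the optional
#' columns `unique_peptides` (integer) and `is_contaminant` (logical) are
#' recognised, and empty cells or `NA` (case-insensitive) denote missing
#' values; a literal `0` intensity is rejected because label-free
#' quantification intensities are strictly positive where observed, and
#' conflating dropout with zero hides the distinction. For `kind = "counts"`
#' all cells must be non-negative integers.
#'
#' @param path TSV file path.
#' @param kind `"counts"` for integer read counts, `"intensities"` for
#'   positive real label-free intensities with missing values allowed.
#' @return A tibble with `feature_id` first, then one numeric column per
#'   sample (plus `unique_peptides`/`is_contaminant` when present).
#' @export
read_matrix <- function(path, kind = c("counts", "intensities")) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  if (ncol(raw) < 2L) stop_input("matrix file needs a feature column and >=1 sample")
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) {
    stop_input("duplicate feature_id: ",
               paste(unique(raw$feature_id[duplicated(raw$feature_id)]),
                     collapse = ", "))
  }
  meta_cols <- intersect(c("unique_peptides", "is_contaminant"), names(raw))
  value_cols <- setdiff(names(raw), c("feature_id", meta_cols))

  parse_col <- function(x, col) {
    is_missing <- tolower(x) %in% MISSING_TOKENS
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is_missing & is.na(v))
    if (length(bad) > 0L) {
      stop_input("non-numeric cell at feature '", raw$feature_id[bad[1]],
                 "', sample '", col, "': '", x[bad[1]], "'")
    }
    v[is_missing] <- NA_real_
    if (kind == "counts") {
      if (anyNA(v)) {
        stop_input("missing cell not allowed in a count matrix (feature '",
                   raw$feature_id[which(is.na(v))[1]], "', sample '", col, "')")
      }
      if (any(v < 0)) {
        stop_input("negative count at feature '",
                   raw$feature_id[which(v < 0)[1]], "', sample '", col, "'")
      }
      if (any(v != round(v))) {
        stop_input("non-integer count at feature '",
                   raw$feature_id[which(v != round(v))[1]], "', sample '", col, "'")
      }
    } else {
      nonpos <- which(!is.na(v) & v <= 0)
      if (length(nonpos) > 0L) {
        stop_input("non-positive intensity at feature '",
                   raw$feature_id[nonpos[1]], "', sample '", col,
                   "': observed LFQ intensities must be > 0 (use NA for missing)")
      }
    }
    v
  }

  out <- tibble(feature_id = raw$feature_id)
  for (col in value_cols) out[[col]] <- parse_col(raw[[col]], col)
  if ("unique_peptides" %in% meta_cols) {
    up <- suppressWarnings(as.integer(raw$unique_peptides))
    if (anyNA(up) || any(up < 0)) stop_input("unique_peptides must be integers >= 0")
    out$unique_peptides <- up
  }
  if ("is_contaminant" %in% meta_cols) {
    ic <- tolower(raw$is_contaminant) %in% c("true", "t", "1", "yes")
    out$is_contaminant <- ic
  }
  out
}

#' Write a feature-by-sample matrix to canonical TSV
#'
#' Rows are sorted by `feature_id` and numbers written in a fixed format so
#' that `write_matrix(read_matrix(path))` is byte-identical for canonical
#' files.
#'
#' @param df matrix tibble as returned by [read_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(df, path) {
  df <- dplyr::arrange(df, .data$feature_id)
  out <- df
  for (col in sample_cols(df)) {
    v <- fmt_num(df[[col]])
    v[is.na(df[[col]])] <- "NA"
    out[[col]] <- v
  }
  if ("is_contaminant" %in% names(out)) {
    out$is_contaminant <- ifelse(out$is_contaminant, "TRUE", "FALSE")
  }
  lines <- c(
    paste(names(out), collapse = "\t"),
    do.call(paste, c(as.list(out), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-protein correspondence file
#'
#' A two-column TSV (`protein_id`, `gene_id`); a header line is auto-detected
#' (a first line repeated nowhere else whose fields look like column labels is
#' treated as data unless named `protein_id`/`gene_id`). Each protein must map
#' to exactly one gene; genes may carry several proteins.
#'
#' @param path TSV file path.
#' @return A tibble with columns `protein_id` and `gene_id`.
#' @export
read_gene_protein_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warn("empty gene-protein map")
    return(tibble(protein_id = character(), gene_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop_input("gene-protein map line ", which(lengths(fields) != 2L)[1],
               " does not have exactly 2 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  # header auto-detection: explicit labels, or a first row whose entries never
  # reappear as identifiers in the data rows
  has_header <- identical(tolower(m[1, ]), c("protein_id", "gene_id")) ||
    (nrow(m) > 1L && !m[1, 1] %in% m[-1, 1] && !m[1, 2] %in% m[-1, 2] &&
       grepl("^[A-Za-z_]+$", m[1, 1]) && grepl("^[A-Za-z_]+$", m[1, 2]) &&
       tolower(m[1, 1]) %in% c("protein", "protein_id", "prot") &&
       tolower(m[1, 2]) %in% c("gene", "gene_id"))
  if (has_header) m <- m[-1, , drop = FALSE]
  map <- tibble(protein_id = m[, 1], gene_id = m[, 2])
  dup <- unique(map$protein_id[duplicated(map$protein_id)])
  if (length(dup) > 0L) {
    conflicting <- map |>
      dplyr::filter(.data$protein_id %in% dup) |>
      dplyr::distinct() |>
      dplyr::count(.data$protein_id) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(conflicting) > 0L) {
      stop_input("protein_id mapped to multiple genes: ",
                 paste(conflicting$protein_id, collapse = ", "))
    }
    map <- dplyr::distinct(map)
  }
  if (nrow(map) == 0L) warn("empty gene-protein map")
  map
}

#' Read a GMT annotation file
#'
#' Each line is `term_id TAB term_name TAB member TAB member ...`. Members are
#' de-duplicated within a term. The namespace (BP/MF/CC/KEGG) is inferred from
#' the term identifier prefix (`GO:BP:`/`BP:` style prefixes or a leading
#' `KEGG`/`ko`/`map`); anything unrecognised defaults to BP.
#'
#' @param path GMT file path.
#' @return A long tibble with one row per (term, member): columns `term_id`,
#'   `term_name`, `namespace`, `gene_id`, plus `term_size` and a `singleton`
#'   flag on size-1 terms.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_input("GMT line ", short[1], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_input("duplicate term_id in GMT: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- purrr::map(fields, function(f) {
    members <- unique(f[-(1:2)])
    tibble(term_id = f[1], term_name = f[2], gene_id = members)
  })
  ann <- dplyr::bind_rows(rows) |>
    dplyr::mutate(namespace = infer_namespace(.data$term_id)) |>
    dplyr::group_by(.data$term_id) |>
    dplyr::mutate(term_size = dplyr::n(), singleton = dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select("term_id", "term_name", "namespace", "gene_id",
                  "term_size", "singleton")
  ann
}

infer_namespace <- function(term_id) {
  up <- toupper(term_id)
  dplyr::case_when(
    grepl("^(GO:)?MF", up) ~ "MF",
    grepl("^(GO:)?CC", up) ~ "CC",
    grepl("^(KEGG|KO\\d|MAP\\d|PATH)", up) ~ "KEGG",
    TRUE ~ "BP"
  )
}

#' Write an annotation tibble back to GMT
#' @param ann tibble as returned by [read_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  lines <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(line = paste(.data$gene_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$term_id)
  writeLines(paste(lines$term_id, lines$term_name, lines$line, sep = "\t"),
             path)
  invisible(path)
}

#' Validate that every matrix sample is described in the sample table
#'
#' @param df matrix tibble.
#' @param samples sample table (see [sample_table()]).
#' @return `df`, invisibly; errors if any matrix column lacks metadata.
#' @export
validate_matrix_samples <- function(df, samples) {
  assert_samples_in_table(df, samples)
}
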