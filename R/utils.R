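# Internal helpers shared across modules. Feature matrices travel through the
# package as wide tibbles (feature_id + one numeric column per sample); these
# helpers convert to/from base matrices for numerics.

GROUP_LEVELS <- c("F1F", "F1M", "wtF", "wtM")

# columns of a matrix tibble that are not samples
NON_SAMPLE_COLS <- c("feature_id", "unique_peptides", "is_contaminant")

sample_cols <- function(df) {
  setdiff(names(df), NON_SAMPLE_COLS)
}

#' Convert a matrix tibble to a base numeric matrix
#'
#' @param df tibble with a `feature_id` column and one numeric column per
#'   sample (extra protein metadata columns are dropped).
#' @return numeric matrix, features in rows, samples in columns.
#' @keywords internal
#' @noRd
as_feature_matrix <- function(df) {
  cols <- sample_cols(df)
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  m
}

as_matrix_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dplyr::bind_cols(tibble(feature_id = ids), out)
}

stop_input <- function(...) {
  abort(paste0(...), class = "omicsconcord_input_error")
}

assert_samples_in_table <- function(df, samples) {
  sc <- sample_cols(df)
  missing <- setdiff(sc, samples$sample_id)
  if (length(missing) > 0L) {
    stop_input(
      "matrix columns absent from the sample table: ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

group_samples <- function(samples, group, present = NULL) {
  ids <- samples$sample_id[samples$group == group]
  if (!is.null(present)) ids <- intersect(ids, present)
  ids
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
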