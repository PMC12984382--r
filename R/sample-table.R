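#' Build a validated sample table
#'
#' A sample table maps each sample to one of the four design groups, combining
#' sex (female/male) with origin (first-generation captive-bred `F1` versus
#' wild-type `wt`). Sex and origin columns are derived from the group label.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector, one of `"F1F"`, `"F1M"`, `"wtF"`, `"wtM"`.
#' @return A tibble with columns `sample_id`, `group`, `sex` (`"F"`/`"M"`) and
#'   `origin` (`"F1"`/`"wt"`).
#' @examples
#' sample_table(c("F1F1", "wtM1"), c("F1F", "wtM"))
#' @export
sample_table <- function(sample_id, group) {
  if (length(sample_id) != length(group)) {
    stop_input("sample_id and group must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop_input("duplicate sample_id: ",
               paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop_input("unknown group label(s): ", paste(bad, collapse = ", "),
               " (expected F1F, F1M, wtF, wtM)")
  }
  tibble(
    sample_id = as.character(sample_id),
    group = as.character(group),
    sex = substr(group, nchar(group), nchar(group)),
    origin = substr(group, 1L, nchar(group) - 1L)
  )
}

#' Read a sample table from a TSV file
#'
#' @param path TSV file with columns `sample_id` and `group`.
#' @return A validated sample table (see [sample_table()]).
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop_input("sample table must have columns sample_id and group")
  }
  sample_table(df$sample_id, df$group)
}

#' Define a two-group contrast
#'
#' Fold changes are reported as log2 of the numerator group relative to the
#' denominator group: a positive log2FC means higher abundance in the
#' numerator (first-named) group.
#'
#' @param numerator,denominator distinct group labels.
#' @return A list with elements `name` (e.g. `"F1F_vs_F1M"`), `numerator` and
#'   `denominator`, of class `"omics_contrast"`.
#' @examples
#' contrast("F1F", "F1M")
#' @export
contrast <- function(numerator, denominator) {
  for (g in c(numerator, denominator)) {
    if (!g %in% GROUP_LEVELS) stop_input("unknown group: ", g)
  }
  if (identical(numerator, denominator)) {
    stop_input("contrast groups must be distinct")
  }
  structure(
    list(
      name = paste0(numerator, "_vs_", denominator),
      numerator = numerator,
      denominator = denominator
    ),
    class = "omics_contrast"
  )
}

#' @export
print.omics_contrast <- function(x, ...) {
  cat("<contrast>", x$name, "\n")
  invisible(x)
}

#' The four canonical contrasts of the sex-by-origin design
#'
#' Two sex contrasts (within origin) and two origin contrasts (within sex):
#' F1F vs F1M, F1F vs wtF, F1M vs wtM, and wtF vs wtM.
#'
#' @return A named list of [contrast()] objects.
#' @export
canonical_contrasts <- function() {
  cs <- list(
    contrast("F1F", "F1M"),
    contrast("F1F", "wtF"),
    contrast("F1M", "wtM"),
    contrast("wtF", "wtM")
  )
  names(cs) <- vapply(cs, `[[`, "", "name")
  cs
}

as_contrast <- function(x) {
  if (inherits(x, "omics_contrast")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "_vs_|:", fixed = FALSE)[[1]]
    if (length(parts) == 2L) return(contrast(parts[1], parts[2]))
  }
  stop_input("cannot interpret contrast; use contrast() or 'A_vs_B'")
}
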