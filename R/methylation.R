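# Per-CpG differential methylation between pooled groups, with coverage and
# variability filters and genomic-feature annotation against a gene model.
# The test is Fisher's exact on group-pooled 2x2 tables: the original RRBS
# pipelines the study defers to are replicate-aware, and the pooled test's
# loss of between-replicate variance is a documented limitation.

meth_sample_ids <- function(mt) {
  cols <- grep("_meth$", names(mt), value = TRUE)
  sub("_meth$", "", cols)
}

meth_counts <- function(mt, ids, what = c("meth", "total")) {
  what <- match.arg(what)
  m <- as.matrix(mt[, paste0(ids, "_", what), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Read a CpG methylation count table
#'
#' TSV with columns `chrom`, `pos` (1-based), `strand`, then per sample a
#' pair of columns `<sample>_meth` (methylated reads) and `<sample>_total`
#' (total reads).
#'
#' @param path TSV file path.
#' @return A validated methylation tibble.
#' @export
read_methylation <- function(path) {
  mt <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "d", strand = "c", .default = "d"))
  validate_methylation(mt)
}

validate_methylation <- function(mt) {
  if (!all(c("chrom", "pos", "strand") %in% names(mt))) {
    stop_input("methylation table needs chrom, pos, strand columns")
  }
  ids <- meth_sample_ids(mt)
  if (length(ids) == 0L) stop_input("no <sample>_meth/_total column pairs found")
  missing_tot <- setdiff(paste0(ids, "_total"), names(mt))
  if (length(missing_tot) > 0L) {
    stop_input("missing total-count columns: ", paste(missing_tot, collapse = ", "))
  }
  m <- meth_counts(mt, ids, "meth"); t <- meth_counts(mt, ids, "total")
  if (any(m < 0) || any(t < 0) || any(m > t)) {
    stop_input("methylated counts must satisfy 0 <= m <= total")
  }
  key <- paste(mt$chrom, mt$pos, mt$strand)
  if (anyDuplicated(key)) stop_input("duplicate CpG positions")
  mt
}

#' Coverage and variability filter for CpGs
#'
#' Retains CpGs with strictly more than `min_coverage` reads in every sample
#' of both contrast groups (a site with exactly `min_coverage` reads anywhere
#' is dropped) and with nonzero variability: sites whose pooled methylation
#' proportion across the two groups is exactly 0 or 1 carry no signal and are
#' removed.
#'
#' @param mt methylation tibble.
#' @param samples sample table.
#' @param contrast a [contrast()] or `"A_vs_B"` string.
#' @param min_coverage coverage bound (default 8; retention requires `> 8`).
#' @return The filtered methylation tibble.
#' @export
filter_cpgs <- function(mt, samples, contrast, min_coverage = 8L) {
  contrast <- as_contrast(contrast)
  ids <- meth_sample_ids(mt)
  g1 <- group_samples(samples, contrast$numerator, ids)
  g2 <- group_samples(samples, contrast$denominator, ids)
  if (length(g1) == 0L || length(g2) == 0L) {
    stop_input("contrast groups have no methylation samples")
  }
  tot <- meth_counts(mt, c(g1, g2), "total")
  met <- meth_counts(mt, c(g1, g2), "meth")
  covered <- rowSums(tot > min_coverage) == ncol(tot)
  pooled_p <- rowSums(met) / pmax(rowSums(tot), 1)
  variable <- pooled_p > 0 & pooled_p < 1
  mt[covered & variable, , drop = FALSE]
}

# Two-sided Fisher exact p for 2x2 tables, vectorised over rows via the
# conditional hypergeometric distribution (sum of table probabilities not
# exceeding the observed one, with the standard relative tolerance).
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 == 0 || m2 == 0 || k == 0 || (b[i] + d[i]) == 0) {
      p[i] <- 1
      next
    }
    lo <- max(0, k - m2); hi <- min(k, m1)
    x <- lo:hi
    dens <- dhyper(x, m1, m2, k)
    dobs <- dhyper(a[i], m1, m2, k)
    p[i] <- min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
  }
  p
}

#' Differential methylation test for one contrast
#'
#' Counts are pooled within each group into a methylated/unmethylated by
#' group 2x2 table per CpG and tested with a two-sided Fisher's exact test;
#' BH adjustment runs across CpGs. The effect is reported both as the pooled
#' proportion difference `delta = p1 - p2` (numerator minus denominator
#' group) and as `log2_ratio = log2(p1/p2)` with proportions clamped to
#' `[1/(T+1), T/(T+1)]` (T the group's pooled total) to keep the ratio
#' finite. A CpG is differentially methylated (`is_dm`) when
#' `fdr < fdr_threshold`.
#'
#' @param mt filtered methylation tibble (see [filter_cpgs()]).
#' @param samples sample table.
#' @param contrast a [contrast()] or string.
#' @param fdr_threshold FDR rule for `is_dm` (default 0.01).
#' @return A tibble with `chrom`, `pos`, `strand`, `delta`, `log2_ratio`,
#'   `pvalue`, `fdr`, `is_dm`.
#' @export
dm_test <- function(mt, samples, contrast, fdr_threshold = 0.01) {
  contrast <- as_contrast(contrast)
  ids <- meth_sample_ids(mt)
  g1 <- group_samples(samples, contrast$numerator, ids)
  g2 <- group_samples(samples, contrast$denominator, ids)
  m1 <- rowSums(meth_counts(mt, g1, "meth"))
  t1 <- rowSums(meth_counts(mt, g1, "total"))
  m2 <- rowSums(meth_counts(mt, g2, "meth"))
  t2 <- rowSums(meth_counts(mt, g2, "total"))
  p1 <- m1 / pmax(t1, 1); p2 <- m2 / pmax(t2, 1)
  clamp <- function(p, t) pmin(pmax(p, 1 / (t + 1)), t / (t + 1))
  pvalue <- fisher_exact_p(m1, t1 - m1, m2, t2 - m2)
  fdr <- benjamini_hochberg(pvalue)
  tibble(
    chrom = mt$chrom, pos = mt$pos, strand = mt$strand,
    delta = p1 - p2,
    log2_ratio = log2(clamp(p1, t1) / clamp(p2, t2)),
    pvalue = pvalue,
    fdr = fdr,
    is_dm = fdr < fdr_threshold
  )
}

#' Read a gene model from GFF3 or BED
#'
#' GFF3 is parsed natively (exon features grouped by transcript); BED input
#' (0-based half-open) is converted to 1-based inclusive coordinates on read,
#' with BED12 block structure expanded to exons and BED6 intervals treated as
#' single-exon transcripts.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @return An exon-level tibble: `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @export
read_gene_model <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    if ("blocks" %in% names(S4Vectors::mcols(gr))) {
      ex <- rtracklayer::blocks(gr)
      names(ex) <- S4Vectors::mcols(gr)$name %||% as.character(seq_along(gr))
      exu <- unlist(ex)
      tibble(
        transcript_id = names(exu),
        chrom = as.character(GenomicRanges::seqnames(exu)),
        start = GenomicRanges::start(exu),
        end = GenomicRanges::end(exu),
        strand = as.character(GenomicRanges::strand(exu))
      )
    } else {
      tibble(
        transcript_id = S4Vectors::mcols(gr)$name %||%
          as.character(seq_along(gr)),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr))
      )
    }
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop_input("gene model has no exon features")
    parent <- as.character(S4Vectors::unstrsplit(ex$Parent, sep = ","))
    tibble(
      transcript_id = parent,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex),
      strand = as.character(GenomicRanges::strand(ex))
    )
  }
}

#' Annotate differential CpGs with their genomic feature context
#'
#' Each CpG gets exactly one label with precedence
#' promoter > exon > first_intron > other_intron > intergenic across all
#' overlapping transcripts. The promoter is `[TSS - upstream, TSS +
#' downstream]` in transcript orientation (defaults 2000/500); the first
#' intron is the 5'-most intron of the transcript. CpG strand is ignored;
#' the transcript strand orients the promoter. CpGs on chromosomes absent
#' from the model are intergenic and flagged in `unannotated_chrom`.
#'
#' @param dm DM result tibble (needs `chrom`, `pos`).
#' @param gene_model exon tibble from [read_gene_model()].
#' @param promoter_upstream,promoter_downstream promoter window sizes in bp
#'   around the TSS.
#' @return `dm` with added `feature_context` and `unannotated_chrom` columns.
#' @export
annotate_context <- function(dm, gene_model, promoter_upstream = 2000L,
                             promoter_downstream = 500L) {
  cpg <- GenomicRanges::GRanges(dm$chrom,
                                IRanges::IRanges(dm$pos, width = 1L))
  feats <- build_feature_ranges(gene_model, promoter_upstream,
                                promoter_downstream)
  label <- rep("intergenic", nrow(dm))
  for (ctx in c("other_intron", "first_intron", "exon", "promoter")) {
    hits <- GenomicRanges::findOverlaps(cpg, feats[[ctx]])
    label[unique(S4Vectors::queryHits(hits))] <- ctx
  }
  dm$feature_context <- label
  dm$unannotated_chrom <- !dm$chrom %in% unique(gene_model$chrom)
  dm
}

build_feature_ranges <- function(gene_model, up, down) {
  gr_of <- function(df) {
    if (nrow(df) == 0L) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  exons <- gene_model
  tx <- exons |>
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  promoter <- tx |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "-", .data$end, .data$start),
      pstart = ifelse(.data$strand == "-", .data$tss - down, .data$tss - up),
      pend = ifelse(.data$strand == "-", .data$tss + up, .data$tss + down)
    ) |>
    dplyr::transmute(chrom = .data$chrom, start = pmax(1, .data$pstart),
                     end = .data$pend)
  introns <- exons |>
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      istart = list(utils::head(.data$end, -1) + 1L),
      iend = list(utils::tail(.data$start, -1) - 1L),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("istart", "iend")) |>
    dplyr::filter(.data$istart <= .data$iend) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      is_first = ifelse(.data$strand == "-",
                        dplyr::row_number() == dplyr::n(),
                        dplyr::row_number() == 1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(start = "istart", end = "iend")
  list(
    promoter = gr_of(promoter),
    exon = gr_of(exons),
    first_intron = gr_of(dplyr::filter(introns, .data$is_first)),
    other_intron = gr_of(dplyr::filter(introns, !.data$is_first))
  )
}
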