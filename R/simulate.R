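# Matched multi-omics simulator with planted ground truth, emulating a
# 4-group (sex x origin) gonad study: a dominant sex effect on a subset of
# genes, weak origin effects, per-effect coupling between gene and protein
# fold changes, intensity-dependent (MNAR) protein dropout, partial
# gene-to-protein mapping, and binomial CpG methylation with a female-global
# offset. Every stage draws from its own seeded stream (root seed plus a
# fixed offset) so adding a stage never perturbs earlier draws.

STREAM_OFFSETS <- c(rna = 101L, protein = 202L, methylation = 303L,
                    annotations = 404L, gene_model = 505L)

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: ~30,000 genes of which
#' 2,000 map to quantified proteins; RNA replicates 5/5/5/4 and protein
#' replicates 5/5/5/3 across F1F/F1M/wtF/wtM; a sex effect on 10% of genes
#' (mean |log2FC| 2) versus origin effects on 1% per sex (mean |log2FC| 1),
#' so sex contrasts dominate; per-contrast gene-protein fold-change coupling
#' of 0.25/0.09/0.19/0.10, inside the weak correlation range such studies
#' report; NB dispersion 0.2; and logistic intensity-dependent dropout tuned
#' so most proteins stay at least 70% complete. The four couplings are
#' linearly dependent (the contrasts span only three free effects), so the
#' sex coupling is taken from `wtF_vs_wtM`, the origin-in-females coupling
#' from `F1F_vs_wtF`, the origin-in-males coupling from `F1M_vs_wtM`, and
#' the `F1F_vs_F1M` entry is implied by those three.
#'
#' @param n_genes number of genes.
#' @param n_mapped_proteins number of genes with a mapped quantified protein.
#' @param rna_design,protein_design named integer vectors of replicates per
#'   group.
#' @param frac_sex_de fraction of genes with a planted sex effect
#'   (assignment is deterministic: the first `floor(frac * n)` genes of a
#'   seeded shuffle, so planted counts are exact).
#' @param frac_origin_de_per_sex fraction with a planted origin effect,
#'   separately within females and within males.
#' @param sex_lfc_scale,origin_lfc_scale mean of the |log2FC| draws
#'   (random sign times Exponential).
#' @param coupling named vector in \[-1, 1\] per canonical contrast: target
#'   correlation between true gene and protein log2FC.
#' @param nb_dispersion NB dispersion for counts (0 gives Poisson).
#' @param protein_noise_sd residual sd of log2 intensities.
#' @param miss_intercept,miss_slope logistic missingness on the log2
#'   intensity: `P(missing) = plogis(miss_intercept + miss_slope * log2I)`.
#' @param frac_single_peptide fraction of proteins assigned one unique
#'   peptide (to exercise the peptide filter).
#' @param frac_contaminant fraction flagged as contaminants.
#' @param n_cpgs number of CpG sites.
#' @param frac_meth_sex,frac_meth_origin fractions of CpGs with planted sex /
#'   origin methylation differences (logit-scale shifts).
#' @param meth_effect mean |logit shift| of planted methylation effects.
#' @param female_meth_offset global logit-scale offset added to female
#'   groups (positive: females more methylated overall).
#' @param coverage_mean,coverage_size negative-binomial read-coverage model.
#' @param rng_seed root seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 30000L,
                       n_mapped_proteins = 2000L,
                       rna_design = c(F1F = 5L, F1M = 5L, wtF = 5L, wtM = 4L),
                       protein_design = c(F1F = 5L, F1M = 5L, wtF = 5L, wtM = 3L),
                       frac_sex_de = 0.10,
                       frac_origin_de_per_sex = 0.01,
                       sex_lfc_scale = 2,
                       origin_lfc_scale = 1,
                       coupling = c(F1F_vs_F1M = 0.25, F1F_vs_wtF = 0.09,
                                    F1M_vs_wtM = 0.19, wtF_vs_wtM = 0.10),
                       nb_dispersion = 0.2,
                       protein_noise_sd = 0.5,
                       miss_intercept = 20,
                       miss_slope = -1,
                       frac_single_peptide = 0.10,
                       frac_contaminant = 0.02,
                       n_cpgs = 10000L,
                       frac_meth_sex = 0.05,
                       frac_meth_origin = 0.01,
                       meth_effect = 1.5,
                       female_meth_offset = 0.2,
                       coverage_mean = 30,
                       coverage_size = 5,
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_mapped_proteins = as.integer(n_mapped_proteins),
    rna_design = rna_design, protein_design = protein_design,
    frac_sex_de = frac_sex_de,
    frac_origin_de_per_sex = frac_origin_de_per_sex,
    sex_lfc_scale = sex_lfc_scale, origin_lfc_scale = origin_lfc_scale,
    coupling = coupling,
    nb_dispersion = nb_dispersion,
    protein_noise_sd = protein_noise_sd,
    miss_intercept = miss_intercept, miss_slope = miss_slope,
    frac_single_peptide = frac_single_peptide,
    frac_contaminant = frac_contaminant,
    n_cpgs = as.integer(n_cpgs),
    frac_meth_sex = frac_meth_sex, frac_meth_origin = frac_meth_origin,
    meth_effect = meth_effect,
    female_meth_offset = female_meth_offset,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c(cfg$frac_sex_de, cfg$frac_origin_de_per_sex, cfg$frac_meth_sex,
             cfg$frac_meth_origin, cfg$frac_single_peptide,
             cfg$frac_contaminant)
  if (any(fracs < 0 | fracs > 1)) stop_input("fractions must lie in [0, 1]")
  if (any(abs(cfg$coupling) > 1)) stop_input("coupling must lie in [-1, 1]")
  if (cfg$n_mapped_proteins > cfg$n_genes) {
    stop_input("n_mapped_proteins cannot exceed n_genes")
  }
  if (cfg$nb_dispersion < 0) stop_input("nb_dispersion must be >= 0")
  if (!all(GROUP_LEVELS %in% names(cfg$rna_design)) ||
      !all(GROUP_LEVELS %in% names(cfg$protein_design))) {
    stop_input("designs must name all four groups")
  }
  structure(cfg, class = "sim_config")
}

set_stream <- function(cfg, stage) {
  set.seed(cfg$rng_seed + STREAM_OFFSETS[[stage]])
}

design_samples <- function(design) {
  sample_table(
    sample_id = unlist(lapply(GROUP_LEVELS,
                              function(g) paste0(g, seq_len(design[[g]])))),
    group = rep(GROUP_LEVELS, times = design[GROUP_LEVELS])
  )
}

# signed sparse effect vector: the first floor(frac*n) positions of a seeded
# shuffle get sign * Exponential(mean = scale); everything else is exactly 0
planted_effects <- function(n, frac, scale) {
  e <- numeric(n)
  k <- floor(frac * n)
  if (k > 0L) {
    idx <- sample.int(n)[seq_len(k)]
    e[idx] <- sample(c(-1, 1), k, replace = TRUE) * rexp(k, rate = 1 / scale)
  }
  e
}

# per-gene true log2FC for each canonical contrast given the three structural
# effects (sex applied to female groups, origin-in-females, origin-in-males)
effects_to_contrast_lfc <- function(sex, oF, oM) {
  list(
    F1F_vs_F1M = sex + oF - oM,
    F1F_vs_wtF = oF,
    F1M_vs_wtM = oM,
    wtF_vs_wtM = sex
  )
}

lfc_truth_table <- function(ids, lfcs, prefix) {
  purrr::imap_dfr(lfcs, function(v, ctr) {
    tibble(feature_id = ids, contrast = ctr, true_log2fc = v,
           true_de = v != 0,
           true_status = ifelse(v > 0, "UP", ifelse(v < 0, "DOWN", "NS")))
  }) |>
    dplyr::rename(!!paste0(prefix, "_log2fc") := "true_log2fc",
                  !!paste0(prefix, "_de") := "true_de",
                  !!paste0(prefix, "_status") := "true_status")
}

#' Simulate an RNA-seq count matrix with planted effects
#'
#' Gene baseline means are log-uniform over \[2, 2^12\]; group means shift
#' the baseline by the planted structural log2 effects; counts are negative
#' binomial with the configured dispersion, with mild log-normal
#' library-size variation across samples. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return A list: `counts` (matrix tibble), `samples` (sample table),
#'   `effects` (per-gene structural effects), `truth` (long tibble of true
#'   log2FC, DE indicator and direction per gene and contrast).
#' @export
simulate_rna <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_stream(cfg, "rna")
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  samples <- design_samples(cfg$rna_design)

  base_log2 <- runif(n, 1, 12)
  sex <- planted_effects(n, cfg$frac_sex_de, cfg$sex_lfc_scale)
  oF <- planted_effects(n, cfg$frac_origin_de_per_sex, cfg$origin_lfc_scale)
  oM <- planted_effects(n, cfg$frac_origin_de_per_sex, cfg$origin_lfc_scale)

  group_log2 <- function(g) {
    base_log2 +
      (substr(g, nchar(g), nchar(g)) == "F") * sex +
      (g == "F1F") * oF + (g == "F1M") * oM
  }
  lib <- exp(rnorm(nrow(samples), 0, 0.15))
  mu <- sapply(seq_len(nrow(samples)), function(j) {
    lib[j] * 2^group_log2(samples$group[j])
  })
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
           nrow = n)
  } else {
    matrix(rpois(length(mu), as.vector(mu)), nrow = n)
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- samples$sample_id
  lfcs <- effects_to_contrast_lfc(sex, oF, oM)
  list(
    counts = as_matrix_tibble(counts),
    samples = samples,
    effects = tibble(gene_id = gene_ids, sex_lfc = sex,
                     originF_lfc = oF, originM_lfc = oM),
    truth = lfc_truth_table(gene_ids, lfcs, "rna") |>
      dplyr::rename(gene_id = "feature_id")
  )
}

#' Simulate a matched protein intensity matrix
#'
#' A seeded subset of `n_mapped_proteins` genes gets a quantified protein.
#' Each protein-level structural effect is the coupled mixture
#' `c * rna_effect + sqrt(1 - c^2) * e`, where `e` is an independent sparse
#' signed-exponential vector with the same planted fraction and scale as its
#' RNA counterpart, so the true fold-change correlation per contrast equals
#' the configured coupling. Log2 intensities are normal around group means;
#' dropout is logistic in the realised log2 intensity (MNAR); ~10% of
#' proteins get a single unique peptide and ~2% a contaminant flag, to
#' exercise the filters.
#'
#' @param cfg a [sim_config()].
#' @param rna result of [simulate_rna()] under the same config.
#' @return A list: `intensities` (matrix tibble with `unique_peptides`,
#'   `is_contaminant`), `samples`, `map` (protein_id, gene_id), `truth`
#'   (long tibble per protein and contrast).
#' @export
simulate_protein <- function(cfg, rna) {
  stopifnot(inherits(cfg, "sim_config"))
  set_stream(cfg, "protein")
  n_map <- cfg$n_mapped_proteins
  if (n_map > nrow(rna$effects)) stop_input("mapped set larger than n_genes")
  mapped_idx <- sort(sample.int(nrow(rna$effects))[seq_len(n_map)])
  genes <- rna$effects$gene_id[mapped_idx]
  protein_ids <- paste0("P_", genes)
  samples <- design_samples(cfg$protein_design)

  couple <- function(rna_effect, c_target, frac, scale) {
    e <- planted_effects(n_map, frac, scale)
    c_target * rna_effect + sqrt(1 - c_target^2) * e
  }
  sexP <- couple(rna$effects$sex_lfc[mapped_idx],
                 cfg$coupling[["wtF_vs_wtM"]],
                 cfg$frac_sex_de, cfg$sex_lfc_scale)
  oFP <- couple(rna$effects$originF_lfc[mapped_idx],
                cfg$coupling[["F1F_vs_wtF"]],
                cfg$frac_origin_de_per_sex, cfg$origin_lfc_scale)
  oMP <- couple(rna$effects$originM_lfc[mapped_idx],
                cfg$coupling[["F1M_vs_wtM"]],
                cfg$frac_origin_de_per_sex, cfg$origin_lfc_scale)

  base_log2 <- rnorm(n_map, 24, 2.5)
  group_log2 <- function(g) {
    base_log2 +
      (substr(g, nchar(g), nchar(g)) == "F") * sexP +
      (g == "F1F") * oFP + (g == "F1M") * oMP
  }
  vals <- sapply(seq_len(nrow(samples)), function(j) {
    group_log2(samples$group[j]) + rnorm(n_map, 0, cfg$protein_noise_sd)
  })
  p_miss <- stats::plogis(cfg$miss_intercept + cfg$miss_slope * vals)
  miss <- matrix(runif(length(vals)) < p_miss, nrow = n_map)
  intens <- 2^vals
  intens[miss] <- NA_real_
  rownames(intens) <- protein_ids
  colnames(intens) <- samples$sample_id

  k1 <- floor(cfg$frac_single_peptide * n_map)
  single <- sample.int(n_map)[seq_len(k1)]
  peptides <- 2L + rpois(n_map, 3)
  peptides[single] <- 1L
  kc <- floor(cfg$frac_contaminant * n_map)
  contaminant <- rep(FALSE, n_map)
  contaminant[sample.int(n_map)[seq_len(kc)]] <- TRUE

  out <- as_matrix_tibble(intens)
  out$unique_peptides <- peptides
  out$is_contaminant <- contaminant
  lfcs <- effects_to_contrast_lfc(sexP, oFP, oMP)
  list(
    intensities = out,
    samples = samples,
    map = tibble(protein_id = protein_ids, gene_id = genes),
    truth = lfc_truth_table(protein_ids, lfcs, "prot") |>
      dplyr::rename(protein_id = "feature_id") |>
      dplyr::mutate(gene_id = rep(genes, times = 4), .before = 1)
  )
}

#' Simulate a CpG methylation count table
#'
#' Per-CpG baseline proportions are Beta-distributed (bimodal, as CpG
#' methylation typically is); planted sex and origin subsets receive
#' logit-scale shifts, and all female-group samples get a global positive
#' logit offset (females more methylated overall). Coverage is negative
#' binomial and methylated reads binomial. CpGs are placed on five
#' chromosomes at seeded positions.
#'
#' @param cfg a [sim_config()].
#' @return A list: `methylation` (count tibble), `samples` (sample table,
#'   RNA design), `truth` (long tibble of the true per-contrast methylation
#'   proportion difference per CpG).
#' @export
simulate_methylation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_stream(cfg, "methylation")
  n <- cfg$n_cpgs
  samples <- design_samples(cfg$rna_design)
  chrom <- paste0("chr", sample.int(5L, n, replace = TRUE))
  pos <- sample.int(1000000L, n, replace = TRUE)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- sample.int(1000000L, sum(dup), replace = TRUE)
    key <- paste(chrom, pos)
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  p0 <- rbeta(n, 0.4, 0.4)
  p0 <- pmin(pmax(p0, 0.01), 0.99)
  sexm <- planted_effects(n, cfg$frac_meth_sex, cfg$meth_effect)
  oFm <- planted_effects(n, cfg$frac_meth_origin, cfg$meth_effect)
  oMm <- planted_effects(n, cfg$frac_meth_origin, cfg$meth_effect)
  logit0 <- log(p0 / (1 - p0))
  group_p <- function(g) {
    stats::plogis(
      logit0 +
        (substr(g, nchar(g), nchar(g)) == "F") *
          (cfg$female_meth_offset + sexm) +
        (g == "F1F") * oFm + (g == "F1M") * oMm
    )
  }
  mt <- tibble(chrom = chrom, pos = as.double(pos), strand = "+")
  for (j in seq_len(nrow(samples))) {
    tot <- rnbinom(n, mu = cfg$coverage_mean, size = cfg$coverage_size)
    met <- rbinom(n, tot, group_p(samples$group[j]))
    mt[[paste0(samples$sample_id[j], "_meth")]] <- as.double(met)
    mt[[paste0(samples$sample_id[j], "_total")]] <- as.double(tot)
  }
  pg <- lapply(setNames(GROUP_LEVELS, GROUP_LEVELS), group_p)
  truth <- purrr::imap_dfr(canonical_contrasts(), function(ctr, nm) {
    tibble(chrom = chrom, pos = as.double(pos), contrast = nm,
           true_delta = pg[[ctr$numerator]] - pg[[ctr$denominator]])
  })
  list(methylation = mt, samples = samples, truth = truth)
}

#' Simulate a GMT annotation collection over the gene universe
#'
#' Random terms of size 10-100 drawn from the gene universe; the first three
#' terms are biased toward genes with the strongest planted sex effects so
#' the enrichment stage has recoverable signal.
#'
#' @param cfg a [sim_config()].
#' @param effects per-gene effect tibble from [simulate_rna()].
#' @param n_terms number of terms.
#' @return An annotation tibble (see [read_annotations()]).
#' @export
simulate_annotations <- function(cfg, effects, n_terms = 50L) {
  set_stream(cfg, "annotations")
  genes <- effects$gene_id
  w <- abs(effects$sex_lfc)
  top <- order(w, decreasing = TRUE)
  rows <- purrr::map_dfr(seq_len(n_terms), function(i) {
    size <- sample(10:100, 1L)
    members <- if (i <= 3L) {
      sample(genes[top[seq_len(max(200L, size * 2L))]], size)
    } else {
      sample(genes, size)
    }
    tibble(term_id = sprintf("T%03d", i),
           term_name = sprintf("synthetic term %d", i),
           gene_id = members)
  })
  rows |>
    dplyr::mutate(namespace = "BP") |>
    dplyr::group_by(.data$term_id) |>
    dplyr::mutate(term_size = dplyr::n(), singleton = dplyr::n() == 1L) |>
    dplyr::ungroup()
}

#' Simulate a small gene model for feature annotation
#'
#' Multi-exon transcripts scattered over the five simulated chromosomes,
#' returned as an exon tibble compatible with [annotate_context()].
#'
#' @param cfg a [sim_config()].
#' @param n_transcripts number of transcripts.
#' @return An exon tibble (`transcript_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_gene_model <- function(cfg, n_transcripts = 150L) {
  set_stream(cfg, "gene_model")
  purrr::map_dfr(seq_len(n_transcripts), function(i) {
    chrom <- paste0("chr", sample.int(5L, 1L))
    strand <- sample(c("+", "-"), 1L)
    n_exon <- sample(2:6, 1L)
    tss <- sample.int(950000L, 1L)
    exon_len <- sample(100:400, n_exon, replace = TRUE)
    intron_len <- sample(500:5000, n_exon - 1L, replace = TRUE)
    starts <- tss + cumsum(c(0L, exon_len[-n_exon] + intron_len))
    tibble(transcript_id = sprintf("tx%04d", i), chrom = chrom,
           start = starts, end = starts + exon_len - 1L, strand = strand)
  })
}

#' Simulate the full matched multi-omics dataset
#'
#' Runs every stage of the generator and, when `outdir` is given, writes
#' `counts.tsv`, `intensities.tsv`, `map.tsv`, `samples.tsv`,
#' `methylation.tsv`, `terms.gmt`, `genes.gff3` and `truth.tsv`.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory (created if needed).
#' @return A list with all stage outputs and a `truth` list (`rna`,
#'   `protein`, `pairs`, `methylation`); the pair truth applies the same
#'   classification rule as the estimator to the planted indicators.
#' @export
simulate_multiomics <- function(cfg = sim_config(), outdir = NULL) {
  rna <- simulate_rna(cfg)
  prot <- simulate_protein(cfg, rna)
  meth <- simulate_methylation(cfg)
  ann <- simulate_annotations(cfg, rna$effects)
  gm <- simulate_gene_model(cfg)

  pair_truth <- prot$truth |>
    dplyr::select("gene_id", "protein_id", "contrast", "prot_log2fc",
                  "prot_status") |>
    dplyr::inner_join(rna$truth, by = c("gene_id", "contrast")) |>
    dplyr::mutate(true_pair_class = classify_pair(
      .data$rna_status, .data$rna_log2fc,
      .data$prot_status, .data$prot_log2fc
    ))

  out <- list(
    config = cfg,
    counts = rna$counts, samples_rna = rna$samples,
    effects = rna$effects,
    intensities = prot$intensities, samples_protein = prot$samples,
    map = prot$map,
    methylation = meth$methylation, samples_methylation = meth$samples,
    annotations = ann, gene_model = gm,
    truth = list(rna = rna$truth, protein = prot$truth,
                 pairs = pair_truth, methylation = meth$truth)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_matrix(out$counts, file.path(outdir, "counts.tsv"))
    write_matrix(out$intensities, file.path(outdir, "intensities.tsv"))
    readr::write_tsv(out$map, file.path(outdir, "map.tsv"))
    readr::write_tsv(out$samples_rna[, c("sample_id", "group")],
                     file.path(outdir, "samples.tsv"))
    readr::write_tsv(out$methylation, file.path(outdir, "methylation.tsv"))
    write_annotations(out$annotations, file.path(outdir, "terms.gmt"))
    write_gene_model_gff3(gm, file.path(outdir, "genes.gff3"))
    readr::write_tsv(pair_truth, file.path(outdir, "truth.tsv"))
  }
  out
}

#' Write an exon tibble as GFF3
#' @param gm exon tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(gm, path) {
  tx <- gm |>
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  tx_lines <- sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                      tx$chrom, tx$start, tx$end, tx$strand,
                      tx$transcript_id)
  ex_lines <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                      gm$chrom, gm$start, gm$end, gm$strand,
                      gm$transcript_id)
  writeLines(c("##gff-version 3", tx_lines, ex_lines), path)
  invisible(path)
}
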