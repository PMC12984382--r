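# End-to-end driver: simulate (or read) inputs, run per-layer differential
# analysis for every contrast, integrate, enrich, test methylation, compute
# exploratory views, and write a deterministic JSON manifest of outputs.

#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or explicit input paths
#' (`counts`, `intensities`, `map`, `samples`, `methylation`, `annotations`,
#' `gene_model`). Thresholds default to the published rules: genes
#' |log2FC| >= 1 at FDR < 0.05, proteins |log2FC| >= 0.5 at FDR < 0.05,
#' CpG coverage > 8 and FDR < 0.01.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param inputs named list of input paths (ignored when simulating).
#' @param contrasts list of [contrast()]s; default the four canonical ones.
#' @param rna_lfc,rna_fdr,prot_lfc,prot_fdr,meth_cov,meth_fdr thresholds.
#' @param enrich_alpha adjusted-p cutoff for concordant enriched terms.
#' @param seed root seed (overrides the simulate block's seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            contrasts = canonical_contrasts(),
                            rna_lfc = 1, rna_fdr = 0.05,
                            prot_lfc = 0.5, prot_fdr = 0.05,
                            meth_cov = 8, meth_fdr = 0.01,
                            enrich_alpha = 0.05, seed = NULL) {
  thr <- c(rna_lfc, rna_fdr, prot_lfc, prot_fdr, meth_cov, meth_fdr,
           enrich_alpha)
  if (any(thr <= 0)) stop_input("thresholds must be positive")
  if (!is.null(seed) && !is.null(simulate)) {
    simulate$rng_seed <- as.integer(seed)
  }
  structure(
    list(simulate = simulate, inputs = inputs, contrasts = contrasts,
         rna_lfc = rna_lfc, rna_fdr = rna_fdr,
         prot_lfc = prot_lfc, prot_fdr = prot_fdr,
         meth_cov = meth_cov, meth_fdr = meth_fdr,
         enrich_alpha = enrich_alpha),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' A flat schema mirroring [pipeline_config()]: threshold keys at the top
#' level, an optional `simulate:` mapping passed to [sim_config()], an
#' optional `inputs:` mapping of paths, and an optional `contrasts:` list of
#' `"A_vs_B"` strings.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate) else NULL
  contrasts <- if (!is.null(y$contrasts)) {
    lapply(y$contrasts, as_contrast)
  } else {
    canonical_contrasts()
  }
  args <- y[intersect(names(y), c("rna_lfc", "rna_fdr", "prot_lfc",
                                  "prot_fdr", "meth_cov", "meth_fdr",
                                  "enrich_alpha", "seed"))]
  do.call(pipeline_config,
          c(list(simulate = sim, inputs = y$inputs, contrasts = contrasts),
            args))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full integrative pipeline
#'
#' Stages: simulate or read inputs; RNA and protein differential analysis per
#' contrast; gene-protein pair construction, classification and concordance
#' summaries; ranked-list enrichment per layer and direction with
#' cross-layer concordant terms; CpG filtering, differential methylation and
#' feature annotation per contrast; PCA of the matched RNA matrix and of the
#' protein matrix. Outputs are written under `outdir` as TSV/JSON plus a
#' `manifest.json` with md5 hashes and per-stage summaries; the manifest is
#' deterministic so reruns under the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())

  if (!is.null(config$simulate)) {
    stage_log("simulate", "generating synthetic dataset (seed ",
              config$simulate$rng_seed, ")")
    sim <- simulate_multiomics(config$simulate, outdir = file.path(outdir, "inputs"))
    counts <- sim$counts; samples <- sim$samples_rna
    intensities <- sim$intensities
    map <- sim$map; meth <- sim$methylation
    ann <- sim$annotations; gm <- sim$gene_model
    manifest$seed <- config$simulate$rng_seed
  } else {
    inp <- config$inputs
    stage_log("read", "loading inputs")
    counts <- read_matrix(inp$counts, "counts")
    intensities <- read_matrix(inp$intensities, "intensities")
    map <- read_gene_protein_map(inp$map)
    samples <- read_sample_table(inp$samples)
    meth <- if (!is.null(inp$methylation)) read_methylation(inp$methylation)
    ann <- if (!is.null(inp$annotations)) read_annotations(inp$annotations)
    gm <- if (!is.null(inp$gene_model)) read_gene_model(inp$gene_model)
  }
  validate_matrix_samples(counts, samples)
  validate_matrix_samples(intensities, samples)
  manifest$stages$inputs <- list(
    n_genes = nrow(counts), n_rna_samples = length(sample_cols(counts)),
    n_proteins = nrow(intensities),
    n_protein_samples = length(sample_cols(intensities)),
    n_mapped = nrow(map)
  )

  # protein filtering + normalisation (shared across contrasts)
  flt <- filter_proteins(intensities)
  norm <- normalize_intensities(flt$intensities)
  jsonlite::write_json(as.list(flt$report),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$protein_filter <- as.list(flt$report)
  stage_log("filter", flt$report$n_retained, "/", flt$report$n_input,
            " proteins retained")

  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, samples, sf)

  summaries <- list()
  for (ctr in config$contrasts) {
    nm <- ctr$name
    stage_log("de", nm)
    deg <- nb_wald_contrast(counts, samples, ctr, sf, disp,
                            lfc_threshold = config$rna_lfc,
                            fdr_threshold = config$rna_fdr)
    dep <- moderated_t_contrast(norm, samples, ctr,
                                lfc_threshold = config$prot_lfc,
                                fdr_threshold = config$prot_fdr)
    readr::write_tsv(tidy(deg), file.path(outdir, paste0("degs_", nm, ".tsv")))
    readr::write_tsv(tidy(dep), file.path(outdir, paste0("deps_", nm, ".tsv")))

    pairs <- build_pairs(deg, dep, map)
    readr::write_tsv(tidy(pairs), file.path(outdir, paste0("pairs_", nm, ".tsv")))
    conc <- summarize_concordance(pairs)

    enr <- NULL
    if (!is.null(ann)) {
      mapped_genes <- unique(map$gene_id)
      deg_m <- deg[deg$feature_id %in% mapped_genes & !is.na(deg$pvalue), ]
      dep_g <- dep
      dep_g$feature_id <- map$gene_id[match(dep$feature_id, map$protein_id)]
      enr <- purrr::map_dfr(c("up", "down"), function(dir) {
        dplyr::bind_rows(
          ordered_query_enrichment(deg_m, deg_m$feature_id, ann, dir) |>
            dplyr::mutate(layer = "RNA"),
          ordered_query_enrichment(dep_g, unique(dep_g$feature_id), ann, dir) |>
            dplyr::mutate(layer = "PROT")
        )
      })
      readr::write_tsv(enr, file.path(outdir, paste0("enrichment_", nm, ".tsv")))
      cterms <- concordant_terms(enr[enr$layer == "RNA", ],
                                 enr[enr$layer == "PROT", ],
                                 alpha = config$enrich_alpha)
      readr::write_tsv(cterms,
                       file.path(outdir, paste0("concordant_terms_", nm, ".tsv")))
    }

    dm_summary <- NULL
    if (!is.null(meth)) {
      mf <- filter_cpgs(meth, samples, ctr, min_coverage = config$meth_cov)
      dm <- dm_test(mf, samples, ctr, fdr_threshold = config$meth_fdr)
      if (!is.null(gm)) dm <- annotate_context(dm, gm)
      readr::write_tsv(dm, file.path(outdir, paste0("dm_", nm, ".tsv")))
      dm_summary <- list(n_tested = nrow(dm), n_dm = sum(dm$is_dm))
    }

    summaries[[nm]] <- list(
      n_deg = sum(deg$status != "NS"),
      n_deg_up = sum(deg$status == "UP"),
      n_deg_down = sum(deg$status == "DOWN"),
      n_dep = sum(dep$status != "NS"),
      n_dep_up = sum(dep$status == "UP"),
      n_dep_down = sum(dep$status == "DOWN"),
      concordance = as.list(conc),
      n_enriched_terms = if (!is.null(enr)) sum(enr$adjusted_p < config$enrich_alpha),
      methylation = dm_summary
    )
  }
  manifest$stages$contrasts <- summaries

  stage_log("pca", "matched RNA matrix and protein matrix")
  matched <- counts[counts$feature_id %in% map$gene_id, , drop = FALSE]
  pca_rna <- run_pca(matched, log_mode = TRUE)
  complete <- stats::complete.cases(norm[, sample_cols(norm)])
  pca_prot <- run_pca(norm[complete, , drop = FALSE])
  readr::write_tsv(pca_rna$scores, file.path(outdir, "pca_rna_scores.tsv"))
  readr::write_tsv(pca_prot$scores, file.path(outdir, "pca_prot_scores.tsv"))
  manifest$stages$pca <- list(
    rna_pc1_pct = pca_rna$variance_explained_pct[1],
    rna_pc2_pct = pca_rna$variance_explained_pct[2],
    prot_pc1_pct = pca_prot$variance_explained_pct[1],
    prot_pc2_pct = pca_prot$variance_explained_pct[2]
  )

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", outdir, "/?"), "", files)
  manifest$files <- as.list(hashes)
  manifest$version <- as.character(utils::packageVersion("omicsconcord"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
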