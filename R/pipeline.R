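#' Run the full synthetic-study pipeline
#'
#' End-to-end orchestration at synthetic scale: generate a multi-cohort
#' study with planted ground truth, preprocess every dataset
#' (normalization, contamination residualization, outlier removal), fit
#' per-dataset moderated-t differential expression, overlap the DE sets
#' across tissues with mitochondrial annotation, aggregate the
#' per-dataset rankings through the tiered order-statistics integration,
#' and run set-permutation enrichment of a planted-plus-random gene-set
#' collection on the final ranking. Every stage output is written as TSV
#' under `out_dir` together with a manifest recording seeds, thresholds
#' and file hashes, so a rerun with the same config and seed reproduces
#' identical files.
#'
#' @param config a [sim_config()]; its seed is replaced by `seed`.
#' @param seed integer master seed for the run.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param B_rank permutations per integration step.
#' @param B_gsea permutations per enrichment set size.
#' @param de_spec a [de_call_spec()] for per-dataset DE calls.
#' @param overlap_spec the (more permissive) [de_call_spec()] used when
#'   comparing DE sets across proteomes; the multi-proteome integration
#'   convention is |Z| > 2 with FDR < 0.2.
#' @param n_random_sets random same-size sets added next to the planted
#'   signature and module sets in the enrichment collection.
#' @return A list of class `pipeline_result`: `truth`, `preprocessed`,
#'   `de` (named list of `de_result`s), `de_sets`, `overlap`,
#'   `ranking` (the `integrated_ranking`), `enrichment`, `paths`.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         out_dir = NULL, B_rank = 1000, B_gsea = 1000,
                         de_spec = de_call_spec(),
                         overlap_spec = de_spec_preset("integration"),
                         n_random_sets = 18) {
  stopifnot(inherits(config, "sim_config"))
  config$seed <- as.integer(seed)

  sim <- simulate_study(config)
  truth <- sim$truth
  datasets <- sim$datasets
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_fixture_bundle(datasets, truth, file.path(out_dir, "sim"))
  }

  prep <- lapply(datasets, preprocess_dataset,
                 marker_panel = truth$contamination_marker_ids)
  de <- lapply(prep, function(p) {
    covar <- if (p$correction_applied) p$scores[colnames(p$corrected)] else NULL
    out <- fit_moderated_t(p$corrected, p$groups, covariate = covar)
    attr(out, "dataset_id") <- p$dataset_id
    out
  })

  de_sets <- lapply(de, call_de, spec = de_spec)
  overlap_sets <- lapply(de, call_de, spec = overlap_spec)
  tissues <- vapply(datasets, function(d) d$tissue, "")
  roles <- vapply(datasets, function(d) d$cohort_role, "")
  disc <- names(datasets)[roles == "discovery"]
  by_tissue <- split(disc, tissues[disc])
  tissue_sets <- lapply(by_tissue, function(ids) {
    sort(unique(unlist(overlap_sets[ids], use.names = FALSE)))
  })
  overlap <- NULL
  if (length(tissue_sets) >= 2L) {
    overlap <- overlap_de_sets(tissue_sets, universe = config$n_proteins)
    overlap <- annotate_overlap(overlap, truth$annotation)
  }

  lists <- lapply(de, rank_proteins)
  plan <- default_tier_plan(config$datasets)
  csf_ids <- names(datasets)[tissues == "csf"]
  ser_ids <- names(datasets)[tissues == "serum"]
  keep <- NULL
  if (length(csf_ids) || length(ser_ids)) {
    keep <- filter_unchanged(
      universe = unique(unlist(lapply(lists, `[[`, "protein"))),
      csf_de = de[csf_ids], serum_de = de[ser_ids]
    )
  }
  ranking <- tiered_integration(lists, plan, B = B_rank,
                                seed = child_seed(config$seed, 7L),
                                keep = keep)

  collection <- build_truth_collection(truth, ranking$protein,
                                       n_random = n_random_sets,
                                       seed = child_seed(config$seed, 11L))
  enrichment <- run_enrichment(ranking, collection, B = B_gsea,
                               seed = child_seed(config$seed, 13L))

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_pipeline_outputs(out_dir, config, de, overlap, ranking,
                                    enrichment, de_spec)
  }
  structure(list(
    truth = truth, preprocessed = prep, de = de, de_sets = de_sets,
    overlap = overlap, ranking = ranking, enrichment = enrichment,
    paths = paths
  ), class = "pipeline_result")
}

# Gene-set collection with the planted signature and module next to
# random same-size draws from the ranked universe (null context for BH).
build_truth_collection <- function(truth, universe, n_random = 18,
                                   seed = 1L) {
  sig <- intersect(truth$signature_ids, universe)
  mod <- intersect(truth$mito_module_ids, universe)
  sets <- list()
  if (length(sig) >= 5L) sets$planted_signature <- sig
  if (length(mod) >= 5L) sets$planted_mito_module <- mod
  with_seed(seed, {
    m <- max(length(sig), 10L)
    for (i in seq_len(n_random)) {
      sets[[sprintf("random_%02d", i)]] <- sample(universe, m)
    }
  })
  structure(sets, class = "gene_set_collection")
}

write_pipeline_outputs <- function(out_dir, config, de, overlap, ranking,
                                   enrichment, de_spec) {
  paths <- character(0)
  for (nm in names(de)) {
    p <- file.path(out_dir, paste0("de_", nm, ".tsv"))
    readr::write_tsv(tidy(de[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(overlap)) {
    p <- file.path(out_dir, "overlap.tsv")
    readr::write_tsv(tidy(overlap), p, progress = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "integrated_ranking.tsv")
  readr::write_tsv(tidy(ranking), p, progress = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "enrichment.tsv")
  readr::write_tsv(tidy(enrichment), p, progress = FALSE)
  paths <- c(paths, p)

  hashes <- tools::md5sum(paths)
  man <- file.path(out_dir, "pipeline_manifest.txt")
  spec_txt <- sprintf(
    "de_spec: |Z| > %g and %s, direction %s", de_spec$z_min,
    if (!is.null(de_spec$fdr_max)) sprintf("FDR < %g", de_spec$fdr_max)
    else sprintf("p < %g", de_spec$p_max),
    de_spec$direction)
  writeLines(c(
    sprintf("seed: %d", config$seed),
    sprintf("n_proteins: %d", config$n_proteins),
    sprintf("B_rank: %d", attr(ranking, "B")),
    sprintf("B_gsea: %d", attr(enrichment, "B")),
    spec_txt,
    "hashes:",
    sprintf("  %s: %s", basename(names(hashes)), unname(hashes))
  ), man)
  c(paths, man)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d datasets; final ranking of %d proteins; %d/%d sets enriched\n",
    length(x$de), nrow(x$ranking), sum(x$enrichment$enriched),
    nrow(x$enrichment)))
  invisible(x)
}
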