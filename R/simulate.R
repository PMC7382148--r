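#' Configuration for a synthetic multi-cohort proteome study
#'
#' The generator emulates the structure of a multi-dataset AD proteome
#' study: a wide log10 abundance dynamic range, a set of cross-tissue
#' signature proteins whose AD mean shift follows a tissue direction map
#' (up in cortex, down in biofluids), a correlated mitochondrial module
#' planted in a low-abundance band so it is invisible to shallow
#' profiling, a blood-contamination covariate loading strongly on an
#' erythrocyte marker panel and weakly on everything else, and
#' dataset-specific profiling depth (only the top-`depth` most abundant
#' proteins are quantified; the rest are missing).
#'
#' @param n_proteins size of the protein universe.
#' @param datasets data frame with one row per dataset: `dataset_id`,
#'   `tissue`, `species`, `cohort_role`, `n_ad`, `n_ctl`, `n_mci`,
#'   `depth`. Defaults to a five-cohort human study (cortex
#'   discovery/reference, CSF discovery/reference, serum discovery) with
#'   10 AD vs 10 control samples each.
#' @param abundance_range_log10 span of baseline mean abundances in
#'   decades (default 5, the dynamic range typical of deep biofluid
#'   profiling).
#' @param n_signature number of planted cross-tissue signature proteins.
#' @param effect_size_sd AD mean shift for planted proteins, in units of
#'   the within-group noise SD.
#' @param mito_module_size,mito_module_rho size and equicorrelation of
#'   the co-varying mitochondrial block.
#' @param mito_band abundance-rank band (as fractions of the universe)
#'   into which the mitochondrial module is planted; the default
#'   (0.5, 0.7) puts it below mid-depth so shallow profiles miss it.
#' @param direction_map named signs giving the AD effect direction per
#'   tissue for planted proteins.
#' @param contamination_strength log2 units of marker-panel response per
#'   SD of the per-sample contamination score.
#' @param contamination_bleed fraction of `contamination_strength`
#'   applied to non-marker proteins.
#' @param marker_panel_size number of erythrocyte marker proteins (placed
#'   at the very top of the abundance range, as hemoglobin is).
#' @param n_outlier_samples number of grossly contaminated samples
#'   planted in the CSF discovery cohort.
#' @param outlier_shift contamination-score shift (in SD) of planted
#'   outlier samples.
#' @param noise_sd within-group log2 measurement noise SD.
#' @param mci_effect_frac fraction of the AD effect applied to MCI
#'   samples (MCI is intermediate; it never enters the AD-vs-Ctl test).
#' @param seed integer seed; the whole study is a deterministic function
#'   of the config including this seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       datasets = default_sim_datasets(),
                       abundance_range_log10 = 5,
                       n_signature = 20,
                       effect_size_sd = 1.5,
                       mito_module_size = 50,
                       mito_module_rho = 0.5,
                       mito_band = c(0.5, 0.7),
                       direction_map = c(cortex = 1, csf = -1, serum = -1),
                       contamination_strength = 1,
                       contamination_bleed = 0.05,
                       marker_panel_size = 5,
                       n_outlier_samples = 0,
                       outlier_shift = 5,
                       noise_sd = 0.5,
                       mci_effect_frac = 0.5,
                       seed = 1L) {
  datasets <- tibble::as_tibble(datasets)
  needed <- c("dataset_id", "tissue", "species", "cohort_role",
              "n_ad", "n_ctl", "n_mci", "depth")
  miss <- setdiff(needed, names(datasets))
  if (length(miss)) {
    abort(paste0("`datasets` missing columns: ", paste(miss, collapse = ", ")))
  }
  assert_scalar_number(n_proteins, "n_proteins", min = 10)
  assert_scalar_number(effect_size_sd, "effect_size_sd", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  if (mito_module_rho < 0 || mito_module_rho >= 1) {
    abort("`mito_module_rho` must be in [0, 1)")
  }
  if (any(datasets$depth > n_proteins)) {
    abort("dataset `depth` cannot exceed `n_proteins`")
  }
  if (mito_module_size + n_signature + marker_panel_size > n_proteins) {
    abort("planted sets larger than the protein universe")
  }
  if (length(mito_band) != 2L || mito_band[1] >= mito_band[2] ||
      mito_band[1] < 0 || mito_band[2] > 1) {
    abort("`mito_band` must be an increasing pair of fractions in [0, 1]")
  }
  if (mito_module_size > floor((mito_band[2] - mito_band[1]) * n_proteins)) {
    abort("mitochondrial module does not fit in `mito_band`")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    datasets = datasets,
    abundance_range_log10 = abundance_range_log10,
    n_signature = as.integer(n_signature),
    effect_size_sd = effect_size_sd,
    mito_module_size = as.integer(mito_module_size),
    mito_module_rho = mito_module_rho,
    mito_band = mito_band,
    direction_map = direction_map,
    contamination_strength = contamination_strength,
    contamination_bleed = contamination_bleed,
    marker_panel_size = as.integer(marker_panel_size),
    n_outlier_samples = as.integer(n_outlier_samples),
    outlier_shift = outlier_shift,
    noise_sd = noise_sd,
    mci_effect_frac = mci_effect_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default five-cohort study layout
#'
#' Two cortex cohorts (discovery + reference), two CSF cohorts
#' (discovery + reference, the reference shallower), and one serum
#' discovery cohort; 10 AD vs 10 Ctl each, human.
#'
#' @param n_proteins universe size the depths are scaled to.
#' @return A tibble with one row per dataset.
#' @export
default_sim_datasets <- function(n_proteins = 2000) {
  tibble::tibble(
    dataset_id = c("ctx_disc", "ctx_ref", "csf_disc", "csf_ref", "ser_disc"),
    tissue = c("cortex", "cortex", "csf", "csf", "serum"),
    species = "human",
    cohort_role = c("discovery", "reference", "discovery", "reference",
                    "discovery"),
    n_ad = 10L, n_ctl = 10L, n_mci = 0L,
    depth = as.integer(round(n_proteins * c(1, 0.8, 1, 0.5, 0.75)))
  )
}

#' Generate a synthetic multi-cohort study with planted ground truth
#'
#' Log2 intensities are drawn as an abundance baseline (evenly spaced on
#' log10 over the configured span, so depth censoring is rank-stable) plus
#' a group effect on planted proteins (signed by the tissue direction
#' map), a contamination covariate times per-protein loading, an
#' equicorrelated module factor inside the mitochondrial block, and
#' independent Gaussian noise. Only the top-`depth` proteins by baseline
#' abundance are observed in each dataset; intensities are exported as
#' `2^log2`.
#'
#' @param config a [sim_config()].
#' @return A list with `datasets` (named list of [proteome_dataset()]s)
#'   and `truth` (a `synthetic_truth` manifest: planted signature table
#'   with per-tissue signs, module / marker / outlier ids, per-dataset
#'   observed proteins, annotation table, and the seed).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  n <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))

  # abundance rank assignment: markers on top, module in its band,
  # signature spread over the well-observed top 40%
  ranks <- integer(n)
  marker_ids <- proteins[seq_len(config$marker_panel_size)]
  sig_ids <- proteins[seq_len(config$n_signature) + config$marker_panel_size]
  mod_ids <- proteins[seq_len(config$mito_module_size) +
                        config$marker_panel_size + config$n_signature]

  band_lo <- max(1L, ceiling(config$mito_band[1] * n))
  band_hi <- floor(config$mito_band[2] * n)
  rank_slots <- seq_len(n)
  marker_ranks <- seq_len(config$marker_panel_size)
  mod_ranks <- if (config$mito_module_size > 0) {
    sort(sample(setdiff(band_lo:band_hi, marker_ranks),
                config$mito_module_size))
  } else integer(0)
  top_pool <- setdiff(seq_len(floor(0.4 * n)), c(marker_ranks, mod_ranks))
  sig_ranks <- if (config$n_signature > 0) {
    sort(sample(top_pool, config$n_signature))
  } else integer(0)
  rest <- setdiff(rank_slots, c(marker_ranks, mod_ranks, sig_ranks))
  ranks[match(marker_ids, proteins)] <- marker_ranks
  ranks[match(mod_ids, proteins)] <- mod_ranks
  ranks[match(sig_ids, proteins)] <- sig_ranks
  others <- setdiff(proteins, c(marker_ids, mod_ids, sig_ids))
  ranks[match(others, proteins)] <- sample(rest)

  # evenly spaced baselines over the span, most abundant = rank 1
  log10_base <- 10 - (ranks - 1) / (n - 1) * config$abundance_range_log10
  log2_base <- log10_base * log2(10)
  names(log2_base) <- proteins

  effect <- config$effect_size_sd * config$noise_sd
  planted <- tibble::tibble(
    protein = c(sig_ids, mod_ids),
    role = rep(c("signature", "mito_module"),
               c(length(sig_ids), length(mod_ids)))
  )

  datasets <- vector("list", nrow(config$datasets))
  names(datasets) <- config$datasets$dataset_id
  observed <- vector("list", nrow(config$datasets))
  names(observed) <- config$datasets$dataset_id
  outlier_ids <- character(0)

  csf_disc_row <- which(config$datasets$tissue == "csf" &
                          config$datasets$cohort_role == "discovery")[1]

  for (d in seq_len(nrow(config$datasets))) {
    ds <- config$datasets[d, ]
    sign_d <- unname(config$direction_map[[ds$tissue]])
    n_samp <- ds$n_ad + ds$n_ctl + ds$n_mci
    sample_id <- sprintf("%s_S%02d", ds$dataset_id, seq_len(n_samp))
    group <- rep(c("AD", "Ctl", "MCI"), c(ds$n_ad, ds$n_ctl, ds$n_mci))

    gamma <- rnorm(n_samp)
    is_outlier <- rep(FALSE, n_samp)
    if (!is.na(csf_disc_row) && d == csf_disc_row &&
        config$n_outlier_samples > 0) {
      take <- sample(n_samp, config$n_outlier_samples)
      # contaminated samples sit AT +outlier_shift SD of the covariate
      gamma[take] <- config$outlier_shift
      is_outlier[take] <- TRUE
      outlier_ids <- c(outlier_ids, sample_id[take])
    }
    f <- rnorm(n_samp) # shared module factor

    delta <- numeric(n)
    delta[match(c(sig_ids, mod_ids), proteins)] <- sign_d * effect
    group_mult <- ifelse(group == "AD", 1,
                         ifelse(group == "MCI", config$mci_effect_frac, 0))

    lambda <- rep(config$contamination_bleed * config$contamination_strength, n)
    lambda[match(marker_ids, proteins)] <- config$contamination_strength

    eps <- matrix(rnorm(n * n_samp, sd = config$noise_sd), n, n_samp)
    in_mod <- proteins %in% mod_ids
    rho <- config$mito_module_rho
    if (rho > 0) {
      eps[in_mod, ] <- sqrt(1 - rho) * eps[in_mod, ] +
        sqrt(rho) * config$noise_sd *
          matrix(rep(f, each = sum(in_mod)), sum(in_mod), n_samp)
    }

    log2_mat <- matrix(log2_base, n, n_samp) +
      outer(delta, group_mult) +
      outer(lambda, gamma) +
      eps
    dimnames(log2_mat) <- list(proteins, sample_id)

    keep <- ranks <= ds$depth
    mat <- 2^log2_mat
    mat[!keep, ] <- NA_real_
    observed[[ds$dataset_id]] <- proteins[keep]

    datasets[[ds$dataset_id]] <- proteome_dataset(
      intensities = mat[keep, , drop = FALSE],
      sample_info = tibble::tibble(sample_id = sample_id, group = group,
                                   planted_outlier = is_outlier),
      dataset_id = ds$dataset_id,
      tissue = ds$tissue,
      species = ds$species,
      cohort_role = ds$cohort_role
    )
  }

  signature <- tidyr::expand_grid(
    protein = c(sig_ids, mod_ids),
    tissue = unique(config$datasets$tissue)
  )
  signature$sign <- unname(config$direction_map[signature$tissue])
  signature$effect_log2 <- signature$sign * effect

  annotation <- tibble::tibble(
    protein_id = proteins,
    gene_symbol = toupper(proteins),
    is_mitochondrial = proteins %in% mod_ids
  )
  class(annotation) <- c("protein_annotation", class(annotation))

  truth <- structure(list(
    signature_ids = sig_ids,
    mito_module_ids = mod_ids,
    planted = planted,
    signature_effects = signature,
    contamination_marker_ids = marker_ids,
    outlier_sample_ids = outlier_ids,
    observed_proteins = observed,
    abundance_rank = setNames(ranks, proteins),
    annotation = annotation,
    effect_log2 = effect,
    seed = config$seed
  ), class = "synthetic_truth")

  list(datasets = datasets, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d signature + %d module proteins, %d markers, %d planted outliers (seed %d)\n",
    length(x$signature_ids), length(x$mito_module_ids),
    length(x$contamination_marker_ids), length(x$outlier_sample_ids), x$seed))
  invisible(x)
}

#' Generate a mouse CSF counterpart of a synthetic study
#'
#' Emulates a small transgenic-amyloidosis (5xFAD vs wild-type) CSF
#' cohort sharing part of the human signature: a shallow (~1000-protein)
#' CSF dataset in which a configurable fraction of the planted signature
#' and module proteins carry the same CSF-direction effect (homolog
#' overlap); 5xFAD maps to the `AD` label and WT to `Ctl`.
#'
#' @param config the [sim_config()] used for the human study.
#' @param truth the `synthetic_truth` returned by [simulate_study()].
#' @param shared_fraction fraction of planted proteins carried over with
#'   the human CSF sign (1 = full homology, 0 = no shared biology).
#' @param depth number of proteins quantified.
#' @param n_ad,n_ctl group sizes (defaults 6 transgenic vs 5 wild-type).
#' @param seed seed for this dataset (derived from the study seed by
#'   default).
#' @return A [proteome_dataset()] with `dataset_id = "mouse_csf"`.
#' @export
simulate_mouse_counterpart <- function(config, truth, shared_fraction = 1,
                                       depth = 1000L, n_ad = 6L, n_ctl = 5L,
                                       seed = child_seed(config$seed, 99L)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1]")
  }
  if (depth > config$n_proteins) abort("`depth` cannot exceed the universe")
  with_seed(seed, {
    n <- config$n_proteins
    proteins <- names(truth$abundance_rank)
    ranks <- truth$abundance_rank
    planted_all <- c(truth$signature_ids, truth$mito_module_ids)
    n_shared <- round(shared_fraction * length(planted_all))
    shared <- if (n_shared > 0) sample(planted_all, n_shared) else character(0)

    effect <- truth$effect_log2
    sign_csf <- unname(config$direction_map[["csf"]])
    n_samp <- n_ad + n_ctl
    sample_id <- sprintf("mouse_csf_S%02d", seq_len(n_samp))
    group <- rep(c("AD", "Ctl"), c(n_ad, n_ctl))

    log2_base <- 10 * log2(10) -
      (ranks - 1) / (n - 1) * config$abundance_range_log10 * log2(10)
    delta <- numeric(n)
    delta[match(shared, proteins)] <- sign_csf * effect
    eps <- matrix(rnorm(n * n_samp, sd = config$noise_sd), n, n_samp)
    log2_mat <- matrix(log2_base, n, n_samp) +
      outer(delta, as.numeric(group == "AD")) + eps
    dimnames(log2_mat) <- list(proteins, sample_id)

    keep <- ranks <= depth
    mat <- 2^log2_mat[keep, , drop = FALSE]
    proteome_dataset(
      intensities = mat,
      sample_info = tibble::tibble(sample_id = sample_id, group = group),
      dataset_id = "mouse_csf",
      tissue = "csf",
      species = "mouse",
      cohort_role = "discovery"
    )
  })
}

#' Write a synthetic study to disk as a reloadable fixture bundle
#'
#' Writes each dataset's matrix and sample sheet TSV, the annotation
#' table, a `truth_*.tsv` set of manifests and a `manifest.txt` recording
#' the seed, so the whole bundle can be reloaded with
#' [read_fixture_bundle()] / [read_dataset()].
#'
#' @param datasets named list of [proteome_dataset()]s.
#' @param truth the matching `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(datasets, truth, dir) {
  if (!length(datasets)) abort("empty dataset list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(datasets)) {
    mp <- file.path(dir, paste0("matrix_", nm, ".tsv"))
    sp <- file.path(dir, paste0("samples_", nm, ".tsv"))
    write_dataset(datasets[[nm]], mp, sp)
    paths <- c(paths, mp, sp)
  }
  ann_path <- file.path(dir, "annotation.tsv")
  readr::write_tsv(truth$annotation, ann_path, progress = FALSE)
  sig_path <- file.path(dir, "truth_signature.tsv")
  readr::write_tsv(truth$signature_effects, sig_path, progress = FALSE)
  sets_path <- file.path(dir, "truth_sets.tsv")
  sets <- tibble::tibble(
    id = c(truth$signature_ids, truth$mito_module_ids,
           truth$contamination_marker_ids, truth$outlier_sample_ids),
    role = rep(c("signature", "mito_module", "contamination_marker",
                 "outlier_sample"),
               c(length(truth$signature_ids), length(truth$mito_module_ids),
                 length(truth$contamination_marker_ids),
                 length(truth$outlier_sample_ids))))
  readr::write_tsv(sets, sets_path, progress = FALSE)
  man_path <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("seed: %d", truth$seed),
    sprintf("n_datasets: %d", length(datasets)),
    sprintf("datasets: %s", paste(names(datasets), collapse = ", ")),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), man_path)
  invisible(c(paths, ann_path, sig_path, sets_path, man_path))
}

#' Reload the datasets of a fixture bundle
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return Named list of [proteome_dataset()]s.
#' @export
read_fixture_bundle <- function(dir) {
  mats <- sort(list.files(dir, pattern = "^matrix_.*\\.tsv$"))
  if (!length(mats)) abort("no matrix_*.tsv files found in bundle")
  ids <- sub("^matrix_(.*)\\.tsv$", "\\1", mats)
  out <- lapply(ids, function(id) {
    read_dataset(file.path(dir, paste0("matrix_", id, ".tsv")),
                 file.path(dir, paste0("samples_", id, ".tsv")))
  })
  names(out) <- ids
  out
}
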