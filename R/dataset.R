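#' Proteome dataset container
#'
#' A `proteome_dataset` bundles one cohort's protein-by-sample intensity
#' matrix with its sample sheet and dataset descriptors. Intensities are
#' strictly positive; missing quantifications are `NA` (never 0, which
#' would corrupt the log transform downstream).
#'
#' @param intensities numeric matrix, proteins in rows (rownames = protein
#'   ids), samples in columns (colnames = sample ids). `NA` marks a missing
#'   quantification; every present value must be > 0.
#' @param sample_info data frame with one row per sample: `sample_id`,
#'   `group` (one of `"AD"`, `"MCI"`, `"Ctl"`) and optional numeric
#'   covariate columns.
#' @param dataset_id short label for the cohort (e.g. `"csf_disc"`).
#' @param tissue one of `"cortex"`, `"csf"`, `"serum"`.
#' @param species one of `"human"`, `"mouse"`.
#' @param cohort_role one of `"discovery"`, `"reference"`.
#'
#' @return An object of class `proteome_dataset`: a list with elements
#'   `intensities`, `samples` (tibble), `dataset_id`, `tissue`, `species`,
#'   `cohort_role`.
#' @export
proteome_dataset <- function(intensities, sample_info, dataset_id,
                             tissue = c("cortex", "csf", "serum"),
                             species = c("human", "mouse"),
                             cohort_role = c("discovery", "reference")) {
  tissue <- match.arg(tissue)
  species <- match.arg(species)
  cohort_role <- match.arg(cohort_role)
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    abort("`intensities` must have protein rownames and sample colnames")
  }
  sample_info <- tibble::as_tibble(sample_info)
  if (!all(c("sample_id", "group") %in% names(sample_info))) {
    abort("`sample_info` must have columns `sample_id` and `group`")
  }
  x <- structure(
    list(
      intensities = intensities,
      samples = sample_info,
      dataset_id = as.character(dataset_id),
      tissue = tissue,
      species = species,
      cohort_role = cohort_role
    ),
    class = "proteome_dataset"
  )
  validate_proteome_dataset(x)
}

validate_proteome_dataset <- function(x) {
  prot <- rownames(x$intensities)
  samp <- colnames(x$intensities)
  dup_p <- unique(prot[duplicated(prot)])
  if (length(dup_p)) {
    abort(paste0("duplicate protein ids: ", paste(dup_p, collapse = ", ")))
  }
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s)) {
    abort(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  if (!identical(samp, as.character(x$samples$sample_id))) {
    abort("sample sheet order/ids must match intensity matrix columns")
  }
  bad_grp <- setdiff(unique(as.character(x$samples$group)),
                     c("AD", "MCI", "Ctl"))
  if (length(bad_grp)) {
    abort(paste0("unknown group label: ", paste(bad_grp, collapse = ", "),
                 " (allowed: AD, MCI, Ctl)"))
  }
  v <- x$intensities
  if (any(!is.na(v) & v <= 0)) {
    idx <- which(!is.na(v) & v <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "nonpositive intensity at protein %s, sample %s (missing must be NA, never 0)",
      prot[idx[1L]], samp[idx[2L]]))
  }
  x
}

#' @export
print.proteome_dataset <- function(x, ...) {
  cat(sprintf(
    "<proteome_dataset '%s'> %s %s (%s cohort)\n  %d proteins x %d samples (%s)\n",
    x$dataset_id, x$species, x$tissue, x$cohort_role,
    nrow(x$intensities), ncol(x$intensities),
    paste(sprintf("%s=%d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.proteome_dataset <- function(x) dim(x$intensities)

#' Turn a proteome dataset into a long tibble
#'
#' @param x a `proteome_dataset`.
#' @param ... unused.
#' @return A tibble with columns `protein`, `sample_id`, `group`,
#'   `intensity` (missing quantifications dropped).
#' @export
tidy.proteome_dataset <- function(x, ...) {
  long <- tibble::tibble(
    protein = rep(rownames(x$intensities), times = ncol(x$intensities)),
    sample_id = rep(colnames(x$intensities), each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  long <- dplyr::filter(long, !is.na(.data$intensity))
  dplyr::left_join(long,
                   dplyr::select(x$samples, "sample_id", "group"),
                   by = "sample_id")
}

#' Read a proteome dataset from TSV files
#'
#' The matrix file is tab-delimited with protein ids in the first column
#' and one column per sample; empty cells or `NA` mark missing
#' quantifications. The sample sheet maps `sample_id` to `group` and the
#' dataset descriptors (`dataset_id`, `tissue`, `species`, `cohort_role`),
#' plus any numeric covariate columns. Row and column order are preserved
#' from file.
#'
#' @param matrix_path path to the intensity matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return A validated [proteome_dataset()].
#' @export
read_dataset <- function(matrix_path, sample_sheet_path) {
  mat_df <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_double(),
    protein = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  if (names(mat_df)[1L] != "protein") {
    abort("matrix file must have `protein` as its first column")
  }
  ss <- readr::read_tsv(sample_sheet_path, col_types = readr::cols(),
                        na = c("", "NA"), progress = FALSE)
  needed <- c("sample_id", "group", "dataset_id", "tissue", "species",
              "cohort_role")
  miss <- setdiff(needed, names(ss))
  if (length(miss)) {
    abort(paste0("sample sheet missing columns: ", paste(miss, collapse = ", ")))
  }
  mat <- as.matrix(mat_df[-1L])
  rownames(mat) <- mat_df$protein
  if (!identical(colnames(mat), as.character(ss$sample_id))) {
    abort("sample sheet rows must match matrix columns (same ids, same order)")
  }
  for (field in c("dataset_id", "tissue", "species", "cohort_role")) {
    if (length(unique(ss[[field]])) != 1L) {
      abort(sprintf("sample sheet column `%s` must be constant within a dataset",
                    field))
    }
  }
  proteome_dataset(
    intensities = mat,
    sample_info = ss[setdiff(names(ss),
                             c("dataset_id", "tissue", "species", "cohort_role"))],
    dataset_id = ss$dataset_id[1L],
    tissue = ss$tissue[1L],
    species = ss$species[1L],
    cohort_role = ss$cohort_role[1L]
  )
}

#' Write a proteome dataset to TSV files
#'
#' Inverse of [read_dataset()]: missing cells are written as the missing
#' token (default `"NA"`), never as 0.
#'
#' @param dataset a `proteome_dataset`.
#' @param matrix_path,sample_sheet_path output paths.
#' @param missing_token string written for missing cells.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_dataset <- function(dataset, matrix_path, sample_sheet_path,
                          missing_token = "NA") {
  stopifnot(inherits(dataset, "proteome_dataset"))
  mat_df <- tibble::as_tibble(dataset$intensities, rownames = "protein")
  readr::write_tsv(mat_df, matrix_path, na = missing_token, progress = FALSE)
  ss <- dplyr::mutate(dataset$samples,
                      dataset_id = dataset$dataset_id,
                      tissue = dataset$tissue,
                      species = dataset$species,
                      cohort_role = dataset$cohort_role)
  readr::write_tsv(ss, sample_sheet_path, na = missing_token, progress = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Read a protein annotation table
#'
#' Tab-delimited with header `protein_id`, `gene_symbol`,
#' `is_mitochondrial` (parsed from `true`/`false`/`1`/`0`) and optionally
#' `functional_class`. Proteins absent from the table are treated as
#' non-mitochondrial when queried through [is_mitochondrial()].
#'
#' @param path annotation TSV path.
#' @return A tibble of class `protein_annotation`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  needed <- c("protein_id", "gene_symbol", "is_mitochondrial")
  miss <- setdiff(needed, names(ann))
  if (length(miss)) {
    abort(paste0("annotation missing columns: ", paste(miss, collapse = ", ")))
  }
  dup <- unique(ann$protein_id[duplicated(ann$protein_id)])
  if (length(dup)) {
    abort(paste0("duplicate protein_id in annotation: ",
                 paste(dup, collapse = ", ")))
  }
  raw <- tolower(ann$is_mitochondrial)
  ok <- raw %in% c("true", "false", "1", "0")
  if (any(!ok)) {
    abort(sprintf("unparseable is_mitochondrial value '%s' for %s",
                  ann$is_mitochondrial[!ok][1L], ann$protein_id[!ok][1L]))
  }
  ann$is_mitochondrial <- raw %in% c("true", "1")
  class(ann) <- c("protein_annotation", class(ann))
  ann
}

#' Query the mitochondrial flag for protein ids
#'
#' @param annotation a `protein_annotation` tibble (from
#'   [read_annotation()] or built in code).
#' @param ids character vector of protein ids.
#' @return Logical vector; ids not present in the annotation are `FALSE`.
#' @export
is_mitochondrial <- function(annotation, ids) {
  idx <- match(ids, annotation$protein_id)
  flag <- annotation$is_mitochondrial[idx]
  flag[is.na(idx)] <- FALSE
  flag
}
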