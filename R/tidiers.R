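#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for proteorank result objects
#'
#' `tidy()` returns the per-protein (or per-set) table as a plain
#' tibble; `glance()` returns a one-row summary of the fit or run.
#'
#' @param x a result object.
#' @param ... unused.
#' @return A tibble.
#' @name tidy.de_result
NULL

#' @rdname tidy.de_result
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_tested = sum(!is.na(x$p_raw)),
    d0 = attr(x, "d0", exact = TRUE),
    s0sq = attr(x, "s0sq", exact = TRUE)
  )
}

#' @rdname tidy.de_result
#' @export
tidy.integrated_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.de_result
#' @export
glance.integrated_ranking <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    B = attr(x, "B", exact = TRUE),
    seed = attr(x, "seed", exact = TRUE),
    n_fdr05 = sum(x$fdr < 0.05, na.rm = TRUE)
  )
}

#' @rdname tidy.de_result
#' @export
tidy.overlap_report <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$members <- NULL
  out$sets_in <- NULL
  out
}

#' @rdname tidy.de_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$leading_edge <- vapply(x$leading_edge, function(m) {
    paste(m, collapse = ";")
  }, "")
  out
}

#' @rdname tidy.de_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_enriched = sum(x$enriched),
    B = attr(x, "B", exact = TRUE),
    weight = attr(x, "weight", exact = TRUE)
  )
}

#' @rdname tidy.de_result
#' @export
tidy.depth_curve <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.de_result
#' @export
glance.depth_curve <- function(x, ...) {
  tibble::tibble(
    set_size = attr(x, "set_size", exact = TRUE),
    median_rank = attr(x, "median_rank", exact = TRUE)
  )
}

#' @rdname tidy.de_result
#' @export
tidy.pca_qc <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.de_result
#' @export
glance.pca_qc <- function(x, ...) {
  ve <- attr(x, "var_explained", exact = TRUE)
  tibble::tibble(var_pc1 = ve[1], var_pc2 = ve[2])
}
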