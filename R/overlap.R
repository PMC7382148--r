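#' Venn decomposition of named DE protein sets
#'
#' Decomposes 2-4 named sets into their exclusive Venn regions, with
#' deterministic (lexicographic) member ordering. When a `universe` size
#' is supplied, every pairwise overlap additionally gets an upper-tail
#' hypergeometric enrichment p-value as context (the counts themselves
#' carry the biology; the p-value is labeled added context).
#'
#' @param sets named list of 2-4 character vectors.
#' @param universe optional integer: size of the common quantified
#'   universe for the hypergeometric context test.
#' @return A tibble of class `overlap_report` with columns `region`
#'   (e.g. `"A&B"`), `sets_in` (list-column), `n`, `members`
#'   (list-column); attributes `set_sizes` and (if `universe` given)
#'   `pairwise` (tibble with overlap counts and hypergeometric p).
#' @export
overlap_de_sets <- function(sets, universe = NULL) {
  if (length(sets) < 2L || length(sets) > 4L) {
    abort("between 2 and 4 named sets are required")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named")
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) {
    abort(paste0("duplicate set names: ", paste(dup, collapse = ", ")))
  }
  sets <- lapply(sets, unique)
  all_ids <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  regions <- split(all_ids, pattern)

  # enumerate all non-empty membership patterns so empty regions show 0
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)
  }))
  out <- tibble::tibble(
    region = combos,
    sets_in = strsplit(combos, "&", fixed = TRUE),
    n = vapply(combos, function(cc) length(regions[[cc]] %||% character(0)),
               0L, USE.NAMES = FALSE),
    members = lapply(combos, function(cc) regions[[cc]] %||% character(0))
  )

  pairwise <- NULL
  if (!is.null(universe) && length(sets) >= 2L) {
    pr <- utils::combn(names(sets), 2L, simplify = FALSE)
    pairwise <- purrr::map_dfr(pr, function(p) {
      a <- sets[[p[1]]]; b <- sets[[p[2]]]
      ov <- length(intersect(a, b))
      tibble::tibble(
        set_a = p[1], set_b = p[2],
        n_a = length(a), n_b = length(b), overlap = ov,
        p_hyper = phyper(ov - 1L, length(a), universe - length(a),
                         length(b), lower.tail = FALSE)
      )
    })
  }
  structure(out,
            set_sizes = vapply(sets, length, 0L),
            n_union = length(all_ids),
            pairwise = pairwise,
            class = c("overlap_report", class(out)))
}

#' @export
print.overlap_report <- function(x, ...) {
  sz <- attr(x, "set_sizes")
  cat(sprintf("<overlap_report> %s; union %d\n",
              paste(sprintf("%s=%d", names(sz), sz), collapse = ", "),
              attr(x, "n_union")))
  print(tibble::as_tibble(x[c("region", "n",
                              intersect(c("n_mito", "pct_mito"), names(x)))]))
  invisible(x)
}

#' Classify the cross-tissue direction pattern of one protein
#'
#' Given the Z-scored fold changes of a protein in several tissues,
#' labels the pattern: consistent increase or decrease everywhere,
#' cortex moving against the biofluids (CSF/serum agreeing with each
#' other, the amyloid-peptide-like pattern), or mixed.
#'
#' @param z named numeric vector with names among `cortex`, `csf`,
#'   `serum`; at least two non-missing entries required.
#' @return One of `"all-up"`, `"all-down"`, `"cortex-up/fluid-down"`,
#'   `"cortex-down/fluid-up"`, `"mixed"`.
#' @export
direction_pattern <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 2L) abort("need Z in at least two tissues")
  bad <- setdiff(names(z), c("cortex", "csf", "serum"))
  if (length(bad)) abort(paste0("unknown tissue: ", paste(bad, collapse = ", ")))
  s <- sign(z)
  if (all(s > 0)) return("all-up")
  if (all(s < 0)) return("all-down")
  fluid <- s[names(s) %in% c("csf", "serum")]
  ctx <- s[names(s) == "cortex"]
  if (length(ctx) == 1L && length(fluid) >= 1L &&
      length(unique(fluid)) == 1L && unique(fluid) != ctx) {
    return(if (ctx > 0) "cortex-up/fluid-down" else "cortex-down/fluid-up")
  }
  "mixed"
}

#' Attach mitochondrial fractions to an overlap report
#'
#' Per Venn region: count of members flagged mitochondrial and the
#' fraction (full precision in `frac_mito`, half-up integer percent in
#' `pct_mito` for display; empty regions report missing).
#'
#' @param report an `overlap_report`.
#' @param annotation a `protein_annotation` table.
#' @return The report with columns `n_mito`, `frac_mito`, `pct_mito`
#'   added.
#' @export
annotate_overlap <- function(report, annotation) {
  stopifnot(inherits(report, "overlap_report"))
  n_mito <- vapply(report$members, function(m) {
    sum(is_mitochondrial(annotation, m))
  }, 0L, USE.NAMES = FALSE)
  frac <- ifelse(report$n > 0, n_mito / report$n, NA_real_)
  report$n_mito <- n_mito
  report$frac_mito <- frac
  report$pct_mito <- ifelse(is.na(frac), NA_real_, floor(frac * 100 + 0.5))
  report
}
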