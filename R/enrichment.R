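#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then members. Members are
#' deduplicated within a set; duplicate set names and lines with fewer
#' than 3 fields are errors.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors with
#'   a `description` attribute per set.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    abort(paste0("duplicate set name in GMT: ", paste(dup, collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  structure(sets,
            description = setNames(vapply(parts, `[[`, "", 2L), nm),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list of character vectors (or a
#'   `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(collection, "description") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Weighted KS running-sum extremum from hit positions only (O(set size)).
# positions: sorted 1-based ranks of the hits; w: matching weights.
es_from_positions <- function(positions, w, n_total) {
  m <- length(positions)
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1, m) # all-zero weights fall back to unweighted
  wsum <- sum(w)
  miss_step <- 1 / (n_total - m)
  cum_hit <- cumsum(w) / wsum
  k <- seq_len(m)
  # running sum just after each hit, and just before each hit
  after <- cum_hit - (positions - k) * miss_step
  before <- c(0, cum_hit[-m]) - (positions - k) * miss_step
  hi <- max(after)
  lo <- min(before)
  es <- if (hi >= -lo) hi else lo
  list(es = es, hi = hi, lo = lo,
       peak_pos = which.max(after), peak_neg = which.min(before))
}

#' GSEA-style enrichment score of a set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum over the ranking: hits
#' increment proportionally to `|score|^weight`, misses decrement
#' `1/(N - n_set)`; the enrichment score is the signed maximum
#' deviation. With `weight = 0` this is the classical (unweighted) KS
#' walk.
#'
#' @param ranking an `integrated_ranking`, a `ranked_list`, or a
#'   character vector of proteins ordered most-significant first.
#' @param set character vector of member ids.
#' @param weight weight exponent on the per-protein score (default 1).
#' @param scores per-protein scores aligned with the ranking; defaults
#'   to `-log10(p_emp)` when the ranking carries empirical p-values,
#'   else to the reversed rank.
#' @return List with `es`, `leading_edge` (members at or before the
#'   extremum on the enriched side) and `n_hits`.
#' @export
enrichment_score <- function(ranking, set, weight = 1, scores = NULL) {
  proteins <- ranking_proteins(ranking)
  if (is.null(scores)) scores <- ranking_scores(ranking)
  n <- length(proteins)
  hits <- which(proteins %in% set)
  if (!length(hits)) abort("empty intersection between set and ranking")
  if (length(hits) == n) abort("set equals universe: enrichment undefined")
  w <- abs(scores[hits])^weight
  prof <- es_from_positions(hits, w, n)
  leading <- if (prof$es >= 0) {
    proteins[hits[seq_len(prof$peak_pos)]]
  } else {
    proteins[hits[prof$peak_neg:length(hits)]]
  }
  list(es = prof$es, leading_edge = leading, n_hits = length(hits))
}

ranking_proteins <- function(ranking) {
  if (is.character(ranking)) return(ranking)
  if (is.data.frame(ranking) && "protein" %in% names(ranking)) {
    return(ranking$protein)
  }
  abort("`ranking` must be a ranked table with a `protein` column or a character vector")
}

ranking_scores <- function(ranking) {
  if (is.data.frame(ranking) && "p_emp" %in% names(ranking)) {
    return(-log10(pmax(ranking$p_emp, .Machine$double.xmin)))
  }
  n <- length(ranking_proteins(ranking))
  rev(seq_len(n)) / n
}

#' Set-permutation enrichment over a gene-set collection
#'
#' For every set (after size filtering against the ranked universe), the
#' observed enrichment score is compared with null scores of `B` random
#' same-size sets drawn from the universe; the empirical p uses the
#' add-one rule on `|es|`, and BH across sets gives the FDR. Sets with
#' `fdr < 0.05` are flagged enriched.
#'
#' @param ranking as in [enrichment_score()].
#' @param collection a `gene_set_collection` or named list of id
#'   vectors.
#' @param B permutations per set size (study default 1000).
#' @param seed integer seed.
#' @param weight weight exponent (default 1).
#' @param min_size,max_size set-size filter after intersection with the
#'   universe.
#' @return A tibble of class `enrichment_result` with columns `set`,
#'   `size`, `es`, `p_emp`, `fdr`, `enriched`, `leading_edge`
#'   (list-column).
#' @export
run_enrichment <- function(ranking, collection, B = 1000, seed = 1L,
                           weight = 1, min_size = 5, max_size = Inf) {
  assert_scalar_number(B, "B", min = 1)
  proteins <- ranking_proteins(ranking)
  scores <- ranking_scores(ranking)
  n <- length(proteins)
  sets <- lapply(collection, function(s) intersect(s, proteins))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) abort("no set passes the size filter")
  sets <- sets[keep]
  sizes <- sizes[keep]

  obs <- lapply(sets, function(s) enrichment_score(proteins, s,
                                                   weight = weight,
                                                   scores = scores))
  es_obs <- vapply(obs, `[[`, 0, "es")

  null_by_size <- with_seed(seed, {
    out <- list()
    for (m in sort(unique(sizes))) {
      out[[as.character(m)]] <- vapply(seq_len(B), function(b) {
        hits <- sort(sample.int(n, m))
        es_from_positions(hits, abs(scores[hits])^weight, n)$es
      }, 0)
    }
    out
  })

  p_emp <- vapply(seq_along(sets), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    (1 + sum(abs(null) >= abs(es_obs[i]))) / (1 + length(null))
  }, 0)
  fdr <- bh_adjust(p_emp)

  out <- tibble::tibble(
    set = names(sets),
    size = as.integer(sizes),
    es = es_obs,
    p_emp = p_emp,
    fdr = fdr,
    enriched = fdr < 0.05,
    leading_edge = lapply(obs, `[[`, "leading_edge")
  )
  structure(out, B = B, seed = seed, weight = weight,
            class = c("enrichment_result", class(out)))
}
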