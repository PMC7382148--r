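#' Significance-ordered ranked list for one dataset
#'
#' Orders proteins by ascending raw DE p-value (ties broken by
#' descending |Z|, then protein id) and normalizes ranks by the list
#' length, giving `r = rank / N` in `(0, 1]`.
#'
#' @param de a `de_result` from [fit_moderated_t()], or any data frame
#'   with columns `protein`, `p_raw` and optionally `z`.
#' @return A tibble of class `ranked_list` with columns `protein`,
#'   `rank`, `r`; the dataset id and `N` are attributes.
#' @export
rank_proteins <- function(de) {
  keep <- !is.na(de$p_raw)
  if (!any(keep)) abort("no protein with a defined p-value")
  d <- de[keep, , drop = FALSE]
  zmag <- if ("z" %in% names(d)) -abs(d$z) else rep(0, nrow(d))
  zmag[is.na(zmag)] <- 0
  ord <- order(d$p_raw, zmag, d$protein)
  n <- nrow(d)
  out <- tibble::tibble(
    protein = d$protein[ord],
    rank = seq_len(n),
    r = seq_len(n) / n
  )
  structure(out, N = n, dataset_id = attr(de, "dataset_id", exact = TRUE),
            class = c("ranked_list", class(out)))
}

ranked_list_from_order <- function(proteins, dataset_id = NULL) {
  n <- length(proteins)
  out <- tibble::tibble(protein = proteins, rank = seq_len(n), r = seq_len(n) / n)
  structure(out, N = n, dataset_id = dataset_id,
            class = c("ranked_list", class(out)))
}

#' Joint order-statistics Q for one protein's normalized ranks
#'
#' The probability that N independent uniforms have each sorted value at
#' or below the observed sorted normalized ranks: small Q marks a
#' protein consistently near the top across lists. Computed by the
#' alternating factorial recursion over the sorted ranks
#' (`V_0 = 1`, `V_k = sum_i (-1)^(i-1) r_(N-k+1)^i / i! V_(k-i)`,
#' `q = N! V_N`). This pure-R scalar version is the reference; the
#' permutation engine uses an equivalent compiled row-wise kernel.
#'
#' @param r sorted (nondecreasing) normalized ranks in `(0, 1]`.
#' @return Scalar q in `[0, 1]`.
#' @export
q_statistic <- function(r) {
  if (!length(r)) abort("empty rank tuple")
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
    abort("ranks must lie in (0, 1]")
  }
  if (is.unsorted(r)) abort("ranks must be sorted nondecreasing")
  n <- length(r)
  V <- numeric(n + 1)
  V[1] <- 1
  for (k in seq_len(n)) {
    rk <- r[n - k + 1]
    i <- seq_len(k)
    V[k + 1] <- sum((-1)^(i - 1) * rk^i / factorial(i) * V[k + 1 - i])
  }
  q <- factorial(n) * V[n + 1]
  min(max(q, 0), 1)
}

# Assemble the protein x list matrix of normalized ranks for a set of
# ranked lists (NA where a protein is absent from a list).
rank_matrix <- function(lists) {
  universe <- sort(unique(unlist(lapply(lists, function(l) l$protein))))
  mat <- matrix(NA_real_, length(universe), length(lists),
                dimnames = list(universe, names(lists)))
  for (j in seq_along(lists)) {
    l <- lists[[j]]
    mat[match(l$protein, universe), j] <- l$r
  }
  mat
}

#' Permutation null for the order-statistics Q
#'
#' Protein labels are shuffled independently within every list `B`
#' times; the Q of every protein is recomputed for each shuffle. Null
#' samples are pooled per `n_avail` stratum (number of lists a protein
#' appears in), since the scale of Q depends on how many ranks enter it.
#'
#' @param lists named list of `ranked_list`s.
#' @param B number of permutations (study default 1000).
#' @param seed integer seed; results are deterministic given it.
#' @return Named list (by `n_avail`) of numeric null-Q vectors.
#' @export
permutation_null <- function(lists, B = 1000, seed = 1L) {
  assert_scalar_number(B, "B", min = 1)
  mat <- rank_matrix(lists)
  with_seed(seed, permutation_null_impl(mat, B))
}

permutation_null_impl <- function(mat, B) {
  n_avail <- rowSums(!is.na(mat))
  strata <- sort(unique(n_avail[n_avail > 0]))
  null <- lapply(strata, function(s) vector("list", B))
  names(null) <- as.character(strata)
  perm <- mat
  for (b in seq_len(B)) {
    for (j in seq_len(ncol(mat))) {
      obs <- which(!is.na(mat[, j]))
      perm[obs, j] <- mat[obs[sample.int(length(obs))], j]
    }
    qb <- q_stat_rows(perm)
    for (s in strata) {
      null[[as.character(s)]][[b]] <- qb[n_avail == s]
    }
  }
  lapply(null, function(x) unlist(x, use.names = FALSE))
}

#' Empirical p-value of a Q against its permutation null
#'
#' Add-one rule: `p = (1 + #(null <= q)) / (1 + #null)`, never zero, so
#' BH adjustment downstream is well-defined.
#'
#' @param q observed Q value(s).
#' @param null_samples null Q samples for the matching `n_avail`
#'   stratum.
#' @return Empirical p-value(s) in `(0, 1]`.
#' @export
empirical_p <- function(q, null_samples) {
  if (!length(null_samples)) abort("empty null stratum")
  sorted <- sort(null_samples)
  (1 + findInterval(q, sorted)) / (1 + length(sorted))
}

#' Combine ranked lists by order statistics with a permutation null
#'
#' The level primitive of the tiered integration: per protein, Q over
#' its available normalized ranks; an empirical p against the
#' within-stratum permutation null; output re-ranked by ascending
#' empirical p (ties by Q, then protein id).
#'
#' @param lists named list of `ranked_list`s.
#' @param B permutations for the null.
#' @param seed integer seed.
#' @param name label for the combined list.
#' @return A `ranked_list` with extra columns `q`, `p_emp`, `n_avail`.
#' @export
combine_ranked_lists <- function(lists, B = 1000, seed = 1L, name = NULL) {
  if (length(lists) == 1L) {
    l <- lists[[1L]]
    out <- tibble::tibble(protein = l$protein, rank = l$rank, r = l$r,
                          q = l$r, p_emp = l$r, n_avail = 1L)
    return(structure(out, N = nrow(out), dataset_id = name,
                     class = c("ranked_list", class(out))))
  }
  mat <- rank_matrix(lists)
  n_avail <- rowSums(!is.na(mat))
  q <- q_stat_rows(mat)
  null <- with_seed(seed, permutation_null_impl(mat, B))
  p_emp <- rep(NA_real_, length(q))
  for (s in names(null)) {
    idx <- which(n_avail == as.integer(s))
    p_emp[idx] <- empirical_p(q[idx], null[[s]])
  }
  ord <- order(p_emp, q, rownames(mat))
  n <- length(ord)
  out <- tibble::tibble(
    protein = rownames(mat)[ord],
    rank = seq_len(n),
    r = seq_len(n) / n,
    q = q[ord],
    p_emp = p_emp[ord],
    n_avail = as.integer(n_avail[ord])
  )
  structure(out, N = n, dataset_id = name,
            class = c("ranked_list", class(out)))
}

#' Retain proteins with biofluid DE evidence
#'
#' The pre-final filter of the tiered integration: a protein survives if
#' it shows at least nominal evidence of change (`p_raw < p_max`) in at
#' least one CSF or serum dataset; proteins without any biofluid change
#' are dropped before the final integration.
#'
#' @param universe protein ids entering the final level.
#' @param csf_de,serum_de lists of `de_result`s for CSF and serum
#'   datasets.
#' @param p_max nominal evidence threshold (default 0.05).
#' @return Character vector of retained protein ids.
#' @export
filter_unchanged <- function(universe, csf_de, serum_de, p_max = 0.05) {
  evidence <- character(0)
  for (de in c(csf_de, serum_de)) {
    hit <- de$protein[!is.na(de$p_raw) & de$p_raw < p_max]
    evidence <- union(evidence, hit)
  }
  retained <- intersect(universe, evidence)
  if (!length(retained)) abort("filter removed all proteins")
  retained
}

#' Tier plan for hierarchical integration
#'
#' Level 1 consolidates cohorts of the same tissue and role (discovery
#' vs reference separately); level 2 merges the level-1 groups of each
#' tissue; level 3 integrates the tissue rankings into the final list
#' after the biofluid-change filter.
#'
#' @param level1 named list: group name -> dataset ids.
#' @param level2 named list: tissue name -> level-1 group names.
#' @return A `tier_plan` list.
#' @export
tier_plan <- function(level1, level2) {
  all_ds <- unlist(level1, use.names = FALSE)
  dup <- unique(all_ds[duplicated(all_ds)])
  if (length(dup)) {
    abort(paste0("dataset in more than one level-1 group: ",
                 paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unlist(level2, use.names = FALSE), names(level1))
  if (length(bad)) {
    abort(paste0("level-2 references unknown level-1 group: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(level1 = level1, level2 = level2), class = "tier_plan")
}

#' Default tier plan for a set of datasets
#'
#' Groups datasets by tissue and cohort role at level 1 and by tissue at
#' level 2.
#'
#' @param info data frame with columns `dataset_id`, `tissue`,
#'   `cohort_role` (e.g. the `datasets` table of a [sim_config()]).
#' @return A [tier_plan()].
#' @export
default_tier_plan <- function(info) {
  key <- paste(info$tissue, substr(info$cohort_role, 1, 4), sep = "_")
  level1 <- split(info$dataset_id, key)
  tissues <- split(names(level1),
                   vapply(strsplit(names(level1), "_"), `[[`, "", 1L))
  tier_plan(level1 = level1, level2 = tissues)
}

#' Three-step tiered integration of per-dataset rankings
#'
#' Cohort rankings are consolidated within level-1 groups, the groups
#' merged into per-tissue rankings, and — after dropping proteins with
#' no evidence of change in any CSF or serum dataset — the tissue
#' rankings are integrated into the final list. Each combination step
#' uses the order-statistics Q with its own permutation null and
#' empirical p; the final level adds BH FDR and the final rank. When a
#' protein set `keep` is supplied, the tissue rankings are subset to it
#' and re-normalized before the final integration.
#'
#' @param lists named list of per-dataset `ranked_list`s (names =
#'   dataset ids).
#' @param plan a [tier_plan()] covering every list.
#' @param B permutations per combination step (study default 1000).
#' @param seed integer seed; level seeds are derived from it.
#' @param keep optional protein ids surviving the pre-final filter
#'   (from [filter_unchanged()]); `NULL` keeps everything.
#' @return A tibble of class `integrated_ranking` with columns
#'   `protein`, `n_avail`, `q`, `p_emp`, `fdr`, `final_rank`, plus one
#'   `rank_<tissue>` column per level-2 group; attributes `B`, `seed`,
#'   `levels` (the intermediate `ranked_list`s).
#' @export
tiered_integration <- function(lists, plan, B = 1000, seed = 1L, keep = NULL) {
  stopifnot(inherits(plan, "tier_plan"))
  missing_ds <- setdiff(unlist(plan$level1, use.names = FALSE), names(lists))
  if (length(missing_ds)) {
    abort(paste0("plan names datasets with no ranked list: ",
                 paste(missing_ds, collapse = ", ")))
  }
  uncovered <- setdiff(names(lists), unlist(plan$level1, use.names = FALSE))
  if (length(uncovered)) {
    abort(paste0("plan missing datasets: ", paste(uncovered, collapse = ", ")))
  }

  l1 <- vector("list", length(plan$level1))
  names(l1) <- names(plan$level1)
  for (g in names(plan$level1)) {
    l1[[g]] <- combine_ranked_lists(lists[plan$level1[[g]]], B = B,
                                    seed = child_seed(seed, match(g, names(plan$level1))),
                                    name = g)
  }
  l2 <- vector("list", length(plan$level2))
  names(l2) <- names(plan$level2)
  for (t in names(plan$level2)) {
    l2[[t]] <- combine_ranked_lists(l1[plan$level2[[t]]], B = B,
                                    seed = child_seed(seed, 100L + match(t, names(plan$level2))),
                                    name = t)
  }

  l2_final <- l2
  if (!is.null(keep)) {
    l2_final <- lapply(l2, function(l) {
      ranked_list_from_order(l$protein[l$protein %in% keep],
                             dataset_id = attr(l, "dataset_id", exact = TRUE))
    })
    l2_final <- l2_final[vapply(l2_final, nrow, 0L) > 0L]
    if (!length(l2_final)) abort("filter removed all proteins")
  }
  final <- combine_ranked_lists(l2_final, B = B,
                                seed = child_seed(seed, 1000L),
                                name = "final")

  out <- tibble::tibble(
    protein = final$protein,
    n_avail = final$n_avail,
    q = final$q,
    p_emp = final$p_emp,
    fdr = bh_adjust(final$p_emp),
    final_rank = final$rank
  )
  for (t in names(l2)) {
    out[[paste0("rank_", t)]] <- l2[[t]]$rank[match(out$protein, l2[[t]]$protein)]
  }
  structure(out, B = B, seed = seed,
            levels = list(level1 = l1, level2 = l2),
            class = c("integrated_ranking", class(out)))
}

#' @export
print.integrated_ranking <- function(x, ...) {
  cat(sprintf("<integrated_ranking> %d proteins (B = %d, seed = %d)\nTop of the list:\n",
              nrow(x), attr(x, "B"), attr(x, "seed")))
  print(tibble::as_tibble(head(x, 5L)))
  invisible(x)
}
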