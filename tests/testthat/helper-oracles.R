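# Independent oracles and small fixture builders shared across tests.

# Brute-force step-up BH: sort, scale by n/i, cumulative min from the
# bottom, cap at 1, unsort.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Textbook pooled two-sample t (equal-variance), two-sided p.
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * pt(abs(tt), nx + ny - 2, lower.tail = FALSE),
       df = nx + ny - 2)
}

# Vectorized pooled t p-values over matrix rows (complete data).
row_pooled_p <- function(mat, groups) {
  a <- mat[, groups == "AD", drop = FALSE]
  b <- mat[, groups == "Ctl", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
    (na + nb - 2)
  tt <- (rowMeans(a) - rowMeans(b)) / sqrt(s2 * (1 / na + 1 / nb))
  2 * pt(abs(tt), na + nb - 2, lower.tail = FALSE)
}

# Vectorized row sort for small column counts via a bubble
# compare-exchange network (used by the Monte-Carlo q oracle, where
# apply() would be too slow on 1e6 rows).
sort_rows_small <- function(m) {
  k <- ncol(m)
  for (pass in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      lo <- pmin(m[, j], m[, j + 1])
      hi <- pmax(m[, j], m[, j + 1])
      m[, j] <- lo
      m[, j + 1] <- hi
    }
  }
  m
}

# Monte-Carlo estimate of P(U_(i) <= r_i for all i) given a matrix of
# pre-sorted uniform tuples.
mc_q_from_sorted <- function(sorted_u, r) {
  ok <- rep(TRUE, nrow(sorted_u))
  for (j in seq_along(r)) ok <- ok & (sorted_u[, j] <= r[j])
  mean(ok)
}

# Brute-force Venn decomposition by per-element membership enumeration.
brute_venn_counts <- function(sets) {
  ids <- sort(unique(unlist(sets)))
  pat <- vapply(ids, function(id) {
    paste(names(sets)[vapply(sets, function(s) id %in% s, TRUE)],
          collapse = "&")
  }, "")
  table(pat)
}

# Brute-force unweighted KS running sum over a full ranking.
brute_ks_es <- function(proteins, set) {
  n <- length(proteins)
  m <- sum(proteins %in% set)
  step <- ifelse(proteins %in% set, 1 / m, -1 / (n - m))
  walk <- cumsum(step)
  walk[which.max(abs(walk))]
}

# A small valid proteome dataset with optional missing cells.
make_test_dataset <- function(n_prot = 6, n_samp = 4, seed = 1,
                              missing = 0, groups = NULL) {
  set.seed(seed)
  mat <- matrix(2^rnorm(n_prot * n_samp, mean = 10), n_prot, n_samp,
                dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                                sprintf("S%02d", seq_len(n_samp))))
  if (missing > 0) {
    idx <- sample(length(mat), missing)
    mat[idx] <- NA_real_
  }
  if (is.null(groups)) {
    groups <- rep(c("AD", "Ctl"), length.out = n_samp)
  }
  proteome_dataset(
    intensities = mat,
    sample_info = tibble::tibble(sample_id = colnames(mat), group = groups,
                                 age = round(runif(n_samp, 60, 90))),
    dataset_id = "test_ds", tissue = "csf", species = "human",
    cohort_role = "discovery"
  )
}

# Compact simulated single-cortex-dataset config used by several tests.
one_dataset_config <- function(n_proteins, seed, tissue = "cortex", ...) {
  ds <- tibble::tibble(
    dataset_id = "d1", tissue = tissue, species = "human",
    cohort_role = "discovery", n_ad = 10L, n_ctl = 10L, n_mci = 0L,
    depth = as.integer(n_proteins)
  )
  sim_config(n_proteins = n_proteins, datasets = ds, seed = seed, ...)
}
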