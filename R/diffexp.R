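#' Empirical-Bayes moderated two-sample t-test (AD vs Ctl)
#'
#' Per protein, the AD-vs-Ctl log2 fold change is tested with the
#' standard moderated t: the pooled residual variance `s2` (df
#' `d = n_ad + n_ctl - 2`) is shrunk towards a prior `s0sq` with prior
#' degrees of freedom `d0`, giving `s2_tilde = (d0*s0sq + d*s2)/(d0 + d)`
#' and `t = log2fc / sqrt(s2_tilde * (1/n_ad + 1/n_ctl))` on `d + d0`
#' degrees of freedom. `d0` and `s0sq` are estimated by moment matching
#' on `log(s2)` (digamma/trigamma inversion by bisection); if the
#' trigamma equation has no positive root, `d0 = Inf` (full shrinkage).
#' MCI samples never enter the contrast. Fold changes are additionally
#' Z-standardized across proteins and BH-adjusted.
#'
#' @param corrected_matrix normalized (and residualized) log2 matrix.
#' @param groups named character vector of group labels (`AD`, `Ctl`,
#'   `MCI`) for the matrix columns.
#' @param d0 prior degrees of freedom; `NULL` (default) estimates it,
#'   a number forces it (0 gives the ordinary pooled t, `Inf` full
#'   shrinkage).
#' @param df_loss residual degrees of freedom consumed upstream per
#'   protein (1 when a covariate slope was regressed out of the matrix,
#'   0 otherwise); subtracted from `d` so the variance estimate and the
#'   t reference distribution stay calibrated. Implied by `covariate`.
#' @param covariate optional named per-sample covariate values that were
#'   residualized out of `corrected_matrix` upstream. When supplied, the
#'   standard error uses the exact analysis-of-covariance form
#'   `s2_tilde * (1/n_ad + 1/n_ctl + (xbar_ad - xbar_ctl)^2 / Sxx_within)`
#'   and one residual df is charged, so the test stays calibrated even
#'   when the covariate happens to align with the group split.
#' @return A tibble of class `de_result` with per-protein columns
#'   `protein`, `log2fc`, `z`, `t`, `p_raw`, `fdr`, `mean_abund`,
#'   `n_ad`, `n_ctl`, `s2`; estimated `d0` and `s0sq` are attributes.
#'   Proteins with fewer than 2 usable samples in either group carry
#'   missing statistics and are excluded from the Z standardization.
#' @export
fit_moderated_t <- function(corrected_matrix, groups, d0 = NULL,
                            df_loss = 0L, covariate = NULL) {
  if (is.null(names(groups))) {
    if (length(groups) != ncol(corrected_matrix)) {
      abort("`groups` must have one label per sample")
    }
    names(groups) <- colnames(corrected_matrix)
  }
  groups <- groups[colnames(corrected_matrix)]
  ad_cols <- which(groups == "AD")
  ctl_cols <- which(groups == "Ctl")
  if (!length(ad_cols) || !length(ctl_cols)) {
    abort("both AD and Ctl samples are required for the contrast")
  }
  mat_ad <- corrected_matrix[, ad_cols, drop = FALSE]
  mat_ctl <- corrected_matrix[, ctl_cols, drop = FALSE]

  n_ad <- rowSums(!is.na(mat_ad))
  n_ctl <- rowSums(!is.na(mat_ctl))
  mean_ad <- rowMeans(mat_ad, na.rm = TRUE)
  mean_ctl <- rowMeans(mat_ctl, na.rm = TRUE)
  log2fc <- mean_ad - mean_ctl

  ss_ad <- rowSums((mat_ad - mean_ad)^2, na.rm = TRUE)
  ss_ctl <- rowSums((mat_ctl - mean_ctl)^2, na.rm = TRUE)
  if (!is.null(covariate)) df_loss <- max(df_loss, 1L)
  d <- n_ad + n_ctl - 2 - df_loss
  ok <- n_ad >= 2L & n_ctl >= 2L & d >= 1L
  s2 <- ifelse(ok, (ss_ad + ss_ctl) / pmax(d, 1L), NA_real_)
  log2fc[!ok] <- NA_real_

  # unscaled variance of the contrast: plain two-sample, plus the
  # covariate-alignment term when a covariate slope was removed upstream
  v_contrast <- 1 / n_ad + 1 / n_ctl
  if (!is.null(covariate)) {
    x <- covariate[colnames(corrected_matrix)]
    if (anyNA(x)) abort("`covariate` must cover every sample")
    xbar_diff <- rowSums(sweep(!is.na(mat_ad), 2L, x[ad_cols], "*")) / n_ad -
      rowSums(sweep(!is.na(mat_ctl), 2L, x[ctl_cols], "*")) / n_ctl
    sxx_w <- rep(0, nrow(corrected_matrix))
    for (g in unique(groups)) {
      cols <- which(groups == g)
      m_g <- !is.na(corrected_matrix[, cols, drop = FALSE])
      n_g <- rowSums(m_g)
      sx <- rowSums(sweep(m_g, 2L, x[cols], "*"))
      sx2 <- rowSums(sweep(m_g, 2L, x[cols]^2, "*"))
      add <- ifelse(n_g > 0, sx2 - sx^2 / pmax(n_g, 1L), 0)
      sxx_w <- sxx_w + add
    }
    v_contrast <- v_contrast + ifelse(sxx_w > 0, xbar_diff^2 / sxx_w, 0)
  }

  if (is.null(d0)) {
    eb <- estimate_variance_prior(s2[ok & d > 0], d[ok & d > 0])
    d0 <- eb$d0
    s0sq <- eb$s0sq
  } else {
    if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0) {
      abort("`d0` must be a single number >= 0 (Inf allowed)")
    }
    s0sq <- if (d0 > 0) mean(s2[ok], na.rm = TRUE) else NA_real_
    if (is.infinite(d0) && is.na(s0sq)) s0sq <- 0
  }

  s2_tilde <- if (is.infinite(d0)) rep(s0sq, length(s2)) else if (d0 == 0) s2
              else (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * v_contrast)
  tstat <- log2fc / se
  df_total <- if (is.infinite(d0)) Inf else d + d0
  p_raw <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  p_raw[!ok] <- NA_real_
  tstat[!ok] <- NA_real_

  z <- rep(NA_real_, length(log2fc))
  defined <- which(ok & is.finite(log2fc))
  if (length(defined) >= 2L) {
    z[defined] <- z_transform_logfc(log2fc[defined])
  }

  out <- tibble::tibble(
    protein = rownames(corrected_matrix),
    log2fc = unname(log2fc),
    z = unname(z),
    t = unname(tstat),
    p_raw = unname(p_raw),
    fdr = unname(bh_adjust(p_raw)),
    mean_abund = unname(rowMeans(corrected_matrix, na.rm = TRUE)),
    n_ad = unname(n_ad), n_ctl = unname(n_ctl), s2 = unname(s2)
  )
  structure(out, d0 = d0, s0sq = s0sq,
            class = c("de_result", class(out)))
}

# Moment matching of the scaled inverse-chi-square variance prior on
# log(s2): follows the standard empirical-Bayes derivation (e_g =
# log s2_g - digamma(d_g/2) + log(d_g/2); trigamma(d0/2) solved by
# bisection to 1e-10).
estimate_variance_prior <- function(s2, d) {
  keep <- is.finite(s2) & s2 > 0 & d > 0
  s2 <- s2[keep]; d <- d[keep]
  n <- length(s2)
  if (n < 2L) return(list(d0 = 0, s0sq = if (n) mean(s2) else NA_real_))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(d / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    # no positive root: variances are less dispersed than any finite
    # prior allows -> full shrinkage
    return(list(d0 = Inf, s0sq = exp(ebar)))
  }
  half_d0 <- inv_trigamma(rhs)
  d0 <- 2 * half_d0
  s0sq <- exp(ebar + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0sq = s0sq)
}

# Monotone bisection inverse of trigamma on (0, Inf), tolerance 1e-10.
inv_trigamma <- function(y) {
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-10) break
  }
  sqrt(lo * hi)
}

#' Z-standardize a log2 fold-change vector
#'
#' `(x - mean(x)) / sd(x)` with the sample SD (n-1 denominator), across
#' proteins within one dataset.
#'
#' @param x numeric vector of log2 fold changes (>= 2 finite values).
#' @return Standardized vector (mean 0, SD 1).
#' @export
z_transform_logfc <- function(x) {
  if (sum(is.finite(x)) < 2L) abort("need at least 2 finite fold changes")
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("degenerate fold-change vector: zero SD")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement; missing p-values get
#' missing FDRs without affecting the others' adjustment.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression call specification
#'
#' Thresholds on the Z-scored fold change plus exactly one of a raw-p or
#' an FDR ceiling, with an optional direction restriction. Named presets
#' cover the cutoffs used throughout the analysis:
#' `"default"` (|Z| > 2 & FDR < 0.05), `"stringent"` (|Z| > 5 &
#' FDR < 0.01), `"nominal"` (|Z| > 2 & p < 0.05) and `"integration"`
#' (|Z| > 2 & FDR < 0.2).
#'
#' @param z_min positive threshold on |Z|.
#' @param p_max,fdr_max exactly one must be non-`NULL`.
#' @param direction `"both"`, `"up"` or `"down"` (sign of Z).
#' @return A `de_call_spec` list.
#' @export
de_call_spec <- function(z_min = 2, p_max = NULL, fdr_max = 0.05,
                         direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  assert_scalar_number(z_min, "z_min", min = 0, strict_min = TRUE)
  if (is.null(p_max) == is.null(fdr_max)) {
    abort("exactly one of `p_max` and `fdr_max` must be set")
  }
  structure(list(z_min = z_min, p_max = p_max, fdr_max = fdr_max,
                 direction = direction),
            class = "de_call_spec")
}

#' @rdname de_call_spec
#' @param preset one of `"default"`, `"stringent"`, `"nominal"`,
#'   `"integration"`.
#' @export
de_spec_preset <- function(preset = c("default", "stringent", "nominal",
                                      "integration")) {
  switch(match.arg(preset),
    default = de_call_spec(z_min = 2, fdr_max = 0.05),
    stringent = de_call_spec(z_min = 5, fdr_max = 0.01),
    nominal = de_call_spec(z_min = 2, p_max = 0.05, fdr_max = NULL),
    integration = de_call_spec(z_min = 2, fdr_max = 0.2)
  )
}

#' Call differentially expressed proteins
#'
#' @param de a `de_result` from [fit_moderated_t()].
#' @param spec a [de_call_spec()].
#' @return Character vector of protein ids passing the thresholds.
#' @export
call_de <- function(de, spec = de_call_spec()) {
  stopifnot(inherits(spec, "de_call_spec"))
  sig <- !is.na(de$z) & abs(de$z) > spec$z_min
  if (!is.null(spec$fdr_max)) {
    sig <- sig & !is.na(de$fdr) & de$fdr < spec$fdr_max
  } else {
    sig <- sig & !is.na(de$p_raw) & de$p_raw < spec$p_max
  }
  if (spec$direction == "up") sig <- sig & de$z > 0
  if (spec$direction == "down") sig <- sig & de$z < 0
  de$protein[sig]
}

#' Rank proteins by mean abundance
#'
#' Rank 1 is the most abundant protein by mean log2 intensity; ties are
#' broken by lexicographic protein id, so the ranking is deterministic.
#'
#' @param corrected_matrix log2 matrix (proteins x samples).
#' @return Named integer vector of ranks.
#' @export
abundance_rank <- function(corrected_matrix) {
  if (!nrow(corrected_matrix)) abort("empty matrix")
  m <- rowMeans(corrected_matrix, na.rm = TRUE)
  ord <- order(-m, rownames(corrected_matrix))
  ranks <- integer(length(m))
  ranks[ord] <- seq_along(ord)
  setNames(ranks, rownames(corrected_matrix))
}

#' Detectability of a protein set as a function of profiling depth
#'
#' For each depth cutoff, how many members of a query set fall within
#' the top-depth most abundant proteins. Low-abundance sets (such as the
#' mitochondrial module in CSF) only become detectable under deep
#' profiling.
#'
#' @param query_set protein ids (must all be present in the ranking).
#' @param abundance_ranks named ranks from [abundance_rank()].
#' @param depth_grid increasing depth cutoffs.
#' @return A tibble of class `depth_curve` with columns `depth`,
#'   `detected`, `fraction`; the set's median abundance rank is in
#'   attribute `median_rank`.
#' @export
depth_detection_curve <- function(query_set, abundance_ranks, depth_grid) {
  missing_ids <- setdiff(query_set, names(abundance_ranks))
  if (length(missing_ids)) {
    abort(paste0("query protein absent from ranking: ",
                 paste(head(missing_ids, 5L), collapse = ", ")))
  }
  r <- abundance_ranks[query_set]
  out <- tibble::tibble(
    depth = as.numeric(depth_grid),
    detected = vapply(depth_grid, function(d) sum(r <= d), numeric(1)),
    fraction = vapply(depth_grid, function(d) mean(r <= d), numeric(1))
  )
  structure(out, median_rank = median(r), set_size = length(query_set),
            class = c("depth_curve", class(out)))
}

#' Pearson correlation between two quantifications of the same samples
#'
#' Used to compare an orthogonal assay (targeted MS, ELISA) against the
#' discovery quantification over shared samples.
#'
#' @param quant_a,quant_b numeric vectors; pairs with a missing value in
#'   either are dropped (>= 3 complete pairs required).
#' @return Pearson r (scalar), with the number of pairs as attribute
#'   `n`.
#' @export
validation_correlation <- function(quant_a, quant_b) {
  if (length(quant_a) != length(quant_b)) abort("vectors must be paired")
  ok <- is.finite(quant_a) & is.finite(quant_b)
  if (sum(ok) < 3L) abort("need at least 3 complete pairs")
  a <- quant_a[ok]; b <- quant_b[ok]
  if (sd(a) == 0 || sd(b) == 0) abort("zero variance in a quantification")
  structure(cor(a, b), n = sum(ok))
}
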