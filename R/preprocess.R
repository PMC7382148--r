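#' Log2-transform and median-center a proteome matrix
#'
#' Elementwise log2 followed by median-centering of every sample column;
#' missing cells stay missing. Median-centering is idempotent: feeding
#' back `2^normalized` returns the same matrix.
#'
#' @param x a [proteome_dataset()] or a positive intensity matrix
#'   (proteins x samples, `NA` = missing).
#' @return The normalized log2 matrix.
#' @export
log2_median_normalize <- function(x) {
  mat <- if (inherits(x, "proteome_dataset")) x$intensities else x
  if (!is.matrix(mat) || !is.numeric(mat)) abort("input must be a numeric matrix")
  if (any(!is.na(mat) & mat <= 0)) {
    abort("nonpositive present value; intensities must be > 0")
  }
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs == 0L)) {
    abort(sprintf("empty sample: %s has no observed proteins",
                  colnames(mat)[which(n_obs == 0L)[1L]]))
  }
  lg <- log2(mat)
  med <- apply(lg, 2L, median, na.rm = TRUE)
  sweep(lg, 2L, med, "-")
}

#' Per-sample blood-contamination score
#'
#' The score of a sample is the mean of its normalized log2 values over
#' the observed proteins of an erythrocyte marker panel (hemoglobin-type
#' markers by default in the bundled annotations).
#'
#' @param log2_matrix normalized log2 matrix.
#' @param marker_panel character vector of marker protein ids.
#' @return Named numeric vector of per-sample scores.
#' @export
contamination_score <- function(log2_matrix, marker_panel) {
  present <- intersect(marker_panel, rownames(log2_matrix))
  if (!length(present)) abort("no marker panel protein present in the matrix")
  sub <- log2_matrix[present, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  if (any(n_obs == 0L)) {
    abort(sprintf("no marker panel protein observed in sample %s",
                  colnames(sub)[which(n_obs == 0L)[1L]]))
  }
  colMeans(sub, na.rm = TRUE)
}

# Huber linear regression (IRLS with MAD rescaling) for an arbitrary
# design matrix. The final step is a plain WLS solve with the converged
# weights, so the weighted normal equations hold to machine precision
# (needed for the residual-orthogonality invariant).
huber_lm <- function(X, y, c = 1.345, tol = 1e-8, maxit = 100L) {
  w <- rep(1, length(y))
  b <- coef_wls(X, y, w)
  for (it in seq_len(maxit)) {
    e <- y - drop(X %*% b)
    s <- mad(e, center = 0, constant = 1.4826)
    if (s < .Machine$double.eps) {
      w <- rep(1, length(y))
      b <- coef_wls(X, y, w)
      break
    }
    u <- e / s
    w <- ifelse(abs(u) <= c, 1, c / abs(u))
    b_new <- coef_wls(X, y, w)
    rel <- max(abs(b_new - b)) / max(1, max(abs(b)))
    b <- b_new
    if (rel < tol) break
  }
  e <- y - drop(X %*% b)
  list(coef = b, weights = w, residuals = e)
}

coef_wls <- function(X, y, w) {
  sw <- sqrt(w)
  qr.coef(qr(X * sw), y * sw)
}

huber_fit <- function(x, y, c = 1.345, tol = 1e-8, maxit = 100L) {
  fit <- huber_lm(cbind(1, x), y, c = c, tol = tol, maxit = maxit)
  list(intercept = fit$coef[1], slope = fit$coef[2],
       weights = fit$weights, residuals = fit$residuals)
}

# Row-parallel Huber IRLS for the model y ~ per-group mean + slope * score
# (groups NULL -> one intercept + slope). The weighted normal equations
# close over per-group weighted sums, so the whole matrix is fitted with
# rowSums operations; per-row robust scale is the MAD of that row's
# residuals, and the last step re-solves with the converged weights.
huber_residualize <- function(Y, scores, groups = NULL,
                              c = 1.345, tol = 1e-8, maxit = 100L) {
  n <- nrow(Y); p <- ncol(Y)
  M <- !is.na(Y)
  # protected mode centers the score so subtracting the covariate term
  # leaves each protein's level untouched; simple mode keeps the raw
  # score so residual + intercept reproduces y - slope * score exactly
  x <- if (is.null(groups)) scores else scores - mean(scores)
  if (is.null(groups)) groups <- rep("all", p)
  glev <- unique(groups)
  gidx <- lapply(glev, function(g) which(groups == g))
  n_par <- length(glev) + 1L
  fitted_ok <- rowSums(M) >= n_par + 1L
  Y0 <- ifelse(M, Y, 0)

  solve_wls <- function(W) {
    # returns list(slope, means = list per group, E = residuals)
    sxy <- rowSums(W * Y0 * rep(x, each = n))
    sxx <- rowSums(W * rep(x^2, each = n))
    adj_num <- 0; adj_den <- 0
    gw <- gx <- gy <- vector("list", length(glev))
    for (k in seq_along(glev)) {
      j <- gidx[[k]]
      Wk <- W[, j, drop = FALSE]
      gw[[k]] <- rowSums(Wk)
      gx[[k]] <- rowSums(Wk * rep(x[j], each = n))
      gy[[k]] <- rowSums(Wk * Y0[, j, drop = FALSE])
      adj_num <- adj_num + ifelse(gw[[k]] > 0, gx[[k]] * gy[[k]] / pmax(gw[[k]], 1e-300), 0)
      adj_den <- adj_den + ifelse(gw[[k]] > 0, gx[[k]]^2 / pmax(gw[[k]], 1e-300), 0)
    }
    den <- sxx - adj_den
    slope <- ifelse(abs(den) > 1e-12, (sxy - adj_num) / den, 0)
    means <- matrix(0, n, p)
    for (k in seq_along(glev)) {
      j <- gidx[[k]]
      mk <- ifelse(gw[[k]] > 0, (gy[[k]] - slope * gx[[k]]) / pmax(gw[[k]], 1e-300), 0)
      means[, j] <- mk
    }
    # zero-filled residuals (masked cells contribute nothing downstream)
    E <- (Y0 - means - outer(slope, x)) * M
    list(slope = slope, means = means, E = E)
  }

  W <- M * 1
  fit <- solve_wls(W)
  for (it in seq_len(maxit)) {
    s <- row_mad_masked(fit$E, M)
    ratio <- (c * s) / pmax(abs(fit$E), 1e-300)
    W_new <- M * pmin(1, ratio)
    W_new[s <= .Machine$double.eps, ] <- 1
    W_new <- W_new * M
    old_slope <- fit$slope
    fit <- solve_wls(W_new)
    W <- W_new
    rel <- max(abs(fit$slope - old_slope) / pmax(1, abs(old_slope)))
    if (is.finite(rel) && rel < tol) break
  }

  slope <- fit$slope
  res <- Y
  if (length(glev) > 1L) {
    # group-protected: subtract only the covariate term
    res <- Y - outer(slope, x)
  } else {
    # simple regression: residual + intercept (abundance preserved)
    res <- fit$E + fit$means
  }
  res[!M] <- NA_real_
  res[!fitted_ok, ] <- Y[!fitted_ok, ]
  W[!M] <- NA_real_
  W[!fitted_ok, ] <- NA_real_
  intercept <- rowSums(ifelse(M, W, 0) * ifelse(M, res, 0), na.rm = TRUE) /
    pmax(rowSums(ifelse(M, W, 0), na.rm = TRUE), 1e-300)
  intercept[!fitted_ok] <- NA_real_
  slope[!fitted_ok] <- NA_real_
  list(res = res, wts = W, slope = slope, intercept = intercept,
       fitted = fitted_ok)
}


#' Residualize a contamination covariate out of every protein
#'
#' Per protein, a robust regression (Huber M-estimator, tuning constant
#' 1.345, IRLS to relative tolerance 1e-8) of the normalized log2 value
#' on the per-sample contamination score. With the default
#' `groups = NULL` this is a simple regression on the score, and the
#' returned residuals (intercept re-added, so the abundance scale is
#' preserved) are exactly weighted-orthogonal to the score. When group
#' labels are supplied, the score slope is estimated jointly with
#' per-group means and only the score term is subtracted — the
#' group-protected form standard for covariate removal before
#' differential expression, which keeps a chance alignment between the
#' score and the group split from eating (or faking) the group effect.
#' Proteins with fewer than 3 observations (or fewer than the model's
#' parameters) are passed through unchanged and flagged.
#'
#' @param log2_matrix normalized log2 matrix.
#' @param scores per-sample contamination scores (named, matching
#'   columns).
#' @param groups optional named per-sample group labels; when given, the
#'   fit protects the group structure as described above.
#' @param c Huber tuning constant.
#' @param tol IRLS relative convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return A `contamination_model`: list with `scores`, `coefficients`
#'   (tibble: protein, intercept, slope, n_obs, fitted), `robust_weights`
#'   matrix, `residual_matrix` (the corrected log2 values) and `df_used`
#'   (regression df consumed beyond the group means: 1).
#' @export
regress_out_contamination <- function(log2_matrix, scores, groups = NULL,
                                      c = 1.345, tol = 1e-8, maxit = 100L) {
  if (length(scores) != ncol(log2_matrix)) {
    abort("`scores` must have one value per sample")
  }
  if (sd(scores) < .Machine$double.eps) abort("degenerate covariate: constant scores")
  protect <- !is.null(groups)
  if (protect) {
    groups <- as.character(groups[colnames(log2_matrix)])
    if (anyNA(groups)) abort("`groups` must cover every sample")
  }
  fit <- huber_residualize(log2_matrix, scores,
                           groups = if (protect) groups else NULL,
                           c = c, tol = tol, maxit = maxit)
  res <- fit$res
  wts <- fit$wts
  coefs <- tibble::tibble(
    protein = rownames(log2_matrix),
    intercept = unname(fit$intercept), slope = unname(fit$slope),
    n_obs = unname(rowSums(!is.na(log2_matrix))), fitted = unname(fit$fitted)
  )
  structure(list(
    scores = scores,
    coefficients = coefs,
    robust_weights = wts,
    residual_matrix = res,
    group_protected = protect,
    df_used = 1L
  ), class = "contamination_model")
}

#' @export
print.contamination_model <- function(x, ...) {
  cat(sprintf(
    "<contamination_model> %d/%d proteins residualized against a %d-sample score\n",
    sum(x$coefficients$fitted), nrow(x$coefficients), length(x$scores)))
  invisible(x)
}

#' @rdname tidy.de_result
#' @export
tidy.contamination_model <- function(x, ...) x$coefficients

#' Flag contamination-outlier samples
#'
#' Samples whose score exceeds `median + k * 1.4826 * MAD` are flagged;
#' when the MAD is zero the SD is used instead. Scale-equivariant:
#' rescaling the scores flags the same samples.
#'
#' @param scores named per-sample scores (>= 4 samples).
#' @param k threshold multiplier (default 3).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(scores, k = 3) {
  if (length(scores) < 4L) abort("need at least 4 samples")
  m <- median(scores)
  s <- mad(scores, constant = 1.4826)
  if (s == 0) s <- sd(scores)
  if (s == 0) return(character(0))
  names(scores)[scores > m + k * s]
}

#' PCA quality control of samples
#'
#' Complete-case proteins (observed in every sample) are row-centered and
#' decomposed by SVD; sample scores on the first two components and the
#' explained-variance fractions are returned. Component signs follow a
#' deterministic convention: the largest-magnitude protein loading on
#' each component is positive.
#'
#' @param log2_matrix normalized log2 matrix (proteins x samples).
#' @return A tibble of class `pca_qc` with columns `sample_id`, `PC1`,
#'   `PC2`; explained-variance fractions in attribute `var_explained`.
#' @export
pca_qc <- function(log2_matrix) {
  if (ncol(log2_matrix) < 2L) abort("PCA needs at least 2 samples")
  cc <- log2_matrix[complete.cases(log2_matrix), , drop = FALSE]
  if (nrow(cc) == 0L) abort("no complete-case proteins for PCA")
  cc <- cc - rowMeans(cc)
  sv <- svd(cc)
  flip <- vapply(seq_along(sv$d), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$v, 2L, sv$d * flip, "*")
  varfrac <- sv$d^2 / sum(sv$d^2)
  k <- min(2L, ncol(scores))
  out <- tibble::tibble(
    sample_id = colnames(log2_matrix),
    PC1 = scores[, 1L],
    PC2 = if (k >= 2L) scores[, 2L] else 0
  )
  structure(out, var_explained = varfrac,
            class = c("pca_qc", class(out)))
}

#' Preprocess one proteome dataset
#'
#' Runs the standard chain: log2 median normalization, contamination
#' scoring on a marker panel, outlier-sample detection and removal, and
#' robust residualization of the contamination score. When
#' `skip_correction_if_confounded = TRUE` and the score is associated
#' with the AD/Ctl contrast (two-sample t, `alpha`), residualization is
#' skipped (outlier removal still applies) so the correction cannot eat
#' the group effect in small confounded cohorts.
#'
#' @param dataset a [proteome_dataset()].
#' @param marker_panel marker protein ids for the contamination score.
#' @param outlier_k multiplier for [detect_outlier_samples()].
#' @param skip_correction_if_confounded test score~group association
#'   first and skip residualization when it is significant.
#' @param alpha significance level for the confounding check.
#' @return A list of class `preprocessed_dataset`: `corrected` (log2
#'   matrix after outlier removal and, unless skipped, residualization),
#'   `model` (the `contamination_model`, or `NULL` if skipped), `scores`,
#'   `outliers`, `groups` (named per-sample labels of retained samples),
#'   `correction_applied`, `dataset_id`, `tissue`.
#' @export
preprocess_dataset <- function(dataset, marker_panel, outlier_k = 3,
                               skip_correction_if_confounded = FALSE,
                               alpha = 0.05) {
  stopifnot(inherits(dataset, "proteome_dataset"))
  lg <- log2_median_normalize(dataset)
  scores <- contamination_score(lg, marker_panel)

  outliers <- if (ncol(lg) >= 4L) detect_outlier_samples(scores, k = outlier_k)
              else character(0)
  keep <- setdiff(colnames(lg), outliers)
  lg <- lg[, keep, drop = FALSE]
  scores_k <- scores[keep]
  groups <- setNames(as.character(dataset$samples$group),
                     dataset$samples$sample_id)[keep]

  apply_correction <- TRUE
  if (skip_correction_if_confounded) {
    g <- groups[groups %in% c("AD", "Ctl")]
    if (length(unique(g)) == 2L &&
        min(table(g)) >= 2L) {
      pv <- t.test(scores_k[names(g)[g == "AD"]],
                   scores_k[names(g)[g == "Ctl"]])$p.value
      if (pv < alpha) apply_correction <- FALSE
    }
  }
  model <- NULL
  corrected <- lg
  if (apply_correction && sd(scores_k) > .Machine$double.eps) {
    model <- regress_out_contamination(lg, scores_k, groups = groups)
    corrected <- model$residual_matrix
  }
  applied <- apply_correction && !is.null(model)
  structure(list(
    corrected = corrected,
    model = model,
    scores = scores,
    outliers = outliers,
    groups = groups,
    correction_applied = applied,
    df_loss = if (applied) model$df_used else 0L,
    dataset_id = dataset$dataset_id,
    tissue = dataset$tissue
  ), class = "preprocessed_dataset")
}

#' @export
print.preprocessed_dataset <- function(x, ...) {
  cat(sprintf(
    "<preprocessed_dataset '%s'> %d proteins x %d samples; %d outlier(s) removed; correction %s\n",
    x$dataset_id, nrow(x$corrected), ncol(x$corrected), length(x$outliers),
    if (x$correction_applied) "applied" else "skipped"))
  invisible(x)
}
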