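test_that("log2 median normalization centers columns and keeps NAs", {
  mat <- matrix(c(2, 8, 4, 16), 2, 2,
                dimnames = list(c("P1", "P2"), c("S1", "S2")))
  lg <- log2_median_normalize(mat)
  expect_equal(unname(lg[, 1]), c(-1, 1))
  expect_equal(unname(apply(lg, 2, median)), c(0, 0))

  mat[1, 2] <- NA
  lg2 <- log2_median_normalize(mat)
  expect_true(is.na(lg2[1, 2]))

  # feeding back 2^normalized is a fixed point
  again <- log2_median_normalize(2^lg)
  expect_equal(again, lg, tolerance = 1e-12)

  bad <- mat; bad[2, 1] <- -1
  expect_error(log2_median_normalize(bad), "nonpositive")
  empty <- mat; empty[, 2] <- NA
  expect_error(log2_median_normalize(empty), "empty sample: S2")
})

test_that("contamination score is the panel mean and is order-invariant", {
  lg <- matrix(c(10, 12, 5, 8, 11, 6), 3, 2,
               dimnames = list(c("HB1", "HB2", "P1"), c("S1", "S2")))
  expect_equal(unname(contamination_score(lg, c("HB1", "HB2"))), c(11, 9.5))
  expect_equal(contamination_score(lg, c("HB2", "HB1")),
               contamination_score(lg, c("HB1", "HB2")))
  expect_equal(unname(contamination_score(lg, "HB1")), unname(lg["HB1", ]))
  lg["HB1", 2] <- NA; lg["HB2", 2] <- NA
  expect_error(contamination_score(lg[c("HB1", "HB2", "P1"), ],
                                   c("HB1", "HB2")),
               "no marker panel protein observed in sample S2")
})

test_that("an exact linear relation is recovered without residue", {
  sc <- setNames(seq(-2, 2, length.out = 8), sprintf("S%d", 1:8))
  y <- rbind(exact = 2 * sc + 5)
  noise <- matrix(rnorm(3 * 8, sd = 0.2), 3, 8,
                  dimnames = list(paste0("P", 1:3), names(sc)))
  m <- regress_out_contamination(rbind(y, noise + 8), sc)
  expect_equal(m$coefficients$slope[1], 2, tolerance = 1e-8)
  expect_equal(unname(m$residual_matrix["exact", ]), rep(5, 8),
               tolerance = 1e-8)
})

test_that("residuals are weighted-orthogonal to the score", {
  for (seed in 1:5) {
    set.seed(seed)
    sc <- setNames(rnorm(12), sprintf("S%02d", 1:12))
    Y <- matrix(rnorm(40 * 12, mean = 8), 40, 12,
                dimnames = list(sprintf("P%02d", 1:40), names(sc)))
    Y[sample(length(Y), 20)] <- NA
    m <- regress_out_contamination(Y, sc)
    for (i in which(m$coefficients$fitted)) {
      obs <- !is.na(Y[i, ])
      w <- m$robust_weights[i, obs]
      e <- m$residual_matrix[i, obs]
      x <- sc[obs]
      xw <- x - sum(w * x) / sum(w)
      ew <- e - sum(w * e) / sum(w)
      denom <- sqrt(sum(w * xw^2) * sum(w * ew^2))
      expect_lt(abs(sum(w * xw * ew)) / denom, 1e-8)
    }
    expect_false(any(m$coefficients$fitted[rowSums(!is.na(Y)) < 3]))
  }
  expect_error(regress_out_contamination(
    matrix(1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z"))),
    rep(2, 3)), "degenerate covariate")
})

test_that("Huber matches ordinary least squares when nothing is downweighted", {
  x <- 1:6
  y <- 2 * x + c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  sc <- setNames(as.numeric(x), paste0("S", 1:6))
  Y <- rbind(p1 = y, p2 = y + 1)
  colnames(Y) <- names(sc)
  m <- regress_out_contamination(Y, sc)
  expect_true(all(abs(m$robust_weights - 1) < 1e-12, na.rm = TRUE))
  ols <- coef(lm(y ~ x))
  expect_equal(m$coefficients$slope[1], unname(ols[2]), tolerance = 1e-10)
})

test_that("Huber slope agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  sc <- setNames(rnorm(15), sprintf("S%02d", 1:15))
  Y <- matrix(rnorm(60 * 15, mean = 6), 60, 15,
              dimnames = list(sprintf("P%02d", 1:60), names(sc)))
  Y[5, ] <- Y[5, ] + 3 * sc # a protein genuinely loading on the score
  m <- regress_out_contamination(Y, sc)
  ref <- vapply(seq_len(nrow(Y)), function(i) {
    unname(coef(MASS::rlm(Y[i, ] ~ sc, psi = MASS::psi.huber, k = 1.345,
                          maxit = 200, acc = 1e-10))[2])
  }, 0)
  expect_equal(m$coefficients$slope, ref, tolerance = 1e-4)
})

test_that("Huber resists a gross outlier better than least squares", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(100 + seed)
    x <- rnorm(20)
    y <- x + rnorm(20, sd = 0.1)
    y[which.max(x)] <- y[which.max(x)] + 8 # gross contamination
    sc <- setNames(x, sprintf("S%02d", 1:20))
    Y <- rbind(p = y); colnames(Y) <- names(sc)
    hub <- regress_out_contamination(rbind(Y, Y + 1), sc)$coefficients$slope[1]
    xb <- mean(x); yb <- mean(y)
    ols <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    if (abs(hub - 1) < abs(ols - 1)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("group-protected residualization spares a confounded group effect", {
  # score aligned with the group split; protein carries a true AD shift
  g <- rep(c("AD", "Ctl"), each = 8)
  set.seed(42)
  sc <- setNames(ifelse(g == "AD", 1, -1) + rnorm(16, sd = 0.4),
                 sprintf("S%02d", 1:16))
  shift <- ifelse(g == "AD", 1, 0)
  Y <- matrix(rnorm(30 * 16, sd = 0.3), 30, 16,
              dimnames = list(sprintf("P%02d", 1:30), names(sc)))
  Y <- Y + matrix(shift, 30, 16, byrow = TRUE)
  fc <- function(m) mean(rowMeans(m[, g == "AD"]) - rowMeans(m[, g == "Ctl"]))
  naive <- regress_out_contamination(Y, sc)$residual_matrix
  prot <- regress_out_contamination(Y, sc, groups = setNames(g, names(sc)))
  expect_lt(fc(naive), 0.5)            # simple regression eats the effect
  expect_equal(fc(prot$residual_matrix), 1, tolerance = 0.1)
  expect_true(prot$group_protected)
})

test_that("outlier flagging follows the median + k*MAD rule", {
  sc <- setNames(c(0, 0, 0, 8), paste0("S", 1:4))
  expect_identical(detect_outlier_samples(sc, k = 3), character(0))
  expect_identical(detect_outlier_samples(sc, k = 1), "S4")
  expect_identical(detect_outlier_samples(setNames(rep(2, 5), paste0("S", 1:5))),
                   character(0))
  set.seed(1)
  sc2 <- setNames(c(rnorm(10), 9), sprintf("S%02d", 1:11))
  expect_identical(detect_outlier_samples(sc2 * 13), detect_outlier_samples(sc2))
})

test_that("planted contamination outliers are recovered", {
  # 3 of 20 contaminated samples inflate the MAD itself (the rule's
  # breakdown behavior), so the planted shift must clear the threshold
  # with margin; +8 SD separates cleanly, +5 SD sits at the boundary
  for (seed in 1:3) {
    cfg <- sim_config(n_proteins = 600, datasets = default_sim_datasets(600),
                      n_signature = 5, mito_module_size = 10,
                      n_outlier_samples = 3, outlier_shift = 8, seed = 130 + seed)
    sim <- simulate_study(cfg)
    pp <- preprocess_dataset(sim$datasets$csf_disc,
                             sim$truth$contamination_marker_ids)
    expect_setequal(pp$outliers, sim$truth$outlier_sample_ids)
  }
})

test_that("PCA QC is deterministic and separates planted groups", {
  set.seed(9)
  base <- matrix(rnorm(50 * 6, mean = 5), 50, 6,
                 dimnames = list(sprintf("P%02d", 1:50), sprintf("S%d", 1:6)))
  dup <- cbind(base, S7 = base[, 1])
  qc <- pca_qc(dup)
  expect_equal(qc$PC1[7], qc$PC1[1], tolerance = 1e-9)
  expect_equal(qc$PC2[7], qc$PC2[1], tolerance = 1e-9)
  expect_lte(sum(attr(qc, "var_explained")), 1 + 1e-9)

  sep <- 0L
  for (seed in 1:10) {
    set.seed(300 + seed)
    g <- rep(c("AD", "Ctl"), each = 8)
    Y <- matrix(rnorm(200 * 16), 200, 16,
                dimnames = list(sprintf("P%03d", 1:200), sprintf("S%02d", 1:16)))
    Y[1:20, g == "AD"] <- Y[1:20, g == "AD"] + 3
    qc <- pca_qc(Y)
    lo <- range(qc$PC1[g == "AD"]); hi <- range(qc$PC1[g == "Ctl"])
    if (lo[2] < hi[1] || hi[2] < lo[1]) sep <- sep + 1L
  }
  expect_gte(sep, 9L)
  expect_error(pca_qc(base[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("confounded cohorts skip the correction but still drop outliers", {
  cfg <- one_dataset_config(300, seed = 61, tissue = "serum")
  sim <- simulate_study(cfg)
  d <- sim$datasets$d1
  # force the marker panel to track the group split
  g <- d$samples$group
  d$intensities[sim$truth$contamination_marker_ids, ] <-
    d$intensities[sim$truth$contamination_marker_ids, ] *
    matrix(2^ifelse(g == "AD", 2, -2), length(sim$truth$contamination_marker_ids),
           ncol(d$intensities), byrow = TRUE)
  pp <- preprocess_dataset(d, sim$truth$contamination_marker_ids,
                           skip_correction_if_confounded = TRUE)
  expect_false(pp$correction_applied)
  pp2 <- preprocess_dataset(d, sim$truth$contamination_marker_ids)
  expect_true(pp2$correction_applied)
})
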