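de_from_vectors <- function(x, y, d0 = NULL) {
  mat <- rbind(p1 = c(x, y), p2 = c(x, y) * 1.3 + rnorm(length(c(x, y)), sd = 0.2))
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  g <- setNames(rep(c("AD", "Ctl"), c(length(x), length(y))), colnames(mat))
  fit_moderated_t(mat, g, d0 = d0)
}

test_that("with d0 = 0 the moderated t is the ordinary pooled t", {
  set.seed(1)
  de <- de_from_vectors(c(1, 2, 3), c(4, 5, 6), d0 = 0)
  oracle <- pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(de$t[1], oracle$t, tolerance = 1e-12)
  expect_equal(de$t[1], -3.674235, tolerance = 1e-6)
  expect_equal(de$p_raw[1], oracle$p, tolerance = 1e-12)
  expect_equal(de$p_raw[1], 0.02131164, tolerance = 1e-6)

  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    de <- de_from_vectors(x, y, d0 = 0)
    oracle <- pooled_t(x, y)
    expect_equal(de$t[1], oracle$t, tolerance = 1e-12)
    expect_equal(de$p_raw[1], oracle$p, tolerance = 1e-12)
  }
})

test_that("d0 = Inf gives the full-shrinkage limit", {
  set.seed(2)
  mat <- matrix(rnorm(50 * 8, mean = 4), 50, 8,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("S%d", 1:8)))
  g <- setNames(rep(c("AD", "Ctl"), each = 4), colnames(mat))
  de <- fit_moderated_t(mat, g, d0 = Inf)
  s0 <- sqrt(attr(de, "s0sq"))
  expect_equal(de$t, de$log2fc / (s0 * sqrt(1 / 4 + 1 / 4)), tolerance = 1e-12)
  expect_equal(de$p_raw, 2 * pnorm(abs(de$t), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("empirical-Bayes shrinkage matches the limma reference", {
  skip_if_not_installed("limma")
  set.seed(12)
  sdr <- sqrt(4 / rchisq(400, df = 4)) # dispersed true variances
  Y <- matrix(rnorm(400 * 12), 400, 12) * sdr
  dimnames(Y) <- list(sprintf("P%03d", 1:400), sprintf("S%02d", 1:12))
  g <- setNames(rep(c("AD", "Ctl"), each = 6), colnames(Y))
  de <- fit_moderated_t(Y, g)
  design <- cbind(AD = as.numeric(g == "AD"), Ctl = as.numeric(g == "Ctl"))
  ref <- limma::eBayes(limma::contrasts.fit(limma::lmFit(Y, design), c(1, -1)))
  expect_equal(attr(de, "d0"), ref$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "s0sq"), ref$s2.prior, tolerance = 1e-8)
  expect_equal(de$t, unname(ref$t[, 1]), tolerance = 1e-10)
  expect_equal(de$p_raw, unname(ref$p.value[, 1]), tolerance = 1e-10)
})

test_that("MCI samples never enter the contrast", {
  set.seed(3)
  mat <- matrix(rnorm(20 * 9, mean = 6), 20, 9,
                dimnames = list(sprintf("P%02d", 1:20), sprintf("S%d", 1:9)))
  g <- setNames(rep(c("AD", "Ctl", "MCI"), each = 3), colnames(mat))
  de_full <- fit_moderated_t(mat, g)
  mat2 <- mat
  mat2[, g == "MCI"] <- mat2[, g == "MCI"] + 100
  de_shift <- fit_moderated_t(mat2, g)
  expect_equal(de_full$t, de_shift$t, tolerance = 1e-12)
  expect_equal(de_full$n_ad, rep(3, 20), ignore_attr = TRUE)
})

test_that("Z transform standardizes and is affine-invariant", {
  expect_equal(z_transform_logfc(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(30)
  z <- z_transform_logfc(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z_transform_logfc(3 * x + 7), z, tolerance = 1e-12)
  expect_error(z_transform_logfc(rep(1, 5)), "zero SD")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.5)), c(0.02, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
  p <- c(0.2, NA, 0.01)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], brute_bh(p[c(1, 3)]))
})

test_that("DE calling applies thresholds, nesting and direction", {
  de <- tibble::tibble(protein = c("A", "B"), z = c(5.1, 1.0),
                       p_raw = c(1e-4, 0.4), fdr = c(0.001, 0.5))
  expect_identical(call_de(de, de_call_spec(z_min = 2, fdr_max = 0.05)), "A")

  set.seed(5)
  big <- tibble::tibble(protein = sprintf("P%03d", 1:200),
                        z = rnorm(200, sd = 3),
                        p_raw = runif(200)^2)
  big$fdr <- bh_adjust(big$p_raw)
  strict <- call_de(big, de_spec_preset("stringent"))
  loose <- call_de(big, de_spec_preset("default"))
  expect_true(all(strict %in% loose))

  de2 <- tibble::tibble(protein = c("A", "B"), z = c(-3, 3),
                        p_raw = c(0.001, 0.001), fdr = c(0.01, 0.01))
  expect_identical(call_de(de2, de_call_spec(direction = "down")), "A")
  expect_error(de_call_spec(p_max = 0.05), "exactly one")
})

test_that("DE calling on planted effects is sensitive and FDP-controlled", {
  # 200 planted of 5000 at 1.5 within-group SD, 10 vs 10; the DE
  # operation is exercised directly (no contamination in play)
  sens <- fdp <- numeric(10)
  for (s in 1:10) {
    cfg <- one_dataset_config(5000, seed = 800 + s, n_signature = 200,
                              mito_module_size = 0, effect_size_sd = 1.5,
                              contamination_strength = 0,
                              contamination_bleed = 0)
    sim <- simulate_study(cfg)
    lg <- log2_median_normalize(sim$datasets$d1)
    g <- setNames(sim$datasets$d1$samples$group,
                  sim$datasets$d1$samples$sample_id)
    de <- fit_moderated_t(lg, g)
    called <- call_de(de, de_call_spec())
    sens[s] <- mean(sim$truth$signature_ids %in% called)
    fdp[s] <- if (length(called)) mean(!called %in% sim$truth$signature_ids) else 0
  }
  expect_gte(mean(sens), 0.5)
  expect_lte(mean(fdp), 0.10)
})

test_that("abundance ranks are dense, deterministic and recover the baseline", {
  mat <- matrix(c(100, 100, 10, 1), 4, 1,
                dimnames = list(c("B", "A", "C", "D"), "S1"))
  r <- abundance_rank(mat)
  expect_equal(unname(r[c("A", "B", "C", "D")]), c(1, 2, 3, 4))

  cfg <- one_dataset_config(400, seed = 9)
  sim <- simulate_study(cfg)
  lg <- log2_median_normalize(sim$datasets$d1)
  r2 <- abundance_rank(lg)
  truth_r <- sim$truth$abundance_rank[names(r2)]
  expect_gt(cor(r2, truth_r, method = "spearman"), 0.999)
})

test_that("depth detection curves count, saturate and stay monotone", {
  ranks <- setNames(c(10, 3000), c("A", "B"))
  universe <- setNames(seq_len(4000), sprintf("U%04d", 1:4000))
  universe[c(10, 3000)] <- 0 # free those rank values
  ranks_all <- c(ranks, universe[universe != 0])
  crv <- depth_detection_curve(c("A", "B"), ranks_all, c(500, 4000))
  expect_equal(crv$detected, c(1, 2))
  expect_equal(attr(crv, "median_rank"), 1505)
  expect_error(depth_detection_curve("ZZZ", ranks_all, 10), "absent.*ZZZ")

  set.seed(10)
  ranks3 <- setNames(sample(1000), sprintf("P%04d", 1:1000))
  qs <- sample(names(ranks3), 50)
  crv3 <- depth_detection_curve(qs, ranks3, seq(100, 1000, by = 100))
  expect_true(all(diff(crv3$detected) >= 0))
  expect_equal(crv3$detected[10], 50)
})

test_that("validation correlation behaves like Pearson r", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(as.numeric(validation_correlation(x, x)), 1)
  expect_equal(as.numeric(validation_correlation(x, -x)), -1)
  expect_error(validation_correlation(x, rep(1, 5)), "zero variance")
  expect_error(validation_correlation(c(1, NA, 3), c(2, 5, NA)), "3 complete pairs")
  hits <- 0L
  for (seed in 1:10) {
    set.seed(500 + seed)
    a <- rnorm(20)
    b <- a + rnorm(20, sd = 0.1 * sd(a))
    if (as.numeric(validation_correlation(a, b)) > 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
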