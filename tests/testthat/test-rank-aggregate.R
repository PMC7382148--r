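test_that("rank_proteins orders by p, breaks ties by |z| then id", {
  de <- tibble::tibble(protein = c("A", "B", "C"),
                       p_raw = c(0.001, 0.01, 0.5), z = c(1, 2, 3))
  rl <- rank_proteins(de)
  expect_identical(rl$protein, c("A", "B", "C"))
  expect_equal(rl$r, c(1 / 3, 2 / 3, 1))

  tied <- tibble::tibble(protein = c("A", "B"), p_raw = c(0.02, 0.02),
                         z = c(2, -4))
  expect_identical(rank_proteins(tied)$protein[1], "B")

  single <- tibble::tibble(protein = "A", p_raw = 0.5, z = 1)
  expect_equal(rank_proteins(single)$r, 1)
  expect_error(rank_proteins(tibble::tibble(protein = "A", p_raw = NA_real_,
                                            z = 1)), "no protein")
})

test_that("q_statistic matches its closed forms and validates input", {
  expect_equal(q_statistic(0.3), 0.3, tolerance = 1e-15)
  expect_equal(q_statistic(c(0.5, 0.5)), 0.25, tolerance = 1e-12)
  expect_equal(q_statistic(c(0.2, 1.0)), 0.36, tolerance = 1e-12)
  # N=2 closed form 2ab - a^2 on random pairs
  for (seed in 1:20) {
    set.seed(seed)
    a <- runif(1); b <- runif(1, min = a)
    expect_equal(q_statistic(c(a, b)), 2 * a * b - a^2, tolerance = 1e-12)
  }
  expect_error(q_statistic(c(0.5, 0.2)), "sorted")
  expect_error(q_statistic(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(q_statistic(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("q is monotone: improving any rank never increases q", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:6, 1)
    r <- sort(runif(n))
    i <- sample(n, 1)
    r2 <- r
    r2[i] <- r2[i] * runif(1)
    r2 <- sort(r2)
    expect_lte(q_statistic(r2), q_statistic(r) + 1e-12)
  }
})

test_that("the compiled row kernel agrees with the scalar reference", {
  set.seed(6)
  mat <- matrix(runif(200 * 5), 200, 5)
  mat[sample(length(mat), 150)] <- NA
  keep <- rowSums(!is.na(mat)) > 0
  mat <- mat[keep, ]
  qc <- proteorank:::q_stat_rows(mat)
  qr_ref <- apply(mat, 1, function(r) q_statistic(sort(r[!is.na(r)])))
  expect_equal(qc, qr_ref, tolerance = 1e-12)
})

test_that("a protein's q ignores lists it does not appear in", {
  set.seed(7)
  r3 <- sort(runif(3))
  with_na <- c(r3[1], NA, r3[2], NA, r3[3])
  q_direct <- q_statistic(r3)
  q_row <- proteorank:::q_stat_rows(matrix(with_na, 1))
  expect_equal(q_row, q_direct, tolerance = 1e-14)
})

test_that("q_statistic matches a Monte-Carlo oracle at small N", {
  set.seed(77)
  draws <- 1e5
  for (n in 3:4) {
    U <- sort_rows_small(matrix(runif(draws * n), draws, n))
    for (k in 1:5) {
      r <- sort(runif(n))
      mc <- mc_q_from_sorted(U, r)
      q <- q_statistic(r)
      mc_sd <- sqrt(q * (1 - q) / draws)
      expect_lt(abs(mc - q), 4 * mc_sd + 1e-9)
    }
  }
})

test_that("permutation null is deterministic and reduces to identity for one list", {
  lists <- list(
    a = rank_proteins(tibble::tibble(protein = sprintf("P%02d", 1:20),
                                     p_raw = runif(20), z = rnorm(20)))
  )
  n1 <- permutation_null(lists, B = 3, seed = 42)
  n2 <- permutation_null(lists, B = 3, seed = 42)
  expect_identical(n1, n2)
  # single list: null q values are a permutation of the observed q (= r)
  expect_equal(sort(n1[["1"]][1:20]), sort(lists$a$r), tolerance = 1e-12)
})

test_that("empirical p follows the add-one rule", {
  null <- seq_len(1000) / 1000
  expect_equal(empirical_p(0.00001, null), 1 / 1001)
  expect_equal(empirical_p(2, null), 1)
  expect_equal(empirical_p(0.5, null), (1 + 500) / 1001)
  expect_error(empirical_p(0.5, numeric(0)), "empty null stratum")
})

test_that("combining identical lists preserves their shared order", {
  de <- tibble::tibble(protein = sprintf("P%02d", 1:15),
                       p_raw = sort(runif(15)), z = rnorm(15))
  rl <- rank_proteins(de)
  out <- combine_ranked_lists(list(a = rl, b = rl), B = 200, seed = 1)
  expect_identical(out$protein, rl$protein)
  expect_true(all(diff(out$p_emp) >= 0))
})

test_that("the biofluid-change filter keeps nominal evidence only", {
  csf <- tibble::tibble(protein = c("A", "B", "C"), p_raw = c(0.2, 0.8, 0.04))
  ser <- tibble::tibble(protein = c("A", "B", "D"), p_raw = c(0.01, 0.9, 0.5))
  kept <- filter_unchanged(c("A", "B", "C", "D"), list(csf), list(ser))
  expect_setequal(kept, c("A", "C"))
  expect_error(filter_unchanged("B", list(csf), list(ser)),
               "filter removed all proteins")
})

test_that("tier plans validate coverage and duplicates", {
  expect_error(tier_plan(list(g1 = c("a", "b"), g2 = "a"),
                         list(t1 = c("g1", "g2"))),
               "more than one level-1 group")
  expect_error(tier_plan(list(g1 = "a"), list(t1 = "gX")),
               "unknown level-1 group")
  plan <- default_tier_plan(default_sim_datasets(100))
  expect_setequal(unlist(plan$level1), default_sim_datasets(100)$dataset_id)
  expect_setequal(names(plan$level2), c("cortex", "csf", "serum"))
})

test_that("a single-dataset integration is the identity", {
  de <- tibble::tibble(protein = sprintf("P%02d", 1:12),
                       p_raw = sort(runif(12)), z = rnorm(12))
  rl <- rank_proteins(de)
  plan <- tier_plan(list(solo = "d1"), list(all = "solo"))
  ir <- tiered_integration(list(d1 = rl), plan, B = 100, seed = 3)
  expect_identical(ir$protein, rl$protein)
  expect_equal(ir$final_rank, seq_len(12))
  expect_true(all(ir$fdr >= ir$p_emp - 1e-12))
  expect_error(tiered_integration(list(d1 = rl, d2 = rl), plan, B = 10, seed = 1),
               "plan missing datasets: d2")
})

test_that("planted signature proteins rise to the top of the integration", {
  cfg <- sim_config(n_proteins = 400, datasets = default_sim_datasets(400),
                    n_signature = 10, mito_module_size = 0,
                    seed = 900)
  sim <- simulate_study(cfg)
  prep <- lapply(sim$datasets, preprocess_dataset,
                 marker_panel = sim$truth$contamination_marker_ids)
  de <- lapply(prep, function(p) {
    fit_moderated_t(p$corrected, p$groups,
                    covariate = p$scores[colnames(p$corrected)])
  })
  lists <- lapply(de, rank_proteins)
  ir <- tiered_integration(lists, default_tier_plan(cfg$datasets),
                           B = 100, seed = 901)
  med <- median(ir$final_rank[ir$protein %in% sim$truth$signature_ids])
  expect_lt(med / nrow(ir), 0.1)
})
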