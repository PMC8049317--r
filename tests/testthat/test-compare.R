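test_that("threshold filtering keeps proteins strictly below tau", {
  vals <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),       # 0.0 missing
                c(1, 2, 3, 4, 5, NA, NA, NA, NA, NA),    # 0.5
                c(1, NA, NA, NA, NA, NA, NA, NA, NA, NA))# 0.9
  m <- pm(vals)
  expect_equal(ncol(filter_by_threshold(m, 0.8)$values), 2)
  expect_equal(ncol(filter_by_threshold(m, 0.5)$values), 1)
  expect_equal(ncol(filter_by_threshold(m, 0)$values), 0)
  # strict inequality: a fully missing protein is dropped even at tau = 1
  m2 <- pm(cbind(c(1, 2), c(NA_real_, NA_real_)))
  expect_equal(filter_by_threshold(m2, 1)$protein_ids, "p1")
})

test_that("kept sets are nested along a threshold sweep", {
  sim <- simulate_dataset(ckd_like_preset("small"))
  m <- sim$observed
  taus <- seq(0.05, 0.95, by = 0.05)
  kept <- lapply(taus, function(t) filter_by_threshold(m, t)$protein_ids)
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("per-sample mean intensity averages observed values only", {
  m <- pm(matrix(c(2, 1, 4, 1, NA, 1), nrow = 2,
                 dimnames = NULL))  # s1: 2, 4, NA -> 3
  v <- mean_intensity_per_sample(m)
  expect_equal(unname(v["s1"]), 3)
  # an all-masked sample is excluded and reported
  m2 <- pm(rbind(c(1, 2), c(NA, NA)))
  expect_message(v2 <- mean_intensity_per_sample(m2), "s2")
  expect_equal(names(v2), "s1")
  expect_equal(attr(v2, "excluded"), "s2")
  expect_error(mean_intensity_per_sample(pm(rbind(c(NA_real_, NA_real_)))),
               "every sample")
})

test_that("density estimation finds known modes and handles degeneracy", {
  set.seed(21)
  d <- estimate_density(rnorm(10000))
  expect_lt(abs(density_peak(d)), 0.1)
  expect_equal(trapezoid_integral(d), 1, tolerance = 1e-3)
  expect_warning(ds <- estimate_density(c(5, 5, 5)), "constant")
  expect_equal(density_peak(ds), 5, tolerance = 1e-4)
  expect_error(estimate_density(3), "at least 2")
})

test_that("density curves integrate to one and peaks break ties leftward", {
  set.seed(22)
  for (i in 1:5) {
    d <- estimate_density(rnorm(50 + 10 * i, i, 1 + i / 5))
    expect_equal(trapezoid_integral(d), 1, tolerance = 1e-3)
  }
  d <- list(grid = c(1, 2, 3, 4), density = c(0.1, 0.4, 0.4, 0.1))
  class(d) <- "DensityCurve"
  expect_equal(density_peak(d), 2)  # leftmost of the tied argmax
})

test_that("KS statistic matches hand-enumeration and edge cases", {
  ks <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5))
  expect_equal(ks$D, brute_ks_D(c(1, 2, 3), c(1.5, 2.5)))
  expect_equal(ks$D, 1 / 3)
  same <- ks_two_sample(c(4, 7, 1), c(4, 7, 1))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disjoint <- ks_two_sample(c(1, 2), c(10, 11, 12))
  expect_equal(disjoint$D, 1)
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("KS p-values agree with the reference asymptotic implementation", {
  set.seed(30)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    y <- rnorm(sample(5:50, 1), 0.4)
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    ks <- ks_two_sample(x, y)
    expect_equal(ks$D, unname(kt$statistic))
    expect_equal(ks$p, kt$p.value, tolerance = 1e-3)
  }
  # exact small-sample path
  x <- c(1, 2, 3); y <- c(1.5, 2.5, 3.5)
  expect_equal(ks_two_sample(x, y, exact = TRUE)$p,
               stats::ks.test(x, y, exact = TRUE)$p.value)
})

test_that("comparison of a matrix with itself is the null record", {
  m <- pm(matrix(rnorm(80, 14, 2), 10, 8))
  tc <- compare_at_threshold(m, m, 0.5)
  expect_equal(tc$peak_distance, 0)
  expect_equal(tc$ks_D, 0)
  expect_equal(tc$pct_missing_imputed, 0)
  expect_equal(tc$n_proteins_kept, 8)
})

test_that("ThresholdComparison fields equal independent recomputation", {
  sim <- simulate_dataset(simulation_config(40, 25, mcar_rate = 0.2, seed = 14))
  m <- sim$observed
  imp <- impute(m, "lowest_value")$completed
  tau <- 0.6
  tc <- compare_at_threshold(m, imp, tau)
  keep <- names(which(protein_missing_fraction(m) < tau))
  expect_equal(tc$n_proteins_kept, length(keep))
  v_ni <- mean_intensity_per_sample(subset_matrix(m, proteins = keep))
  v_im <- mean_intensity_per_sample(subset_matrix(imp, proteins = keep))
  expect_equal(tc$peak_non_imputed, density_peak(estimate_density(v_ni)))
  expect_equal(tc$peak_imputed, density_peak(estimate_density(v_im)))
  expect_equal(tc$peak_distance, abs(tc$peak_imputed - tc$peak_non_imputed))
  expect_equal(tc$ks_D, ks_two_sample(v_ni, v_im)$D)
  expect_equal(tc$quartiles_non_imputed,
               stats::quantile(v_ni, c(0.25, 0.5, 0.75), names = FALSE))
  expect_error(compare_at_threshold(m, imp, 0), "no protein")
  expect_error(compare_at_threshold(m, m, 0.9), "missing values")
})

test_that("lowest-value bias grows with the missingness threshold on MNAR data", {
  sim <- simulate_dataset(ckd_like_preset("small"))
  m <- sim$observed
  low <- impute(m, "lowest_value")$completed
  tc_hi <- compare_at_threshold(m, low, 0.9)
  tc_lo <- compare_at_threshold(m, low, 0.2)
  expect_gte(tc_hi$peak_distance, tc_lo$peak_distance)
})

test_that("sweep returns one row per feasible threshold, deterministically", {
  sim <- simulate_dataset(simulation_config(30, 20, mcar_rate = 0.25, seed = 15))
  m <- sim$observed
  imp <- impute(m, "lowest_value")$completed
  taus <- c(0.2, 0.5, 0.8)
  tab <- threshold_sweep(m, imp, taus = taus)
  expect_equal(tab$tau, taus)
  expect_true(all(diff(tab$n_proteins_kept) >= 0))
  tab2 <- threshold_sweep(m, imp, taus = taus)
  expect_identical(tab, tab2)
  for (i in seq_along(taus)) {
    tc <- compare_at_threshold(m, imp, taus[i])
    expect_equal(tab$ks_D[i], tc$ks_D)
    expect_equal(tab$peak_distance[i], tc$peak_distance)
  }
})

test_that("single-protein comparison respects the length contract", {
  vals <- cbind(rnorm(10, 14), c(rnorm(3, 14), rep(NA, 7)))
  m <- pm(vals)
  imp <- impute(m, "lowest_value")$completed
  rec <- compare_protein(m, imp, "p2")
  expect_length(rec$values_non_imputed, 3)
  expect_length(rec$values_imputed, 10)
  expect_equal(rec$missing_fraction, 0.7)
  complete <- compare_protein(m, imp, "p1")
  expect_equal(complete$ks_D, 0)
  expect_error(compare_protein(m, imp, "p9"), "unknown protein")
})

test_that("KS p-values are healthy under MCAR with a MAR-style imputer", {
  ps <- vapply(1:50, function(s) {
    sim <- simulate_dataset(simulation_config(
      40, 8, rank = 2, noise_sd = 0.5, mcar_rate = 0.10,
      protein_sd = 1, sample_sd = 0.3, seed = s))
    imp <- impute(sim$observed, "chained_equations",
                  params = list(deterministic = TRUE))
    compare_at_threshold(sim$observed, imp$completed, 0.9)$ks_p
  }, 0)
  expect_gt(stats::median(ps), 0.1)
})
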