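test_that("marker normalisation divides channels and rejects bad markers", {
  rec <- tibble::tibble(
    animal_id = c("a", "b", "c"), time_h = c(0, 0, 8),
    fl_signal = c(100, 0, 80), payload_signal = c(50, 10, 20),
    extract_signal = c(5, 1, 2)
  )
  expect_warning(out <- normalize_to_marker(rec), "non-positive marker")
  expect_equal(nrow(out), 2)
  expect_equal(out$payload_ratio, c(0.5, 0.25))
  expect_equal(out$extract_ratio, c(0.05, 0.025))
  # scaling both channels of a sample leaves its ratio unchanged
  rec2 <- dplyr::mutate(rec[c(1, 3), ],
                        fl_signal = fl_signal * 7,
                        payload_signal = payload_signal * 7)
  expect_equal(normalize_to_marker(rec2)$payload_ratio, out$payload_ratio)
  expect_error(suppressWarnings(
    normalize_to_marker(dplyr::mutate(rec, fl_signal = 0))
  ), "No records")
})

test_that("t0-referenced log ratios behave as specified", {
  expect_equal(log_ratio_vs_t0(1, t0_ratios = c(0.9, 1.1)), 0)
  expect_equal(log_ratio_vs_t0(0.5, t0_ratios = 1), -log(2))
  expect_warning(y <- log_ratio_vs_t0(c(1, -2, 0.5), 1), "non-positive")
  expect_equal(y, c(0, NA, -log(2)))
  expect_error(log_ratio_vs_t0(1, numeric(0)), "t0")
  # noise-free cohort: transformed values are exactly -k t
  k <- half_life_to_rate(63)
  rec <- normalize_to_marker(simulate_release_cohort(noise_free_design(), k))
  y <- log_ratio_vs_t0(rec$payload_ratio,
                       rec$payload_ratio[rec$time_h == 0])
  expect_equal(y, -k * rec$time_h)
})

test_that("noise-free cohorts are fitted exactly with R^2 = 1", {
  rec <- simulate_release_cohort(noise_free_design(), half_life_to_rate(63))
  fit <- fit_release_halflife(rec)
  expect_s3_class(fit, "halflife_fit")
  expect_equal(fit$t_half_hat, 63, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$no_release)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "t_half_h"], 63, tolerance = 1e-9)
  expect_equal(glance(fit)$nobs, 15)
  expect_true(all(fit$ci_95[1] <= fit$t_half_hat,
                  fit$t_half_hat <= fit$ci_95[2]))
})

test_that("recovery rescaling per animal leaves the ratiometric fit identical", {
  rec <- simulate_release_cohort(cohort_design(), half_life_to_rate(43),
                                 seed = 3)
  base <- fit_release_halflife(rec)
  # power-of-two scales are exact in floating point, so the invariance is
  # bit-level; arbitrary scales agree to rounding error
  scales2 <- 2^sample(-3:3, nrow(rec), replace = TRUE)
  rec2 <- dplyr::mutate(rec, fl_signal = fl_signal * scales2,
                        payload_signal = payload_signal * scales2)
  again <- fit_release_halflife(rec2)
  expect_identical(base$k_hat, again$k_hat)
  expect_identical(base$r_squared, again$r_squared)
  scales3 <- stats::runif(nrow(rec), 0.2, 4)
  rec3 <- dplyr::mutate(rec, fl_signal = fl_signal * scales3,
                        payload_signal = payload_signal * scales3)
  expect_equal(fit_release_halflife(rec3)$k_hat, base$k_hat,
               tolerance = 1e-12)
})

test_that("a stable payload yields a flagged no-release result", {
  rec <- tibble::tibble(
    animal_id = sprintf("a%d", 1:6),
    time_h = rep(c(0, 8, 24), each = 2),
    fl_signal = c(100, 80, 120, 90, 110, 70),
    payload_signal = 0.5 * c(100, 80, 120, 90, 110, 70),
    extract_signal = 0
  )
  fit <- fit_release_halflife(rec)
  expect_true(fit$no_release)
  expect_equal(fit$t_half_hat, Inf)
  expect_equal(tidy(fit)$estimate[2], Inf)
})

test_that("fits demand at least three distinct time points", {
  rec <- simulate_release_cohort(
    noise_free_design(time_points_h = c(0, 24)), half_life_to_rate(43))
  expect_error(fit_release_halflife(rec), "3 distinct")
})

test_that("ratio-metric fitting shrugs off time-degrading recovery, naive does not", {
  k <- half_life_to_rate(43)
  d <- cohort_design(recovery_time_slope = -0.01)
  set.seed(21)
  fits <- purrr::map_dfr(seq_len(120), function(i) {
    rec <- simulate_release_cohort(d, k)
    tibble::tibble(
      ratio = fit_release_halflife(rec, method = "ratiometric")$t_half_hat,
      naive = fit_release_halflife(rec, method = "naive")$t_half_hat
    )
  })
  expect_lt(abs(mean(fits$ratio) - 43) / 43, 0.05)
  expect_gt(abs(mean(fits$naive) - 43) / 43, 0.20)
})

test_that("two-pool fits agree when clearance is fast", {
  # noise-free: both pools recover the release half-life almost exactly
  d <- noise_free_design(time_points_h = 24 * c(0, 1, 2, 4, 7, 10, 14),
                         n_per_time = 4)
  k <- half_life_to_rate(156)
  rec <- simulate_release_cohort(d, k, k_local = half_life_to_rate(1.5))
  tp <- suppressWarnings(fit_two_pool(rec, k_local = half_life_to_rate(1.5)))
  expect_equal(tp$pellet$t_half_hat, 156, tolerance = 0.001)
  expect_equal(tp$extract$t_half_hat, 156, tolerance = 0.02)
  expect_equal(nrow(tidy(tp)), 4)

  # noisy replicate cohorts: pellet and extract concordant in most cohorts
  set.seed(31)
  rel_diff <- vapply(seq_len(120), function(i) {
    rec <- simulate_release_cohort(cohort_design(
      time_points_h = 24 * c(0, 1, 2, 4, 7, 10, 14), n_per_time = 4
    ), half_life_to_rate(156), k_local = half_life_to_rate(1.5))
    suppressWarnings(fit_two_pool(rec, k_local = half_life_to_rate(1.5)))$rel_diff
  }, numeric(1))
  expect_gte(mean(rel_diff <= 0.15), 0.9)
})
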