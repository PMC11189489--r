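test_that("local free-drug amount behaves like the two-step cascade", {
  p <- depot_params(10, k_rel = half_life_to_rate(156),
                    k_local = half_life_to_rate(1.5))
  expect_equal(local_amount(p, 0), 0)
  # quasi-steady state: with fast clearance the free pool tracks the depot
  tt <- c(24, 96, 240)
  expect_equal(local_amount(p, tt),
               p$k_rel / p$k_local * depot_amount(p, tt),
               tolerance = 0.02)
  expect_error(local_amount(p, -5), "non-negative")
})

test_that("the equal-rate branch joins the general solution continuously", {
  k <- half_life_to_rate(40)
  tt <- seq(0, 300, by = 7.5)
  equal <- local_amount(depot_params(10, k, k), tt)
  for (eps in c(1e-10, 1e-7, 1e-5)) {
    near <- local_amount(depot_params(10, k, k * (1 + eps)), tt)
    expect_equal(near, equal, tolerance = 1e-4)
  }
  # and the near-degenerate evaluation stays finite and smooth
  expect_true(all(is.finite(local_amount(depot_params(10, k, k * (1 + 1e-12)), tt))))
})

test_that("exposure profiles conserve mass and are unimodal", {
  for (halves in list(c(156, 1.5), c(40, 40), c(30, 25), c(2, 200))) {
    p <- depot_params(10, half_life_to_rate(halves[1]),
                      half_life_to_rate(halves[2]))
    prof <- exposure_profile(p, seq(0, 600, by = 2))
    expect_equal(prof$depot_nmol + prof$free_nmol + prof$cleared_nmol,
                 rep(10, nrow(prof)), tolerance = 1e-9)
    expect_true(all(prof$free_nmol >= 0))
    # single interior maximum: the sign of the derivative changes once
    d <- diff(prof$free_nmol)
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)
  }
})

test_that("peak exposure matches the profile argmax and is rate-symmetric", {
  p <- depot_params(10, half_life_to_rate(156), half_life_to_rate(1.5),
                    v_local_ml = 0.15)
  peak <- peak_exposure(p)
  grid <- seq(0, 100, by = 0.01)
  vals <- local_amount(p, grid)
  expect_equal(peak$t_max_h, grid[which.max(vals)], tolerance = 0.01)
  expect_equal(peak$c_max_nmol, max(vals), tolerance = 1e-6)
  # swapping the two rates leaves t_max unchanged
  q <- depot_params(10, p$k_local, p$k_rel)
  expect_equal(peak_exposure(q)$t_max_h, peak$t_max_h)
  # equal rates: t_max = 1/k
  k <- half_life_to_rate(40)
  expect_equal(peak_exposure(depot_params(1, k, k))$t_max_h, 1 / k)
  # a 10 nmol dose in a biopsy-plug volume peaks near 1 uM
  expect_gt(peak$c_max_uM, 0.1)
  expect_lt(peak$c_max_uM, 10)
})

test_that("time above threshold agrees with fine-grid indicator integration", {
  p <- depot_params(10, half_life_to_rate(156), half_life_to_rate(1.5),
                    v_local_ml = 0.15)
  for (thresh in c(0.01, 0.1, 0.5)) {
    dt <- 0.01 * 1.5
    grid <- seq(0, 3000, by = dt)
    numeric_window <- sum(local_amount(p, grid) / 0.15 > thresh) * dt
    expect_equal(as.numeric(time_above_threshold(p, thresh)), numeric_window,
                 tolerance = dt * 2)
  }
  # threshold above the peak: zero window
  expect_equal(as.numeric(time_above_threshold(p, 10)), 0)
  # threshold approaching zero: window truncated at the horizon and flagged
  expect_warning(w <- time_above_threshold(p, 1e-12, horizon_h = 1000),
                 "truncated")
  expect_equal(as.numeric(w), 1000, tolerance = 1)
  expect_true(attr(w, "truncated"))
  # concentration thresholds need a local volume
  p2 <- depot_params(10, 0.01, 0.1, v_local_ml = NULL)
  expect_error(time_above_threshold(p2, 0.01), "v_local")
})
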