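test_that("untreated noise-free groups grow exponentially, exactly", {
  g <- log(2000 / 265) / 24
  tr <- simulate_tumor_group(n_animals = 3, days = seq(0, 21, by = 3),
                             volume_cv = 0, growth_rate_cv = 0, seed = 1)
  one <- dplyr::filter(tr, animal_id == tr$animal_id[1])
  expect_equal(one$volume_mm3, 265 * exp(g * one$day))
})

test_that("a constant exposure balancing growth holds volume flat", {
  g <- log(2000 / 265) / 24
  ex <- exposure_constant(1, duration_d = 100)
  tr <- simulate_tumor_group(n_animals = 2, days = seq(0, 28, by = 7),
                             kill_coefficient = g, exposure = ex,
                             volume_cv = 0, growth_rate_cv = 0, seed = 1)
  expect_equal(tr$volume_mm3, rep(265, nrow(tr)), tolerance = 1e-9)
})

test_that("trajectories stop at the 2000 mm^3 threshold", {
  tr <- simulate_tumor_group(n_animals = 6, seed = 2)
  last <- tr |>
    dplyr::group_by(animal_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  per_animal_max_before <- tr |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(over = sum(volume_mm3 >= 2000))
  expect_true(all(per_animal_max_before$over <= 1))
})

test_that("group summaries use the median and median absolute difference", {
  tr <- tibble::tibble(
    animal_id = c("a", "b", "c"), group = "g", day = 0,
    volume_mm3 = c(100, 200, 300)
  )
  s <- group_median_mad(tr)
  expect_equal(s$median_mm3, 200)
  expect_equal(s$mad_mm3, 100)
  expect_equal(group_median_mad(tr[1, ])$mad_mm3, 0)
  same <- dplyr::mutate(tr, volume_mm3 = 150)
  expect_equal(group_median_mad(same)$mad_mm3, 0)
})

test_that("fractional TG is 1 against itself, 0 for a flat anchored arm", {
  veh <- exact_exponential_group(group = "vehicle")
  self <- dplyr::mutate(veh, group = "copy",
                        animal_id = sub("vehicle", "copy", animal_id))
  both <- dplyr::bind_rows(veh, self)
  out <- fractional_tg(both, "copy", "vehicle")
  expect_equal(out$tg, 1)
  expect_equal(out$tgi_percent, 0)
  # a treated arm pinned at baseline: anchored TG = 0, TGI = 100%
  flat <- dplyr::mutate(veh, group = "flat", volume_mm3 = 265,
                        animal_id = sub("vehicle", "flat", animal_id))
  out2 <- fractional_tg(dplyr::bind_rows(veh, flat), "flat", "vehicle",
                        baseline_subtract = TRUE)
  expect_equal(out2$tg, 0)
  expect_equal(out2$tgi_percent, 100)
})

test_that("TG errors name the group whose curve is too short", {
  veh <- exact_exponential_group(group = "vehicle")
  short <- exact_exponential_group(group = "treated",
                                   days = seq(0, 12, by = 3))
  expect_error(
    fractional_tg(dplyr::bind_rows(veh, short), "treated", "vehicle",
                  window_end = 21),
    "treated"
  )
})

test_that("noise-free TG decreases as dose increases", {
  ex <- exposure_exponential(1, t_half_d = 10)
  tgs <- vapply(c(0.02, 0.05, 0.1, 0.2), function(kill) {
    coh <- dplyr::bind_rows(
      simulate_tumor_group(3, group = "vehicle", volume_cv = 0,
                           growth_rate_cv = 0),
      simulate_tumor_group(3, group = "trt", kill_coefficient = kill,
                           exposure = ex, volume_cv = 0, growth_rate_cv = 0)
    )
    fractional_tg(coh, "trt", "vehicle")$tg
  }, numeric(1))
  expect_true(all(diff(tgs) < 0))
})

test_that("additivity index reproduces its defining arithmetic", {
  res <- additivity_index(0.33, 0.38, 0.04)
  expect_equal(res$tg_calc, 0.33 * 0.38)
  expect_equal(res$index, 0.33 * 0.38 / 0.04)
  expect_equal(res$classification, "supra-additive")
  # observed equal to calculated: exactly additive
  res2 <- additivity_index(0.4, 0.5, 0.2)
  expect_equal(res2$index, 1)
  expect_equal(res2$classification, "approximately additive")
  # no single-agent effect but combination effect: supra-additive
  res3 <- additivity_index(1, 1, 0.5)
  expect_equal(res3$index, 2)
  expect_equal(res3$classification, "supra-additive")
  expect_error(additivity_index(0, 0.5, 0.5), "positive")
})

test_that("the four-arm analysis is exactly additive for pulse-like exposures", {
  # a near-instantaneous exposure delivers its whole kill before the second
  # measurement; relative volumes are then time-constant and the fractional
  # AUC product rule is exact up to the first-interval transient
  pulse <- tibble::tibble(time_d = c(0, 0.2, 0.2001, 60),
                          conc = c(1, 1, 0, 0))
  coh <- simulate_combination_cohort(
    kill_a = 3, kill_b = 4, exposure_a = pulse, exposure_b = pulse,
    volume_cv = 0, growth_rate_cv = 0
  )
  out <- analyze_combination(coh, "agent_a", "agent_b", "combination")
  expect_equal(out$index, 1, tolerance = 0.02)
})

test_that("the index from a vehicle-equal triple is exactly 1", {
  veh <- exact_exponential_group(group = "vehicle", n = 6)
  arms <- purrr::map(c("agent_a", "agent_b", "combination"), function(gname) {
    dplyr::mutate(veh, group = gname,
                  animal_id = sub("vehicle", gname, animal_id))
  })
  coh <- dplyr::bind_rows(veh, arms)
  out <- analyze_combination(coh, "agent_a", "agent_b", "combination")
  expect_equal(out$tg_a, 1)
  expect_equal(out$index, 1)
})

test_that("the sustained-exposure Bliss null gives an index at or below 1", {
  # both agents' relative-volume curves fall over the window, so the
  # fractional-AUC index is conservative (below 1) under independence
  coh <- simulate_combination_cohort(volume_cv = 0, growth_rate_cv = 0)
  out <- analyze_combination(coh, "agent_a", "agent_b", "combination")
  expect_lt(out$index, 1)
  expect_gt(out$index, 0.5)
  # and weakening both agents moves the null index towards 1
  weak <- simulate_combination_cohort(kill_a = 0.01, kill_b = 0.008,
                                      volume_cv = 0, growth_rate_cv = 0)
  out_weak <- analyze_combination(weak, "agent_a", "agent_b", "combination")
  expect_gt(out_weak$index, out$index)
  expect_equal(out_weak$index, 1, tolerance = 0.02)
})

test_that("combination cohorts are reproducible by seed", {
  a <- simulate_combination_cohort(seed = 17)
  b <- simulate_combination_cohort(seed = 17)
  expect_identical(a, b)
})
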