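# Shared fixtures: all synthetic, built in code.

noise_free_design <- function(...) {
  cohort_design(recovery_cv = 0, signal_cv = 0, ...)
}

rat_sc_design <- function(...) {
  # seven harvest times (one rat each), four injection sites per rat
  cohort_design(time_points_h = 24 * c(0, 1, 2, 4, 7, 10, 14),
                n_per_time = 4, ...)
}

# deterministic exponential tumor trajectories, no noise
exact_exponential_group <- function(v0 = 265, g = log(2000 / 265) / 24,
                                    days = seq(0, 42, by = 3), n = 4,
                                    group = "vehicle") {
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(animal_id = sprintf("%s_%02d", group, i), group = group,
                   day = days, volume_mm3 = v0 * exp(g * days))
  })
}
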