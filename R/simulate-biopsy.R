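#' Destructive-sampling cohort design
#'
#' Describes a biopsy time-course experiment in which each animal (or
#' injection site) is harvested once: the time grid, replication per time
#' point, and the noise structure of tissue recovery and fluorescence
#' measurement. Defaults mirror the intratumoral dye time course: harvests at
#' 0, 8, 24, 32 and 48 h with three tumors per conjugate per time.
#'
#' Recovery is the fraction of deposited microspheres captured by the biopsy
#' punch and carried through homogenisation and washing. It varies between
#' samples (lognormal with mean `recovery_mean` and CV `recovery_cv`) and may
#' drift with time on study (`recovery_time_slope`, a per-hour multiplicative
#' change of the mean) - the nuisance the ratio-metric assay is built to
#' cancel.
#'
#' @param time_points_h Harvest times (h); must be non-negative and include
#'   t = 0, which anchors the ratio normalisation.
#' @param n_per_time Samples per time point (default 3).
#' @param recovery_mean Mean recovered fraction, above 0 and at most 1
#'   (default 0.7).
#' @param recovery_cv CV of recovery between samples (default 0.1).
#' @param recovery_time_slope Per-hour multiplicative drift of mean recovery
#'   (default 0; e.g. -0.01 models recovery degrading 1% per hour).
#' @param signal_cv Multiplicative measurement noise CV per fluorescence
#'   channel (default 0.1).
#' @return An object of class `cohort_design`.
#' @examples
#' cohort_design()
#' cohort_design(time_points_h = 24 * c(0, 1, 2, 4, 7, 10, 14), n_per_time = 4)
#' @export
cohort_design <- function(time_points_h = c(0, 8, 24, 32, 48),
                          n_per_time = 3,
                          recovery_mean = 0.7,
                          recovery_cv = 0.1,
                          recovery_time_slope = 0,
                          signal_cv = 0.1) {
  check_positive(time_points_h, "time_points_h", allow_zero = TRUE)
  if (!any(time_points_h == 0)) {
    abort("`time_points_h` must include t = 0 (needed for t0 normalisation).")
  }
  check_positive(n_per_time, "n_per_time")
  check_positive(recovery_mean, "recovery_mean")
  if (recovery_mean > 1) abort("`recovery_mean` must lie in (0, 1].")
  check_positive(recovery_cv, "recovery_cv", allow_zero = TRUE)
  check_positive(signal_cv, "signal_cv", allow_zero = TRUE)
  if (!is.numeric(recovery_time_slope) || length(recovery_time_slope) != 1) {
    abort("`recovery_time_slope` must be a single number.")
  }
  if (any(1 + recovery_time_slope * time_points_h <= 0)) {
    abort("`recovery_time_slope` drives mean recovery non-positive within the design.")
  }
  structure(
    list(time_points_h = sort(time_points_h), n_per_time = as.integer(n_per_time),
         recovery_mean = recovery_mean, recovery_cv = recovery_cv,
         recovery_time_slope = recovery_time_slope, signal_cv = signal_cv),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> t = {%s} h, n = %d/time; recovery %.2f (cv %.2f, slope %+.3g/h); signal cv %.2f\n",
    paste(x$time_points_h, collapse = ", "), x$n_per_time,
    x$recovery_mean, x$recovery_cv, x$recovery_time_slope, x$signal_cv
  ))
  invisible(x)
}

design_grid <- function(design) {
  tibble::tibble(
    time_h = rep(design$time_points_h, each = design$n_per_time)
  ) |>
    dplyr::mutate(animal_id = sprintf("a%02d", dplyr::row_number()))
}

draw_recovery <- function(design, time_h) {
  mean_t <- design$recovery_mean * (1 + design$recovery_time_slope * time_h)
  rlnorm_mean_cv(length(time_h), mean_t, design$recovery_cv)
}

#' Simulate a dual-labelled release cohort
#'
#' Generates biopsy records for microspheres carrying a stable fluorescent
#' marker plus a payload on a cleavable linker. Each record shares one hidden
#' recovery fraction `E` across its channels, which is what makes the
#' payload/marker ratio a recovery-free quantity:
#' \itemize{
#'   \item `fl_signal = E * marker_scale * (1 + eps1)` - stable marker;
#'   \item `payload_signal = E * marker_scale * scale_ratio *
#'     exp(-k_rel t) * (1 + eps2)` - payload still on the depot;
#'   \item `extract_signal = E * marker_scale * scale_ratio * (B(t)/D) *
#'     (1 + eps3)` - free payload in the tissue extract, where `B(t)` is the
#'     depot cascade of [local_amount()] with clearance `k_local`.
#' }
#' The `eps` are independent mean-zero multiplicative errors with CV
#' `design$signal_cv` (normal, truncated at -3 SD). t = 0 samples are
#' simulated as real harvested samples, noise and all, because the estimator
#' normalises to measured t0 ratios.
#'
#' @param design A [cohort_design()].
#' @param release A [release_model()] or bare release rate (1/h).
#' @param scale_ratio Payload-to-marker signal scale at full loading
#'   (default 1; arbitrary fluorescence units - only ratios are meaningful).
#' @param marker_scale Marker signal at full recovery (default 100 a.u.).
#' @param k_local Local free-drug clearance rate (1/h) used for the extract
#'   channel; defaults to a 1.5 h tissue half-life.
#' @param seed Optional RNG seed for reproducibility.
#' @return A tibble of biopsy records: `animal_id`, `time_h`, `fl_signal`,
#'   `payload_signal`, `extract_signal`, `true_recovery` (simulation-only
#'   diagnostic, dropped by [write_biopsy_csv()] unless asked for).
#' @examples
#' simulate_release_cohort(cohort_design(), release_model(half_life_to_rate(43)),
#'                         seed = 1)
#' @export
simulate_release_cohort <- function(design, release, scale_ratio = 1,
                                    marker_scale = 100,
                                    k_local = half_life_to_rate(1.5),
                                    seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  k <- release_rate(release)
  check_positive(scale_ratio, "scale_ratio")
  check_positive(marker_scale, "marker_scale")
  check_positive(k_local, "k_local")
  if (!is.null(seed)) set.seed(seed)
  grid <- design_grid(design)
  n <- nrow(grid)
  E <- draw_recovery(design, grid$time_h)
  cascade <- depot_params(dose_nmol = 1, k_rel = k, k_local = k_local,
                          v_local_ml = NULL)
  free_frac <- local_amount(cascade, grid$time_h)
  tibble::tibble(
    animal_id = grid$animal_id,
    time_h = grid$time_h,
    fl_signal = E * marker_scale * rnoise(n, design$signal_cv),
    payload_signal = E * marker_scale * scale_ratio * exp(-k * grid$time_h) *
      rnoise(n, design$signal_cv),
    extract_signal = E * marker_scale * scale_ratio * free_frac *
      rnoise(n, design$signal_cv),
    true_recovery = E
  )
}

#' Simulate a free-payload tissue-clearance cohort
#'
#' Emulates the experiment estimating how fast *free* payload leaves tissue:
#' stable marker microspheres are co-injected with free payload, and staggered
#' sites are harvested so the extract signal decays with the tissue clearance
#' rate while the marker stays put. The depot channel is empty
#' (`payload_signal = 0`): nothing is linker-bound here.
#'
#' @param design A [cohort_design()]; the classic layout is six staggered
#'   sites harvested together, i.e. `n_per_time = 1` over six times.
#' @param k_tissue Free-payload tissue clearance rate (1/h).
#' @param free_scale Extract-to-marker signal scale at t = 0 (default 1).
#' @inheritParams simulate_release_cohort
#' @return A tibble of biopsy records (same schema as
#'   [simulate_release_cohort()]).
#' @examples
#' d <- cohort_design(time_points_h = c(0, 0.75, 1.5, 3, 4.5, 6), n_per_time = 1)
#' simulate_free_payload_cohort(d, k_tissue = half_life_to_rate(1.5), seed = 1)
#' @export
simulate_free_payload_cohort <- function(design, k_tissue, free_scale = 1,
                                         marker_scale = 100, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  check_positive(k_tissue, "k_tissue")
  check_positive(free_scale, "free_scale")
  check_positive(marker_scale, "marker_scale")
  if (!is.null(seed)) set.seed(seed)
  grid <- design_grid(design)
  n <- nrow(grid)
  E <- draw_recovery(design, grid$time_h)
  tibble::tibble(
    animal_id = grid$animal_id,
    time_h = grid$time_h,
    fl_signal = E * marker_scale * rnoise(n, design$signal_cv),
    payload_signal = 0,
    extract_signal = E * marker_scale * free_scale *
      exp(-k_tissue * grid$time_h) * rnoise(n, design$signal_cv),
    true_recovery = E
  )
}
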