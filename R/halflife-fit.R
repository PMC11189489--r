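#' Normalise biopsy signals to the stable marker
#'
#' Divides each record's payload (and extract) signal by its stable-marker
#' signal. Because both channels are proportional to the same recovered
#' microsphere mass, the ratio is independent of recovery efficiency - the
#' core of the ratio-metric assay. Records with a non-positive marker signal
#' cannot be normalised and are dropped with a warning.
#'
#' @param records A tibble of biopsy records (see
#'   [simulate_release_cohort()] or [read_biopsy_csv()]).
#' @return The records with added columns `payload_ratio`
#'   (`payload_signal / fl_signal`) and, when an extract channel is present,
#'   `extract_ratio`.
#' @examples
#' rec <- simulate_release_cohort(cohort_design(), half_life_to_rate(43), seed = 1)
#' normalize_to_marker(rec)
#' @export
normalize_to_marker <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("time_h", "fl_signal", "payload_signal")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(sprintf("`records` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  bad <- !is.finite(records$fl_signal) | records$fl_signal <= 0
  if (any(bad)) {
    warn(sprintf("Dropping %d record(s) with non-positive marker signal.", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    abort("No records left after rejecting non-positive marker signals.")
  }
  records$payload_ratio <- records$payload_signal / records$fl_signal
  if ("extract_signal" %in% names(records)) {
    records$extract_ratio <- records$extract_signal / records$fl_signal
  }
  tibble::as_tibble(records)
}

#' Log-ratio transform against the t0 reference
#'
#' Implements the assay's normalisation
#' \eqn{y = \ln\left[(R/F) / \overline{(R/F)}_{t0}\right]}: each
#' marker-normalised ratio is referenced to the arithmetic mean of the t = 0
#' ratios, then logged. Noise-free data give exactly \eqn{y = -k_{rel} t}.
#' The t0 reference is the mean (not a single sample) for stability. Records
#' with non-positive ratios cannot be logged and are dropped with a warning.
#'
#' @param ratios Numeric vector of marker-normalised ratios.
#' @param t0_ratios Ratios measured at t = 0 (must have positive mean).
#' @return Numeric vector `log(ratios / mean(t0_ratios))`, `NA` where
#'   rejected.
#' @examples
#' log_ratio_vs_t0(c(1, 0.5, 0.25), t0_ratios = c(0.98, 1.02))
#' @export
log_ratio_vs_t0 <- function(ratios, t0_ratios) {
  if (length(t0_ratios) == 0 || !is.finite(mean(t0_ratios)) ||
      mean(t0_ratios) <= 0) {
    abort("`t0_ratios` must be non-empty with a positive mean.")
  }
  bad <- !is.finite(ratios) | ratios <= 0
  if (any(bad)) {
    warn(sprintf("Dropping %d non-positive ratio(s) from the log transform.", sum(bad)))
  }
  out <- rep(NA_real_, length(ratios))
  out[!bad] <- log(ratios[!bad] / mean(t0_ratios))
  out
}

new_halflife_fit <- function(fit, data, method, pool, n_rejected) {
  # summary.lm warns on an exactly collinear (noise-free) fit; that case is
  # legitimate here and returns R^2 = 1 with zero slope SE
  s <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- s$coefficients[2, 2]
  ci_slope <- suppressWarnings(confint(fit, level = 0.95)[2, ])
  k_hat <- -slope
  no_release <- slope >= 0
  t_half_hat <- if (no_release) Inf else log(2) / k_hat
  # slope CI maps monotonically to a t1/2 CI; a CI bound at slope >= 0 means
  # the data cannot exclude "no release" and the t1/2 bound is +Inf
  bound <- function(sl) if (sl >= 0) Inf else log(2) / (-sl)
  ci_t_half <- sort(c(bound(ci_slope[1]), bound(ci_slope[2])))
  structure(
    list(
      k_hat = k_hat, t_half_hat = t_half_hat,
      r_squared = s$r.squared, se_log_slope = se,
      ci_95 = unname(ci_t_half), n_points = length(fit$residuals),
      n_rejected = n_rejected, no_release = no_release,
      method = method, pool = pool, lm_fit = fit, data = data
    ),
    class = "halflife_fit"
  )
}

#' Estimate a release (or clearance) half-life from biopsy records
#'
#' Log-linear estimation of the first-order rate governing the decay of a
#' biopsy signal over time. Two methods:
#' \describe{
#'   \item{`"ratiometric"`}{regresses
#'     \eqn{\ln[(S/F)/\overline{(S/F)}_{t0}]} on time, where `S` is the
#'     chosen signal and `F` the stable marker - insensitive to per-sample
#'     recovery. (For the extract pool, where the signal is zero at t = 0,
#'     the un-referenced \eqn{\ln(S/F)} is regressed instead; the reference
#'     only shifts the intercept.)}
#'   \item{`"naive"`}{regresses \eqn{\ln S} on time without marker
#'     normalisation - biased whenever recovery drifts with time; provided
#'     for comparison.}
#' }
#' The regression is ordinary least squares on individual samples (not
#' time-point means), preserving degrees of freedom at small n; the rate is
#' minus the slope, and the 95% CI on the half-life is obtained by mapping
#' the t-distribution CI of the slope through \eqn{t_{1/2} = \ln 2 / k}.
#' A non-negative slope (no detectable release) yields a flagged result with
#' an infinite half-life.
#'
#' @param records Biopsy records with at least three distinct time points;
#'   the ratiometric method additionally needs t = 0 samples for its
#'   reference.
#' @param method `"ratiometric"` (default) or `"naive"`.
#' @param pool Which signal decays: `"pellet"` (payload still on recovered
#'   microspheres, the default) or `"extract"` (free payload in the tissue
#'   extract, used for clearance fits).
#' @param exclude_before_h Drop samples earlier than this time (h) before
#'   fitting; used to cut the rise phase of extract data. Default 0 keeps
#'   everything. t = 0 samples are always retained for the ratio reference.
#' @return An object of class `halflife_fit` with fields `k_hat` (1/h),
#'   `t_half_hat` (h), `r_squared`, `se_log_slope`, `ci_95` (h), `n_points`,
#'   `method`, and a `no_release` flag. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @examples
#' rec <- simulate_release_cohort(cohort_design(signal_cv = 0, recovery_cv = 0),
#'                                half_life_to_rate(63))
#' fit_release_halflife(rec)  # recovers 63 h exactly, R^2 = 1
#' @export
fit_release_halflife <- function(records,
                                 method = c("ratiometric", "naive"),
                                 pool = c("pellet", "extract"),
                                 exclude_before_h = 0) {
  method <- match.arg(method)
  pool <- match.arg(pool)
  records <- normalize_to_marker(records)
  signal_col <- if (pool == "pellet") "payload_signal" else "extract_signal"
  ratio_col <- if (pool == "pellet") "payload_ratio" else "extract_ratio"
  if (!ratio_col %in% names(records)) {
    abort(sprintf("`records` lacks the %s pool (column %s).", pool, signal_col))
  }

  if (method == "ratiometric" && pool == "pellet") {
    t0 <- records[[ratio_col]][records$time_h == 0]
    if (length(t0) == 0) {
      abort("Ratiometric fitting needs t = 0 records for the reference ratio.")
    }
    y <- log_ratio_vs_t0(records[[ratio_col]], t0)
  } else if (method == "ratiometric") {
    # extract pool: free drug is absent at t = 0, so a t0-referenced ratio is
    # undefined; regress the plain log marker-ratio (the reference only
    # shifts the intercept, never the slope)
    r <- records[[ratio_col]]
    bad <- !is.finite(r) | r <= 0
    if (any(bad)) {
      warn(sprintf("Dropping %d non-positive ratio(s) from the extract fit.", sum(bad)))
    }
    y <- ifelse(bad, NA_real_, log(pmax(r, .Machine$double.xmin)))
  } else {
    s <- records[[signal_col]]
    bad <- !is.finite(s) | s <= 0
    if (any(bad)) {
      warn(sprintf("Dropping %d non-positive signal(s) from the naive fit.", sum(bad)))
    }
    y <- ifelse(bad, NA_real_, log(pmax(s, .Machine$double.xmin)))
  }

  keep <- !is.na(y) & records$time_h >= exclude_before_h
  n_rejected <- sum(!keep)
  df <- tibble::tibble(time_h = records$time_h[keep], y = y[keep])
  if (nrow(df) == 0) abort("All records were rejected; cannot fit.")
  if (dplyr::n_distinct(df$time_h) < 3) {
    abort("Need at least 3 distinct time points to fit a half-life.")
  }
  fit <- lm(y ~ time_h, data = df)
  new_halflife_fit(fit, df, method, pool, n_rejected)
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("<halflife_fit: %s, %s pool>\n", x$method, x$pool))
  if (x$no_release) {
    cat("  no detectable release (slope >= 0); t1/2 reported as Inf\n")
  }
  cat(sprintf(
    "  t1/2 = %.4g h (95%% CI %.4g-%.4g); k = %.4g /h; R^2 = %.3f; n = %d\n",
    x$t_half_hat, x$ci_95[1], x$ci_95[2], x$k_hat, x$r_squared, x$n_points
  ))
  if (x$n_rejected > 0) cat(sprintf("  (%d record(s) rejected)\n", x$n_rejected))
  invisible(x)
}

#' @rdname fit_release_halflife
#' @param x,object A `halflife_fit`.
#' @param ... Unused.
#' @method tidy halflife_fit
#' @export
tidy.halflife_fit <- function(x, ...) {
  # delta method on t1/2 = ln2/k: se(t1/2) = ln2 * se(k) / k^2
  se_t_half <- if (x$no_release) NA_real_ else log(2) * x$se_log_slope / x$k_hat^2
  tibble::tibble(
    term = c("k_per_h", "t_half_h"),
    estimate = c(x$k_hat, x$t_half_hat),
    std.error = c(x$se_log_slope, se_t_half),
    conf.low = c(log(2) / x$ci_95[2], x$ci_95[1]),
    conf.high = c(log(2) / x$ci_95[1], x$ci_95[2])
  )
}

#' @rdname fit_release_halflife
#' @method glance halflife_fit
#' @export
glance.halflife_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$lm_fit))$sigma,
    nobs = x$n_points,
    n_rejected = x$n_rejected,
    method = x$method,
    pool = x$pool,
    no_release = x$no_release
  )
}

#' Concordant two-pool (pellet and extract) half-life fits
#'
#' Fits the depot-bound payload (pellet) and the free payload in the extract
#' independently, both ratio-metrically. In the usual regime where local
#' clearance is much faster than release, the extract tracks the depot in
#' quasi-steady state and both pools report the release half-life, so their
#' agreement is an internal consistency check of the assay.
#'
#' A mono-exponential description of the extract is only valid on its
#' terminal phase, after the early rise while free drug accumulates. When
#' `k_local` is supplied, samples earlier than the cascade's predicted peak
#' time (computed from the pellet fit's release rate via [peak_exposure()])
#' are excluded from the extract fit; t = 0 records always remain as the
#' ratio reference, and since free drug is zero at t = 0 those records are
#' rejected from the log fit anyway.
#'
#' @inheritParams fit_release_halflife
#' @param k_local Optional local clearance rate (1/h) used to locate the
#'   extract rise phase. `NULL` (default) skips rise-phase exclusion.
#' @return An object of class `two_pool_fit`: a list with elements `pellet`
#'   and `extract`, both `halflife_fit`s, plus the relative difference of the
#'   two half-life estimates.
#' @examples
#' rec <- simulate_release_cohort(
#'   cohort_design(time_points_h = 24 * c(0, 1, 2, 4, 7, 10, 14), n_per_time = 4),
#'   release_model(half_life_to_rate(156)), seed = 1
#' )
#' fit_two_pool(rec, k_local = half_life_to_rate(1.5))
#' @export
fit_two_pool <- function(records, k_local = NULL) {
  pellet <- fit_release_halflife(records, method = "ratiometric", pool = "pellet")
  exclude <- 0
  if (!is.null(k_local) && !pellet$no_release) {
    check_positive(k_local, "k_local")
    cascade <- depot_params(1, k_rel = pellet$k_hat, k_local = k_local,
                            v_local_ml = NULL)
    exclude <- peak_exposure(cascade)$t_max_h
  }
  extract <- fit_release_halflife(records, method = "ratiometric",
                                  pool = "extract", exclude_before_h = exclude)
  rel_diff <- abs(pellet$t_half_hat - extract$t_half_hat) /
    mean(c(pellet$t_half_hat, extract$t_half_hat))
  structure(
    list(pellet = pellet, extract = extract, rel_diff = rel_diff,
         rise_excluded_h = exclude),
    class = "two_pool_fit"
  )
}

#' @export
print.two_pool_fit <- function(x, ...) {
  cat("<two_pool_fit>\n")
  cat(sprintf("  pellet : t1/2 = %.4g h (R^2 = %.3f)\n",
              x$pellet$t_half_hat, x$pellet$r_squared))
  cat(sprintf("  extract: t1/2 = %.4g h (R^2 = %.3f; rise < %.3g h excluded)\n",
              x$extract$t_half_hat, x$extract$r_squared, x$rise_excluded_h))
  cat(sprintf("  relative difference: %.1f%%\n", 100 * x$rel_diff))
  invisible(x)
}

#' @method tidy two_pool_fit
#' @export
tidy.two_pool_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$pellet), pool = "pellet"),
    dplyr::mutate(tidy(x$extract), pool = "extract")
  )
}
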