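#' Time-to-threshold survival records from tumor trajectories
#'
#' Converts each animal's volume trajectory to a time-to-event record, the
#' event being the tumor reaching `threshold` (default 2000 mm^3). The
#' crossing day is found by log-linear interpolation between the bracketing
#' measurements (volumes grow exponentially between visits, so the crossing
#' is linear in log-volume); the first crossing wins if the trajectory is
#' non-monotone. An animal already at or above threshold on day 0 gets time
#' 0.
#'
#' Animals that never reach threshold on study are handled two ways. With
#' `extrapolate = TRUE` (default), exponential growth is fitted to the
#' terminal segment at or above `extrapolate_above` (default 1000 mm^3) and
#' projected forward to the threshold; this mirrors the practice of
#' estimating control group crossing times from established exponential
#' growth, and the projected time is recorded as an event. Trajectories
#' without at least two points above `extrapolate_above`, or without positive
#' terminal growth, cannot be projected and are censored at the last
#' observation with a warning.
#'
#' @inheritParams group_median_mad
#' @param threshold Volume endpoint (mm^3), default 2000.
#' @param extrapolate Project non-crossing trajectories from their terminal
#'   exponential segment (default `TRUE`).
#' @param extrapolate_above Lower volume bound of the terminal segment used
#'   for projection (default 1000 mm^3).
#' @return A tibble `animal_id`, `group`, `time_days`, `event` (1 = reached
#'   threshold, possibly by projection; 0 = censored), `extrapolated`.
#' @examples
#' tr <- simulate_tumor_group(group = "vehicle", seed = 1)
#' survival_times(tr)
#' @export
survival_times <- function(trajectories, threshold = 2000,
                           extrapolate = TRUE, extrapolate_above = 1000) {
  check_trajectories(trajectories)
  check_positive(threshold, "threshold")
  check_flag(extrapolate, "extrapolate")
  check_positive(extrapolate_above, "extrapolate_above")

  one_animal <- function(df, key) {
    df <- dplyr::arrange(df, .data$day)
    v <- df$volume_mm3
    d <- df$day
    if (v[1] >= threshold) {
      return(tibble::tibble(time_days = 0, event = 1L, extrapolated = FALSE))
    }
    cross <- which(v >= threshold)
    if (length(cross) > 0) {
      i <- cross[1]
      t_hit <- d[i - 1] + (d[i] - d[i - 1]) *
        (log(threshold) - log(v[i - 1])) / (log(v[i]) - log(v[i - 1]))
      return(tibble::tibble(time_days = t_hit, event = 1L, extrapolated = FALSE))
    }
    if (extrapolate) {
      seg <- which(v >= extrapolate_above)
      if (length(seg) >= 2) {
        fit <- lm(log(v[seg]) ~ d[seg])
        slope <- coef(fit)[2]
        if (slope > 0) {
          t_hit <- unname((log(threshold) - coef(fit)[1]) / slope)
          return(tibble::tibble(time_days = t_hit, event = 1L,
                                extrapolated = TRUE))
        }
      }
      warn(sprintf(
        "Animal %s never exceeds %g mm^3 with a usable terminal segment; censored.",
        key$animal_id, extrapolate_above
      ))
    }
    tibble::tibble(time_days = max(d), event = 0L, extrapolated = FALSE)
  }

  trajectories |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::group_modify(one_animal) |>
    dplyr::ungroup() |>
    dplyr::select("animal_id", "group", "time_days", "event", "extrapolated")
}

#' Kaplan-Meier median survival per group
#'
#' Product-limit median with right censoring, one row per group. The median
#' is the first time at which the Kaplan-Meier curve drops strictly below
#' 0.5; when the curve sits exactly at 0.5 after an event, the drop happens
#' at the next event time. When the curve never falls below 0.5 the median
#' is not attained and is reported as an open bound (`reached = FALSE`,
#' `label = "> last time"`), the convention used when a treated arm
#' outlives the study.
#'
#' @param surv Survival records: `group`, `time_days`, `event` (see
#'   [survival_times()]).
#' @return A tibble `group`, `median_days`, `reached`, `label`.
#' @examples
#' km_median(tibble::tibble(group = "vehicle",
#'                          time_days = c(10, 20, 30), event = 1))
#' @export
km_median <- function(surv) {
  required <- c("group", "time_days", "event")
  missing <- setdiff(required, names(surv))
  if (length(missing) > 0) {
    abort(sprintf("Survival records lack column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  one_group <- function(df) {
    fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = df)
    # first time the product-limit curve falls strictly below 0.5
    at <- which(fit$surv < 0.5 - 1e-12)
    if (length(at) > 0) {
      med <- fit$time[at[1]]
      tibble::tibble(median_days = med, reached = TRUE,
                     label = format(med, trim = TRUE))
    } else {
      last <- max(df$time_days)
      tibble::tibble(median_days = last, reached = FALSE,
                     label = paste0("> ", format(last, trim = TRUE)))
    }
  }
  surv |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup()
}
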