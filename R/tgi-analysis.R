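#' Per-day median and median-absolute-difference summaries
#'
#' Tumor studies here are summarised robustly: for each group and day, the
#' median volume over animals still on study and the median absolute
#' difference from that median (MAD without the normal-consistency constant).
#'
#' @param trajectories Long-format trajectories: `animal_id`, `group`, `day`,
#'   `volume_mm3` (see [simulate_tumor_group()] or [read_tumor_csv()]).
#' @return A tibble `group`, `day`, `median_mm3`, `mad_mm3`, `n_alive`.
#' @examples
#' tr <- simulate_tumor_group(group = "vehicle", seed = 1)
#' group_median_mad(tr)
#' @export
group_median_mad <- function(trajectories) {
  check_trajectories(trajectories)
  trajectories |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      median_mm3 = median(.data$volume_mm3),
      mad_mm3 = median(abs(.data$volume_mm3 - median(.data$volume_mm3))),
      n_alive = dplyr::n(),
      .groups = "drop"
    )
}

check_trajectories <- function(trajectories) {
  required <- c("animal_id", "group", "day", "volume_mm3")
  missing <- setdiff(required, names(trajectories))
  if (length(missing) > 0) {
    abort(sprintf("Trajectories lack column(s): %s.", paste(missing, collapse = ", ")))
  }
  invisible(trajectories)
}

# Last day on which every listed group still has >= min_alive animals on
# study; used as the default AUC window so survivor attrition cannot bias
# the comparison.
common_window <- function(trajectories, groups, min_alive = 3) {
  med <- group_median_mad(dplyr::filter(trajectories, .data$group %in% groups))
  med |>
    dplyr::filter(.data$n_alive >= min_alive) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(last = max(.data$day), .groups = "drop") |>
    dplyr::pull(.data$last) |>
    min()
}

median_auc <- function(trajectories, grp, window_end, baseline_subtract) {
  med <- group_median_mad(dplyr::filter(trajectories, .data$group == grp))
  if (nrow(med) == 0) abort(sprintf("No trajectories for group '%s'.", grp))
  if (max(med$day) < window_end) {
    abort(sprintf(
      "Group '%s' median curve ends at day %g, before the window end %g.",
      grp, max(med$day), window_end
    ))
  }
  med <- dplyr::filter(med, .data$day <= window_end)
  y <- med$median_mm3
  if (baseline_subtract) y <- y - med$median_mm3[med$day == min(med$day)]
  trapz(med$day, y)
}

#' Fractional tumor growth (TG) and growth inhibition (TGI)
#'
#' TG is the fractional AUC of the treated group's median tumor-volume curve
#' relative to the vehicle group's over a common window:
#' \eqn{TG = AUC_{treated}/AUC_{vehicle}}, \eqn{TGI = 100(1 - TG)} percent.
#' Identical groups give TG = 1 by construction.
#'
#' The default window runs from treatment start to the last day on which
#' every compared group retains at least 3 animals, so survivor attrition in
#' the faster-growing arm cannot inflate the comparison. AUCs are trapezoidal
#' on the group median curves. `baseline_subtract = TRUE` anchors both curves
#' at their day-0 median before integrating; the default is `FALSE`, the
#' convention under which observed combination TG values stay positive and
#' the Bliss product rule is meaningful (see the methods vignette).
#'
#' @inheritParams group_median_mad
#' @param treated_group,vehicle_group Group labels to compare.
#' @param window_end Last day of the AUC window; `NULL` (default) uses the
#'   common >= 3-animals rule across the two groups.
#' @param baseline_subtract Subtract each group's day-0 median before
#'   integrating (default `FALSE`).
#' @param min_alive Minimum animals on study defining the automatic window.
#' @return A one-row tibble: `treated_group`, `vehicle_group`, `window_end`,
#'   `tg`, `tgi_percent`.
#' @examples
#' tr <- dplyr::bind_rows(
#'   simulate_tumor_group(group = "vehicle", seed = 1),
#'   simulate_tumor_group(group = "treated", seed = 2,
#'                        kill_coefficient = 0.1,
#'                        exposure = exposure_exponential(1, 10))
#' )
#' fractional_tg(tr, "treated", "vehicle")
#' @export
fractional_tg <- function(trajectories, treated_group,
                          vehicle_group = "vehicle",
                          window_end = NULL,
                          baseline_subtract = FALSE,
                          min_alive = 3) {
  check_trajectories(trajectories)
  check_flag(baseline_subtract, "baseline_subtract")
  groups <- c(treated_group, vehicle_group)
  present <- unique(trajectories$group)
  if (!all(groups %in% present)) {
    abort(sprintf("Group(s) not found: %s.",
                  paste(setdiff(groups, present), collapse = ", ")))
  }
  if (is.null(window_end)) {
    window_end <- common_window(trajectories, groups, min_alive)
  }
  auc_t <- median_auc(trajectories, treated_group, window_end, baseline_subtract)
  auc_v <- median_auc(trajectories, vehicle_group, window_end, baseline_subtract)
  if (auc_v <= 0) abort("Vehicle AUC is non-positive; cannot form a fractional TG.")
  tg <- auc_t / auc_v
  tibble::tibble(
    treated_group = treated_group, vehicle_group = vehicle_group,
    window_end = window_end, tg = tg, tgi_percent = 100 * (1 - tg)
  )
}

#' Bliss-style additivity index for a drug combination
#'
#' Under Bliss independence the fractional growths of two agents multiply:
#' the expected combination TG is \eqn{TG_{calc} = TG_A \times TG_B}. The
#' additivity index compares this null with the observed combination,
#' \eqn{index = TG_{calc} / TG_{obsd}}: below 1 is infra-additive, 1 is
#' additive, above 1 supra-additive (synergistic). Because a measured index
#' of exactly 1 has probability zero, values inside `band` are classified
#' `"approximately additive"`.
#'
#' @param tg_a,tg_b Single-agent fractional TGs (> 0; vehicle is 1 by
#'   definition).
#' @param tg_obsd Observed combination fractional TG (> 0).
#' @param band Closed interval of indices reported as approximately additive
#'   (default `c(0.8, 1.25)`).
#' @return A one-row tibble of class `combination_result`: `tg_a`, `tg_b`,
#'   `tg_calc`, `tg_obsd`, `index`, `classification`.
#' @examples
#' additivity_index(tg_a = 0.33, tg_b = 0.38, tg_obsd = 0.04)
#' @export
additivity_index <- function(tg_a, tg_b, tg_obsd, band = c(0.8, 1.25)) {
  check_positive(tg_a, "tg_a")
  check_positive(tg_b, "tg_b")
  check_positive(tg_obsd, "tg_obsd")
  if (length(band) != 2 || band[1] > 1 || band[2] < 1) {
    abort("`band` must be an interval containing 1.")
  }
  tg_calc <- tg_a * tg_b
  index <- tg_calc / tg_obsd
  classification <- dplyr::case_when(
    index < band[1] ~ "infra-additive",
    index > band[2] ~ "supra-additive",
    .default = "approximately additive"
  )
  out <- tibble::tibble(
    tg_a = tg_a, tg_b = tg_b, tg_calc = tg_calc, tg_obsd = tg_obsd,
    index = index, classification = classification
  )
  class(out) <- c("combination_result", class(out))
  out
}

#' Analyse a four-arm combination study
#'
#' Computes fractional TGs for two single agents and their combination
#' against a shared vehicle arm over one common window (the last day all
#' four groups retain `min_alive` animals), then forms the Bliss additivity
#' index.
#'
#' @inheritParams fractional_tg
#' @param agent_a,agent_b,combination Group labels of the three treated arms.
#' @param ... Passed to [additivity_index()] (e.g. `band`).
#' @return A `combination_result` tibble (see [additivity_index()]) with the
#'   window and single-arm TGI columns appended.
#' @export
analyze_combination <- function(trajectories,
                                agent_a, agent_b, combination,
                                vehicle_group = "vehicle",
                                window_end = NULL,
                                baseline_subtract = FALSE,
                                min_alive = 3, ...) {
  check_trajectories(trajectories)
  groups <- c(vehicle_group, agent_a, agent_b, combination)
  if (is.null(window_end)) {
    window_end <- common_window(trajectories, groups, min_alive)
  }
  tg_of <- function(grp) {
    fractional_tg(trajectories, grp, vehicle_group, window_end = window_end,
                  baseline_subtract = baseline_subtract)$tg
  }
  res <- additivity_index(tg_of(agent_a), tg_of(agent_b), tg_of(combination), ...)
  res$window_end <- window_end
  res$tgi_a_percent <- 100 * (1 - res$tg_a)
  res$tgi_b_percent <- 100 * (1 - res$tg_b)
  res
}
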