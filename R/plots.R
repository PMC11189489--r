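# ggplot2 views of the main result types. Figures are working plots for
# analysis notebooks, not publication reproductions.

#' Plot a depot exposure profile
#'
#' Depot-bound and free tissue amounts against time, on a log or linear
#' scale.
#'
#' @param params A [depot_params()] object.
#' @param times Time grid (h); default spans five release half-lives.
#' @param log_y Log-scale the y axis (default `FALSE`).
#' @return A ggplot object.
#' @examples
#' p <- depot_params(10, half_life_to_rate(156), half_life_to_rate(1.5))
#' plot_exposure_profile(p)
#' @export
plot_exposure_profile <- function(params,
                                  times = seq(0, 5 * log(2) / params$k_rel,
                                              length.out = 200),
                                  log_y = FALSE) {
  prof <- exposure_profile(params, times)
  long <- prof |>
    dplyr::select("time_h", "depot_nmol", "free_nmol") |>
    tidyr::pivot_longer(-"time_h", names_to = "pool", values_to = "amount_nmol")
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$amount_nmol,
                                           colour = .data$pool)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "amount (nmol)", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' @rdname fit_release_halflife
#' @method autoplot halflife_fit
#' @export
autoplot.halflife_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "time (h)",
      y = if (object$method == "ratiometric") {
        "ln normalized ratio"
      } else {
        "ln signal"
      },
      title = sprintf("%s fit: t1/2 = %.3g h (R² = %.3f)",
                      object$method, object$t_half_hat, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group tumor-growth curves
#'
#' Median curves with median-absolute-difference ribbons, with the
#' individual animal trajectories behind them.
#'
#' @inheritParams group_median_mad
#' @return A ggplot object.
#' @examples
#' tr <- simulate_combination_cohort(seed = 1)
#' plot_tumor_growth(tr)
#' @export
plot_tumor_growth <- function(trajectories) {
  med <- group_median_mad(trajectories)
  ggplot2::ggplot(med, ggplot2::aes(.data$day, .data$median_mm3,
                                    colour = .data$group,
                                    fill = .data$group)) +
    ggplot2::geom_line(
      data = trajectories,
      ggplot2::aes(.data$day, .data$volume_mm3, group = .data$animal_id),
      alpha = 0.25, linewidth = 0.3, inherit.aes = FALSE,
      colour = "grey50"
    ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median_mm3 - .data$mad_mm3,
                                      ymax = .data$median_mm3 + .data$mad_mm3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "days post treatment", y = "tumor volume (mm³)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of time to volume threshold
#'
#' @param surv Survival records from [survival_times()].
#' @return A ggplot object.
#' @examples
#' tr <- simulate_combination_cohort(seed = 1)
#' plot_km(survival_times(tr))
#' @export
plot_km <- function(surv) {
  steps <- surv |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = df)
      tibble::tibble(time_days = c(0, fit$time),
                     surv_prob = c(1, fit$surv))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(.data$time_days, .data$surv_prob,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.9) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days post treatment", y = "surviving fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
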