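#' Convert a first-order release half-life to a rate constant
#'
#' Beta-eliminative linker cleavage is first order, so a half-life
#' \eqn{t_{1/2}} and a rate constant \eqn{k} are interchangeable through
#' \eqn{k = \ln 2 / t_{1/2}}. All half-lives and rates in this package use
#' consistent time units; biopsy-side functions work in hours.
#'
#' @param t_half Half-life (> 0), any time unit.
#' @param k Rate constant (> 0), inverse of the same time unit.
#' @return `half_life_to_rate()` returns the rate constant; `rate_to_half_life()`
#'   returns the half-life. Both are vectorised.
#' @examples
#' half_life_to_rate(27)            # linker with a 27 h half-life
#' rate_to_half_life(half_life_to_rate(160))
#' @export
half_life_to_rate <- function(t_half) {
  check_positive(t_half, "t_half")
  log(2) / t_half
}

#' @rdname half_life_to_rate
#' @export
rate_to_half_life <- function(k) {
  check_positive(k, "k")
  log(2) / k
}

#' Rescale a release rate between pH environments
#'
#' Linker cleavage is a specific-base (hydroxide) catalysed elimination, so
#' the first-order rate scales with hydroxide concentration: moving from
#' `ph_from` to `ph_to` multiplies the rate by `10^(ph_to - ph_from)` and the
#' half-life by the reciprocal factor. One pH unit therefore changes the rate
#' tenfold. This is the model used to translate rates measured at an
#' accelerated pH (e.g. 8.4) to physiological pH 7.4, and to express the
#' slower release seen in acidic tumor tissue as an equivalent pH offset.
#'
#' @param k Rate constant (> 0).
#' @param t_half Half-life (> 0).
#' @param ph_from,ph_to pH of the source and target environment, in (0, 14).
#' @return Rescaled rate constant (`adjust_rate_for_ph()`) or half-life
#'   (`adjust_half_life_for_ph()`).
#' @examples
#' adjust_rate_for_ph(half_life_to_rate(16), ph_from = 8.4, ph_to = 7.4)
#' adjust_half_life_for_ph(43, ph_from = 7.4, ph_to = 7.4 - log10(1.5))
#' @export
adjust_rate_for_ph <- function(k, ph_from, ph_to) {
  check_positive(k, "k")
  check_ph(ph_from, "ph_from")
  check_ph(ph_to, "ph_to")
  k * 10^(ph_to - ph_from)
}

#' @rdname adjust_rate_for_ph
#' @export
adjust_half_life_for_ph <- function(t_half, ph_from, ph_to) {
  check_positive(t_half, "t_half")
  check_ph(ph_from, "ph_from")
  check_ph(ph_to, "ph_to")
  t_half * 10^(ph_from - ph_to)
}

#' Apply a tissue fold-factor to a release half-life
#'
#' Release from the same conjugate is slower in acidic tumor tissue than in
#' subcutaneous tissue; empirically the tumor half-life is about 1.5-fold the
#' subcutaneous one. Because tumor pH is rarely known numerically, the
#' correction is exposed directly as a fold-factor (the equivalent pH offset
#' is `log10(factor)`; see [adjust_half_life_for_ph()]).
#'
#' @param t_half Half-life (> 0).
#' @param factor Multiplicative tissue correction (> 0); values above 1 slow
#'   release (subcutaneous to tumor), below 1 speed it up.
#' @return Corrected half-life, same units as `t_half`.
#' @examples
#' adjust_half_life_by_tissue_factor(6.6, 1.5)  # SC days -> intratumoral days
#' @export
adjust_half_life_by_tissue_factor <- function(t_half, factor) {
  check_positive(t_half, "t_half")
  check_positive(factor, "factor")
  t_half * factor
}

#' First-order release model
#'
#' Bundles a release rate constant with the pH and temperature it refers to.
#' Temperature is metadata only: all supported conversions are at constant
#' temperature (the experimental systems are at 37 degrees C throughout).
#'
#' @param k_rel First-order release rate constant (1/h), > 0.
#' @param ph pH of the environment (default 7.4).
#' @param temp_c Temperature in degrees C (default 37), carried as metadata.
#' @return An object of class `release_model`.
#' @examples
#' release_model(half_life_to_rate(63))
#' @export
release_model <- function(k_rel, ph = 7.4, temp_c = 37) {
  check_positive(k_rel, "k_rel")
  check_ph(ph)
  structure(
    list(k_rel = k_rel, ph = ph, temp_c = temp_c),
    class = "release_model"
  )
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf(
    "<release_model> k_rel = %.5g /h (t1/2 = %.4g h) at pH %.2f, %g C\n",
    x$k_rel, log(2) / x$k_rel, x$ph, x$temp_c
  ))
  invisible(x)
}

release_rate <- function(model) {
  if (inherits(model, "release_model")) return(model$k_rel)
  check_positive(model, "model (rate constant)")
  model
}

#' Fraction of payload remaining on the depot
#'
#' Under first-order cleavage the fraction of the originally attached payload
#' still depot-bound at time `t` is \eqn{e^{-k_{rel} t}}: 1 at `t = 0` and
#' 0.5 at one half-life.
#'
#' @param model A [release_model()] or a bare positive rate constant (1/h).
#' @param t Time since deposition (h), >= 0; vectorised.
#' @return Fraction remaining in (0, 1].
#' @examples
#' fraction_remaining(release_model(half_life_to_rate(63)), c(0, 48, 63))
#' @export
fraction_remaining <- function(model, t) {
  k <- release_rate(model)
  check_positive(t, "t", allow_zero = TRUE)
  exp(-k * t)
}
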