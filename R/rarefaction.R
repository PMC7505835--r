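#' Probability that a species is missed in a subsample of plots
#'
#' For a species detected in `Qi` of `T` reference plots, the probability
#' that none of `t` plots drawn without replacement contain it is the
#' hypergeometric term C(T - Qi, t) / C(T, t). The binomial coefficients are
#' evaluated through log-gamma, which extends the formula continuously to
#' real `t` (needed because retention proportions map to non-integer plot
#' counts) and avoids overflow for large T.
#'
#' @param T Number of reference plots (positive integer).
#' @param Qi Incidence frequency, 0..T. Vectorized.
#' @param t Subsample size in [0, T], real. Vectorized (recycled against
#'   `Qi`).
#' @return Probability in [0, 1]; exactly 0 at every integer `t > T - Qi`,
#'   with the continuous extension reaching 0 at `t = T - Qi + 1`.
#' @examples
#' miss_probability(4, 2, 2) # 1/6: one of the six 2-plot subsets avoids both
#' @export
miss_probability <- function(T, Qi, t) {
  stopifnot(length(T) == 1L, T >= 1)
  if (any(Qi < 0) || any(Qi > T)) stop("`Qi` must lie in [0, T].")
  if (any(t < 0) || any(t > T)) stop("`t` must lie in [0, T].")
  n <- max(length(Qi), length(t))
  Qi <- rep_len(Qi, n)
  t <- rep_len(t, n)
  out <- numeric(n)
  # The log-gamma form reproduces C(T - Qi, t) / C(T, t) at every integer t
  # and interpolates continuously in between; it reaches 0 at t = T - Qi + 1
  # (where lgamma(T - Qi - t + 1) diverges), one step past the last subsample
  # size that can avoid the species, and is held at 0 beyond. Truncating at
  # t = T - Qi instead would match the same integers but jump at fractional t.
  ok <- t <= (T - Qi + 1)
  if (any(ok)) {
    out[ok] <- exp(lgamma(T - Qi[ok] + 1) - lgamma(T - Qi[ok] - t[ok] + 1) -
                     lgamma(T + 1) + lgamma(T - t[ok] + 1))
  }
  # round-off guard: the exact value lies in [0, 1]
  pmin(pmax(out, 0), 1)
}

#' Rarefied (interpolated) species richness
#'
#' Expected number of species detected in `t` plots drawn without replacement
#' from the reference sample: the sum over species of one minus the miss
#' probability. At `t = T` this equals the observed richness exactly; at
#' `t = 0` it is zero.
#'
#' @param freqs An `incidence_freq` object from [to_incidence()].
#' @param t Real subsample size in [0, T]; vectorized.
#' @return Expected richness, one value per `t`.
#' @export
rarefied_richness <- function(freqs, t) {
  stopifnot(inherits(freqs, "incidence_freq"))
  if (any(t > freqs$T))
    stop("t exceeds the reference sample; use extrapolated_richness().")
  if (any(t < 0)) stop("t must be non-negative.")
  vapply(t, function(tt) {
    sum(1 - miss_probability(freqs$T, freqs$Q, tt))
  }, numeric(1))
}

#' Chao2 estimate of the number of undetected species
#'
#' Uses the frequencies of uniques (Q1) and duplicates (Q2):
#' ((T-1)/T) * Q1^2 / (2 Q2) when Q2 > 0, and the bias-corrected variant
#' ((T-1)/T) * Q1 (Q1 - 1) / 2 when Q2 = 0 (which avoids division by zero
#' while keeping the Q1 signal). Zero when there are no uniques.
#'
#' @param freqs An `incidence_freq` object.
#' @return Estimated count of species present but never detected (>= 0).
#' @export
chao2_undetected <- function(freqs) {
  stopifnot(inherits(freqs, "incidence_freq"))
  T <- freqs$T
  if (freqs$Q1 == 0) return(0)
  if (freqs$Q2 > 0) {
    (T - 1) / T * freqs$Q1^2 / (2 * freqs$Q2)
  } else {
    (T - 1) / T * freqs$Q1 * (freqs$Q1 - 1) / 2
  }
}

#' Extrapolated species richness beyond the reference sample
#'
#' Expected richness in `T + t_star` plots, estimated from the Chao2
#' undetected count Q0:
#' `S_obs + Q0 * (1 - (1 - Q1 / (Q1 + T * Q0))^t_star)`.
#' Non-decreasing in `t_star` with asymptote `S_obs + Q0`; equals `S_obs`
#' when `t_star = 0` or when no undetected species are estimated.
#'
#' @param freqs An `incidence_freq` object.
#' @param t_star Real number of additional plots beyond T (>= 0); vectorized.
#' @return Expected richness, one value per `t_star`.
#' @export
extrapolated_richness <- function(freqs, t_star) {
  stopifnot(inherits(freqs, "incidence_freq"))
  if (any(t_star < 0)) stop("t_star must be non-negative.")
  Q0 <- chao2_undetected(freqs)
  if (Q0 == 0) return(rep(freqs$S_obs, length(t_star)))
  freqs$S_obs + Q0 * (1 - (1 - freqs$Q1 / (freqs$Q1 + freqs$T * Q0))^t_star)
}

#' Rarefaction/extrapolation curve over a grid of sample sizes
#'
#' The non-parametric species-area relationship of one habitat: rarefied
#' richness up to the reference size T, Chao2-based extrapolation beyond; the
#' two branches agree at T, where the curve equals the observed richness.
#'
#' @param freqs An `incidence_freq` object.
#' @param t_max Largest sample size on the grid (default `2 * T`).
#' @param n_points Number of grid points (>= 2).
#' @return A tibble of class `richness_curve` with columns `t`, `richness`,
#'   and `regime` (`interpolated` / `observed` / `extrapolated`).
#' @export
richness_curve <- function(freqs, t_max = 2 * freqs$T, n_points = 101L) {
  stopifnot(inherits(freqs, "incidence_freq"), n_points >= 2L, t_max > 0)
  t <- seq(0, t_max, length.out = n_points)
  if (!any(t == freqs$T) && t_max >= freqs$T) t <- sort(c(t, freqs$T))
  richness <- ifelse(t <= freqs$T,
                     rarefied_richness(freqs, pmin(t, freqs$T)),
                     extrapolated_richness(freqs, pmax(t - freqs$T, 0)))
  out <- tibble::tibble(
    t = t,
    richness = richness,
    regime = dplyr::case_when(t < freqs$T ~ "interpolated",
                              t == freqs$T ~ "observed",
                              TRUE ~ "extrapolated")
  )
  attr(out, "T_ref") <- freqs$T
  attr(out, "S_obs") <- freqs$S_obs
  class(out) <- c("richness_curve", class(out))
  out
}

#' @rdname richness_curve
#' @param object A `richness_curve`.
#' @param ... Unused.
#' @export
autoplot.richness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$richness,
                                       linetype = .data$regime)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$regime == "observed")) +
    ggplot2::labs(x = "Plots sampled", y = "Expected species richness",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
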