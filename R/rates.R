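#' Linear pH trend of a kinetic rate
#'
#' A kinetic rate (binding or dissociation of a RecA monomer at the
#' filament end) modelled as linear in pH:
#' \deqn{k(\mathrm{pH}) = \max\{0,\; k_{ref} + s\,(\mathrm{pH} - \mathrm{pH}_{ref})\}}
#' The slope carries the pH dependence of the rate; the reference value
#' anchors its absolute magnitude, which pH-trend slopes alone do not fix.
#'
#' @param k_ref rate at the reference pH, in s^-1; must be > 0.
#' @param slope rate change per pH unit, in s^-1 per pH unit.
#' @param pH_ref reference pH (default 7.0).
#' @return An object of class `rate_trend`.
#' @seealso [rate_at_pH()]
#' @examples
#' tr <- rate_trend(k_ref = 0.2, slope = -0.10)
#' rate_at_pH(tr, c(6, 7, 8))
#' @export
rate_trend <- function(k_ref, slope, pH_ref = 7) {
  stopifnot(is.numeric(k_ref), length(k_ref) == 1L, is.finite(k_ref),
            is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(pH_ref), length(pH_ref) == 1L, is.finite(pH_ref))
  if (k_ref <= 0) stop("'k_ref' must be > 0")
  structure(list(k_ref = k_ref, slope = slope, pH_ref = pH_ref),
            class = "rate_trend")
}

#' @export
print.rate_trend <- function(x, ...) {
  cat(sprintf("rate trend: k(pH) = %.4g %+.4g * (pH - %.3g)  [s^-1]\n",
              x$k_ref, x$slope, x$pH_ref))
  invisible(x)
}

#' Evaluate a rate trend at given pH values
#'
#' Negative extrapolated rates are clamped at zero with a warning: a
#' first-order rate cannot be negative, and the linear trend is only an
#' empirical description over the measured pH window.
#'
#' @param trend a [rate_trend()] object.
#' @param pH numeric vector of pH values (finite).
#' @return Numeric vector of rates in s^-1, same length as `pH`.
#' @export
rate_at_pH <- function(trend, pH) {
  stopifnot(inherits(trend, "rate_trend"), is.numeric(pH), all(is.finite(pH)))
  k <- trend$k_ref + trend$slope * (pH - trend$pH_ref)
  if (any(k < 0)) {
    warning(sprintf("rate trend evaluates negative at pH %s; clamped to 0",
                    paste(format(pH[k < 0]), collapse = ", ")))
    k <- pmax(k, 0)
  }
  k
}

#' Equilibrium occupancy of the filament-end birth--death chain
#'
#' For the chain M0 <-> M1 <-> M2 with a single binding rate `k_on`
#' (both up-steps) and a single dissociation rate `k_off` (both
#' down-steps), detailed balance gives the stationary distribution
#' \deqn{(P_{M0}, P_{M1}, P_{M2}) = (1, K, K^2) / (1 + K + K^2), \qquad K = k_{on}/k_{off}.}
#'
#' @param k_on binding rate, s^-1 (>= 0).
#' @param k_off dissociation rate, s^-1 (> 0).
#' @return Named numeric vector `c(M0 =, M1 =, M2 =)` summing to 1.
#' @examples
#' equilibrium_distribution(0.2, 0.2)   # K = 1: uniform
#' equilibrium_distribution(0.4, 0.2)   # K = 2: (1, 2, 4)/7
#' @export
equilibrium_distribution <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, k_on >= 0,
            is.numeric(k_off), length(k_off) == 1L, k_off >= 0)
  if (k_off == 0)
    stop("degenerate chain: k_off = 0 has no proper equilibrium distribution")
  K <- k_on / k_off
  w <- c(M0 = 1, M1 = K, M2 = K^2)
  w / sum(w)
}

#' Mean number of bound monomers from state populations
#'
#' `N_average = 2 * P(M2) + 1 * P(M1) + 0 * P(M0)`: the average number of
#' RecA monomers bound between the donor and acceptor dyes, the scalar
#' summary of filament-end stability tracked across pH.
#'
#' @param p named numeric vector or list with elements `M0`, `M1`, `M2`
#'   (probabilities), e.g. from [equilibrium_distribution()] or
#'   [populations_from_fit()].
#' @return N_average, a number in \[0, 2\].
#' @export
average_monomers <- function(p) {
  p <- unlist(p)
  stopifnot(all(c("M0", "M1", "M2") %in% names(p)))
  pr <- p[c("M0", "M1", "M2")]
  if (any(pr < -1e-9) || abs(sum(pr) - 1) > 1e-6)
    stop("'p' must be a probability vector over M0/M1/M2 summing to 1")
  unname(2 * pr[["M2"]] + pr[["M1"]])
}

# Invert N_average -> K = k_on/k_off.
# N(K) = (K + 2 K^2)/(1 + K + K^2) gives (N-2) K^2 + (N-1) K + N = 0;
# the positive root is unique for N in (0, 2).
n_average_to_K <- function(N) {
  stopifnot(is.numeric(N), all(is.finite(N)))
  if (any(N <= 0 | N >= 2))
    stop("target N_average must lie strictly inside (0, 2)")
  disc <- (N - 1)^2 - 4 * N * (N - 2)
  ((1 - N) - sqrt(disc)) / (2 * (N - 2))
}

#' Per-pH rates calibrated to a linear N_average-vs-pH truth
#'
#' Chooses `k_on` at each pH (holding `k_off` fixed) so that the
#' equilibrium `N_average` of the occupancy chain is exactly linear in pH
#' with the requested slope, `N_average(pH_ref) = N_ref`.  Used to build
#' generator truths whose occupancy trend matches an observed slope.
#'
#' @param slope target N_average change per pH unit (monomers/pH).
#' @param pH_values pH grid; default [default_ph_grid()].
#' @param N_ref N_average at `pH_ref` (default 1.0).
#' @param pH_ref reference pH (default 7.0).
#' @param k_off fixed dissociation rate, s^-1 (default 0.2).
#' @return A `rate_table` data frame with columns `pH`, `k_on`, `k_off`.
#' @examples
#' occupancy_calibration(-0.29)
#' @export
occupancy_calibration <- function(slope, pH_values = default_ph_grid(),
                                  N_ref = 1.0, pH_ref = 7.0, k_off = 0.2) {
  stopifnot(length(slope) == 1L, is.finite(slope), k_off > 0)
  N <- N_ref + slope * (pH_values - pH_ref)
  K <- n_average_to_K(N)
  structure(data.frame(pH = pH_values, k_on = K * k_off, k_off = k_off),
            class = c("rate_table", "data.frame"))
}

#' Default pH grid
#'
#' `c(6.0, 6.3, 6.6, 7.0, 7.5, 8.0)`: the pH range accessible with
#' Mes (6.0--6.3), Mops (6.6--7.0) and Tris (7.5) buffers, plus pH 8.0.
#' @return Numeric vector of six pH values.
#' @export
default_ph_grid <- function() c(6.0, 6.3, 6.6, 7.0, 7.5, 8.0)
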