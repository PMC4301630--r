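# Linear pH-trend regression of occupancy and kinetic rates.

#' Fit a linear trend of a quantity versus pH
#'
#' Ordinary least squares of `y` on pH (weighted by `1/sigma^2` when
#' per-point errors are supplied).  pH is the controlled variable, so OLS
#' rather than orthogonal regression is appropriate.  The intercept is
#' also re-expressed at a reference pH for interpretability.
#'
#' @param pH numeric vector of distinct pH values (>= 3 points).
#' @param y response (e.g. N_average in monomers, or a rate in s^-1).
#' @param y_errors optional per-point standard errors.
#' @param pH_ref reference pH at which the fitted line is also reported.
#'
#' @details When per-point errors are supplied, the reported slope
#'   standard error is the larger of the residual-based (external) and
#'   error-propagated (internal) estimates, so a sample that happens to
#'   scatter less than its stated errors cannot understate the slope
#'   uncertainty.
#' @return Object of class `trend_fit`: `slope` (y units per pH unit),
#'   `intercept`, `value_at_ref`, `stderr_slope`, `r_squared`,
#'   `n_points`, and the underlying `lm` fit.
#' @examples
#' f <- fit_trend(6:8, 2 - 0.29 * (6:8))
#' f$slope      # -0.29 exactly
#' @export
fit_trend <- function(pH, y, y_errors = NULL, pH_ref = 7.0) {
  stopifnot(is.numeric(pH), is.numeric(y), length(pH) == length(y))
  if (length(pH) < 3L) stop("need at least 3 points to fit a pH trend")
  if (anyDuplicated(pH)) stop("pH values must be distinct")
  w <- NULL
  if (!is.null(y_errors)) {
    stopifnot(length(y_errors) == length(y), all(y_errors > 0))
    w <- 1 / y_errors^2
  }
  d <- data.frame(pH = pH, y = y)
  fm <- if (is.null(w)) lm(y ~ pH, data = d) else lm(y ~ pH, data = d, weights = w)
  sm <- summary(fm)
  stderr_slope <- sm$coefficients[2L, 2L]
  if (!is.null(w) && sm$sigma < 1)
    stderr_slope <- stderr_slope / sm$sigma   # internal (propagated) error
  structure(list(slope = unname(coef(fm)[2L]),
                 intercept = unname(coef(fm)[1L]),
                 value_at_ref = unname(predict(fm, data.frame(pH = pH_ref))),
                 pH_ref = pH_ref,
                 stderr_slope = stderr_slope,
                 r_squared = sm$r.squared,
                 n_points = length(pH),
                 fit = fm),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: slope %.4g +/- %.3g per pH unit (r^2 = %.3f, n = %d); value at pH %.1f: %.4g\n",
              x$slope, x$stderr_slope, x$r_squared, x$n_points,
              x$pH_ref, x$value_at_ref))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Assemble a per-condition summary with pH trends
#'
#' Joins per-pH populations and rates on a common pH grid, fits linear
#' trends to N_average, k_bind and k_diss, and computes the
#' binding/dissociation slope-magnitude ratio, the summary statistic for
#' whether pH acts more strongly on binding than on dissociation.
#'
#' @param populations data frame with columns `pH`, `P_M0`, `P_M1`,
#'   `P_M2` (and optionally `N_average`, recomputed otherwise, and
#'   `se_N_average`, used as weights in the N_average trend fit).
#' @param rates data frame with columns `pH`, `k_bind`, `k_diss` (and
#'   optionally `se_bind`, `se_diss`, used as weights in the trend fits).
#' @param condition label, e.g. `"WT"`.
#' @return Object of class `condition_summary`: `condition`, `table`
#'   (per-pH), `trend_n_average`, `trend_bind`, `trend_diss`
#'   ([fit_trend()] objects), `slope_ratio`.
#' @export
summarize_condition <- function(populations, rates = NULL, condition = "WT") {
  stopifnot(is.data.frame(populations),
            all(c("pH", "P_M0", "P_M1", "P_M2") %in% names(populations)))
  populations <- populations[order(populations$pH), ]
  if (!"N_average" %in% names(populations))
    populations$N_average <- 2 * populations$P_M2 + populations$P_M1
  tab <- populations
  trend_bind <- trend_diss <- NULL
  if (!is.null(rates)) {
    stopifnot(is.data.frame(rates), all(c("pH", "k_bind", "k_diss") %in% names(rates)))
    rates <- rates[order(rates$pH), ]
    if (!isTRUE(all.equal(populations$pH, rates$pH)))
      stop("pH grids differ between populations and rates: {",
           paste(format(setdiff(union(populations$pH, rates$pH),
                                intersect(populations$pH, rates$pH))),
                 collapse = ", "), "}")
    tab <- cbind(populations, rates[, setdiff(names(rates), "pH"), drop = FALSE])
    se_b <- if ("se_bind" %in% names(rates) && all(is.finite(rates$se_bind)))
      rates$se_bind else NULL
    se_d <- if ("se_diss" %in% names(rates) && all(is.finite(rates$se_diss)))
      rates$se_diss else NULL
    trend_bind <- fit_trend(rates$pH, rates$k_bind, se_b)
    trend_diss <- fit_trend(rates$pH, rates$k_diss, se_d)
  }
  se_n <- if ("se_N_average" %in% names(populations) &&
              all(is.finite(populations$se_N_average)) &&
              all(populations$se_N_average > 0))
    populations$se_N_average else NULL
  trend_n <- fit_trend(tab$pH, tab$N_average, se_n)
  slope_ratio <- if (!is.null(trend_bind) && trend_diss$slope != 0)
    abs(trend_bind$slope / trend_diss$slope) else NA_real_
  structure(list(condition = condition, table = tab,
                 trend_n_average = trend_n,
                 trend_bind = trend_bind, trend_diss = trend_diss,
                 slope_ratio = slope_ratio),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition_summary [%s]\n", x$condition))
  print(round(as.data.frame(lapply(x$table, as.numeric)), 4), row.names = FALSE)
  cat(sprintf("  N_average slope: %.3f +/- %.3f monomers/pH\n",
              x$trend_n_average$slope, x$trend_n_average$stderr_slope))
  if (!is.null(x$trend_bind)) {
    cat(sprintf("  k_bind slope:    %.3f +/- %.3f s^-1/pH\n",
                x$trend_bind$slope, x$trend_bind$stderr_slope))
    cat(sprintf("  k_diss slope:    %.3f +/- %.3f s^-1/pH\n",
                x$trend_diss$slope, x$trend_diss$stderr_slope))
    cat(sprintf("  |slope_bind / slope_diss| = %.2f\n", x$slope_ratio))
  }
  invisible(x)
}
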