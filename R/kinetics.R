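# The one-call model-fitting interface: run the full analysis chain on a
# dataset of intensity traces and return a classed result.

#' Fit pH-dependent filament-end kinetics to an smFRET dataset
#'
#' Runs the complete analysis on a set of intensity traces grouped by pH:
#' FRET trajectories, per-molecule FRET values (first-10-frames rule),
#' four-Gaussian histogram decomposition into populations and N_average,
#' per-molecule HMM idealization with Viterbi decoding, transition
#' classification and binding/dissociation rate estimation, and linear pH
#' trends of N_average and of both rates.
#'
#' @param dataset a `fret_dataset` from [simulate_dataset()] /
#'   [read_traces()], or a plain list of `intensity_trace` objects with
#'   `pH` fields.
#' @param rates if `FALSE`, only the histogram/occupancy branch is run
#'   (no HMM), which is much faster when only populations and N_average
#'   are needed.
#' @param n_states,restarts HMM settings, see [fit_hmm()].
#' @param bin_width histogram bin width.
#' @param state_means reference peak positions used for HMM
#'   initialization bookkeeping and occupancy mapping.
#' @param min_frames minimum analyzable frames for a trace to enter the
#'   kinetic branch.
#' @param n_boot bootstrap-over-molecules replicates for the per-pH rate
#'   standard errors (see [estimate_rates()]); molecule-level resampling
#'   captures trace-to-trace heterogeneity that per-event counting errors
#'   miss.  Set 0 for plain Poisson errors.
#' @return Object of class `fret_kinetics`: `table` (per-pH data frame
#'   with populations, N_average, rates and SEs, molecule/transition
#'   counts), `trend_n_average`, `trend_bind`, `trend_diss`
#'   ([fit_trend()] objects; rate trends `NULL` when `rates = FALSE`),
#'   `slope_ratio`, `histogram_fits` (per pH), `condition`, `exclusions`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(wt_config(n_molecules = 20, n_frames = 200,
#'                                  pH_values = c(6.0, 7.0, 8.0), seed = 7))
#' fit <- fret_kinetics(ds, rates = FALSE)
#' coef(fit)
#' }
#' @export
fret_kinetics <- function(dataset, rates = TRUE, n_states = 3L, restarts = 5L,
                          bin_width = 0.025,
                          state_means = c(M0 = 0.75, M1 = 0.60, M2 = 0.40),
                          min_frames = 30L, n_boot = 30L) {
  groups <- split_by_ph(dataset)
  condition <- if (inherits(dataset, "fret_dataset"))
    dataset$config$condition else "unknown"
  if (length(groups) == 0L) stop("dataset contains no traces")

  rows <- list()
  hist_fits <- list()
  rate_rows <- list()
  excl <- c(short = 0L, dark = 0L, hmm_failed = 0L)

  for (g in names(groups)) {
    traces <- groups[[g]]
    pH <- traces[[1L]]$pH
    ftr <- lapply(traces, compute_fret)

    vals <- vapply(ftr, molecule_fret_value, numeric(1))
    excl["short"] <- excl["short"] + sum(is.na(vals))
    hist_g <- build_histogram(vals, bin_width = bin_width)
    fit_g <- fit_histogram(hist_g)
    pops <- populations_from_fit(fit_g)
    hist_fits[[g]] <- fit_g

    row <- data.frame(pH = pH, P_M0 = pops[["M0"]], P_M1 = pops[["M1"]],
                      P_M2 = pops[["M2"]],
                      N_average = average_monomers(pops),
                      n_molecules = hist_g$n_molecules)
    if (n_boot > 0L) {
      # molecule-level bootstrap of the histogram decomposition; captures
      # the (heavy-tailed) instability of the bounded mixture fit that
      # per-bin counting errors miss
      v0 <- vals[!is.na(vals)]
      nb <- replicate(n_boot, tryCatch({
        p <- populations_from_fit(fit_histogram(build_histogram(
          sample(v0, replace = TRUE), bin_width = bin_width)))
        average_monomers(p)
      }, error = function(e) NA_real_))
      row$se_N_average <- stats::sd(nb, na.rm = TRUE)
    }
    if (rates) {
      ideals <- list()
      for (f in ftr) {
        af <- analyzable_frames(f)
        if (length(af) < min_frames) {
          excl["dark"] <- excl["dark"] + 1L
          next
        }
        id <- tryCatch({
          m <- suppressWarnings(fit_hmm(f, n_states = n_states,
                                        restarts = restarts))
          most_likely_path(m, f)
        }, error = function(e) NULL)
        if (is.null(id)) excl["hmm_failed"] <- excl["hmm_failed"] + 1L
        else ideals[[length(ideals) + 1L]] <- id
      }
      if (length(ideals) == 0L)
        stop("no usable traces for kinetic analysis at pH ", pH)
      re <- suppressWarnings(estimate_rates(ideals, state_means = state_means,
                                            n_boot = n_boot))
      row$k_bind <- re$k_bind
      row$k_diss <- re$k_diss
      row$se_bind <- re$se_bind
      row$se_diss <- re$se_diss
      row$n_transitions <- sum(re$n_by_class)
      rate_rows[[g]] <- re
    }
    rows[[g]] <- row
  }

  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$pH), ]
  rownames(tab) <- NULL
  if (nrow(tab) >= 3L) {
    summ <- summarize_condition(
      tab[, intersect(c("pH", "P_M0", "P_M1", "P_M2", "N_average",
                        "se_N_average"), names(tab))],
      if (rates) tab[, c("pH", "k_bind", "k_diss", "se_bind", "se_diss")] else NULL,
      condition = condition)
    trend_n <- summ$trend_n_average
    trend_b <- summ$trend_bind
    trend_d <- summ$trend_diss
    ratio <- summ$slope_ratio
  } else {
    trend_n <- trend_b <- trend_d <- NULL
    ratio <- NA_real_
  }

  structure(list(table = tab, trend_n_average = trend_n,
                 trend_bind = trend_b, trend_diss = trend_d,
                 slope_ratio = ratio, histogram_fits = hist_fits,
                 rate_estimates = if (rates) rate_rows else NULL,
                 condition = condition, exclusions = excl,
                 call = match.call()),
            class = "fret_kinetics")
}

#' @export
print.fret_kinetics <- function(x, ...) {
  cat(sprintf("fret_kinetics [%s]: %d pH conditions, %d molecules\n",
              x$condition, nrow(x$table), sum(x$table$n_molecules)))
  cols <- intersect(c("pH", "P_M0", "P_M1", "P_M2", "N_average",
                      "k_bind", "k_diss"), names(x$table))
  print(round(x$table[, cols], 4), row.names = FALSE)
  if (!is.null(x$trend_n_average))
    cat(sprintf("N_average slope: %.3f +/- %.3f monomers/pH\n",
                x$trend_n_average$slope, x$trend_n_average$stderr_slope))
  if (!is.null(x$trend_bind)) {
    cat(sprintf("k_bind slope: %.4f +/- %.4f, k_diss slope: %.4f +/- %.4f s^-1/pH",
                x$trend_bind$slope, x$trend_bind$stderr_slope,
                x$trend_diss$slope, x$trend_diss$stderr_slope))
    cat(sprintf("  (|ratio| = %.2f)\n", x$slope_ratio))
  }
  invisible(x)
}

#' @export
summary.fret_kinetics <- function(object, ...) {
  structure(list(fit = object), class = "summary.fret_kinetics")
}

#' @export
print.summary.fret_kinetics <- function(x, ...) {
  print(x$fit)
  cat("\nExclusions:", paste(names(x$fit$exclusions), x$fit$exclusions,
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$fit$trend_n_average)) {
    cat("\nN_average trend:\n  "); print(x$fit$trend_n_average)
  }
  if (!is.null(x$fit$trend_bind)) {
    cat("k_bind trend:\n  "); print(x$fit$trend_bind)
    cat("k_diss trend:\n  "); print(x$fit$trend_diss)
  }
  invisible(x)
}

#' @export
coef.fret_kinetics <- function(object, ...) {
  out <- c(slope_n_average = object$trend_n_average$slope)
  if (!is.null(object$trend_bind))
    out <- c(out, slope_k_bind = object$trend_bind$slope,
             slope_k_diss = object$trend_diss$slope,
             slope_ratio = object$slope_ratio)
  out
}

#' @export
plot.fret_kinetics <- function(x, ...) {
  has_rates <- !is.null(x$trend_bind)
  op <- par(mfrow = c(1, if (has_rates) 2 else 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- x$table
  plot(t$pH, t$N_average, pch = 15, ylim = c(0, 2), xlab = "pH",
       ylab = expression(N[average] ~ "(monomers)"),
       main = x$condition, ...)
  if (!is.null(x$trend_n_average))
    abline(x$trend_n_average$fit, lty = 2, col = "red")
  if (has_rates) {
    ylim <- range(0, t$k_bind, t$k_diss) * c(1, 1.2)
    plot(t$pH, t$k_bind, pch = 16, col = "blue", ylim = ylim,
         xlab = "pH", ylab = expression(rate ~ (s^-1)), main = x$condition)
    points(t$pH, t$k_diss, pch = 17, col = "darkorange")
    abline(x$trend_bind$fit, lty = 2, col = "blue")
    abline(x$trend_diss$fit, lty = 2, col = "darkorange")
    legend("topright", c("binding", "dissociation"), pch = c(16, 17),
           col = c("blue", "darkorange"), bty = "n")
  }
  invisible(x)
}

#' Compare fitted conditions side by side
#'
#' @param ... named [fret_kinetics()] fits (e.g. `WT = fit1, deltaC17 =
#'   fit2`).
#' @return Data frame with one row per condition: slopes, standard
#'   errors and slope ratio.
#' @export
compare_conditions <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "fret_kinetics")) fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, logical(1), "fret_kinetics")))
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, `[[`, character(1), "condition")
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(condition = nm[i],
               slope_n_average = f$trend_n_average$slope,
               se_n_average = f$trend_n_average$stderr_slope,
               slope_k_bind = if (!is.null(f$trend_bind)) f$trend_bind$slope else NA,
               slope_k_diss = if (!is.null(f$trend_diss)) f$trend_diss$slope else NA,
               slope_ratio = f$slope_ratio)
  }))
}
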