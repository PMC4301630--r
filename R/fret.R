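# Trace processing: FRET trajectories, per-molecule FRET values,
# per-condition histograms and their four-Gaussian decomposition.

#' Compute the FRET trajectory of one molecule
#'
#' Per-frame proximity ratio `E = acceptor / (donor + acceptor)`.  Values
#' are not clamped to \[0, 1\]: excursions outside carry noise information
#' used by the histogram fit.  Frames with non-positive total intensity
#' are marked invalid.  Donor photobleaching — detected as a collapse of
#' the 5-frame running mean of total intensity below 25% of the initial
#' (first-10-frame) level — truncates the analyzable range.
#'
#' @param trace an `intensity_trace`.
#' @return Object of class `fret_trace`: list with `molecule_id`,
#'   `efficiency` (per frame; NA where invalid), `valid` (logical per
#'   frame), `valid_range` (first/last analyzable frame), `dt`, `pH`.
#' @export
compute_fret <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$donor)
  if (n == 0L) stop("empty trace")
  total <- trace$donor + trace$acceptor
  E <- ifelse(total > 0, trace$acceptor / total, NA_real_)

  init_total <- mean(total[seq_len(min(10L, n))])
  last_good <- n
  if (is.finite(init_total) && init_total > 0 && n >= 5L) {
    run <- stats::filter(total, rep(1 / 5, 5), sides = 1)
    dead <- which(!is.na(run) & run < 0.25 * init_total)
    if (length(dead) > 0L) last_good <- max(dead[1L] - 5L, 0L)
  }
  valid <- seq_len(n) <= last_good & is.finite(E)
  structure(list(molecule_id = trace$molecule_id,
                 efficiency = E, valid = valid,
                 valid_range = if (any(valid)) range(which(valid)) else c(NA_integer_, NA_integer_),
                 dt = trace$dt, pH = trace$pH),
            class = "fret_trace")
}

#' Per-molecule FRET value from the first ten frames
#'
#' The molecule's FRET value is the arithmetic mean of its first 10 valid
#' frames (the convention used to build per-condition histograms from
#' thousands of molecules).  Molecules with fewer than 10 valid frames —
#' e.g. donor bleaching almost immediately — are excluded by returning
#' `NA` rather than raising.
#'
#' @param ftrace a [compute_fret()] result.
#' @return A single FRET value, or `NA_real_` when the molecule is
#'   excluded.
#' @export
molecule_fret_value <- function(ftrace) {
  stopifnot(inherits(ftrace, "fret_trace"))
  v <- ftrace$efficiency[ftrace$valid]
  if (length(v) < 10L) return(NA_real_)
  mean(v[1:10])
}

#' Build a per-condition FRET histogram
#'
#' Uniform bins of width `bin_width` (default 0.025, five-plus bins
#' between the M1 and M0 peaks) spanning at least `limits`, widened to
#' cover the data.  One count per molecule.
#'
#' @param values per-molecule FRET values ([molecule_fret_value()]);
#'   `NA`s (excluded molecules) are dropped.
#' @param bin_width bin width in FRET units.
#' @param limits minimal histogram span.
#' @return Object of class `fret_histogram`: list with `bin_edges`,
#'   `counts`, `n_molecules`.
#' @export
build_histogram <- function(values, bin_width = 0.025, limits = c(-0.2, 1.2)) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no FRET values to histogram")
  lo <- bin_width * floor(min(c(values, limits[1])) / bin_width)
  hi <- bin_width * ceiling(max(c(values, limits[2])) / bin_width)
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- graphics::hist(values, breaks = edges, plot = FALSE)$counts
  structure(list(bin_edges = edges, counts = counts,
                 n_molecules = length(values)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("fret_histogram: %d molecules in %d bins of width %.3g on [%.3g, %.3g]\n",
              x$n_molecules, length(x$counts), diff(x$bin_edges[1:2]),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.fret_histogram <- function(x, fit = NULL, ...) {
  ctr <- bin_centers(x)
  plot(ctr, x$counts, type = "h", lwd = 3, col = "grey60",
       xlab = "FRET efficiency", ylab = "molecules", ...)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "histogram_fit"))
    xx <- seq(min(x$bin_edges), max(x$bin_edges), length.out = 400)
    tot <- rep(0, length(xx))
    for (i in seq_len(nrow(fit$peaks))) {
      yy <- fit$peaks$amplitude[i] *
        exp(-(xx - fit$peaks$center[i])^2 / (2 * fit$peaks$width[i]^2))
      lines(xx, yy, col = i + 1, lwd = 1)
      tot <- tot + yy
    }
    lines(xx, tot, lwd = 2)
  }
  invisible(x)
}

bin_centers <- function(hist) {
  (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
}

#' Decompose a FRET histogram into donor-only + M2/M1/M0 Gaussian peaks
#'
#' Bounded Levenberg--Marquardt least squares of a four-Gaussian sum to
#' the binned counts with iterated Poisson weights: the first pass uses
#' observed-count weights, then the weights are recomputed from the
#' fitted model and the fit repeated (IRLS, approximating the Poisson
#' maximum likelihood).  Weighting by observed counts alone would
#' over-weight downward-fluctuating sparse bins and systematically
#' shrink minority peaks.  The
#' donor-only center is constrained to \[-0.05, 0.1\]; the state peaks are
#' initialized at the canonical positions 0.40 / 0.60 / 0.75 and kept in
#' non-overlapping windows (M2 in \[0.3, 0.5\], M1 in \[0.5, 0.7\], M0 in
#' \[0.65, 0.85\]) to prevent label swapping.  Widths are bounded in
#' \[0.01, 0.15\].
#'
#' @param hist a [build_histogram()] result with at least 4 occupied bins.
#' @param init_centers starting centers, named
#'   `donor_only`/`M2`/`M1`/`M0`.
#' @param max_iter maximum LM iterations.
#' @return Object of class `histogram_fit`: list with `peaks` (data frame
#'   `label`, `center`, `width`, `weight` — the peak's fraction of fitted
#'   area — and `amplitude`), `residual` (weighted SSE), `n_iter`,
#'   `converged`, plus the source histogram for plotting.
#' @export
fit_histogram <- function(hist,
                          init_centers = c(donor_only = 0, M2 = 0.40,
                                           M1 = 0.60, M0 = 0.75),
                          max_iter = 400) {
  stopifnot(inherits(hist, "fret_histogram"))
  if (sum(hist$counts > 0) < 4L)
    stop("histogram has fewer than 4 occupied bins; cannot fit 4 peaks")
  x <- bin_centers(hist)
  y <- hist$counts

  labels <- c("donor_only", "M2", "M1", "M0")
  ctr0 <- unname(init_centers[labels])
  amp0 <- vapply(ctr0, function(c0) max(y[abs(x - c0) <= 0.05], 1), numeric(1))
  par0 <- c(amp0, ctr0, rep(0.05, 4))
  lower <- c(rep(0, 4), c(-0.05, 0.30, 0.50, 0.65), rep(0.01, 4))
  upper <- c(rep(Inf, 4), c(0.10, 0.50, 0.70, 0.85), rep(0.15, 4))

  model <- function(p) {
    a <- p[1:4]; mu <- p[5:8]; s <- p[9:12]
    rowSums(vapply(1:4, function(i) a[i] * exp(-(x - mu[i])^2 / (2 * s[i]^2)),
                   numeric(length(x))))
  }

  w <- 1 / sqrt(pmax(y, 1))
  fit <- NULL
  for (pass in 1:4) {     # pass 1: observed weights; then model weights
    fit <- minpack.lm::nls.lm(par = if (is.null(fit)) par0 else fit$par,
                              lower = lower, upper = upper,
                              fn = function(p) w * (model(p) - y),
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, maxfev = 10000))
    # intermediate passes may exhaust maxiter (info -1) while the weights
    # are still moving; only the final pass must converge
    if (!(fit$info %in% c(1:4, if (pass < 4) -1L)))
      stop("histogram fit did not converge (nls.lm info = ", fit$info, ", ",
           fit$message, "); initial centers were ",
           paste(format(ctr0), collapse = ", "),
           "; final residual ", format(fit$deviance))
    w <- 1 / sqrt(pmax(model(fit$par), 0.5))
  }
  p <- fit$par
  a <- p[1:4]; mu <- p[5:8]; s <- p[9:12]
  area <- a * s * sqrt(2 * pi)
  peaks <- data.frame(label = labels, center = mu, width = s,
                      weight = if (sum(area) > 0) area / sum(area) else rep(0, 4),
                      amplitude = a, stringsAsFactors = FALSE)
  # canonical ordering among the three state peaks (windows overlap at
  # [0.65, 0.7]; relabel by center if the fit inverted M1/M0 there)
  st <- peaks[peaks$label != "donor_only", ]
  st <- st[order(st$center), ]
  st$label <- c("M2", "M1", "M0")
  peaks <- rbind(peaks[peaks$label == "donor_only", ], st)
  rownames(peaks) <- peaks$label

  structure(list(peaks = peaks, residual = fit$deviance,
                 n_iter = fit$niter, converged = TRUE, hist = hist),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("histogram_fit: %d molecules, weighted SSE %.4g\n",
              x$hist$n_molecules, x$residual))
  print(x$peaks[, c("label", "center", "width", "weight")], row.names = FALSE)
  invisible(x)
}

#' State populations from a histogram fit
#'
#' Normalized probabilities of the three occupancy states.  The
#' donor-only peak is an acceptor-photophysics artifact, not a filament
#' state, and is excluded before normalization.
#'
#' @param fit a [fit_histogram()] result.
#' @return Named numeric vector `c(M0 =, M1 =, M2 =)` summing to 1.
#' @export
populations_from_fit <- function(fit) {
  stopifnot(inherits(fit, "histogram_fit"))
  w <- setNames(fit$peaks$weight, fit$peaks$label)[c("M0", "M1", "M2")]
  if (sum(w) <= 0) stop("all three state weights are zero; no populations")
  w / sum(w)
}
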