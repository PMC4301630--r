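# Synthetic smFRET trace generator: continuous-time birth-death occupancy
# chain observed through a noisy two-channel emission model.

#' Simulate one occupancy state path of the filament end
#'
#' Exact (Gillespie) continuous-time simulation of the birth--death chain
#' M0 <-> M1 <-> M2 with up-rate `k_on` from M0 and M1 and down-rate
#' `k_off` from M1 and M2, discretized to frames by majority occupancy:
#' each frame is labelled with the state occupying the largest share of
#' its interval, so events shorter than about dt/2 are blurred away, as in
#' real camera-limited recordings.
#'
#' The initial state is drawn from [equilibrium_distribution()] when
#' `init_state` is `NULL` (falling back to M0/M2 for frozen or absorbing
#' parameter choices).  Uses R's global RNG stream.
#'
#' @param k_on,k_off binding and dissociation rates, s^-1 (>= 0).
#' @param n_frames number of frames.
#' @param dt frame interval, seconds.
#' @param init_state optional initial occupancy in `0:2`.
#' @return Object of class `state_path`: list with `states` (integer
#'   occupancy 0/1/2 per frame), `dt`, `transitions` (data frame `time`,
#'   `from`, `to`, exact event record) and `init_state`.
#' @export
simulate_state_path <- function(k_on, k_off, n_frames, dt, init_state = NULL) {
  stopifnot(k_on >= 0, k_off >= 0, n_frames >= 1, dt > 0)
  if (is.null(init_state)) {
    init_state <- if (k_off > 0) {
      sample(0:2, 1L, prob = equilibrium_distribution(k_on, k_off))
    } else if (k_on > 0) 2L else 0L
  }
  init_state <- as.integer(init_state)
  stopifnot(init_state %in% 0:2)

  t_end <- n_frames * dt
  cap <- max(16L, ceiling(1.5 * t_end * (k_on + k_off)) + 32L)
  times <- numeric(cap); froms <- integer(cap); tos <- integer(cap)
  n_ev <- 0L
  s <- init_state; t_now <- 0
  repeat {
    up <- if (s < 2L) k_on else 0
    down <- if (s > 0L) k_off else 0
    r_tot <- up + down
    if (r_tot <= 0) break
    t_now <- t_now + rexp(1L, r_tot)
    if (t_now >= t_end) break
    s_new <- if (runif(1L) < up / r_tot) s + 1L else s - 1L
    n_ev <- n_ev + 1L
    if (n_ev > length(times)) {   # grow geometrically
      times <- c(times, numeric(length(times)))
      froms <- c(froms, integer(length(froms)))
      tos <- c(tos, integer(length(tos)))
    }
    times[n_ev] <- t_now; froms[n_ev] <- s; tos[n_ev] <- s_new
    s <- s_new
  }
  times <- times[seq_len(n_ev)]
  froms <- froms[seq_len(n_ev)]
  tos <- tos[seq_len(n_ev)]

  states <- discretize_majority(init_state, times, tos, n_frames, dt)
  structure(list(states = states, dt = dt,
                 transitions = data.frame(time = times, from = froms, to = tos),
                 init_state = init_state),
            class = "state_path")
}

# Majority-occupancy discretization of a piecewise-constant path.
discretize_majority <- function(init_state, times, tos, n_frames, dt) {
  if (length(times) == 0L) return(rep(init_state, n_frames))
  t_end <- n_frames * dt
  edges <- (0:n_frames) * dt
  brk <- sort(unique(c(edges, times)))
  brk <- brk[brk <= t_end]
  if (brk[length(brk)] < t_end) brk <- c(brk, t_end)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  seg_len <- diff(brk)
  seg_state <- c(init_state, tos)[findInterval(mid, times) + 1L]
  seg_frame <- pmin(floor(mid / dt) + 1L, n_frames)
  occ <- matrix(0, nrow = n_frames, ncol = 3L)
  for (k in seq_along(seg_len))
    occ[seg_frame[k], seg_state[k] + 1L] <-
      occ[seg_frame[k], seg_state[k] + 1L] + seg_len[k]
  max.col(occ, ties.method = "first") - 1L
}

#' Emit donor/acceptor intensities for a state path
#'
#' Per frame, the mean acceptor intensity is `E * total_intensity` and the
#' mean donor intensity `(1 - E) * total_intensity`, where E is the FRET
#' efficiency of the frame's occupancy state; independent Gaussian noise
#' of SD `noise_sd` is added to each channel, so the resulting FRET noise
#' is state-dependent, as in real data.  With probability
#' `donor_only_fraction` the molecule has no active acceptor and emits at
#' E = 0 throughout.  An exponential acceptor-bleach time switches the
#' remaining frames to E = 0; an exponential donor-bleach time zeroes both
#' channels, ending the analyzable trace.
#'
#' @param path a [simulate_state_path()] result.
#' @param cfg an [emission_config()].
#' @param molecule_id identifier stored with the trace.
#' @return Object of class `intensity_trace`: list with `molecule_id`,
#'   `donor`, `acceptor`, `dt`, `pH` (NA here; set by
#'   [simulate_dataset()]), and `truth` (state path, donor-only flag and
#'   bleach times, kept for parameter-recovery oracles).
#' @export
emit_intensities <- function(path, cfg, molecule_id = "mol") {
  stopifnot(inherits(path, "state_path"), inherits(cfg, "emission_config"))
  n <- length(path$states)
  if (n == 0L) stop("empty state path")
  donor_only <- runif(1L) < cfg$donor_only_fraction
  t_acc <- if (cfg$acceptor_bleach_rate > 0) rexp(1L, cfg$acceptor_bleach_rate) else Inf
  t_don <- if (cfg$donor_bleach_rate > 0) rexp(1L, cfg$donor_bleach_rate) else Inf

  tmid <- (seq_len(n) - 0.5) * path$dt
  E <- unname(cfg$state_means[path$states + 1L])
  if (donor_only) E[] <- 0
  E[tmid >= t_acc] <- 0
  acc_mean <- E * cfg$total_intensity
  don_mean <- (1 - E) * cfg$total_intensity
  dead <- tmid >= t_don
  acc_mean[dead] <- 0
  don_mean[dead] <- 0
  donor <- don_mean + rnorm(n, 0, cfg$noise_sd)
  acceptor <- acc_mean + rnorm(n, 0, cfg$noise_sd)

  structure(list(molecule_id = molecule_id, donor = donor,
                 acceptor = acceptor, dt = path$dt, pH = NA_real_,
                 truth = list(states = path$states,
                              transitions = path$transitions,
                              donor_only = donor_only,
                              acceptor_bleach_time = t_acc,
                              donor_bleach_time = t_don)),
            class = "intensity_trace")
}

# Per-molecule seed derived from the root seed by counter, kept below
# 2^31 so set.seed() accepts it; doubles are exact in this range.
molecule_seed <- function(root, index) {
  as.integer((abs(as.numeric(root)) %% 2147483647 * 48271 + index * 7919) %%
               2147483629) + 1L
}

#' Simulate a full synthetic smFRET dataset
#'
#' Generates `n_molecules` intensity traces at each pH of the configured
#' grid, with true rates taken from the configured trends (or explicit
#' rate table), each trace carrying its ground truth.  Each molecule uses
#' its own counter-derived RNG stream, so the output is fully reproducible
#' under the root seed and invariant to subsetting.
#'
#' @param config a [simulation_config()], e.g. [wt_config()].
#' @return Object of class `fret_dataset`: list with `traces` (list of
#'   `intensity_trace`) and `config`.
#' @examples
#' ds <- simulate_dataset(wt_config(n_molecules = 3, pH_values = c(6, 8),
#'                                  n_frames = 50, seed = 42))
#' length(ds$traces)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rt <- true_rates(config)
  traces <- vector("list", nrow(rt) * config$n_molecules)
  idx <- 0L
  for (i in seq_len(nrow(rt))) {
    for (m in seq_len(config$n_molecules)) {
      idx <- idx + 1L
      set.seed(molecule_seed(config$seed, idx))
      path <- simulate_state_path(rt$k_on[i], rt$k_off[i],
                                  config$n_frames, config$dt)
      tr <- emit_intensities(path, config$emission,
                             molecule_id = sprintf("pH%s_m%04d",
                                                   format(rt$pH[i]), m))
      tr$pH <- rt$pH[i]
      traces[[idx]] <- tr
    }
  }
  structure(list(traces = traces, config = config), class = "fret_dataset")
}

#' @export
print.fret_dataset <- function(x, ...) {
  pHs <- vapply(x$traces, `[[`, numeric(1), "pH")
  cat(sprintf("fret_dataset [%s]: %d traces, %d frames each (dt = %g s)\n",
              x$config$condition, length(x$traces), x$config$n_frames,
              x$config$dt))
  print(table(pH = pHs))
  invisible(x)
}

#' Split a dataset's traces by pH condition
#'
#' @param dataset a `fret_dataset` (or plain list of `intensity_trace`).
#' @return Named list of trace lists, one per pH, in increasing pH order.
#' @export
split_by_ph <- function(dataset) {
  traces <- if (inherits(dataset, "fret_dataset")) dataset$traces else dataset
  pHs <- vapply(traces, `[[`, numeric(1), "pH")
  out <- split(traces, factor(pHs, levels = sort(unique(pHs))))
  out
}
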