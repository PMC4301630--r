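# Hidden Markov model trace idealization: Gaussian emissions on FRET
# efficiency, per-molecule Baum-Welch fitting and Viterbi decoding.

#' Frames of a FRET trace usable for kinetic idealization
#'
#' Valid frames (before donor bleaching) with any trailing acceptor-bleach
#' plateau removed: a run of frames whose 20-frame running mean of E stays
#' below 0.1 through the end of the trace is an acceptor-dark segment, not
#' a biochemical state, and is excluded from HMM fitting.  Whole-trace
#' dark molecules (donor-only) yield an empty result.
#'
#' @param ftrace a [compute_fret()] result.
#' @param window running-mean window (frames).
#' @param threshold E level below which a trailing plateau counts as dark.
#' @return Integer vector of frame indices (possibly empty).
#' @export
analyzable_frames <- function(ftrace, window = 20L, threshold = 0.1) {
  stopifnot(inherits(ftrace, "fret_trace"))
  idx <- which(ftrace$valid)
  n <- length(idx)
  if (n == 0L) return(integer(0))
  E <- ftrace$efficiency[idx]
  if (n >= window) {
    rm <- stats::filter(E, rep(1 / window, window), sides = 1)
    rm <- rm[window:n]  # rm[j] = mean of E[j:(j+window-1)], j = 1..n-window+1
    low <- !is.na(rm) & rm < threshold
    if (any(low)) {
      # earliest window start from which every later window is also dark
      # and the tail mean itself is dark
      start <- which(rev(cumprod(rev(low))) == 1)
      if (length(start) > 0L) {
        j <- start[1L]
        if (mean(E[j:n]) < threshold) idx <- idx[seq_len(j - 1L)]
      }
    }
  }
  idx
}

#' Fit a Gaussian-emission HMM to one FRET trace
#'
#' Baum--Welch EM on the analyzable frames, with `n_states` hidden states
#' emitting Gaussian-distributed FRET efficiencies.  Initialization places
#' the state means at the canonical peak positions (0.75/0.60/0.40 for 3
#' states), SDs at 0.05, and transitions at 0.9 self-probability; further
#' random restarts perturb the means and the best-likelihood solution is
#' kept.  States are canonicalized by descending mean (M0 first) so
#' decoded paths are label-unique.  States accumulating less than one
#' frame of posterior occupancy are flagged as pruned.
#'
#' @param ftrace a [compute_fret()] result (or bare numeric vector of E
#'   values).
#' @param n_states number of hidden states (default 3: M0/M1/M2).
#' @param init optional `hmm_model` used as the sole initialization.
#' @param restarts number of initializations (first canonical, rest
#'   randomly perturbed).
#' @param max_iter EM iteration cap.
#' @param tol convergence when the log-likelihood gain per frame drops
#'   below this.
#' @param sd_floor lower bound on emission SDs, in E units.
#' @return Object of class `hmm_model`: `n_states`, `means`, `sds`,
#'   `transition_matrix`, `initial_probs`, `log_likelihood`,
#'   `loglik_trace`, `n_iter`, `converged`, `pruned`, `restart`,
#'   `occupancy`.
#' @export
fit_hmm <- function(ftrace, n_states = 3L, init = NULL, restarts = 5L,
                    max_iter = 500L, tol = 1e-6, sd_floor = 1e-3) {
  x <- if (inherits(ftrace, "fret_trace"))
    ftrace$efficiency[analyzable_frames(ftrace)] else as.numeric(ftrace)
  if (length(x) < 30L)
    stop("trace has fewer than 30 analyzable frames; cannot fit an HMM")
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 1L)

  canonical_means <- if (n_states == 3L) c(0.75, 0.60, 0.40)
    else seq(max(x), min(x), length.out = n_states)

  make_init <- function(r) {
    if (!is.null(init)) {
      stopifnot(inherits(init, "hmm_model"))
      return(list(means = init$means, sds = init$sds,
                  trans = init$transition_matrix, pi0 = init$initial_probs))
    }
    mu <- canonical_means
    if (r > 1L) mu <- pmin(pmax(mu + rnorm(n_states, 0, 0.05), -0.1), 1.1)
    A <- matrix(if (n_states > 1L) 0.1 / (n_states - 1L) else 0,
                n_states, n_states)
    diag(A) <- 0.9
    if (n_states == 1L) A[] <- 1
    list(means = mu, sds = rep(0.05, n_states), trans = A,
         pi0 = rep(1 / n_states, n_states))
  }

  n_try <- if (!is.null(init)) 1L else max(1L, as.integer(restarts))
  best <- NULL
  best_degen <- TRUE
  for (r in seq_len(n_try)) {
    ini <- make_init(r)
    em <- .hmm_em_cpp(x, ini$means, ini$sds, ini$trans, ini$pi0,
                      as.integer(max_iter), tol, sd_floor)
    # Gaussian-likelihood degeneracy: a state whose SD collapses to the
    # floor on a handful of frames has unbounded likelihood but no
    # physical meaning; prefer non-degenerate solutions when selecting
    # among restarts.
    degen <- any(em$sds <= 1.5 * sd_floor & em$occupancy < 5)
    take <- if (is.null(best)) TRUE
      else if (best_degen && !degen) TRUE
      else if (!best_degen && degen) FALSE
      else em$loglik > best$loglik
    if (take) {
      best <- em
      best$restart <- r
      best_degen <- degen
    }
  }
  dll <- diff(best$loglik_trace)
  if (length(dll) > 0 && any(dll < -1e-6 * pmax(abs(best$loglik_trace[-1]), 1)))
    warning("EM log-likelihood decreased during fitting (numerical issue)")
  if (!best$converged)
    warning("HMM fit did not converge within ", max_iter, " iterations")

  ord <- order(best$means, decreasing = TRUE)
  model <- structure(list(
    n_states = n_states,
    means = best$means[ord],
    sds = best$sds[ord],
    transition_matrix = matrix(best$trans, n_states)[ord, ord, drop = FALSE],
    initial_probs = best$init[ord],
    log_likelihood = best$loglik,
    loglik_trace = best$loglik_trace,
    n_iter = best$n_iter,
    converged = best$converged,
    occupancy = best$occupancy[ord],
    pruned = best$occupancy[ord] < 1,
    restart = best$restart), class = "hmm_model")
  model
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("hmm_model: %d states, logLik %.2f (%d EM iterations%s)\n",
              x$n_states, x$log_likelihood, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  tab <- data.frame(mean = x$means, sd = x$sds, occupancy = x$occupancy,
                    pruned = x$pruned)
  print(round(tab, 4))
  invisible(x)
}

#' Most likely state path of a trace (Viterbi decoding)
#'
#' @param model a fitted [fit_hmm()] model (canonical state order:
#'   descending mean, M0 first).
#' @param ftrace the [compute_fret()] trace to decode.
#' @return Object of class `idealized_trace`: `molecule_id`, `state_path`
#'   (1-based indices into `state_means`), `state_means`,
#'   `log_likelihood` (of the decoded path), `frames` (decoded frame
#'   indices), `dt`, `pH`.
#' @export
most_likely_path <- function(model, ftrace) {
  stopifnot(inherits(model, "hmm_model"), inherits(ftrace, "fret_trace"))
  frames <- analyzable_frames(ftrace)
  if (length(frames) == 0L) stop("trace has no analyzable frames to decode")
  x <- ftrace$efficiency[frames]
  vit <- .hmm_viterbi_cpp(x, model$means, model$sds,
                          model$transition_matrix, model$initial_probs)
  structure(list(molecule_id = ftrace$molecule_id,
                 state_path = as.integer(vit$path),
                 state_means = model$means,
                 transition_matrix = model$transition_matrix,
                 occupancy = model$occupancy,
                 log_likelihood = vit$loglik,
                 frames = frames, dt = ftrace$dt, pH = ftrace$pH),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("idealized_trace %s: %d frames, %d states, %d transitions\n",
              x$molecule_id, length(x$state_path), length(x$state_means),
              sum(diff(x$state_path) != 0)))
  invisible(x)
}

#' Kinetic rates from an HMM transition matrix
#'
#' Converts per-frame transition probabilities to rates with the exact
#' exponential correction for the frame interval: the total exit rate
#' from state i is `-log(T_ii)/dt` (equivalently `-log(1 - p_leave)/dt`),
#' apportioned among destinations by their relative per-frame
#' probabilities.  For small `p` this reduces to `p/dt`.
#'
#' @param model a [fit_hmm()] model (or a bare row-stochastic matrix).
#' @param dt frame interval, seconds (> 0).
#' @return Matrix of rates in s^-1 (diagonal 0), rows = from-state.
#' @examples
#' A <- matrix(c(0.98, 0.02, 0.03, 0.97), 2, byrow = TRUE)
#' transition_rates_from_model(A, dt = 0.1)  # k12 = -log(0.98)/0.1
#' @export
transition_rates_from_model <- function(model, dt) {
  stopifnot(dt > 0)
  A <- if (inherits(model, "hmm_model")) model$transition_matrix else as.matrix(model)
  if (any(abs(rowSums(A) - 1) > 1e-6)) stop("transition matrix rows must sum to 1")
  off <- A; diag(off) <- 0
  if (any(off >= 1))
    stop("per-frame transition probability of 1: dt too coarse to resolve rates")
  S <- nrow(A)
  k <- matrix(0, S, S, dimnames = dimnames(A))
  for (i in seq_len(S)) {
    p_leave <- 1 - A[i, i]
    if (p_leave > 0) {
      k_exit <- -log(A[i, i]) / dt
      k[i, -i] <- k_exit * A[i, -i] / p_leave
    }
  }
  k
}

#' BIC-based selection of the number of HMM states
#'
#' Fits [fit_hmm()] for each candidate state count and returns the model
#' minimizing the Bayesian information criterion.  Off by default in the
#' pipeline: three FRET states (M0/M1/M2) are asserted by the assay
#' design, but the option documents that the data support that choice.
#'
#' @param ftrace a [compute_fret()] result.
#' @param states candidate state counts.
#' @param ... passed to [fit_hmm()].
#' @return The selected `hmm_model`, with a `bic_table` attribute.
#' @export
select_n_states <- function(ftrace, states = 2:4, ...) {
  x <- ftrace$efficiency[analyzable_frames(ftrace)]
  fits <- lapply(states, function(s) fit_hmm(ftrace, n_states = s, ...))
  n_par <- vapply(states, function(s) s * (s - 1) + 2 * s + (s - 1), numeric(1))
  bic <- -2 * vapply(fits, `[[`, numeric(1), "log_likelihood") +
    n_par * log(length(x))
  best <- which.min(bic)
  out <- fits[[best]]
  attr(out, "bic_table") <- data.frame(n_states = states, bic = bic)
  out
}
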