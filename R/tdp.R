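# Transition density plot analysis: collect transitions from idealized
# traces, classify them into binding/dissociation groups, estimate rates.

#' Extract state transitions from an idealized trace
#'
#' One record per state change in the Viterbi path, with the FRET level
#' before and after and the dwell time preceding the change.  The first
#' dwell of every trace is censored (its start was not observed) and is
#' marked so dwell statistics can exclude it.
#'
#' @param ideal a [most_likely_path()] result.
#' @return Data frame (class `transition_records`) with columns
#'   `molecule_id`, `frame`, `E_before`, `E_after`, `dwell_before` (s),
#'   `censored`.  Zero rows for constant paths.
#' @export
extract_transitions <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  p <- ideal$state_path
  r <- rle(p)
  n_runs <- length(r$lengths)
  if (n_runs < 2L) {
    out <- data.frame(molecule_id = character(0), frame = integer(0),
                      E_before = numeric(0), E_after = numeric(0),
                      dwell_before = numeric(0), censored = logical(0))
  } else {
    ends <- cumsum(r$lengths)
    out <- data.frame(
      molecule_id = ideal$molecule_id,
      frame = ideal$frames[ends[-n_runs] + 1L],
      E_before = ideal$state_means[r$values[-n_runs]],
      E_after = ideal$state_means[r$values[-1L]],
      dwell_before = r$lengths[-n_runs] * ideal$dt,
      censored = c(TRUE, rep(FALSE, n_runs - 2L)),
      stringsAsFactors = FALSE)
  }
  class(out) <- c("transition_records", "data.frame")
  out
}

#' Build a transition density plot (TDP)
#'
#' 2D histogram of (E before, E after) over all transitions.  Binding and
#' dissociation events fall on opposite sides of the diagonal; with three
#' FRET states the plot shows four off-diagonal groups.
#'
#' @param records row-bound [extract_transitions()] output.
#' @param bin_width bin width on both axes.
#' @param limits axis span.
#' @return Object of class `tdp_histogram`: `bin_edges`, `counts`
#'   (matrix, rows = E_before), `n_transitions`, `n_molecules`.
#' @export
build_tdp <- function(records, bin_width = 0.025, limits = c(-0.1, 1.1)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  lo <- bin_width * floor(min(c(records$E_before, records$E_after, limits[1])) / bin_width)
  hi <- bin_width * ceiling(max(c(records$E_before, records$E_after, limits[2])) / bin_width)
  edges <- seq(lo, hi, by = bin_width)
  bx <- cut(records$E_before, edges, include.lowest = TRUE)
  by <- cut(records$E_after, edges, include.lowest = TRUE)
  counts <- unclass(table(bx, by))
  dimnames(counts) <- NULL
  structure(list(bin_edges = edges, counts = counts,
                 n_transitions = nrow(records),
                 n_molecules = length(unique(records$molecule_id))),
            class = "tdp_histogram")
}

#' @export
print.tdp_histogram <- function(x, ...) {
  cat(sprintf("tdp_histogram: %d transitions from %d molecules (%d x %d bins)\n",
              x$n_transitions, x$n_molecules, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
plot.tdp_histogram <- function(x, ...) {
  ctr <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  image(ctr, ctr, x$counts, xlab = "E before transition",
        ylab = "E after transition",
        col = hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Classify transitions into binding/dissociation groups
#'
#' Each endpoint FRET level is assigned to the nearest reference state
#' mean; the (from, to) occupancy pair gives the class.  With three
#' states there are four legitimate groups: two binding (occupancy +1)
#' and two dissociation (occupancy -1).  Pairs differing by two occupancy
#' levels within one frame are physically two unresolved events and are
#' flagged `ANOMALOUS` (excluded from rate averages); equal-occupancy
#' pairs (possible when an HMM split one level across two states) are
#' flagged `SAME`.  Equidistant assignments break ties toward the lower
#' occupancy (higher-FRET) state.
#'
#' @param E_before,E_after FRET levels flanking each transition
#'   (vectorized), or a `transition_records` data frame as first argument.
#' @param state_means reference state means, descending (M0 first).
#' @return Character vector of labels among `BIND_M0_M1`, `BIND_M1_M2`,
#'   `DISS_M2_M1`, `DISS_M1_M0`, `SAME`, `ANOMALOUS`.
#' @examples
#' classify_transition(0.74, 0.61)                 # BIND_M0_M1
#' classify_transition(0.41, 0.59)                 # DISS_M2_M1
#' classify_transition(0.76, 0.40)                 # ANOMALOUS
#' @export
classify_transition <- function(E_before, E_after = NULL,
                                state_means = c(M0 = 0.75, M1 = 0.60, M2 = 0.40)) {
  if (is.data.frame(E_before)) {
    E_after <- E_before$E_after
    E_before <- E_before$E_before
  }
  state_means <- sort(unlist(state_means), decreasing = TRUE)  # occupancy 0,1,2
  nearest <- function(E)
    vapply(E, function(e) which.min(abs(e - state_means)) - 1L, integer(1))
  o_from <- nearest(E_before)
  o_to <- nearest(E_after)
  d <- o_to - o_from
  label <- character(length(d))
  label[d == 0] <- "SAME"
  label[abs(d) == 2] <- "ANOMALOUS"
  label[d == 1 & o_from == 0] <- "BIND_M0_M1"
  label[d == 1 & o_from == 1] <- "BIND_M1_M2"
  label[d == -1 & o_from == 2] <- "DISS_M2_M1"
  label[d == -1 & o_from == 1] <- "DISS_M1_M0"
  label
}

# Map each of a trace's fitted state means to the occupancy level (0/1/2)
# of the nearest reference mean. Duplicate mappings are legitimate: a
# 3-state HMM fit to a trace visiting fewer levels can split one level.
# States farther than `tol` from every reference level (e.g. a state
# capturing residual acceptor-dark frames near E = 0, or an in-between
# level) are unassignable and return NA; rate estimation excludes them,
# mirroring TDP practice of classifying only the on-group clusters.
# tol defaults to half the smallest inter-peak separation.
map_states_to_occupancy <- function(state_means,
                                    reference = c(M0 = 0.75, M1 = 0.60, M2 = 0.40),
                                    tol = NULL) {
  reference <- sort(unlist(reference), decreasing = TRUE)
  if (is.null(tol)) tol <- min(abs(diff(reference))) / 2
  vapply(state_means, function(m) {
    i <- which.min(abs(m - reference))
    if (abs(m - reference[i]) > tol) NA_integer_ else i - 1L
  }, integer(1))
}

#' Estimate binding and dissociation rates from idealized traces
#'
#' Pools all idealized traces of one condition.  Each trace's fitted
#' state means are mapped to the reference occupancy levels, and the
#' per-molecule HMM transition matrices are pooled with their posterior
#' state occupancies (frames per state) into one per-frame transition
#' probability matrix for the condition; per-frame probabilities are then
#' converted to rates with the exact frame-interval correction
#' (`k_exit = -log(1 - p_leave)/dt`, apportioned by destination, see
#' [transition_rates_from_model()]).  Using the Baum--Welch matrices
#' rather than Viterbi change-point counts matters: the posterior
#' accounts probabilistically for events too brief to survive Viterbi
#' smoothing, removing most of the missed-event bias.  For idealized
#' traces lacking a fitted matrix (e.g. constructed by hand) the Viterbi
#' path counts are used instead.
#'
#' The two binding channels (M0->M1, M1->M2) are combined into a single
#' `k_bind` by dwell weighting (weights = frames spent in each source
#' state) — equivalent to pooling dwells, so short traces do not
#' dominate — and likewise for `k_diss`.  Double-jump probability mass
#' (M0<->M2 within one frame) is anomalous (unresolved double events)
#' and excluded from both class averages.
#'
#' Uncertainties are Poisson counting errors (`k/sqrt(n_events)`), or
#' bootstrap-over-molecules SEs when `n_boot > 0`.
#'
#' @param ideals list of [most_likely_path()] results.
#' @param dt frame interval in seconds; defaults to the traces' own.
#' @param state_means reference peak positions used for occupancy
#'   mapping.
#' @param n_boot bootstrap replicates over molecules (0 = Poisson SEs).
#' @return Object of class `rate_estimates`: `k_bind`, `k_diss`,
#'   `se_bind`, `se_diss`, `n_by_class` (named Viterbi event counts),
#'   `n_anomalous`, `n_molecules`, `pH`.
#' @export
estimate_rates <- function(ideals, dt = NULL,
                           state_means = c(M0 = 0.75, M1 = 0.60, M2 = 0.40),
                           n_boot = 0L) {
  stopifnot(is.list(ideals), length(ideals) >= 1L)
  if (inherits(ideals, "idealized_trace")) ideals <- list(ideals)
  if (is.null(dt)) dt <- ideals[[1L]]$dt

  tally <- function(subset) {
    num <- matrix(0, 3, 3)   # expected frame-pair counts, occupancy x occupancy
    n_trans <- matrix(0, 3, 3)  # Viterbi change-point counts (bookkeeping)
    for (ideal in subset) {
      occ_map <- map_states_to_occupancy(ideal$state_means, state_means)
      # states with per-frame self-probability < 0.5 imply dwells shorter
      # than the frame discretization can represent; below the resolution
      # limit, not kinetic states -> unassignable
      if (!is.null(ideal$transition_matrix))
        occ_map[diag(ideal$transition_matrix) < 0.5] <- NA_integer_
      occ <- occ_map[ideal$state_path]
      if (length(occ) >= 2L) {
        from <- occ[-length(occ)] + 1L
        to <- occ[-1L] + 1L
        ok <- !is.na(from) & !is.na(to)
        for (i in 1:3) for (j in 1:3)
          if (i != j) n_trans[i, j] <- n_trans[i, j] + sum(ok & from == i & to == j)
      }
      if (!is.null(ideal$transition_matrix)) {
        A <- ideal$transition_matrix
        w <- ideal$occupancy
        for (i in seq_along(occ_map)) for (j in seq_along(occ_map)) {
          if (is.na(occ_map[i]) || is.na(occ_map[j])) next
          num[occ_map[i] + 1L, occ_map[j] + 1L] <-
            num[occ_map[i] + 1L, occ_map[j] + 1L] + w[i] * A[i, j]
        }
      } else if (length(occ) >= 2L) {
        from <- occ[-length(occ)] + 1L
        to <- occ[-1L] + 1L
        ok <- !is.na(from) & !is.na(to)
        for (i in 1:3) for (j in 1:3)
          num[i, j] <- num[i, j] + sum(ok & from == i & to == j)
      }
    }
    n_anom <- n_trans[1, 3] + n_trans[3, 1]
    n_frames <- rowSums(num)
    k <- pooled_rate_matrix(num, dt)
    w_bind <- n_frames[1:2]
    w_diss <- n_frames[2:3]
    k_bind <- if (sum(w_bind) > 0)
      sum(w_bind * c(k[1, 2], k[2, 3])) / sum(w_bind) else 0
    k_diss <- if (sum(w_diss) > 0)
      sum(w_diss * c(k[2, 1], k[3, 2])) / sum(w_diss) else 0
    list(k_bind = k_bind, k_diss = k_diss, n_trans = n_trans,
         n_anom = n_anom, n_frames = n_frames)
  }

  full <- tally(ideals)
  n_bind <- full$n_trans[1, 2] + full$n_trans[2, 3]
  n_diss <- full$n_trans[2, 1] + full$n_trans[3, 2]
  if (n_bind == 0) warning("no binding transitions observed; k_bind reported as 0 (data sparsity)")
  if (n_diss == 0) warning("no dissociation transitions observed; k_diss reported as 0 (data sparsity)")

  if (n_boot > 0L) {
    bs <- replicate(n_boot, {
      res <- tally(ideals[sample.int(length(ideals), replace = TRUE)])
      c(res$k_bind, res$k_diss)
    })
    se_bind <- sd(bs[1, ])
    se_diss <- sd(bs[2, ])
  } else {
    se_bind <- if (n_bind > 0) full$k_bind / sqrt(n_bind) else NA_real_
    se_diss <- if (n_diss > 0) full$k_diss / sqrt(n_diss) else NA_real_
  }

  pHs <- unique(vapply(ideals, function(i) i$pH %||% NA_real_, numeric(1)))
  structure(list(k_bind = full$k_bind, k_diss = full$k_diss,
                 se_bind = se_bind, se_diss = se_diss,
                 n_by_class = c(BIND_M0_M1 = full$n_trans[1, 2],
                                BIND_M1_M2 = full$n_trans[2, 3],
                                DISS_M1_M0 = full$n_trans[2, 1],
                                DISS_M2_M1 = full$n_trans[3, 2]),
                 n_anomalous = full$n_anom,
                 n_molecules = length(ideals),
                 pH = if (length(pHs) == 1L) pHs else NA_real_),
            class = "rate_estimates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert pooled per-frame transition-pair mass (rows = from-occupancy)
# into a rate matrix.  Primary route: generator estimation for a
# discretely observed Markov chain, Q = logm(P)/dt via eigendecomposition
# — the multi-state generalization of the scalar -log(1 - p)/dt
# correction, exact for point-sampled chains; the double-jump mass
# (M0<->M2 within one frame, two unresolved events) is thereby used to
# inform the one-step rates instead of being discarded, though it never
# enters a class average directly.  Falls back to the scalar per-row
# correction when the matrix log is not well defined (e.g. extremely
# sparse data).
pooled_rate_matrix <- function(num, dt) {
  n_frames <- rowSums(num)
  P <- num
  for (i in 1:3)
    P[i, ] <- if (n_frames[i] > 0) num[i, ] / n_frames[i]
              else replace(rep(0, 3), i, 1)
  Q <- tryCatch({
    e <- eigen(P)
    if (any(Mod(e$values) < 1e-12)) stop("singular")
    L <- Re(e$vectors %*% diag(log(as.complex(e$values)), 3) %*% solve(e$vectors)) / dt
    if (any(!is.finite(L))) stop("non-finite")
    L
  }, error = function(e) NULL)
  if (is.null(Q)) {
    # scalar fallback; double-jump mass excluded
    num[1, 3] <- num[3, 1] <- 0
    Q <- matrix(0, 3, 3)
    for (i in 1:3) {
      n_out <- sum(num[i, -i])
      if (n_frames[i] > 0 && n_out > 0) {
        p_leave <- n_out / n_frames[i]
        if (p_leave >= 1)
          stop("per-frame exit probability of 1: dt too coarse to resolve rates")
        Q[i, -i] <- -log(1 - p_leave) / dt * num[i, -i] / n_out
      }
    }
  }
  pmax(Q, 0) * (1 - diag(3))  # off-diagonal rates, clamped at 0
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("rate_estimates%s: k_bind = %.4g +/- %.2g s^-1, k_diss = %.4g +/- %.2g s^-1\n",
              if (is.finite(x$pH)) sprintf(" (pH %.1f)", x$pH) else "",
              x$k_bind, x$se_bind, x$k_diss, x$se_diss))
  cat("  transitions:", paste(names(x$n_by_class), x$n_by_class,
                              sep = "=", collapse = ", "),
      sprintf("(anomalous excluded: %d)\n", x$n_anomalous))
  invisible(x)
}

#' Replicate spread of rate estimates
#'
#' Applies [estimate_rates()] to each replicate set of idealized traces
#' and reports the mean and standard deviation across replicates — the
#' convention for error bars from independent measurements.
#'
#' @param replicate_sets list of lists of idealized traces.
#' @param ... passed to [estimate_rates()].
#' @return Data frame with one row per replicate plus attributes
#'   `mean_bind`, `mean_diss`, `sd_bind`, `sd_diss`.
#' @export
estimate_rates_replicates <- function(replicate_sets, ...) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 2L)
  ests <- lapply(replicate_sets, estimate_rates, ...)
  out <- data.frame(replicate = seq_along(ests),
                    k_bind = vapply(ests, `[[`, numeric(1), "k_bind"),
                    k_diss = vapply(ests, `[[`, numeric(1), "k_diss"))
  attr(out, "mean_bind") <- mean(out$k_bind)
  attr(out, "mean_diss") <- mean(out$k_diss)
  attr(out, "sd_bind") <- sd(out$k_bind)
  attr(out, "sd_diss") <- sd(out$k_diss)
  out
}
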