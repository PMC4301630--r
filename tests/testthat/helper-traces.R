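# Shared fixture builders; everything is generated in code at test time.

# Emission settings with no nuisance processes, for tests that isolate a
# single stage.
clean_emission <- function(noise_sd = 0) {
  emission_config(noise_sd = noise_sd, donor_only_fraction = 0,
                  acceptor_bleach_rate = 0, donor_bleach_rate = 0)
}

# Intensity trace realizing a prescribed occupancy sequence.
trace_from_states <- function(states, dt = 0.1, cfg = clean_emission(),
                              molecule_id = "fix") {
  path <- structure(list(states = as.integer(states), dt = dt,
                         transitions = data.frame(time = numeric(0),
                                                  from = integer(0),
                                                  to = integer(0)),
                         init_state = as.integer(states[1])),
                    class = "state_path")
  emit_intensities(path, cfg, molecule_id = molecule_id)
}

# Hand-built idealized trace (no HMM behind it).
ideal_from_path <- function(path, state_means = c(0.75, 0.60, 0.40),
                            dt = 0.1, molecule_id = "fix", pH = NA_real_) {
  structure(list(molecule_id = molecule_id,
                 state_path = as.integer(path),
                 state_means = state_means,
                 transition_matrix = NULL, occupancy = NULL,
                 log_likelihood = NA_real_,
                 frames = seq_along(path), dt = dt, pH = pH),
            class = "idealized_trace")
}

# Idealize every usable trace of a dataset; returns list of idealized traces.
idealize_all <- function(dataset, min_frames = 30L, ...) {
  ideals <- list()
  for (tr in dataset$traces) {
    f <- compute_fret(tr)
    if (length(analyzable_frames(f)) < min_frames) next
    id <- tryCatch(
      most_likely_path(suppressWarnings(fit_hmm(f, ...)), f),
      error = function(e) NULL)
    if (!is.null(id)) ideals[[length(ideals) + 1L]] <- id
  }
  ideals
}
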