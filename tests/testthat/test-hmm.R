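test_that("noiseless two-state trace is recovered exactly", {
  states <- rep(rep(c(0L, 1L), 20), each = 5)  # 0.75/0.60 alternating, 5-frame dwells
  f <- compute_fret(trace_from_states(states))
  m <- fit_hmm(f, n_states = 2L, restarts = 1L)
  expect_equal(m$means, c(0.75, 0.60), tolerance = 1e-8)
  # per-frame flip probability equals the flip count ratio
  n01 <- sum(states[-length(states)] == 0L & states[-1] == 1L)
  n0 <- sum(states[-length(states)] == 0L)
  expect_equal(m$transition_matrix[1, 2], n01 / n0, tolerance = 0.01)
  expect_true(m$converged)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(411)
  cfg <- clean_emission(noise_sd = 100)
  ds <- simulate_dataset(simulation_config(
    binding_trend = rate_trend(0.4, 0), dissociation_trend = rate_trend(0.4, 0),
    emission = cfg, pH_values = 7, n_molecules = 3, n_frames = 400, seed = 19))
  for (tr in ds$traces) {
    m <- suppressWarnings(fit_hmm(compute_fret(tr)))
    expect_true(all(diff(m$loglik_trace) > -1e-6 * abs(m$loglik_trace[-1])))
  }
})

test_that("state means are recovered within 0.03 at 10% intensity noise", {
  set.seed(412)
  cfg <- simulation_config(
    binding_trend = rate_trend(0.5, 0), dissociation_trend = rate_trend(0.5, 0),
    emission = clean_emission(noise_sd = 100),
    pH_values = 7, n_molecules = 8, n_frames = 600, seed = 37)
  ds <- simulate_dataset(cfg)
  got <- 0L
  for (tr in ds$traces) {
    if (length(unique(tr$truth$states)) < 3) next
    m <- suppressWarnings(fit_hmm(compute_fret(tr)))
    keep <- m$occupancy > 20          # states with real support in this trace
    ref <- c(0.75, 0.60, 0.40)[recafret:::map_states_to_occupancy(m$means[keep]) + 1]
    expect_equal(m$means[keep], ref, tolerance = 0.03)
    got <- got + 1L
  }
  expect_gt(got, 3L)
})

test_that("zero-noise Viterbi decoding reproduces the true path exactly", {
  set.seed(413)
  hits <- 0L
  for (r in 1:5) {
    p <- simulate_state_path(0.5, 0.5, 400, 0.1)
    if (length(unique(p$states)) < 3) next
    tr <- emit_intensities(p, clean_emission())
    f <- compute_fret(tr)
    id <- most_likely_path(suppressWarnings(fit_hmm(f)), f)
    occ <- recafret:::map_states_to_occupancy(id$state_means)[id$state_path]
    expect_identical(occ, p$states)
    hits <- hits + 1L
  }
  expect_gt(hits, 1L)
})

test_that("decoding at 10% noise agrees with the true path on >= 95% of frames", {
  set.seed(414)
  agree <- total <- 0
  for (r in 1:6) {
    p <- simulate_state_path(0.3, 0.3, 600, 0.1)
    tr <- emit_intensities(p, clean_emission(noise_sd = 100))
    f <- compute_fret(tr)
    id <- most_likely_path(suppressWarnings(fit_hmm(f)), f)
    occ <- recafret:::map_states_to_occupancy(id$state_means)[id$state_path]
    ok <- !is.na(occ)
    agree <- agree + sum(occ[ok] == p$states[ok])
    total <- total + sum(ok)
  }
  expect_gt(agree / total, 0.95)
})

test_that("Viterbi never uses zero-probability transitions", {
  A <- matrix(c(0.95, 0.05, 0.00,
                0.05, 0.90, 0.05,
                0.00, 0.05, 0.95), 3, 3, byrow = TRUE)
  model <- structure(list(n_states = 3L, means = c(0.75, 0.60, 0.40),
                          sds = rep(0.05, 3), transition_matrix = A,
                          initial_probs = rep(1 / 3, 3)), class = "hmm_model")
  # an abrupt 0.75 -> 0.40 jump must be decoded through the middle state
  f <- compute_fret(trace_from_states(c(rep(0L, 30), rep(2L, 30))))
  id <- most_likely_path(model, f)
  expect_true(all(abs(diff(id$state_path)) <= 1L))
})

test_that("a constant trace collapses to a single effective state", {
  f <- compute_fret(trace_from_states(rep(0L, 120),
                                      cfg = clean_emission(noise_sd = 10)))
  m <- suppressWarnings(fit_hmm(f, restarts = 1L))
  expect_identical(sum(!m$pruned), 1L)
  expect_equal(m$means[!m$pruned], 0.75, tolerance = 0.01)
})

test_that("frame-interval correction converts probabilities to rates", {
  A <- matrix(c(0.98, 0.02, 0.03, 0.97), 2, 2, byrow = TRUE)
  k <- transition_rates_from_model(A, dt = 0.1)
  expect_equal(k[1, 2], -log(0.98) / 0.1, tolerance = 1e-12)  # 0.2020 s^-1
  expect_equal(k[2, 1], -log(0.97) / 0.1, tolerance = 1e-12)

  expect_equal(transition_rates_from_model(diag(2), dt = 0.1),
               matrix(0, 2, 2))
  bad <- matrix(c(0, 1, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(transition_rates_from_model(bad, dt = 0.1), "dt too coarse")
  # multi-destination apportioning preserves the total exit rate
  A3 <- matrix(c(0.96, 0.03, 0.01,
                 0.02, 0.96, 0.02,
                 0.00, 0.04, 0.96), 3, 3, byrow = TRUE)
  k3 <- transition_rates_from_model(A3, dt = 0.1)
  expect_equal(sum(k3[1, ]), -log(0.96) / 0.1)
  expect_equal(k3[1, 2] / k3[1, 3], 3)
})

test_that("recovered rates approach truth as dt shrinks at fixed rates", {
  # missed-event bias grows with dt; at dt = 0.2 s the mean M1 dwell is
  # only ~8 frames, so the tolerance is wider there
  set.seed(415)
  tol <- c("0.2" = 0.20, "0.1" = 0.15, "0.05" = 0.15)
  for (dt in c(0.2, 0.1, 0.05)) {
    cfg <- simulation_config(
      binding_trend = rate_trend(0.3, 0), dissociation_trend = rate_trend(0.3, 0),
      emission = clean_emission(noise_sd = 100), pH_values = 7,
      n_molecules = 30, n_frames = round(60 / dt), dt = dt,
      seed = 1000 + round(100 * dt))
    ideals <- idealize_all(simulate_dataset(cfg))
    re <- suppressWarnings(estimate_rates(ideals))
    expect_lt(abs(re$k_bind - 0.3) / 0.3, tol[[as.character(dt)]])
    expect_lt(abs(re$k_diss - 0.3) / 0.3, tol[[as.character(dt)]])
  }
})
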