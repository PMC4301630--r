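test_that("frozen chain stays in its initial state", {
  p <- simulate_state_path(0, 0, 50, 0.1, init_state = 1L)
  expect_identical(p$states, rep(1L, 50))
  expect_identical(nrow(p$transitions), 0L)
})

test_that("every recorded transition changes occupancy by exactly one", {
  set.seed(402)
  for (r in 1:20) {
    p <- simulate_state_path(runif(1, 0.1, 0.8), runif(1, 0.1, 0.8), 200, 0.1)
    if (nrow(p$transitions) == 0) next
    expect_true(all(abs(p$transitions$to - p$transitions$from) == 1L))
    expect_true(all(diff(p$transitions$time) > 0))
    expect_true(all(p$states %in% 0:2))
  }
})

test_that("mean M0 dwell before a binding event approaches 1/k_on", {
  set.seed(403)
  k_on <- 0.5
  p <- simulate_state_path(k_on, 0.5, 1.6e5, 0.1)
  ev <- p$transitions
  # continuous-time dwells in M0 terminated by binding, first dwell censored
  enter0 <- ev$time[ev$to == 0L]
  leave0 <- ev$time[ev$from == 0L]
  if (p$init_state == 0L) leave0 <- leave0[-1L]  # drop censored first dwell
  n <- min(length(enter0), length(leave0))
  dwells <- leave0[seq_len(n)] - enter0[seq_len(n)]
  expect_gt(length(dwells), 2000)
  expect_lt(abs(mean(dwells) - 1 / k_on) / (1 / k_on), 0.05)
})

test_that("noiseless emission is an exact function of the state path", {
  p <- structure(list(states = c(0L, 0L, 1L, 2L, 1L), dt = 0.1,
                      transitions = data.frame(), init_state = 0L),
                 class = "state_path")
  tr <- emit_intensities(p, clean_emission())
  E <- tr$acceptor / (tr$donor + tr$acceptor)
  expect_equal(E, c(0.75, 0.75, 0.60, 0.40, 0.60))
  tr2 <- emit_intensities(p, clean_emission())
  expect_identical(tr$donor, tr2$donor)
  expect_identical(tr$acceptor, tr2$acceptor)
})

test_that("a donor-only molecule emits zero FRET throughout", {
  cfg <- emission_config(noise_sd = 0, donor_only_fraction = 1,
                         acceptor_bleach_rate = 0, donor_bleach_rate = 0)
  tr <- trace_from_states(c(0L, 1L, 2L, 1L), cfg = cfg)
  expect_equal(tr$acceptor, rep(0, 4))
  expect_equal(tr$donor, rep(cfg$total_intensity, 4))
  expect_true(tr$truth$donor_only)
})

test_that("noisy emission reproduces the configured state mean", {
  set.seed(404)
  cfg <- clean_emission(noise_sd = 0.05 * 1000)
  tr <- trace_from_states(rep(1L, 1e4), cfg = cfg)
  E <- tr$acceptor / (tr$donor + tr$acceptor)
  se <- sd(E) / sqrt(length(E))
  # 3 SE plus a small allowance for the ratio-estimator bias
  expect_lt(abs(mean(E) - 0.6), 3 * se + 1e-3)
})

test_that("dataset simulation is reproducible and bookkeeps truth", {
  cfg <- wt_config(n_molecules = 5, pH_values = c(6.0, 8.0), n_frames = 60,
                   seed = 17)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_length(ds1$traces, 10L)
  expect_true(all(vapply(ds1$traces, function(t) !is.null(t$truth), logical(1))))
  expect_equal(ds1, ds2)

  # byte-identical files under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_traces(ds1, d1); write_traces(ds2, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("lower pH means higher true occupancy under the WT trends", {
  cfg <- wt_config(n_molecules = 60, pH_values = c(6.0, 8.0), n_frames = 200,
                   seed = 23)
  ds <- simulate_dataset(cfg)
  occ <- vapply(ds$traces, function(t) mean(t$truth$states), numeric(1))
  pH <- vapply(ds$traces, `[[`, numeric(1), "pH")
  expect_gt(mean(occ[pH == 6.0]), mean(occ[pH == 8.0]))
})

test_that("invalid configurations name the offending field", {
  expect_error(wt_config(n_frames = 5), "n_frames")
  expect_error(wt_config(dt = 0), "dt")
  expect_error(wt_config(n_molecules = 0), "n_molecules")
  expect_error(emission_config(state_means = c(M0 = 0.4, M1 = 0.6, M2 = 0.75)),
               "state_means")
  expect_error(emission_config(donor_only_fraction = 1.2), "donor_only_fraction")
  expect_error(simulation_config(rate_table = data.frame(pH = 7)), "rate_table")
})
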