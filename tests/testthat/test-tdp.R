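test_that("transitions are extracted with dwell times and censoring flags", {
  id <- ideal_from_path(c(rep(1L, 5), rep(2L, 5), rep(1L, 5)))  # M0,M1,M0
  rec <- extract_transitions(id)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$E_before, c(0.75, 0.60))
  expect_equal(rec$E_after, c(0.60, 0.75))
  expect_equal(rec$dwell_before[2], 0.5)
  expect_identical(rec$censored, c(TRUE, FALSE))

  expect_identical(nrow(extract_transitions(ideal_from_path(rep(2L, 40)))), 0L)
})

test_that("transitions classify into the four binding/dissociation groups", {
  expect_identical(classify_transition(0.74, 0.61), "BIND_M0_M1")
  expect_identical(classify_transition(0.59, 0.41), "BIND_M1_M2")
  expect_identical(classify_transition(0.41, 0.59), "DISS_M2_M1")
  expect_identical(classify_transition(0.61, 0.74), "DISS_M1_M0")
  expect_identical(classify_transition(0.76, 0.40), "ANOMALOUS")
  expect_identical(classify_transition(0.74, 0.76), "SAME")
  # equidistant between M0 (0.75) and M1 (0.60): tie-break to lower
  # occupancy, i.e. 0.675 is assigned to M0
  expect_identical(classify_transition(0.675, 0.59), "BIND_M0_M1")
  expect_identical(classify_transition(0.675, 0.76), "SAME")
})

test_that("the TDP concentrates where transitions happen", {
  recs <- data.frame(molecule_id = "m", frame = 1:3,
                     E_before = c(0.74, 0.75, 0.76),
                     E_after = c(0.59, 0.60, 0.61),
                     dwell_before = 1, censored = FALSE)
  tdp <- build_tdp(recs)
  expect_identical(tdp$n_transitions, 3L)
  expect_identical(sum(tdp$counts), 3L)
  ctr <- (tdp$bin_edges[-1] + tdp$bin_edges[-length(tdp$bin_edges)]) / 2
  hot <- which(tdp$counts > 0, arr.ind = TRUE)
  expect_true(all(abs(ctr[hot[, 1]] - 0.75) < 0.05))
  expect_true(all(abs(ctr[hot[, 2]] - 0.60) < 0.05))
})

test_that("synthetic equilibrium data yields four transition groups and detailed balance", {
  set.seed(421)
  cfg <- simulation_config(
    binding_trend = rate_trend(0.3, 0), dissociation_trend = rate_trend(0.3, 0),
    emission = clean_emission(noise_sd = 100), pH_values = 7,
    n_molecules = 40, n_frames = 500, seed = 53)
  ds <- simulate_dataset(cfg)
  ideals <- idealize_all(ds)
  recs <- do.call(rbind, lapply(ideals, extract_transitions))
  cls <- classify_transition(recs)

  # the number of detected transitions tracks the frame-blurred truth
  truth_events <- sum(vapply(ds$traces,
                             function(t) sum(diff(t$truth$states) != 0),
                             numeric(1)))
  expect_lt(abs(nrow(recs) - truth_events) / truth_events, 0.10)
  tab <- table(factor(cls, levels = c("BIND_M0_M1", "BIND_M1_M2",
                                      "DISS_M2_M1", "DISS_M1_M0",
                                      "SAME", "ANOMALOUS")))
  expect_true(all(tab[1:4] > 0))
  expect_lt((tab[["SAME"]] + tab[["ANOMALOUS"]]) / nrow(recs), 0.05)

  # at equilibrium, binding and dissociation counts balance within
  # counting error (each trace can contribute at most a +/-2 imbalance)
  n_bind <- tab[["BIND_M0_M1"]] + tab[["BIND_M1_M2"]]
  n_diss <- tab[["DISS_M2_M1"]] + tab[["DISS_M1_M0"]]
  expect_lt(abs(n_bind - n_diss), 4 * sqrt(n_bind + n_diss))

  # TDP is approximately mirror-symmetric across the diagonal
  tdp <- build_tdp(recs)
  expect_lt(sum(abs(tdp$counts - t(tdp$counts))) / sum(tdp$counts), 0.5)
})

test_that("rates are recovered within 10% and are order invariant", {
  set.seed(422)
  cfg <- simulation_config(
    binding_trend = rate_trend(0.5, 0), dissociation_trend = rate_trend(0.2, 0),
    pH_values = 7, n_molecules = 80, n_frames = 600, seed = 71)
  ideals <- idealize_all(simulate_dataset(cfg))
  re <- suppressWarnings(estimate_rates(ideals))
  expect_gt(re$k_bind, 0.45); expect_lt(re$k_bind, 0.55)
  expect_gt(re$k_diss, 0.18); expect_lt(re$k_diss, 0.22)
  expect_true(all(re$n_by_class > 0))

  re_rev <- suppressWarnings(estimate_rates(rev(ideals)))
  expect_equal(re_rev$k_bind, re$k_bind)
  expect_equal(re_rev$k_diss, re$k_diss)
})

test_that("absent dissociation yields a zero rate with a sparsity warning", {
  # k_off = 0: filament frozen at full occupancy, no events at all
  ids <- lapply(1:4, function(i) ideal_from_path(rep(3L, 60)))
  w <- capture_warnings(re <- estimate_rates(ids, dt = 0.1))
  expect_match(w, "sparsity", all = FALSE)
  expect_identical(re$k_diss, 0)
  expect_identical(re$k_bind, 0)
})

test_that("replicate simulations give an honest replicate SD", {
  set.seed(423)
  sets <- lapply(1:3, function(r) {
    cfg <- simulation_config(
      binding_trend = rate_trend(0.4, 0), dissociation_trend = rate_trend(0.4, 0),
      emission = clean_emission(noise_sd = 100),
      pH_values = 7, n_molecules = 15, n_frames = 400, seed = 100 + r)
    idealize_all(simulate_dataset(cfg))
  })
  reps <- suppressWarnings(estimate_rates_replicates(sets))
  expect_identical(nrow(reps), 3L)
  # replicate SD is of the order of the counting error, not wildly off
  n_ev <- 15 * 40 * 0.4 * 2 / 3   # rough expected event count per replicate
  expect_lt(attr(reps, "sd_bind"), 6 * 0.4 / sqrt(n_ev))
  expect_gt(attr(reps, "sd_bind"), 0)
})
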