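test_that("FRET is the proximity ratio, unclamped", {
  tr <- structure(list(molecule_id = "m", donor = c(250, 500),
                       acceptor = c(750, 500), dt = 0.1, pH = NA_real_,
                       truth = NULL), class = "intensity_trace")
  f <- compute_fret(tr)
  expect_equal(f$efficiency, c(0.75, 0.5))
  expect_true(all(f$valid))

  noiseless_m1 <- trace_from_states(rep(1L, 40))
  expect_equal(compute_fret(noiseless_m1)$efficiency, rep(0.6, 40))
})

test_that("molecule FRET value averages exactly the first ten valid frames", {
  f <- compute_fret(trace_from_states(rep(2L, 30)))
  expect_equal(molecule_fret_value(f), 0.4)

  f2 <- compute_fret(trace_from_states(c(rep(1L, 10), rep(2L, 20))))
  expect_equal(molecule_fret_value(f2), 0.6)

  short <- compute_fret(trace_from_states(rep(0L, 9)))
  expect_true(is.na(molecule_fret_value(short)))
})

test_that("donor bleaching truncates the analyzable range", {
  cfg <- clean_emission(noise_sd = 20)
  tr <- trace_from_states(rep(0L, 100), cfg = cfg)
  tr$donor[61:100] <- rnorm(40, 0, 20)     # donor dark from frame 61
  tr$acceptor[61:100] <- rnorm(40, 0, 20)
  f <- compute_fret(tr)
  expect_lt(sum(f$valid), 65)
  expect_gt(sum(f$valid), 40)
})

test_that("histograms bookkeep counts and are permutation invariant", {
  h <- build_histogram(rep(0.75, 100))
  expect_identical(sum(h$counts), 100L)
  expect_identical(sum(h$counts > 0), 1L)

  vals <- rep(c(0.0, 0.4, 0.6, 0.75), times = c(10, 20, 30, 40))
  h4 <- build_histogram(vals)
  expect_identical(sum(h4$counts > 0), 4L)
  expect_identical(h4$n_molecules, 100L)

  set.seed(405)
  noisy <- rnorm(500, 0.6, 0.05)
  expect_identical(build_histogram(noisy)$counts,
                   build_histogram(sample(noisy))$counts)

  expect_true(is.na(molecule_fret_value(compute_fret(trace_from_states(0:5)))))
  h5 <- build_histogram(c(0.5, NA, 0.5))
  expect_identical(h5$n_molecules, 2L)
})

test_that("four-Gaussian fit recovers mixture parameters", {
  set.seed(406)
  vals <- c(rnorm(300, 0.00, 0.03), rnorm(500, 0.40, 0.05),
            rnorm(600, 0.60, 0.05), rnorm(600, 0.75, 0.05))
  fit <- fit_histogram(build_histogram(vals))
  pk <- fit$peaks
  expect_equal(pk["donor_only", "center"], 0.00, tolerance = 0.03)
  expect_equal(pk["M2", "center"], 0.40, tolerance = 0.03)
  expect_equal(pk["M1", "center"], 0.60, tolerance = 0.03)
  expect_equal(pk["M0", "center"], 0.75, tolerance = 0.03)
  expect_equal(pk["donor_only", "weight"], 0.15, tolerance = 0.03)
  pops <- populations_from_fit(fit)
  expect_equal(unname(pops),
               c(600, 600, 500) / 1700, tolerance = 0.05)
  expect_equal(sum(pops), 1, tolerance = 1e-9)
})

test_that("degenerate histograms fit sensibly", {
  set.seed(407)
  # no donor-only molecules -> near-zero donor-only weight
  v1 <- c(rnorm(400, 0.40, 0.05), rnorm(400, 0.60, 0.05), rnorm(400, 0.75, 0.05))
  f1 <- fit_histogram(build_histogram(v1))
  expect_lt(f1$peaks["donor_only", "weight"], 0.02)

  # single-state M0 sample -> M0 dominates (the M1 window, which extends
  # to 0.7, may absorb a little of the left tail)
  v2 <- rnorm(600, 0.75, 0.05)
  f2 <- fit_histogram(build_histogram(v2))
  expect_gt(f2$peaks["M0", "weight"], 0.85)
  p2 <- populations_from_fit(f2)
  expect_gt(p2[["M0"]], 0.85)
  expect_lt(p2[["M2"]], 0.05)

  expect_error(fit_histogram(build_histogram(rep(0.6, 50))), "occupied bins")
})

test_that("populations renormalize after excluding the donor-only peak", {
  fake <- structure(list(peaks = data.frame(
    label = c("donor_only", "M2", "M1", "M0"),
    center = c(0, 0.4, 0.6, 0.75), width = rep(0.05, 4),
    weight = c(0.2, 0.2, 0.2, 0.4), amplitude = rep(1, 4),
    row.names = c("donor_only", "M2", "M1", "M0"))),
    class = "histogram_fit")
  p <- populations_from_fit(fake)
  expect_equal(unname(p[c("M0", "M1", "M2")]), c(0.5, 0.25, 0.25))

  fake$peaks$weight <- c(0, 1, 0, 0)
  expect_equal(unname(populations_from_fit(fake)), c(0, 0, 1))

  fake$peaks$weight <- c(1, 0, 0, 0)
  expect_error(populations_from_fit(fake), "zero")
})

test_that("histogram-level and truth-level donor-only exclusion agree", {
  set.seed(408)
  cfg <- wt_config(n_molecules = 400, pH_values = 7.0, n_frames = 60, seed = 31)
  ds <- simulate_dataset(cfg)
  vals <- vapply(lapply(ds$traces, compute_fret), molecule_fret_value, numeric(1))
  donly <- vapply(ds$traces, function(t) t$truth$donor_only, logical(1))
  p_fit <- populations_from_fit(fit_histogram(build_histogram(vals)))
  p_truth <- populations_from_fit(fit_histogram(build_histogram(vals[!donly])))
  expect_lt(max(abs(p_fit - p_truth)), 0.02)
})
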