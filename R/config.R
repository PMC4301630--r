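#' Emission model configuration
#'
#' Parameters of the two-channel (donor/acceptor) observation model.
#' Each occupancy state has a characteristic FRET efficiency; per frame the
#' mean acceptor count is `E * total_intensity` and the mean donor count is
#' `(1 - E) * total_intensity`, each perturbed by independent Gaussian
#' noise.  A fraction of molecules lacks an active acceptor (donor-only,
#' E = 0 throughout); acceptor photobleaching (exponential time) drops the
#' remaining frames to E = 0; donor photobleaching ends the usable trace.
#'
#' @param state_means FRET efficiency per state, named `M0`, `M1`, `M2`,
#'   strictly decreasing with occupancy (filament growth stretches the
#'   ssDNA and lowers FRET).  Defaults 0.75/0.60/0.40.
#' @param total_intensity mean summed photon counts per frame (a.u.).
#' @param noise_sd per-channel Gaussian noise SD (a.u.); default 10% of
#'   `total_intensity`.
#' @param donor_only_fraction probability a molecule lacks an active
#'   acceptor; default 0.15.
#' @param acceptor_bleach_rate,donor_bleach_rate photobleaching rates,
#'   s^-1.
#' @return An object of class `emission_config`.
#' @export
emission_config <- function(state_means = c(M0 = 0.75, M1 = 0.60, M2 = 0.40),
                            total_intensity = 1000,
                            noise_sd = 0.10 * total_intensity,
                            donor_only_fraction = 0.15,
                            acceptor_bleach_rate = 0.01,
                            donor_bleach_rate = 0.005) {
  state_means <- unlist(state_means)
  if (is.null(names(state_means)) || !all(c("M0", "M1", "M2") %in% names(state_means)))
    names(state_means) <- c("M0", "M1", "M2")
  state_means <- state_means[c("M0", "M1", "M2")]
  if (!(state_means[["M0"]] > state_means[["M1"]] &&
        state_means[["M1"]] > state_means[["M2"]]))
    stop("configuration error in field 'state_means': must be strictly ",
         "decreasing with occupancy (M0 > M1 > M2)")
  if (any(state_means < 0 | state_means > 1))
    stop("configuration error in field 'state_means': values must lie in [0, 1]")
  stopifnot(total_intensity > 0)
  if (noise_sd < 0)
    stop("configuration error in field 'noise_sd': must be >= 0")
  if (donor_only_fraction < 0 || donor_only_fraction > 1)
    stop("configuration error in field 'donor_only_fraction': must be in [0, 1]")
  if (acceptor_bleach_rate < 0 || donor_bleach_rate < 0)
    stop("configuration error in field 'acceptor_bleach_rate'/'donor_bleach_rate': must be >= 0")
  structure(list(state_means = state_means,
                 total_intensity = total_intensity,
                 noise_sd = noise_sd,
                 donor_only_fraction = donor_only_fraction,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 donor_bleach_rate = donor_bleach_rate),
            class = "emission_config")
}

#' Simulation configuration for a synthetic smFRET dataset
#'
#' Bundles the kinetic truth (either a pair of linear [rate_trend()]s or an
#' explicit per-pH `rate_table`, e.g. from [occupancy_calibration()]), the
#' [emission_config()], and the acquisition geometry.
#'
#' @param binding_trend,dissociation_trend [rate_trend()] objects; ignored
#'   when `rate_table` is supplied.
#' @param rate_table optional data frame with columns `pH`, `k_on`,
#'   `k_off` giving the true rates explicitly at each pH.
#' @param emission an [emission_config()].
#' @param pH_values pH grid; default [default_ph_grid()].
#' @param n_molecules molecules per pH condition.
#' @param n_frames frames per trace; must be >= 11 so the first-10-frames
#'   histogram rule is satisfiable.
#' @param dt frame interval in seconds (> 0); default 0.1 s, a typical
#'   EMCCD exposure.
#' @param seed integer root seed; per-molecule streams are derived from it
#'   by counter so any subset of molecules is reproducible.
#' @param condition free-form label (e.g. `"WT"`, `"deltaC17"`).
#' @return An object of class `simulation_config`.
#' @seealso [wt_config()], [deltac17_config()], [simulate_dataset()]
#' @export
simulation_config <- function(binding_trend = NULL, dissociation_trend = NULL,
                              rate_table = NULL,
                              emission = emission_config(),
                              pH_values = default_ph_grid(),
                              n_molecules = 150, n_frames = 600, dt = 0.1,
                              seed = 1L, condition = "WT") {
  if (is.null(rate_table)) {
    if (!inherits(binding_trend, "rate_trend") ||
        !inherits(dissociation_trend, "rate_trend"))
      stop("configuration error in field 'binding_trend'/'dissociation_trend': ",
           "supply two rate_trend objects or an explicit 'rate_table'")
  } else {
    if (!is.data.frame(rate_table) ||
        !all(c("pH", "k_on", "k_off") %in% names(rate_table)))
      stop("configuration error in field 'rate_table': needs columns pH, k_on, k_off")
    pH_values <- rate_table$pH
  }
  if (!inherits(emission, "emission_config"))
    stop("configuration error in field 'emission': not an emission_config")
  if (length(pH_values) < 1 || any(!is.finite(pH_values)))
    stop("configuration error in field 'pH_values': non-empty finite values required")
  if (n_molecules < 1)
    stop("configuration error in field 'n_molecules': must be >= 1")
  if (n_frames < 11)
    stop("configuration error in field 'n_frames': must be >= 11 ",
         "(per-molecule FRET values average the first 10 frames)")
  if (dt <= 0)
    stop("configuration error in field 'dt': must be > 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("configuration error in field 'seed': not an integer")
  structure(list(binding_trend = binding_trend,
                 dissociation_trend = dissociation_trend,
                 rate_table = rate_table,
                 emission = emission,
                 pH_values = as.numeric(pH_values),
                 n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames),
                 dt = dt, seed = seed, condition = condition),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config [%s]: %d molecules x %d frames (dt = %g s) at pH {%s}\n",
              x$condition, x$n_molecules, x$n_frames, x$dt,
              paste(format(x$pH_values), collapse = ", ")))
  rt <- true_rates(x)
  print(rt, row.names = FALSE)
  invisible(x)
}

#' True per-pH rates implied by a simulation configuration
#'
#' @param config a [simulation_config()].
#' @return Data frame with columns `pH`, `k_on`, `k_off`.
#' @export
true_rates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$rate_table))
    return(as.data.frame(config$rate_table))
  data.frame(pH = config$pH_values,
             k_on = rate_at_pH(config$binding_trend, config$pH_values),
             k_off = rate_at_pH(config$dissociation_trend, config$pH_values))
}

#' Default wild-type and C-terminal-truncation configurations
#'
#' `wt_config()` applies the wild-type rate slopes (dissociation
#' +0.05 s^-1/pH, binding -0.10 s^-1/pH).  `deltac17_config()` applies the
#' slopes measured for the RecA mutant lacking the 17 charged C-terminal
#' residues (dissociation +0.01, binding -0.07).  In both, the absolute
#' anchor is k_off(pH 7) = 0.2 s^-1 with k_on(pH 7) chosen so the
#' equilibrium N_average at pH 7 equals 1.0 (i.e. k_on(pH 7) = 0.2 s^-1) —
#' a calibration of this package, since only the slopes are measured
#' quantities.
#'
#' `wt_occupancy_config()` / `deltac17_occupancy_config()` instead use
#' [occupancy_calibration()] so the true equilibrium N_average is exactly
#' linear in pH with slope -0.29 (WT) or -0.34 (deltaC17); these serve the
#' histogram/occupancy branch of the analysis, which probes equilibrium
#' populations rather than rates.
#'
#' @param n_molecules molecules per pH.
#' @param seed root seed.
#' @param ... further arguments passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
wt_config <- function(n_molecules = 150, seed = 1L, ...) {
  simulation_config(binding_trend = rate_trend(0.2, -0.10),
                    dissociation_trend = rate_trend(0.2, 0.05),
                    n_molecules = n_molecules, seed = seed,
                    condition = "WT", ...)
}

#' @rdname wt_config
#' @export
deltac17_config <- function(n_molecules = 150, seed = 1L, ...) {
  simulation_config(binding_trend = rate_trend(0.2, -0.07),
                    dissociation_trend = rate_trend(0.2, 0.01),
                    n_molecules = n_molecules, seed = seed,
                    condition = "deltaC17", ...)
}

#' @rdname wt_config
#' @export
wt_occupancy_config <- function(n_molecules = 500, seed = 1L, ...) {
  simulation_config(rate_table = occupancy_calibration(-0.29),
                    n_molecules = n_molecules, seed = seed,
                    condition = "WT", ...)
}

#' @rdname wt_config
#' @export
deltac17_occupancy_config <- function(n_molecules = 500, seed = 1L, ...) {
  simulation_config(rate_table = occupancy_calibration(-0.34),
                    n_molecules = n_molecules, seed = seed,
                    condition = "deltaC17", ...)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the [simulation_config()] fields.  Rate trends are
#' given as mappings with keys `k_ref`, `slope`, `pH_ref`; an explicit
#' `rate_table` may be given as a list of `{pH, k_on, k_off}` records.
#'
#' @param path path to a YAML file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  trend_of <- function(x) {
    if (is.null(x)) return(NULL)
    rate_trend(k_ref = x$k_ref, slope = x$slope,
               pH_ref = if (is.null(x$pH_ref)) 7 else x$pH_ref)
  }
  em_args <- y$emission
  em <- if (is.null(em_args)) emission_config()
        else do.call(emission_config, em_args)
  rt <- if (!is.null(y$rate_table))
          do.call(rbind, lapply(y$rate_table, as.data.frame))
        else NULL
  args <- list(binding_trend = trend_of(y$binding_trend),
               dissociation_trend = trend_of(y$dissociation_trend),
               rate_table = rt, emission = em)
  for (f in c("pH_values", "n_molecules", "n_frames", "dt", "seed", "condition"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(simulation_config, args)
}

#' Write a simulation configuration to YAML
#'
#' @param config a [simulation_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  y <- list(condition = config$condition,
            pH_values = config$pH_values,
            n_molecules = config$n_molecules,
            n_frames = config$n_frames,
            dt = config$dt,
            seed = config$seed,
            emission = unclass(config$emission))
  y$emission$state_means <- as.list(config$emission$state_means)
  if (!is.null(config$rate_table)) {
    rt <- as.data.frame(config$rate_table)
    y$rate_table <- lapply(seq_len(nrow(rt)), function(i) as.list(rt[i, ]))
  } else {
    y$binding_trend <- unclass(config$binding_trend)
    y$dissociation_trend <- unclass(config$dissociation_trend)
  }
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}
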