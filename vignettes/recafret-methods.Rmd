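---
title: "Models and methods behind recafret"
author: "recafret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recafret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recafret)
```

# The kinetic model

The probed ssDNA segment at the 5′ disassembly end of a RecA filament
holds zero, one or two monomers between the FRET dyes.  Occupancy evolves
as a continuous-time birth–death chain

$$\mathrm{M0} \underset{k_{off}}{\overset{k_{on}}{\rightleftarrows}}
  \mathrm{M1} \underset{k_{off}}{\overset{k_{on}}{\rightleftarrows}}
  \mathrm{M2},$$

with one binding rate $k_{on}$ shared by both up-steps and one
dissociation rate $k_{off}$ shared by both down-steps — the granularity at
which the assay reports rates (one binding and one dissociation rate per
condition).  Binding is pseudo-first-order: the free RecA concentration is
held constant in the experiment, so concentration is not a simulator
variable.  The stationary distribution is
$(1, K, K^2)/(1+K+K^2)$ with $K = k_{on}/k_{off}$
(`equilibrium_distribution()`), and the mean occupancy is
$N_{average} = 2P(\mathrm{M2}) + P(\mathrm{M1})$.

Both rates are modelled as linear in pH over the measured window
(`rate_trend()`): $k(\mathrm{pH}) = k_{ref} + s\,(\mathrm{pH}-7)$, clamped
at zero.  The slopes $s$ are the headline quantities; they are in
s$^{-1}$ per pH unit.

# What the synthetic generator emulates

`simulate_dataset()` produces per-molecule donor/acceptor intensity traces
with the statistical structure the analysis assumes:

* exact Gillespie simulation of the occupancy chain, initial state drawn
  from equilibrium (the molecules have been at equilibrium long before
  acquisition starts);
* discretization to frames by **majority occupancy** within each frame
  interval, so events shorter than about half a frame are blurred away, as
  in camera-limited recordings;
* emission means $I_A = E\,I_{tot}$, $I_D = (1-E)\,I_{tot}$ with state
  FRET levels $E = 0.75/0.60/0.40$ for M0/M1/M2 (filament growth
  stretches the ssDNA, lowering FRET), plus independent Gaussian noise per
  channel — noise on intensities, not on $E$, so FRET noise is
  state-dependent as in real data;
* a donor-only subpopulation (no active acceptor, $E=0$ throughout), an
  exponential acceptor-bleach time after which $E=0$, and an exponential
  donor-bleach time that ends the usable trace.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `dt` | 0.1 s | typical EMCCD frame time; trace dynamics span tens of seconds |
| `n_frames` | 600 | 60 s traces |
| `k_off` at pH 7 | 0.2 s⁻¹ | absolute rates are a calibration of this package (only slopes are measured quantities); 0.2 s⁻¹ gives several transitions per trace |
| `k_on` at pH 7 | 0.2 s⁻¹ | chosen so equilibrium $N_{average}(\mathrm{pH}\,7) = 1.0$ ($K=1$) |
| rate slopes | WT: +0.05 (diss), −0.10 (bind); ΔC17: +0.01, −0.07 | the measured pH slopes |
| `noise_sd` | 10% of `total_intensity` | realistic per-frame FRET SD ≈ 0.07–0.08 |
| `donor_only_fraction` | 0.15 | typical labelled-sample acceptor dropout |
| `acceptor_bleach_rate` | 0.01 s⁻¹ | mean 100 s, so a minority of traces lose the acceptor mid-record |
| `donor_bleach_rate` | 0.005 s⁻¹ | mean 200 s; a few percent of molecules fail the 10-frame rule |
| pH grid | 6.0, 6.3, 6.6, 7.0, 7.5, 8.0 | the Mes/Mops/Tris buffer ranges plus pH 8 |

Two calibrations are provided per condition.  The *rate-trend* configs
(`wt_config()`, `deltac17_config()`) apply the measured rate slopes and
serve the kinetic branch.  The *occupancy* configs
(`wt_occupancy_config()`, `deltac17_occupancy_config()`) instead solve
$K(\mathrm{pH})$ from a target linear $N_{average}$ law (slope −0.29 WT /
−0.34 ΔC17, $N_{average}=1$ at pH 7, $k_{off}$ fixed at 0.2 s⁻¹;
`occupancy_calibration()` inverts the quadratic
$(N-2)K^2+(N-1)K+N=0$) and serve the histogram branch.  The two laws are
not simultaneously satisfiable by one linear-rate configuration — the
equilibrium $N_{average}$ of linear rate trends is not linear in pH — which
mirrors the fact that the occupancy and rate measurements are separate
experiments.

What the generator does **not** emulate: filament nucleation, dye
blinking and spectral cross-talk, molecule-to-molecule brightness
variation, baseline drift, and non-exponential (hydrolysis-coupled) dwell
structure.  Passing recovery tests therefore validates the inference
chain under its own model assumptions; on real data the absolute rates
would additionally carry calibration error from these effects.

RNG: one root seed; each molecule uses a counter-derived stream
(`molecule_seed()`), so any subset of molecules is reproducible and
`simulate_dataset()` is byte-deterministic.

# Trace processing and the histogram branch

`compute_fret()` forms the proximity ratio $E = I_A/(I_A+I_D)$ without
clamping (out-of-range excursions carry noise information the mixture fit
uses).  Donor bleaching is detected as a collapse of the 5-frame running
mean of total intensity below 25% of the initial level and truncates the
analyzable range.

A molecule's FRET value is the mean of its **first 10 valid frames**
(`molecule_fret_value()`); molecules bleaching within 10 frames are
excluded.  Values are binned at width 0.025 — five-plus bins between the
0.60 and 0.75 peaks — and decomposed by `fit_histogram()` into four
Gaussians: donor-only (center in [−0.05, 0.1]) plus M2/M1/M0 initialized
at 0.40/0.60/0.75 and constrained to windows [0.3, 0.5], [0.5, 0.7],
[0.65, 0.85] to prevent label swapping; widths are bounded in
[0.01, 0.15] and not shared (a shared-width constraint is not assumed).
The least-squares weights are **iterated Poisson weights**: a first pass
with observed-count weights, then weights recomputed from the fitted
model (IRLS, approximating Poisson maximum likelihood).  Weighting by
observed counts alone over-weights downward-fluctuating sparse bins and
measurably shrinks minority peaks, which would steepen recovered
$N_{average}$ slopes.  Populations are the three state-peak areas
renormalized after dropping the donor-only peak
(`populations_from_fit()`), and $N_{average}$ follows.

Because ~20–40% of molecules undergo a transition inside the 1-s
averaging window, the histogram carries inter-peak smear; the windowed
Gaussian fit absorbs it, and the population estimator is unbiased in the
large-sample limit (verified by recovery at 1,500–4,000 molecules per
condition).  At the working scale of 500 molecules per pH the residual
per-point scatter of $N_{average}$ is ≈ 0.03–0.04, dominated by the
multinomial sampling floor; per-pH uncertainties are therefore estimated
by a molecule-level bootstrap of the whole decomposition.

# The kinetic branch

## Idealization

`fit_hmm()` fits a Gaussian-emission hidden Markov model **per molecule**
(trace-by-trace, aggregating afterwards): molecule-to-molecule intensity
variation breaks a shared emission model, and per-trace fitting matches
standard smFRET practice.  Emissions are Gaussian on $E$; three states by
default (the assay asserts three FRET levels; `select_n_states()` offers
BIC selection over 2–4 but is off by default).  Baum–Welch EM runs to a
log-likelihood gain below $10^{-6}$ per frame or 500 iterations, from
means 0.75/0.60/0.40, SDs 0.05, 0.9 self-transition probability; four
further random restarts perturb the means and the best solution is kept.
Two numerical safeguards matter in practice:

* **Degeneracy rejection.** A Gaussian state whose SD collapses onto a
  handful of frames has unbounded likelihood and no physical meaning;
  restart selection prefers non-degenerate solutions (SD above the floor
  of $10^{-3}$ or ≥ 5 frames of posterior occupancy).  Without this, the
  best-of-restarts rule actively selects pathological fits whose
  transition rows inject phantom fast events.
* **Bleach-plateau exclusion.** Frames after acceptor bleaching (trailing
  20-frame mean of $E$ below 0.1) are excluded from fitting rather than
  modelled as a fourth state, keeping the kinetic states biochemical.

States are canonicalized by descending mean, making Viterbi decoding
(`most_likely_path()`) label-unique.  EM monotonicity is checked on every
trace.

## From paths and matrices to rates

Each trace's fitted state means are mapped to the reference levels
0.75/0.60/0.40 by nearest mean; a 3-state fit to a trace that visits
fewer levels often splits one level, and the mapping merges such
duplicates instead of letting them masquerade as kinetics.  Two classes
of states are *unassignable* and excluded: states farther than 0.075
(half the smallest inter-peak gap) from every reference level (e.g.
residual acceptor-dark levels near $E=0$), and states with per-frame
self-probability below 0.5, whose implied dwells are shorter than the
frame discretization can represent.  This mirrors TDP practice, where
only the four on-group clusters are classified.

`estimate_rates()` pools the per-molecule Baum–Welch transition matrices,
weighted by posterior state occupancy, into one per-frame transition
matrix per condition, and converts it to rates by generator estimation
$\hat Q = \log_m(\hat P)/\Delta t$ (eigendecomposition) — the multi-state
form of the scalar correction $k = -\ln(1-p)/\Delta t$
(`transition_rates_from_model()`), exact for a discretely observed chain.
Using the Baum–Welch matrices rather than Viterbi change-point counts
removes most missed-event bias: the posterior accounts probabilistically
for events too brief to survive Viterbi smoothing (Viterbi counting was
~10% low in recovery tests; the matrix route is within ~2–4%).
Double-jump probability mass (M0↔M2 within a frame, two unresolved
events) informs the matrix logarithm but never enters a class average.
The two binding channels are combined into one $k_{bind}$ by
dwell-weighting (weights = frames in each source state, equivalent to
pooling dwells, so short traces do not dominate), likewise $k_{diss}$.
Viterbi paths still drive the TDP itself (`extract_transitions()`,
`build_tdp()`, `classify_transition()`), with censored first dwells
flagged and anomalous double jumps excluded.

Residual missed-event bias is documented and bounded: below 10% whenever
mean dwells exceed 10 frames (tested), growing to ~15–20% at
$\Delta t = 0.2$ s where the mean M1 dwell is ~8 frames.

## Trends and uncertainties

`fit_trend()` regresses each per-pH summary on pH by OLS — pH is the
controlled variable, so orthogonal regression is not needed — weighted by
$1/\sigma^2$ when per-point errors are available.  Per-point errors are
molecule-level bootstraps (30 replicates by default): for rates they
capture trace-to-trace heterogeneity that per-event Poisson errors miss;
for $N_{average}$ they capture the mixture-fit variability.  The reported
slope error is the **larger of the residual-based and error-propagated
estimates**, so a sample that happens to scatter less than its stated
errors cannot understate the uncertainty.  The intercept is re-expressed
at pH 7 for interpretability.  `summarize_condition()` assembles the
per-condition table, the three trend fits and the slope-magnitude ratio
$|s_{bind}/s_{diss}|$; with the wild-type truths the ratio recovers ≈ 2,
i.e. pH acts about twice as strongly on binding as on dissociation.

# Degenerate inputs and tie-breaks

* Frozen chains ($k_{on}=k_{off}=0$) keep their initial state;
  $k_{off}=0$ alone has no equilibrium and is rejected where one is
  required.
* Frame-discretization ties (two states occupying exactly half a frame)
  resolve to the earlier-entered state.
* Nearest-level classification ties (an $E$ exactly between two peaks)
  resolve toward the lower occupancy.
* Traces with fewer than 30 analyzable frames are excluded from the
  kinetic branch; fewer than 10 valid frames excludes a molecule from the
  histogram.  All exclusions are counted and reported.
* A pooled transition matrix too sparse for the matrix logarithm falls
  back to the scalar per-row correction.

# Problem sizes

The package's own validation runs use 1,000 molecules at one pH for peak
recovery, 150 molecules per pH across six pH values for the kinetic
branch, and 500 molecules per pH for the histogram branch — sizes at
which the recovered slopes' uncertainties are a few times smaller than
the effects being measured, chosen as the package's standard validation
scale.  A 6-seed replicate study at the kinetic-branch scale gives mean
recovered slopes within 1% of truth with calibrated standard errors.

# Known limitations

* Absolute rates inherit the package's own anchor ($k_{off} = 0.2$ s⁻¹ at
  pH 7); only slopes are compared against measured values.
* The HMM assumes Gaussian $E$-noise; the true proximity-ratio noise is a
  ratio of Gaussians (slightly heavy-tailed), which contributes a small
  spurious-transition floor at high noise.
* Dwell-time *distributions* are not modelled (no single/double
  exponential MLE); rates are mean-based, as in the assay's analysis.
* The WT-vs-ΔC17 comparison is purely parametric — no electrostatics or
  structural modelling of the C-terminal domain.
* Real-microscope corrections (gamma factor, cross-talk, background) are
  out of scope; external data enter through the documented TSV contract
  at the user's own calibration.
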