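# recafret

Kinetic analysis of RecA filament-end dynamics from single-molecule FRET
trajectories.

## The scientific problem

RecA polymerizes on single-stranded DNA (ssDNA) into a helical
nucleoprotein filament that catalyzes homologous strand exchange.  Filament
stability is set at the 5′ disassembly end, where monomer binding (rate
k<sub>on</sub>) competes with monomer dissociation (rate k<sub>off</sub>),
and it changes markedly with pH — a property linked to bacterial acid
stress survival.  In the single-molecule assay this package analyzes, a
Cy3/Cy5 FRET pair flanks a short ssDNA segment next to the filament end,
so the number of monomers bound between the dyes appears as one of three
discrete FRET levels:

| state | monomers bound | FRET efficiency E |
|-------|----------------|-------------------|
| M0    | 0 (naked ssDNA)| ≈ 0.75            |
| M1    | 1              | ≈ 0.60            |
| M2    | 2              | ≈ 0.40            |

The occupancy dynamics form a birth–death Markov chain
M0 ⇄ M1 ⇄ M2 with up-rate k<sub>on</sub> and down-rate k<sub>off</sub>;
its stationary distribution is (1, K, K²)/(1 + K + K²) with
K = k<sub>on</sub>/k<sub>off</sub>.  Two summaries are tracked across pH:

* **N<sub>average</sub> = 2·P(M2) + 1·P(M1)** — the mean number of bound
  monomers, from Gaussian decomposition of per-condition FRET histograms
  (per-molecule FRET value = mean of the first 10 frames; a fourth peak at
  E ≈ 0 absorbs donor-only molecules and is excluded from the
  populations);
* **k<sub>bind</sub>, k<sub>diss</sub>** — from hidden-Markov-model
  idealization of single traces, transition-density-plot (TDP)
  classification of the four transition groups (two binding, two
  dissociation), and per-frame transition probabilities converted to rates
  with the exact frame-interval correction k = −ln(1 − p)/Δt (generalized
  to the matrix logarithm of the pooled transition matrix).

Linear regression of each summary on pH gives the headline slopes.  No
public experimental trace dataset exists for this assay, so the package
pairs the analysis chain with a fully parameterized synthetic
trace generator (continuous-time Gillespie simulation observed through a
noisy two-channel emission model with donor-only molecules and
photobleaching); every stage is validated by parameter recovery.

## Worked example

```r
library(recafret)
set.seed(42)
cfg <- wt_config(n_molecules = 40, pH_values = c(6.0, 6.6, 7.0, 7.5, 8.0),
                 seed = 42)
ds  <- simulate_dataset(cfg)   # 200 synthetic molecules with ground truth
fit <- fret_kinetics(ds)       # histograms + HMM + TDP + trends
fit
```

```
fret_kinetics [WT]: 5 pH conditions, 198 molecules
  pH   P_M0   P_M1   P_M2 N_average k_bind k_diss
 6.0 0.1426 0.3110 0.5464    1.4038 0.2642 0.1520
 6.6 0.1310 0.3054 0.5636    1.4326 0.2261 0.1931
 7.0 0.2404 0.4792 0.2804    1.0401 0.2285 0.2634
 7.5 0.3472 0.3755 0.2773    0.9300 0.1623 0.2116
 8.0 0.5294 0.2631 0.2075    0.6782 0.0846 0.2112
N_average slope: -0.379 +/- 0.081 monomers/pH
k_bind slope: -0.0952 +/- 0.0136, k_diss slope: 0.0362 +/- 0.0290 s^-1/pH  (|ratio| = 2.63)
```

Reading the output: populations shift from M2-dominated at pH 6 to
M0-dominated at pH 8, so the filament end is more stable in acid.  The
binding rate falls with pH (slope ≈ −0.10 s⁻¹/pH in the generator truth)
while the dissociation rate rises more gently (+0.05 s⁻¹/pH), and the
recovered slopes reproduce that truth within the regression uncertainty —
at 40 molecules per pH the errors are still large; the acceptance runs use
150–500.  `coef(fit)` returns the three slopes and the
|binding/dissociation| slope ratio; `plot(fit)` draws N<sub>average</sub>
and both rates against pH with their fitted lines; `summary(fit)` adds
exclusion counts and per-trend detail.

Lower-level entry points (`simulate_state_path()`, `emit_intensities()`,
`compute_fret()`, `fit_histogram()`, `fit_hmm()`, `most_likely_path()`,
`extract_transitions()`, `build_tdp()`, `estimate_rates()`, `fit_trend()`)
expose each stage separately; `run_pipeline()` drives the same chain
through plain-text artifacts (trace TSVs, histogram TSV/JSON, summary CSV)
with a JSON manifest of seeds and file digests, and `read_traces()` /
`read_config()` define the TSV/YAML contracts for external data.

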