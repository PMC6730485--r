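# fnirsnet

Simulation and network analysis of prefrontal fNIRS recordings in R.

`fnirsnet` is for researchers analysing multi-channel functional
near-infrared spectroscopy (fNIRS) from block-design cognitive experiments —
in particular working-memory studies comparing healthy controls (HC) with
mild-cognitive-impairment (MCI) cohorts across treatment visits. It
implements the complete chain from raw two-wavelength light intensities to
group-level network statistics, plus a synthetic-cohort generator with known
ground truth so the whole chain is testable without clinical data.

## What it computes

1. **Hemoglobin conversion** — optical density against a resting-state
   baseline and the modified Beer–Lambert inversion

   `ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR] · d · DPF(λ)`

   solved per channel/time point for ΔHbO, ΔHbR (µM).
2. **Filtering** — zero-phase cascaded 4th-order Butterworth band-pass,
   0.026–0.15 Hz (the low cut is 1/38 s, the trial period).
3. **Activation** — a designed hemodynamic response (double-gamma HRF,
   peak 6 s, undershoot 16 s, ratio 1/6, convolved with the 24-s task
   boxcars) fitted per channel by robust IRLS regression with bisquare
   weights; active channels are those with `t = β/SE` above the t critical
   value at α = 0.01; normalized spatial t-maps over the montage.
4. **Functional connectivity** — Pearson `r` matrices per segment (resting
   state / task session), Fisher `z = atanh(r)` handling, group averaging in
   z-space, binarization by fixed threshold (0.8) or proportional sparsity.
5. **Graph metrics** — degree, nodal efficiency
   `E_nodal(i) = (1/(N−1)) Σ_j 1/D(i,j)`, clustering
   `C(i) = 2L_i/(Z_i(Z_i−1))`, global/local efficiency, characteristic path
   length, and small-worldness `σ = (K/C_rand)/(L/L_rand)` against
   degree-preserving rewired nulls, swept over sparsity 0.5–0.9 (step 0.05)
   with mean ± SD summaries.
6. **Group statistics** — pooled/Welch two-sample t-tests (from raw data or
   printed summaries), paired t-tests, mean-z connectivity comparisons,
   metric–score Pearson correlations, and the per-group sample-size formula
   `n = ⌈2(z_{1−α/2}+z_{1−β})²/d²⌉` with dropout inflation.
7. **Synthetic cohorts** — 20-channel, 7.81 Hz recordings of a 4-min resting
   state plus nine 38-s working-memory trials, with group-graded evoked
   amplitude, latent background connectivity and physiological noise, pushed
   through the forward Beer–Lambert model to raw intensities.

## Worked example

```r
library(fnirsnet)

# simulate a small two-group cohort and run the full pipeline
cfg <- pipeline_config(n_per_group = 3, small_world = FALSE, seed = 42,
                       profiles = list(group_profile("A", 0.4),
                                       group_profile("B", 0.1)))
report <- run_pipeline(cfg)
report$stats
#>   comparison         endpoint  statistic df          p significant
#> 1     A vs B mean evoked dHbO  3.1013794  4 0.03617270       FALSE
#> 2     A vs B   resting mean z -0.2022835  4 0.84956693       FALSE
#> 3     A vs B      task mean z -2.3581849  4 0.07781686       FALSE
```

The evoked-response endpoint (mean fitted dHRF amplitude) separates the
0.4 µM group from the 0.1 µM group (t = 3.1, p = 0.036 — detectable even at
n = 3, though clearing the protocol's strict α = 0.01 needs a realistic cohort
size such as n = 11). The connectivity endpoints are null because both
groups share the same default latent connectivity — exactly what the report
should say. Reruns with the same config and seed are bit-identical.

Single stages are plain functions on classed objects:

```r
sim  <- simulate_subject(default_profiles()[["HC"]], seed = 1)
hemo <- hemoglobin_series(sim$recording)             # MBLL + band-pass
dhrf <- build_dhrf(make_default_schedule(), fs = 7.81)
act  <- channel_activation(hemo, dhrf)               # per-channel robust GLM
fc   <- fc_matrix(hemo, "resting")                   # Pearson r
sw   <- sparsity_sweep(fc_group_average(list(fc)))   # graph metrics
plot(sw)
```

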