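---
title: "From raw fNIRS intensities to brain-network metrics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw fNIRS intensities to brain-network metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsnet)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through the scalp: near-infrared light at two wavelengths (here 760 and
850 nm) is injected by emitters and collected by detectors a few centimetres
away, and attenuation changes are converted into concentration changes of
oxy- and deoxyhemoglobin (dHbO, dHbR). In studies of mild cognitive
impairment (MCI), prefrontal fNIRS during a working-memory task is used to
quantify (i) the evoked hemodynamic response, (ii) the functional
connectivity (FC) between channels, and (iii) graph-theoretic summaries of
the channel network, and to track how these change across treatment visits
relative to healthy controls (HC).

`fnirsnet` implements that full chain for a 20-channel prefrontal montage
(8 emitters, 7 detectors) sampled at 7.81 Hz, together with a synthetic
cohort generator. The clinical recordings this kind of study rests on are
typically not publicly deposited, so the generator is a first-class module:
it produces recordings with *known* evoked amplitude, latent connectivity
and physiological noise, which is what the test suite and the acceptance
script exercise.

## The paradigm

The experiment is a block design: a 4-min resting state, then nine
working-memory trials of 38 s each (8 s encoding, 14 s retention, 2 s
probe — a 24-s task period — followed by 14 s rest whose final 2 s carry
the ready cue for the next trial), i.e. a 342-s task session, then 30 s of
post-rest. `make_default_schedule()` encodes exactly this; all durations are
arguments of `build_schedule()`.

## Preprocessing

**Optical density and MBLL.** Raw intensities are referenced to the mean
intensity of the resting-state window, `dOD = -log10(I / I0)`, and the
2x2 modified Beer-Lambert system is solved per channel and time point:

    dOD(lambda) = [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR] * d * DPF(lambda)

with emitter-detector distance `d` (2.78-2.8 cm in the default montage,
values above 5 cm rejected as unstable), differential pathlength factor 6.0
at both wavelengths, and extinction coefficients from the standard compiled
in-vivo tabulation (0.000586 / 0.00154852 cm^-1 uM^-1 at 760 nm and
0.001058 / 0.00069132 at 850 nm for HbO / HbR). Since no partial-volume
correction is applied, absolute micromolar values are convention-dependent;
every constant is overridable through `default_geometry()`.

**Filtering.** Physiological nuisance (cardiac ~1.1 Hz, respiration
~0.25 Hz, very-low-frequency drift) is removed with cascaded 4th-order
Butterworth low- and high-pass sections at 0.15 and 0.026 Hz; the low cut
is the reciprocal of the 38-s trial period. Filtering is zero-phase
(forward-backward) so that response timing is preserved for the regression
stage; the phase handling is our choice, since single-pass filtering would
shift the response by several seconds at these cutoffs. Before filtering,
each series is demeaned and extended by odd reflection (about three
high-pass time constants per side) so that edge transients are suppressed
and a constant input maps to numerically zero output.

## Activation

The predicted response (dHRF) is a canonical double-gamma HRF — unit-rate
gamma lobes with mode 6 s (peak) and 16 s (undershoot), undershoot ratio
1/6 — convolved with a unit boxcar over each 24-s task period and scaled to
unit peak, so a regression slope is in micromolar. The 24-s block is
modelled as a single boxcar rather than separate encode/retain/probe
regressors, matching a single-dHRF fit; phase-wise regressors would be a
configuration extension.

Each channel's filtered dHbO series (task session onward) is regressed on
the dHRF by iteratively reweighted least squares with bisquare weights
(tuning constant 4.685, i.e. 95% Gaussian efficiency; scale from the
leverage-adjusted median absolute residual; convergence at a coefficient
change below 1e-8 or 50 iterations). The slope standard error is the
M-estimation asymptotic (psi-based) estimate, which reduces to the ordinary
least-squares formula when all weights are one; the Monte-Carlo null test in
the suite confirms its calibration, and a cross-check against an independent
bisquare implementation confirms the point estimates. A channel is *active*
when its t-value exceeds the t-distribution critical value at alpha = 0.01
(the protocol's significance level applied to activation selection; the session
is fitted as a whole rather than trial-wise). Spatial t-maps are
inverse-distance-weighted interpolations over the montage plane, min-max
normalized to [0, 1]; any interpolant that is exact at the channel positions
preserves the channel rank order, which is the property the tests pin down.
When all t-values coincide the normalized map is defined as all zeros.

## Connectivity

FC matrices are pairwise Pearson correlations of the channel dHbO series
over either the resting state or the full task session (including
inter-trial rests — the evoked response is deliberately *not* regressed
out, which inflates task-segment correlations among co-active channels and
is documented as a limitation of that segment). A zero-variance channel
yields a zero row/column with a warning. Averaging across subjects is done
on the Fisher-z scale (`tanh(mean(atanh(r)))`) because correlations are not
additive; `fisher_z()` clips r at +/-(1 - 1e-7) to keep the transform
finite. Binarization is either fixed-threshold (edge iff r > 0.8, signed r,
matching the displayed binary matrices) or proportional: the
`round(s * N(N-1)/2)` strongest off-diagonal entries are kept, ties broken
by channel index so results are deterministic.

## Graph metrics

On binary undirected networks the package computes degree, nodal efficiency
`E_nodal(i) = mean_j 1/D(i,j)`, clustering `C(i) = 2 L_i / (Z_i (Z_i - 1))`,
global efficiency (the mean nodal efficiency), local efficiency (mean
global efficiency of the neighbourhood subgraphs) and characteristic path
length. Conventions for degenerate cases: `1/Inf = 0` for unreachable
pairs, `C(i) = 0` for degree < 2, the characteristic path length is taken
on the largest connected component, and the global efficiency of a
subgraph with fewer than two nodes is 0. Small-worldness is
`sigma = (K / C_rand) / (L / L_rand)` against the mean of degree-preserving
Maslov-Sneppen rewired nulls (default 100 nulls, 10 |E| swap attempts each,
seeded); `sigma > 1` indicates a small-world organisation. Because some
fNIRS reports quote small-worldness on a 0-1 scale, a normalized variant
`sigma / (1 + sigma)` is also emitted; both are computed, neither is used
as an external anchor. The sparsity sweep evaluates all metrics on the grid
0.5 to 0.9 in steps of 0.05 and reports mean +/- SD across levels, since
metrics vary little over that dense range.

## Group statistics

Two-sample comparisons can be run from raw values or directly from printed
summary statistics (mean, SD, n), in pooled-Student or Welch form — the
summary form is what lets reported cohort tables be checked. Connectivity
comparisons reduce each subject's matrix to its mean off-diagonal Fisher z
and then apply a paired or two-sample t-test. The per-group sample-size
computation uses the normal-deviate formula
`n = ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2)` at alpha = 0.05 and power
0.80 and inflates by the anticipated dropout:
`ceil(n / (1 - dropout))`; a base of 10 with 15% dropout gives 12 per
group. No multiple-testing correction is applied by default (the fixed
alpha = 0.01 convention); a Bonferroni option would be a one-line wrapper
around `p.adjust` and is intentionally left to the caller.

Two quantitative quirks worth recording: with the printed cognitive-score
summaries (27.17 +/- 2.34 vs 19.33 +/- 2.21, n = 12 each) both t-test
variants give p far below 0.001, as expected; but the corresponding *age*
comparison reproduces as p ~= 0.065 rather than the reported 0.0755 under
both variants — printed-value rounding is the likely cause, so the package
treats the summary-form test itself (validated exactly against raw-data
tests) as the source of truth and does not chase the discrepancy.

## The synthetic cohort: what it emulates and what it does not

`simulate_subject()` builds, per channel,

    dHbO(t) = amplitude * dHRF(t) + background(t) + nuisance(t)

and maps (dHbO, dHbR) through the forward MBLL to two-wavelength
intensities (unit baseline). dHbR is -1/3 of the evoked dHbO plus
independent noise — enough to exercise the two-wavelength inversion;
downstream analysis uses dHbO only, mirroring its better signal-to-noise
ratio in practice.

* **Evoked response:** subject amplitude ~ N(group amplitude, 0.05 uM),
  truncated at zero, on 8 mid-montage active channels (6-13). Group
  amplitudes 0.40 / 0.30 / 0.20 / 0.10 uM for HC / MCI-1 / MCI-2 / MCI-0
  encode the reported ordering of response strength across visits.
* **Background:** white noise coloured by a symmetric square root of the
  latent correlation matrix, smoothed into a broad low-frequency band
  (0.01-0.5 Hz) with the same filter for every channel — identical
  per-channel filtering preserves the target cross-channel correlations
  exactly — and rescaled so its standard deviation *within the analysis
  band* is 0.15 uM per channel. Generating the background broadband rather
  than restricted to the analysis band both resembles real low-frequency
  oscillations and maximises the effective degrees of freedom available to
  the correlation estimator after filtering.
* **Latent connectivity:** a uniformly integrated core (r = 0.6) from
  which lateral channels progressively decouple
  (`decoupled_connectivity()`): decoupled channels keep moderate mutual
  coherence (0.45) but only weak coupling to the core (0.1). HC has no
  decoupled channels; MCI-1/-2/-0 have 1, 2 and 3. This grading was chosen
  because proportional thresholding is rank-based — uniformly scaling all
  correlations up or down leaves the thresholded topology, and hence every
  graph metric, unchanged — so group differences in network integration
  must be encoded in the *pattern* of the latent matrix. Progressive
  channel decoupling produces disconnected components over a graded range
  of sparsity levels and therefore a strictly ordered, noise-robust global
  efficiency (HC > MCI-1 > MCI-2 > MCI-0), while mean connectivity
  strength follows the same order. It is a deliberately stylised model of
  the channel-level hypoconnectivity reported in MCI, not an anatomical
  claim about which channels decouple.
* **Noise:** cardiac 1.1 Hz (0.2 uM), respiration 0.25 Hz (0.1 uM), a
  small in-band Mayer-wave component 0.1 Hz (0.02 uM, a genuine confound
  kept realistic but small), random-walk drift 0.01 uM/sqrt(s), white
  measurement noise 0.05 uM. Cardiac and respiratory bands are fully
  removed by the 0.026-0.15 Hz filter; the drift leaks only marginally
  into the band.
* **Seeding:** per-subject seeds derive deterministically from
  (master seed, group label, subject index), so cohorts are reproducible
  and no two subjects share a realization.

What the generator does *not* emulate: photon transport through scalp and
skull (no Monte-Carlo optics), motion artifacts, short-separation systemic
contamination, serially correlated measurement noise, or any intervention
physiology. Passing recovery tests on this cohort therefore demonstrates
that the analysis chain is correct and sensitive under controlled
conditions — not that it would be robust to every artifact of clinical
recordings.

## Problem sizes used by the automated checks

The recovery checks simulate 4 groups x 11 subjects (the cohort size used
in the emulated cohort) over 20 master seeds in the test suite and
10 in the acceptance script, plus two 11-subject groups with uniform latent
connectivity 0.4 vs 0.2 for the connectivity-difference power check; the
type-I calibration uses 2000 null replicates at n = 11. Long-duration
convergence checks extend the resting state tenfold. These sizes keep each
property estimable while the whole suite stays desk-scale.

## Known limitations

* The montage is a plausible geometric reconstruction (counts and
  separations as specified); real channel positions would come from a
  digitizer.
* Session-wise (not trial-wise) regression; no prewhitening, so GLM
  t-values inherit some autocorrelation optimism — the active/inactive
  ranking, which is what the pipeline consumes, is unaffected.
* Task-segment FC retains the evoked common signal, as discussed above.
* Absolute concentration scaling depends on the DPF/partial-volume
  convention.
* With 20 nodes and sparsity 0.5-0.9, thresholded networks are dense;
  metric differences between realistic groups are small, which is exactly
  why the generator encodes integration differences structurally.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_per_group = 3, small_world = FALSE, seed = 42)
report <- run_pipeline(cfg, out_dir = "fnirs-report")
report$stats
plot(report$sweeps[["HC.resting"]])
```
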