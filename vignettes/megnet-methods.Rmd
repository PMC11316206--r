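---
title: "Envelope connectivity and multi-threshold network statistics: methods"
author: "megnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope connectivity and multi-threshold network statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnet)
```

## Scope and model

`megnet` analyses resting-state MEG recordings that have already been
source-reconstructed and parcellated: its entry point is a per-subject set of
non-overlapping 10-s epochs of signal for the 68 cortical regions of the
Desikan–Killiany atlas.  Everything upstream — acquisition, coregistration,
head modelling, beamforming, artifact rejection — is out of scope.

The analysis chain is:

1. **Spectral stage.** Each epoch is band-pass filtered into the bands of
   interest (delta 1–4 Hz, theta 5–8 Hz by default) with a zero-phase
   Butterworth filter and Hilbert-transformed; the complex magnitude is the
   amplitude envelope.  An order-4 low-pass (70 Hz cut-off) utility mirrors
   common MEG preprocessing and is available for broadband inputs.
2. **Connectivity stage.** Functional coupling between regions is the
   amplitude envelope correlation (AEC) of orthogonalized signal pairs.
   For an ordered pair (i, j) the analytic signal of j is projected off
   region i at every sample, `y_perp(t) = Im(y(t) conj(x(t)) / |x(t)|)`,
   which removes the zero-lag collinear component that source leakage
   produces; the envelope of the residual is then Pearson-correlated with
   region i's envelope, and the two directions averaged.  Per-epoch 68×68
   matrices are averaged across epochs, negative correlations are set to
   zero, and the matrix is rescaled so the strongest connection is exactly 1
   (division by the maximum — not min–max scaling — so that 0 keeps meaning
   "no connection").
3. **Graph stage.** Each normalized matrix is proportionally thresholded at
   densities 10–30 % in steps of 4 % (six graphs per band), keeping the
   strongest connections *with their weights*.  Three weighted measures are
   computed per graph: modularity Q (Louvain search with seeded restarts,
   scored by the exact Newman formula), global efficiency (mean inverse
   shortest-path length, lengths `1/w`, disconnected pairs contributing 0),
   and mean local efficiency in the 2017-corrected weighted formulation
   (cube-root weight combination with neighbourhood-restricted shortest
   paths on cube-rooted lengths, normalized by `k(k-1)`), which is bounded
   by 1 and reduces to the classic binary local efficiency on 0/1 graphs.
4. **Group statistics.** Group differences are tested with a
   multi-threshold permutation correction (MTPC): a one-sided
   pooled-variance t statistic per threshold (oriented so "reduced in
   patients" is positive), a max-statistic permutation null across
   thresholds, a critical value `S_crit` at the 95th percentile of the null
   maxima, supracritical clusters of consecutive thresholds, and a decision
   that compares the observed cluster AUC (`A_mtpc`, trapezoids over the
   density axis) against the mean supracritical AUC of the permutations
   (`A_crit`).  Per-analysis p-values (add-one max-statistic estimates) are
   then corrected across analyses by Benjamini–Hochberg.
5. **Association stage.** For each band and metric, subjects' values at the
   density with the largest group difference enter ordinary least-squares
   regressions on cognitive scores (working-memory and processing-speed
   indices), controlling for sex by default, with standardized
   coefficients, exact t/p/CI, a linearity diagnostic, a Spearman fallback,
   and BH correction of the metric-term p-values across the seven-model
   family.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `epoch_seconds` | 10 | s | non-overlapping epochs; partial trailing data discarded |
| band edges | 1–4, 5–8 | Hz | configurable list; upper edge must clear Nyquist |
| filter order | 4 | — | overall order; band-pass designs are two-sided, so `signal::butter` receives order/2 |
| `edge_trim_s` | 1 | s | envelope samples dropped at each epoch edge before correlation, suppressing filter/Hilbert transients (the 1 Hz lower band edge is transient-sensitive on 10-s epochs); exposed as a flag |
| `thresholds` | 0.10–0.30 by 0.04 | density | retained fraction of the `n(n−1)/2` possible connections |
| `n_restarts` | 100 | — | Louvain restarts; best Q kept; seeded |
| `n_permutations` | 5000 | — | MTPC label shuffles; the same seeded sequence is reused across metrics within a run so analyses are comparable |
| `alpha` | 0.05 | — | one-sided MTPC level |
| `direction` | patient &lt; control | — | sign convention recorded in the result |
| `include_sex` | TRUE | — | sex coded 0 = F, 1 = M; the metric's standardized β is invariant to the coding |

## The synthetic cohort generator

The generator exists because patient recordings of this kind are not
publicly deposited; it emulates the *structure* of such a study so that
every downstream stage can be tested against a known ground truth.  Default
conditions: 12 patients and 12 controls; epoch counts drawn as rounded
Gaussians (means 37.5 / 37.33, SDs 1.6 / 1.1, clipped at 30); 10-s epochs;
68 regions; delta and theta bands.  The default sampling rate is 250 Hz
rather than an acquisition-grade 2 kHz: the bands of interest lie below
8 Hz, all filters scale with `fs`, and the lower rate keeps simulation
affordable; `fs` is configurable.

Per subject, epoch and band the generator draws a latent Gaussian process
per region (white noise low-passed at 0.5 Hz, standardized), imposes the
group's cross-region envelope correlation by a Cholesky factor, and maps it
through `exp(sigma * latent)` to a positive envelope; `sigma =
sqrt(log(1.25))` makes the lognormal envelope's coefficient of variation
0.5.  The envelope multiplies an independent constant-modulus narrowband
carrier — the cosine of the instantaneous phase of band-limited noise.  A
raw filtered-noise carrier would contribute its own Rayleigh-like amplitude
fluctuations and corrupt the planted envelope; the constant-modulus carrier
keeps the band signal's Hilbert envelope equal to the planted one up to the
additive broadband noise (SD 0.2 against unit-SD carriers), so envelope
recovery is testable (r > 0.8 at high SNR).

The planted coupling is block-modular: four 17-region modules, envelope
correlation 0.35 within and 0.05 between modules.  Patients' within-module
coupling is scaled by `effect_size_local = 0.6`, a reduction of local
(segregated) connectivity.  Cognitive scores follow
`score = intercept + beta_metric * metric_gt + beta_sex * male + noise`,
with the ground-truth metric evaluated on the group's noise-free planted
network; intercepts and slopes are set so scores land in a WISC-like range
(≈ 100 ± 15).  Note one subtlety: the ground-truth metric is computed on
the planted correlation matrix *without* the divide-by-maximum step —
planted correlations are already in [0, 1], and dividing by the maximum
would cancel the uniform within-module scaling and hide the true group
effect.  The empirical pipeline, whose inputs are noisy estimates, keeps
the normalization.

One top-level seed expands to per-subject child seeds, so any subject can
be regenerated independently and identically.  Sex is Bernoulli(0.5) by
default and can be pinned to fixed per-group counts.

What the generator does **not** emulate: volume conduction / leakage
mixing between parcels (signals are generated leak-free, so
orthogonalization is exercised by its mathematical contract rather than by
realistic leakage), 1/f background spectra, non-stationarity, artifacts,
age effects on connectivity, and spatial geometry of the atlas.  Passing
tests therefore demonstrate the correctness and calibration of the
*methods*, not claims about real recordings.

## Numerical choices and edge cases

- **Pipeline order is fixed**: per-epoch AEC → average across epochs →
  zero negatives → normalize → threshold → metrics.  Averaging and
  post-processing do not commute, and weighted efficiencies are not
  invariant to global rescaling, which is why normalization precedes
  thresholding.
- Epoch weighting in the across-epoch average is uniform; with equal-length
  epochs this equals duration weighting.
- Orthogonalization samples where `|x| = 0` contribute 0; a pair whose
  orthogonalized residual is numerically null (an exact scaled copy)
  or whose envelope has zero variance gets correlation 0 with a warning.
- Proportional-threshold ties are broken by (weight descending, row,
  column), making thresholded graphs byte-reproducible.
- `S_crit` is the type-1 (order-statistic) empirical quantile of the null
  maxima.  A single-threshold cluster has zero trapezoidal AUC: it is
  reported but cannot beat a positive `A_crit`.  If no permutation shows a
  supracritical threshold, `A_crit = 0` and any observed cluster with
  positive area is significant.  `A_crit` averages over all permutations
  with any supracritical threshold, including zero-area singletons.
- Under a global null with *independent* threshold columns the MTPC
  rejection rate is essentially zero — exceedances occur at rate ≈ α but
  never form multi-threshold runs.  With realistically correlated curves
  (AR(1), ρ = 0.8 across densities, emulating the strong dependence of
  metrics at nested densities) the measured family-wise rate is ≈ 0.02,
  still conservative relative to the nominal 0.05.  Power against a 3-SD
  uniform reduction at 12 vs 12 exceeds 0.95.
- Degenerate inputs: all-zero connectivity passes post-processing with a
  warning; a zero-weight graph has Q = 0 (single community) and zero
  efficiencies; nodes with fewer than two neighbours have local efficiency
  0; zero pooled variance yields t = 0 with a warning; constant regression
  predictors raise an error naming the column.

## Design decisions on genuinely open points

- The band filter family/order for delta and theta is not dictated by the
  measure itself; a zero-phase order-4 Butterworth band-pass was chosen to
  match the low-pass family, and is configurable.
- Whether envelope edges were trimmed before correlation is an open choice;
  trimming 1 s per edge is the default and a flag disables it.
- "Weighted averages" of epochs is interpreted as duration weighting, which
  is uniform for equal 10-s epochs; the weights argument is exposed.
- Thresholded graphs are treated as weighted (consistent with normalizing
  weights before thresholding); a binary variant can be obtained by passing
  a binarized matrix, and the binary reduction of local efficiency is
  tested.
- The per-analysis p-value is the add-one max-statistic estimate; a
  per-threshold BH variant across the six densities would be an
  alternative reading and can be built from the returned `t_observed` and
  `null_max`, but the max-statistic p is what feeds the across-analysis
  FDR.
- The association family is the seven-model layout (modularity → working
  memory in both bands; modularity and both efficiencies → processing
  speed), and the FDR family is the seven metric-term p-values; both are
  arguments, and the family actually used is recorded in the output.

## Problem sizes used in the shipped checks

The package's own test suite runs reduced-scale cohorts (typically 6–8
subjects, 8–12 regions, 3–5 epochs of 4–5 s at 100 Hz) for end-to-end
checks, full 68-region single subjects for structural checks, and
closed-form or exhaustively enumerated graphs (≤ 8 nodes) for the metric
oracles.  Statistical calibration uses 200 simulated cohorts × 500
permutations for the null rejection rate and the same for power; CI
coverage uses 500 OLS simulations.  These sizes were chosen so the whole
suite completes in a few minutes while keeping Monte-Carlo margins tight
enough to be informative; the full-scale study configuration (24 subjects,
37 × 10-s epochs, 5000 permutations) is the package default for `run_all()`
and runs in well under an hour on a laptop.

## Known limitations

- Louvain is a heuristic; `modularity_q` reports the best of `n_restarts`
  seeded runs, not a certified global optimum (the exact evaluation of any
  returned partition is tested against hand computation and igraph).
- The Spearman p-value uses the tie-corrected t approximation, adequate for
  the n ≈ 11–24 regime it serves.
- The generator's leakage-free signals mean orthogonalization is validated
  against its definition, not against a forward-model simulation.
- Graph metrics on fragmented low-density graphs depend on the
  disconnected-pair convention (contribute 0); this matches the standard
  weighted-efficiency convention but differs from harmonic-mean variants.
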