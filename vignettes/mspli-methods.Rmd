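---
title: "Microstate-segmented PLI connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate-segmented PLI connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspli)
```

## The scientific problem

`mspli` implements a quantitative-EEG analysis chain that asks whether a
behavioural score — in the motivating application, informant-rated apathy
(AES) in Parkinson's disease — is associated with band-limited functional
connectivity between cortical regions. The chain is:

1. **Band-pass filtering** into four analysis bands (theta 4–8, alpha1
   8–10, alpha2 10–13, beta 13–30 Hz), zero-phase Butterworth.
2. **Instantaneous phase** by a sliding-window Hilbert transform.
3. **Microstate segmentation**: the scalp topography is clustered into k
   quasi-stable template maps (k chosen by the Krzanowski–Lai criterion;
   the operating point is k = 4) and every sample is labelled.
4. **msPLI**: the phase lag index computed on stitched epochs of samples
   sharing a microstate label (four epochs of 4,000 samples per class),
   all available epoch matrices averaged into one connectivity matrix per
   subject and band, then aggregated into 22 regions of interest (11 per
   hemisphere, midline excluded).
5. **Weighted graph measures** (degree, Cw, Gamma, Lw, Lambda, Rw, Kw,
   radius, diameter) with surrogate normalisation.
6. **Statistics**: log-transform of msPLI, OLS residualisation on five
   confounds (age, sex, education, MMS, LED), square-root transform of the
   apathy score, edge-wise Spearman correlation, and family-wise
   max-statistic permutation correction; plus a median-split ROC
   classification from a single edge.

Patient EEG is not publicly available, so the package ships a synthetic-data
generator with planted ground truth; every stage is validated against it.

## The phase lag index

For a channel pair with instantaneous phase difference
$\Delta\phi_t$, $\mathrm{PLI} = \lvert \mathrm{mean}_t\,
\mathrm{sign}(\Delta\phi_t) \rvert \in [0, 1]$, with the difference wrapped
to $(-\pi, \pi]$ and $\mathrm{sign}(0) = 0$. A consistent non-zero lag gives
1; zero-lag (volume-conduction) coupling contributes nothing. For
independent phases of length $L$ the null expectation is
$\mathbb{E}[\mathrm{PLI}] = \sqrt{2 / (\pi L)}$ (mean absolute value of a
centred binomial proportion); the test suite verifies this to within 10%
over 1,000 simulated pairs.

A caveat the tests make explicit: that null expectation assumes
*independent* sign samples. Band-limited signals have autocorrelated phase
differences — a 3-Hz-wide carrier decorrelates over hundreds of
milliseconds — so the effective number of sign samples in an EEG-level
epoch is far below its length, and empirical null PLI on narrowband
signals sits well above the i.i.d. value. The i.i.d. bound is therefore
asserted on uniform phase tensors pushed through the real epoch-extraction
and PLI code path, and EEG-level nulls are checked at bounds derived from
the carrier bandwidth.

## Sliding-window Hilbert phase

Windows of 4 s with 50% overlap are tapered with a periodic Hann window;
each window's FFT analytic signal contributes the phase of its central
half, tiling the interior of the recording exactly once. Samples in the
first and last quarter-window and samples with numerically zero analytic
amplitude are flagged invalid rather than given an arbitrary phase — a
zero-amplitude "phase of 0" would bias PLI sign counts.

Numerical accuracy: with the periodic taper, a sinusoid on the window's
DFT grid has an exactly three-bin spectrum, so a planted constant lag
between two tone carriers is recovered to ~1e-12 rad by the phase stage.
Adding the 8th-order transfer-function Butterworth band-pass in front
raises the floor to ~2e-6 rad (polynomial transfer-function conditioning,
not a property of the phase estimator); both levels are asserted in the
suite.

## Microstate segmentation

Maps at local GFP maxima (GFP = spatial SD per sample) are unit-normalised
and clustered with a *modified* k-means whose assignment uses the squared
template projection — making a map and its polarity reversal equivalent,
the EEG microstate convention — and whose template update is the dominant
eigenvector of the within-cluster scatter. The best of `n_restarts` seeded
restarts by explained variance is kept. Backfitting labels every sample by
maximal absolute spatial correlation and optionally merges segments
shorter than 30 ms.

The number of classes is selected by the Krzanowski–Lai index
$KL(k) = |\mathrm{DIFF}(k)| / |\mathrm{DIFF}(k+1)|$ with
$\mathrm{DIFF}(k) = (k-1)^{2/m} W_{k-1} - k^{2/m} W_k$, where $W_k$ is the
within-cluster dispersion (residual map variance under the
polarity-invariant fit) and $m$ the channel count. When the KL curve has no
finite interior maximum (single-template data), the smallest candidate k is
returned — the documented fallback. The cited "adaptive pruning / L-curve"
refinement of the original study's toolbox is not specified anywhere in
detail; plain KL maximisation reproduces the operating point (k = 4 is
selected in ≥ 90% of seeded synthetic runs) and an explicit k override is
available.

Design choices the literature leaves open, fixed here: clustering uses GFP
peaks only (backfitting covers all samples); models are fitted per subject;
the smoothing window is 30 ms.

## msPLI stitching

For every microstate class, valid labelled samples are concatenated in
temporal order and cut into up to four epochs of 4,000 phase samples; one
PLI matrix per epoch is computed and all available matrices (target
4 epochs × 4 classes = 16) are averaged. Classes with fewer labelled
samples contribute what they have; the per-class shortfall is recorded in
the output's coverage table, and a run with *no* complete epoch fails
loudly naming the shortfall. Epochs are taken as the *first* available
stretches in temporal order — a deterministic choice where the procedure
was unspecified. A single-class label vector makes msPLI collapse exactly
(< 1e-12) onto plain windowed PLI over the same samples, which the suite
asserts.

ROI aggregation maps electrodes into 22 regions (11 per hemisphere;
midline channels deliberately unmapped) and averages the PLI over all
electrode pairs spanning two regions (configurable to the median);
within-region pairs never enter off-diagonal entries.

## Graph measures

All eight measures operate on the weighted matrix W directly. Degree is
the mean link weight of a node; the weighted clustering coefficient and
the harmonic-mean path length (edge length 1/w, infinite for absent edges)
follow the standard weighted-graph definitions; radius and diameter are
the extreme eccentricities — reading "min(L)"/"max(L)" as eccentricity
extremes rather than extreme pairwise distances, since the minimum pairwise
distance would trivially be the strongest edge. Gamma and Lambda normalise
Cw and Lw by their means over surrogates obtained by randomly permuting
the off-diagonal upper-triangle weights (symmetry and the weight
distribution preserved; degree-preserving rewiring is ill-defined for
dense weighted matrices). A matrix whose off-diagonal weights are all
equal returns Gamma = Lambda = 1 exactly. Two conventions worth noting:

* **Degree diversity Kw and assortativity Rw** are computed from node
  *strength* (sum of link weights), the convention of the weighted
  brain-network literature; Rw is unaffected by the distinction (it is a
  correlation) and Kw differs only by the constant factor n−1. An
  undefined Rw (zero strength variance, e.g. regular graphs) returns NaN,
  never a silent 0.
* The core is implemented in C++ (Rcpp). A fully independent brute-force
  oracle — exhaustive simple-path enumeration for distances, direct
  definition sums, two-pass Pearson — ships alongside it, and
  `validate_graph_metrics()` sweeps *every* weighted graph on up to 5
  nodes with weights in {0, 0.25, 0.5, 1} (1,048,576 graphs at n = 5),
  comparing all eight measures, Gamma/Lambda included, on identical
  surrogate permutation streams. The suite requires agreement to 1e-10.

## Statistics

msPLI values are log-transformed (they are right-skewed ratios), each
edge is residualised on the five confounds by OLS with intercept, and the
apathy outcome is square-root transformed. Because Spearman correlation
is rank-based, both monotone transforms leave every rho unchanged — the
suite asserts this — and matter only for normality reporting (the
Lilliefors test is available via `lilliefors_test()`). Family-wise
correction shuffles the outcome, recomputes every |rho|, and keeps the
maximum per permutation; corrected p-values use the add-one convention
(1 + B)/(1 + N), which cannot return zero. Two-sided testing on |rho| is
used throughout: the motivating finding is directional, but no one-sided
procedure was specified.

One property of the scheme deserves emphasis. The outcome itself is *not*
residualised (an option exists but is off by default, matching the
procedure as described). When the outcome is correlated with the
confounds, permuting the raw outcome against confound-orthogonal residuals
is mildly conservative — on synthetic cohorts with the default confound
structure the measured family-wise error is near zero rather than 0.05.
Calibration is therefore asserted under the exchangeable global null
(confound–outcome correlations zero), where the max-statistic procedure
is exact: measured FWER 0.05 ± 0.02 across 400 synthetic cohorts of 40
subjects and 231 edges.

The initiation composite averages oriented z-scores of five tests
(fluency-type tests as-is, timed tests reversed) and reports Cronbach's
alpha with the conventional 0.70 acceptability flag. The median-split ROC
splits subjects at AES 24/25, computes the trapezoidal AUC over all
thresholds of a single edge's connectivity (via pROC), and reports the
Youden-optimal operating point; the orientation (lower connectivity =
more apathetic) is an explicit argument, never silently auto-selected
unless requested.

## The synthetic-data generator

`sim_config()` / `generate_cohort()` emulate, at desk scale, the features
the analysis depends on — not realistic scalp physics (no head model, no
artifacts):

* **Scale**: 32 channels (22 lateral carrying the ROI map + 10 midline),
  250 Hz, 180 s; the study's 256 channels / 1,000 Hz / 12 min remain
  configurable but are not the test operating point.
* **Microstate structure**: k = 4 smooth orthonormal topographies over
  schematic sensor positions, switching by a Markov chain at a mean dwell
  of 80 ms with a 30 ms refractory minimum (empirical microstate duration
  distributions are peaked, not geometric from one sample; the minimum
  also keeps the ground truth compatible with the 30 ms backfit
  smoothing). Realised mean dwell matches the target within 10%.
* **Coupling**: a coupled pair shares one narrowband unit-amplitude
  complex carrier; channel i carries Re(z), channel j carries
  s·Re(z·e^(−iθ)) + (1−s)·Re(z′) with an independent carrier z′ — giving
  analytic control of the expected PLI rather than Kuramoto dynamics.
  Carriers are band-pass-filtered white noise by default (realistic phase
  diffusion) or constant-frequency tones (`carrier = "tone"`) for exactness
  tests. Effect edges set s = strength + slope·z(AES), clipped to [0, 1].
* **Covariates**: AES is drawn right-skewed over 18–39 (beta quantile
  transform of a Gaussian latent; the study reports only median/quartiles/
  range, so the skew shape is a free choice fixed once); age, sex,
  education, MMS and LED are tied to the AES latent through a Gaussian
  copula with configurable correlations and marginals matching the study
  cohort's summary table; five initiation-test z-scores load on the same
  latent (timed tests with reversed sign).
* **A statistics-level shortcut**: `generate_connectivity_cohort()` emits
  per-subject edge msPLI values directly (log-normal around an edge
  baseline, confound loadings, planted apathy correlation `effect_r`,
  default −0.9). Calibration studies at realistic replicate counts (400
  null cohorts, 50 power cohorts) would be prohibitive through full EEG
  synthesis; the full path is itself exercised end-to-end on small
  cohorts. The planted effect size is deliberately strong: confound
  correlations with both sides attenuate the recoverable partial
  association, and −0.9 yields ~90% family-wise-corrected power at
  n = 40 over 231 edges.

What passing these tests shows — and does not show. They validate the
*machinery*: filters, phase estimation, clustering, stitching, graph
algebra, and the statistical engine, against analytic fixtures and planted
truth. They do not certify performance on real patient EEG, where
artifacts, volume conduction, non-stationarity and reference choices
(average reference is this package's default; the original recordings were
vertex-referenced) all matter.

## Numerical and problem-size choices

* Butterworth order 4, forward–backward (zero phase); attenuation well
  over 20 dB one octave outside the passband.
* Delta is defined 1–4 Hz and the relative-power denominator 1–30 Hz
  (both configurable); frequency bins are assigned half-open so a tiling
  band set sums to exactly 1.
* Welch PSD: 2-s Hann segments, 50% overlap.
* k-means: up to 100 iterations, explained-variance tolerance 1e-8,
  10 restarts by default (5 inside `select_k`).
* Suite problem sizes: 60-s recordings for microstate recovery (20 seeded
  runs), 140-s for the planted-lag msPLI check, 400 × (40 × 231) null
  cohorts at 500 permutations and 50 power cohorts at 1,000 permutations
  for the statistical calibration; the study-scale 10,000 permutations
  remain the function default.
* All randomness is seeded; identical config + seed reproduces every
  output bit-for-bit, and the pipeline manifest records the seeds and a
  config hash.

## Known limitations

* No EDF reader/writer in this build; EEG I/O uses a documented TSV
  matrix dialect (plus CSV/JSON for tables, models and results).
* No artifact simulation or rejection; synthetic data are clean by
  construction.
* Group-level microstate templates and minimum-spanning-tree /
  community-detection graph variants are out of scope.
* Whether the original analysis computed graph measures on electrode- or
  ROI-level matrices is not fully documented; this package defaults to
  ROI matrices for both graph measures and statistics, configurable.
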