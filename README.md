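# mspli — microstate-segmented PLI connectivity analysis for resting-state EEG

`mspli` is an R package for quantitative-EEG network analysis of the kind
used to relate behavioural scores (e.g. apathy ratings in Parkinson's
disease) to band-limited functional connectivity. It implements, as one
tested pipeline:

* **Preprocessing** — zero-phase Butterworth band-pass filtering into
  theta / alpha1 / alpha2 / beta, instantaneous phase by a sliding-window
  (4 s, 50% overlap, Hann) Hilbert transform, and Welch relative band
  power per region.
* **Microstate segmentation** — polarity-invariant (modified) k-means on
  maps at GFP peaks, Krzanowski–Lai selection of the number of classes,
  and per-sample backfitting with minimum-duration smoothing.
* **msPLI connectivity** — the phase lag index
  `PLI = |mean_t sign(Δφ_t)|` computed on stitched epochs of samples
  sharing a microstate label (4 epochs × 4,000 samples per class), all
  available epoch matrices averaged per subject and band, then aggregated
  into 22 regions of interest (11 per hemisphere, midline excluded).
* **Weighted graph measures** — degree, clustering coefficient `Cw`,
  path length `Lw` (harmonic mean over `1/W` edge lengths), their
  surrogate-normalised ratios `Gamma = Cw/Cr` and `Lambda = Lw/Lr`,
  assortativity `Rw`, degree diversity `Kw = ⟨k²⟩/⟨k⟩`, radius and
  diameter — with a C++ core and an exhaustive brute-force oracle that
  verifies all eight measures on every weighted graph up to five nodes.
* **Statistics** — log transform of msPLI, OLS residualisation on five
  confounds (age, sex, education, MMS, LED), square-root transform of the
  apathy score, edge-wise Spearman correlation, max-statistic permutation
  correction (family-wise, `(1+B)/(1+N)`), Cronbach's-alpha composite
  scores, Lilliefors normality checks, and median-split ROC
  classification from a single edge.
* **Synthetic data** — a seeded generator of desk-scale EEG cohorts with
  planted microstate structure, phase-lag coupling, and a planted
  monotone apathy–connectivity association with correlated confounds, so
  every stage can be validated against ground truth.

## Worked example: a cohort with a planted apathy effect

Forty synthetic subjects, 231 ROI edges, a planted negative association
between apathy and connectivity at the left frontopolar–right parietal
lateral edge, confounds correlated with both sides:

```r
library(mspli)
planted <- "frontopolar_L--parietal_lateral_R"
cohort <- generate_connectivity_cohort(n_subjects = 40,
                                       effect_edges = planted, seed = 42)
res <- correlate_edges(cohort$edges, cohort$cohort,
                       n_perm = 10000, seed = 42)
head(res[order(res$p_corrected), ], 3)
#>                               edge    rho p_uncorrected p_corrected  n
#>  frontopolar_L--parietal_lateral_R -0.771      5.79e-09      0.0001 40
#>    parietal_L--temporal_anterior_L  0.429      5.70e-03      0.7023 40
#>             central_R--occipital_R  0.424      6.34e-03      0.7371 40
```

The planted edge is recovered with a strong negative Spearman rho and a
family-wise-corrected p of 1/10001; no other edge survives correction.
The same edge supports a median-split classification (low apathy, AES ≤ 24,
vs mildly apathetic, AES ≥ 25; lower connectivity indicates the apathetic
class):

```r
roc <- median_split_roc(cohort$edges[, planted], cohort$cohort$aes,
                        direction = "lower")
#> AUC 0.907, sensitivity 0.67, specificity 1.00
```

## Worked example: the EEG path for one subject

```r
cfg <- sim_config(n_subjects = 8, duration = 60, seed = 7,
                  coupling_spec = data.frame(ch_i = "Fp1", ch_j = "P8",
                                             band = "alpha2",
                                             lag = pi / 4, strength = 0.8))
sub <- generate_subject_eeg(cfg, subject_index = 1, apathy_score = 27)
model <- fit_microstates(sub$recording, k = 4, seed = 1)
#> <microstate_model> k = 4, GEV = 0.465, 32 channels
labels <- backfit(sub$recording, model)
#> <label_vector> 15000 samples, k = 4; coverage: 1:3966 2:3942 3:3554 4:3538
W <- ms_pli(sub$recording, labels, analysis_bands()$alpha2,
            epoch_len = 1000, n_epochs = 4)
W["Fp1", "P8"]
#> 0.738
R <- roi_aggregate(W, default_roi_map())
graph_metrics(R, n_surrogates = 50, seed = 1)
#>   degree    cw gamma   lw lambda      rw   kw radius diameter n_surrogates
#> 1  0.137 0.137     1 7.23      1 -0.0476 2.89   9.23     12.4           50
```

The coupled pair stands out from the ~0.13 background (its PLI falls
short of the 0.8 coupling strength because background oscillations and
noise dilute the shared carrier — the expected behaviour of PLI on
mixtures). On full-length default recordings (180 s) every microstate
class reaches the 4 × 4,000-sample epoch target, giving the full
16-matrix average.

A whole cohort runs through `run_pipeline()`, which reads TSV recordings,
fits and backfits microstates, computes msPLI per band, aggregates to
ROIs, computes graph measures, runs the residualised Spearman +
permutation statistics, and writes per-stage CSVs plus a JSON manifest
with every seed and a config hash. See the methods vignette
(`vignettes/mspli-methods.Rmd`) for the model details and design choices.

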