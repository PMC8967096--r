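# lfpstates

Transient spectral states in subthalamic local field potentials (LFPs), and
their link to parkinsonian motor impairment.

Deep-brain LFPs recorded from the subthalamic nucleus in Parkinson's disease
contain transient oscillatory events — bursts — in the theta (4–7 Hz), alpha
(8–12 Hz), low beta (13–21 Hz) and high beta (22–35 Hz) bands. Low-beta
bursting is suppressed by dopaminergic medication while theta/alpha activity
is enhanced, and the balance between these competing states tracks motor
impairment. `lfpstates` is a toolkit for studying that balance, written for
electrophysiologists and methodologists who want the full analysis chain as
tested, reusable functions rather than a one-off script.

## What it implements

* **TDE-HMM state detection.** A hidden Markov model with zero-mean Gaussian
  emissions fitted to time-delay embedded data
  (`embed_delay()`, `fit_hmm()`, `decode_states()`): each state captures a
  distinct autocovariance, hence a distinct spectral signature
  (`state_spectra()`). Inference is exact maximum-likelihood EM with
  segment-aware forward–backward recursions (C++/RcppArmadillo), validated
  against brute-force path enumeration and an independent reference
  implementation.
* **Band assignment** of states to theta/alpha/low-beta/high-beta or
  background by correlating state time courses with band-limited Hilbert
  envelopes (`band_envelopes()`, `assign_bands()`).
* **State dynamics features**: fractional occupancy, life time, interval
  time, occurrence rate, switching rate, duration-binned visit counts and
  band-to-band transition probabilities (`feature_table()` and friends).
* **The standard percentile-thresholding burst detector** as a comparator
  (`common_threshold()`, `detect_bursts()`, `burst_features()`), over the
  55th–99th percentile grid in steps of 2 (23 threshold models).
* **Ridge regression with leave-one-out cross-validation** linking feature
  changes to hemibody UPDRS scores,
  `beta = (X'X + kappa I)^-1 X'y`, with the penalty chosen on a `2^v`
  grid, `v` in −30…30 (`hemibody_scores()`, `build_design()`,
  `ridge_predict_scores()`).
* **Sign-flip permutation tests and Benjamini–Hochberg FDR**
  (`paired_permutation_test()`, `fdr_bh()`, `sign_consistency_test()`).
* **A synthetic cohort generator** (`cohort_spec()`, `simulate_cohort()`)
  that plants bursty band-limited oscillations over 1/f background in
  64 hemispheres × 2 medication conditions and couples clinical scores to
  the true burst statistics with a calibrated explainable variance — so the
  whole pipeline can be validated against ground truth.
* **One orchestrator**, `run_full_analysis()`, running simulate →
  preprocess → HMM model grid → bands → features → threshold comparator →
  ridge prediction → permutation/FDR statistics into a single report.

The methods vignette (`vignettes/state-dynamics.Rmd`) documents the models,
the parameter defaults and every design decision in detail.

## Worked example

A desk-scale end-to-end run: a synthetic 64-hemisphere cohort with 40 s
sessions and default condition effects (low beta suppressed ON medication,
theta/alpha enhanced), the default 6-model HMM grid and the 23-threshold
comparator, predicting the percent change in hemibody score.

```r
library(lfpstates)

cfg <- desk_config(seed = 1)
report <- run_full_analysis(cfg)
print(report)
#> State-dynamics analysis report
#>   6 HMM models (0 failed), 23 threshold models
#>   median LOOCV r2 by arm:
#>        arm  mode target        r2
#>        hmm delta  total 0.3844623
#>  threshold delta  total 0.3221816

subset(report$stats_delta, level == "band" & feature == "occurrence_rate",
       select = c(unit, median_delta, p_adjusted, rejected))
#>          unit median_delta p_adjusted rejected
#> 16      alpha   0.13812169 0.05859375    FALSE
#> 17 background  -0.13808385 0.05859375    FALSE
#> 18  high_beta   0.03763171 0.05859375    FALSE
#> 19   low_beta  -0.22579027 0.05859375    FALSE
#> 20      theta   0.12556517 0.05859375    FALSE
```

Reading the output: the state-model features predict the medication-induced
change in hemibody score with a median cross-validated r² of 0.38 across the
six HMM models, against 0.32 for the percentile-thresholding comparator, and
the per-band occurrence-rate changes recover the planted condition effects —
the low-beta state becomes rarer ON medication (negative delta, −0.23
visits/s), theta and alpha states more frequent. On these synthetic cohorts
half of the score-change variance is explainable by construction, so an r²
near 0.4 is close to the attainable ceiling once feature-estimation noise at
40 s sessions is accounted for. The adjusted p-values illustrate a desk-scale
limit rather than a bug: each cell's sign-flip test pools one median per HMM
model, and with a 6-model grid the smallest achievable two-sided p is
2/2⁶ = 0.031, which cannot survive Benjamini–Hochberg correction across 20
cells — cross-model consistency tests only become powerful with the large
model grids (dozens of models) used on real cohorts.

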