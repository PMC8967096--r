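---
title: "Transient spectral states in subthalamic LFPs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient spectral states in subthalamic LFPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Subthalamic local field potentials (LFPs) in Parkinson's disease show
transient oscillatory events — bursts — in several frequency bands below
40 Hz: theta (4–7 Hz), alpha (8–12 Hz), low beta (13–21 Hz) and high beta
(22–35 Hz). Low-beta bursting is the classical marker of the parkinsonian
OFF-medication state, but the bands do not act in isolation: dopaminergic
medication suppresses low-beta states while enhancing theta and alpha
states, and the balance between these competing states carries information
about motor impairment beyond what any single band provides.

`lfpstates` implements the full analysis chain for studying this balance:

1. a **time-delay embedded hidden Markov model (TDE-HMM)** that segments the
   LFP into recurring spectral states without pre-defining bands;
2. **band assignment** of states by correlation with band-limited Hilbert
   envelopes;
3. **state-dynamics features** (fractional occupancy, life time, interval
   time, occurrence rate, switching rate, duration-binned visit counts,
   band-to-band transition probabilities);
4. the standard **percentile-thresholding burst detector** as a comparator;
5. **ridge regression with leave-one-out cross-validation (LOOCV)** linking
   feature changes to hemibody motor scores;
6. **sign-flip permutation tests** with Benjamini–Hochberg false-discovery
   control;
7. a **synthetic cohort generator** that plants bursty oscillations with
   known statistics and couples clinical scores to them, so every stage can
   be validated against ground truth.

# The TDE-HMM

## Model

The preprocessed signal (2–48 Hz bandpass, 100 Hz, z-normalized per
session) is delay-embedded: row $t$ of the design is
$(x_{t-L}, \dots, x_t, \dots, x_{t+L})$, a window of $2L+1$ samples. A
hidden Markov chain with $K$ states emits these rows from zero-mean
multivariate Gaussians; each state is therefore characterized purely by a
$(2L+1)\times(2L+1)$ covariance, i.e. by a local autocovariance sequence,
i.e. by a spectral signature. The emission mean is pinned at zero because
the signal is z-normalized and all information of interest is in the
autocovariance.

Windows never span session boundaries, and the forward–backward recursions
restart at every boundary with pooled sufficient statistics, so no state
visit or transition is ever counted across hemispheres or medication
conditions.

## Inference

Parameters are estimated by maximum-likelihood EM (Baum–Welch) rather than
the variational-Bayes machinery used by some toolboxes: every downstream
quantity here (state time courses and their summary statistics) depends
only on point estimates and posteriors over states, not on posterior
distributions over parameters, so ML-EM keeps the implementation
self-contained and exactly testable against brute-force path enumeration.
The E-step, M-step and Viterbi decoder are written in C++ (RcppArmadillo)
because cohort-scale fits involve $10^5$–$10^6$ embedded rows.

Numerical choices:

* covariances are regularized by adding $\varepsilon = 10^{-6}$ to the
  diagonal at every M-step;
* forward–backward uses per-sample scaling with a row-wise max-shift of the
  log-densities, stable for $T \ge 10^5$;
* initialization assigns random contiguous 50-sample blocks to states with
  0.9 responsibility (sampling variability then differentiates the initial
  covariances); `n_restarts` seeded initializations each get a few EM
  iterations and the best by log-likelihood continues to `max_iter`
  (default 4 restarts, 20 iterations, relative-change tolerance
  $5\times10^{-4}$);
* the hard state course is the per-sample argmax of the posteriors (ties to
  the lower state index); Viterbi decoding is available via
  `hmm_config(pathing = "viterbi")`;
* non-convergence and near-empty states (occupancy below 10 samples) set
  flags on the model instead of failing.

State spectra are computed from each state's covariance: the lag-$\tau$
autocovariance is read off the matrix diagonals, Hann-tapered and Fourier
transformed. Windows shorter than 11 samples set a low-resolution flag.

## Model grid

The analysis is deliberately run over many $(K, L)$ combinations and
results are pooled across models, so conclusions do not hinge on one
arbitrary choice of state count or window length. The desk-scale default
grid is $K \in \{6, 8, 10\} \times L \in \{7, 11\}$ (6 models); the grid is
fully configurable.

# Band assignment

Each state's hard 0/1 time course is correlated (zero-lag Pearson) with the
Hilbert envelopes of the four bands. Bands with positive correlation are
candidates: no candidate → background; one candidate → that band; two or
more → the state is assigned to the top band only if the two most positive
correlations are both low-frequency (theta, alpha) or both high-frequency
(low beta, high beta), otherwise background. The positive-candidate
restriction matters on synthetic data with well-separated bands, where a
clean state can have one strongly positive correlation and noise-level
negative correlations everywhere else; without the restriction the
top-two test pairs it with a negative band and discards it as a straddle.
On real spectra, neighbouring bands correlate positively and the two
readings coincide. Zero lag is the minimal reading of "cross-correlating";
a posterior-probability course is available via `use_posterior = TRUE`.

# Features

Visits are maximal runs of the hard course within one session; no minimum
duration is imposed. Per state and session: fractional occupancy, life time
(mean visit duration), interval time (mean gap to the next visit of the
same state; missing with fewer than two visits), occurrence rate
(visits/s), plus the session-level switching rate, duration-binned visit
counts (<0.1, 0.1–0.2, …, >0.9 s; half-open bins), and band-to-band
transition probabilities on the visit sequence. Band-level features sum
occupancy and rates over member states and occupancy-weight life and
interval times (the collapse rule for times is not standardized; weighting
by occupancy is the natural choice). Undefined values propagate as missing,
never as zero.

Two accounting identities hold for every session and are tested
everywhere: state occupancies sum to 1, and
$\mathrm{FO} \times \mathrm{duration} = \mathrm{life\ time} \times
\mathrm{visit\ count}$.

# The thresholding comparator

The standard burst definition: per hemisphere and band, one common
amplitude threshold — the mean of the OFF and ON envelope percentiles — and
maximal supra-threshold runs as bursts, with no minimum duration. The
percentile grid is 55th–99th in steps of 2 (23 threshold models). Burst
features are rate, mean duration and the duration-binned relative counts;
the fraction of time above threshold is also reported in the tables but is
not part of the standard burst feature set and is not used as a regressor.
Percentiles use linear interpolation; the comparison is `>=` so ties fall
inside bursts. Thresholds are per-hemisphere (per-recording envelopes), the
natural reading of the per-subject mean-of-conditions rule.

# Clinical scores and prediction

Hemibody bradykinesia–rigidity is the sum of UPDRS-III sub-items 22–26,
tremor of sub-items 20–21; improvement is $100 \times
(\mathrm{OFF}-\mathrm{ON})/\mathrm{OFF}$ (undefined when OFF is 0).

Ridge regression $\hat\beta = (X^\top X + \kappa I)^{-1} X^\top y$ is fit
per model on the state-level feature deltas (or OFF values), with columns
standardized inside every training fold, LOOCV for out-of-fold predictions,
and the penalty grid $\kappa = 2^v$, $v \in \{-30,\dots,30\}$ — the
"penalty varied between −30 and 30" is read as exponents of 2, since a
negative raw penalty is not meaningful in the ridge normal equations.

Two reporting decisions deserve emphasis:

* **Penalty selection uses out-of-fold skill** $1 - \mathrm{SSE}/\mathrm{SST}$
  (equivalent to minimizing LOOCV mean squared error), then extends to the
  smallest $\kappa$ within 0.005 of the maximum (the "prediction power
  converged" reading). An unsigned squared correlation cannot be used as
  the selection target: in the strong-shrinkage limit each leave-one-out
  prediction approaches the training-fold mean, which is exactly
  *anti*-correlated with the held-out observation, so $r^2 \to 1$ on pure
  noise and the selector would always choose the largest penalty.
* **The headline $r^2$ is the squared Pearson correlation** between
  out-of-fold predictions and observations (the scatter-plot reading),
  zeroed when the correlation is negative for the same reason;
  $1-\mathrm{SSE}/\mathrm{SST}$ is reported alongside.

The default regression design uses the dwell features (per-state
fractional occupancy, life time, interval time, occurrence rate, plus the
session switching rate; for the comparator, per-band burst rate and mean
duration). The duration-binned counts are always computed and reported, and
can be added to the designs with `include_duration_bins = TRUE`; at
desk-scale cohort sizes ($n = 64$ hemispheres) they contribute ~100 mostly
empty, collinear columns that measurably dilute cross-validated prediction,
so they are not regressors by default. Missing feature cells are imputed by
the column median (with a log); constant and all-missing columns are
dropped.

# Statistics

Medication effects are tested cell-wise (band × feature, including
transition cells) with sign-flip permutation tests on per-model medians
across hemispheres — each model contributes one median, mirroring the
pooling-across-models logic of the analysis — and Benjamini–Hochberg FDR
across cells. Sign flips are enumerated exactly whenever $2^n$ does not
exceed the permutation budget. The permutation statistic is the mean of the
per-model values: a median statistic is degenerate under sign flips at
small model counts (with six equal values, flipping one leaves the median
unchanged, so no pattern is ever more extreme than the observed one and the
smallest achievable two-sided p-value collapses); the median is still
reported descriptively. Bivariate feature–score correlations default to
Spearman for robustness.

Cross-model tests inherit their resolution from the model grid: with $M$
models the smallest achievable two-sided sign-flip p-value is $2/2^M$,
i.e. 0.031 for the 6-model desk grid — too coarse to survive FDR
correction across twenty-odd cells. This is a property of the design, not
a defect; the large grids used on real cohorts (dozens of models) are what
give these consistency tests their power.

# The synthetic cohort generator

## What it emulates

The generator stands in for the study's raw data (64 hemispheres, OFF and
ON sessions of roughly 390 s): three bipolar-like channels of $1/f$
background with Hann-tapered sinusoidal burst events planted on the
designated channel (channel 2, exercising contact selection), Poisson event
onsets, gamma-distributed durations, per-band carrier frequencies at the
band centers, and condition-dependent statistics — low-beta bursting
suppressed and briefer ON medication, theta/alpha (and mildly high-beta)
enhanced. Overlapping same-band events merge; different bands may overlap
(the single-active-state limitation of the HMM is then exercised
deliberately).

Defaults (per-band rate in events/s OFF → ON): theta 0.25 → 0.50, alpha
0.25 → 0.40, low beta 0.80 → 0.45, high beta 0.30 → 0.40; mean durations
0.25–0.55 s (gamma, shape 2); amplitudes 2.5–3.2 z-units against unit
background — the well-separated regime (envelope SNR ≈ 3), with low beta
the most prominent transient, as in parkinsonian STN recordings.

Cohort heterogeneity is essential and deliberately large: per hemisphere
and condition, rates, durations and amplitudes carry log-normal multipliers
(log-SDs 0.45, 0.30, 0.20), and the $1/f$ exponent is drawn per recording
(SD 0.12) because the aperiodic background is not stable across subjects or
medication states. With much smaller spreads the across-cohort feature
variance sinks toward the per-session estimation-noise floor and no
estimator — threshold or state model — can recover feature–score couplings
at $n = 64$; the large spread matches the wide distribution of burst
metrics reported across patients.

## Score coupling

Clinical scores are built in two layers. OFF scores are a baseline plus a
scaled projection of the true OFF burst features onto the coupling weights
plus noise. ON scores are constructed from the OFF scores through a percent
improvement whose patient-to-patient variation carries the coupled
component of the true ON−OFF feature deltas; the noise on that percent
change is calibrated so the coupled component explains a target fraction
(default 0.5) of the score-change variance. Scores are rounded to integers,
truncated at zero, and split multinomially over the UPDRS sub-items to
mimic item granularity. With all coupling weights zero and zero score
noise, OFF and ON hemibody scores are identical by construction.

The default coupling weights put most weight on fractional occupancy and
mean duration (low beta positive; theta, alpha, high beta negative) and
only a little on the latent event rate: once events merge and ride on a
$1/f$ background, the latent Poisson rate is only weakly identified by any
amplitude-referenced detector, whereas occupancy and duration are measured
well. Coupling impairment to occupancy/duration also matches the
empirical pattern that burst *time* rather than event count tracks motor
state.

## What it does not emulate

Real LFPs have non-sinusoidal, waveform-asymmetric bursts, drifting carrier
frequencies, artifacts, tremor-locked components, volume conduction and
electrode-geometry effects; none of these are modelled. Consequently the
planted bursts are, by construction, exactly the kind of event an amplitude
threshold detects, which makes the thresholding comparator unrealistically
strong relative to its performance on patient data: passing recovery tests
here demonstrates the pipeline's correctness and calibration, not the full
real-data advantage of state modelling over thresholding, and the absolute
prediction levels reported on patient cohorts are not reproducible from
synthetic data.

# Problem sizes and reproducibility

All randomness flows from one root seed through named substreams
(`derive_seed`), making cohorts, fits and permutation tests bit-for-bit
reproducible. The desk-scale configuration (`desk_config()`) used by the
examples, tests and the reproduction script runs the full 64-hemisphere
cohort with 40 s sessions, fits each HMM on a 10-hemisphere subset of
sessions and decodes the whole cohort; a complete 6-model grid with the
23-threshold comparator completes in about half a minute per cohort on one
core. Session length and the EM subset trade statistical precision for
time; both are configuration fields, and the full-length (390 s, fit on
all sessions) configuration is a parameter change, not a code change.

```{r example}
library(lfpstates)
cfg <- desk_config(seed = 1)
report <- run_full_analysis(cfg)
print(report)
```

# Known limitations

* Only one state is active at a time; concurrent cross-band events are
  resolved in favour of the dominant state.
* Band attribution inherits the arbitrariness of canonical band edges.
* The EM fit is a local optimizer; restarts mitigate but do not eliminate
  initialization dependence, and small-$K$ models may merge bands.
* LOOCV $r^2$ at $n = 64$ has substantial sampling variance (roughly
  ±0.1), so per-cohort values scatter widely around the explainable
  variance even when the pipeline is working correctly.
* The penalty is selected on the same LOOCV that produces the reported
  $r^2$ (as in the source analysis), which carries mild selection optimism.
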