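---
title: "Methods: from early-ICU monitoring to feature-network importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from early-ICU monitoring to feature-network importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvnet)
```

`hrvnet` analyses the first hours of intensive-care monitoring of
traumatic brain injury patients as a *network of features*: 51 per-patient
quantities — 16 heart-rate-variability (HRV) features, 16 vital-sign
features, 13 pathology analytes, 4 Glasgow Coma Scale (GCS) scores and 2
demographics — are correlated pairwise, thresholded into a graph, and
ranked by an unsupervised graph-convolutional embedding. Because ICU
monitoring data cannot be redistributed, the package ships a seeded
synthetic-cohort generator with *planted*, analytically known correlation
structure; every stage is validated against that ground truth or against
brute-force oracles.

## The observation window and exclusion rule

Monitoring begins at ICU admission. The first hour is typically dominated
by stabilization artifacts, so the default analysis window is **[2 h,
14 h)** — twelve consecutive hourly segments starting at the second hour.
Patients whose recording is shorter than `min_hours = 12` are excluded
before assembly (`apply_exclusions()`), and the screened/excluded/retained
counts are logged. Both window endpoints and the minimum duration are
configuration parameters, because reasonable designs differ on whether
"the first 12 hours" means 11 or 12 usable segments; the default honours
twelve hourly segments.

## HRV features

R peaks are detected from the 240 Hz ECG by a Hilbert-envelope detector:
an 8–40 Hz zero-phase Butterworth band-pass (order 3, forward–backward,
with odd-reflection padding so filter transients cannot masquerade as
beats), the envelope as the modulus of the FFT-based analytic signal, an
adaptive threshold `median + 3·MAD` (floored at 20 % of the envelope
maximum), one candidate per above-threshold region, a 250 ms refractory
rule keeping the stronger candidate, and refinement to the raw-signal
maximum within ±60 ms. On noise-free synthetic input every planted beat
is recovered to within one sample. Intervals outside 300–2000 ms are then
discarded (`clean_rr()`).

Per hourly window the 16 features are:

* **Time domain** — `MeanRR`, `SDNN` (sample SD), `SDANN` (SD of 5-min
  segment means), `RMSSD`, `pNN50` (strictly greater than 50 ms, with the
  total interval count as denominator — the printed definition, kept even
  though successive-difference counts are the more common denominator).
* **Frequency domain** — the series is resampled to a uniform 4 Hz grid
  by cubic splines, mean-detrended, and its PSD estimated by Welch's
  method (256-sample Hann segments, 50 % overlap). Band powers integrate
  VLF [0.005, 0.04), LF [0.04, 0.15) and HF [0.15, 0.4) Hz; `p_VLF`,
  `p_LF`, `p_HF` are percentages of the VLF+LF+HF total (so they sum to
  100), and `HF_LF` is the HF/LF power ratio, in that order, matching the
  feature symbol. The VLF band starts at 0.005 Hz; a variant that starts
  at 0 can be passed through the `bands` argument.
* **Poincaré** — closed forms with population variances:
  `SD1 = sqrt(var(diff(rr))/2)`,
  `SD2 = sqrt(2·var(rr) − var(diff(rr))/2)`, which satisfy
  `SD1² + SD2² = 2·var(rr)` exactly.
* **Recurrence analysis** — delay embedding (dimension 10, delay 1 beat),
  Euclidean distances thresholded at 10 % of the maximum distance;
  `REC` = % recurrent points (main diagonal excluded), `DET` and `LAM` =
  fraction of recurrent points on diagonal / vertical lines of length ≥ 2.
  These parameters are conventional rather than canonical; all are
  overridable via `rqa_params()`. On a constant series `DET` is
  `(N(N−1)−2)/(N(N−1))`, not exactly 1, because the two length-1 corner
  diagonals are correctly excluded by the line-length rule. For cost
  reasons a window is truncated to its first 1500 intervals (contiguous,
  preserving successive-beat structure) before the O(N²) recurrence
  matrix is formed.
* **Detrended fluctuation analysis** — profile integration, per-box
  linear detrending, RMS fluctuation; `Alpha1` is the log–log slope over
  4–16-beat boxes, `Alpha2` over 16–64. Note that over such short boxes
  DFA-1 has a known upward finite-size bias on uncorrelated data: white
  noise calibrates near 0.58 rather than 0.50 (an independent
  implementation agrees), which is still within the ±0.1 calibration band
  the tests assert.

Each feature is computed per hourly window and averaged over the windows
in which its preconditions hold (e.g. the spectral features need ≥ 5 min
of beats); the per-feature count of contributing windows is recorded.

## Vital-sign and clinical features

The five minute-by-minute channels (HR, DBP, SBP, ABPM, SpO2) contain
gaps of varying length. Missing minutes are imputed by **k-nearest
neighbours on the time axis within a channel** (k = 5, ties toward the
earlier sample): the published description names only the method, so the
neighbourhood definition is the minimal univariate-in-time reading, and
imputation never alters observed values (it is idempotent). Per channel
the features are the mean, sample SD, and ordinary-least-squares slope
(units/hour) over the analysis window, computed on the full minute-level
series rather than on hourly means — the wording of the source protocol
admits both; the alternative is one `tapply` away and the choice is
documented here. Temperature is a single pass-through value. GCS
components are range-checked ordinals (eyes 1–4, motor 1–6, verbal 1–5,
total 3–15) treated as numeric downstream; gender is coded female = 0 /
male = 1 so its Pearson correlation with a continuous feature equals the
point-biserial correlation. Respiratory rate is excluded by design.

## Correlation network

Pearson correlations are computed on pairwise-complete observations;
pairs with fewer than 3 complete observations or zero variance are
undefined and never become edges. Edges connect features with
**|r| ≥ 0.5**, inclusively, and carry the signed correlation. p-values
(t transform, n−2 df) are reported in the artifacts but play no role in
edge selection, and no multiplicity correction is applied — edge
selection is by effect size, not significance. Centralities are
normalized as `degree/(n−1)` and `betweenness/((n−1)(n−2)/2)` on the
unweighted graph with full shortest-path multiplicity accounting
(disconnected pairs contribute zero); a `1/|r|`-weighted variant sits
behind a flag. Group densities divide realized by possible pairs within
and between the five feature groups.

## Graph-convolutional importance

The embedding model is a two-layer graph-convolutional autoencoder,
written in plain matrix algebra with hand-derived gradients and Adam
(β = 0.9/0.999, ε = 1e−8; weight init N(0, 0.1²), seeded):

$$H = \mathrm{relu}(\hat A X W_1), \qquad \hat X = \hat A H W_2,$$

minimizing the mean squared reconstruction error. $\hat A =
\tilde D^{-1/2}(A + I)\tilde D^{-1/2}$ is the renormalized adjacency;
**by default $A$ carries |r| edge weights** — in a correlation network
the edge weight is the defining quantity, and discarding it makes a
0.5 and a 0.95 correlation propagate identically. An unweighted operator
is available (`weighted = FALSE`).

**Node features are the thresholded signed correlation profiles**: row
$i$ of $X$ is feature $i$'s correlations with every feature, zeroed below
the threshold, with a unit diagonal. This is a deliberate design choice,
and the package's most consequential one. The obvious alternative —
giving each node its z-scored patient-value vector — was implemented
first and rejected on evidence: z-scoring equalizes all row norms, an
overcomplete hidden layer (the 32–256 grid exceeds a 29-patient feature
dimension) reconstructs every node near-perfectly, and the resulting
embedding norms carry *no* connectivity signal — isolated nodes actually
score highest, because their self-loop passes their features through
unattenuated while aggregation shrinks connected nodes. With correlation
profiles, a node's input is literally its connectivity pattern, and the
embedding L2 norm expresses how strongly and how widely a feature is
correlated — which is exactly the quantity the ranking is meant to
report. These scores indicate connectivity, not causal importance.

Model selection follows a grid search over hidden dimensions
(32, 64, 128, 256) and learning rates (0.001, 0.01, 0.1), 1000 epochs per
arm, selecting the lowest **validation MSE** on a seeded random 20 % of
the entries of $X$ masked out of the training loss (an unsupervised task
has no natural split; entry-masking is the minimal construction that
defines one, and it is recorded with the run). Ties break toward the
smaller hidden dimension, then the smaller rate; diverging arms are
excluded. The selected configuration is retrained for 10,000 epochs.
Importance is the L2 norm of each node's embedding row divided by the
maximum (top feature = 1.0; a min–max variant is available), with
descending ranks.

### What hub recovery does and does not show

The test suite plants a hub: one feature with population |r| = 0.8 to
eight spokes, all other features independent. Positive-semidefiniteness
forces the spokes of such a star to inter-correlate — the minimum
feasible spoke–spoke correlation is $r^2 - (1-r^2)/(m-1) \approx 0.59$,
which the generator attains by giving the spokes centered, mutually
canceling factor loadings — so the planted "hub" is necessarily the
strongest member of a 9-clique rather than a pure star center. Under the
fixed test protocol (hidden 64, learning rate 0.01, 2000 epochs, 25
seeds) the hub lands inside its planted community essentially always,
but beats all of its spokes (top-3 of 51) only in roughly a third to
two-thirds of seeds depending on the seed set: at n = 29 the sampling noise of individual
correlations (±≈0.1) is comparable to the 0.8-vs-0.59 population gap
that separates hub from spokes. Slower training preserves more of the
input-profile signal and would raise that rate, but the protocol is kept
fixed rather than selected on outcomes. The honest summary: the
embedding ranking reliably separates connected communities from
weakly-connected features, and identifies the hub *approximately*, not
certainly, at this sample size.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 34 patients, 5 of them
with recordings under 12 h (8 h by default) to exercise the exclusion
rule, 14 h of monitoring otherwise, ECG at 240 Hz (or R-R series directly
— `ecg_mode = "rr"` — since waveform synthesis and re-detection are exact
inverses on clean data and expensive at scale). R-R series follow a
two-tone model (LF and HF sinusoidal modulation plus white noise;
defaults 25/15/18 ms at a mean of 850 ± 70 ms between patients), with
rejection-resampling below 300 ms. The ECG waveform plants a Ricker
(second-derivative-of-Gaussian) pulse per beat — the simplest template
with a single sharp R-like maximum. Vitals are minute-level with shared
latent factors, per-patient trends, and Poisson-count/geometric-length
gaps (about one 6-min gap every two hours per channel). Pathology, GCS
and demographics are truncated-normal/ordinal draws in plausible adult
ICU ranges; two patient-level factors (autonomic, severity) plant
cross-group correlations, and the implied population correlation matrix
is emitted as `ground_truth.csv`. None of these values is calibrated to
any real cohort — they make the statistical *structure* of the analysis
testable (planted correlations are recovered, exclusions counted,
artifacts reproducible), not its clinical content. Passing tests
demonstrate correctness of the machinery, not validity of any clinical
claim; real recordings differ in ectopy, artifacts, non-stationarity and
treatment effects that the generator deliberately omits.

`simulate_feature_table()` skips the signal level entirely and draws the
51-feature table from an explicit loadings matrix, giving closed-form
population correlations for the network- and embedding-recovery suites.

## Numerical choices and degenerate inputs

* Intervals below 300 ms or above 2000 ms are removed, never clamped.
* `HF_LF` is `NA` (not infinity) when LF power is zero.
* `SD2`'s radicand is clipped at zero against rounding.
* Zero-variance feature columns abort standardization with a named error;
  undefined correlations yield missing matrix entries but never graph
  errors.
* An empty graph (threshold near 1) degrades the embedding input to the
  identity profile; the stage warns and completes.
* All randomness flows from one master seed through a deterministic
  splitter, so `run_pipeline()` is byte-reproducible; FFT lengths are
  padded to 2-3-5-smooth sizes to keep the Hilbert transform O(n log n)
  for arbitrary trace lengths.

## Problem sizes in the test suite

The suite exercises the study-scale pieces (34-patient cohorts at the
interval level; 29-patient feature tables for 50-seed network recovery;
25-seed hub recovery at 2000 epochs) but runs the waveform-level
pipeline on miniatures (4–6 patients, ~1 h at 240 Hz), which already
covers every code path including detection, imputation and artifact
round-trips. `scripts/acceptance.R` re-runs the full 34-patient pipeline
with the complete 12-point grid search and 10,000-epoch final training.

## Known limitations

* The R-peak detector targets clean-to-moderately-noisy single-lead
  signals with dominant R waves; it does not classify ectopy or handle
  polarity inversions.
* `pNN50`'s denominator and the `HF_LF` orientation follow the printed
  feature definitions; both differ from the most common conventions in
  the HRV literature, and values are not directly comparable to tools
  using the other convention.
* Betweenness is computed on the unweighted graph by default; with
  weights it uses `1/|r|` distances, which is one of several defensible
  choices.
* Importance scores rank connectivity in one fitted embedding; they are
  not stable feature-selection statistics and carry no causal meaning.
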