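# hrvnet

Correlation networks and graph-convolutional importance for early-ICU
physiological features.

Managing traumatic brain injury (TBI) in intensive care means watching
dozens of interacting signals at once: heart-rate variability (HRV)
reflecting autonomic state, minute-by-minute vital signs, blood-gas and
electrolyte panels, Glasgow Coma Scale (GCS) scores, demographics.
`hrvnet` is for researchers who want to study how those markers
*co-vary* in the first hours after admission. It extracts a 51-feature
table per patient (16 HRV + 16 vital-sign + 13 pathology + 4 injury-score
+ 2 demographic features), treats the features as nodes of a correlation
network, and ranks them by an unsupervised graph-neural embedding.
Because ICU monitoring data cannot be shipped, the package includes a
seeded synthetic-cohort generator (240 Hz ECG or R-R series, gappy
minute-level vitals, clinical panels) with *planted*, analytically known
correlation structure, so the entire pipeline is testable end to end.

## The method

For patients retained by the exclusion rule (recordings of at least
12 h), features are computed over the window from the 2nd to the 14th
hour after admission: HRV features per hourly segment (time-domain
SDNN/SDANN/MeanRR/RMSSD/pNN50; Welch band powers p_VLF/p_LF/p_HF and
the HF/LF ratio; Poincaré SD1/SD2; recurrence measures REC/DET/LAM; DFA
exponents α₁/α₂), averaged across segments; vital-sign mean, SD and
regression slope per channel after k-NN imputation of gaps; pathology,
GCS and demographic values as recorded.

The network stage computes pairwise Pearson correlations `r_ij` and
keeps an edge wherever `|r_ij| ≥ 0.5`. Node centralities are normalized
as

```
degree_i / (n − 1)        and        betweenness_i / [(n − 1)(n − 2) / 2]
```

with group-wise edge densities summarizing the five feature groups.

The importance stage fits a two-layer graph-convolutional autoencoder

```
H = relu(Â X W₁),    X̂ = Â H W₂,    minimize mean((X̂ − X)²)
```

where `Â` is the renormalized (|r|-weighted) adjacency with self-loops
and each node's feature vector in `X` is its thresholded correlation
profile. Hyperparameters come from a grid search (hidden 32/64/128/256 ×
learning rate 0.001/0.01/0.1, 1000 epochs each, lowest validation MSE on
masked entries), the final model trains for 10,000 epochs with Adam, and
each feature's importance is the L2 norm of its embedding row normalized
by the maximum. High scores mean high connectivity in the correlation
network — not causal importance.

## Worked example

Simulate two hours of beat intervals with low- and high-frequency
modulation, and summarize them the way the pipeline does:

```r
library(hrvnet)
rr <- generate_rr_series(mean_rr = 850, sd_lf = 25, sd_hf = 15, sd_noise = 18,
                         duration = 2 * 3600, seed = 1)
hourly_hrv(rr, window_start = 0, window_end = 2)
#> HRV features (window averages):
#>     SDNN    SDANN   MeanRR    RMSSD    pNN50    p_VLF     p_LF     p_HF
#>  34.3582   0.8554 848.8882  34.2944  14.4440   1.7013  64.8455  33.4532
#>    HF_LF      REC      DET      LAM      SD1      SD2   Alpha1   Alpha2
#>   0.5161   0.0030   0.7355   0.0000  24.2498  42.0988   1.0056   0.1495
```

The mean interval and SDNN reproduce the generator settings (850 ms;
modulation SDs 25/15/18 ms combine to ≈ 34 ms), and the band powers
split between LF and HF as planted.

Now a 29-patient feature table with a planted hub — `DBP_std` correlated
at |r| = 0.8 with eight other features — pushed through the network and
embedding stages:

```r
hl  <- hub_loadings("DBP_std",
                    c("GCS_final", "GCS_motor_12h", "SDNN", "RMSSD",
                      "SD1", "SD2", "pNN50", "MeanRR"), r = 0.8)
sim <- simulate_feature_table(29, hl$loadings, noise_sd = hl$noise_sd, seed = 5)
fm  <- assemble_features(sim$hrv, sim$vitals, sim$clinical)
net <- feature_network(fm, threshold = 0.5)
net
#> Feature correlation network (|r| >= 0.5 )
#>   nodes: 51  edges: 37

fit <- feature_gcn(net, hidden = 64, lr = 0.01, epochs = 2000, seed = 5)
node_importance(fit, groups = setNames(net$schema$group, net$schema$feature))
#> Feature importance (embedding L2 norms), top 10 of 51
#>        feature        group l2_norm normalized_score rank
#>        DBP_std   VitalSigns  1.8795           1.0000    1
#>          RMSSD          HRV  1.7711           0.9423    2
#>         MeanRR          HRV  1.7248           0.9177    3
#>  GCS_motor_12h InjuryScores  1.7197           0.9149    4
#>      GCS_final InjuryScores  1.7079           0.9087    5
#>  ...
```

The planted hub tops the ranking and its correlated community fills the
next slots — the embedding norm is reading out connectivity strength.

The whole chain (simulate → HRV → vitals → assemble → network → embed →
rank) runs as one seeded, byte-reproducible call writing per-stage CSV /
GraphML artifacts and a checksum manifest:

```r
run_pipeline(default_config(seed = 1), output_dir = "run1")
```

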