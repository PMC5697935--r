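# thetasync

Analysis pipeline for dual-region electrophysiology (medial prefrontal
cortex, mPFC, and ventral tegmental area, VTA) recorded during an
instrumental task in which every action is rewarded but is punished with a
blockwise-varying probability (P(shock|action) = 0, 0.06, 0.1 across three
50-trial blocks). The package asks, at desk scale and with full ground
truth, the questions such recordings are used to answer:

* **Do single units encode punishment risk?** Per-unit, time-resolved
  bias-corrected percent explained variance,

  ωPEV = (SS_blocks − df_blocks · MS_error) / (SS_total + MS_error),

  compared against pointwise and *global* significance bands built from
  1,000 trial-label shuffles (the global band controls the family-wise
  error across time bins at α = 0.01). Response direction comes from the
  standardized regression coefficient of spike counts on block index
  (equal to Pearson's r in this simple regression).
* **Which VTA units are putative dopamine neurons?** The dual criterion:
  baseline rate < 12 Hz and waveform width > 1.2 ms, *and* membership in
  the reward-response cluster with phasic post-reward excitation
  (auROC profiles in 100 ms bins over (−0.5, 1) s around reward, PCA by
  SVD, 2-component Gaussian-mixture clustering by EM).
* **Do population trajectories track behavior?** Gaussian-process factor
  analysis (GPFA) of square-rooted spike counts, y_t | x_t ~ N(Cx_t + d, R)
  with independent GP priors x_i ~ N(0, K_i) over time, fitted by EM;
  cross-validated dimensionality; and the correlation between each trial's
  trajectory deviation from the safe-block mean trajectory and its
  log response-time deviation.
* **Does theta-band synchrony decline with risk?** Multitaper (nine
  Slepian tapers, 500 ms windows, 50 ms steps) spectrograms and
  magnitude-squared coherence; bivariate spectral Granger causality
  I_{1→2}(f) from an AIC-order VAR with permutation confidence bounds
  (α = 0.001); and spike–field phase locking: 5–15 Hz zero-phase bandpass,
  Hilbert phase, mean resultant length resampled 1,000 × 100 spikes (PLV),
  Rayleigh z-test, and time-lagged profiles (−100..100 ms in 4 ms steps)
  whose negative peak lags indicate that the oscillation leads the spikes.

A seeded synthetic-session generator (`generate_session()`) reproduces the
task's statistical structure — block-modulated lognormal response times,
pseudo-random shock trials (0/3/5 per block), event-locked firing-rate
bumps with block gains, an action-locked theta burst declining over blocks,
a delayed VTA→mPFC theta copy, and von Mises spike-phase coupling — so
every stage can be validated against `ground_truth()`.

## Worked example

```r
library(thetasync)

session <- generate_session(session_config(seed = 3))
session
#> <ephys_session>
#>   trials: 150 in 3 blocks (8 shock)
#>   units : mPFC=16, VTA=13
#>   lfp   : VTA, mPFC @ 1000 Hz
#>   duration: 1544.6 s; seed: 3

behavioral_summary(session$trials)$per_block[, 1:3]
#> # A tibble: 3 × 3
#>   block mean_rt var_rt
#> 1     1    1.05  0.110
#> 2     2    1.87  0.545
#> 3     3    3.10  1.82

enc <- encode_units(session, n_shuffles = 1000, seed = 1)
table(enc$region, enc$encoder)
#>        FALSE TRUE
#>   mPFC     6   10
#>   VTA      4    9
```

The rising per-block mean and variance of the response time mirror the
behavioral signature of punishment risk; roughly half the units cross
their global ωPEV band, matching the encoder fraction programmed into the
generator. Continuing:

```r
gc <- granger_blockwise(session)
attr(gc, "theta_summary")
#> # A tibble: 3 × 4
#>   block gc_vta_to_mpfc gc_mpfc_to_vta order
#> 1     1        0.118          0.0296     19
#> 2     2        0.0343         0.0161     19
#> 3     3        0.00418        0.00225    19
```

Theta-band Granger causality is asymmetric in the bottom-up (VTA→mPFC)
direction and collapses as the programmed theta amplitude declines with
risk. `phase_locking_analysis()` + `blockwise_plv_comparison()` show the
corresponding drop in spike–field PLV, and
`population_trajectories(session, "mPFC")` reproduces the
trajectory-deviation/response-time correlation.

## Package layout

* `R/session.R`, `R/generate.R` — session container, TSV/JSON session
  directories, synthetic-session generator with ground truth.
* `R/binning.R`, `R/encoding.R` — peri-event tensors, baseline z-scoring,
  ωPEV, surrogate bands, SRC, baseline-modulation and rate–RT tests.
* `R/cellclass.R` — auROC reward profiles, PCA/GMM clustering, the dual
  DA criterion.
* `R/gpfa.R` — GPFA EM, cross-validated dimensionality, orthonormalized
  trajectories, deviation/RT correlation.
* `R/spectra.R`, `R/granger.R` — Slepian tapers, multitaper spectrograms
  and coherence, VAR fitting, spectral Granger causality, permutation
  bounds.
* `R/phase.R` — bandpass/Hilbert phase, spike phases, MRL/PLV, Rayleigh
  test, lagged profiles, blockwise comparisons.
* `R/pipeline.R`, `R/plots.R` — `run_all()` orchestration, behavioral
  summaries, `autoplot()`/`plot_*()` figures.

See the methods vignette (`vignettes/thetasync-methods.Rmd`) for the
modeling choices, parameter defaults, and known limitations.
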