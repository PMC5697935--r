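---
title: "Models and methods behind thetasync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thetasync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thetasync analyzes trial-structured dual-region recordings (mPFC and VTA)
from an instrumental task in which every action is rewarded but carries a
blockwise punishment risk (P(shock|action) = 0, 0.06, 0.1 over three
50-trial blocks). This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generator does and does not emulate, and the package's known limitations.

## Session data and conventions

Timestamps are seconds from session start as doubles, 0-based; all
intervals are half-open `[start, end)`. Sessions live in a directory of
plain-text files (`trials.tsv`, `spikes.tsv`, `lfp.tsv`, `session.json`)
read and written losslessly at full double precision; per-channel sampling
rate and origin travel in the JSON sidecar. Validation is strict by
default — event order, the derived response-time column, shock flags
confined to risky blocks, sorted spike times, positive waveform widths,
and a ≥ 250 Hz LFP rate (the analysis ceiling is 125 Hz) — because silent
coordinate bugs dominate the failure modes of this analysis class. An
opt-out exists for deliberately malformed inputs.

Trials on which a shock was delivered (3 and 5 in blocks 2 and 3 at the
default contingencies) are excluded from every neural analysis; the
electrical artifact makes them unusable. `exclude_shock_trials()` is the
single chokepoint for this rule.

The baseline epoch is always the 2 s window beginning 2.5 s before cue
onset; peri-event epochs span −2 to 2 s around cue, action, or reward.

## Single-unit encoding (ωPEV)

Spike counts are formed in a 200 ms window moving in 50 ms steps over the
−1..1 s peri-event epoch. For each bin, the one-way layout across blocks
yields the bias-corrected effect size

ωPEV = (SS_blocks − df_blocks · MS_error) / (SS_total + MS_error),

which has expectation zero when block means are equal, reaches 1 when
within-block variance vanishes while means differ, and is defined as 0 in
the fully degenerate case SS_total + MS_error = 0 (all counts identical).

Significance comes from 1,000 trial-label shuffles: labels are permuted
jointly for all bins of a trial, preserving within-trial temporal
correlation, and the full ωPEV trace is recomputed per shuffle. Starting
at the surrogate distribution's mean and stepping upward by one-hundredth
of its standard deviation, the pointwise band at a bin is the lowest level
exceeded by strictly fewer than α (default 0.01) of the surrogates at
that bin; the global band is the lowest level such that strictly fewer
than α of the surrogate *traces* exceed it in any bin, which controls the
family-wise error across time bins. The search terminates at
max(surrogate) + SD if the criterion is never met (bounded, conservative).
A unit is an encoder iff its trace crosses the global band; a fine-grid
variant (50 ms window, 5 ms step) resolves crossing times. Bands are built
per unit, with a reproducible RNG substream keyed by unit id.

Response direction is the standardized regression coefficient
β·(Sx/Sy) of counts on the block index (1, 2, 3) — the Pearson
correlation in this simple regression — pooled over a peri-event
sub-epoch, default (−0.5, 0.5) s (the sub-epoch boundaries are
configurable; no authoritative values exist for them). Baseline
(inter-trial interval) modulation is tested with a Kruskal–Wallis test at
α = 0.05 (the choice of test is ours; only "significant modulation" is
specified by the analysis design), with direction from the block-index
SRC on baseline counts. Firing-rate/behavior coupling is the Pearson
correlation of per-trial peri-action counts with log response time — the
log transform keeps the heavy-tailed RT distribution from dominating.

## VTA cell classification

Two criteria. First, electrophysiology: baseline rate strictly below
12 Hz and waveform width strictly above 1.2 ms. Second, reward-response
shape: for each unit, the auROC (Mann–Whitney identity, ties 0.5) of
across-trial firing rates in fifteen 100 ms bins spanning −0.5..1 s
around reward against the across-trial baseline rates; profiles are
column-mean-centered (standard PCA — the centering is our choice),
decomposed by SVD, mapped to the top-3 PC space, and clustered with a
2-component Gaussian mixture. The cluster whose mean profile has the
larger mean auROC within 0–300 ms post-reward is `Type1` (phasic
excitation to reward, the dopamine signature); anchoring by this criterion
makes the labels invariant to mixture-component indexing. A unit is
putative DA iff it satisfies both criteria.

Two numerical choices matter at realistic unit counts. The mixture's
covariance structure is chosen by BIC over a ladder (spherical, variable
spherical, shared full, unconstrained full): an unconstrained full
covariance alone is under-determined in 3-D with a few dozen units and
demonstrably falls into poor local optima. And EM is run both from
mclust's model-based hierarchical initialization and from k-means-seeded
restarts (20 starts), keeping the solution with the best BIC. With three
response families in the data (phasic, sustained-excited, suppressed) and
two components, either split of the non-phasic families still yields
correct DA labels because the electrophysiological criterion filters the
non-DA members of the phasic-anchored cluster. Classification is meant to
run on units pooled across sessions (on the order of 50–100 units); a
single session's ~13 VTA units under-determine any mixture.

mPFC units are never classified; units above 20 Hz baseline are flagged
as metadata only.

## Population trajectories (GPFA)

Square-rooted spike counts in 20 ms bins over the −0.5..0.5 s peri-action
window (the window is standard for this task; the GPFA bin width is our
choice) are modeled as y_t | x_t ~ N(Cx_t + d, R) with diagonal R and
independent GP priors per latent, squared-exponential kernel with unit
prior variance (for identifiability), timescales initialized at 100 ms,
and an innovation floor of 1e−3 on the kernel diagonal. EM runs to a
relative log-likelihood tolerance of 1e−8 or 200 iterations; the E-step is
the closed-form joint-Gaussian posterior over all latents and bins
(computed via the posterior precision, one Cholesky per iteration shared
across trials), the M-step updates C, d, R in closed form (R floored at
1e−6) and each timescale by 1-D numerical maximization of its expected
complete-data term over [bin/2, 2] s. The log-likelihood is evaluated
through the same determinant/Woodbury identities and is verified against a
direct dense evaluation in the tests; it is monotone over EM iterations.

Dimensionality is selected by cross-validated held-out likelihood
(4 folds over trials, seeded) with the 1-SE plateau rule: the smallest
candidate within one standard error of the maximum ("peaked or
plateaued" needs a concrete rule; this is ours). For cross-population
comparability a fixed default of p = 5 is used by
`population_trajectories()`, with per-run override.

Loadings are orthonormalized by SVD (C = UΣVᵀ; basis U, latents ΣVᵀx),
which preserves the reconstruction exactly and gives the latent space
Euclidean ("PCA-like") geometry. Each trial's neural deviation is the
mean over time bins of the Euclidean distance to the block-1 mean
trajectory, computed in the full orthonormalized space (not just the
3 visualization dimensions; both the bin-mean and the full-space choices
are configurable because either could be defended). Behavioral deviation
is log RT minus the block-1 mean log RT; Pearson correlations are
reported pooled and per block.

## Field spectra and directed coupling

Slepian (DPSS) tapers are computed from the standard symmetric
tridiagonal eigenproblem and cached; with a 500 ms window and nine tapers
the time-bandwidth product is NW = 5, i.e. a ±10 Hz concentration band.
A consequence worth remembering: a pure tone appears as a ≈20 Hz-wide
plateau, so narrowband structure should be read at band level, not bin
level. Spectrograms average taper power over nine tapers in 500 ms
windows stepping 50 ms, zero-padded to a 1 Hz grid, scaled as a one-sided
density (band-integrated power matches signal variance); per-trial
window-averaged power is retained so baseline normalization can z-score
each frequency by the across-trial baseline mean and SD. Coherence pools
cross- and auto-spectra over tapers and trials per window
(|S_xy|²/(S_x S_y) ∈ [0, 1]); its small-sample bias floor is
≈ 1/(tapers × trials).

Granger causality uses a bivariate VAR on demeaned, per-segment linearly
detrended peri-action segments, decimated to 200 Hz behind an anti-alias
filter (theta is the focus; the decimation keeps AIC orders manageable),
least-squares fit pooled across trial segments, order by AIC over 1..20.
The spectral measure in the 1→2 direction is

I₁→₂(f) = −ln(1 − (Σ₁₁ − Σ₁₂²/Σ₂₂)|H₂₁(f)|² / S₂₂(f)),

with H(f) the inverse Fourier-transformed coefficient matrix and
S = HΣH*. Its band integral over (0, Nyquist) equals the time-domain
Granger measure, which the tests verify against the closed form ln 1.25
for a unit-noise lag-one coupling of weight 0.5. Confidence bounds come
from permuting whole trial segments of one channel against the other
(preserving autocorrelation, destroying cross-channel timing), refitting
at the observed order, and taking the per-frequency 1−α quantile
(α = 0.001, 1,000 permutations by default). Frequencies where the VAR
characteristic matrix is numerically singular are flagged and excluded.

## Spike–field phase locking

The LFP is bandpass filtered to 5–15 Hz with a 4th-order Butterworth
applied forward–backward (zero phase, reflection-padded edges) and the
instantaneous phase taken from the analytic signal; phase 0 sits at the
oscillation peak (cosine convention — preferred-phase values depend on
it). Each peri-action spike receives the phase at spike time + lag,
interpolated between samples on the unit circle (at 1 kHz the difference
from nearest-sample phase is negligible, but the convention is fixed).
Because the mean resultant length is biased by spike count, the
phase-locking value is the MRL averaged over 1,000 draws of 100 spikes
without replacement; units with ≤ 100 peri-action spikes in any block are
excluded outright rather than computed on fewer spikes. Rayleigh
significance uses z = nR² with
p = exp(√(1 + 4n + 4(n² − n²R²)) − (1 + 2n)).

The time-lagged profile recomputes the PLV at lags −100..100 ms in 4 ms
steps. The spike set is fixed across lags by selecting spikes from a
window shrunk by the largest |lag|: if spikes were instead dropped per
lag at the window edges, removing unlocked edge spikes would inflate the
MRL with |lag| and bias the peak outward — a subtle artifact found and
eliminated during development. Peak-lag ties break toward zero and then
toward the negative lag, conservative with respect to directionality
claims. Blockwise comparisons use paired Wilcoxon signed-rank tests
across units plus per-block proportions of Rayleigh-significant units.

## The synthetic generator

`generate_session()` emulates the statistical structure the analyses
assume; its defaults are the study conditions.

* **Task**: 3 blocks × 50 trials; contingencies (0, 0.06, 0.1) realized
  as round(contingency × trials) = 0/3/5 pseudo-randomly placed shock
  trials; cue → action → reward chains with 6–8 s inter-trial intervals
  and 20 s block timeouts.
* **Behavior**: per-block lognormal response times (meanlog
  log 0.8 / log 1.4 / log 2.2, sdlog 0.25/0.35/0.45) so both the mean and
  the trial-to-trial variance rise with risk, as the task produces;
  retrieval latency is block-independent.
* **Spikes**: inhomogeneous Poisson by thinning; rate = baseline ×
  per-block baseline offset + per-event Gaussian bumps (block-gain
  scaled) × a shared per-trial latent modulation. The default roster has
  16 mPFC units (up- and down-gain encoders, baseline-modulated units),
  7 DA-like VTA units (slow, broad waveforms, sharp phasic bumps,
  strong phase coupling declining over blocks), and 6 non-DA-like units
  (faster, narrow, sustained excited or suppressed reward responses).
  Encoder effect sizes are set for mid-power detection — detection should
  be non-trivial, not saturated; no authoritative effect sizes exist.
* **LFP**: 1 kHz (a decision; only the 125 Hz low-pass is given),
  spectrally shaped 1/f-amplitude noise plus an action-locked theta burst
  (1 s Hann envelope; session frequency uniform in 6–10 Hz with 2 Hz
  per-trial jitter; block amplitude multipliers 1/0.65/0.35). The mPFC
  trace embeds a 20 ms-delayed, 0.8-gain copy of the VTA theta component:
  the VTA→mPFC direction Granger causality should recover.
* **Phase coupling**: spikes are thinned against a von Mises density of
  the burst phase evaluated 20 ms before the spike (the oscillation
  leads), normalized by its Bessel mean so the coupling is
  rate-preserving — without that normalization, block-declining coupling
  concentration would masquerade as a block rate effect. Per-trial
  frequency jitter matters here too: with a fixed burst frequency the
  lagged PLV profile is periodic in the lag and the true peak is not
  identifiable against its one-cycle aliases.
* **Latent↔RT link**: one half-normal scalar per trial multiplies the
  population's event-response amplitude and adds to log RT, making the
  trajectory-deviation/RT correlation recoverable by construction and
  switchable off. `no_shock_config()` turns off every block effect at
  once, reproducing the no-shock control condition under which every
  blockwise detection is a false positive.

All randomness flows from one session seed; per-unit and per-stage
substreams are derived by hashing stable keys, so stages can be re-run
independently and reruns are byte-identical.

What the generator does **not** emulate: biophysical waveforms,
refractoriness, conduction delays, non-Poisson spiking statistics,
nonstationary drift, volume conduction, or common-reference artifacts.
Passing recovery tests therefore demonstrates that the estimators detect
the statistical structures they target at realistic effect sizes — not
that they are robust to every pathology of real recordings.

## Known limitations

* With block-varying phase-coupling concentration and event bumps sharper
  than a theta cycle, trial exchangeability is mildly violated: the
  across-trial count variance differs by block even when means match, and
  flat-gain units occasionally cross the shuffle band. This mirrors a
  genuine property of permutation tests under heteroscedasticity, and it
  is why the encoder-recovery study condition uses block-constant
  coupling.
* The GMM cell classification is only as good as the unit count;
  below ~20 units any 2-component mixture in 3-D PC space is fragile
  regardless of initialization.
* GPFA timescale estimates are weakly identified when a latent's loading
  norm is small; the subspace (principal angles) is the robust quantity.
* The permutation GC bound refits at the observed AIC order for speed;
  order re-selection per permutation would be slightly more conservative.

## Problem sizes

The shipped tests and the calibration script run at desk scale, chosen to
make every Monte-Carlo check statistically meaningful: 150-trial sessions
with 29 units; 200 null units for the ωPEV centering check; 1,000
surrogates and 1,000 null traces for the family-wise band calibration;
1,000 × 100 resampling for PLV; 100-trial, 12-unit simulations for GPFA
recovery with 3-fold cross-validation over candidates 1–3; 30–50 k sample
VAR simulations for the Granger oracles.
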