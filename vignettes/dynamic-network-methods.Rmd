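---
title: "Methods: dynamic oscillatory network models and their task responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic oscillatory network models and their task responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what the test
suite does and does not establish.

## The problem

Brain activity recorded with M/EEG and projected to source space arrives
as parcel time courses: one signal per region of interest. Oscillatory
activity in these signals is transient — it comes in bursts — and it is
coordinated across parcels into functional networks that form and
dissolve on sub-second timescales. Two questions drive the package: how
to identify such dynamic networks without reference to a task, and how to
measure their task-locked responses with valid group statistics.

## Simulated study conditions

The synthetic-data generator (`simulate_parcels()`) produces the
conditions under which everything else is tested, with full ground truth.
Its defaults are the study conditions and are not tuning knobs:

- 38 parcels, 25600 samples at 250 Hz;
- two networks: a "visual" network of six parcels oscillating at 10 Hz
  and a "motor" network of four parcels at 20 Hz;
- each network's on/off burst time course is an independent two-state
  Markov chain with self-transition probability 0.95 in both states, so
  dwell times are Geometric(0.05) with mean 20 samples (80 ms) and the
  stationary occupancy of the on state is 1/2;
- during a burst each member parcel carries `A sin(2 pi f t + phi) + eps`
  with `eps ~ N(0, 0.2)`; off bursts and on non-member parcels only the
  noise remains;
- burst amplitudes alternate A = 1 (low) and A = 2 (high) within each
  network;
- the phase `phi ~ Uniform(0, 2 pi)` is drawn independently per parcel
  and per burst. The generating description calls only for random
  inter-regional phase lags and does not fix a refresh policy; per-burst,
  per-parcel draws guarantee those lags and non-degenerate coherence, and
  we verified the choice barely moves the embedded-PCA variance profile
  (a fraction of a percentage point);
- amplitude alternation starts at the low amplitude, and the initial
  Markov state is drawn from the stationary distribution, both fixed for
  determinism;
- finally, symmetric orthogonalisation removes zero-lag correlations, as
  applied to real parcel time courses to correct source leakage.

`symmetric_orthogonalise()` finds the closest matrix with mutually
orthogonal columns by alternating the polar-factor (orthogonal
Procrustes) projection with optimal per-column rescaling, stopping when
the relative change in reconstruction error falls below 1e-8 (cap 50
iterations; the method converges in a handful). Columns are mean-centred
first: the output columns are then exact linear combinations of zero-mean
columns, so their pairwise Pearson correlations vanish identically rather
than to O(1/n). Output columns are rescaled to the centred input's norms.

What the simulation does *not* emulate about real data: 1/f background
spectra, measurement noise correlated across parcels, non-sinusoidal
waveforms, inter-subject variability, and volume-conduction structure
beyond zero-lag leakage. Tests passing under these conditions show the
inference machinery is correct, not that real-data conclusions are
automatic.

## Preparation: time-delay embedding and PCA

`time_delay_embed()` augments each parcel with lagged copies at lags
-L..+L (parcel-major ordering, fixed so stored PCA loadings remain
interpretable). The covariance of the embedded data then contains the
auto- and cross-correlation functions out to lag 2L, which is what lets
zero-mean Gaussian observation models express spectra and
frequency-specific phase coupling. Edges are trimmed, not zero-padded, to
avoid spurious boundary covariance; `align_time_course()` pads model time
courses back to the original clock (replicating edge values) before
epoching or spectral weighting.

For the simulation we use L = 2 (190 embedded channels) and 120 PCA
components; for real 250 Hz source data L = 7 with around 80 components
(roughly 70% explained variance) is the recommended operating point.
Standardisation is the final step before model training. On the
simulated conditions the 120 leading components explain about 81–82% of
variance (reported by `prepare()` and recomputed by the acceptance
script); the figure of merit usually quoted for this configuration is
"approximately 85%", and the gap is stable across seeds and robust to
the phase-refresh policy and to skipping orthogonalisation, so we report
our measured value rather than adjust the generator toward the quoted
one.

## TDE-HMM

`tde_hmm()` fits a hidden Markov model whose states are zero-mean
multivariate Gaussians, each with its own covariance — on TDE-PCA data a
state covariance *is* a frequency-resolved network. Exactly one state is
active per sample, and inference is exact expectation-maximisation
(scaled forward–backward messages, compiled), which is deterministic
given the initialisation and lets the tests assert per-epoch monotonicity
of the objective within 1e-8. Covariances are regularised by
`1e-6 * mean(diag) * I`. Initialisation draws flat-Dirichlet
responsibilities; `n_init = 10` seeded restarts run a few EM iterations
each, the restart with the lowest negative log-likelihood continues to
convergence (relative change < 1e-6, cap 100 epochs). Running only the
selection phase briefly, rather than ten full fits, is the standard
practice in HMM software for this model class and changes nothing about
which solution is kept in our tests.

Three states are the default for the simulation (visual, motor,
background); six are typical for real data. The Viterbi path
(`viterbi_decode()`, `predict()`) provides the binarised state time
course used for network responses; `fractional_occupancy()` summarises
it.

## Dynamic mode mixture (DyNeMo-style)

`dynemo()` drops mutual exclusivity: the instantaneous covariance is a
convex mixture `Sigma_t = sum_j alpha_jt D_j` with `alpha_t =
softmax(theta_t)`, so modes can overlap in time — the property that lets
co-activating bursts be separated into distinct networks instead of
being fragmented into combinatorial states.

The implementation is a compact amortised variational scheme written for
this package (no deep-learning framework is involved):

- *Generative side*: mode covariances `D_j` parameterised by Cholesky
  factors with log-diagonals (positive definiteness by construction); a
  single-layer tanh recurrent sequence model (width 64 by default) maps
  the previous latent `theta` to the mean of `p(theta_t | theta_<t)`,
  with learned global log-standard deviations.
- *Inference side*: a second single-layer tanh RNN runs over per-block
  log-variance features of the data and outputs the posterior means of
  `q(theta_t)`; `q` has learned global log-standard deviations. This is
  the smallest architecture that expresses history-dependent mixing and
  is fully seedable.
- *Objective*: one-sample reparameterised evidence lower bound
  (log-likelihood minus KL), Adam (lr 0.01), with the KL weight annealed
  linearly from 0 to 1 over the first half of training — the standard
  remedy for posterior collapse.
- *Temporal resolution*: logits are modelled on non-overlapping blocks of
  5 samples (20 ms at 250 Hz) and upsampled to sample resolution on
  output. A per-sample treatment costs a 120x120 Cholesky factorisation
  and inverse per sample per pass and would make the study pipeline take
  hours rather than minutes; 20 ms sits far below the mean burst duration
  (80 ms), and burst-timing conclusions are unaffected.
- *Model selection*: `n_init = 10` short seeded runs scored by full-data
  variational free energy; the best run trains to completion. The
  reported mode time course is the posterior mean logit passed through
  softmax (a maximum a posteriori estimate of the mixing coefficients).

`renormalise_alpha()` weights coefficients by the trace of the
corresponding mode covariance, expressing each mode's share of
instantaneous variance; `mode_state_overlap()` summarises how the
continuous decomposition maps onto HMM states.

## Frequency-resolved network descriptions

State spectra (`multitaper_state_spectra()`) cut the parcel data into
non-overlapping 2 s windows, compute DPSS-tapered cross-spectra
(bandwidth 4 Hz, hence 7 tapers), and average windows weighted by each
state's mean posterior probability in the window. Two seconds resolves
0.5 Hz at 250 Hz while leaving 51 windows on 25600 samples; states with
zero weight are flagged, never zero-filled.

Mode spectra (`glm_mode_spectra()`) regress the windowed multitaper
spectrogram, per parcel (pair) and frequency, on the window-averaged,
demeaned mixing coefficients plus an intercept; the mode-j spectrum is
its coefficient plus the intercept, a PSD-scaled quantity comparable to
state spectra. Because simplex rows sum to one, demeaned mode regressors
plus an intercept are exactly collinear; the documented behaviour is a
degeneracy warning and a minimum-norm (pseudo-inverse) solution, which
distributes the shared component evenly and leaves mode contrasts
untouched. Window means are used to downsample alpha because they
preserve mass.

Coherence follows the usual normalised cross-spectral magnitude. For HMM
maps the frequency band is selected by the first of two NNMF components
fitted to stacked coherence spectra (multiplicative updates, 10 seeded
restarts, components ordered by spectral centroid); mode maps average
the full 1–45 Hz range. Edge thresholding keeps the top 2% of edges by
absolute value with a deterministic lexicographic tie-break. Power maps
are shown relative to the across-entity mean, without thresholding.

## Task responses and statistics

Epoching covers `onset + round(tmin fs)` to `onset + round(tmax fs)`
(inclusive start, exclusive end; rounding half-away-from-zero, fixed for
reproducibility), dropping and counting out-of-bounds trials. The
network response is the trial-averaged state/mode time course minus its
mean over the 100 ms pre-stimulus baseline; it mixes evoked and induced
contributions by construction, which is a documented limitation of the
network approach. The conventional Morlet decomposition (4-cycle
wavelets, 6–30 Hz in 0.5 Hz steps, decimation 3, magnitudes not squared
power) separates them: full = trial-mean of per-trial magnitudes, evoked
= magnitude of the trial mean, induced = full - evoked. Baseline
correction is applied per frequency to full, evoked and induced
independently (correcting full before subtraction would differ only by a
shared offset; independent correction is recorded in the configuration).
`project_tf()` multiplies a network response by the entities' PSDs to
show the oscillatory content a fitted dynamic model implies.

Group inference uses a permutation GLM with max-|COPE| familywise-error
control, the maximum taken jointly over time, entities and frequencies.
One-sample designs are permuted by sign-flipping (valid under a
symmetric null; group tests here are one-sample on subject responses or
contrasts); multi-regressor designs permute design rows. Testing is
two-tailed because both activations and deactivations are of interest;
p-values use the add-one rule with the identity permutation always
included; 1000 permutations and alpha = 0.05 are the defaults.

## Problem sizes used by the tests

The test suite fits the full study conditions once (38 parcels, 25600
samples; DyNeMo best-of-10 plus HMM) and reuses the fits across
acceptance checks; unit tests run on smaller simulations (6000–20000
samples, 4–12 channels). The familywise-error calibration uses 200
replicates of 20 subjects x 50 time points x 6 entities with 1000
sign-flip permutations, computed by a single matrix product per
replicate. The statistical power check plants a 2-SD mean shift in one
element and requires detection in over 90% of replicates.

## Known limitations

- The mode-mixture optimiser is stochastic minibatch inference: the free
  energy trend is monotone only on average, and different seeds can find
  mode permutations (handled by `match_networks()`).
- Real-data preprocessing (filtering, beamforming, parcellation, sign
  flipping) is out of scope; the pipeline starts at parcel time series.
- The simulation's noise is white and spatially independent; spectra on
  real data have 1/f backgrounds that the NNMF band selection is designed
  to handle but the tests do not exercise.
- Network responses cannot distinguish evoked from induced oscillatory
  activity; use the Morlet decomposition when that distinction matters.
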