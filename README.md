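# burstnet

Dynamic oscillatory network analysis of electrophysiological data in R.

Source-space M/EEG recordings contain transient, frequency-specific
functional networks — bursts of oscillatory activity coordinated across
brain parcels — that conventional single-channel time-frequency analysis
cannot see as networks. `burstnet` implements the full analysis chain for
identifying these dynamic networks and measuring their task responses:

- **Simulation** of bursting oscillatory network data with known ground
  truth: two-state Markov burst dynamics, sinusoidal network activity with
  random inter-regional phase lags, alternating burst amplitudes, and
  symmetric orthogonalisation (leakage correction).
- **Preparation**: time-delay embedding (TDE), which encodes spectra and
  cross-correlation structure into the covariance of the augmented data,
  followed by PCA and standardisation.
- **TDE-HMM** (`tde_hmm()`): a hidden Markov model with zero-mean
  multivariate-Gaussian states, `x_t | s_t = k ~ N(0, C_k)`, fitted by
  exact Baum–Welch EM. States are mutually exclusive networks; the model
  yields posterior probabilities, the Viterbi path, fractional occupancies
  and state covariances.
- **DyNeMo-style mode mixture** (`dynemo()`): a dynamic mixture of mode
  covariances, `x_t ~ N(0, Σ_j α_jt D_j)` with `α_t = softmax(θ_t)` on the
  probability simplex and a learned recurrent sequence model over the
  logits, trained by amortised variational inference. Modes can overlap in
  time, so co-activating networks are separated rather than fragmented.
- **Post-hoc spectra**: multitaper state spectra, GLM mode spectra,
  coherence `C_xy(f) = |P_xy(f)| / sqrt(P_xx(f) P_yy(f))`, power maps,
  NNMF frequency-band selection, and top-2% edge thresholding.
- **Task analysis**: BIDS-style event tables, epoching, trial-averaged
  baseline-corrected network responses, conventional Morlet
  full/evoked/induced TF decomposition, and model-projected TF responses
  `TF(t, f) = Σ_k response_k(t) · PSD_k(f)`.
- **Statistics**: non-parametric permutation GLM with maximum-COPE
  familywise-error control (sign-flipping for one-sample designs).

## Worked example

The package's own simulation study: 38 parcels at 250 Hz with a 10 Hz
"visual" network (parcels 1–6) and a 20 Hz "motor" network (parcels 7–10)
bursting independently.

```r
library(burstnet)

sim <- simulate_parcels(sim_config(seed = 1))
print(sim)
#> Simulated parcel data: 25600 samples x 38 parcels @ 250 Hz
#>   network 'visual': 6 parcels, 10 Hz
#>   network 'motor': 4 parcels, 20 Hz
#>   burst occupancy: visual=0.510, motor=0.527

pd  <- prepare(sim, n_lags = 2, n_components = 120)
print(pd)
#> Prepared data: 25596 samples x 120 components (trim 2 each edge)
#>   cumulative explained variance: 81.7%; standardised

fit <- dynemo(pd, n_modes = 3, seed = 2)        # ~3-4 min on one core
alpha <- align_time_course(fit$alpha, fit$trim, nrow(sim$x))
sp  <- glm_mode_spectra(sim$x, alpha, fs = sim$fs)
maps <- power_map(sp)
m   <- match_networks(maps, list(visual = 1:6, motor = 7:10))

# matched modes recover the simulated networks:
sort(order(maps[m[1], ], decreasing = TRUE)[1:6])   # 1 2 3 4 5 6
sort(order(maps[m[2], ], decreasing = TRUE)[1:4])   # 7 8 9 10
```

The matched modes' spectra peak at the simulated frequencies (9.5 and
20.0 Hz with these seeds, at 0.5 Hz spectral resolution), and the visual
mode's mixing coefficient is substantially larger
during high-amplitude bursts than low-amplitude ones (about 0.40 vs 0.13
with the seeds above) — the model reads burst amplitude directly off the
mixing coefficients.

The same pipeline runs through a single configuration-driven call that
writes a text container with every product and its provenance:

```r
res <- run_pipeline(list(
  seed = 1,
  simulate = list(),                       # defaults = the study conditions
  prep     = list(n_lags = 2, n_components = 120),
  dynemo   = list(n_modes = 3),
  spectra  = list(),
  respond  = list(model = "dynemo"),       # epochs on simulated burst onsets
  test     = list(n_perm = 1000)
), out = "analysis")
```

An equivalent HMM analysis (`hmm = list(n_states = 3)`) shows the
instructive contrast: HMM states mix the two networks (mutual exclusivity
cannot represent co-activation), yet its model-projected TF response still
concentrates power at the right frequencies after each burst type.

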