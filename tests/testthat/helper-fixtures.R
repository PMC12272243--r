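# Lazily computed, cached fixtures shared across test files. Heavy objects
# (the full simulation-study pipeline) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small simulation for unit tests (shorter recording, fewer parcels)
small_sim <- function() fixture("small_sim", function() {
  simulate_parcels(sim_config(
    n_parcels = 12, n_samples = 6000,
    networks = list(network_spec("visual", 1:3, freq = 10),
                    network_spec("motor", 4:5, freq = 20)),
    seed = 42))
})

# full study-conditions simulation (38 parcels, 25600 samples)
study_sim <- function() fixture("study_sim", function() {
  simulate_parcels(sim_config(seed = 1))
})

study_prep <- function() fixture("study_prep", function() {
  prepare(study_sim(), n_lags = 2, n_components = 120)
})

# full DyNeMo fit on the study simulation plus derived spectra and matching
study_dynemo <- function() fixture("study_dynemo", function() {
  sim <- study_sim()
  fit <- dynemo(study_prep(), n_modes = 3, seed = 2)
  alpha <- align_time_course(fit$alpha, fit$trim, nrow(sim$x))
  spectra <- suppressWarnings(
    glm_mode_spectra(sim$x, alpha, fs = sim$fs, want_csd = FALSE))
  maps <- power_map(spectra)
  match <- match_networks(maps, list(visual = 1:6, motor = 7:10))
  list(fit = fit, alpha = alpha, spectra = spectra, maps = maps,
       match = match)
})

# full HMM fit on the study simulation plus multitaper spectra
study_hmm <- function() fixture("study_hmm", function() {
  sim <- study_sim()
  fit <- tde_hmm(study_prep(), n_states = 3, seed = 2)
  gamma <- align_time_course(fit$gamma, fit$trim, nrow(sim$x))
  spectra <- multitaper_state_spectra(sim$x, gamma, fs = sim$fs,
                                      want_csd = FALSE)
  viterbi <- align_time_course(fit$viterbi, fit$trim, nrow(sim$x))
  list(fit = fit, gamma = gamma, viterbi = viterbi, spectra = spectra)
})

# parcel-averaged PSD of one entity as a vector
entity_psd <- function(spectra, k) {
  m <- spectra$psd[k, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colMeans(m)
}
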