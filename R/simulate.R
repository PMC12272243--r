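#' Describe one simulated oscillatory network
#'
#' A network is a set of parcels that share bursts of sinusoidal activity at
#' a single frequency. Burst amplitudes alternate between `amp_low` and
#' `amp_high` across successive bursts of the network.
#'
#' @param name Network label.
#' @param parcels Integer vector of 1-based parcel indices belonging to the
#'   network.
#' @param freq Oscillation frequency in Hz.
#' @param amp_low,amp_high Amplitudes (unitless) of alternating low/high
#'   bursts.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(name, parcels, freq, amp_low = 1, amp_high = 2) {
  parcels <- as.integer(parcels)
  if (length(parcels) == 0L) stopf("network '%s': parcels must be non-empty", name)
  if (anyDuplicated(parcels)) stopf("network '%s': duplicate parcel indices", name)
  if (any(parcels < 1L)) stopf("network '%s': parcel indices are 1-based", name)
  if (freq <= 0) stopf("network '%s': freq must be positive", name)
  if (amp_low > amp_high) stopf("network '%s': amp_low must be <= amp_high", name)
  structure(list(name = name, parcels = parcels, freq = freq,
                 amp_low = amp_low, amp_high = amp_high),
            class = "network_spec")
}

#' Configuration of the bursting-network simulation
#'
#' Defaults reproduce the study conditions: 38 parcels, 25600 samples at
#' 250 Hz, Gaussian noise variance 0.2, two-state Markov bursts with
#' self-transition probability 0.95, a 10 Hz occipital network on six
#' parcels and a 20 Hz motor network on four parcels, with burst amplitudes
#' alternating between 1 and 2.
#'
#' @param n_parcels Number of parcels.
#' @param n_samples Number of time samples.
#' @param fs Sampling frequency in Hz.
#' @param noise_var Variance of the additive Gaussian noise.
#' @param stay_prob Self-transition probability of the symmetric two-state
#'   burst Markov chain.
#' @param networks List of [network_spec()] objects. `NULL` gives the
#'   default visual (parcels 1-6, 10 Hz) and motor (parcels 7-10, 20 Hz)
#'   networks.
#' @param allow_overlap Allow networks to share parcels (off by default).
#' @param seed RNG seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_parcels = 38, n_samples = 25600, fs = 250,
                       noise_var = 0.2, stay_prob = 0.95, networks = NULL,
                       allow_overlap = FALSE, seed = NULL) {
  if (is.null(networks)) {
    networks <- list(
      network_spec("visual", 1:6, freq = 10),
      network_spec("motor", 7:10, freq = 20)
    )
  }
  if (stay_prob <= 0 || stay_prob >= 1) stopf("stay_prob must be in (0, 1)")
  if (noise_var <= 0) stopf("noise_var must be positive")
  for (nw in networks) {
    if (!inherits(nw, "network_spec")) stopf("networks must be network_spec objects")
    if (any(nw$parcels > n_parcels))
      stopf("network '%s': parcel index exceeds n_parcels = %d", nw$name, n_parcels)
    if (nw$freq >= fs / 2)
      stopf("network '%s': freq %g Hz is not below Nyquist (%g Hz)", nw$name, nw$freq, fs / 2)
  }
  all_parcels <- unlist(lapply(networks, `[[`, "parcels"))
  if (!allow_overlap && anyDuplicated(all_parcels))
    stopf("networks share parcels; set allow_overlap = TRUE to permit this")
  structure(list(n_parcels = as.integer(n_parcels),
                 n_samples = as.integer(n_samples), fs = fs,
                 noise_var = noise_var, stay_prob = stay_prob,
                 networks = networks, allow_overlap = allow_overlap,
                 seed = seed),
            class = "sim_config")
}

#' Sample a binary burst time course from a symmetric two-state Markov chain
#'
#' The chain has self-transition probability `stay_prob` in both the on and
#' off state, so dwell times are Geometric(1 - stay_prob) with mean
#' 1 / (1 - stay_prob) samples, and the stationary occupancy of each state
#' is 1/2. The initial state is drawn from the stationary distribution.
#'
#' @param stay_prob Self-transition probability, in (0, 1].
#' @param n_samples Length of the time course.
#' @param seed Optional RNG seed.
#' @return Integer vector of 0 (off) / 1 (on) of length `n_samples`.
#' @export
sample_burst_time_course <- function(stay_prob, n_samples, seed = NULL) {
  if (!is.numeric(stay_prob) || stay_prob <= 0 || stay_prob > 1)
    stopf("stay_prob must be a probability in (0, 1]")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  with_seed(seed, {
    # state flips whenever a uniform draw exceeds stay_prob
    flips <- runif(n_samples - 1L) > stay_prob
    s0 <- rbinom(1L, 1L, 0.5)
    as.integer((s0 + c(0L, cumsum(flips))) %% 2L)
  })
}

# runs of consecutive 1s: data.frame(start, end) with inclusive 1-based bounds
burst_intervals <- function(on) {
  r <- rle(as.integer(on))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Simulate bursting oscillatory network data in parcel space
#'
#' Each network's burst on/off time course is sampled independently from the
#' two-state Markov chain. During a burst every member parcel carries
#' `A * sin(2*pi*f*t + phi) + eps`, with a phase `phi ~ Uniform(0, 2*pi)`
#' drawn independently per parcel and per burst (random inter-regional phase
#' lags), and `eps ~ N(0, noise_var)`. Burst amplitudes alternate
#' low, high, low, ... within each network. Outside bursts, and on parcels
#' belonging to no network, only the noise is present. Finally, symmetric
#' orthogonalisation removes zero-lag correlations between parcels.
#'
#' @param config A [sim_config()].
#' @return An object of class `parcel_sim` with elements:
#'   \describe{
#'     \item{x}{numeric matrix, time x parcels (orthogonalised).}
#'     \item{fs}{sampling frequency (Hz).}
#'     \item{parcel_names}{character labels.}
#'     \item{ground_truth}{list with `on` (time x networks binary matrix),
#'       `bursts` (data.frame: network, start, end, amp_label, amplitude)
#'       and `phases` (list of per-burst phase matrices).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_parcels <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_parcels
    nets <- config$networks
    x <- matrix(rnorm(n * p, sd = sqrt(config$noise_var)), n, p)
    on <- matrix(0L, n, length(nets),
                 dimnames = list(NULL, vapply(nets, `[[`, "", "name")))
    bursts <- list()
    phases <- list()
    tt <- (seq_len(n) - 1L) / config$fs
    for (j in seq_along(nets)) {
      nw <- nets[[j]]
      on[, j] <- sample_burst_time_course(config$stay_prob, n)
      iv <- burst_intervals(on[, j])
      if (nrow(iv) == 0L) next
      amps <- rep(c(nw$amp_low, nw$amp_high), length.out = nrow(iv))
      lab <- rep(c("low", "high"), length.out = nrow(iv))
      ph <- matrix(runif(nrow(iv) * length(nw$parcels), 0, 2 * pi),
                   nrow(iv), length(nw$parcels))
      for (b in seq_len(nrow(iv))) {
        idx <- iv$start[b]:iv$end[b]
        for (q in seq_along(nw$parcels)) {
          x[idx, nw$parcels[q]] <- x[idx, nw$parcels[q]] +
            amps[b] * sin(2 * pi * nw$freq * tt[idx] + ph[b, q])
        }
      }
      bursts[[j]] <- data.frame(network = nw$name, start = iv$start,
                                end = iv$end, amp_label = lab,
                                amplitude = amps)
      phases[[nw$name]] <- ph
    }
    x <- symmetric_orthogonalise(x)
    structure(list(
      x = x, fs = config$fs,
      parcel_names = sprintf("parcel_%02d", seq_len(p)),
      ground_truth = list(on = on,
                          bursts = do.call(rbind, bursts),
                          phases = phases),
      config = config), class = "parcel_sim")
  })
}

#' @export
print.parcel_sim <- function(x, ...) {
  cat(sprintf("Simulated parcel data: %d samples x %d parcels @ %g Hz\n",
              nrow(x$x), ncol(x$x), x$fs))
  for (nw in x$config$networks)
    cat(sprintf("  network '%s': %d parcels, %g Hz\n",
                nw$name, length(nw$parcels), nw$freq))
  occ <- colMeans(x$ground_truth$on)
  cat("  burst occupancy:", paste(sprintf("%s=%.3f", names(occ), occ),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Symmetric orthogonalisation (leakage correction)
#'
#' Finds the closest matrix (in the least-squares sense) whose columns are
#' mutually orthogonal, by alternating the orthogonal Procrustes (polar
#' factor) projection with optimal per-column rescaling, then scaling the
#' result back to the original column norms. Columns are mean-centred
#' first, so the returned columns have exactly zero pairwise Pearson
#' correlation. This is the standard leakage-correction step for
#' source-space M/EEG parcel time courses.
#'
#' @param x Numeric matrix, time x parcels, with more rows than columns and
#'   full column rank.
#' @param tol Relative reconstruction-error change at which iteration stops.
#' @param max_iter Iteration cap.
#' @return Matrix of the same shape with mutually uncorrelated, zero-mean
#'   columns whose norms match those of the centred input.
#' @export
symmetric_orthogonalise <- function(x, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x)) stopf("need more time points than parcels")
  xc <- sweep(x, 2, colMeans(x))
  qrx <- qr(xc)
  if (qrx$rank < ncol(xc)) {
    bad <- sort(qrx$pivot[seq(qrx$rank + 1L, ncol(xc))])
    stopf("input is rank deficient; offending column(s): %s",
          paste(bad, collapse = ", "))
  }
  norms <- sqrt(colSums(xc^2))
  d <- norms
  err_prev <- Inf
  O <- NULL
  for (it in seq_len(max_iter)) {
    s <- svd(sweep(xc, 2, d, `*`))
    O <- s$u %*% t(s$v)              # orthonormal polar factor
    d <- colSums(O * xc)             # optimal per-column scale
    err <- sum((sweep(O, 2, d, `*`) - xc)^2)
    if (is.finite(err_prev) && abs(err_prev - err) <= tol * err) break
    err_prev <- err
  }
  out <- sweep(O, 2, norms, `*`)     # rescale to original (centred) norms
  dimnames(out) <- dimnames(x)
  out
}
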