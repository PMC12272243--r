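#' Read or build an event table
#'
#' Events follow the BIDS events.tsv dialect with sample indices instead
#' of seconds: a tab-separated file with header columns `onset_sample`
#' (0-based sample index), `duration` and `trial_type`.
#'
#' @param file Path to a tab-separated events file.
#' @return A data.frame of class `event_table`, sorted by onset.
#' @export
read_events <- function(file) {
  ev <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset_sample", "trial_type")
  if (!all(need %in% names(ev)))
    stopf("events file must have columns: %s", paste(need, collapse = ", "))
  if (is.null(ev$duration)) ev$duration <- 0
  event_table(ev$onset_sample, ev$trial_type, ev$duration)
}

#' @rdname read_events
#' @param onset_sample 0-based sample indices of event onsets.
#' @param trial_type Condition label per event.
#' @param duration Event durations in samples (kept for format fidelity).
#' @export
event_table <- function(onset_sample, trial_type = "event", duration = 0) {
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   duration = duration,
                   trial_type = as.character(trial_type))
  ev <- ev[order(ev$onset_sample), , drop = FALSE]
  if (any(ev$onset_sample < 0)) stopf("onsets must be non-negative (0-based)")
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write an event table to a BIDS-style TSV
#' @param events An `event_table`.
#' @param file Output path.
#' @export
write_events <- function(events, file) {
  write.table(as.data.frame(events), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Epoch a continuous time series around events
#'
#' Trial t covers samples `onset + round(tmin * fs)` to
#' `onset + round(tmax * fs)` (inclusive start, exclusive end; rounding is
#' half-away-from-zero). Trials whose window exceeds the recording are
#' dropped and counted.
#'
#' @param series Matrix (time x channels).
#' @param events An `event_table` (0-based onsets).
#' @param fs Sampling frequency in Hz.
#' @param tmin,tmax Epoch window in seconds relative to the event.
#' @return An object of class `epochs`: list with `data` (trials x time x
#'   channels), `times` (seconds relative to the event), `labels`
#'   (trial_type per trial), `fs`, `n_dropped`.
#' @export
epoch <- function(series, events, fs, tmin = -0.1, tmax = 1.0) {
  series <- as.matrix(series)
  n <- nrow(series)
  o0 <- round_hafz(tmin * fs)
  o1 <- round_hafz(tmax * fs)
  len <- o1 - o0
  if (len < 1) stopf("empty epoch window")
  # onsets are 0-based; R rows are 1-based
  start <- events$onset_sample + o0 + 1L
  ok <- start >= 1L & (start + len - 1L) <= n
  n_dropped <- sum(!ok)
  if (!any(ok)) stopf("no trials survive epoching")
  starts <- start[ok]
  dat <- array(0, c(length(starts), len, ncol(series)))
  for (i in seq_along(starts))
    dat[i, , ] <- series[starts[i]:(starts[i] + len - 1L), ]
  structure(list(data = dat,
                 times = (o0:(o1 - 1L)) / fs,
                 labels = events$trial_type[ok],
                 fs = fs, n_dropped = n_dropped),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("Epochs: %d trials x %d samples x %d channels (%.3f to %.3f s)%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times),
              if (x$n_dropped) sprintf("; %d trials dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Task-evoked network response
#'
#' The trial-averaged, baseline-corrected epoched state or mode time
#' course: for each entity the mean over trials, minus the mean over the
#' baseline window. Because each state/mode carries a specific pattern of
#' oscillatory network activity, this single time course summarises a set
#' of oscillatory responses across the network; note it mixes evoked
#' (phase-locked) and induced (non-phase-locked) contributions.
#'
#' @param epochs An `epochs` object built from a Viterbi path (HMM) or
#'   mixing coefficients (DyNeMo), after re-alignment with
#'   [align_time_course()].
#' @param baseline Window in seconds (two values) averaged and subtracted
#'   per entity.
#' @return Object of class `network_response`: list with `response`
#'   (time x entities), `times`, `baseline`, `n_trials`.
#' @export
network_response <- function(epochs, baseline = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "epochs"))
  bidx <- which(epochs$times >= baseline[1] & epochs$times < baseline[2])
  if (!length(bidx)) stopf("baseline window contains no samples")
  resp <- apply(epochs$data, c(2, 3), mean)
  base <- colMeans(resp[bidx, , drop = FALSE])
  resp <- sweep(resp, 2, base)
  structure(list(response = resp, times = epochs$times, baseline = baseline,
                 n_trials = dim(epochs$data)[1]),
            class = "network_response")
}

#' @export
print.network_response <- function(x, ...) {
  cat(sprintf("Network response: %d time points x %d entities (%d trials, baseline %g-%g s)\n",
              nrow(x$response), ncol(x$response), x$n_trials,
              x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' @export
plot.network_response <- function(x, ...) {
  graphics::matplot(x$times, x$response, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "response",
                    main = "Task-evoked network response", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# complex Morlet wavelet, amplitude-normalised; total length n_cycles / f
morlet_wavelet <- function(f, fs, n_cycles) {
  half <- round(n_cycles / f * fs / 2)
  t <- (-half:half) / fs
  sigma <- n_cycles / (2 * pi * f)
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  w / sum(abs(w))
}

# |wavelet transform| of one channel (vector) at several freqs; FFT conv
wavelet_power <- function(x, freqs, fs, n_cycles) {
  n <- length(x)
  out <- matrix(0, n, length(freqs))
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], fs, n_cycles)
    nw <- length(w)
    nfft <- stats::nextn(n + nw - 1, 2)
    conv <- fft(fft(c(x, rep(0, nfft - n))) *
                fft(c(w, rep(0, nfft - nw))), inverse = TRUE) / nfft
    centre <- (nw - 1) / 2
    out[, fi] <- Mod(conv[(1 + centre):(n + centre)])
  }
  out
}

#' Morlet time-frequency responses (full / evoked / induced)
#'
#' The full TF response is the trial average of per-trial wavelet-transform
#' magnitudes; the evoked (phase-locked) response is the magnitude of the
#' wavelet transform of the trial-averaged time series; the induced
#' (non-phase-locked) response is their difference. Magnitude, not squared
#' power, is used throughout. The time axis is decimated.
#'
#' @param epochs An `epochs` object.
#' @param freqs Frequency grid in Hz (default 6-30 Hz in 0.5 Hz steps).
#' @param n_cycles Wavelet length in cycles.
#' @param decim Temporal decimation factor.
#' @param channel Channel index to analyse.
#' @return Object of class `tf_response`: list with `full`, `evoked`,
#'   `induced` (time x freqs), `times`, `freqs`, `kind = "amplitude"`.
#' @export
morlet_tf <- function(epochs, freqs = seq(6, 30, by = 0.5), n_cycles = 4,
                      decim = 3, channel = 1) {
  stopifnot(inherits(epochs, "epochs"))
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stopf("frequencies must be below Nyquist (%g Hz)", fs / 2)
  nt <- dim(epochs$data)[2]
  longest <- max(round(n_cycles / min(freqs) * fs / 2) * 2 + 1)
  if (nt < longest)
    stopf("epoch length %d < longest wavelet %d samples", nt, longest)
  ntr <- dim(epochs$data)[1]
  full <- matrix(0, nt, length(freqs))
  for (tr in seq_len(ntr))
    full <- full + wavelet_power(epochs$data[tr, , channel], freqs, fs, n_cycles)
  full <- full / ntr
  avg <- apply(epochs$data[, , channel, drop = FALSE], 2, mean)
  evoked <- wavelet_power(avg, freqs, fs, n_cycles)
  keep <- seq(1, nt, by = decim)
  structure(list(full = full[keep, , drop = FALSE],
                 evoked = evoked[keep, , drop = FALSE],
                 induced = full[keep, , drop = FALSE] - evoked[keep, , drop = FALSE],
                 times = epochs$times[keep], freqs = freqs,
                 kind = "amplitude"),
            class = "tf_response")
}

#' @export
print.tf_response <- function(x, ...) {
  cat(sprintf("TF response (%s): %d time points x %d frequencies (%g-%g Hz)\n",
              x$kind, nrow(x$full), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
plot.tf_response <- function(x, component = c("full", "evoked", "induced"), ...) {
  component <- match.arg(component)
  graphics::image(x$times, x$freqs, x[[component]],
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = sprintf("%s TF response", component), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Baseline-correct a TF response
#'
#' Per frequency, and for the full, evoked and induced components
#' independently, subtracts the mean over the baseline window. Idempotent.
#'
#' @param tf A `tf_response`.
#' @param window Baseline window in seconds.
#' @return The corrected `tf_response`.
#' @export
baseline_correct_tf <- function(tf, window = c(-0.1, 0)) {
  stopifnot(inherits(tf, "tf_response"))
  bidx <- which(tf$times >= window[1] & tf$times < window[2])
  if (!length(bidx)) stopf("baseline window outside the epoch")
  for (comp in c("full", "evoked", "induced")) {
    m <- tf[[comp]]
    tf[[comp]] <- sweep(m, 2, colMeans(m[bidx, , drop = FALSE]))
  }
  tf$baseline <- window
  tf
}

#' Model-projected time-frequency response
#'
#' Projects a network response through the entities' power spectra:
#' `TF(t, f) = sum_k response_k(t) * PSD_k(f)`, with PSDs parcel-averaged
#' (or restricted to given parcels). This shows the oscillatory content
#' implied by the fitted dynamic network model's response, comparable to a
#' conventional wavelet TF map.
#'
#' @param response A `network_response` (entities matching the spectra).
#' @param spectra A `spectra_result` for the same entities.
#' @param parcels Optional parcel subset to average the PSDs over.
#' @return List of class `tf_response` with component `full` (time x
#'   freqs), plus `times` and `freqs`.
#' @export
project_tf <- function(response, spectra, parcels = NULL) {
  stopifnot(inherits(response, "network_response"),
            inherits(spectra, "spectra_result"))
  K <- ncol(response$response)
  if (dim(spectra$psd)[1] != K)
    stopf("response has %d entities but spectra have %d", K, dim(spectra$psd)[1])
  parcels <- parcels %||% seq_len(dim(spectra$psd)[2])
  psd <- vapply(seq_len(K), function(k) {
    m <- spectra$psd[k, parcels, , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    colMeans(m)
  }, numeric(dim(spectra$psd)[3]))  # freqs x K
  tf <- response$response %*% t(psd)  # time x freqs
  structure(list(full = tf, times = response$times, freqs = spectra$freqs,
                 kind = "model-projected"),
            class = "tf_response")
}
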