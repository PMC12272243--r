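#' Time-delay embedding
#'
#' Augments each channel with time-lagged copies at lags -L..+L so that the
#' covariance matrix of the embedded data encodes the auto- and
#' cross-correlation functions of the original channels, and hence their
#' spectra and frequency-specific phase coupling. Embedded channels are
#' ordered parcel-major: all 2L+1 lags of channel 1, then channel 2, and so
#' on, with lags running -L..+L within a channel. Row t of the output
#' aligns lag 0 with original sample t+L; the first and last L samples are
#' trimmed.
#'
#' @param x Numeric matrix (time x channels) or a `parcel_sim`.
#' @param L Lag half-width in samples (non-negative integer).
#' @return Numeric matrix (time - 2L) x (channels * (2L+1)), with an
#'   attribute `trim = L`.
#' @export
time_delay_embed <- function(x, L) {
  if (inherits(x, "parcel_sim")) x <- x$x
  x <- as.matrix(x)
  L <- as.integer(L)
  if (L < 0L) stopf("L must be non-negative")
  n <- nrow(x); p <- ncol(x)
  if (n <= 2L * L) stopf("need more than 2L = %d samples, got %d", 2L * L, n)
  nt <- n - 2L * L
  out <- matrix(0, nt, p * (2L * L + 1L))
  cn <- colnames(x) %||% sprintf("ch%d", seq_len(p))
  nm <- character(ncol(out))
  k <- 0L
  for (j in seq_len(p)) {
    for (lag in -L:L) {
      k <- k + 1L
      # value at output row t is x[t + L + lag, j]
      out[, k] <- x[(1L + L + lag):(nt + L + lag), j]
      nm[k] <- sprintf("%s_lag%+d", cn[j], lag)
    }
  }
  colnames(out) <- nm
  attr(out, "trim") <- L
  out
}

#' PCA dimensionality reduction of embedded data
#'
#' Projects onto the leading eigenvectors of the channel covariance matrix
#' (components sorted by descending eigenvalue). The loading matrix is
#' retained so covariances fitted in component space can be projected back
#' to embedded-channel space.
#'
#' @param y Numeric matrix (time x channels), typically the output of
#'   [time_delay_embed()].
#' @param n_components Number of components to keep.
#' @return An object of class `prepared_data`: list with `y` (time x
#'   components), `explained_variance_ratio` (per kept component),
#'   `cumulative_explained_variance`, `pca_weights` (channels x components),
#'   `center` (channel means), `trim`, and `scaling` (filled by
#'   [standardise()]).
#' @export
pca_reduce <- function(y, n_components) {
  trim <- attr(y, "trim") %||% 0L
  y <- as.matrix(y)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(y)))
    stopf("n_components must be in [1, %d]", min(dim(y)))
  mu <- colMeans(y)
  yc <- sweep(y, 2, mu)
  cv <- crossprod(yc) / (nrow(yc) - 1)
  e <- eigen(cv, symmetric = TRUE)
  tot <- sum(diag(cv))
  W <- e$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(
    y = yc %*% W,
    explained_variance_ratio = e$values[seq_len(n_components)] / tot,
    cumulative_explained_variance = sum(e$values[seq_len(n_components)]) / tot,
    pca_weights = W,
    center = mu,
    trim = trim,
    scaling = NULL), class = "prepared_data")
}

#' Standardise (z-transform) columns
#'
#' Removes each column's mean and scales to unit variance; the scaling
#' parameters are retained. Applied to a `prepared_data` object it
#' standardises the component time courses in place (the usual final step
#' before model training).
#'
#' @param y Numeric matrix or `prepared_data`.
#' @return Same type as the input, standardised; matrices gain a `scaling`
#'   attribute, `prepared_data` objects fill their `scaling` field.
#' @export
standardise <- function(y) {
  if (inherits(y, "prepared_data")) {
    z <- standardise(y$y)
    y$y <- as.matrix(z)
    y$scaling <- attr(z, "scaling")
    attr(y$y, "scaling") <- NULL
    return(y)
  }
  y <- as.matrix(y)
  mu <- colMeans(y)
  sdv <- apply(y, 2, sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    stopf("zero-variance column(s): %s",
          paste(which(sdv <= 0 | !is.finite(sdv)), collapse = ", "))
  }
  out <- sweep(sweep(y, 2, mu), 2, sdv, `/`)
  attr(out, "scaling") <- list(mean = mu, sd = sdv)
  out
}

#' Prepare parcel data for dynamic network modelling
#'
#' Convenience wrapper: time-delay embedding with lag half-width `n_lags`,
#' PCA to `n_components`, then (optionally) standardisation. Defaults match
#' the simulation-study settings (+-2 lags, 120 components); for real
#' source-space M/EEG data +-7 lags with around 80 components (roughly 70%
#' explained variance) is the recommended operating point.
#'
#' @param x Matrix (time x parcels) or `parcel_sim`.
#' @param n_lags Lag half-width in samples.
#' @param n_components PCA components to keep.
#' @param standardise Standardise the component time courses (default TRUE).
#' @return A `prepared_data` object (see [pca_reduce()]).
#' @export
prepare <- function(x, n_lags = 2, n_components = 120, standardise = TRUE) {
  emb <- time_delay_embed(x, n_lags)
  pd <- pca_reduce(emb, n_components)
  if (standardise) pd <- standardise(pd)
  pd
}

#' @export
print.prepared_data <- function(x, ...) {
  cat(sprintf("Prepared data: %d samples x %d components (trim %d each edge)\n",
              nrow(x$y), ncol(x$y), x$trim))
  cat(sprintf("  cumulative explained variance: %.1f%%%s\n",
              100 * x$cumulative_explained_variance,
              if (is.null(x$scaling)) "" else "; standardised"))
  invisible(x)
}

#' Re-align a model time course to the original sampling clock
#'
#' Time-delay embedding trims L samples at each edge, so state/mode time
#' courses are offset by L samples relative to the raw data. This pads the
#' time course back to the original length by replicating the first and
#' last rows, suitable for epoching against event times on the original
#' clock or weighting spectra computed from the raw parcel data.
#'
#' @param tc Matrix (time' x entities) of state probabilities, a Viterbi
#'   one-hot matrix, or mode mixing coefficients.
#' @param trim Number of samples trimmed at each edge (the prep `trim`).
#' @param n_samples Original number of samples; defaults to
#'   `nrow(tc) + 2 * trim`.
#' @return Matrix (n_samples x entities).
#' @export
align_time_course <- function(tc, trim, n_samples = nrow(tc) + 2L * trim) {
  tc <- as.matrix(tc)
  if (nrow(tc) + 2L * trim != n_samples)
    stopf("time course length %d + 2*%d does not match n_samples = %d",
          nrow(tc), trim, n_samples)
  if (trim == 0L) return(tc)
  rbind(tc[rep(1L, trim), , drop = FALSE], tc,
        tc[rep(nrow(tc), trim), , drop = FALSE])
}
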