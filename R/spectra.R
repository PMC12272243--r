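#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose leading eigenvectors are the DPSS sequences; tapers are normalised
#' to unit energy and sign-fixed so each has non-negative mean (symmetric
#' tapers) or non-negative initial slope.
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product.
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return Matrix n x k, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k = 2 * nw - 1) {
  k <- as.integer(k)
  if (k < 1 || k > n) stopf("k must be in [1, n]")
  w <- nw / n
  tvec <- 0:(n - 1)
  dg <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  od <- tvec[-1] * (n - tvec[-1]) / 2
  M <- matrix(0, n, n)
  diag(M) <- dg
  M[cbind(2:n, 1:(n - 1))] <- od
  M[cbind(1:(n - 1), 2:n)] <- od
  e <- eigen(M, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) > 1e-10) { if (s < 0) tap[, j] <- -tap[, j] }
    else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

# multitaper cross-spectra of one window (samples x parcels).
# Returns list(psd = parcels x F, csd = parcels x parcels x F complex),
# one-sided density scaling (x2 except DC/Nyquist), units signal^2/Hz.
window_csd <- function(xw, tapers, fs, fidx, want_csd = TRUE) {
  n <- nrow(xw); p <- ncol(xw); K <- ncol(tapers)
  nf <- length(fidx)
  psd <- matrix(0, p, nf)
  csd <- if (want_csd) array(0 + 0i, c(p, p, nf)) else NULL
  for (k in seq_len(K)) {
    Fk <- stats::mvfft(xw * tapers[, k])[fidx, , drop = FALSE] # nf x p
    psd <- psd + t(Re(Fk)^2 + Im(Fk)^2)
    if (want_csd) {
      for (fi in seq_len(nf)) {
        v <- Fk[fi, ]
        csd[, , fi] <- csd[, , fi] + outer(v, Conj(v))
      }
    }
  }
  sc <- 2 / (K * fs) # one-sided density (no DC/Nyquist in 1-45 Hz range)
  psd <- psd * sc
  if (want_csd) csd <- csd * sc
  list(psd = psd, csd = csd)
}

new_spectra_result <- function(freqs, psd, csd, kind) {
  structure(list(freqs = freqs, psd = psd, csd = csd, kind = kind),
            class = "spectra_result")
}

#' @export
print.spectra_result <- function(x, ...) {
  cat(sprintf("%s spectra: %d entities x %d parcels x %d frequencies (%g-%g Hz)\n",
              x$kind, dim(x$psd)[1], dim(x$psd)[2], dim(x$psd)[3],
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Multitaper state power and cross spectra
#'
#' Frequency-resolved description of each HMM state: the parcel data are
#' cut into non-overlapping windows, DPSS-tapered cross-spectra are
#' computed per window, and state-k spectra are the occupancy-weighted
#' average of window spectra, with weights given by the mean posterior
#' state probability in each window.
#'
#' @param x Parcel data: a `parcel_sim`, or numeric matrix (time x
#'   parcels) with `fs` supplied.
#' @param gamma State probabilities (time x K) aligned to `x` (use
#'   [align_time_course()] if the model was fitted to trimmed embedded
#'   data).
#' @param fs Sampling frequency (ignored if `x` is a `parcel_sim`).
#' @param window_s Window length in seconds.
#' @param bandwidth Spectral smoothing bandwidth in Hz (the full
#'   multitaper bandwidth; `nw = window_s * bandwidth / 2`).
#' @param frange Frequency range in Hz.
#' @param want_csd Compute cross-spectra as well (needed for coherence).
#' @return A `spectra_result`: list with `freqs`, `psd`
#'   (states x parcels x freqs, signal^2/Hz) and `csd`
#'   (states x parcels x parcels x freqs, complex Hermitian). States with
#'   zero total weight give NA spectra with a warning.
#' @export
multitaper_state_spectra <- function(x, gamma, fs = NULL, window_s = 2,
                                     bandwidth = 4, frange = c(1, 45),
                                     want_csd = TRUE) {
  if (inherits(x, "parcel_sim")) { fs <- x$fs; x <- x$x }
  if (is.null(fs)) stopf("fs must be supplied for matrix input")
  x <- as.matrix(x); gamma <- as.matrix(gamma)
  if (nrow(gamma) != nrow(x))
    stopf("gamma (%d) not aligned to data (%d samples)", nrow(gamma), nrow(x))
  nwin_len <- round(window_s * fs)
  nwin <- nrow(x) %/% nwin_len
  if (nwin < 2) stopf("fewer than 2 windows; shorten window_s")
  nw <- window_s * bandwidth / 2
  tapers <- dpss_tapers(nwin_len, nw)
  fgrid <- (0:(nwin_len - 1)) * fs / nwin_len
  fidx <- which(fgrid >= frange[1] & fgrid <= frange[2])
  freqs <- fgrid[fidx]
  K <- ncol(gamma); p <- ncol(x); nf <- length(fidx)
  psd <- array(0, c(K, p, nf))
  csd <- if (want_csd) array(0 + 0i, c(K, p, p, nf)) else NULL
  wsum <- numeric(K)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * nwin_len + 1):(w * nwin_len)
    xw <- x[idx, , drop = FALSE]
    xw <- sweep(xw, 2, colMeans(xw))
    wc <- window_csd(xw, tapers, fs, fidx, want_csd)
    gw <- colMeans(gamma[idx, , drop = FALSE])
    for (k in seq_len(K)) {
      if (gw[k] == 0) next
      psd[k, , ] <- psd[k, , ] + gw[k] * wc$psd
      if (want_csd) csd[k, , , ] <- csd[k, , , ] + gw[k] * wc$csd
    }
    wsum <- wsum + gw
  }
  for (k in seq_len(K)) {
    if (wsum[k] <= 0) {
      warning(sprintf("state %d has zero total weight; spectra undefined", k))
      psd[k, , ] <- NA_real_
      if (want_csd) csd[k, , , ] <- NA_complex_
    } else {
      psd[k, , ] <- psd[k, , ] / wsum[k]
      if (want_csd) csd[k, , , ] <- csd[k, , , ] / wsum[k]
    }
  }
  new_spectra_result(freqs, psd, csd, "multitaper state")
}

#' GLM mode spectra
#'
#' Frequency-resolved description of each DyNeMo mode: a windowed
#' multitaper spectrogram is computed per parcel (and parcel pair), the
#' mode mixing coefficients are downsampled to window means, and per
#' frequency the spectrogram is regressed on the demeaned coefficients
#' plus an intercept. The mode-j spectrum is its regression coefficient
#' plus the intercept (the spectrum when mode j is fully active at its
#' mean-plus-one-unit loading, on the scale of a PSD).
#'
#' @param x Parcel data (`parcel_sim` or matrix).
#' @param alpha Mode mixing coefficients (time x J) aligned to `x`.
#' @param fs Sampling frequency for matrix input.
#' @param window_s Window length in seconds.
#' @param bandwidth Multitaper bandwidth in Hz.
#' @param frange Frequency range in Hz.
#' @param want_csd Compute cross-spectra as well.
#' @return A `spectra_result` with `psd` (modes x parcels x freqs) and
#'   `csd` (modes x parcels x parcels x freqs).
#' @export
glm_mode_spectra <- function(x, alpha, fs = NULL, window_s = 2,
                             bandwidth = 4, frange = c(1, 45),
                             want_csd = TRUE) {
  if (inherits(x, "parcel_sim")) { fs <- x$fs; x <- x$x }
  if (is.null(fs)) stopf("fs must be supplied for matrix input")
  x <- as.matrix(x); alpha <- as.matrix(alpha)
  if (nrow(alpha) != nrow(x))
    stopf("alpha (%d) not aligned to data (%d samples)", nrow(alpha), nrow(x))
  nwin_len <- round(window_s * fs)
  nwin <- nrow(x) %/% nwin_len
  J <- ncol(alpha); p <- ncol(x)
  if (nwin < J + 2) stopf("too few windows for %d mode regressors", J)
  nw <- window_s * bandwidth / 2
  tapers <- dpss_tapers(nwin_len, nw)
  fgrid <- (0:(nwin_len - 1)) * fs / nwin_len
  fidx <- which(fgrid >= frange[1] & fgrid <= frange[2])
  freqs <- fgrid[fidx]; nf <- length(fidx)
  P <- array(0, c(nwin, p, nf))
  Cs <- if (want_csd) array(0 + 0i, c(nwin, p * p, nf)) else NULL
  aw <- matrix(0, nwin, J)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * nwin_len + 1):(w * nwin_len)
    xw <- x[idx, , drop = FALSE]
    xw <- sweep(xw, 2, colMeans(xw))
    wc <- window_csd(xw, tapers, fs, fidx, want_csd)
    P[w, , ] <- wc$psd
    if (want_csd) Cs[w, , ] <- wc$csd
    aw[w, ] <- colMeans(alpha[idx, , drop = FALSE])
  }
  X <- cbind(1, sweep(aw, 2, colMeans(aw)))
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || (max(sv) / min(sv))^2 > 1e8) {
    warning("mode regressors nearly collinear; using pseudo-inverse")
    Xp <- svd_pinv(X)
  } else Xp <- solve(crossprod(X), t(X))
  # coefficients: (J+1) x (p*nf); mode spectrum = coef_j + intercept
  B <- Xp %*% matrix(P, nwin)
  psd <- array(0, c(J, p, nf))
  for (j in seq_len(J))
    psd[j, , ] <- array(B[1, ] + B[j + 1, ], c(p, nf))
  csd <- NULL
  if (want_csd) {
    Bc <- Xp %*% matrix(Cs, nwin)
    csd <- array(0 + 0i, c(J, p, p, nf))
    for (j in seq_len(J))
      csd[j, , , ] <- array(Bc[1, ] + Bc[j + 1, ], c(p, p, nf))
  }
  new_spectra_result(freqs, psd, csd, "GLM mode")
}

svd_pinv <- function(X) {
  s <- svd(X)
  keep <- s$d > max(s$d) * 1e-12
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Coherence from power and cross spectra
#'
#' `C_xy(f) = |P_xy(f)| / sqrt(P_xx(f) P_yy(f))`: the normalised
#' cross-spectral magnitude, a frequency-specific measure of phase
#' coupling, in [0, 1].
#'
#' @param spectra A `spectra_result` with cross-spectra.
#' @return Array (entities x parcels x parcels x freqs); zero-PSD entries
#'   give NA.
#' @export
coherence <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_result"))
  if (is.null(spectra$csd)) stopf("spectra were computed without csd")
  dm <- dim(spectra$csd)
  K <- dm[1]; p <- dm[2]; nf <- dm[4]
  out <- array(NA_real_, dm)
  for (k in seq_len(K)) {
    for (fi in seq_len(nf)) {
      pxx <- Re(diag(spectra$csd[k, , , fi]))
      den <- sqrt(outer(pxx, pxx))
      cm <- Mod(spectra$csd[k, , , fi]) / den
      cm[den <= 0 | !is.finite(den)] <- NA_real_
      out[k, , , fi] <- pmin(cm, 1)
    }
  }
  out
}

#' Band-averaged coherence network
#'
#' Averages a coherence array over frequency with the given non-negative
#' weights (a band mask or an NNMF spectral profile), returning one
#' symmetric zero-diagonal network per entity.
#'
#' @param coh Array from [coherence()].
#' @param freqs Frequency grid matching the last dimension.
#' @param weights Non-negative spectral weights (length nf), or NULL for a
#'   flat average.
#' @return Array (entities x parcels x parcels).
#' @export
coherence_network <- function(coh, freqs, weights = NULL) {
  nf <- dim(coh)[4]
  weights <- weights %||% rep(1, nf)
  if (any(weights < 0) || sum(weights) == 0) stopf("weights must be non-negative, not all zero")
  w <- weights / sum(weights)
  out <- array(0, dim(coh)[1:3])
  for (fi in seq_len(nf))
    out <- out + w[fi] * array(coh[, , , fi], dim(coh)[1:3])
  for (k in seq_len(dim(out)[1])) {
    m <- out[k, , ]; diag(m) <- 0; out[k, , ] <- (m + t(m)) / 2
  }
  out
}

#' Power maps from spectra
#'
#' The weighted average of each entity's PSD over frequency, per parcel
#' (units signal^2/Hz weighted-mean, i.e. band power density). With
#' `relative = TRUE` the across-entity mean map is subtracted, showing
#' each state/mode relative to the average — the standard display
#' convention for state/mode power maps.
#'
#' @param spectra A `spectra_result`.
#' @param weights Non-negative frequency weights (band mask or NNMF
#'   profile); NULL averages the full computed range.
#' @param relative Subtract the across-entity mean map.
#' @return Matrix (entities x parcels).
#' @export
power_map <- function(spectra, weights = NULL, relative = FALSE) {
  stopifnot(inherits(spectra, "spectra_result"))
  nf <- dim(spectra$psd)[3]
  weights <- weights %||% rep(1, nf)
  if (length(weights) != nf) stopf("weights must have length %d", nf)
  if (any(weights < 0) || sum(weights) == 0)
    stopf("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  K <- dim(spectra$psd)[1]
  maps <- matrix(0, K, dim(spectra$psd)[2])
  for (k in seq_len(K)) maps[k, ] <- spectra$psd[k, , ] %*% w
  if (relative) maps <- sweep(maps, 2, colMeans(maps))
  maps
}

#' Non-negative matrix factorisation of stacked coherence spectra
#'
#' Factorises stacked (subject/state x frequency) coherence spectra into
#' non-negative spectral profiles by multiplicative updates (Frobenius
#' objective), with seeded restarts keeping the best reconstruction.
#' Components are sorted by ascending spectral centroid; the first
#' component is the canonical band-weight profile for HMM power and
#' coherence maps (typically covering roughly 1-22 Hz on real data).
#'
#' @param x Non-negative matrix (observations x frequencies).
#' @param n_components Number of components (default 2).
#' @param n_restarts Seeded restarts.
#' @param max_iter Multiplicative-update iterations.
#' @param seed RNG seed.
#' @return List with `profiles` (components x frequencies, unit-sum rows),
#'   `weights` (observations x components) and `recon_error`.
#' @export
nnmf_bands <- function(x, n_components = 2, n_restarts = 10,
                       max_iter = 500, seed = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stopf("input must be non-negative")
  if (any(!is.finite(x))) stopf("input must be finite")
  r <- as.integer(n_components)
  best <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_restarts)) {
      W <- matrix(runif(nrow(x) * r, 0.1, 1), ncol = r)
      H <- matrix(runif(r * ncol(x), 0.1, 1), nrow = r)
      for (it in seq_len(max_iter)) {
        H <- H * (t(W) %*% x) / (t(W) %*% W %*% H + 1e-12)
        W <- W * (x %*% t(H)) / (W %*% H %*% t(H) + 1e-12)
      }
      err <- sum((x - W %*% H)^2)
      if (is.null(best) || err < best$recon_error)
        best <- list(W = W, H = H, recon_error = err)
    }
    best
  })
  # order by spectral centroid (ascending), normalise profiles to unit sum
  fidx <- seq_len(ncol(x))
  centroid <- apply(best$H, 1, function(h) sum(fidx * h) / sum(h))
  ord <- order(centroid)
  H <- best$H[ord, , drop = FALSE]
  W <- best$W[, ord, drop = FALSE]
  sc <- rowSums(H)
  list(profiles = H / sc, weights = sweep(W, 2, sc, `*`),
       recon_error = best$recon_error)
}

#' Threshold a network to its strongest edges
#'
#' Keeps the `ceiling(top_fraction * n_edges)` upper-triangle edges of
#' largest absolute value (irrespective of sign). Ties are broken
#' deterministically by (row, column) lexicographic order.
#'
#' @param network Symmetric matrix (parcels x parcels).
#' @param top_fraction Fraction of edges to retain (default 0.02).
#' @return Logical symmetric matrix marking retained edges.
#' @export
threshold_edges <- function(network, top_fraction = 0.02) {
  network <- as.matrix(network)
  p <- nrow(network)
  if (p != ncol(network)) stopf("network must be square")
  ut <- which(upper.tri(network), arr.ind = TRUE)
  n_keep <- ceiling(top_fraction * nrow(ut))
  v <- abs(network[ut])
  ord <- order(-v, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(n_keep, length(ord)))]
  mask <- matrix(FALSE, p, p)
  mask[ut[keep, , drop = FALSE]] <- TRUE
  mask | t(mask)
}

#' Match modes or states to ground-truth networks by power-map overlap
#'
#' Assigns each ground-truth network the entity whose power map best
#' correlates with the network's parcel-membership indicator, using an
#' exclusive assignment that maximises the total correlation (exhaustive
#' over permutations; entity counts here are small).
#'
#' @param maps Matrix (entities x parcels) of power maps.
#' @param truth List of integer vectors of member parcels (1-based), one
#'   per ground-truth network.
#' @return Integer vector: for each truth network, the matched entity
#'   index, with the correlations as an attribute.
#' @export
match_networks <- function(maps, truth) {
  K <- nrow(maps); M <- length(truth)
  if (M > K) stopf("more truth networks than entities")
  cors <- matrix(-Inf, M, K)
  for (m in seq_len(M)) {
    ind <- as.numeric(seq_len(ncol(maps)) %in% truth[[m]])
    for (k in seq_len(K)) cors[m, k] <- suppressWarnings(cor(maps[k, ], ind))
  }
  cors[!is.finite(cors)] <- -1
  perms <- all_permutations(K, M)
  sc <- apply(perms, 1, function(pr) sum(cors[cbind(seq_len(M), pr)]))
  best <- perms[which.max(sc), ]
  attr(best, "correlation") <- cors[cbind(seq_len(M), best)]
  best
}

# ordered selections of M distinct entities out of K (rows)
all_permutations <- function(K, M, used = integer(0)) {
  if (M == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  out <- NULL
  for (a in setdiff(seq_len(K), used))
    out <- rbind(out, cbind(a, all_permutations(K, M - 1, c(used, a))))
  unname(out)
}
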