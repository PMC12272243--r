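test_that("Slepian tapers are orthonormal and band-concentrated", {
  tap <- dpss_tapers(500, 4, 7)
  expect_equal(dim(tap), c(500, 7))
  expect_equal(unname(crossprod(tap)), diag(7), tolerance = 1e-8)
  # the leading taper concentrates its energy inside the design bandwidth
  h <- abs(fft(c(tap[, 1], rep(0, 3500))))^2
  inband <- sum(h[1:33]) / sum(h[1:2000]) # 4/500 half-bandwidth of 4000-pt fft
  expect_gt(inband, 0.99)
})

test_that("multitaper state spectra behave on constructed assignments", {
  set.seed(1)
  fs <- 250; n <- 25600
  # white noise, single always-on state: flat PSD
  x <- matrix(rnorm(2 * n), n, 2)
  sp <- multitaper_state_spectra(x, matrix(1, n, 1), fs = fs, want_csd = FALSE)
  expect_lt(max(sp$psd[1, 1, ]) / min(sp$psd[1, 1, ]), 1.5)

  # pure 10 Hz sinusoid assigned wholly to state 1 of 2
  tt <- (0:(n - 1)) / fs
  xs <- cbind(sin(2 * pi * 10 * tt), rnorm(n, sd = .1))
  g <- cbind(rep(1, n), rep(0, n))
  expect_warning(sp2 <- multitaper_state_spectra(xs, g, fs = fs,
                                                 want_csd = FALSE),
                 "zero total weight")
  expect_equal(sp2$freqs[which.max(sp2$psd[1, 1, ])], 10)
  expect_true(all(is.na(sp2$psd[2, , ])))

  # occupancy-weighted sum of state PSDs matches the whole-data PSD
  sim <- small_sim()
  set.seed(2)
  gam <- matrix(rgamma(nrow(sim$x) * 2, 1), ncol = 2)
  gam <- gam / rowSums(gam)
  sps <- multitaper_state_spectra(sim$x, gam, fs = sim$fs, want_csd = FALSE)
  spw <- multitaper_state_spectra(sim$x, matrix(1, nrow(sim$x), 1),
                                  fs = sim$fs, want_csd = FALSE)
  # weights: total gamma mass per state over windows
  wlen <- 2 * sim$fs; nwin <- nrow(sim$x) %/% wlen
  gw <- colMeans(gam[seq_len(nwin * wlen), ])
  mix <- gw[1] * sps$psd[1, , ] + gw[2] * sps$psd[2, , ]
  expect_lt(max(abs(mix - spw$psd[1, , ]) / spw$psd[1, , ]), 0.05)
})

test_that("multitaper PSD integrates to the band variance (Parseval)", {
  set.seed(3)
  fs <- 250; n <- 25600
  # band-limited signal inside 1-45 Hz: a 12 Hz sinusoid
  x <- matrix(sin(2 * pi * 12 * (0:(n - 1)) / fs) * sqrt(2), n, 1)
  sp <- multitaper_state_spectra(x, matrix(1, n, 1), fs = fs, want_csd = FALSE)
  bandpow <- sum(sp$psd[1, 1, ]) * diff(sp$freqs[1:2])
  expect_equal(bandpow, var(x[, 1]), tolerance = 0.1)
})

test_that("GLM mode spectra attribute oscillations to the right modes", {
  fs <- 250; n <- 25600
  tt <- (0:(n - 1)) / fs
  set.seed(4)
  # two modes with disjoint on-periods carrying 10 and 20 Hz oscillations
  half <- n / 2
  on1 <- c(rep(1, half), rep(0, half))
  blocks <- rep(rep(0:1, each = 1000), length.out = n) # interleave activity
  on1 <- blocks; on2 <- 1 - blocks
  x <- matrix(rnorm(n * 2, sd = .3), n, 2)
  x[, 1] <- x[, 1] + on1 * sin(2 * pi * 10 * tt) + on2 * sin(2 * pi * 20 * tt)
  x[, 2] <- x[, 2] + on1 * sin(2 * pi * 10 * tt + 1)
  alpha <- cbind(on1, on2)
  sp <- suppressWarnings(glm_mode_spectra(x, alpha, fs = fs, want_csd = FALSE))
  expect_equal(sp$freqs[which.max(sp$psd[1, 1, ])], 10)
  expect_equal(sp$freqs[which.max(sp$psd[2, 1, ])], 20)

  # an alpha independent of the data contributes almost nothing
  # (random at the window scale, as a mixing coefficient would be)
  set.seed(5)
  x3 <- matrix(rnorm(n, sd = .3) + sin(2 * pi * 10 * tt), n, 1)
  a3 <- matrix(rep(runif(ceiling(n / 500)), each = 500)[1:n], ncol = 1)
  sp3 <- glm_mode_spectra(x3, a3, fs = fs, want_csd = FALSE)
  static <- multitaper_state_spectra(x3, matrix(1, n, 1), fs = fs,
                                     want_csd = FALSE)
  pk <- which.max(static$psd[1, 1, ])
  coef_mag <- abs(sp3$psd[1, 1, pk] - static$psd[1, 1, pk])
  expect_lt(coef_mag, 0.1 * static$psd[1, 1, pk])
})

test_that("coherence obeys its analytic bounds and invariances", {
  set.seed(6)
  fs <- 250; n <- 25600
  tt <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 10 * tt) + rnorm(n, sd = .2)
  # identical signals: coherence 1 everywhere
  x <- cbind(s, s)
  sp <- multitaper_state_spectra(x, matrix(1, n, 1), fs = fs)
  coh <- coherence(sp)
  expect_equal(range(coh[1, 1, 2, ]), c(1, 1), tolerance = 1e-9)

  # independent white noise: low band-averaged coherence
  x2 <- matrix(rnorm(2 * n), n, 2)
  sp2 <- multitaper_state_spectra(x2, matrix(1, n, 1), fs = fs)
  coh2 <- coherence(sp2)
  expect_lt(mean(coh2[1, 1, 2, ]), 0.15)
  expect_true(all(coh2 >= 0 & coh2 <= 1, na.rm = TRUE))

  # invariant to per-channel rescaling
  x3 <- x2; x3[, 2] <- 3 * x3[, 2]
  coh3 <- coherence(multitaper_state_spectra(x3, matrix(1, n, 1), fs = fs))
  expect_equal(coh3[1, 1, 2, ], coh2[1, 1, 2, ], tolerance = 1e-9)
})

test_that("power maps average PSDs and centre across entities", {
  freqs <- 1:20
  psd <- array(0, c(3, 4, 20))
  psd[1, , ] <- 2; psd[2, , ] <- 5; psd[3, , ] <- 1
  sp <- structure(list(freqs = freqs, psd = psd, csd = NULL, kind = "test"),
                  class = "spectra_result")
  # flat PSD of height p with uniform weights gives p
  expect_equal(unname(power_map(sp)[, 1]), c(2, 5, 1))
  # relative maps have zero across-entity mean
  rel <- power_map(sp, relative = TRUE)
  expect_lt(max(abs(colMeans(rel))), 1e-12)
  expect_error(power_map(sp, weights = rep(0, 20)), "not all zero")
  expect_error(power_map(sp, weights = rep(-1, 20)), "non-negative")
})

test_that("NNMF separates synthetic low/high coherence bands", {
  freqs <- seq(1, 45, by = 0.5)
  low <- exp(-(freqs - 8)^2 / 18); high <- exp(-(freqs - 30)^2 / 30)
  set.seed(7)
  W <- cbind(runif(60, 0, 1), runif(60, 0, 1))
  X <- W %*% rbind(low, high) + matrix(runif(60 * length(freqs), 0, .02), 60)
  nf <- nnmf_bands(X, 2, seed = 8)
  expect_true(all(nf$profiles >= 0) && all(nf$weights >= 0))
  # components ordered by spectral centroid: first is the low band
  expect_gt(cor(nf$profiles[1, ], low), 0.9)
  expect_gt(cor(nf$profiles[2, ], high), 0.9)
  # reconstruction error does not increase with more components
  nf1 <- nnmf_bands(X, 1, seed = 8)
  expect_lte(nf$recon_error, nf1$recon_error * (1 + 1e-9))
  expect_error(nnmf_bands(-X), "non-negative")
})

test_that("edge thresholding keeps the strongest edges deterministically", {
  set.seed(9)
  p <- 38
  m <- matrix(rnorm(p * p), p); m <- (m + t(m)) / 2; diag(m) <- 0
  mask <- threshold_edges(m, 0.02)
  # ceil(0.02 * 703) = 15 edges for 38 parcels
  expect_equal(sum(mask) / 2, 15)
  expect_true(isSymmetric(mask))
  # the retained edges are the 15 largest |values|
  ut <- which(upper.tri(m))
  expect_equal(sort(abs(m[ut])[mask[ut]]), sort(abs(m[ut]))[689:703])

  # all-equal values: lexicographic tie-break keeps the first rows
  me <- matrix(1, 5, 5); diag(me) <- 0
  mk <- threshold_edges(me, 0.2) # ceil(0.2 * 10) = 2 edges
  expect_equal(which(mk[upper.tri(mk)]), c(1L, 2L))
  # top_fraction = 1 keeps everything
  expect_equal(sum(threshold_edges(me, 1)) / 2, 10)
})

test_that("network matching assigns entities exclusively by map overlap", {
  maps <- rbind(c(5, 5, 1, 1, 1, 1), # entity 1: parcels 1-2
                c(1, 1, 5, 5, 5, 1), # entity 2: parcels 3-5
                c(1, 1, 1, 1, 1, 1)) # flat
  m <- match_networks(maps, list(a = 1:2, b = 3:5))
  expect_equal(as.integer(m), c(1L, 2L))
  expect_true(all(attr(m, "correlation") > 0.9))
})
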