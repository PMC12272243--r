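test_that("epoching uses inclusive-start exclusive-end sample windows", {
  fs <- 250
  x <- matrix(seq_len(2000), 2000, 1)
  # event at 0-based sample 1000 covers 0-based samples 975..1249
  ep <- epoch(x, event_table(1000L), fs, tmin = -0.1, tmax = 1.0)
  expect_equal(dim(ep$data)[2], 275)
  expect_equal(ep$data[1, 1, 1], 976) # R 1-based row of 0-based sample 975
  expect_equal(ep$data[1, 275, 1], 1250)
  expect_equal(ep$times[1], -0.1)
  expect_equal(ep$times[length(ep$times)], 1.0 - 1 / fs)

  # an event too close to the recording start is dropped and counted
  ep2 <- epoch(x, event_table(c(10L, 1000L)), fs, tmin = -0.1, tmax = 1.0)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$n_dropped, 1)
  expect_error(epoch(x, event_table(10L), fs, tmin = -0.1, tmax = 1.0),
               "no trials")

  # n in-bounds events give exactly n trials
  ev <- event_table(seq(100L, 1500L, by = 100L))
  expect_equal(dim(epoch(x, ev, fs)$data)[1], nrow(ev))
})

test_that("event tables round-trip through the BIDS-style TSV dialect", {
  ev <- event_table(c(30L, 10L, 20L), c("b", "a", "c"), duration = 2)
  # sorted ascending by onset
  expect_equal(ev$onset_sample, c(10L, 20L, 30L))
  f <- tempfile(fileext = ".tsv")
  write_events(ev, f)
  ev2 <- read_events(f)
  expect_equal(ev2$onset_sample, ev$onset_sample)
  expect_equal(ev2$trial_type, ev$trial_type)
  expect_error(event_table(-5L), "non-negative")
})

test_that("network responses are trial means with an exact zero baseline", {
  fs <- 250
  # constant time course: zero response everywhere
  xc <- matrix(1, 3000, 2)
  ev <- event_table(c(500L, 1500L, 2500L))
  nr <- network_response(epoch(xc, ev, fs, tmax = 0.5))
  expect_lt(max(abs(nr$response)), 1e-12)

  # a one-hot state locked 200 ms after each event peaks at 0.2 s
  x <- matrix(0, 3000, 1)
  for (o in ev$onset_sample) x[o + 50 + (0:5) + 1, 1] <- 1
  nr2 <- network_response(epoch(x, ev, fs, tmax = 0.5))
  expect_lt(abs(nr2$times[which.max(nr2$response[, 1])] - 0.2), 1 / fs + 1e-9)

  # baseline window mean is exactly zero after correction
  set.seed(1)
  xr <- matrix(rnorm(3000 * 2), 3000, 2)
  nr3 <- network_response(epoch(xr, ev, fs, tmax = 0.5))
  bidx <- nr3$times >= -0.1 & nr3$times < 0
  expect_lt(max(abs(colMeans(nr3$response[bidx, ]))), 1e-9)
  expect_error(network_response(epoch(xr, ev, fs), baseline = c(5, 6)),
               "baseline")
})

test_that("Morlet TF separates phase-locked from induced responses", {
  fs <- 250
  n_ep <- 275; n_tr <- 100
  tt <- (0:(n_ep - 1)) / fs
  build_epochs <- function(phases) {
    dat <- array(0, c(n_tr, n_ep, 1))
    for (i in seq_len(n_tr))
      dat[i, , 1] <- sin(2 * pi * 10 * tt + phases[i]) + rnorm(n_ep, sd = .05)
    structure(list(data = dat, times = tt - 0.1, labels = rep("e", n_tr),
                   fs = fs, n_dropped = 0), class = "epochs")
  }
  # identical phase in every trial: evoked ~ full, induced ~ 0
  set.seed(2)
  tf_locked <- morlet_tf(build_epochs(rep(0, n_tr)))
  expect_lt(max(abs(tf_locked$induced)), 0.05 * max(tf_locked$full))
  # random phase per trial: evoked collapses
  set.seed(3)
  tf_rand <- morlet_tf(build_epochs(runif(n_tr, 0, 2 * pi)))
  i10 <- which.min(abs(tf_rand$freqs - 10))
  expect_lt(max(tf_rand$evoked[, i10]), 0.15 * max(tf_rand$full[, i10]))

  # frequency localisation: argmax at the bin nearest the true frequency
  f0 <- 17.3
  dat <- array(sin(2 * pi * f0 * tt), c(1, n_ep, 1))
  epf <- structure(list(data = dat, times = tt - 0.1, labels = "e",
                        fs = fs, n_dropped = 0), class = "epochs")
  tff <- morlet_tf(epf)
  mid <- nrow(tff$full) %/% 2
  expect_equal(tff$freqs[which.max(tff$full[mid, ])], 17.5)

  # decomposition identity holds exactly
  expect_equal(tf_rand$full - tf_rand$evoked - tf_rand$induced,
               matrix(0, nrow(tf_rand$full), ncol(tf_rand$full)),
               tolerance = 1e-12)
  expect_error(morlet_tf(epf, freqs = c(10, 200)), "Nyquist")
})

test_that("TF baseline correction is exact, idempotent and windowed", {
  fs <- 250
  set.seed(4)
  n_ep <- 275
  dat <- array(rnorm(50 * n_ep), c(50, n_ep, 1))
  ep <- structure(list(data = dat, times = (0:(n_ep - 1)) / fs - 0.1,
                       labels = rep("e", 50), fs = fs, n_dropped = 0),
                  class = "epochs")
  tf <- morlet_tf(ep)
  tfb <- baseline_correct_tf(tf)
  bidx <- tfb$times >= -0.1 & tfb$times < 0
  for (comp in c("full", "evoked", "induced"))
    expect_lt(max(abs(colMeans(tfb[[comp]][bidx, ]))), 1e-9)
  # idempotent
  tfb2 <- baseline_correct_tf(tfb)
  expect_equal(tfb2$full, tfb$full, tolerance = 1e-12)
  # stationary signal: corrected TF stays near zero everywhere
  interior <- tfb$times > 0.1 & tfb$times < 0.9
  se <- apply(tf$full[bidx, ], 2, sd)
  expect_true(mean(abs(tfb$full[interior, ]) <
                     3 * rep(se + 1e-12, each = sum(interior))) > 0.95)
  expect_error(baseline_correct_tf(tf, c(5, 6)), "outside")
})

test_that("model-projected TF places entity spectra at response times", {
  freqs <- seq(6, 30, by = 0.5)
  psd <- array(0, c(1, 3, length(freqs)))
  psd[1, , ] <- matrix(exp(-(freqs - 10)^2), 3, length(freqs), byrow = TRUE)
  sp <- structure(list(freqs = freqs, psd = psd, csd = NULL, kind = "t"),
                  class = "spectra_result")
  resp <- structure(list(response = matrix(c(0, 0, 1, 0), 4, 1),
                         times = c(-0.1, 0, 0.1, 0.2), baseline = c(-0.1, 0),
                         n_trials = 10), class = "network_response")
  tf <- project_tf(resp, sp)
  expect_equal(tf$full[3, ], exp(-(freqs - 10)^2))
  expect_equal(tf$full[c(1, 2, 4), ], matrix(0, 3, length(freqs)))
  # zero response gives zero TF
  resp$response[] <- 0
  expect_true(all(project_tf(resp, sp)$full == 0))
  # entity mismatch is a shape error
  resp2 <- resp; resp2$response <- cbind(resp$response, resp$response)
  expect_error(project_tf(resp2, sp), "entities")
})

test_that("trial averaging commutes with channel-wise linear maps", {
  set.seed(5)
  fs <- 250
  x <- matrix(rnorm(3000 * 2), 3000, 2)
  ev <- event_table(c(500L, 1500L, 2500L))
  A <- matrix(c(2, 1, 0, -1), 2)
  ep1 <- epoch(x %*% A, ev, fs, tmax = 0.5)
  ep2 <- epoch(x, ev, fs, tmax = 0.5)
  m1 <- apply(ep1$data, c(2, 3), mean)
  m2 <- apply(ep2$data, c(2, 3), mean) %*% A
  expect_equal(m1, m2, tolerance = 1e-12)
})
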