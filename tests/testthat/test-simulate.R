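test_that("burst time course follows the symmetric two-state chain", {
  # absorbing case
  expect_true(all(sample_burst_time_course(1, 500, seed = 1) %in% c(0, 1)))
  tc1 <- sample_burst_time_course(1, 500, seed = 1)
  expect_true(all(tc1 == tc1[1]))

  tc <- sample_burst_time_course(0.95, 200000, seed = 7)
  r <- rle(tc)
  on_runs <- r$lengths[r$values == 1]
  # geometric dwell: mean run length 1 / (1 - 0.95) = 20 samples
  expect_equal(mean(on_runs), 20, tolerance = 0.05)
  # stationary occupancy of a symmetric chain is 1/2
  expect_equal(mean(tc), 0.5, tolerance = 0.04)
  # run lengths are Geometric(0.05): discrete Kolmogorov-Smirnov distance
  grid <- seq_len(max(on_runs))
  ks <- max(abs(stats::ecdf(on_runs)(grid) - stats::pgeom(grid - 1, 0.05)))
  expect_lt(ks, 0.02)

  expect_error(sample_burst_time_course(1.2, 10), "probability")
  expect_error(sample_burst_time_course(-0.1, 10), "probability")
})

test_that("simulated parcels carry the configured oscillations and noise", {
  sim <- small_sim()
  expect_equal(dim(sim$x), c(6000, 12))
  expect_true(all(is.finite(sim$x)))

  # noise-only parcel variance ~ noise_var (before orthogonalisation the
  # target is exact; after, leakage of a few percent is possible)
  expect_equal(var(sim$x[, 10]), 0.2, tolerance = 0.15)

  # spectral peaks at the network frequencies
  pk <- function(j) {
    s <- stats::spec.pgram(sim$x[, j], spans = 5, plot = FALSE)
    s$freq[which.max(s$spec)] * sim$fs
  }
  expect_lt(abs(pk(1) - 10), 1.5)
  expect_lt(abs(pk(4) - 20), 1.5)

  # near-pure sinusoid: no noise, one always-on network, A = 1
  cfg <- sim_config(n_parcels = 4, n_samples = 2000, noise_var = 1e-12,
                    stay_prob = 0.9999999,
                    networks = list(network_spec("v", 1:2, 10, 1, 1)),
                    seed = 3)
  s2 <- simulate_parcels(cfg)
  on <- s2$ground_truth$on[, 1]
  if (mean(on) > 0.99) # chain stayed on throughout
    expect_equal(var(s2$x[, 1]), 0.5, tolerance = 0.02)
})

test_that("ground truth tiles bursts and alternates amplitudes", {
  sim <- small_sim()
  gt <- sim$ground_truth
  for (j in seq_len(ncol(gt$on))) {
    nw <- colnames(gt$on)[j]
    b <- gt$bursts[gt$bursts$network == nw, ]
    # bursts exactly tile the runs of 1s
    on2 <- integer(nrow(gt$on))
    for (i in seq_len(nrow(b))) on2[b$start[i]:b$end[i]] <- 1L
    expect_identical(on2, as.integer(gt$on[, j]))
    # amplitude labels alternate low, high, low, ...
    expect_identical(b$amp_label, rep(c("low", "high"), length.out = nrow(b)))
    expect_identical(b$amplitude, ifelse(b$amp_label == "low", 1, 2))
    # phases in [0, 2pi)
    ph <- gt$phases[[nw]]
    expect_true(all(ph >= 0 & ph < 2 * pi))
  }
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_parcels = 8, n_samples = 2000,
                    networks = list(network_spec("v", 1:2, 10)), seed = 5)
  a <- simulate_parcels(cfg)
  b <- simulate_parcels(cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(stay_prob = 1), "stay_prob")
  expect_error(sim_config(noise_var = 0), "noise_var")
  expect_error(network_spec("v", integer(0), 10), "non-empty")
  expect_error(network_spec("v", 1:2, 10, amp_low = 3, amp_high = 1), "amp_low")
  expect_error(sim_config(networks = list(network_spec("v", 1:50, 10))),
               "exceeds n_parcels")
  expect_error(sim_config(networks = list(network_spec("v", 1:2, 200))),
               "Nyquist")
  # overlapping parcel sets need explicit opt-in
  nets <- list(network_spec("a", 1:3, 10), network_spec("b", 3:4, 20))
  expect_error(sim_config(networks = nets), "allow_overlap")
  expect_s3_class(sim_config(networks = nets, allow_overlap = TRUE), "sim_config")
})

test_that("symmetric orthogonalisation removes zero-lag correlations", {
  set.seed(1)
  # correlated input
  x <- matrix(rnorm(3000), 1000, 3)
  x[, 2] <- x[, 2] + 0.7 * x[, 1]
  y <- symmetric_orthogonalise(x)
  cc <- cor(y)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  # column norms preserved relative to the centred originals
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(sqrt(colSums(y^2)), sqrt(colSums(xc^2)), tolerance = 1e-9)

  # zero-mean input with orthogonal columns is a fixed point
  # (QR of a column-centred matrix: orthonormal linear combinations of
  # zero-mean columns are themselves zero-mean)
  q <- qr.Q(qr(sweep(x, 2, colMeans(x))))
  expect_lt(max(abs(symmetric_orthogonalise(q) - q)), 1e-10)

  # duplicated columns: rank deficiency is reported with the column
  xb <- cbind(x, x[, 1])
  expect_error(symmetric_orthogonalise(xb), "rank deficient")
  expect_error(symmetric_orthogonalise(t(x)), "more time points")
})

test_that("simulated parcel data are fully decorrelated after leakage correction", {
  sim <- small_sim()
  cc <- cor(sim$x)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
})
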