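test_that("mixing coefficients live on the probability simplex", {
  set.seed(1)
  y <- matrix(rnorm(4000 * 6), 4000, 6)
  fit <- dynemo(y, n_modes = 2, n_init = 1, init_epochs = 2, n_epochs = 5,
                seed = 2)
  expect_true(all(fit$alpha >= 0))
  expect_lt(max(abs(rowSums(fit$alpha) - 1)), 1e-6)
  expect_lt(max(abs(rowSums(fit$alpha_renorm) - 1)), 1e-6)
  expect_equal(nrow(fit$alpha), 4000)
  # covariances are symmetric positive definite
  for (D in fit$mode_covariances) {
    expect_lt(max(abs(D - t(D))), 1e-10)
    expect_gt(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_true(is.finite(fit$free_energy))
  expect_error(dynemo(y, 0), "n_modes")
})

test_that("overlapping bursting networks are separated into modes", {
  # two independently bursting variance patterns that frequently co-occur:
  # a mutually exclusive decomposition cannot represent this, a mixture of
  # covariances can
  set.seed(2)
  n <- 10000; d <- 10
  on1 <- sample_burst_time_course(0.98, n)
  on2 <- sample_burst_time_course(0.98, n)
  x <- matrix(rnorm(n * d, sd = 0.5), n, d)
  x[, 1:4] <- x[, 1:4] + matrix(rnorm(n * 4), n, 4) * on1 * 1.5
  x[, 5:8] <- x[, 5:8] + matrix(rnorm(n * 4), n, 4) * on2 * 1.5
  fit <- dynemo(x, n_modes = 3, n_init = 5, init_epochs = 20, n_epochs = 150,
                data_frac = 1, seed = 1)
  co <- cor(fit$alpha, cbind(on1, on2))
  # each ground-truth pattern has a dedicated mode tracking it
  m1 <- which.max(co[, 1]); m2 <- which.max(co[, 2])
  expect_true(m1 != m2)
  expect_gt(co[m1, 1], 0.7)
  expect_gt(co[m2, 2], 0.7)
  # and the matched mode covariances have elevated variance on the right
  # channels
  v1 <- diag(fit$mode_covariances[[m1]])
  v2 <- diag(fit$mode_covariances[[m2]])
  expect_true(all(v1[1:4] > v1[5:8]))
  expect_true(all(v2[5:8] > v2[1:4]))
})

test_that("time-averaged model covariance matches the data covariance", {
  set.seed(3)
  n <- 6000
  on1 <- sample_burst_time_course(0.97, n)
  x <- matrix(rnorm(n * 6, sd = 0.7), n, 6)
  x[, 1:3] <- x[, 1:3] + matrix(rnorm(n * 3), n, 3) * on1
  fit <- dynemo(x, n_modes = 2, n_init = 3, init_epochs = 10, n_epochs = 60,
                data_frac = 1, seed = 4)
  Sbar <- Reduce(`+`, lapply(seq_len(2), function(j)
    mean(fit$alpha[, j]) * fit$mode_covariances[[j]]))
  S <- cov(x)
  expect_lt(norm(Sbar - S, "F") / norm(S, "F"), 0.10)
})

test_that("alpha renormalisation follows the trace-weighting formula", {
  set.seed(4)
  J <- 4
  alpha <- matrix(rgamma(50 * J, 1), 50, J)
  alpha <- alpha / rowSums(alpha)
  covs <- lapply(c(1, 2.5, 0.3, 7), function(s) s * diag(3))
  out <- renormalise_alpha(alpha, covs)
  # direct elementwise recomputation
  tr <- vapply(covs, function(D) sum(diag(D)), 0)
  want <- sweep(alpha, 2, tr, `*`)
  want <- want / rowSums(want)
  expect_equal(out, want, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(out) - 1)), 1e-12)

  # equal traces leave alpha unchanged
  eq <- renormalise_alpha(alpha, rep(list(2 * diag(3)), J))
  expect_equal(eq, alpha, tolerance = 1e-12)

  # a vanishing-trace mode loses its weight
  covs2 <- covs; covs2[[2]] <- 1e-12 * diag(3)
  out2 <- renormalise_alpha(alpha, covs2)
  expect_lt(max(out2[, 2]), 1e-10)
})

test_that("mode-state overlap is a masked mean minus the global mean", {
  # constant alpha: all entries zero
  al <- matrix(rep(c(.2, .8), each = 20), 20, 2)
  vit <- cbind(rep(1:0, 10), rep(0:1, 10))
  expect_true(all(abs(mode_state_overlap(al, vit)) < 1e-12))
  # K = 1: row of zeros
  expect_true(all(abs(mode_state_overlap(al, matrix(1L, 20, 1))) < 1e-12))

  # constructed case: mode 1 active only with state 1
  set.seed(5)
  vit2 <- matrix(0L, 100, 2); s <- rbinom(100, 1, 0.4)
  vit2[cbind(1:100, s + 1)] <- 1L
  al2 <- cbind(ifelse(s == 0, 0.9, 0.1), ifelse(s == 0, 0.1, 0.9))
  ov <- mode_state_overlap(al2, vit2)
  expect_gt(ov[1, 1], 0)
  direct <- mean(al2[vit2[, 1] == 1, 1]) - mean(al2[, 1])
  expect_equal(ov[1, 1], direct, tolerance = 1e-12)

  # zero-occupancy state is flagged
  vit3 <- cbind(rep(1L, 20), rep(0L, 20))
  expect_warning(ov3 <- mode_state_overlap(al, vit3), "zero occupancy")
  expect_true(all(is.na(ov3[2, ])))
})

test_that("the generative model round-trips through simulate()", {
  set.seed(6)
  y <- matrix(rnorm(3000 * 4), 3000, 4)
  fit <- dynemo(y, n_modes = 2, n_init = 1, init_epochs = 2, n_epochs = 6,
                seed = 7)
  sim <- simulate(fit, nsim = 500, seed = 8)
  expect_equal(dim(sim$y), c(500, 4))
  expect_equal(dim(sim$alpha), c(500, 2))
  expect_lt(max(abs(rowSums(sim$alpha) - 1)), 1e-6)
  # deterministic under seed
  sim2 <- simulate(fit, nsim = 500, seed = 8)
  expect_identical(sim, sim2)
})

test_that("training is reproducible in the seed", {
  set.seed(9)
  y <- matrix(rnorm(2000 * 4), 2000, 4)
  f1 <- dynemo(y, 2, n_init = 2, init_epochs = 2, n_epochs = 4, seed = 3)
  f2 <- dynemo(y, 2, n_init = 2, init_epochs = 2, n_epochs = 4, seed = 3)
  expect_identical(f1$mode_covariances, f2$mode_covariances)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$free_energy, f2$free_energy)
})
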