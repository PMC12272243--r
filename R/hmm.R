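#' Fit a time-delay-embedded hidden Markov model
#'
#' Hidden Markov model with zero-mean multivariate-Gaussian observation
#' model: each state has its own covariance matrix (a functional network)
#' and exactly one state is active per sample. Applied to time-delay
#' embedded, PCA-reduced data ("TDE-HMM"), the state covariances encode
#' frequency-resolved network structure. Parameters are estimated by exact
#' expectation-maximisation (Baum-Welch with scaled forward-backward
#' messages); state covariances are regularised by adding
#' `1e-6 * mean(diag(cov)) * I` to stay positive definite.
#'
#' `n_init` seeded restarts are run for `init_epochs` EM iterations each;
#' the restart with the best objective (lowest negative log-likelihood) is
#' then trained to convergence and returned.
#'
#' @param y A `prepared_data` object (see [prepare()]) or numeric matrix
#'   (time x channels).
#' @param n_states Number of states K. Three captures the simulation study
#'   (visual, motor, background); six is typical for real source-space
#'   M/EEG data.
#' @param n_init Number of seeded restarts (default 10).
#' @param init_epochs EM iterations per restart before selection.
#' @param max_epochs EM iteration cap for the selected run.
#' @param tol Relative change in the objective declaring convergence.
#' @param seed RNG seed.
#' @return An object of class `tde_hmm`: list with `covariances` (list of
#'   K matrices), `transition` (K x K row-stochastic), `initial`,
#'   `loss_history` (per-epoch negative log-likelihood per sample), `gamma`
#'   (time x K posterior state probabilities), `viterbi` (time x K one-hot),
#'   `loglik`, `trim`, and the call configuration.
#' @export
tde_hmm <- function(y, n_states = 3, n_init = 10, init_epochs = 5,
                    max_epochs = 100, tol = 1e-6, seed = NULL) {
  trim <- 0L
  if (inherits(y, "prepared_data")) { trim <- y$trim; y <- y$y }
  y <- as.matrix(y)
  K <- as.integer(n_states)
  n <- nrow(y)
  if (K < 1L) stopf("n_states must be >= 1")
  if (K > n) stopf("n_states exceeds the number of samples")
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- hmm_em(y, K, max_epochs = init_epochs, tol = 0)
      if (is.null(best) || tail(fit$loss_history, 1) < tail(best$loss_history, 1))
        best <- fit
    }
    fit <- hmm_em(y, K, max_epochs = max_epochs, tol = tol, init = best$par)
  })
  stc <- hmm_posterior(fit$par, y)
  structure(list(
    covariances = fit$par$covs, transition = fit$par$A,
    initial = fit$par$Pi, loss_history = fit$loss_history,
    gamma = stc$gamma, viterbi = stc$viterbi, loglik = fit$loglik,
    n_states = K, n_channels = ncol(y), n_samples = n, trim = trim,
    config = list(n_init = n_init, init_epochs = init_epochs,
                  max_epochs = max_epochs, tol = tol, seed = seed)),
    class = "tde_hmm")
}

# one EM run; init = NULL draws a fresh Dirichlet responsibility matrix
hmm_em <- function(y, K, max_epochs, tol, init = NULL) {
  n <- nrow(y); d <- ncol(y)
  reg <- function(S) { S + diag(1e-6 * mean(diag(S)), d) }
  if (is.null(init)) {
    # random soft assignment (flat Dirichlet via normalised exponentials)
    g <- matrix(rgamma(n * K, shape = 1), n, K)
    g <- g / rowSums(g)
    covs <- lapply(seq_len(K), function(k) {
      w <- g[, k] / sum(g[, k])
      reg(crossprod(y * sqrt(w)))
    })
    A <- matrix(0.2 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.8 else 1
    par <- list(covs = covs, A = A, Pi = rep(1 / K, K))
  } else par <- init
  loss <- numeric(0)
  prev <- Inf
  loglik <- NA_real_
  for (ep in seq_len(max_epochs)) {
    logB <- mvn_logdens(y, par$covs)
    fb <- hmm_forward_backward(logB, par$Pi, par$A)
    if (!is.finite(fb$loglik))
      stopf("non-finite objective at EM iteration %d", ep)
    loglik <- fb$loglik
    loss <- c(loss, -loglik / n)
    g <- fb$gamma
    par$Pi <- pmax(g[1, ], 1e-12); par$Pi <- par$Pi / sum(par$Pi)
    if (K > 1) {
      A <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
      par$A <- A
    }
    par$covs <- lapply(seq_len(K), function(k) {
      w <- g[, k] / sum(g[, k])
      reg(crossprod(y * sqrt(w)))
    })
    if (is.finite(prev) && abs(prev - tail(loss, 1)) < tol * abs(prev)) break
    prev <- tail(loss, 1)
  }
  list(par = par, loss_history = loss, loglik = loglik)
}

hmm_posterior <- function(par, y) {
  logB <- mvn_logdens(y, par$covs)
  fb <- hmm_forward_backward(logB, par$Pi, par$A)
  path <- hmm_viterbi(logB, par$Pi, par$A)
  K <- length(par$Pi)
  vit <- matrix(0L, nrow(y), K)
  vit[cbind(seq_len(nrow(y)), path)] <- 1L
  list(gamma = fb$gamma, viterbi = vit)
}

#' Viterbi decoding of the most probable state path
#'
#' @param model A fitted [tde_hmm()] object.
#' @param y Numeric matrix (time x channels) with the dimensionality the
#'   model was trained on, or a `prepared_data`.
#' @return One-hot integer matrix (time x K).
#' @export
viterbi_decode <- function(model, y) {
  stopifnot(inherits(model, "tde_hmm"))
  if (inherits(y, "prepared_data")) y <- y$y
  y <- as.matrix(y)
  if (ncol(y) != model$n_channels)
    stopf("data has %d channels but the model was trained on %d",
          ncol(y), model$n_channels)
  par <- list(covs = model$covariances, A = model$transition,
              Pi = model$initial)
  hmm_posterior(par, y)$viterbi
}

#' Fractional occupancy of each state or mode
#'
#' The fraction of samples each state is active (column means of the
#' one-hot Viterbi path), or for mixing coefficients the mean coefficient.
#'
#' @param stc A `tde_hmm` fit, a one-hot/probability matrix (time x K), or a
#'   `dynemo` fit (mean mixing coefficients are returned).
#' @return Numeric vector of length K summing to 1.
#' @export
fractional_occupancy <- function(stc) {
  m <- if (inherits(stc, "tde_hmm")) stc$viterbi
       else if (inherits(stc, "dynemo")) stc$alpha
       else as.matrix(stc)
  colMeans(m)
}

#' @export
print.tde_hmm <- function(x, ...) {
  cat(sprintf("TDE-HMM: %d states, %d channels, %d samples\n",
              x$n_states, x$n_channels, x$n_samples))
  cat(sprintf("  log-likelihood: %.1f (%.4f per sample)\n",
              x$loglik, x$loglik / x$n_samples))
  fo <- fractional_occupancy(x)
  cat("  fractional occupancy:", paste(sprintf("%.3f", fo), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.tde_hmm <- function(object, ...) {
  fo <- fractional_occupancy(object)
  dwell <- vapply(seq_len(object$n_states), function(k) {
    r <- rle(object$viterbi[, k])
    lens <- r$lengths[r$values == 1L]
    if (length(lens)) mean(lens) else 0
  }, 0)
  out <- list(n_states = object$n_states,
              fractional_occupancy = fo,
              mean_lifetime_samples = dwell,
              transition = object$transition,
              loss_history = object$loss_history)
  class(out) <- "summary.tde_hmm"
  out
}

#' @export
print.summary.tde_hmm <- function(x, ...) {
  cat(sprintf("TDE-HMM with %d states\n", x$n_states))
  tab <- rbind(`fractional occupancy` = x$fractional_occupancy,
               `mean lifetime (samples)` = x$mean_lifetime_samples)
  colnames(tab) <- sprintf("state %d", seq_len(x$n_states))
  print(round(tab, 3))
  cat("Transition matrix:\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' @export
coef.tde_hmm <- function(object, ...) object$covariances

#' @export
logLik.tde_hmm <- function(object, ...) {
  K <- object$n_states; d <- object$n_channels
  df <- K * d * (d + 1) / 2 + K * (K - 1) + (K - 1)
  structure(object$loglik, df = df, nobs = object$n_samples,
            class = "logLik")
}

#' @export
predict.tde_hmm <- function(object, newdata = NULL,
                            type = c("viterbi", "gamma"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(if (type == "viterbi") object$viterbi else object$gamma)
  if (inherits(newdata, "prepared_data")) newdata <- newdata$y
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_channels)
    stopf("newdata has %d channels but the model was trained on %d",
          ncol(newdata), object$n_channels)
  par <- list(covs = object$covariances, A = object$transition,
              Pi = object$initial)
  post <- hmm_posterior(par, newdata)
  if (type == "viterbi") post$viterbi else post$gamma
}

#' Simulate data from a fitted (or hand-built) HMM
#'
#' Draws a state path from the Markov chain and zero-mean Gaussian
#' observations from the active state's covariance. Useful for
#' self-consistency checks: a model fitted to its own simulated output
#' should recover the state path.
#'
#' @param object A `tde_hmm` fit, or a list with `covariances`,
#'   `transition`, `initial`.
#' @param nsim Number of samples to draw.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return List with `y` (nsim x d matrix) and `states` (integer path).
#' @export
simulate.tde_hmm <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_hmm_data(object$covariances, object$transition, object$initial,
                    nsim, seed)
}

#' @rdname simulate.tde_hmm
#' @param covariances List of K covariance matrices.
#' @param transition K x K row-stochastic matrix.
#' @param initial Initial state distribution (default uniform).
#' @param n_samples Number of samples.
#' @export
simulate_hmm_data <- function(covariances, transition,
                              initial = NULL, n_samples = 1000, seed = NULL) {
  K <- length(covariances)
  d <- nrow(covariances[[1]])
  initial <- initial %||% rep(1 / K, K)
  with_seed(seed, {
    states <- integer(n_samples)
    states[1] <- sample.int(K, 1, prob = initial)
    for (t in seq_len(n_samples)[-1])
      states[t] <- sample.int(K, 1, prob = transition[states[t - 1], ])
    chols <- lapply(covariances, chol)
    y <- matrix(rnorm(n_samples * d), n_samples, d)
    for (k in seq_len(K)) {
      idx <- which(states == k)
      if (length(idx)) y[idx, ] <- y[idx, , drop = FALSE] %*% chols[[k]]
    }
    list(y = y, states = states)
  })
}

#' @export
plot.tde_hmm <- function(x, which = c("loss", "states"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    plot(x$loss_history, type = "l", xlab = "EM iteration",
         ylab = "negative log-likelihood / sample",
         main = "TDE-HMM training objective", ...)
  } else {
    path <- max.col(x$viterbi)
    plot(path, type = "s", xlab = "sample", ylab = "state",
         yaxt = "n", main = "Viterbi state path", ...)
    graphics::axis(2, at = seq_len(x$n_states))
  }
  invisible(x)
}
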