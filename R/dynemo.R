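#' Fit a dynamic mixture of mode covariances (DyNeMo-style model)
#'
#' Models the data as zero-mean multivariate Gaussian with a time-varying
#' covariance that is a convex mixture of J mode covariances:
#' `Sigma_t = sum_j alpha_jt D_j`, `alpha_t = softmax(theta_t)`. Unlike the
#' mutually exclusive states of an HMM, modes can overlap in time, so
#' co-activating oscillatory networks can be separated. The logits
#' `theta_t` are generated by a learned single-layer recurrent sequence
#' model conditioned on past latents; inference is amortised through a
#' second recurrent network that maps data features to the approximate
#' posterior over logits. Training maximises the evidence lower bound
#' (log-likelihood minus KL) by stochastic gradients with the KL term
#' annealed from 0 to 1 over the first part of training.
#'
#' Mixing-coefficient logits are modelled on short blocks of consecutive
#' samples (`stride`, default 5 samples = 20 ms at 250 Hz, well below
#' typical burst durations) and upsampled to sample resolution on output.
#' `n_init` seeded short runs are scored by full-data variational free
#' energy and the best run is trained to completion.
#'
#' @param y A `prepared_data` (see [prepare()]) or numeric matrix
#'   (time x channels).
#' @param n_modes Number of modes J (3 for the simulation study, 6 is
#'   typical for real data).
#' @param hidden Width of the recurrent sequence models.
#' @param stride Samples per mixing-coefficient block.
#' @param sequence_length Training sequence length in samples.
#' @param batch_size Sequences per gradient step.
#' @param n_epochs Training epochs for the selected run.
#' @param n_init Number of seeded short initialisation runs.
#' @param init_epochs Epochs per initialisation run.
#' @param lr Adam learning rate.
#' @param kl_annealing Fraction of training over which the KL weight ramps
#'   from 0 to 1.
#' @param data_frac Fraction of sequences visited per epoch (stochastic
#'   subsampling; 1 visits all data every epoch).
#' @param seed RNG seed.
#' @return An object of class `dynemo`: list with `mode_covariances`
#'   (list of J matrices), `alpha` (time x J mixing coefficients, rows on
#'   the simplex), `alpha_renorm` (trace-weighted renormalisation),
#'   `free_energy` (per-sample), `loss_history`, `params` (sequence-model
#'   weights), `trim`, and the call configuration.
#' @export
dynemo <- function(y, n_modes = 3, hidden = 64, stride = 5,
                   sequence_length = 250, batch_size = 8, n_epochs = 40,
                   n_init = 10, init_epochs = 8, lr = 0.01,
                   kl_annealing = 0.5, data_frac = 0.5, seed = NULL) {
  trim <- 0L
  if (inherits(y, "prepared_data")) { trim <- y$trim; y <- y$y }
  y <- as.matrix(y)
  J <- as.integer(n_modes)
  if (J < 1L) stopf("n_modes must be >= 1")
  n <- nrow(y)
  if (n <= J) stopf("need many more samples than modes")
  seq_blocks <- max(2L, as.integer(sequence_length / stride))
  fit <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      cand <- dynemo_core(y, J, hidden, stride, seq_blocks, batch_size,
                          init_epochs, lr, kl_annealing, data_frac, FALSE)
      if (is.null(best) || cand$free_energy < best$free_energy) best <- cand
    }
    # train the winning initialisation to completion (warm start)
    dynemo_core(y, J, hidden, stride, seq_blocks, batch_size,
                n_epochs, lr, kl_annealing, data_frac, TRUE,
                init = best$params)
  })
  alpha <- upsample_blocks(fit$alpha_blocks, fit$stride, n)
  covs <- fit$params$mode_covariances
  structure(list(
    mode_covariances = covs,
    alpha = alpha,
    alpha_renorm = renormalise_alpha(alpha, covs),
    free_energy = fit$free_energy,
    loss_history = unlist(fit$loss_history),
    params = fit$params,
    n_modes = J, n_channels = ncol(y), n_samples = n,
    stride = fit$stride, trim = trim,
    config = list(hidden = hidden, stride = stride,
                  sequence_length = sequence_length,
                  batch_size = batch_size, n_epochs = n_epochs,
                  n_init = n_init, init_epochs = init_epochs, lr = lr,
                  kl_annealing = kl_annealing, data_frac = data_frac,
                  seed = seed)),
    class = "dynemo")
}

upsample_blocks <- function(ab, stride, n) {
  full <- ab[rep(seq_len(nrow(ab)), each = stride), , drop = FALSE]
  if (nrow(full) < n)
    full <- rbind(full, full[rep(nrow(full), n - nrow(full)), , drop = FALSE])
  full[seq_len(n), , drop = FALSE]
}

#' Trace-weighted renormalisation of mixing coefficients
#'
#' The raw mixing coefficients weight covariances of very different overall
#' magnitude. Weighting each coefficient by the trace of its mode
#' covariance and renormalising to the simplex,
#' `a_jt = alpha_jt tr(D_j) / sum_k alpha_kt tr(D_k)`, expresses each
#' mode's share of the instantaneous total variance.
#'
#' @param alpha Matrix (time x J) with rows on the probability simplex.
#' @param covariances List of J mode covariance matrices.
#' @return Matrix (time x J), rows summing to 1.
#' @export
renormalise_alpha <- function(alpha, covariances) {
  alpha <- as.matrix(alpha)
  tr <- vapply(covariances, function(D) sum(diag(D)), 0)
  if (length(tr) != ncol(alpha)) stopf("need one covariance per mode")
  w <- sweep(alpha, 2, tr, `*`)
  rs <- rowSums(w)
  if (any(rs <= 0)) stopf("all-zero trace-weighted row(s): %s",
                          paste(head(which(rs <= 0)), collapse = ", "))
  w / rs
}

#' Mean renormalised mode activation within each HMM state
#'
#' For each HMM state k and mode j, the mean renormalised mixing
#' coefficient over the samples where state k is active, minus the global
#' mean — summarising how the continuous mode decomposition maps onto the
#' mutually exclusive state decomposition.
#'
#' @param alpha_renorm Matrix (time x J) of renormalised coefficients.
#' @param viterbi One-hot matrix (time x K).
#' @return Matrix (K x J). States with zero occupancy yield NA rows with a
#'   warning.
#' @export
mode_state_overlap <- function(alpha_renorm, viterbi) {
  alpha_renorm <- as.matrix(alpha_renorm)
  viterbi <- as.matrix(viterbi)
  if (nrow(alpha_renorm) != nrow(viterbi))
    stopf("time courses differ in length")
  base <- colMeans(alpha_renorm)
  K <- ncol(viterbi)
  out <- matrix(NA_real_, K, ncol(alpha_renorm))
  for (k in seq_len(K)) {
    idx <- viterbi[, k] == 1L
    if (!any(idx)) { warning(sprintf("state %d has zero occupancy", k)); next }
    out[k, ] <- colMeans(alpha_renorm[idx, , drop = FALSE]) - base
  }
  dimnames(out) <- list(sprintf("state_%d", seq_len(K)),
                        sprintf("mode_%d", seq_len(ncol(alpha_renorm))))
  out
}

#' @export
print.dynemo <- function(x, ...) {
  cat(sprintf("DyNeMo: %d modes, %d channels, %d samples\n",
              x$n_modes, x$n_channels, x$n_samples))
  cat(sprintf("  variational free energy: %.4f per sample\n", x$free_energy))
  cat("  mean mixing coefficients:",
      paste(sprintf("%.3f", colMeans(x$alpha)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.dynemo <- function(object, ...) {
  out <- list(n_modes = object$n_modes,
              mean_alpha = colMeans(object$alpha),
              mean_alpha_renorm = colMeans(object$alpha_renorm),
              traces = vapply(object$mode_covariances,
                              function(D) sum(diag(D)), 0),
              free_energy = object$free_energy)
  class(out) <- "summary.dynemo"
  out
}

#' @export
print.summary.dynemo <- function(x, ...) {
  cat(sprintf("DyNeMo with %d modes (free energy %.4f / sample)\n",
              x$n_modes, x$free_energy))
  tab <- rbind(`mean alpha` = x$mean_alpha,
               `mean renormalised alpha` = x$mean_alpha_renorm,
               `covariance trace` = x$traces)
  colnames(tab) <- sprintf("mode %d", seq_len(x$n_modes))
  print(round(tab, 3))
  invisible(x)
}

#' @export
coef.dynemo <- function(object, ...) object$mode_covariances

#' @export
plot.dynemo <- function(x, which = c("alpha", "loss"), n_show = 2000, ...) {
  which <- match.arg(which)
  if (which == "loss") {
    plot(x$loss_history, type = "l", xlab = "epoch",
         ylab = "loss (nats / sample)", main = "DyNeMo training loss", ...)
  } else {
    n <- min(n_show, nrow(x$alpha))
    graphics::matplot(seq_len(n), x$alpha[seq_len(n), ], type = "l", lty = 1,
                      xlab = "sample", ylab = "mixing coefficient",
                      main = "Mode time course", ...)
  }
  invisible(x)
}

#' Simulate data from a fitted dynamic mode mixture
#'
#' Draws logits from the learned temporal prior (recurrent sequence model
#' plus Gaussian innovations), forms `Sigma_t = sum_j alpha_jt D_j` on
#' blocks of `stride` samples, and samples zero-mean Gaussian observations.
#'
#' @param object A `dynemo` fit.
#' @param nsim Number of samples.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return List with `y` (nsim x d) and `alpha` (nsim x J).
#' @export
simulate.dynemo <- function(object, nsim = 1000, seed = NULL, ...) {
  p <- object$params
  J <- object$n_modes; d <- object$n_channels
  stride <- object$stride
  nb <- ceiling(nsim / stride)
  with_seed(seed, {
    g <- rep(0, length(p$bp)); th <- rep(0, J)
    alpha_b <- matrix(0, nb, J)
    for (b in seq_len(nb)) {
      g <- tanh(p$Wp %*% th + p$Up %*% g + p$bp)
      mu <- drop(p$Wq %*% g + p$bq)
      th <- mu + exp(p$r) * rnorm(J)
      e <- exp(th - max(th))
      alpha_b[b, ] <- e / sum(e)
    }
    chols <- lapply(p$mode_covariances, chol)
    y <- matrix(0, nb * stride, d)
    for (b in seq_len(nb)) {
      S <- Reduce(`+`, Map(`*`, p$mode_covariances, alpha_b[b, ]))
      idx <- ((b - 1) * stride + 1):(b * stride)
      y[idx, ] <- matrix(rnorm(stride * d), stride, d) %*% chol(S)
    }
    alpha <- upsample_blocks(alpha_b, stride, nsim)
    list(y = y[seq_len(nsim), , drop = FALSE], alpha = alpha)
  })
}
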