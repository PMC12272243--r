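#' Group-level permutation GLM with max-statistic familywise-error control
#'
#' Fits, per element (time point x entity, and frequency for TF data), the
#' GLM `y = X b + e` across subjects and tests the contrast of parameter
#' estimates (COPE) `c' b`. The null distribution is built
#' non-parametrically: for a one-sample design the subject contributions
#' are sign-flipped (valid under a symmetric null); for multi-regressor
#' designs the design-matrix rows are permuted. For each permutation the
#' maximum |COPE| over all tested elements is recorded, which controls the
#' familywise error rate over time, entities and frequencies jointly.
#' Two-tailed p-values are
#' `(1 + #\{null max >= |cope|\}) / (1 + n_perm)`, with the identity
#' permutation always included as the first draw.
#'
#' @param data Numeric array: subjects x elements, or subjects x time x
#'   entities (x frequencies); all dimensions after the first are treated
#'   as one family of tests.
#' @param design Design matrix (subjects x regressors); default a
#'   one-sample column of ones.
#' @param contrast Contrast vector (length regressors); default 1.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level for the returned mask.
#' @param seed RNG seed.
#' @return Object of class `permutation_result`: list with `cope`
#'   (observed COPEs, input element shape), `pvalues` (same shape),
#'   `mask` (`pvalues < alpha`), `null_max` (length n_perm), `alpha`.
#' @export
glm_max_stat_test <- function(data, design = NULL, contrast = NULL,
                              n_perm = 1000, alpha = 0.05, seed = NULL) {
  data <- as.array(data)
  dm <- dim(data)
  if (length(dm) < 2) stopf("data must be subjects x elements")
  ns <- dm[1]
  if (ns < 2) stopf("need at least 2 subjects")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  eshape <- dm[-1]
  Y <- matrix(data, nrow = ns)
  design <- design %||% matrix(1, ns, 1)
  design <- as.matrix(design)
  contrast <- contrast %||% c(1, rep(0, ncol(design) - 1))
  if (nrow(design) != ns) stopf("design has %d rows but data %d subjects", nrow(design), ns)
  if (length(contrast) != ncol(design)) stopf("contrast length must match regressors")
  if (all(contrast == 0)) stopf("contrast must be non-zero")
  if (qr(design)$rank < ncol(design)) stopf("design matrix is rank deficient")

  one_sample <- ncol(design) == 1 && all(design == design[1])
  cope_of <- function(X, Yv) {
    # c' (X'X)^-1 X' Y per element (columns of Yv)
    drop(crossprod(contrast, solve(crossprod(X), crossprod(X, Yv))))
  }
  obs <- cope_of(design, Y)

  null_max <- numeric(n_perm)
  with_seed(seed, {
    if (one_sample) {
      # sign-flipping: COPE is proportional to the flipped mean, computed
      # for all permutations in one matrix product
      S <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
      S[1, ] <- 1                       # identity permutation first
      M <- abs(S %*% Y) * abs(contrast[1] / (ns * design[1]))
      null_max <- apply(M, 1, max)
    } else {
      for (i in seq_len(n_perm)) {
        idx <- if (i == 1) seq_len(ns) else sample.int(ns)
        null_max[i] <- max(abs(cope_of(design[idx, , drop = FALSE], Y)))
      }
    }
  })
  pv <- (1 + vapply(abs(obs), function(v) sum(null_max >= v), 0L)) / (1 + n_perm)
  cope <- array(obs, eshape)
  pvalues <- array(pv, eshape)
  structure(list(cope = cope, pvalues = pvalues, mask = pvalues < alpha,
                 null_max = null_max, alpha = alpha,
                 n_perm = n_perm, one_sample = one_sample),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Max-statistic permutation GLM (%s, %d permutations)\n",
              if (x$one_sample) "sign-flip one-sample" else "design permutation",
              x$n_perm))
  cat(sprintf("  %d of %d elements significant at alpha = %g (min p = %.4g)\n",
              sum(x$mask), length(x$mask), x$alpha, min(x$pvalues)))
  invisible(x)
}

#' Condition contrasts of per-condition responses
#'
#' Per subject, the weighted sum of per-condition trial-averaged responses
#' (for example faces vs scrambled: weights +1/2, +1/2, -1 on famous,
#' unfamiliar, scrambled).
#'
#' @param responses Named list (one entry per subject) of named lists of
#'   per-condition response matrices (time x entities), or a single
#'   subject's named list.
#' @param weights Named numeric vector of condition weights.
#' @return For a single subject, a matrix; otherwise an array
#'   (subjects x time x entities).
#' @export
condition_contrast <- function(responses, weights) {
  if (is.null(names(weights))) stopf("weights must be named by condition")
  single <- all(vapply(responses, is.matrix, TRUE) |
                  vapply(responses, function(r) inherits(r, "network_response"), TRUE))
  contract_one <- function(subj) {
    miss <- setdiff(names(weights), names(subj))
    if (length(miss))
      stopf("missing condition(s): %s", paste(miss, collapse = ", "))
    out <- NULL
    for (cn in names(weights)) {
      m <- subj[[cn]]
      if (inherits(m, "network_response")) m <- m$response
      out <- if (is.null(out)) weights[[cn]] * m else out + weights[[cn]] * m
    }
    out
  }
  if (single) return(contract_one(responses))
  first <- contract_one(responses[[1]])
  out <- array(0, c(length(responses), dim(first)))
  out[1, , ] <- first
  for (s in seq_along(responses)[-1]) {
    m <- contract_one(responses[[s]])
    if (!all(dim(m) == dim(first)))
      stopf("subject %d: response dimensions differ", s)
    out[s, , ] <- m
  }
  out
}
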