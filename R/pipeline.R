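#' Analysis container: hierarchical on-disk store of pipeline products
#'
#' A pipeline run writes its products into a directory tree ("container"):
#' one sub-directory per stage, numeric arrays as TSV files, metadata and
#' provenance (stage, configuration hash, seed, package version) as JSON
#' sidecars. Everything is plain text, so containers diff and checksum
#' cleanly; re-running with an identical configuration and seed reproduces
#' the files bit for bit.
#'
#' @param path Container directory.
#' @name container
NULL

container_write <- function(path, name, value, meta = NULL) {
  dir.create(dirname(file.path(path, name)), recursive = TRUE, showWarnings = FALSE)
  f <- file.path(path, paste0(name, ".tsv"))
  m <- as.matrix(value)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(m)))
  if (!is.null(meta))
    jsonlite::write_json(meta, file.path(path, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(f)
}

container_read <- function(path, name) {
  f <- file.path(path, paste0(name, ".tsv"))
  if (!file.exists(f)) stopf("container dataset not found: %s", name)
  has_header <- length(grep("^[-0-9.]", readLines(f, n = 1))) == 0
  as.matrix(read.delim(f, header = has_header))
}

config_hash <- function(cfg) {
  # stable short hash of the deparsed configuration (provenance only)
  txt <- paste(deparse(cfg), collapse = "")
  sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 1e9
}

stage_meta <- function(stage, cfg, seed) {
  list(stage = stage, config_hash = config_hash(cfg), seed = seed,
       package_version = as.character(utils::packageVersion("burstnet")))
}

#' Run the dynamic-network analysis pipeline
#'
#' Executes the configured stages in the fixed order
#' `simulate -> prep -> hmm/dynemo -> spectra -> respond -> test`,
#' writing every product plus provenance metadata into an on-disk
#' container. Each stage consumes products of earlier stages; a stage
#' whose inputs are missing raises a dependency error naming the stage.
#'
#' The configuration is a named list (or path to a YAML file) with one
#' entry per requested stage:
#' \describe{
#'   \item{simulate}{arguments for [sim_config()].}
#'   \item{prep}{`n_lags`, `n_components`, `standardise`.}
#'   \item{hmm}{arguments for [tde_hmm()] (e.g. `n_states`).}
#'   \item{dynemo}{arguments for [dynemo()] (e.g. `n_modes`).}
#'   \item{spectra}{`window_s`, `bandwidth`, `frange`.}
#'   \item{respond}{`events` (an `event_table`, data.frame, or TSV path),
#'     `tmin`, `tmax`, `model` ("hmm" or "dynemo").}
#'   \item{test}{`n_perm`, `alpha`: one-sample group test of the
#'     responses. For a single run the "group" is the trial dimension.}
#' }
#' plus a global `seed` and optionally `data` (a matrix or `parcel_sim`
#' supplied externally instead of the simulate stage).
#'
#' @param config Named list or YAML file path.
#' @param out Container directory to create (NULL for none).
#' @return Invisibly, a list with all in-memory stage products.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stages <- intersect(c("simulate", "prep", "hmm", "dynemo", "spectra",
                        "respond", "test"),
                      names(config))
  requested <- setdiff(names(config), c("seed", "data"))
  unknown <- setdiff(requested, stages)
  if (length(unknown)) stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  res <- list(config = config, seed = seed)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[burstnet] ", msg)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
  }
  need <- function(what, from, forstage) {
    if (is.null(res[[what]]))
      stopf("stage '%s' requires the '%s' stage (missing %s)", forstage, from, what)
    res[[what]]
  }

  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # ---- data acquisition -----------------------------------------------
  if ("simulate" %in% stages) {
    say("simulate: generating bursting-network data")
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    res$sim <- simulate_parcels(cfg)
    res$x <- res$sim$x; res$fs <- res$sim$fs
    if (!is.null(out)) {
      container_write(out, "simulate/x", res$x,
                      meta = c(stage_meta("simulate", config$simulate, seed),
                               list(fs = res$fs)))
      container_write(out, "simulate/ground_truth_on", res$sim$ground_truth$on)
      container_write(out, "simulate/ground_truth_bursts",
                      res$sim$ground_truth$bursts)
    }
  } else if (!is.null(config$data)) {
    d <- config$data
    if (inherits(d, "parcel_sim")) { res$sim <- d; res$x <- d$x; res$fs <- d$fs }
    else { res$x <- as.matrix(d$x %||% d); res$fs <- d$fs %||% config$fs }
    if (is.null(res$fs)) stopf("external data needs a sampling frequency 'fs'")
  }

  # ---- preparation -----------------------------------------------------
  if ("prep" %in% stages) {
    x <- need("x", "simulate (or external data)", "prep")
    pc <- config$prep %||% list()
    say("prep: TDE +-%d lags, PCA %d", pc$n_lags %||% 2, pc$n_components %||% 120)
    res$prep <- prepare(x, n_lags = pc$n_lags %||% 2,
                        n_components = pc$n_components %||% 120,
                        standardise = pc$standardise %||% TRUE)
    if (!is.null(out)) {
      container_write(out, "prep/y", res$prep$y,
                      meta = c(stage_meta("prep", pc, seed),
                               list(trim = res$prep$trim,
                                    cumulative_explained_variance =
                                      res$prep$cumulative_explained_variance)))
    }
  }

  # ---- models ----------------------------------------------------------
  if ("hmm" %in% stages) {
    pd <- need("prep", "prep", "hmm")
    say("hmm: fitting TDE-HMM")
    res$hmm <- do.call(tde_hmm, c(list(y = pd), config$hmm,
                                  list(seed = seed + 1L)))
    if (!is.null(out)) {
      container_write(out, "hmm/gamma", res$hmm$gamma,
                      meta = stage_meta("hmm", config$hmm, seed + 1L))
      container_write(out, "hmm/viterbi", res$hmm$viterbi)
      container_write(out, "hmm/transition", res$hmm$transition)
      container_write(out, "hmm/loss_history", res$hmm$loss_history)
      for (k in seq_along(res$hmm$covariances))
        container_write(out, sprintf("hmm/covariance_%02d", k),
                        res$hmm$covariances[[k]])
    }
  }
  if ("dynemo" %in% stages) {
    pd <- need("prep", "prep", "dynemo")
    say("dynemo: fitting dynamic mode mixture")
    res$dynemo <- do.call(dynemo, c(list(y = pd), config$dynemo,
                                    list(seed = seed + 2L)))
    if (!is.null(out)) {
      container_write(out, "dynemo/alpha", res$dynemo$alpha,
                      meta = stage_meta("dynemo", config$dynemo, seed + 2L))
      container_write(out, "dynemo/alpha_renorm", res$dynemo$alpha_renorm)
      container_write(out, "dynemo/loss_history", res$dynemo$loss_history)
      for (j in seq_along(res$dynemo$mode_covariances))
        container_write(out, sprintf("dynemo/mode_covariance_%02d", j),
                        res$dynemo$mode_covariances[[j]])
    }
  }

  # ---- spectra ---------------------------------------------------------
  if ("spectra" %in% stages) {
    x <- need("x", "simulate (or external data)", "spectra")
    sc <- config$spectra %||% list()
    args <- list(fs = res$fs, window_s = sc$window_s %||% 2,
                 bandwidth = sc$bandwidth %||% 4,
                 frange = sc$frange %||% c(1, 45))
    if (!is.null(res$hmm)) {
      say("spectra: multitaper state spectra")
      g <- align_time_course(res$hmm$gamma, res$hmm$trim, nrow(x))
      res$spectra_hmm <- do.call(multitaper_state_spectra,
                                 c(list(x = x, gamma = g), args))
      # HMM maps use the first NNMF band of the stacked coherence spectra
      coh <- coherence(res$spectra_hmm)
      res$nnmf <- nnmf_bands(stack_coherence(coh), 2, seed = seed + 3L)
      res$power_hmm <- power_map(res$spectra_hmm,
                                 weights = res$nnmf$profiles[1, ])
      if (!is.null(out)) {
        container_write(out, "spectra/hmm_psd", flatten_entities(res$spectra_hmm$psd),
                        meta = c(stage_meta("spectra", sc, seed),
                                 list(freqs = res$spectra_hmm$freqs,
                                      band = "first NNMF component")))
        container_write(out, "spectra/hmm_power_map", res$power_hmm)
        container_write(out, "spectra/nnmf_profiles", res$nnmf$profiles)
      }
    }
    if (!is.null(res$dynemo)) {
      say("spectra: GLM mode spectra")
      a <- align_time_course(res$dynemo$alpha, res$dynemo$trim, nrow(x))
      res$spectra_dynemo <- do.call(glm_mode_spectra,
                                    c(list(x = x, alpha = a), args))
      # mode maps average the full computed range
      res$power_dynemo <- power_map(res$spectra_dynemo)
      if (!is.null(out)) {
        container_write(out, "spectra/dynemo_psd",
                        flatten_entities(res$spectra_dynemo$psd),
                        meta = c(stage_meta("spectra", sc, seed),
                                 list(freqs = res$spectra_dynemo$freqs,
                                      band = "full range")))
        container_write(out, "spectra/dynemo_power_map", res$power_dynemo)
      }
    }
    if (is.null(res$hmm) && is.null(res$dynemo))
      stopf("stage 'spectra' requires the 'hmm' or 'dynemo' stage")
  }

  # ---- task responses --------------------------------------------------
  if ("respond" %in% stages) {
    rc <- config$respond %||% list()
    model <- rc$model %||% if (!is.null(res$dynemo)) "dynemo" else "hmm"
    fit <- need(model, model, "respond")
    ev <- rc$events
    if (is.null(ev) && !is.null(res$sim))
      ev <- burst_onset_events(res$sim)
    if (is.character(ev)) ev <- read_events(ev)
    if (is.null(ev)) stopf("stage 'respond' requires events (or simulated ground truth)")
    say("respond: epoching %s time courses on %d events", model, nrow(ev))
    tc <- if (model == "hmm") fit$viterbi else fit$alpha
    tc <- align_time_course(tc, fit$trim, nrow(res$x))
    ep <- epoch(tc, ev, res$fs, tmin = rc$tmin %||% -0.1, tmax = rc$tmax %||% 1.0)
    res$epochs <- ep
    res$response <- network_response(ep)
    # per-condition responses when several trial types are present
    types <- unique(ep$labels)
    if (length(types) > 1) {
      res$response_by_type <- lapply(stats::setNames(types, types), function(tt) {
        sub <- ep; keep <- ep$labels == tt
        sub$data <- ep$data[keep, , , drop = FALSE]; sub$labels <- ep$labels[keep]
        network_response(sub)
      })
    }
    if (!is.null(out)) {
      container_write(out, "respond/response", res$response$response,
                      meta = c(stage_meta("respond", rc, seed),
                               list(model = model, times = res$response$times)))
    }
  }

  # ---- statistics ------------------------------------------------------
  if ("test" %in% stages) {
    tc <- config$test %||% list()
    rsp <- need("epochs", "respond", "test")
    say("test: max-statistic permutation GLM over trials")
    # single-recording runs: trials play the role of exchangeable units
    ntr <- dim(res$epochs$data)[1]
    bidx <- which(res$epochs$times >= -0.1 & res$epochs$times < 0)
    dat <- res$epochs$data
    base <- apply(dat[, bidx, , drop = FALSE], c(1, 3), mean)
    dat <- sweep(dat, c(1, 3), base)
    res$test <- glm_max_stat_test(dat, n_perm = tc$n_perm %||% 1000,
                                  alpha = tc$alpha %||% 0.05,
                                  seed = seed + 4L)
    if (!is.null(out)) {
      container_write(out, "test/pvalues", res$test$pvalues,
                      meta = stage_meta("test", tc, seed + 4L))
      container_write(out, "test/cope", res$test$cope)
      container_write(out, "test/null_max", res$test$null_max)
    }
  }

  if (!is.null(out)) {
    cfg_out <- config
    cfg_out$data <- NULL  # external arrays are not serialised into the snapshot
    jsonlite::write_json(list(config = serialisable(cfg_out), seed = seed,
                              package_version =
                                as.character(utils::packageVersion("burstnet"))),
                         file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(log_lines, file.path(out, "pipeline.log"))
  }
  invisible(res)
}

serialisable <- function(x) {
  if (is.list(x)) lapply(x, serialisable)
  else if (is.function(x)) deparse(x)
  else x
}

flatten_entities <- function(a) {
  # entities x parcels x freqs -> (entities*parcels) x freqs
  matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3])
}

stack_coherence <- function(coh) {
  # entities x p x p x f -> stacked upper-triangle rows x f, for NNMF
  K <- dim(coh)[1]; p <- dim(coh)[2]; nf <- dim(coh)[4]
  ut <- which(upper.tri(matrix(0, p, p)))
  out <- matrix(0, K * length(ut), nf)
  for (k in seq_len(K)) {
    m <- matrix(coh[k, , , ], p * p, nf)
    out[((k - 1) * length(ut) + 1):(k * length(ut)), ] <- m[ut, ]
  }
  out[is.na(out)] <- 0
  out
}

#' Events at simulated burst onsets
#'
#' Builds an event table from a simulation's ground truth with one event
#' per burst onset and the network name (optionally suffixed by the
#' low/high amplitude label) as trial type.
#'
#' @param sim A `parcel_sim`.
#' @param by_amplitude Split trial types by amplitude label.
#' @return An `event_table` (0-based onsets).
#' @export
burst_onset_events <- function(sim, by_amplitude = FALSE) {
  b <- sim$ground_truth$bursts
  tt <- if (by_amplitude) paste(b$network, b$amp_label, sep = "_") else b$network
  event_table(b$start - 1L, tt)
}
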