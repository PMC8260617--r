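# Configuration, run-container I/O and the seeded end-to-end experiment
# runner chaining protocol -> generator -> inverse -> decoder -> evaluation
# -> group statistics.

CONTAINER_SCHEMA <- "1"

#' Experiment configuration
#'
#' Bundles every tunable of the pipeline with the study defaults. All
#' deterministic stages are reproducible bit-for-bit from the config plus
#' master seed.
#'
#' @param seed Master integer seed.
#' @param n_dipoles,n_sensors,n_trials Generator sizes (defaults 500 / 64 /
#'   40 per task).
#' @param fs Raw sampling rate in Hz (default 1000).
#' @param noise_sd,evoked_amp,sensor_noise_sd,eye_gain Generator amplitudes.
#' @param reduction,ma_period,target_fs Inverse preprocessing settings.
#' @param with_extra Include extra-brain dipoles in the inverse
#'   (default TRUE).
#' @param vb \code{\link{vb_settings}}.
#' @param slir \code{\link{slir_config}} (lag embedding).
#' @param ard \code{\link{ard_settings}}.
#' @param folds Same-task cross-validation folds (default 10).
#' @param n_perm Permutations for significance testing (default 999).
#' @param alpha FDR level (default 0.05).
#' @param normalization Normalization denominator, "test" or "train".
#' @param n_blocks Pseudo-subject blocks for the group statistics stage
#'   (default 4).
#' @param tasks Tasks to simulate (default all five).
#' @return Object of class \code{run_config} (a named list).
#' @export
run_config <- function(seed = 1L, n_dipoles = 500, n_sensors = 64,
                       n_trials = 40, fs = 1000, noise_sd = 10,
                       evoked_amp = 30, sensor_noise_sd = NULL,
                       eye_gain = 60, reduction = 4L, ma_period = 9L,
                       target_fs = 200, with_extra = TRUE,
                       vb = vb_settings(), slir = slir_config(),
                       ard = ard_settings(), folds = 10L, n_perm = 999L,
                       alpha = 0.05, normalization = "test",
                       n_blocks = 4L, tasks = PURSUIT_TASKS) {
  structure(
    list(seed = as.integer(seed), n_dipoles = n_dipoles,
         n_sensors = n_sensors, n_trials = n_trials, fs = fs,
         noise_sd = noise_sd, evoked_amp = evoked_amp,
         sensor_noise_sd = sensor_noise_sd, eye_gain = eye_gain,
         reduction = reduction, ma_period = ma_period,
         target_fs = target_fs, with_extra = with_extra, vb = vb,
         slir = slir, ard = ard, folds = folds, n_perm = n_perm,
         alpha = alpha, normalization = normalization,
         n_blocks = n_blocks, tasks = tasks),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A \code{run_config}.
#' @param path File path.
#' @return \code{path} invisibly / the restored \code{run_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$slir <- do.call(slir_config,
                      cfg$slir[c("tau", "dtau", "tpred", "fs")])
  structure(cfg, class = "run_config")
}

#' Write a structured run container
#'
#' The container is a versioned directory: a JSON manifest naming the
#' schema version and stored groups, plus one serialized payload per group.
#'
#' @param path Container directory (created if missing).
#' @param data Named list of group payloads (e.g. \code{protocol},
#'   \code{sensors}, \code{inverse}, \code{models}, \code{evaluation},
#'   \code{stats}).
#' @param config Optional \code{run_config} stored alongside.
#' @return \code{path}, invisibly.
#' @export
write_container <- function(path, data, config = NULL) {
  if (is.null(names(data)) || any(names(data) == ""))
    stop("'data' must be a fully named list of groups", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (g in names(data))
    saveRDS(data[[g]], file.path(path, paste0(g, ".rds")))
  manifest <- list(schema_version = CONTAINER_SCHEMA,
                   groups = as.list(names(data)),
                   created = format(Sys.time(), tz = "UTC"))
  if (!is.null(config)) {
    manifest$config_yaml <- yaml::as.yaml(unclass(config))
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run container
#'
#' @param path Container directory.
#' @param allow_partial Tolerate missing groups (e.g. a truncated run);
#'   missing groups are flagged instead of raising an error.
#' @return Named list of group payloads with attributes \code{config_yaml}
#'   (if stored) and \code{missing_groups}.
#' @export
read_container <- function(path, allow_partial = FALSE) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("not a run container (no manifest): ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$schema_version), CONTAINER_SCHEMA))
    stop("unknown container schema version: ", manifest$schema_version,
         call. = FALSE)
  groups <- unlist(manifest$groups)
  out <- list(); missing <- character(0)
  for (g in groups) {
    f <- file.path(path, paste0(g, ".rds"))
    if (file.exists(f)) out[[g]] <- readRDS(f)
    else if (allow_partial) missing <- c(missing, g)
    else stop("container group missing: ", g, call. = FALSE)
  }
  attr(out, "config_yaml") <- manifest$config_yaml
  attr(out, "missing_groups") <- missing
  out
}

#' Run the full experiment chain
#'
#' Executes protocol generation, the current/artifact/sensor simulation,
#' preprocessing and source estimation, per-task decoding, the cross-task
#' generalization matrix with permutation significance, and regional
#' group statistics, writing a run container and returning the results.
#' Stage failures abort with the stage name.
#'
#' @param config A \code{\link{run_config}}.
#' @param container Optional path for the run container (NULL: not
#'   written).
#' @param verbose Log stage progress and wall times (default TRUE).
#' @return List with \code{config}, \code{protocol}, \code{dataset}
#'   (generator output), \code{inverse}, \code{region_stats},
#'   \code{models}, \code{generalization}, \code{significance},
#'   \code{selection}, \code{stats}, \code{timings}.
#' @export
run_experiment <- function(config = run_config(), container = NULL,
                           verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage %-10s %6.1f s", name, timings[[name]])
    out
  }
  seed <- config$seed

  protocol <- stage("protocol", make_protocol(config$n_trials, seed = seed))
  dataset <- stage("simulate", simulate_dataset(
    tasks = config$tasks, n_trials = config$n_trials, fs = config$fs,
    seed = seed, evoked_amp = config$evoked_amp,
    noise_sd = config$noise_sd, sensor_noise_sd = config$sensor_noise_sd,
    eye_gain = config$eye_gain, n_dipoles = config$n_dipoles,
    n_sensors = config$n_sensors))

  inverse <- stage("inverse", {
    pre <- preprocess(dataset$trials, ma_period = config$ma_period,
                      target_fs = config$target_fs)
    smoothing <- build_smoothing(dataset$space, dataset$fm,
                                 reduction = config$reduction)
    sol <- estimate_currents(pre, smoothing, dataset$fm$G_extra,
                             prior = region_prior(dataset$space, smoothing),
                             with_extra = config$with_extra,
                             vb = config$vb)
    list(smoothing = smoothing, solution = sol)
  })

  rstats <- stage("regions", region_stats(
    inverse$solution, dataset$space, inverse$smoothing))

  # Decode from the reduced currents (the estimation's working variables).
  dec <- config$fs %/% config$target_fs
  decode_data <- stage("decode", {
    traj <- lapply(dataset$trajectories, function(tr) {
      keep <- seq(1L, length(tr$time), by = dec)
      tr$time <- tr$time[keep]; tr$position <- tr$position[keep]
      tr$velocity <- tr$velocity[keep]; tr$fs <- config$target_fs
      tr
    })
    currents <- lapply(stats::setNames(config$tasks, config$tasks),
                       function(task) {
                         idx <- which(inverse$solution$task == task)
                         lapply(idx, function(i) inverse$solution$Z[[i]])
                       })
    list(currents = currents, trajectories = traj)
  })
  models <- stage("models", lapply(
    stats::setNames(config$tasks, config$tasks), function(task)
      fit_decoder(decode_data$currents[[task]],
                  decode_data$trajectories[[task]],
                  cfg = config$slir, ard = config$ard)))
  gen <- stage("evaluate", build_generalization_matrix(
    decode_data, cfg = config$slir, ard = config$ard,
    folds = config$folds, seed = child_seed(seed, 11)))

  signif <- stage("significance", {
    cells <- unique(gen[, c("train", "test")])
    ps <- mapply(function(train, test) {
      model <- models[[train]]
      traj <- decode_data$trajectories[[test]]
      preds <- lapply(decode_data$currents[[test]], function(J)
        predict(model, J))
      rows <- preds[[1]]$rows_time
      permutation_test(
        truth = rep(list(traj$position[rows]), length(preds)),
        pred = lapply(preds, `[[`, "position"),
        n_perm = config$n_perm,
        seed = child_seed(seed, 23))$p
    }, cells$train, cells$test)
    cells$p <- as.numeric(ps)
    bh <- bh_correct(cells$p, alpha = config$alpha)
    cells$p_adj <- bh$adjusted
    cells$significant <- bh$rejected
    cells
  })

  selection <- stage("selection", selection_report(
    models, dataset$space,
    dipole_idx = inverse$smoothing$reduced_idx))

  stats_out <- stage("stats", {
    # Pseudo-subject blocks: trials of each task split into n_blocks groups,
    # per-block regional mean currents, one-way block ANOVA per region.
    sol <- inverse$solution
    per_trial <- t(sapply(seq_along(sol$Z), function(i)
      vapply(split(seq_len(dataset$space$n_dipoles), dataset$space$region),
             function(ix) mean(abs(cortical_currents(
               sol, inverse$smoothing, i)[ix, ])), 0)))
    tasks <- sol$task
    res <- list()
    for (region in CORTICAL_REGIONS) {
      vals <- c(); blk <- c(); tk <- c()
      for (task in config$tasks) {
        idx <- which(tasks == task)
        bid <- cut(seq_along(idx), config$n_blocks, labels = FALSE)
        m <- tapply(per_trial[idx, region], bid, mean)
        vals <- c(vals, m); blk <- c(blk, seq_len(config$n_blocks))
        tk <- c(tk, rep(task, config$n_blocks))
      }
      res[[region]] <- rb_anova1(block_design(vals, blk, tk))
    }
    res
  })

  results <- list(config = config, protocol = protocol,
                  dataset = dataset, inverse = inverse,
                  region_stats = rstats, models = models,
                  generalization = gen, significance = signif,
                  selection = selection, stats = stats_out,
                  timings = timings)
  if (!is.null(container))
    write_container(container, list(
      protocol = protocol,
      truth = dataset$truth,
      sensors = dataset$trials,
      inverse = inverse,
      models = models,
      evaluation = list(generalization = gen, significance = signif,
                        selection = selection),
      stats = stats_out), config = config)
  results
}

#' Export a generalization matrix as CSV
#'
#' @param gen A \code{generalization_matrix} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_generalization_csv <- function(gen, path) {
  utils::write.csv(as.data.frame(gen), path, row.names = FALSE)
  invisible(path)
}
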