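# Evaluation machinery: cross-validation, cross-task generalization,
# correlation/determination coefficients, normalization and classification,
# permutation tests with FDR control, shared-dipole categorization, and the
# current-to-target lag sweep.

#' Split trials into balanced cross-validation folds
#'
#' @param n_trials Number of trials (or a \code{trial_set}).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed; folds are deterministic for a fixed seed.
#' @return List of \code{folds} disjoint index vectors whose union is
#'   \code{1:n_trials}; fold sizes differ by at most one.
#' @export
tenfold_split <- function(n_trials, folds = 10L, seed = 1L) {
  if (inherits(n_trials, "trial_set")) n_trials <- length(n_trials$trials)
  if (n_trials < folds)
    stop("need at least ", folds, " trials for ", folds, "-fold splitting",
         call. = FALSE)
  rng <- local_rng(seed)
  fold_id <- rng$sample(rep(seq_len(folds), length.out = n_trials))
  split(seq_len(n_trials), fold_id)
}

#' Pearson correlation between a true and predicted series
#'
#' Evaluates temporal shape similarity only; invariant to affine rescaling
#' of the prediction.
#'
#' @param truth,pred Equal-length numeric series (length >= 3).
#' @return Correlation coefficient in [-1, 1].
#' @export
correlation_coefficient <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 3)
    stop("series must have equal length >= 3", call. = FALSE)
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0)
    stop("correlation undefined for a zero-variance series", call. = FALSE)
  stats::cor(truth, pred)
}

#' Coefficient of determination between a true and predicted series
#'
#' \code{R2 = 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)}.
#' Sensitive to both temporal shape and amplitude; unbounded below.
#'
#' @param truth,pred Equal-length numeric series (length >= 3).
#' @return Determination coefficient (<= 1, may be negative).
#' @export
determination_coefficient <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 3)
    stop("series must have equal length >= 3", call. = FALSE)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0)
    stop("determination undefined for a zero-variance true series",
         call. = FALSE)
  1 - sum((truth - pred)^2) / sst
}

# Per-trial coefficients of a fitted decoder on a list of test trials.
.score_trials <- function(model, trials, trajectory) {
  pos <- list(); vel <- list(); r <- NULL
  for (i in seq_along(trials)) {
    pr <- predict(model, trials[[i]])
    rows <- pr$rows_time
    pos[[i]] <- pr$position
    vel[[i]] <- pr$velocity
    if (is.null(r)) r <- rows
  }
  y_pos <- trajectory$position[r]
  y_vel <- trajectory$velocity[r]
  data.frame(
    trial = seq_along(trials),
    r_position = vapply(pos, function(p) correlation_coefficient(y_pos, p), 0),
    r_velocity = vapply(vel, function(p) correlation_coefficient(y_vel, p), 0),
    R2_position = vapply(pos, function(p)
      determination_coefficient(y_pos, p), 0),
    R2_velocity = vapply(vel, function(p)
      determination_coefficient(y_vel, p), 0))
}

#' Cross-task generalization matrix for one replicate
#'
#' Same-task cells are scored by k-fold cross-validation (train on k-1
#' folds, score the held-out trials); different-task cells train on every
#' trial of the training task and score every trial of the test task.
#' Coefficients are computed per test trial and then averaged.
#'
#' @param dataset Output of \code{\link{simulate_current_dataset}} or any
#'   list with \code{currents} (per task, list of dipoles x samples
#'   matrices) and \code{trajectories} (per task).
#' @param cfg A \code{\link{slir_config}} matching the current sampling
#'   rate.
#' @param ard \code{\link{ard_settings}}.
#' @param folds Cross-validation folds for the diagonal (default 10).
#' @param seed Integer seed (fold assignment).
#' @param keep_predictions Keep per-trial true/predicted series for
#'   permutation testing (default FALSE).
#' @return Data frame of class \code{generalization_matrix}: columns
#'   \code{train}, \code{test}, \code{regressand}, \code{r}, \code{R2},
#'   \code{n_trials}; with \code{keep_predictions}, attribute
#'   \code{predictions}.
#' @export
build_generalization_matrix <- function(dataset, cfg = slir_config(),
                                        ard = ard_settings(),
                                        folds = 10L, seed = 1L,
                                        keep_predictions = FALSE) {
  tasks <- names(dataset$currents)
  if (is.null(tasks) || length(tasks) < 2)
    stop("'dataset' must carry named per-task current trials",
         call. = FALSE)
  preds <- list()
  out <- NULL

  # Per-task fold assignment and fold-level sufficient statistics; any
  # training set (all folds, or all-but-one) is a sum of fold statistics.
  per_task <- lapply(stats::setNames(tasks, tasks), function(task) {
    trials <- dataset$currents[[task]]
    traj <- dataset$trajectories[[task]]
    fold_idx <- tenfold_split(length(trials), folds = folds,
                              seed = child_seed(seed, match(task, tasks)))
    fold_stats <- lapply(fold_idx, function(f)
      .sum_stats(lapply(trials[f], .trial_stats, trajectory = traj,
                        cfg = cfg)))
    list(trials = trials, traj = traj, fold_idx = fold_idx,
         fold_stats = fold_stats, total = .sum_stats(fold_stats))
  })
  full_models <- lapply(per_task, function(pt)
    structure(list(position = .fit_from_stats(pt$total, "position", ard),
                   velocity = .fit_from_stats(pt$total, "velocity", ard),
                   scaling = .stats_scaling(pt$total), cfg = cfg),
              class = "decoding_model"))

  for (train in tasks) {
    for (test in tasks) {
      pt <- per_task[[test]]
      if (train == test) {
        sc <- NULL
        for (k in seq_along(pt$fold_idx)) {
          st <- .sum_stats(pt$fold_stats[-k])
          m <- structure(
            list(position = .fit_from_stats(st, "position", ard),
                 velocity = .fit_from_stats(st, "velocity", ard),
                 scaling = .stats_scaling(st), cfg = cfg),
            class = "decoding_model")
          sc <- rbind(sc, .score_trials(m, pt$trials[pt$fold_idx[[k]]],
                                        pt$traj))
        }
      } else {
        sc <- .score_trials(full_models[[train]], pt$trials, pt$traj)
      }
      for (reg in c("position", "velocity"))
        out <- rbind(out, data.frame(
          train = train, test = test, regressand = reg,
          r = mean(sc[[paste0("r_", reg)]]),
          R2 = mean(sc[[paste0("R2_", reg)]]),
          n_trials = nrow(sc)))
      if (keep_predictions)
        preds[[paste(train, test, sep = "->")]] <- sc
    }
  }
  class(out) <- c("generalization_matrix", "data.frame")
  attr(out, "models") <- full_models
  if (keep_predictions) attr(out, "predictions") <- preds
  out
}

#' Normalize generalization scores by the same-task value
#'
#' Per replicate, each cell's score is divided by the same-task score of
#' (by default) the test task, then averaged across replicates. The
#' same-task diagonal is therefore 1.00 with SD 0.00.
#'
#' @param replicates List of \code{generalization_matrix} data frames (one
#'   per replicate/participant).
#' @param value Column to normalize: "R2" (default) or "r".
#' @param mode Denominator: \code{"test"} (the test task's own diagonal,
#'   default) or \code{"train"} (the training task's diagonal).
#' @param pool_regressands Average position and velocity coefficients
#'   before summarizing (default TRUE, the summary-table convention).
#' @return Data frame with columns \code{train}, \code{test}, (optionally
#'   \code{regressand},) \code{mean}, \code{sd}, \code{normalized_mean},
#'   \code{normalized_sd}, \code{n_replicates}.
#' @export
normalize_scores <- function(replicates, value = "R2",
                             mode = c("test", "train"),
                             pool_regressands = TRUE) {
  mode <- match.arg(mode)
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  per_rep <- lapply(replicates, function(m) {
    m <- as.data.frame(m)
    m$value <- m[[value]]
    diag_key <- if (mode == "test") m$test else m$train
    dv <- m$value[m$train == m$test]
    names(dv) <- paste(m$train[m$train == m$test],
                       m$regressand[m$train == m$test])
    denom <- dv[paste(diag_key, m$regressand)]
    bad <- !is.finite(denom) | denom == 0
    if (any(bad)) {
      warning("replicate excluded for cells with zero same-task score")
      m <- m[!bad, , drop = FALSE]
      denom <- denom[!bad]
    }
    m$normalized <- m$value / denom
    m
  })
  all <- do.call(rbind, Map(function(m, i) {
    m$replicate <- i
    m
  }, per_rep, seq_along(per_rep)))
  keys <- if (pool_regressands) c("train", "test")
          else c("train", "test", "regressand")
  # Pool within replicate first (position & velocity of the same cell),
  # then take mean/SD across replicates.
  pooled <- stats::aggregate(all[c("value", "normalized")],
                             all[c(keys, "replicate")], FUN = mean)
  res <- stats::aggregate(pooled[c("value", "normalized")], pooled[keys],
                          FUN = mean)
  sds <- stats::aggregate(pooled[c("value", "normalized")], pooled[keys],
                          FUN = stats::sd)
  nrep <- stats::aggregate(pooled$replicate, pooled[keys], FUN = length)
  out <- res
  names(out)[names(out) == "value"] <- "mean"
  names(out)[names(out) == "normalized"] <- "normalized_mean"
  out$sd <- sds$value
  out$normalized_sd <- sds$normalized
  out$n_replicates <- nrep$x
  out$sd[is.na(out$sd)] <- 0
  out$normalized_sd[is.na(out$normalized_sd)] <- 0
  out
}

#' Classify a normalized generalization score
#'
#' High for scores >= 0.6, middle for [0.2, 0.6), low below 0.2 (the
#' circle / triangle / cross convention of the summary table).
#'
#' @param x Finite numeric (vectorized).
#' @return Character vector in \{"high", "middle", "low"\}.
#' @export
classify_generalization <- function(x) {
  if (any(!is.finite(x)))
    stop("normalized scores must be finite", call. = FALSE)
  ifelse(x >= 0.6, "high", ifelse(x >= 0.2, "middle", "low"))
}

#' Trial-permutation test for decoding accuracy
#'
#' The observed statistic is the mean over trials of
#' \code{statistic(true_i, pred_i)}. The null distribution permutes the
#' trial correspondence between true and predicted series and applies a
#' seeded circular shift within each trial, preserving each series'
#' autocorrelation. \code{p = (1 + #\{null >= observed\}) / (1 + n_perm)}.
#'
#' @param truth,pred Lists of equal-length numeric series, one per trial
#'   (>= 2 trials).
#' @param statistic Function of (truth, pred), e.g.
#'   \code{\link{correlation_coefficient}}.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with \code{p}, \code{observed}, \code{null} (the permuted
#'   statistics).
#' @export
permutation_test <- function(truth, pred,
                             statistic = correlation_coefficient,
                             n_perm = 999L, seed = 1L) {
  n <- length(truth)
  if (n < 2 || length(pred) != n)
    stop("need >= 2 paired trials", call. = FALSE)
  if (n_perm < 100) stop("'n_perm' must be >= 100", call. = FALSE)
  if (factorial(min(n, 100)) < 100)
    warning("few trials: permutations are not all distinct")
  rng <- local_rng(seed)
  obs <- mean(mapply(statistic, truth, pred))
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- rng$sample(n)
    mean(vapply(seq_len(n), function(i) {
      p <- pred[[perm[i]]]
      k <- rng$sample(length(p), 1L)
      statistic(truth[[i]], c(p[-seq_len(k)], p[seq_len(k)]))
    }, 0))
  }, 0)
  list(p = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
       null = null)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure at level \code{alpha}; adjusted p-values are monotone
#' non-decreasing in rank.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return List with \code{adjusted} (BH-adjusted p-values) and
#'   \code{rejected} (logical flags at level \code{alpha}).
#' @export
bh_correct <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

#' Categorize dipoles shared across task-specific selections
#'
#' Every dipole selected by at least one task falls in exactly one
#' category: exclusive to a single task; shared by exactly the two covert
#' tasks; by exactly the two overt tasks; by exactly the covert and overt
#' task of one frequency; by three or more tasks; or (residual) by another
#' two-task combination (e.g. control plus one pursuit task). Fractions are
#' over the union of all selections.
#'
#' @param sets Named list of 5 integer vectors (selected dipoles per task,
#'   names from \code{\link{PURSUIT_TASKS}}).
#' @return Data frame with columns \code{category}, \code{count},
#'   \code{fraction}; attribute \code{shared_fraction} gives the fraction
#'   selected by two or more tasks.
#' @export
categorize_shared_dipoles <- function(sets) {
  if (!setequal(names(sets), PURSUIT_TASKS))
    stop("'sets' must be named by the five tasks", call. = FALSE)
  sets <- sets[PURSUIT_TASKS]
  universe <- sort(unique(unlist(sets)))
  cats <- c(paste0("exclusive-", PURSUIT_TASKS), "covert-shared",
            "overt-shared", "0.5Hz-shared", "0.8Hz-shared",
            "two-task-other", ">=3-tasks-shared")
  counts <- stats::setNames(integer(length(cats)), cats)
  for (d in universe) {
    members <- PURSUIT_TASKS[vapply(sets, function(s) d %in% s, TRUE)]
    cat_d <- if (length(members) == 1) paste0("exclusive-", members)
    else if (length(members) >= 3) ">=3-tasks-shared"
    else if (setequal(members, c("covert_0.5", "covert_0.8"))) "covert-shared"
    else if (setequal(members, c("overt_0.5", "overt_0.8"))) "overt-shared"
    else if (setequal(members, c("covert_0.5", "overt_0.5"))) "0.5Hz-shared"
    else if (setequal(members, c("covert_0.8", "overt_0.8"))) "0.8Hz-shared"
    else "two-task-other"
    counts[cat_d] <- counts[cat_d] + 1L
  }
  n <- max(length(universe), 1L)
  out <- data.frame(category = cats, count = as.integer(counts),
                    fraction = as.numeric(counts) / n)
  attr(out, "shared_fraction") <-
    sum(counts[!startsWith(cats, "exclusive-")]) / n
  out
}

#' Correlation profile over current-to-target time lags
#'
#' For each lag on the grid the decoder is refit with the currents shifted
#' relative to the target (negative lags mean the currents precede the
#' target) and evaluated on held-out trials; returns the correlation
#' profile and its argmax. A single-tap decoder (dtau = 0) is used so the
#' profile reflects the intrinsic current-to-target delay rather than the
#' embedding window.
#'
#' @param trials List of dipoles x samples current matrices.
#' @param trajectory The \code{target_trajectory} on the same grid.
#' @param lags_ms Numeric grid of lags in ms (within the epoch bounds).
#' @param fs Sampling rate in Hz.
#' @param train_fraction Fraction of trials used for fitting (default 0.5).
#' @param ard \code{\link{ard_settings}}.
#' @param regressand "position" (default) or "velocity".
#' @param seed Integer seed for the train/test split.
#' @return Data frame of \code{lag_ms}, \code{r}; attribute \code{argmax}
#'   holds the lag with maximal correlation.
#' @export
lag_sweep <- function(trials, trajectory, lags_ms = seq(-400, 400, by = 25),
                      fs = trajectory$fs, train_fraction = 0.5,
                      ard = ard_settings(), regressand = "position",
                      seed = 1L) {
  S <- ncol(trials[[1]])
  if (S != length(trajectory$time))
    stop("trials and trajectory must share the sample grid", call. = FALSE)
  shifts <- round(lags_ms * fs / 1000)
  if (any(abs(shifts) >= S))
    stop("lag grid exceeds the epoch bounds", call. = FALSE)
  rng <- local_rng(seed)
  n <- length(trials)
  tr_idx <- sort(rng$sample(n, max(1L, round(train_fraction * n))))
  te_idx <- setdiff(seq_len(n), tr_idx)
  if (length(te_idx) == 0) te_idx <- tr_idx
  y_full <- trajectory[[regressand]]

  r_of_lag <- vapply(shifts, function(k) {
    # Pair target sample t with currents at sample t + k.
    t_idx <- seq_len(S)
    keep <- t_idx + k >= 1 & t_idx + k <= S
    X <- do.call(rbind, lapply(trials[tr_idx], function(J)
      t(J[, t_idx[keep] + k, drop = FALSE])))
    y <- rep(y_full[t_idx[keep]], length(tr_idx))
    fit <- fit_slir(X, y, groups = seq_len(nrow(trials[[1]])), ard = ard)
    mean(vapply(trials[te_idx], function(J) {
      Xt <- t(J[, t_idx[keep] + k, drop = FALSE])
      pred <- drop(Xt %*% fit$weights) + fit$w0
      if (stats::sd(pred) == 0) return(0)
      stats::cor(y_full[t_idx[keep]], pred)
    }, 0))
  }, 0)
  out <- data.frame(lag_ms = lags_ms, r = r_of_lag)
  attr(out, "argmax") <- lags_ms[which.max(r_of_lag)]
  out
}
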