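# Sparse linear regression (SLiR) decoder: temporal lag embedding with
# grouped automatic relevance determination on the spatial dimension only.
#
# Target kinematics at time t are regressed on the currents of every input
# dipole at dtau+1 lags spaced tau samples apart starting tpred samples
# back; a dipole's lag weights share one relevance hyperparameter, so
# sparsity acts on dipoles, never on time.

#' SLiR decoder configuration
#'
#' With the defaults at 200 Hz the lag set is \code{tpred + tau * (0:dtau)}
#' = \{1, 7, ..., 61\} samples, i.e. 11 taps spanning 5 ms to 305 ms before
#' the predicted time point.
#'
#' @param tau Lag spacing in samples of the (resampled) grid (default 6).
#' @param dtau Number of additional lag steps (default 10, giving
#'   \code{dtau + 1} taps).
#' @param tpred Prediction offset in samples (default 1, i.e. 5 ms at
#'   200 Hz).
#' @param fs Sampling rate of the current series in Hz (default 200).
#' @return Object of class \code{slir_config} with the derived \code{lags}
#'   (samples) and \code{lags_ms}.
#' @export
slir_config <- function(tau = 6L, dtau = 10L, tpred = 1L, fs = 200) {
  stopifnot(tau >= 1, dtau >= 0, tpred >= 1, fs > 0)
  lags <- as.integer(tpred + tau * (0:dtau))
  structure(list(tau = as.integer(tau), dtau = as.integer(dtau),
                 tpred = as.integer(tpred), fs = fs, lags = lags,
                 lags_ms = 1000 * lags / fs),
            class = "slir_config")
}

#' Lagged design matrix
#'
#' Row \code{t} holds \code{J_i(t - lag)} for every dipole \code{i} and lag
#' in the config's lag set; rows with incomplete history are dropped.
#' Columns are dipole-major (all lags of dipole 1, then dipole 2, ...).
#'
#' @param currents Matrix dipoles x samples.
#' @param cfg A \code{\link{slir_config}}.
#' @return Matrix (samples - max lag) x (dipoles * (dtau + 1)) with
#'   attributes \code{groups} (dipole index per column) and \code{rows_time}
#'   (the sample index each row predicts).
#' @export
embed_lags <- function(currents, cfg) {
  stopifnot(inherits(cfg, "slir_config"), is.matrix(currents))
  D <- nrow(currents); S <- ncol(currents)
  L <- length(cfg$lags); maxlag <- max(cfg$lags)
  if (S <= maxlag)
    stop("epoch shorter than the maximum lag (", maxlag, " samples)",
         call. = FALSE)
  rows <- (maxlag + 1L):S
  arr <- array(0, dim = c(length(rows), L, D))
  for (j in seq_len(L))
    arr[, j, ] <- t(currents[, rows - cfg$lags[j], drop = FALSE])
  X <- matrix(arr, nrow = length(rows))
  attr(X, "groups") <- rep(seq_len(D), each = L)
  attr(X, "rows_time") <- rows
  X
}

#' ARD settings for SLiR fitting
#'
#' @param max_iter Maximum relevance-update iterations (default 300).
#' @param tol Relative tolerance on the marginal-likelihood objective
#'   (default 1e-8).
#' @param a0,b0 Gamma hyperprior shape/rate on the group precisions
#'   (default shape 1, rate 0: an improper exponential-shape hyperprior
#'   that promotes pruning of marginally relevant dipoles; plain type-II
#'   maximum likelihood keeps chance-level inputs).
#' @param prune_ratio Groups whose relevance-implied prior variance falls
#'   below \code{prune_ratio} times the largest group's are pruned to exact
#'   zero (default 1e-8).
#' @param update_relevance Update the per-group relevances (default TRUE).
#'   FALSE with a fixed \code{alpha_init} gives ridge regression.
#' @param update_noise Update the noise variance (default TRUE).
#' @param alpha_init Initial (or fixed) group precision (default 1).
#' @param sigma2_init Initial (or fixed) noise variance; default one tenth
#'   of the target variance.
#' @return List of settings.
#' @export
ard_settings <- function(max_iter = 300L, tol = 1e-8, a0 = 1, b0 = 0,
                         prune_ratio = 1e-8, update_relevance = TRUE,
                         update_noise = TRUE, alpha_init = 1,
                         sigma2_init = NULL) {
  list(max_iter = as.integer(max_iter), tol = tol, a0 = a0, b0 = b0,
       prune_ratio = prune_ratio, update_relevance = update_relevance,
       update_noise = update_noise, alpha_init = alpha_init,
       sigma2_init = sigma2_init)
}

#' Fit a sparse linear regression decoder
#'
#' Evidence-maximization (type-II maximum likelihood) for a linear model
#' with a Gaussian group prior: all \code{dtau + 1} lag weights of a dipole
#' share one relevance hyperparameter with a gamma hyperprior, so dipoles
#' are kept or removed as units. Irrelevant groups' prior variances
#' collapse; groups below the pruning threshold are fixed at exactly zero
#' and removed from subsequent updates. The intercept is unpenalized
#' (handled by centring).
#'
#' @param design Design matrix from \code{\link{embed_lags}} (or any matrix
#'   with a \code{groups} attribute / \code{groups} argument).
#' @param target Numeric regressand aligned with the design rows.
#' @param groups Integer group (dipole) index per column; defaults to the
#'   design's \code{groups} attribute.
#' @param ard \code{\link{ard_settings}}.
#' @return Object of class \code{slir_model}: \code{weights} (full-length,
#'   pruned groups exactly zero), \code{w0}, \code{relevance} (prior
#'   variance per group), \code{selected} (group ids with nonzero weights),
#'   \code{groups}, \code{sigma2}, \code{trace}, \code{iterations},
#'   \code{converged}, and the centring constants.
#' @export
fit_slir <- function(design, target, groups = attr(design, "groups"),
                     ard = ard_settings()) {
  if (is.null(groups)) stop("'design' needs a group index", call. = FALSE)
  if (nrow(design) != length(target))
    stop("design rows and target length differ", call. = FALSE)
  if (anyNA(design) || anyNA(target))
    stop("missing values in design or target", call. = FALSE)
  stats <- list(H = crossprod(design),
                colsum = colSums(design),
                Xty = drop(crossprod(design, target)),
                ysum = sum(target), yss = sum(target^2),
                n = nrow(design))
  .slir_from_stats(stats, groups, ard, scale = NULL)
}

# Fit from raw (uncentred, unscaled) sufficient statistics. Centring and
# optional per-dipole standardization are applied algebraically, the ARD
# core runs in the transformed space, and the returned weights are mapped
# back to the raw input scale (so prediction needs no transformation).
.slir_from_stats <- function(stats, groups, ard, scale = NULL) {
  p <- length(stats$colsum)
  n <- stats$n
  y_center <- stats$ysum / n
  yty <- stats$yss - n * y_center^2
  col_center <- stats$colsum / n
  if (yty <= 0) {
    # Degenerate regressand: intercept-only model.
    return(structure(
      list(weights = numeric(p), w0 = y_center,
           relevance = stats::setNames(numeric(length(unique(groups))),
                                       sort(unique(groups))),
           selected = integer(0), groups = groups, sigma2 = 0,
           trace = numeric(0), iterations = 0L, converged = TRUE,
           col_center = col_center, y_center = y_center),
      class = "slir_model"))
  }
  H <- stats$H - n * tcrossprod(col_center)
  Xty <- stats$Xty - col_center * stats$ysum
  col_scale <- if (is.null(scale)) rep(1, p) else scale
  if (!is.null(scale)) {
    H <- H / tcrossprod(col_scale)
    Xty <- Xty / col_scale
  }

  core <- .ard_core(H, Xty, yty, n, groups, ard)
  w_raw <- core$weights / col_scale
  structure(
    c(list(weights = w_raw,
           w0 = y_center - sum(col_center * w_raw),
           col_center = col_center, y_center = y_center,
           groups = groups),
      core[c("relevance", "selected", "sigma2", "trace", "iterations",
             "converged")]),
    class = "slir_model")
}

# Grouped-ARD evidence maximization on centred sufficient statistics:
# H = X'X (p x p), Xty = X'y, yty = y'y, n rows.
.ard_core <- function(H, Xty, yty, n, groups, ard) {
  p <- length(Xty)
  gid <- sort(unique(groups))
  ng <- length(gid)
  gindex <- match(groups, gid)

  alpha <- rep_len(ard$alpha_init, ng)
  sigma2 <- if (!is.null(ard$sigma2_init)) ard$sigma2_init else
    0.1 * yty / (n - 1)
  active <- rep(TRUE, ng)
  m_full <- numeric(p)
  trace <- numeric(0)
  obj_prev <- -Inf
  converged <- FALSE
  it_done <- 0L

  for (it in seq_len(ard$max_iter)) {
    it_done <- it
    if (!any(active)) {
      converged <- TRUE
      break
    }
    acols <- which(active[gindex])
    agidx <- gindex[acols]
    P <- H[acols, acols, drop = FALSE] / sigma2
    diag(P) <- diag(P) + alpha[agidx]
    R <- chol(P)
    Sigma <- chol2inv(R)
    m <- drop(Sigma %*% Xty[acols]) / sigma2

    # Marginal likelihood (up to constants) via the Woodbury identity.
    rss <- yty - 2 * sum(m * Xty[acols]) +
      drop(crossprod(m, H[acols, acols] %*% m))
    mAm <- sum(alpha[agidx] * m^2)
    logdetSigma <- -2 * sum(log(diag(R)))
    obj <- -0.5 * (n * log(sigma2) - logdetSigma -
                     sum(log(alpha[agidx])) + rss / sigma2 + mAm)
    trace <- c(trace, obj)

    if (ard$update_relevance) {
      gamma_j <- 1 - alpha[agidx] * diag(Sigma)
      gsum_gamma <- rowsum(gamma_j, agidx)
      gsum_m2 <- rowsum(m^2, agidx)
      ag <- as.integer(rownames(gsum_gamma))
      alpha[ag] <- (drop(gsum_gamma) + 2 * ard$a0) /
        (drop(gsum_m2) + 2 * ard$b0)
      # Group pruning: prior variance far below the most relevant group.
      relev <- 1 / alpha
      relev[!active] <- 0
      drop_g <- active & (relev < ard$prune_ratio * max(relev))
      if (any(drop_g)) active[drop_g] <- FALSE
      if (ard$update_noise)
        sigma2 <- max(rss / max(n - sum(gamma_j), 1), 1e-12)
    } else if (ard$update_noise) {
      gamma_j <- 1 - alpha[agidx] * diag(Sigma)
      sigma2 <- max(rss / max(n - sum(gamma_j), 1), 1e-12)
    }

    if (is.finite(obj_prev) && abs(obj - obj_prev) <
        ard$tol * max(abs(obj_prev), 1)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    if (!ard$update_relevance && !ard$update_noise) {
      converged <- TRUE
      break
    }
  }
  if (!converged && ard$update_relevance)
    warning("SLiR did not converge within ", ard$max_iter, " iterations")

  # Final posterior mean on the surviving groups.
  acols <- which(active[gindex])
  if (length(acols)) {
    P <- H[acols, acols, drop = FALSE] / sigma2
    diag(P) <- diag(P) + alpha[gindex[acols]]
    m_full[acols] <- drop(chol2inv(chol(P)) %*% Xty[acols]) / sigma2
  }
  relevance <- ifelse(active, 1 / alpha, 0)
  has_w <- as.logical(rowsum((m_full != 0) + 0, gindex) > 0)
  selected <- gid[active & has_w]
  list(weights = m_full,
       relevance = stats::setNames(relevance, gid),
       selected = selected, sigma2 = sigma2, trace = trace,
       iterations = it_done, converged = converged)
}

#' @export
print.slir_model <- function(x, ...) {
  cat(sprintf("SLiR model: %d of %d dipole groups selected, %d iterations%s\n",
              length(x$selected), length(x$relevance), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict from a fitted SLiR model
#'
#' @param object A \code{slir_model}.
#' @param currents Matrix dipoles x samples (embedded with the model's
#'   config) or an already-embedded design matrix.
#' @param cfg The \code{slir_config} used at fit time (required when
#'   \code{currents} is a raw current matrix).
#' @param ... Unused.
#' @return Numeric predictions; when embedding internally, carries the
#'   \code{rows_time} attribute aligning them to the sample grid.
#' @export
predict.slir_model <- function(object, currents, cfg = NULL, ...) {
  X <- if (!is.null(attr(currents, "groups")) || is.null(cfg)) currents
       else embed_lags(currents, cfg)
  if (ncol(X) != length(object$weights))
    stop("dipole/lag dimension mismatch with the fitted model",
         call. = FALSE)
  out <- drop(X %*% object$weights) + object$w0
  attr(out, "rows_time") <- attr(X, "rows_time")
  out
}

# Raw per-trial sufficient statistics for decoder fitting: crossproducts of
# the lagged embedding plus per-dipole current moments (for z-scoring).
.trial_stats <- function(J, trajectory, cfg) {
  X <- embed_lags(J, cfg)
  rows <- attr(X, "rows_time")
  y_pos <- trajectory$position[rows]
  y_vel <- trajectory$velocity[rows]
  list(H = crossprod(X), colsum = colSums(X),
       Xty_pos = drop(crossprod(X, y_pos)),
       Xty_vel = drop(crossprod(X, y_vel)),
       ysum_pos = sum(y_pos), yss_pos = sum(y_pos^2),
       ysum_vel = sum(y_vel), yss_vel = sum(y_vel^2),
       n = nrow(X),
       cur_sum = rowSums(J), cur_ss = rowSums(J^2), cur_n = ncol(J),
       groups = attr(X, "groups"))
}

.sum_stats <- function(stat_list) {
  out <- stat_list[[1]]
  for (s in stat_list[-1])
    for (f in c("H", "colsum", "Xty_pos", "Xty_vel", "ysum_pos", "yss_pos",
                "ysum_vel", "yss_vel", "n", "cur_sum", "cur_ss", "cur_n"))
      out[[f]] <- out[[f]] + s[[f]]
  out
}

# Per-dipole z-scoring parameters implied by accumulated current moments.
.stats_scaling <- function(st) {
  N <- st$cur_n
  mu <- st$cur_sum / N
  v <- pmax((st$cur_ss - N * mu^2) / (N - 1), 0)
  list(center = mu, scale = pmax(sqrt(v), .Machine$double.eps))
}

# Fit one regressand from accumulated statistics, standardizing dipoles.
.fit_from_stats <- function(st, regressand, ard) {
  scaling <- .stats_scaling(st)
  L <- length(st$groups) / length(scaling$scale)
  # Dipole-wise standardization: centring is absorbed by column centring;
  # the scale expands to all lag columns of the dipole (dipole-major order).
  col_scale <- rep(scaling$scale, each = L)
  suf <- c(position = "pos", velocity = "vel")[[regressand]]
  stats <- list(H = st$H, colsum = st$colsum,
                Xty = st[[paste0("Xty_", suf)]],
                ysum = st[[paste0("ysum_", suf)]],
                yss = st[[paste0("yss_", suf)]],
                n = st$n)
  .slir_from_stats(stats, st$groups, ard, scale = col_scale)
}

#' Fit position and velocity decoders for one task
#'
#' Standardizes each dipole's current (z-score, parameters learned on the
#' training trials only), embeds lags, pools valid-time rows across trials,
#' and fits independent grouped-ARD models for target position and
#' velocity. The standardization is absorbed into the returned weights, so
#' predictions operate directly on raw currents.
#'
#' @param trials List of dipoles x samples current matrices (training
#'   trials).
#' @param trajectory A \code{target_trajectory} on the same sample grid.
#' @param cfg A \code{\link{slir_config}}.
#' @param ard \code{\link{ard_settings}}.
#' @return Object of class \code{decoding_model}: fields \code{position}
#'   and \code{velocity} (each a \code{slir_model}), \code{scaling},
#'   \code{cfg}.
#' @export
fit_decoder <- function(trials, trajectory, cfg = slir_config(),
                        ard = ard_settings()) {
  st <- .sum_stats(lapply(trials, .trial_stats, trajectory = trajectory,
                          cfg = cfg))
  structure(
    list(position = .fit_from_stats(st, "position", ard),
         velocity = .fit_from_stats(st, "velocity", ard),
         scaling = .stats_scaling(st), cfg = cfg),
    class = "decoding_model")
}

#' Predict target kinematics for one trial
#'
#' @param object A \code{decoding_model}.
#' @param currents Dipoles x samples current matrix.
#' @param ... Unused.
#' @return List with \code{position}, \code{velocity}, \code{rows_time}.
#' @export
predict.decoding_model <- function(object, currents, ...) {
  X <- embed_lags(currents, object$cfg)
  list(position = as.numeric(predict(object$position, X)),
       velocity = as.numeric(predict(object$velocity, X)),
       rows_time = attr(X, "rows_time"))
}

#' Selected-dipole counts per region, task and regressand
#'
#' @param models Named list (per task) of \code{decoding_model}s sharing the
#'   dipole indexing.
#' @param space The \code{source_space}.
#' @param dipole_idx Mapping from design dipole index to source-space dipole
#'   (default identity).
#' @return Data frame with columns \code{task}, \code{regressand},
#'   \code{region}, \code{n_selected}, plus attribute \code{selected_sets}
#'   (per task/regressand index sets on the design indexing) for shared-
#'   dipole categorization.
#' @export
selection_report <- function(models, space,
                             dipole_idx = seq_len(space$n_dipoles)) {
  stopifnot(inherits(space, "source_space"))
  out <- NULL
  sets <- list()
  for (task in names(models)) {
    for (reg in c("position", "velocity")) {
      sel <- models[[task]][[reg]]$selected
      if (any(sel > length(dipole_idx)))
        stop("selected indices exceed the dipole mapping", call. = FALSE)
      sets[[paste(task, reg, sep = ".")]] <- sel
      regs <- space$region[dipole_idx[sel]]
      counts <- table(factor(regs, levels = CORTICAL_REGIONS))
      out <- rbind(out, data.frame(task = task, regressand = reg,
                                   region = names(counts),
                                   n_selected = as.integer(counts)))
    }
  }
  attr(out, "selected_sets") <- sets
  out
}
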