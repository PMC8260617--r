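# Preprocessing and extra-dipole hierarchical Bayesian source estimation.
#
# The observation model is B = [Ghat, G_extra] [Z; J_extra] + noise with a
# per-source Gaussian prior whose precisions carry gamma hyperpriors
# (relevance determination), solved by mean-field variational Bayes with a
# monotone evidence lower bound.

#' Preprocess sensor epochs
#'
#' Per channel: linear detrend, centred simple moving average of
#' \code{ma_period} samples at the raw rate (reflection-padded at the
#' edges), then decimation to \code{target_fs}. With the defaults
#' (nine-period average, 200 Hz) a 1000 Hz epoch of 4401 samples becomes
#' 881 samples with motion onset kept on the grid.
#'
#' @param trials A \code{trial_set}.
#' @param ma_period Moving-average length in samples; odd, >= 1 (default 9).
#' @param target_fs Output rate in Hz; must divide the raw rate
#'   (default 200).
#' @return The preprocessed \code{trial_set} at \code{target_fs}.
#' @export
preprocess <- function(trials, ma_period = 9L, target_fs = 200) {
  stopifnot(inherits(trials, "trial_set"))
  if (ma_period < 1 || ma_period %% 2 == 0)
    stop("'ma_period' must be odd and >= 1", call. = FALSE)
  if (trials$fs %% target_fs != 0)
    stop("'target_fs' must divide the raw sampling rate", call. = FALSE)
  dec <- trials$fs %/% target_fs
  keep <- seq(1L, ncol(trials$trials[[1]]), by = dec)
  trials$trials <- lapply(trials$trials, function(b) {
    out <- t(apply(b, 1, function(ch)
      moving_average(detrend_linear(ch), ma_period)))
    out[, keep, drop = FALSE]
  })
  trials$fs <- target_fs
  trials$onset_index <- as.integer((trials$onset_index - 1L) %/% dec + 1L)
  trials
}

#' Spatial smoothing operator and smoothed lead field
#'
#' Reduced dipoles are chosen by uniform subsampling (every
#' \code{reduction}-th dipole, matching the roughly 4:1 full-to-reduced
#' ratio of dense cortical source grids). Each column of \code{W} is a
#' spatial Gaussian in inter-dipole distance centred on one reduced dipole,
#' non-negative and normalized to unit sum, so cortical currents are
#' \code{J = W Z}. When a forward model is supplied the smoothed lead field
#' \code{Ghat = G W} is computed and cached.
#'
#' @param space A \code{source_space}.
#' @param fm Optional \code{forward_model} used to compute \code{Ghat}.
#' @param sigma Gaussian kernel width in mm; default twice the median
#'   nearest-neighbour dipole distance.
#' @param reduction Integer subsampling factor (>= 1, <= n_dipoles).
#' @return Object of class \code{smoothing_op}: \code{W} (dipoles x
#'   reduced), \code{reduced_idx}, \code{sigma}, \code{reduction}, and
#'   \code{Ghat} (sensors x reduced, or NULL).
#' @export
build_smoothing <- function(space, fm = NULL, sigma = NULL, reduction = 4L) {
  stopifnot(inherits(space, "source_space"))
  if (reduction < 1) stop("'reduction' must be >= 1", call. = FALSE)
  if (reduction > space$n_dipoles)
    stop("'reduction' exceeds the number of dipoles", call. = FALSE)
  pos <- space$positions
  n <- space$n_dipoles
  reduced_idx <- seq(1L, n, by = as.integer(reduction))

  D2 <- as.matrix(stats::dist(pos))^2
  if (is.null(sigma)) {
    nn <- apply(D2 + diag(Inf, n), 1, min)
    sigma <- 2 * stats::median(sqrt(nn))
  }
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)

  W <- exp(-D2[, reduced_idx, drop = FALSE] / (2 * sigma^2))
  W <- sweep(W, 2, colSums(W), "/")
  dimnames(W) <- NULL
  Ghat <- if (!is.null(fm)) fm$G %*% W else NULL
  structure(
    list(W = W, reduced_idx = reduced_idx, sigma = sigma,
         reduction = as.integer(reduction), Ghat = Ghat),
    class = "smoothing_op")
}

#' Region-prior variance magnification
#'
#' Builds the per-reduced-dipole prior variance magnification used by
#' \code{\link{estimate_currents}}: the synthetic stand-in for a functional
#' localizer, boosting the prior current variance inside functionally
#' active regions (magnification >= 1 there, 1 elsewhere).
#'
#' @param space A \code{source_space}.
#' @param smoothing The \code{smoothing_op} (defines the reduced dipoles).
#' @param regions Regions considered active (default: the six task-relevant
#'   regions).
#' @param magnification Variance magnification inside active regions
#'   (default 10).
#' @return Numeric vector, one magnification per reduced dipole.
#' @export
region_prior <- function(space, smoothing,
                         regions = setdiff(CORTICAL_REGIONS, "irrelevant"),
                         magnification = 10) {
  stopifnot(inherits(space, "source_space"),
            inherits(smoothing, "smoothing_op"))
  if (magnification < 1)
    stop("'magnification' must be >= 1", call. = FALSE)
  active <- space$region[smoothing$reduced_idx] %in% regions
  ifelse(active, magnification, 1)
}

#' Variational Bayes settings for source estimation
#'
#' @param max_iter Maximum VB iterations (default 200).
#' @param tol Relative objective tolerance for convergence (default 1e-6).
#' @param a0 Gamma hyperprior shape for source precisions (weakly
#'   informative; default 0.01).
#' @param noise_a0,noise_b0 Gamma hyperprior shape/rate for the sensor noise
#'   precision (default 1e-6 each).
#' @param extra_magnification Prior variance magnification of extra-brain
#'   sources relative to the cortical baseline (default 100; artifact
#'   sources are expected to be large).
#' @param update_hyper Update the variance hyperparameters (default TRUE).
#'   With FALSE the posterior mean is the Tikhonov-regularized solution for
#'   the initial hyperparameters.
#' @param alpha_init,beta_init Optional fixed initial precisions (per-source
#'   vector / scalar); defaults are derived from the data scale.
#' @return List of settings.
#' @export
vb_settings <- function(max_iter = 200L, tol = 1e-6, a0 = 0.01,
                        noise_a0 = 1e-6, noise_b0 = 1e-6,
                        extra_magnification = 100,
                        update_hyper = TRUE,
                        alpha_init = NULL, beta_init = NULL) {
  list(max_iter = as.integer(max_iter), tol = tol, a0 = a0,
       noise_a0 = noise_a0, noise_b0 = noise_b0,
       extra_magnification = extra_magnification,
       update_hyper = update_hyper,
       alpha_init = alpha_init, beta_init = beta_init)
}

# One VB run on concatenated data B (sensors x T). Returns posterior means,
# precisions and the ELBO trace. Exact coordinate-ascent updates on the
# conjugate hierarchical Gaussian model, so the trace is non-decreasing.
.vb_estimate <- function(B, A, b0_vec, vb) {
  M <- nrow(B); Tn <- ncol(B); S <- ncol(A)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  ssB <- sum(B^2)

  a0 <- vb$a0
  c0 <- vb$noise_a0; d0 <- vb$noise_b0
  alpha <- if (!is.null(vb$alpha_init)) rep_len(vb$alpha_init, S)
           else a0 / b0_vec
  beta <- if (!is.null(vb$beta_init)) vb$beta_init
          else 1 / (0.1 * ssB / (M * Tn) + .Machine$double.eps)

  aN <- a0 + Tn / 2
  cN <- c0 + M * Tn / 2
  bN <- b0_vec; dN <- d0
  trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE

  for (it in seq_len(vb$max_iter)) {
    P <- beta * AtA
    diag(P) <- diag(P) + alpha
    R <- tryCatch(chol(P), error = function(e)
      stop("numerical conditioning failure in the sensor model: ",
           conditionMessage(e), call. = FALSE))
    Sigma <- chol2inv(R)
    Mx <- beta * (Sigma %*% AtB)

    S2 <- rowSums(Mx^2) + Tn * diag(Sigma)
    resid <- ssB - 2 * sum(Mx * AtB) + sum(AtA * tcrossprod(Mx)) +
      Tn * sum(AtA * Sigma)

    if (vb$update_hyper) {
      bN <- b0_vec + S2 / 2
      alpha <- aN / bN
      dN <- d0 + resid / 2
      beta <- cN / dN
      Elog_alpha <- digamma(aN) - log(bN)
      Elog_beta <- digamma(cN) - log(dN)
    } else {
      Elog_alpha <- log(alpha)
      Elog_beta <- log(beta)
    }

    # Evidence lower bound at the current factors.
    logdetSigma <- -2 * sum(log(diag(R)))
    elbo <- (M * Tn / 2) * (Elog_beta - log(2 * pi)) - beta * resid / 2 +
      (Tn / 2) * sum(Elog_alpha) - sum(alpha * S2) / 2 -
      (S * Tn / 2) * log(2 * pi) +
      (Tn / 2) * (S * (1 + log(2 * pi)) + logdetSigma)
    if (vb$update_hyper) {
      elbo <- elbo +
        sum(a0 * log(b0_vec) - lgamma(a0) + (a0 - 1) * Elog_alpha -
              b0_vec * alpha) +
        sum(aN - log(bN) + lgamma(aN) + (1 - aN) * digamma(aN)) +
        (c0 * log(d0) - lgamma(c0) + (c0 - 1) * Elog_beta - d0 * beta) +
        (cN - log(dN) + lgamma(cN) + (1 - cN) * digamma(cN))
    }
    trace <- c(trace, elbo)
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) < vb$tol * abs(elbo_prev)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
    if (!vb$update_hyper && it >= 1L) {
      converged <- TRUE
      break
    }
  }
  list(mean = Mx, Sigma = Sigma, alpha = alpha, beta = beta,
       trace = trace, converged = converged)
}

#' Estimate cortical and extra-brain source currents
#'
#' Simultaneously estimates reduced cortical currents \code{Z} and (when
#' \code{with_extra}) the nine extra-brain artifact currents from
#' preprocessed sensor data, by variational Bayes on the hierarchical model
#' \code{B = [Ghat, G_extra] [Z; J_extra] + noise} with per-source gamma
#' variance hyperpriors. Region-prior variance magnifications (the
#' functional-localizer analogue) scale the prior variance of cortical
#' sources. Hyperparameters are updated on trials pooled within a task;
#' posterior current means are returned per trial.
#'
#' @param trials A preprocessed \code{trial_set}.
#' @param smoothing A \code{smoothing_op} with a cached \code{Ghat}.
#' @param G_extra Sensors x 9 extra-brain gain matrix (from the forward
#'   model), or NULL.
#' @param prior Optional per-reduced-dipole variance magnification (>= 1
#'   inside functionally active regions, 1 elsewhere); default all 1.
#' @param with_extra Include the extra-brain columns (default TRUE when
#'   \code{G_extra} is given). FALSE is the ablation mode.
#' @param vb \code{\link{vb_settings}}.
#' @return Object of class \code{inverse_solution}: \code{Z} (list per
#'   trial, reduced dipoles x samples), \code{extra} (list per trial, 9 x
#'   samples or NULL), \code{alpha} (per task), \code{trace} (per task),
#'   \code{converged}, \code{fs}, \code{task}, \code{with_extra},
#'   \code{reduced_idx}. A non-converged task yields a warning and a flag,
#'   not an error. Cortical currents \code{J = W Z} are available through
#'   \code{\link{cortical_currents}}.
#' @export
estimate_currents <- function(trials, smoothing, G_extra = NULL,
                              prior = NULL,
                              with_extra = !is.null(G_extra),
                              vb = vb_settings()) {
  stopifnot(inherits(trials, "trial_set"), inherits(smoothing, "smoothing_op"))
  Ghat <- smoothing$Ghat
  if (is.null(Ghat))
    stop("'smoothing' must carry a cached smoothed lead field (pass the forward model to build_smoothing)",
         call. = FALSE)
  if (with_extra && is.null(G_extra))
    stop("'with_extra = TRUE' requires 'G_extra'", call. = FALSE)
  Sr <- ncol(Ghat)
  A <- if (with_extra) cbind(Ghat, G_extra) else Ghat
  Stot <- ncol(A)
  if (nrow(A) != nrow(trials$trials[[1]]))
    stop("sensor dimension mismatch between trials and lead field",
         call. = FALSE)
  if (is.null(prior)) prior <- rep(1, Sr)
  if (length(prior) != Sr || any(prior < 1))
    stop("'prior' must give one magnification >= 1 per reduced dipole",
         call. = FALSE)

  # Baseline prior variance from the data scale: per-source share of the
  # sensor power mapped back through the lead-field scale.
  Ball <- do.call(cbind, trials$trials)
  v0 <- max(sum(Ball^2) / (ncol(Ball) * sum(A^2)), .Machine$double.xmin)
  mag <- c(prior, if (with_extra) rep(vb$extra_magnification, 9))
  b0_vec <- vb$a0 * v0 * mag

  tasks <- unique(trials$task)
  Z <- vector("list", length(trials$trials))
  extra <- if (with_extra) vector("list", length(trials$trials)) else NULL
  alpha <- list(); trace <- list(); converged <- logical(0)
  ns <- ncol(trials$trials[[1]])
  for (task in tasks) {
    idx <- which(trials$task == task)
    B <- do.call(cbind, trials$trials[idx])
    fit <- .vb_estimate(B, A, b0_vec, vb)
    if (!fit$converged)
      warning("source estimation did not converge for task ", task)
    alpha[[task]] <- fit$alpha
    trace[[task]] <- fit$trace
    converged[task] <- fit$converged
    for (j in seq_along(idx)) {
      cols <- (j - 1L) * ns + seq_len(ns)
      Z[[idx[j]]] <- fit$mean[seq_len(Sr), cols, drop = FALSE]
      if (with_extra)
        extra[[idx[j]]] <- fit$mean[Sr + 1:9, cols, drop = FALSE]
    }
  }
  structure(
    list(Z = Z, extra = extra, alpha = alpha, trace = trace,
         converged = converged, fs = trials$fs, task = trials$task,
         with_extra = with_extra, reduced_idx = smoothing$reduced_idx),
    class = "inverse_solution")
}

#' Cortical currents of one trial
#'
#' Expands reduced currents through the smoothing operator:
#' \code{J = W Z} (exact by construction).
#'
#' @param sol An \code{inverse_solution}.
#' @param smoothing The \code{smoothing_op} used for estimation.
#' @param trial Trial index.
#' @return Matrix dipoles x samples.
#' @export
cortical_currents <- function(sol, smoothing, trial) {
  stopifnot(inherits(sol, "inverse_solution"))
  smoothing$W %*% sol$Z[[trial]]
}

#' Regional current statistics
#'
#' Trial-averaged absolute current per region plus the peak current density
#' (the maximum over dipoles of the trial-averaged absolute current).
#'
#' @param currents Either an \code{inverse_solution} (then \code{smoothing}
#'   is required) or a list of dipoles x samples matrices (e.g. ground
#'   truth).
#' @param space The \code{source_space} sharing the dipole indexing.
#' @param smoothing \code{smoothing_op} for expanding an inverse solution.
#' @param tasks Optional task label per trial; statistics are returned per
#'   task when given.
#' @return Data frame with columns \code{task}, \code{region},
#'   \code{mean_intensity}; attribute \code{peak} holds the per-task peak
#'   density.
#' @export
region_stats <- function(currents, space, smoothing = NULL, tasks = NULL) {
  stopifnot(inherits(space, "source_space"))
  if (inherits(currents, "inverse_solution")) {
    if (is.null(smoothing))
      stop("'smoothing' is required to expand an inverse solution",
           call. = FALSE)
    if (is.null(tasks)) tasks <- currents$task
    sol <- currents
    currents <- lapply(seq_along(sol$Z), function(i)
      cortical_currents(sol, smoothing, i))
  }
  if (is.null(tasks)) tasks <- rep("all", length(currents))
  region <- space$region
  if (nrow(currents[[1]]) != space$n_dipoles)
    stop("dipole count mismatch with the source space", call. = FALSE)

  out <- NULL; peaks <- c()
  for (task in unique(tasks)) {
    idx <- which(tasks == task)
    per_dipole <- rowMeans(sapply(idx, function(i) rowMeans(abs(currents[[i]]))))
    m <- tapply(per_dipole, region, mean)
    out <- rbind(out, data.frame(task = task,
                                 region = names(m),
                                 mean_intensity = as.numeric(m)))
    peaks[task] <- max(per_dipole)
  }
  attr(out, "peak") <- peaks
  out
}

#' Eye-artifact leakage into estimated cortical currents
#'
#' Mean absolute correlation, across trials, between the region-mean
#' estimated current and the trial's horizontal ocular artifact current.
#' In overt pursuit the eye artifact shares the target's waveform with the
#' genuine visual drive, so when a target series is supplied the target is
#' partialled out of both series first (partial correlation), isolating
#' the artifact-specific variance. Used to quantify how much of the
#' eye-movement artifact contaminates cortical estimates with and without
#' extra-brain dipoles.
#'
#' @param sol An \code{inverse_solution}.
#' @param space,smoothing Source space and smoothing operator.
#' @param eye_traces List (per trial) of horizontal eye artifact series at
#'   the raw rate; decimated to the solution's rate if longer.
#' @param region Region whose estimated currents are examined
#'   (default "V1V2").
#' @param trials Optional subset of trial indices.
#' @param target Optional target position series (raw rate or solution
#'   rate) to partial out.
#' @return Mean absolute (partial) correlation (scalar).
#' @export
artifact_leakage <- function(sol, space, smoothing, eye_traces,
                             region = "V1V2", trials = NULL,
                             target = NULL) {
  if (is.null(trials)) trials <- seq_along(sol$Z)
  ridx <- which(space$region == region)
  if (length(ridx) == 0) stop("unknown region: ", region, call. = FALSE)
  match_rate <- function(x, len) {
    if (length(x) == len) return(x)
    dec <- length(x) %/% len
    x[seq(1L, by = dec, length.out = len)]
  }
  rs <- vapply(trials, function(i) {
    J <- cortical_currents(sol, smoothing, i)
    m <- colMeans(J[ridx, , drop = FALSE])
    tr <- match_rate(eye_traces[[i]], length(m))
    if (!is.null(target)) {
      tg <- match_rate(target, length(m))
      m <- stats::residuals(stats::lm(m ~ tg))
      tr <- stats::residuals(stats::lm(tr ~ tg))
    }
    if (stats::sd(tr) == 0 || stats::sd(m) == 0) return(0)
    abs(stats::cor(m, tr))
  }, 0)
  mean(rs)
}
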