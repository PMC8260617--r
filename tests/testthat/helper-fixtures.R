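# Shared fixtures, all generated in code with fixed seeds.

# Small source space + forward model reused across tests.
fixture_space <- function(n = 120, seed = 1) make_source_space(n, seed = seed)

fixture_forward <- function(space, n_sensors = 32, seed = 2)
  make_forward_model(space, n_sensors = n_sensors, seed = seed)

# Hand-built source space with known geometry (for decay-law tests).
fixture_manual_space <- function(positions, orientations = NULL) {
  n <- nrow(positions)
  if (is.null(orientations))
    orientations <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  structure(
    list(positions = positions, orientations = orientations,
         region = factor(rep("irrelevant", n), levels = CORTICAL_REGIONS),
         n_dipoles = n, radius = mean(sqrt(rowSums(positions^2)))),
    class = "source_space")
}

# Lagged-regression fixture: targets generated from `k` of `D` dipole
# groups. noise_sd is relative to the signal SD (so 1/sqrt(10) gives
# SNR 10); noise_sd = 0 is the noiseless interpolation case.
fixture_slir <- function(seed, noise_sd, D = 50, S = 2000,
                         true_g = c(7L, 21L, 40L),
                         cfg = slir_config(tau = 3, dtau = 3)) {
  withr::with_seed(seed, {
    J <- matrix(stats::rnorm(D * S), D, S)
    X <- embed_lags(J, cfg)
    L <- cfg$dtau + 1
    w <- rep(0, ncol(X))
    for (g in true_g) w[(g - 1) * L + seq_len(L)] <- stats::runif(L, -1, 1)
    sig <- drop(X %*% w)
    y <- sig + if (noise_sd > 0)
      stats::rnorm(length(sig), sd = noise_sd * stats::sd(sig)) else 0
    list(J = J, X = X, y = y, w = w, true_g = true_g, cfg = cfg)
  })
}

# Trajectory on the standard epoch at a given rate.
fixture_traj <- function(frequency = 0.5, fs = 200, epoch_start = -0.4)
  make_target_trajectory(frequency, 20, duration = 4, fs = fs,
                         epoch_start = epoch_start)

# Circularly stationary smooth noise (circular moving average of white
# noise): its distribution is exactly invariant under circular shifts, the
# regime in which the permutation scheme is exact.
circular_smooth_noise <- function(n, width = 40) {
  k <- c(rep(1 / width, width), rep(0, n - width))
  Re(stats::fft(stats::fft(stats::rnorm(n)) * stats::fft(k),
                inverse = TRUE)) / n
}

# Independent brute-force Benjamini-Hochberg step-up (oracle).
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  list(adjusted = out, rejected = rej)
}

# Independent randomized-block one-way ANOVA by explicit sums of squares.
oracle_rb_anova1 <- function(y, block, A) {
  a <- length(unique(A)); n <- length(unique(block))
  g <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - g)^2))
  ssB <- sum(tapply(y, block, function(v) length(v) * (mean(v) - g)^2))
  sse <- sum((y - g)^2) - ssA - ssB
  f <- (ssA / (a - 1)) / (sse / ((a - 1) * (n - 1)))
  list(F = f, df1 = a - 1, df2 = (a - 1) * (n - 1),
       p = stats::pf(f, a - 1, (a - 1) * (n - 1), lower.tail = FALSE))
}

# Brute-force shared-dipole categorizer over explicit membership patterns.
oracle_categorize <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  res <- character(0)
  for (d in universe) {
    memb <- names(sets)[vapply(sets, function(s) d %in% s, TRUE)]
    res[as.character(d)] <-
      if (length(memb) == 1) paste0("exclusive-", memb)
      else if (length(memb) >= 3) ">=3-tasks-shared"
      else if (setequal(memb, c("covert_0.5", "covert_0.8"))) "covert-shared"
      else if (setequal(memb, c("overt_0.5", "overt_0.8"))) "overt-shared"
      else if (setequal(memb, c("covert_0.5", "overt_0.5"))) "0.5Hz-shared"
      else if (setequal(memb, c("covert_0.8", "overt_0.8"))) "0.8Hz-shared"
      else "two-task-other"
  }
  res
}
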