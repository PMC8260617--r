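# Synthetic-data generator: cortical source space, forward model,
# task-dependent subpopulation currents, ocular/cardiac artifact sources,
# sensor synthesis, and amplitude-based trial rejection.

#' Cortical region labels of the synthetic source space
#'
#' Six task-relevant regions (precentral cortex, medial superior frontal
#' cortex, lateral occipito-temporal cortex, intraparietal cortex, precuneus,
#' early visual areas V1/V2) plus a task-irrelevant remainder.
#'
#' @format Character vector of length 7.
#' @export
CORTICAL_REGIONS <- c("PreCC", "MSFC", "LOTC", "IPC", "Precuneus", "V1V2",
                      "irrelevant")

default_region_fractions <- function() {
  c(PreCC = 0.08, MSFC = 0.06, LOTC = 0.10, IPC = 0.10,
    Precuneus = 0.06, V1V2 = 0.12, irrelevant = 0.48)
}

#' Synthetic cortical source space
#'
#' Places current dipoles on a sphere-like cortical shell and assigns them
#' to contiguous region patches. Coordinates are in mm with the head centre
#' at the origin (x right, y anterior, z inferior). Orientations are random
#' unit vectors standing in for the local surface normal.
#'
#' @param n_dipoles Number of dipoles (>= 50).
#' @param region_fractions Named numeric vector over
#'   \code{\link{CORTICAL_REGIONS}} summing to 1.
#' @param seed Integer seed; geometry is reproducible.
#' @param radius Shell radius in mm (default 80).
#' @return Object of class \code{source_space}: \code{positions} (n x 3, mm),
#'   \code{orientations} (n x 3, unit rows), \code{region} (factor),
#'   \code{n_dipoles}, \code{radius}.
#' @export
make_source_space <- function(n_dipoles = 500,
                              region_fractions = default_region_fractions(),
                              seed = 1L, radius = 80) {
  .stopifnot_scalar(n_dipoles, "n_dipoles")
  if (n_dipoles < 50) stop("'n_dipoles' must be >= 50", call. = FALSE)
  if (is.null(names(region_fractions)) ||
      !setequal(names(region_fractions), CORTICAL_REGIONS))
    stop("'region_fractions' must be named over all cortical regions",
         call. = FALSE)
  region_fractions <- region_fractions[CORTICAL_REGIONS]
  if (abs(sum(region_fractions) - 1) > 1e-6)
    stop("'region_fractions' must sum to 1", call. = FALSE)

  n_dipoles <- as.integer(n_dipoles)
  rng <- local_rng(seed)
  dirs <- unit_rows(matrix(rng$rnorm(3 * n_dipoles), ncol = 3))
  r <- radius + rng$rnorm(n_dipoles, sd = radius * 0.02)
  positions <- dirs * r
  orientations <- unit_rows(matrix(rng$rnorm(3 * n_dipoles), ncol = 3))

  # Contiguous patches: each region claims its quota of dipoles nearest to a
  # seeded patch centre, in region order.
  quota <- diff(c(0L, round(cumsum(region_fractions) * n_dipoles)))
  centres <- unit_rows(matrix(rng$rnorm(21), ncol = 3)) * radius
  region <- rep(NA_character_, n_dipoles)
  free <- rep(TRUE, n_dipoles)
  for (k in seq_along(CORTICAL_REGIONS)) {
    if (quota[k] == 0L) next
    d <- colSums((t(positions) - centres[k, ])^2)
    d[!free] <- Inf
    take <- order(d)[seq_len(quota[k])]
    region[take] <- CORTICAL_REGIONS[k]
    free[take] <- FALSE
  }
  structure(
    list(positions = positions, orientations = orientations,
         region = factor(region, levels = CORTICAL_REGIONS),
         n_dipoles = n_dipoles, radius = radius),
    class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("Synthetic source space: %d dipoles on a %g mm shell\n",
              x$n_dipoles, x$radius))
  print(table(x$region))
  invisible(x)
}

# Quasi-static dipolar gain of unit sources at `positions` with orientations
# `orient`, seen by sensors at `sensors`: projection of the orientation on
# the source-to-sensor direction with inverse-square distance decay.
.gain_columns <- function(sensors, positions, orient) {
  n_s <- nrow(sensors)
  n_p <- nrow(positions)
  G <- matrix(0, n_s, n_p)
  for (j in seq_len(n_p)) {
    d <- t(sensors) - positions[j, ]
    dist <- sqrt(colSums(d^2))
    G[, j] <- colSums(d * orient[j, ]) / dist^3
  }
  G
}

#' Synthetic forward model (lead field)
#'
#' Builds a sensors x dipoles gain matrix with inverse-square distance decay
#' and orientation-consistent sign, plus nine extra-brain gain columns for
#' two ocular sources and one cardiac source (three orthogonal unit dipoles
#' each). The default heart location is the (15, 0, 350) mm offset from the
#' head-centre origin along the inferior axis.
#'
#' @param space A \code{source_space}.
#' @param n_sensors Number of sensors (>= 10); the reference recording
#'   system has 208.
#' @param eye_positions 2 x 3 matrix of eyeball centres in mm.
#' @param heart_position Length-3 heart position in mm.
#' @param seed Integer seed for sensor placement and gain jitter.
#' @return Object of class \code{forward_model}: \code{G} (sensors x
#'   dipoles), \code{G_extra} (sensors x 9; columns 1-3 left eye, 4-6 right
#'   eye, 7-9 heart, each x/y/z), \code{sensor_positions}, \code{n_sensors}.
#' @export
make_forward_model <- function(space, n_sensors = 64,
                               eye_positions = rbind(c(-32, 85, 30),
                                                     c(32, 85, 30)),
                               heart_position = c(15, 0, 350),
                               seed = 1L) {
  stopifnot(inherits(space, "source_space"))
  .stopifnot_scalar(n_sensors, "n_sensors")
  if (n_sensors < 10)
    stop("'n_sensors' must be >= 10 for a meaningful inverse", call. = FALSE)
  n_sensors <- as.integer(n_sensors)
  rng <- local_rng(seed)

  # Helmet-like array over the superior half of the head (z inferior).
  dirs <- unit_rows(matrix(rng$rnorm(3 * n_sensors), ncol = 3))
  dirs[, 3] <- -abs(dirs[, 3])
  dirs <- unit_rows(dirs)
  sensors <- dirs * (space$radius * 1.4)

  G <- .gain_columns(sensors, space$positions, space$orientations)
  # Small seeded channel-gain jitter (sensor calibration spread).
  G <- G * (1 + 0.05 * matrix(rng$rnorm(length(G)), nrow(G)))
  # Full column relevance: no silent sources.
  cn <- sqrt(colSums(G^2))
  if (any(cn < .Machine$double.eps))
    stop("degenerate forward model: all-zero gain column", call. = FALSE)

  extra_pos <- rbind(eye_positions, heart_position)
  axes <- diag(3)
  G_extra <- do.call(cbind, lapply(1:3, function(s)
    sapply(1:3, function(a)
      .gain_columns(sensors, extra_pos[s, , drop = FALSE],
                    axes[a, , drop = FALSE]))))
  colnames(G_extra) <- c(t(outer(c("eyeL", "eyeR", "heart"),
                                 c("x", "y", "z"), paste, sep = "_")))
  structure(
    list(G = G, G_extra = G_extra, sensor_positions = sensors,
         n_sensors = n_sensors),
    class = "forward_model")
}

#' Task-dependent subpopulation specification
#'
#' Defines the three functional subpopulations embodied by the generator:
#' a visual population (in V1/V2 and LOTC), an attention population (IPC,
#' precuneus, MSFC, PreCC), and an eye-movement population occupying
#' *different* dipoles of the same fronto-parietal regions (PreCC, MSFC,
#' IPC). Gains follow the task-function table: the visual population is
#' active in every task, attention in covert and overt pursuit, and the
#' eye-movement population only in overt pursuit, at twice the gain of the
#' other populations (matching the roughly two-fold overt/covert current
#' density contrast).
#'
#' All populations share a common kinematic encoding (a fixed mixture of
#' normalized target position and velocity) and lead the target by
#' \code{lag_s} (default -0.1 s, i.e. currents precede target motion by
#' 100 ms). Per-dipole encoding weights are drawn once from U(0.5, 1.5).
#'
#' @param space A \code{source_space}.
#' @param seed Integer seed.
#' @param member_fraction Fraction of each region's dipoles recruited into a
#'   population (default 0.4).
#' @param gains Named numeric: baseline gain per population;
#'   default \code{c(visual = 1, attention = 1, eye_movement = 2)}.
#' @param overt_damping Multipliers on the visual and attention gains under
#'   overt tasks (default \code{c(visual = 0.3, attention = 0.3)}). Both
#'   functions remain active in overt pursuit, but with reduced task-locked
#'   amplitude: successful pursuit stabilizes the target near the fovea, so
#'   the retinal-slip drive of visual motion responses shrinks, and the
#'   strong oculomotor drive supplants much of the sustained top-down
#'   attention signal. Overt-task currents are therefore dominated by the
#'   eye-movement population.
#' @param mix Named numeric \code{c(pos = , vel = )}: mixing weights applied
#'   to position/amplitude and velocity/peak-velocity (unit-normalized
#'   kinematics).
#' @param lag_s Response lag in seconds; negative values mean the currents
#'   lead the target.
#' @param amp Current amplitude scale in pA m/mm^2 per unit gain
#'   (default 40, placing active currents in the physiological
#'   25-250 pA m/mm^2 range).
#' @return Object of class \code{subpop_spec} with fields \code{sets},
#'   \code{gain_table} (population x task), \code{mix}, \code{lag_s},
#'   \code{amp}, \code{dipole_weights}.
#' @export
default_subpopulations <- function(space, seed = 1L, member_fraction = 0.4,
                                   gains = c(visual = 1, attention = 1,
                                             eye_movement = 2),
                                   overt_damping = c(visual = 0.3,
                                                     attention = 0.3),
                                   mix = c(pos = 0.8, vel = 0.6),
                                   lag_s = -0.1, amp = 40) {
  stopifnot(inherits(space, "source_space"))
  rng <- local_rng(seed)
  pick <- function(regions, exclude = integer(0)) {
    idx <- setdiff(which(space$region %in% regions), exclude)
    if (length(idx) == 0L) return(integer(0))
    n_take <- max(1L, round(member_fraction * length(idx)))
    sort(idx[rng$sample(length(idx), n_take)])
  }
  visual <- pick(c("V1V2", "LOTC"))
  attention <- pick(c("IPC", "Precuneus", "MSFC", "PreCC"))
  # The pursuit command population concentrates in the precentral cortex
  # (frontal/supplementary eye fields) with a fronto-parietal fringe.
  eye_movement <- sort(c(
    setdiff(which(space$region == "PreCC"), attention),
    pick(c("MSFC", "IPC"), exclude = attention)))

  gain_table <- matrix(0, nrow = 3, ncol = length(PURSUIT_TASKS),
                       dimnames = list(c("visual", "attention",
                                         "eye_movement"), PURSUIT_TASKS))
  for (task in PURSUIT_TASKS)
    for (fn in task_functions(task))
      gain_table[fn, task] <- gains[[fn]] *
        (if (startsWith(task, "overt") && fn %in% names(overt_damping))
           overt_damping[[fn]] else 1)

  w <- stats::setNames(rng$runif(space$n_dipoles, 0.5, 1.5),
                       NULL)
  structure(
    list(sets = list(visual = visual, attention = attention,
                     eye_movement = eye_movement),
         gain_table = gain_table, mix = mix, lag_s = lag_s, amp = amp,
         dipole_weights = w),
    class = "subpop_spec")
}

# Analytic target kinematics at arbitrary times (zero outside the motion
# interval), normalized to unit peak when `normalized`.
traj_eval <- function(trajectory, times, normalized = FALSE) {
  dur <- trajectory$duration
  omega <- 2 * pi * trajectory$frequency
  moving <- times >= 0 & times <= dur
  pos <- ifelse(moving, trajectory$amplitude * sin(omega * times), 0)
  vel <- ifelse(moving, trajectory$peak_velocity * cos(omega * times), 0)
  if (normalized) {
    pos <- pos / trajectory$amplitude
    vel <- vel / trajectory$peak_velocity
  }
  list(position = pos, velocity = vel)
}

#' Simulate ground-truth cortical currents for one trial
#'
#' Each population that is active in the task carries
#' \code{amp * gain(task) * (mix_pos * pos(t - lag) + mix_vel * vel(t - lag))}
#' scaled by its per-dipole encoding weight, the visual population
#' additionally receives a Gaussian evoked transient centred 0.1 s after
#' motion onset (width 30 ms), and every dipole receives white background
#' noise. Populations whose function a task does not require carry noise
#' only.
#'
#' @param space A \code{source_space}.
#' @param spec A \code{subpop_spec}.
#' @param task Task id.
#' @param trajectory A \code{target_trajectory} sampled on the epoch grid
#'   (build with \code{epoch_start = -0.4}).
#' @param evoked_amp Evoked-transient amplitude (default 30).
#' @param noise_sd Background current noise SD (default 20).
#' @param seed Integer seed.
#' @return Matrix n_dipoles x n_samples of currents (pA m/mm^2 scale).
#' @export
simulate_currents <- function(space, spec, task, trajectory,
                              evoked_amp = 30, noise_sd = 10, seed = 1L) {
  stopifnot(inherits(space, "source_space"), inherits(spec, "subpop_spec"))
  .check_task(task)
  if (any(vapply(spec$sets, function(s) any(s > space$n_dipoles), TRUE)))
    stop("population sets index beyond the source space", call. = FALSE)
  t_epoch <- trajectory$time
  if (abs(spec$lag_s) > max(t_epoch) - min(t_epoch))
    stop("population lag exceeds the epoch bounds", call. = FALSE)

  rng <- local_rng(seed)
  n <- space$n_dipoles
  S <- length(t_epoch)
  J <- if (noise_sd > 0)
    matrix(rng$rnorm(n * S, sd = noise_sd), n, S) else matrix(0, n, S)

  kin <- traj_eval(trajectory, t_epoch - spec$lag_s, normalized = TRUE)
  drive <- spec$mix[["pos"]] * kin$position +
    spec$mix[["vel"]] * kin$velocity
  for (fn in names(spec$sets)) {
    g <- spec$gain_table[fn, task]
    if (g == 0) next
    idx <- spec$sets[[fn]]
    J[idx, ] <- J[idx, ] +
      (spec$amp * g * spec$dipole_weights[idx]) %o% drive
  }
  if (evoked_amp != 0) {
    bump <- evoked_amp * exp(-(t_epoch - 0.1)^2 / (2 * 0.03^2))
    idx <- spec$sets$visual
    J[idx, ] <- J[idx, ] + spec$dipole_weights[idx] %o% bump
  }
  J
}

#' Simulate extra-brain artifact source currents for one trial
#'
#' Produces the 9 x samples current matrix of the two ocular and one cardiac
#' source. In overt tasks the horizontal ocular components track the target
#' (the eyes pursue it with a short latency and small tracking noise); in
#' covert and control tasks the eyes hold fixation with low-amplitude jitter.
#' Blink transients load the vertical ocular components, and a periodic
#' pulse train at \code{heart_rate} drives the cardiac components in every
#' task.
#'
#' @param trajectory A \code{target_trajectory} on the epoch grid.
#' @param task Task id.
#' @param heart_rate Cardiac rate in Hz, in (0.5, 3).
#' @param blink_rate Mean blink rate in Hz (default 0.2).
#' @param seed Integer seed.
#' @param eye_gain Ocular dipole current per degree of gaze (default 60).
#' @param blink_amp Blink transient amplitude (default 300).
#' @param heart_amp Cardiac pulse amplitude (default 400).
#' @param pursuit_latency Ocular pursuit latency in seconds (default 0.05).
#' @return List with \code{extra} (9 x samples matrix, rows eyeL x/y/z,
#'   eyeR x/y/z, heart x/y/z) and \code{eye_position} (horizontal gaze in
#'   degrees).
#' @export
simulate_artifacts <- function(trajectory, task, heart_rate = 1.1,
                               blink_rate = 0.2, seed = 1L, eye_gain = 60,
                               blink_amp = 300, heart_amp = 400,
                               pursuit_latency = 0.05) {
  .check_task(task)
  if (heart_rate <= 0.5 || heart_rate >= 3)
    stop("'heart_rate' must lie in (0.5, 3) Hz", call. = FALSE)
  rng <- local_rng(seed)
  t_epoch <- trajectory$time
  S <- length(t_epoch)
  fs <- trajectory$fs

  odd_period <- function(p) {
    p <- min(S, p)
    if (p %% 2L == 0L) p - 1L else p
  }
  overt <- startsWith(task, "overt")
  if (overt) {
    eye_pos <- traj_eval(trajectory, t_epoch - pursuit_latency)$position +
      moving_average(rng$rnorm(S, sd = 0.6), odd_period(101L)) * 3
  } else {
    # Fixation: fast low-amplitude fixational jitter around the centre.
    eye_pos <- moving_average(rng$rnorm(S, sd = 1), odd_period(21L)) * 2
    eye_pos <- eye_pos - mean(eye_pos)
  }

  blink <- numeric(S)
  n_blinks <- rng$rpois(1, blink_rate * (max(t_epoch) - min(t_epoch)))
  if (n_blinks > 0) {
    at <- rng$runif(n_blinks, min(t_epoch), max(t_epoch))
    for (b in at) blink <- blink + exp(-(t_epoch - b)^2 / (2 * 0.06^2))
  }

  phase <- rng$runif(1, 0, 1 / heart_rate)
  beats <- seq(min(t_epoch) + phase, max(t_epoch), by = 1 / heart_rate)
  pulse <- numeric(S)
  for (b in beats) pulse <- pulse + exp(-(t_epoch - b)^2 / (2 * 0.05^2))

  extra <- matrix(0, 9, S,
                  dimnames = list(c("eyeL_x", "eyeL_y", "eyeL_z",
                                    "eyeR_x", "eyeR_y", "eyeR_z",
                                    "heart_x", "heart_y", "heart_z"), NULL))
  extra["eyeL_x", ] <- eye_gain * eye_pos
  extra["eyeR_x", ] <- eye_gain * eye_pos
  extra["eyeL_z", ] <- blink_amp * blink
  extra["eyeR_z", ] <- blink_amp * blink
  extra["heart_x", ] <- heart_amp * 0.8 * pulse
  extra["heart_y", ] <- heart_amp * 0.5 * pulse
  extra["heart_z", ] <- heart_amp * 0.33 * pulse
  list(extra = extra, eye_position = eye_pos)
}

#' Project source currents to the sensor array
#'
#' Sensor data are the linear forward projection of cortical plus
#' extra-brain currents with i.i.d. Gaussian sensor noise:
#' \code{B = G J + G_extra J_extra + noise}.
#'
#' @param fm A \code{forward_model}.
#' @param J Cortical currents, dipoles x samples (or NULL for none).
#' @param extra Extra-brain currents, 9 x samples (or NULL for none).
#' @param sensor_noise_sd Noise SD in sensor units; \code{NULL} (default)
#'   uses 10 percent of the clean-signal RMS.
#' @param seed Integer seed.
#' @return Matrix sensors x samples.
#' @export
synthesize_sensors <- function(fm, J = NULL, extra = NULL,
                               sensor_noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(fm, "forward_model"))
  S <- if (!is.null(J)) ncol(J) else if (!is.null(extra)) ncol(extra) else
    stop("need at least one of 'J', 'extra'", call. = FALSE)
  B <- matrix(0, fm$n_sensors, S)
  if (!is.null(J)) {
    if (nrow(J) != ncol(fm$G) || ncol(J) != S)
      stop("dimension mismatch between 'J' and the lead field",
           call. = FALSE)
    B <- B + fm$G %*% J
  }
  if (!is.null(extra)) {
    if (nrow(extra) != 9L || ncol(extra) != S)
      stop("'extra' must be 9 x samples", call. = FALSE)
    B <- B + fm$G_extra %*% extra
  }
  if (is.null(sensor_noise_sd))
    sensor_noise_sd <- 0.1 * stats::sd(as.numeric(B))
  if (sensor_noise_sd > 0) {
    rng <- local_rng(seed)
    B <- B + matrix(rng$rnorm(length(B), sd = sensor_noise_sd),
                    nrow(B), ncol(B))
  }
  B
}

#' Assemble a trial set
#'
#' @param trials List of sensors x samples matrices.
#' @param fs Sampling rate in Hz.
#' @param task Task label per trial.
#' @param epoch Epoch window in seconds relative to motion onset.
#' @param onset_index Sample index of motion onset.
#' @return Object of class \code{trial_set}.
#' @export
trial_set <- function(trials, fs, task, epoch = c(-0.4, 4),
                      onset_index = round(-epoch[1] * fs) + 1L) {
  ns <- vapply(trials, ncol, 1L)
  if (length(unique(ns)) > 1L)
    stop("all trials must have identical sample counts", call. = FALSE)
  structure(
    list(trials = trials, fs = fs, task = task, epoch = epoch,
         onset_index = as.integer(onset_index),
         retained = rep(TRUE, length(trials))),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials (%d retained), %d sensors, %d samples at %g Hz\n",
              length(x$trials), sum(x$retained), nrow(x$trials[[1]]),
              ncol(x$trials[[1]]), x$fs))
  print(table(x$task[x$retained]))
  invisible(x)
}

#' Reject trials exceeding the recordable range
#'
#' A trial is rejected when any channel sample exceeds
#' \code{threshold_fraction} (default 95 percent) of the recordable range.
#' Retained trials keep their original order.
#'
#' @param trials A \code{trial_set}.
#' @param recordable_range Full-scale absolute field value (> 0).
#' @param threshold_fraction Fraction of the range (in (0, 1]), default 0.95.
#' @return The trial set with an updated \code{retained} mask and a
#'   \code{retention_rate} field.
#' @export
reject_trials <- function(trials, recordable_range,
                          threshold_fraction = 0.95) {
  stopifnot(inherits(trials, "trial_set"))
  .stopifnot_scalar(recordable_range, "recordable_range", positive = TRUE)
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("'threshold_fraction' must lie in (0, 1]", call. = FALSE)
  lim <- threshold_fraction * recordable_range
  ok <- vapply(trials$trials, function(b) max(abs(b)) <= lim, TRUE)
  trials$retained <- ok
  trials$retention_rate <- mean(ok)
  trials
}

#' Keep only retained trials
#'
#' @param trials A \code{trial_set}.
#' @return The trial set restricted to retained trials.
#' @export
retained_trials <- function(trials) {
  keep <- which(trials$retained)
  trials$trials <- trials$trials[keep]
  trials$task <- trials$task[keep]
  trials$retained <- rep(TRUE, length(keep))
  trials
}

#' Simulate a full multi-task sensor dataset
#'
#' Runs the generative chain (trajectories, subpopulation currents, artifact
#' currents, forward projection) for every requested task and trial. Ground
#' truth is kept as per-trial eye traces, extra-brain currents and
#' per-region current summaries; full cortical current matrices are stored
#' only when \code{keep_currents = TRUE}.
#'
#' @param space,fm,spec Source space, forward model and subpopulation spec;
#'   built with defaults when NULL.
#' @param tasks Tasks to simulate (default all five).
#' @param n_trials Trials per task (default 40).
#' @param fs Raw sampling rate in Hz (default 1000).
#' @param seed Master integer seed.
#' @param evoked_amp,noise_sd,sensor_noise_sd,heart_rate,blink_rate,eye_gain
#'   Generator parameters passed through.
#' @param keep_currents Keep full ground-truth current matrices
#'   (memory-heavy; default FALSE).
#' @param n_dipoles,n_sensors Sizes used when \code{space} / \code{fm} are
#'   built internally (defaults 500 / 64).
#' @return List with \code{space}, \code{fm}, \code{spec},
#'   \code{trajectories} (per task), \code{trials} (a \code{trial_set}),
#'   and \code{truth} (per-trial \code{eye_position}, \code{extra},
#'   \code{region_mean}; plus \code{J} if kept).
#' @export
simulate_dataset <- function(space = NULL, fm = NULL, spec = NULL,
                             tasks = PURSUIT_TASKS, n_trials = 40,
                             fs = 1000, seed = 1L, evoked_amp = 30,
                             noise_sd = 10, sensor_noise_sd = NULL,
                             heart_rate = 1.1, blink_rate = 0.2,
                             eye_gain = 60, keep_currents = FALSE,
                             n_dipoles = 500, n_sensors = 64) {
  if (is.null(space)) space <- make_source_space(n_dipoles,
                                                 seed = child_seed(seed, 1))
  if (is.null(fm)) fm <- make_forward_model(space, n_sensors,
                                            seed = child_seed(seed, 2))
  if (is.null(spec)) spec <- default_subpopulations(space,
                                                    seed = child_seed(seed, 3))
  trajectories <- lapply(stats::setNames(tasks, tasks), function(task)
    make_target_trajectory(task_frequency(task), 20, duration = 4, fs = fs,
                           epoch_start = -0.4))
  region_idx <- split(seq_len(space$n_dipoles), space$region)

  trials <- list(); task_lab <- character(0)
  truth <- list(eye_position = list(), extra = list(), region_mean = list(),
                J = if (keep_currents) list() else NULL)
  k <- 0L
  for (task in tasks) {
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      s <- child_seed(seed, 100 + k)
      J <- simulate_currents(space, spec, task, trajectories[[task]],
                             evoked_amp = evoked_amp, noise_sd = noise_sd,
                             seed = s)
      art <- simulate_artifacts(trajectories[[task]], task,
                                heart_rate = heart_rate,
                                blink_rate = blink_rate,
                                eye_gain = eye_gain,
                                seed = child_seed(s, 1))
      trials[[k]] <- synthesize_sensors(fm, J, art$extra,
                                        sensor_noise_sd = sensor_noise_sd,
                                        seed = child_seed(s, 2))
      task_lab[k] <- task
      truth$eye_position[[k]] <- art$eye_position
      truth$extra[[k]] <- art$extra
      truth$region_mean[[k]] <- vapply(region_idx, function(ix)
        mean(abs(J[ix, ])), 0)
      if (keep_currents) truth$J[[k]] <- J
    }
  }
  list(space = space, fm = fm, spec = spec, trajectories = trajectories,
       trials = trial_set(trials, fs, task_lab),
       truth = truth)
}

#' Simulate ground-truth current trials only
#'
#' A lighter-weight generator used for decoder and generalization studies:
#' returns per-task lists of cortical current matrices on a chosen dipole
#' subset at a chosen rate, skipping the sensor array and inverse stages.
#'
#' @inheritParams simulate_dataset
#' @param dipoles Indices of dipoles to keep (default: all population
#'   members plus an equal-sized sample of irrelevant dipoles).
#' @param fs Sampling rate (default 200 Hz, the post-resampling rate).
#' @param epoch_start Epoch start relative to onset (default 0).
#' @return List with \code{space}, \code{spec}, \code{dipoles},
#'   \code{trajectories}, and \code{currents}: per task, a list of
#'   dipoles x samples matrices.
#' @export
simulate_current_dataset <- function(space = NULL, spec = NULL,
                                     tasks = PURSUIT_TASKS, n_trials = 10,
                                     fs = 200, seed = 1L, dipoles = NULL,
                                     evoked_amp = 30, noise_sd = 10,
                                     epoch_start = 0, n_dipoles = 120) {
  if (is.null(space)) space <- make_source_space(n_dipoles,
                                                 seed = child_seed(seed, 1))
  if (is.null(spec)) spec <- default_subpopulations(space,
                                                    seed = child_seed(seed, 3))
  if (is.null(dipoles)) {
    members <- sort(unique(unlist(spec$sets)))
    irr <- which(space$region == "irrelevant")
    rng <- local_rng(child_seed(seed, 4))
    dipoles <- sort(c(members,
                      rng$sample(irr, min(length(irr), length(members)))))
  }
  trajectories <- lapply(stats::setNames(tasks, tasks), function(task)
    make_target_trajectory(task_frequency(task), 20, duration = 4, fs = fs,
                           epoch_start = epoch_start))
  k <- 0L
  currents <- lapply(stats::setNames(tasks, tasks), function(task)
    lapply(seq_len(n_trials), function(tr) {
      k <<- k + 1L
      simulate_currents(space, spec, task, trajectories[[task]],
                        evoked_amp = evoked_amp, noise_sd = noise_sd,
                        seed = child_seed(seed, 500 + k))[dipoles, ,
                                                          drop = FALSE]
    }))
  list(space = space, spec = spec, dipoles = dipoles,
       trajectories = trajectories, currents = currents)
}
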