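#' @keywords internal
"_PACKAGE"

#' Task identifiers of the five-condition pursuit protocol
#'
#' The protocol crosses three task types (control fixation, covert pursuit,
#' overt pursuit) with two target frequencies for the pursuit conditions.
#' The control condition uses the 0.5 Hz target.
#'
#' @format Character vector of length 5.
#' @export
PURSUIT_TASKS <- c("control", "covert_0.5", "covert_0.8",
                   "overt_0.5", "overt_0.8")

.check_task <- function(task) {
  if (length(task) != 1L || !is.character(task) || !(task %in% PURSUIT_TASKS))
    stop("unknown task id: ", paste(task, collapse = ", "),
         " (expected one of ", paste(PURSUIT_TASKS, collapse = ", "), ")",
         call. = FALSE)
  task
}

#' Sinusoidal pursuit-target trajectory
#'
#' Builds the position and velocity time series of a horizontally moving
#' pursuit target. The target is stationary at the screen centre before
#' motion onset and then follows
#' \deqn{x(t) = A \sin(2\pi f t), \qquad A = v_{peak} / (2\pi f),}
#' so that its peak velocity equals \code{peak_velocity} regardless of
#' frequency. A 20 deg/s peak velocity gives peak amplitudes of 6.37 deg at
#' 0.5 Hz and 3.98 deg at 0.8 Hz.
#'
#' @param frequency Target frequency in Hz (> 0).
#' @param peak_velocity Peak target velocity in deg/s (> 0).
#' @param duration Duration of target motion in seconds (> 0).
#' @param fs Sampling rate in Hz; must satisfy \code{fs >= 2 * frequency}.
#' @param epoch_start Start of the sampled epoch in seconds relative to
#'   motion onset (<= 0). Samples before onset have position and velocity 0
#'   (target stationary at centre). Default 0 (motion interval only).
#' @param phase Starting phase in radians; 0 (default) starts the target at
#'   the centre moving at peak velocity.
#' @return An object of class \code{target_trajectory}: a list with fields
#'   \code{time} (s, relative to motion onset), \code{position} (deg),
#'   \code{velocity} (deg/s), \code{frequency}, \code{peak_velocity},
#'   \code{amplitude} (deg), \code{fs}, and \code{onset_index} (first sample
#'   at or after motion onset).
#' @examples
#' tr <- make_target_trajectory(0.5, 20, duration = 4, fs = 200)
#' round(tr$amplitude, 2)  # 6.37
#' @export
make_target_trajectory <- function(frequency, peak_velocity, duration = 4,
                                   fs = 1000, epoch_start = 0, phase = 0) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("'frequency' must be a positive number", call. = FALSE)
  if (!is.numeric(peak_velocity) || length(peak_velocity) != 1L ||
      peak_velocity <= 0)
    stop("'peak_velocity' must be a positive number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a positive number", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive number", call. = FALSE)
  if (fs < 2 * frequency)
    stop("'fs' must be at least twice 'frequency' (Nyquist)", call. = FALSE)
  if (epoch_start > 0)
    stop("'epoch_start' must be <= 0 (relative to motion onset)",
         call. = FALSE)

  amplitude <- peak_velocity / (2 * pi * frequency)
  n_pre  <- as.integer(round(-epoch_start * fs))
  # Epoched trajectories (a pre-onset window) include the motion-offset
  # endpoint, e.g. 4401 samples at 1000 Hz for the [-0.4, 4.0] s epoch.
  n_move <- round(duration * fs) + (n_pre > 0L)
  time <- (seq_len(n_pre + n_move) - 1L - n_pre) / fs
  moving <- time >= 0
  omega <- 2 * pi * frequency
  position <- ifelse(moving, amplitude * sin(omega * time + phase), 0)
  velocity <- ifelse(moving, peak_velocity * cos(omega * time + phase), 0)
  structure(
    list(time = time, position = position, velocity = velocity,
         frequency = frequency, peak_velocity = peak_velocity,
         amplitude = amplitude, fs = fs, duration = duration,
         onset_index = n_pre + 1L),
    class = "target_trajectory")
}

#' @export
print.target_trajectory <- function(x, ...) {
  cat(sprintf(
    "Sinusoidal target trajectory: %.2f Hz, peak %.1f deg/s, amplitude %.2f deg\n",
    x$frequency, x$peak_velocity, x$amplitude))
  cat(sprintf("  %d samples at %g Hz, t in [%.3f, %.3f] s\n",
              length(x$time), x$fs, min(x$time), max(x$time)))
  invisible(x)
}

#' Target frequency of a task
#'
#' @param task Task id (see \code{\link{PURSUIT_TASKS}}). The control task
#'   uses the 0.5 Hz target.
#' @return Frequency in Hz.
#' @export
task_frequency <- function(task) {
  .check_task(task)
  if (grepl("0.8", task, fixed = TRUE)) 0.8 else 0.5
}

#' Trial schedule for one task
#'
#' Each trial shows a central fixation stimulus for 2 s, then the pursuit
#' target at the centre for a further 2 s with a uniform random jitter of
#' +/- 0.5 s, after which the target moves sinusoidally for 4 s. Sensor
#' epochs are extracted from -0.4 s before to 4.0 s after motion onset.
#'
#' @param task Task id.
#' @param n_trials Number of trials (>= 1); the study protocol uses 100
#'   trials per task.
#' @param seed Integer seed; schedules are reproducible for a fixed seed.
#' @param jitter Half-width of the uniform pre-motion jitter in seconds
#'   (default 0.5; 0 gives a fixed 2 s pre-motion interval).
#' @return A data frame of class \code{trial_schedule} with one row per
#'   trial: \code{task}, \code{trial}, \code{fixation_s},
#'   \code{pre_motion_s}, \code{motion_s}, \code{epoch_start},
#'   \code{epoch_end}.
#' @export
make_trial_schedule <- function(task, n_trials = 100, seed = 1L,
                                jitter = 0.5) {
  .check_task(task)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("'n_trials' must be >= 1", call. = FALSE)
  if (jitter < 0 || jitter > 0.5)
    stop("'jitter' must be in [0, 0.5]", call. = FALSE)
  n_trials <- as.integer(n_trials)
  rng <- local_rng(seed)
  pre <- 2 + rng$runif(n_trials, -jitter, jitter)
  out <- data.frame(
    task = task,
    trial = seq_len(n_trials),
    fixation_s = 2.0,
    pre_motion_s = pre,
    motion_s = 4.0,
    epoch_start = -0.4,
    epoch_end = 4.0,
    stringsAsFactors = FALSE)
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Full five-task protocol for one simulated participant
#'
#' @param n_trials Trials per task (default 100, i.e. 500 trials total).
#' @param seed Integer seed.
#' @inheritParams make_trial_schedule
#' @return A \code{trial_schedule} data frame with \code{5 * n_trials} rows.
#' @export
make_protocol <- function(n_trials = 100, seed = 1L, jitter = 0.5) {
  out <- do.call(rbind, lapply(seq_along(PURSUIT_TASKS), function(i)
    make_trial_schedule(PURSUIT_TASKS[i], n_trials,
                        seed = seed + i - 1L, jitter = jitter)))
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Neural functions required by a task
#'
#' The task model assumes three computational brain functions: visual
#' information-processing (all tasks), maintenance of attention (covert and
#' overt pursuit), and eye-movement control (overt pursuit only).
#'
#' @param task Task id.
#' @return Character vector, a subset of
#'   \code{c("visual", "attention", "eye_movement")}.
#' @examples
#' task_functions("control")    # "visual"
#' task_functions("overt_0.5")  # all three
#' @export
task_functions <- function(task) {
  .check_task(task)
  switch(sub("_.*", "", task),
         control = "visual",
         covert  = c("visual", "attention"),
         overt   = c("visual", "attention", "eye_movement"))
}

#' Export a trial schedule as CSV
#'
#' Writes columns \code{task}, \code{trial}, \code{pre_motion_s}.
#'
#' @param schedule A \code{trial_schedule}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule[, c("task", "trial", "pre_motion_s")], path,
                   row.names = FALSE)
  invisible(path)
}
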