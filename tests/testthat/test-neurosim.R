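test_that("source space construction is reproducible and labelled", {
  sp <- make_source_space(500, seed = 1)
  expect_equal(sp$n_dipoles, 500)
  expect_equal(nlevels(droplevels(sp$region)), 7)
  expect_equal(max(abs(rowSums(sp$orientations^2) - 1)), 0, tolerance = 1e-12)
  sp2 <- make_source_space(500, seed = 1)
  expect_identical(sp$positions, sp2$positions)
  # degenerate fractions
  fr <- c(PreCC = 0, MSFC = 0, LOTC = 0, IPC = 0, Precuneus = 0, V1V2 = 0,
          irrelevant = 1)
  sp3 <- make_source_space(60, region_fractions = fr, seed = 2)
  expect_true(all(sp3$region == "irrelevant"))
  fr_bad <- fr; fr_bad["V1V2"] <- 0.5
  expect_error(make_source_space(60, region_fractions = fr_bad), "sum to 1")
  expect_error(make_source_space(10), ">= 50")
})

test_that("lead-field gain decays with source-sensor distance", {
  # Two dipoles with identical orientation; the helmet sits at negative z
  # (superior), so the second dipole is farther from every sensor.
  pos <- rbind(c(0, 0, -60), c(0, 0, 60))
  sp <- fixture_manual_space(pos)
  fm <- make_forward_model(sp, n_sensors = 24, seed = 4)
  d1 <- sqrt(colSums((t(fm$sensor_positions) - pos[1, ])^2))
  d2 <- sqrt(colSums((t(fm$sensor_positions) - pos[2, ])^2))
  expect_true(all(d2 > d1))
  expect_lt(sqrt(sum(fm$G[, 2]^2)), sqrt(sum(fm$G[, 1]^2)))
})

test_that("forward model is reproducible and the heart columns are live", {
  sp <- fixture_space(60, seed = 5)
  fm1 <- make_forward_model(sp, n_sensors = 16, seed = 6)
  fm2 <- make_forward_model(sp, n_sensors = 16, seed = 6)
  expect_identical(fm1$G, fm2$G)
  expect_equal(ncol(fm1$G_extra), 9)
  expect_true(all(colSums(fm1$G_extra[, 7:9]^2) > 0))
  expect_true(all(colSums(fm1$G^2) > 0))
  expect_error(make_forward_model(sp, n_sensors = 5), ">= 10")
})

test_that("population gains respect the task-function table", {
  sp <- fixture_space(150, seed = 7)
  spec <- default_subpopulations(sp, seed = 8)
  gt <- spec$gain_table
  for (task in PURSUIT_TASKS) {
    active <- task_functions(task)
    expect_true(all(gt[active, task] > 0))
    expect_true(all(gt[setdiff(rownames(gt), active), task] == 0))
  }
  # motor subpopulation occupies different dipoles than attention
  expect_length(intersect(spec$sets$attention, spec$sets$eye_movement), 0)
})

test_that("simulated currents gate populations by task", {
  sp <- fixture_space(150, seed = 7)
  spec <- default_subpopulations(sp, seed = 8)
  traj <- fixture_traj(fs = 500)
  # noiseless: inactive populations carry exactly zero
  J <- simulate_currents(sp, spec, "control", traj, evoked_amp = 0,
                         noise_sd = 0, seed = 1)
  expect_true(all(J[spec$sets$eye_movement, ] == 0))
  expect_true(all(J[spec$sets$attention, ] == 0))
  expect_gt(max(abs(J[spec$sets$visual, ])), 0)
  # superposition: evoked bump only, on visual dipoles only
  Jb <- simulate_currents(sp, spec, "control", traj, evoked_amp = 1,
                          noise_sd = 0, seed = 1)
  spec0 <- spec
  spec0$gain_table[] <- 0
  Jb0 <- simulate_currents(sp, spec0, "control", traj, evoked_amp = 1,
                           noise_sd = 0, seed = 1)
  others <- setdiff(seq_len(sp$n_dipoles), spec$sets$visual)
  expect_true(all(Jb0[others, ] == 0))
  peak_at <- traj$time[which.max(Jb0[spec$sets$visual[1], ])]
  expect_equal(peak_at, 0.1, tolerance = 0.01)
  # overt motor current present, correlated with the kinematic drive
  Jo <- simulate_currents(sp, spec, "overt_0.5", traj, evoked_amp = 0,
                          noise_sd = 0, seed = 1)
  expect_gt(max(abs(Jo[spec$sets$eye_movement, ])), 0)
})

test_that("regional mean current in PreCC is larger overt than covert", {
  sp <- fixture_space(300, seed = 9)
  spec <- default_subpopulations(sp, seed = 10)
  traj <- fixture_traj(fs = 500)
  mean_precc <- function(task, seed) {
    J <- simulate_currents(sp, spec, task, traj, seed = seed)
    mean(abs(J[sp$region == "PreCC", ]))
  }
  ov <- mean(vapply(1:5, function(s) mean_precc("overt_0.5", s), 0))
  cv <- mean(vapply(1:5, function(s) mean_precc("covert_0.5", s + 50), 0))
  expect_gt(ov, cv)
})

test_that("artifact sources behave by task", {
  traj <- fixture_traj(fs = 500)
  ov <- simulate_artifacts(traj, "overt_0.5", seed = 3)
  expect_gt(cor(ov$extra["eyeL_x", ], traj$position), 0.9)
  cv <- simulate_artifacts(traj, "covert_0.5", seed = 3)
  expect_lt(abs(cor(cv$extra["eyeL_x", ], traj$position)), 0.2)
  # cardiac pulse train peaks at the heart rate
  hr <- 1.25
  art <- simulate_artifacts(traj, "control", heart_rate = hr, seed = 4)
  spec_est <- stats::spec.pgram(ts(art$extra["heart_x", ], frequency = 500),
                                plot = FALSE, taper = 0)
  peak_hz <- spec_est$freq[which.max(spec_est$spec)]
  expect_equal(peak_hz, hr, tolerance = 0.15)
  expect_error(simulate_artifacts(traj, "control", heart_rate = 4), "heart_rate")
})

test_that("sensor synthesis is linear in the source currents", {
  sp <- fixture_space(60, seed = 11)
  fm <- fixture_forward(sp, n_sensors = 16, seed = 12)
  S <- 50
  J <- matrix(rnorm(60 * S), 60, S)
  B1 <- synthesize_sensors(fm, J, sensor_noise_sd = 0)
  B2 <- synthesize_sensors(fm, 2 * J, sensor_noise_sd = 0)
  expect_equal(B2, 2 * B1, tolerance = 1e-12)
  expect_true(all(synthesize_sensors(fm, 0 * J, sensor_noise_sd = 0) == 0))
  # unit current on dipole k reproduces column k of G
  Jk <- matrix(0, 60, 3); Jk[17, 2] <- 1
  Bk <- synthesize_sensors(fm, Jk, sensor_noise_sd = 0)
  expect_equal(Bk[, 2], fm$G[, 17], tolerance = 1e-12)
  expect_error(synthesize_sensors(fm, matrix(0, 10, 5)), "mismatch")
})

test_that("trial rejection removes only full-range trials", {
  sp <- fixture_space(60, seed = 13)
  fm <- fixture_forward(sp, n_sensors = 16, seed = 14)
  trials <- lapply(1:5, function(i) matrix(rnorm(16 * 40), 16, 40))
  # inject a full-range spike on all channels of trial 3
  trials[[3]][, 20] <- 1000
  ts <- trial_set(trials, fs = 100, task = rep("control", 5),
                  epoch = c(0, 0.4), onset_index = 1L)
  out <- reject_trials(ts, recordable_range = 1000)
  expect_identical(out$retained, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$retention_rate, 0.8)
  # nothing near the range: all retained
  ok <- reject_trials(ts, recordable_range = 1e6)
  expect_true(all(ok$retained))
  expect_identical(formals(reject_trials)$threshold_fraction, 0.95)
  expect_error(reject_trials(ts, recordable_range = -1), "recordable_range")
})

test_that("the full dataset generator is deterministic under a master seed", {
  args <- list(n_trials = 2, seed = 99, tasks = c("control", "overt_0.5"),
               n_dipoles = 60, n_sensors = 12, fs = 250)
  d1 <- do.call(simulate_dataset, args)
  d2 <- do.call(simulate_dataset, args)
  expect_identical(d1$trials$trials, d2$trials$trials)
  expect_identical(d1$truth$eye_position, d2$truth$eye_position)
  # overt eye trace tracks the target; fixation trace does not
  ov <- which(d1$trials$task == "overt_0.5")[1]
  ct <- which(d1$trials$task == "control")[1]
  pos <- d1$trajectories[["overt_0.5"]]$position
  expect_gt(cor(d1$truth$eye_position[[ov]], pos), 0.9)
  expect_lt(abs(cor(d1$truth$eye_position[[ct]],
                    d1$trajectories[["control"]]$position)), 0.3)
})
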