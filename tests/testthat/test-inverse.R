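make_trialset <- function(mats, fs = 200)
  trial_set(mats, fs = fs, task = rep("control", length(mats)),
            epoch = c(0, ncol(mats[[1]]) / fs), onset_index = 1L)

test_that("preprocessing detrends, smooths and decimates as specified", {
  # constant channel survives the moving average untouched
  const <- matrix(5, 2, 1000)
  ts <- trial_set(list(const), fs = 1000, task = "control",
                  epoch = c(0, 1), onset_index = 1L)
  out <- preprocess(ts, ma_period = 9, target_fs = 200)
  expect_equal(max(abs(out$trials[[1]])), 0, tolerance = 1e-10)  # detrended
  # ma_period = 1 leaves the waveform unchanged (up to detrend + decimation)
  x <- sin(2 * pi * 3 * (1:1000) / 1000)
  tsx <- trial_set(list(rbind(x, x)), fs = 1000, task = "control",
                   epoch = c(0, 1), onset_index = 1L)
  out1 <- preprocess(tsx, ma_period = 1, target_fs = 200)
  keep <- seq(1, 1000, by = 5)
  expect_equal(out1$trials[[1]][1, ], detrend_linear(x)[keep],
               tolerance = 1e-10)
  # the standard epoch: 4401 raw samples -> 881 at 200 Hz, onset on grid
  tr <- fixture_traj(fs = 1000)
  big <- trial_set(list(matrix(rnorm(2 * 4401), 2, 4401)), fs = 1000,
                   task = "control")
  outb <- preprocess(big)
  expect_equal(ncol(outb$trials[[1]]), 881)
  expect_equal(outb$onset_index, 81L)
  expect_error(preprocess(big, target_fs = 300), "divide")
  expect_error(preprocess(big, ma_period = 4), "odd")
})

test_that("smoothing operator has unit-sum Gaussian columns", {
  sp <- fixture_space(120, seed = 1)
  fm <- fixture_forward(sp, n_sensors = 24, seed = 2)
  sm <- build_smoothing(sp, fm, reduction = 4)
  expect_equal(length(sm$reduced_idx), 30)  # ceiling(120 / 4)
  expect_equal(max(abs(colSums(sm$W) - 1)), 0, tolerance = 1e-9)
  expect_true(all(sm$W >= 0))
  expect_equal(sm$Ghat, fm$G %*% sm$W, tolerance = 1e-12)
  # 500 dipoles at the reference 4:1 reduction -> 125 reduced dipoles
  sp5 <- make_source_space(500, seed = 3)
  expect_length(build_smoothing(sp5, reduction = 4)$reduced_idx, 125)
  # identity limit
  sm1 <- build_smoothing(sp, fm, sigma = 1e-9, reduction = 1)
  expect_equal(sm1$W, diag(120), tolerance = 1e-12)
  expect_error(build_smoothing(sp, reduction = 121), "exceeds")
})

test_that("fixed-prior posterior equals the Tikhonov solution", {
  sp <- fixture_space(80, seed = 4)
  fm <- fixture_forward(sp, n_sensors = 20, seed = 5)
  sm <- build_smoothing(sp, fm, reduction = 4)
  A <- cbind(sm$Ghat, fm$G_extra)
  set.seed(6)
  B <- matrix(rnorm(20 * 40), 20, 40)
  alpha0 <- runif(ncol(A), 0.5, 3)
  beta0 <- 2.5
  sol <- estimate_currents(make_trialset(list(B)), sm, fm$G_extra,
                           vb = vb_settings(update_hyper = FALSE,
                                            alpha_init = alpha0,
                                            beta_init = beta0))
  oracle <- solve(crossprod(A) + diag(alpha0 / beta0), crossprod(A, B))
  est <- rbind(sol$Z[[1]], sol$extra[[1]])
  expect_equal(est, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the variational objective is non-decreasing", {
  sp <- fixture_space(80, seed = 7)
  fm <- fixture_forward(sp, n_sensors = 20, seed = 8)
  sm <- build_smoothing(sp, fm, reduction = 4)
  set.seed(9)
  z <- matrix(rnorm(ncol(sm$Ghat) * 200, sd = 10), ncol = 200)
  B <- sm$Ghat %*% z + matrix(rnorm(20 * 200), 20, 200)
  sol <- suppressWarnings(estimate_currents(
    make_trialset(list(B)), sm, with_extra = FALSE,
    vb = vb_settings(max_iter = 80)))
  tr <- sol$trace[[1]]
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))
  expect_true(all(sol$alpha[[1]] > 0))
})

test_that("a single noiseless source is recovered near-perfectly", {
  sp <- fixture_space(120, seed = 10)
  fm <- fixture_forward(sp, n_sensors = 30, seed = 11)
  sm <- build_smoothing(sp, fm, reduction = 4)
  S <- 300
  z_true <- matrix(0, ncol(sm$Ghat), S)
  z_true[7, ] <- 40 * sin(2 * pi * 0.5 * (1:S) / 200)
  B <- sm$Ghat %*% z_true
  sol <- suppressWarnings(estimate_currents(
    make_trialset(list(B)), sm, with_extra = FALSE,
    vb = vb_settings(max_iter = 120)))
  expect_gt(cor(sol$Z[[1]][7, ], z_true[7, ]), 0.99)
  # all-zero data give an (essentially) all-zero estimate
  sol0 <- estimate_currents(make_trialset(list(matrix(0, 30, 50))), sm,
                            with_extra = FALSE)
  expect_lt(max(abs(sol0$Z[[1]])), 1e-8)
})

test_that("truly active reduced dipoles are recovered above inactive ones", {
  sp <- make_source_space(300, seed = 12)
  fm <- make_forward_model(sp, n_sensors = 48, seed = 13)
  spec <- default_subpopulations(sp, seed = 14)
  traj <- fixture_traj(fs = 1000)
  sm <- build_smoothing(sp, fm, reduction = 4)
  Js <- lapply(1:2, function(i)
    simulate_currents(sp, spec, "covert_0.5", traj, seed = 20 + i))
  trials <- trial_set(lapply(Js, function(J)
    synthesize_sensors(fm, J, sensor_noise_sd = 0.02, seed = 30)),
    fs = 1000, task = rep("covert_0.5", 2))
  pre <- preprocess(trials)
  sol <- suppressWarnings(estimate_currents(
    pre, sm, with_extra = FALSE, prior = region_prior(sp, sm),
    vb = vb_settings(max_iter = 100, tol = 1e-5)))
  keep <- seq(1, 4401, by = 5)
  # populations carrying signal in a covert trial (eye movement is gated off)
  members <- sort(unique(c(spec$sets$visual, spec$sets$attention)))
  Jhat <- lapply(1:2, function(i) cortical_currents(sol, sm, i))
  cors <- sapply(seq_len(sp$n_dipoles), function(d)
    mean(sapply(1:2, function(i)
      abs(cor(Jhat[[i]][d, ], Js[[i]][d, keep])))))
  grid <- expand.grid(a = cors[members],
                      b = cors[sp$region == "irrelevant"])
  expect_gt(mean(grid$a > grid$b), 0.95)
})

test_that("region statistics scale with the currents", {
  sp <- fixture_space(120, seed = 15)
  J <- list(matrix(2, 120, 10))
  rs <- region_stats(J, sp)
  expect_true(all(rs$mean_intensity == 2))
  expect_equal(attr(rs, "peak")[["all"]], 2)
  rs2 <- region_stats(list(2 * J[[1]]), sp)
  expect_equal(rs2$mean_intensity, 2 * rs$mean_intensity)
})

test_that("region prior magnifies only active regions", {
  sp <- fixture_space(120, seed = 16)
  sm <- build_smoothing(sp, reduction = 4)
  rp <- region_prior(sp, sm, magnification = 8)
  act <- sp$region[sm$reduced_idx] != "irrelevant"
  expect_true(all(rp[act] == 8))
  expect_true(all(rp[!act] == 1))
  expect_error(region_prior(sp, sm, magnification = 0.5), ">= 1")
})
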