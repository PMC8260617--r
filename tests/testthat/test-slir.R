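test_that("the default lag set spans 5-305 ms in 11 taps at 200 Hz", {
  cfg <- slir_config()
  expect_length(cfg$lags, 11)
  expect_equal(cfg$lags, 1 + 6 * (0:10))
  expect_equal(range(cfg$lags_ms), c(5, 305))
})

test_that("lag embedding lays out dipole-major lagged copies", {
  set.seed(1)
  J <- matrix(rnorm(4 * 120), 4, 120)
  cfg <- slir_config(tau = 5, dtau = 2, tpred = 1)
  X <- embed_lags(J, cfg)
  maxlag <- max(cfg$lags)
  expect_equal(dim(X), c(120 - maxlag, 4 * 3))
  expect_equal(attr(X, "rows_time"), (maxlag + 1):120)
  # spot checks across dipoles and lags
  for (i in c(1, 3)) for (j in 1:3) {
    t0 <- maxlag + 5
    expect_equal(X[5, (i - 1) * 3 + j], J[i, t0 - cfg$lags[j]])
  }
  # degenerate embedding: one tap
  X0 <- embed_lags(J, slir_config(tau = 3, dtau = 0, tpred = 1))
  expect_equal(ncol(X0), 4)
  expect_equal(X0[, 2], J[2, 1:119])
  # constant dipole fills its columns with the constant
  Jc <- rbind(J[1, ], 7)
  Xc <- embed_lags(Jc, cfg)
  expect_true(all(Xc[, 4:6] == 7))
  expect_error(embed_lags(J[, 1:10], cfg), "shorter")
})

test_that("fixed-relevance fitting reduces to ridge regression", {
  fx <- fixture_slir(2, 0.3, S = 300)
  alpha0 <- 2; s2 <- 0.5
  fit <- fit_slir(fx$X, fx$y,
                  ard = ard_settings(update_relevance = FALSE,
                                     update_noise = FALSE,
                                     alpha_init = alpha0,
                                     sigma2_init = s2))
  Xc <- scale(fx$X, scale = FALSE)
  yc <- fx$y - mean(fx$y)
  ridge <- solve(crossprod(Xc) + diag(s2 * alpha0, ncol(fx$X)),
                 crossprod(Xc, yc))
  expect_equal(fit$weights, drop(ridge), tolerance = 1e-6)
})

test_that("noiseless support is recovered exactly and interpolated", {
  fx <- fixture_slir(1, 0)
  fit <- suppressWarnings(fit_slir(fx$X, fx$y))
  expect_identical(sort(fit$selected), fx$true_g)
  expect_gt(cor(predict(fit, fx$X), fx$y), 0.999)
})

test_that("grouped sparsity keeps or kills a dipole's lags as a unit", {
  fx <- fixture_slir(3, 0.4)
  fit <- suppressWarnings(fit_slir(fx$X, fx$y))
  L <- fx$cfg$dtau + 1
  for (g in unique(fx$X |> attr("groups"))) {
    wg <- fit$weights[(g - 1) * L + seq_len(L)]
    if (g %in% fit$selected) expect_gt(sum(wg != 0), 0)
    else expect_true(all(wg == 0))
  }
  expect_lte(length(fit$selected), 50)
})

test_that("pure-noise inputs are pruned where least squares keeps all", {
  set.seed(9)
  X <- matrix(rnorm(2000 * 50), 2000, 50)
  attr(X, "groups") <- 1:50
  y <- rnorm(2000)
  fit <- suppressWarnings(fit_slir(X, y))
  expect_lte(length(fit$selected), 5)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(sum(ols$coefficients[-1] != 0), 50)
})

test_that("a constant target yields an intercept-only model", {
  fx <- fixture_slir(4, 0.2, S = 300)
  fit <- fit_slir(fx$X, rep(3.3, nrow(fx$X)))
  expect_equal(fit$w0, 3.3)
  expect_true(all(fit$weights == 0))
  expect_length(fit$selected, 0)
})

test_that("support recovery at SNR 10 over 20 replicates", {
  pr <- vapply(1:20, function(s) {
    fx <- fixture_slir(s, sqrt(1 / 10))
    fit <- suppressWarnings(fit_slir(fx$X, fx$y))
    c(length(intersect(fit$selected, fx$true_g)) /
        max(length(fit$selected), 1),
      length(intersect(fit$selected, fx$true_g)) / length(fx$true_g))
  }, c(precision = 0, recall = 0))
  expect_gte(mean(pr["precision", ]), 0.9)
  expect_gte(mean(pr["recall", ]), 0.9)
})

test_that("predictions are shift-equivariant over valid rows", {
  fx <- fixture_slir(5, 0.3, S = 400)
  fit <- suppressWarnings(fit_slir(fx$X, fx$y))
  J <- fx$J
  Jshift <- J[, c(1, seq_len(ncol(J) - 1))]  # delayed by one sample
  p0 <- predict(fit, embed_lags(J, fx$cfg))
  p1 <- predict(fit, embed_lags(Jshift, fx$cfg))
  n <- length(p0)
  expect_equal(as.numeric(p1[-1]), as.numeric(p0[-n]), tolerance = 1e-10)
  expect_error(predict(fit, fx$X[, 1:20]), "mismatch")
})

test_that("zero-weight models predict the constant intercept", {
  fx <- fixture_slir(6, 0.2, S = 300)
  fit <- fit_slir(fx$X, rep(-1.5, nrow(fx$X)))
  expect_true(all(predict(fit, fx$X) == -1.5))
})

test_that("the task decoder reconstructs held-out kinematics", {
  ds <- simulate_current_dataset(tasks = "covert_0.5", n_trials = 6,
                                 fs = 100, seed = 21)
  cfg <- slir_config(tau = 3, dtau = 10, tpred = 1, fs = 100)
  trials <- ds$currents[["covert_0.5"]]
  traj <- ds$trajectories[["covert_0.5"]]
  model <- fit_decoder(trials[1:4], traj, cfg = cfg)
  pr <- predict(model, trials[[5]])
  rows <- pr$rows_time
  expect_gt(cor(pr$position, traj$position[rows]), 0.8)
  expect_gt(cor(pr$velocity, traj$velocity[rows]), 0.8)
})

test_that("selection reports count selected dipoles by region", {
  sp <- fixture_space(120, seed = 22)
  # two synthetic decoding models with known selections
  v1 <- which(sp$region == "V1V2")[1:3]
  fake_model <- function(sel) {
    m <- list(position = list(selected = sel),
              velocity = list(selected = integer(0)))
    class(m) <- "decoding_model"
    m
  }
  rep1 <- selection_report(list(control = fake_model(v1)), sp)
  expect_equal(sum(rep1$n_selected), 3)
  expect_equal(rep1$n_selected[rep1$region == "V1V2" &
                                 rep1$regressand == "position"], 3L)
  rep0 <- selection_report(list(control = fake_model(integer(0))), sp)
  expect_true(all(rep0$n_selected == 0))
  # identical models give identical counts
  rep2 <- selection_report(list(a = fake_model(v1), b = fake_model(v1)), sp)
  expect_equal(rep2$n_selected[rep2$task == "a"],
               rep2$n_selected[rep2$task == "b"])
})
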