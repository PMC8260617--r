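test_that("cross-validation folds are balanced, disjoint and exhaustive", {
  folds <- tenfold_split(40, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 4))
  expect_identical(sort(unname(unlist(folds))), 1:40)
  # near-balanced when not divisible
  f2 <- tenfold_split(43, seed = 2)
  expect_lte(diff(range(lengths(f2))), 1)
  expect_identical(tenfold_split(25, seed = 5), tenfold_split(25, seed = 5))
  expect_error(tenfold_split(9), "at least")
})

test_that("correlation measures shape only; determination also amplitude", {
  x <- sin(seq(0, 4 * pi, length.out = 100))
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(correlation_coefficient(x, -x), -1)
  expect_equal(correlation_coefficient(x, 2 * x + 5), 1)  # affine invariant
  expect_equal(determination_coefficient(x, x), 1)
  expect_lt(determination_coefficient(x, 2 * x + 5), 0)   # affine sensitive
  expect_equal(determination_coefficient(x, rep(mean(x), 100)), 0)
  expect_equal(determination_coefficient(c(1, 2, 3), c(3, 2, 1)), -3)
  expect_error(correlation_coefficient(x, rep(1, 100)), "zero-variance")
  expect_error(determination_coefficient(rep(1, 100), x), "zero-variance")
})

test_that("normalization yields a unit diagonal and respects the mode", {
  cells <- expand.grid(train = c("a", "b"), test = c("a", "b"),
                       regressand = c("position", "velocity"),
                       stringsAsFactors = FALSE)
  mk <- function(daa, dbb, ab, ba) {
    cells$R2 <- ifelse(cells$train == cells$test,
                       ifelse(cells$train == "a", daa, dbb),
                       ifelse(cells$train == "a", ab, ba))
    cells$r <- cells$R2
    cells
  }
  reps <- list(mk(0.8, 0.4, 0.4, 0.2), mk(0.6, 0.3, 0.3, 0.15))
  ns <- normalize_scores(reps, mode = "test")
  diag_rows <- ns$train == ns$test
  expect_true(all(ns$normalized_mean[diag_rows] == 1))
  expect_true(all(ns$normalized_sd[diag_rows] == 0))
  # by-test-diagonal: the a->b cell equals the b diagonal in each replicate
  ab <- ns[ns$train == "a" & ns$test == "b", ]
  expect_equal(ab$normalized_mean, 1)
  # by-train-diagonal: the same cell is half its training diagonal -> 0.50
  ns_tr <- normalize_scores(reps, mode = "train")
  ab_tr <- ns_tr[ns_tr$train == "a" & ns_tr$test == "b", ]
  expect_equal(ab_tr$normalized_mean, 0.5)
  expect_equal(ab_tr$normalized_sd, 0)
  # switching the mode leaves the diagonal untouched
  expect_true(all(ns_tr$normalized_mean[ns_tr$train == ns_tr$test] == 1))
})

test_that("generalization classes follow the 0.6 / 0.2 thresholds", {
  expect_identical(classify_generalization(c(0.66, 0.6, 0.59, 0.2, 0.19, -1)),
                   c("high", "high", "middle", "middle", "low", "low"))
  expect_error(classify_generalization(NaN), "finite")
})

test_that("permutation p-values behave at the extremes", {
  set.seed(3)
  truth <- lapply(1:10, function(i) rnorm(150))
  # perfect prediction attains the minimal p
  out <- permutation_test(truth, truth, n_perm = 999, seed = 4)
  expect_equal(out$p, 1 / 1000)
  # a permutation-invariant statistic gives p = 1
  const_stat <- function(a, b) 0.42
  outc <- permutation_test(truth, truth, statistic = const_stat,
                           n_perm = 199, seed = 5)
  expect_equal(outc$p, 1)
  expect_error(permutation_test(truth[1], truth[1]), "2 paired")
  expect_error(permutation_test(truth, truth, n_perm = 50), "100")
})

test_that("permutation test is calibrated under the null", {
  # Null emulating the pipeline: the target series is shared across trials
  # and the decoder output is smooth noise unrelated to it.
  set.seed(6)
  target <- 3.98 * sin(2 * pi * 0.8 * (1:400) / 200)
  rej <- vapply(1:200, function(b) {
    truth <- rep(list(target), 8)
    pred <- replicate(8, circular_smooth_noise(400), simplify = FALSE)
    suppressWarnings(permutation_test(truth, pred, n_perm = 199,
                                      seed = sample.int(1e6, 1))$p) <= 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("BH correction matches a brute-force step-up on random inputs", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  out <- bh_correct(p, alpha = 0.05)
  expect_identical(out$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bh_correct(rep(1, 5))$rejected == FALSE))
  expect_true(all(bh_correct(rep(0, 5))$rejected == TRUE))
  set.seed(7)
  for (i in 1:100) {
    pv <- runif(sample(3:30, 1))^sample(1:3, 1)
    a <- runif(1, 0.01, 0.2)
    got <- bh_correct(pv, a)
    want <- oracle_bh(pv, a)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$rejected, want$rejected)
  }
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
})

test_that("shared-dipole categories partition the selected union", {
  # disjoint selections: everything exclusive
  sets <- stats::setNames(list(1:2, 3:4, 5:6, 7:8, 9:10), PURSUIT_TASKS)
  out <- categorize_shared_dipoles(sets)
  expect_equal(sum(out$fraction), 1)
  expect_equal(attr(out, "shared_fraction"), 0)
  # identical selections: all shared by >= 3 tasks
  same <- stats::setNames(rep(list(1:5), 5), PURSUIT_TASKS)
  out2 <- categorize_shared_dipoles(same)
  expect_equal(out2$fraction[out2$category == ">=3-tasks-shared"], 1)
  # randomized membership patterns against the brute-force oracle
  set.seed(8)
  for (i in 1:25) {
    sets_r <- stats::setNames(lapply(1:5, function(k)
      which(runif(12) < 0.4)), PURSUIT_TASKS)
    got <- categorize_shared_dipoles(sets_r)
    want <- table(factor(oracle_categorize(sets_r), levels = got$category))
    expect_equal(got$count, as.integer(want))
    expect_equal(sum(got$fraction), if (sum(got$count)) 1 else 0)
  }
})

test_that("the lag sweep recovers the injected current lead", {
  fr <- c(PreCC = 0, MSFC = 0, LOTC = 0, IPC = 0, Precuneus = 0,
          V1V2 = 0.5, irrelevant = 0.5)
  sp <- make_source_space(60, region_fractions = fr, seed = 2)
  traj <- make_target_trajectory(0.5, 20, duration = 4, fs = 200)
  mk_trials <- function(lag) {
    spec <- default_subpopulations(sp, seed = 2, mix = c(pos = 1, vel = 0),
                                   lag_s = lag)
    lapply(1:6, function(i)
      simulate_currents(sp, spec, "covert_0.5", traj, evoked_amp = 0,
                        seed = 100 + i)[spec$sets$visual, , drop = FALSE])
  }
  sw <- lag_sweep(mk_trials(-0.1), traj, seed = 3)
  expect_lte(abs(attr(sw, "argmax") - (-100)), 25)
  sw0 <- lag_sweep(mk_trials(0), traj, seed = 3)
  expect_lte(abs(attr(sw0, "argmax") - 0), 25)
  # white-noise currents: flat, weak profile
  wn <- lapply(1:6, function(i) matrix(rnorm(10 * 800), 10, 800))
  swn <- lag_sweep(wn, traj, seed = 3)
  expect_lt(max(abs(swn$r)), 0.2)
  expect_error(lag_sweep(wn, traj, lags_ms = c(-6000, 0)), "epoch")
})
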