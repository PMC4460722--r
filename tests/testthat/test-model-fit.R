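# small-window, short-transcript fits keep these tests fast; the full-scale
# parameter-recovery run lives in test-acceptance.R

small_sim <- function(seed, n = 8, len = 300, N = 10,
                      v_range = c(log(5), log(20)),
                      params = gc_bias_params(window_size = 10)) {
  truth <- simulate_truth(n_transcripts = n, length = len, seed = seed,
                          v_range = v_range, params = params)
  list(truth = truth, ds = simulate_counts(truth))
}

test_that("initialization follows the prescribed starting values", {
  tr <- transcript_track("a", strrep("ACGT", 25), c(rep(2, 100)))
  init <- initialize_fit(list(tr), fit_config(window_size = 40))
  expect_equal(unname(init$v["a"]), log(2))
  expect_equal(init$params$positional_weights, rep(1 / 39, 39))
  expect_equal(unname(init$params$stacking_energy), rep(1 / 39, 16))
  expect_equal(init$params$alpha, 0)
  # all-zero tracks are excluded with a warning
  z <- transcript_track("z", strrep("ACGT", 25), rep(0, 100))
  expect_warning(init2 <- initialize_fit(list(tr, z), fit_config()),
                 "all-zero")
  expect_named(init2$v, "a")
  expect_error(suppressWarnings(initialize_fit(list(z), fit_config())),
               class = "stackbias_fit_error")
})

test_that("the least-squares objective matches hand computation", {
  # one eligible position (window = transcript), count 2, affinity 0.5
  tr <- transcript_track("a", "ACGT", c(0, 0, 2, 0))
  p <- stacking_params(energy_table(), rep(1 / 3, 3), window_size = 4)
  obj <- model_objective(list(tr), p, c(a = 0), alpha = 0)
  expect_equal(obj, (2 * log(2))^2)
  # perfect fit: v = log(rate) at every counted position
  tr2 <- transcript_track("b", "ACGTAC", c(0, 0, 1, 1, 0, 0))
  # counts are 1, affinity 0.5 constant, so v = -log(0.5) zeroes residuals
  p2 <- stacking_params(energy_table(), rep(1 / 3, 3), window_size = 4)
  expect_equal(model_objective(list(tr2), p2, c(b = log(2)), 0), 0)
  # no eligible positions
  tr3 <- transcript_track("c", "ACGTAC", rep(0, 6))
  expect_error(model_objective(list(tr3), p2, c(c = 0), 0),
               class = "stackbias_objective_undefined")
})

test_that("poisson deviance matches the loop oracle and its closed cases", {
  expect_gt(poisson_deviance(
    list(transcript_track("a", "ACGTAC", c(0, 0, 3, 5, 0, 0))),
    stacking_params(energy_table(), rep(1 / 3, 3), window_size = 4),
    c(a = 0), alpha = 0), 0)
  # zero-count position against rate 2 contributes 2 * 2
  expect_equal(stackbias:::deviance_from_counts(0, 2), 4)
  expect_equal(stackbias:::deviance_from_counts(c(3, 7), c(3, 7)), 0)
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- rpois(25, 4)
      mu <- runif(25, 0.5, 8)
      expect_equal(stackbias:::deviance_from_counts(n, mu),
                   poisson_deviance_loop(n, mu), tolerance = 1e-10)
    }
  })
  expect_error(stackbias:::deviance_from_counts(2, 0),
               class = "stackbias_infinite_deviance")
})

test_that("exported deviance agrees with a per-position reimplementation", {
  withr::with_seed(4, {
    p <- random_params(6)
    tr <- transcript_track("a", random_sequence(60), rpois(60, 2))
    d <- poisson_deviance(list(tr), p, c(a = 0.3), alpha = 0.1)
    prof <- affinity_profile(tr$sequence, p)
    mu <- exp(0.3 + 0.1) * prof$affinity
    expect_equal(d, poisson_deviance_loop(tr$counts[prof$position + 1], mu),
                 tolerance = 1e-10)
  })
})

test_that("deviance R-squared behaves as 1 - d/d0", {
  expect_equal(r_squared(5, 5), 0)
  expect_equal(r_squared(0, 5), 1)
  expect_equal(r_squared(0.3 * 8, 8), 0.7)
  expect_error(r_squared(1, 0), class = "stackbias_undefined_r2")
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(r_squared(d, 10)) < 0))
})

test_that("fitting simulated bias beats the null model and stays feasible", {
  sim <- small_sim(101, n = 10, len = 400)
  fit <- fit_bias_model(sim$ds, fit_config(window_size = 10, seed = 101))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_true(all(fit$params$positional_weights > 0))
  expect_true(all(fit$params$stacking_energy > 0))
  expect_equal(sum(fit$params$positional_weights), 1, tolerance = 1e-12)
  expect_lt(fit$deviance, fit$null_deviance)
  expect_gt(fit$r_squared, 0)
  # null model evaluated against itself gives R^2 = 0
  d0 <- null_model_deviance(sim$ds, fit_config(window_size = 10))
  expect_equal(r_squared(d0, d0), 0)
})

test_that("fitting uniform-truth data yields a near-constant profile", {
  truth <- simulate_truth(n_transcripts = 10, length = 400, seed = 55,
                          v_range = c(log(8), log(15)),
                          params = null_params(10))
  ds <- simulate_counts(truth)
  fit <- fit_bias_model(ds, fit_config(window_size = 10, seed = 55))
  prof <- affinity_profile(truth$sequences[[1]], fit$params)
  expect_lt(stats::sd(log(prof$affinity)), 0.05)
})

test_that("cross-validation is seed-reproducible and near training R2", {
  sim <- small_sim(7, n = 10, len = 400, v_range = c(log(10), log(30)))
  cfg <- fit_config(window_size = 10, seed = 7)
  cv1 <- cross_validated_r2(sim$ds, cfg)
  cv2 <- cross_validated_r2(sim$ds, cfg)
  expect_identical(as.numeric(cv1), as.numeric(cv2))
  expect_identical(attr(cv1, "folds"), attr(cv2, "folds"))
  fit <- fit_bias_model(sim$ds, cfg)
  expect_lt(abs(as.numeric(cv1) - fit$r_squared), 0.05)
  expect_equal(nrow(attr(cv1, "folds")), 5L)
})

test_that("held-out prediction returns finite fitted rates", {
  sim <- small_sim(3, n = 6, len = 300)
  ids <- names(sim$ds$tracks)
  fit <- fit_bias_model(sim$ds$tracks[ids[-1]],
                        fit_config(window_size = 10, seed = 3))
  pred <- predict_track(sim$ds$tracks[[ids[1]]], fit$params)
  expect_true(all(is.finite(pred$fitted)))
  expect_equal(nrow(pred), 291)   # 300 - 10 + 1 full-context positions
  # fitted totals match observed totals (property of the closed-form v)
  expect_equal(sum(pred$fitted), sum(pred$observed), tolerance = 1e-8)
})
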