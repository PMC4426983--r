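test_that("the three RRP estimators have the model-predicted ordering", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 0)
  fit <- fake_fit(p, tr)
  est <- rrp_estimates(tr, fit)
  v <- setNames(est$value, est$method)

  # ground truth: fused charge from the initially primed pool
  sp <- split_replenishment(p, duration = tr$stim_off)
  F_old <- sp$F_old[nrow(sp)]
  expect_equal(unname(v["model_replenishment"]), F_old,
               tolerance = 0.01)
  # the replenishment current overshoots its steady level after the
  # delayed onset, so C <= A <= B
  expect_lte(v[["model_replenishment"]], v[["baseline_subtraction"]])
  expect_lte(v[["baseline_subtraction"]], v[["integrate_to_timepoint"]])
  # the model steady-state RRP reports the resting pool
  expect_equal(unname(v["model_steady_state"]), 0.5625,
               tolerance = 1e-6)
  expect_equal(est$vesicles, est$value / fit$config$kernel$charge)
})

test_that("without replenishment all integral estimators agree", {
  p0 <- model_params(k1 = 0, k_minus1 = 0.16, k2_max = 3.5)
  tr <- synthesize_trace(p0, noise_sd = 0)
  fit <- fake_fit(p0, tr)
  est <- rrp_estimates(tr, fit)
  v <- setNames(est$value, est$method)
  expect_equal(unname(v["baseline_subtraction"]),
               unname(v["model_replenishment"]), tolerance = 0.01)
  expect_equal(unname(v["integrate_to_timepoint"]),
               unname(v["model_replenishment"]), tolerance = 0.01)
  expect_match(est$flag[est$method == "baseline_subtraction"],
               "no steady phase")
})

test_that("model steady-state RRP is unbiased across noise seeds", {
  p <- default_model_params()
  cfg <- fit_config(global_method = "none", n_starts = 2, fit_dt = 2e-3)
  rrps <- vapply(1:8, function(s) {
    tr <- synthesize_trace(p, noise_sd = 10, seed = 300 + s)
    fit_traces(tr, cfg)$rrp
  }, numeric(1))
  expect_lt(abs(mean(rrps) / 0.5625 - 1), 0.02)
})

test_that("depleted fraction is normalized release", {
  p <- default_model_params()
  p$t0 <- 0
  zero <- p; zero$k2_max <- 0
  traj0 <- integrate_pools(zero, duration = 7, dt = 1e-3,
                           engine = "fixed")
  expect_equal(depleted_fraction(traj0, 0.5625), 0)
  traj <- integrate_pools(p, duration = 7, dt = 1e-3, engine = "fixed")
  own <- traj$R[1] - traj$R[nrow(traj)]
  expect_equal(depleted_fraction(traj, own), 1)
  # consistency with the depletion-curve module
  grid <- c(0.2, 1, 3.5, 10)
  curve <- depletion_curve(p, grid, pulse = 7)
  direct <- vapply(grid, function(k2m) {
    pp <- p; pp$k2_max <- k2m
    tj <- integrate_pools(pp, duration = 7, dt = 1e-3, engine = "fixed")
    depleted_fraction(tj, tj$R[1])
  }, numeric(1))
  expect_equal(direct, curve$fraction, tolerance = 1e-10)
})

test_that("peak release rate grows and accelerates with k2_max", {
  p <- default_model_params()
  flat <- peak_release_rate(integrate_pools(
    model_params(k2_max = 0), duration = 3, dt = 0.01, engine = "fixed"))
  expect_true(flat$flat)
  res <- lapply(c(0.5, 3, 5, 10), function(k2m) {
    pp <- p; pp$k2_max <- k2m
    peak_release_rate(integrate_pools(pp, duration = 7, dt = 1e-3,
                                      engine = "fixed"),
                      reference_rrp = 0.5625)
  })
  rates <- vapply(res, `[[`, numeric(1), "peak_rate")
  tpks <- vapply(res, `[[`, numeric(1), "t_peak")
  expect_true(all(diff(rates) > 0))
  expect_true(all(diff(tpks) < 0))
  expect_equal(res[[2]]$peak_pool_frac, res[[2]]$peak_rate / 0.5625)
})

test_that("spontaneous rate constant divides event frequency by pool size", {
  # 1 Hz over a 10000-vesicle pool
  expect_equal(spontaneous_rate_constant(1, 10000 * 1e-4, 1e-4), 1e-4)
  expect_equal(spontaneous_rate_constant(2, 1.31, 1.31e-4), 2e-4)
  expect_equal(spontaneous_rate_constant(1, 1, 2e-4) /
                 spontaneous_rate_constant(1, 1, 1e-4), 2)
  expect_error(spontaneous_rate_constant(1, 1, 0), "positive")
})

test_that("bootstrap summaries behave like the sampling distribution of the mean", {
  b0 <- bootstrap_means(rep(3.2, 10), n_resamples = 500, seed = 1)
  expect_equal(b0$ci95, c(3.2, 3.2))
  expect_equal(b0$sd, 0)

  set.seed(33)
  x <- rnorm(30)
  b <- bootstrap_means(x, n_resamples = 10000, seed = 2)
  width <- diff(b$ci95)
  expect_lt(abs(width / (2 * 1.96 / sqrt(30)) - 1), 0.15)
  # order invariance for a fixed seed (values are sorted first)
  b_perm <- bootstrap_means(sample(x), n_resamples = 10000, seed = 2)
  expect_identical(b$ci95, b_perm$ci95)
  expect_error(bootstrap_means(1), "at least 2")
})
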