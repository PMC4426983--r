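test_that("the cost function measures squared error on the fit window", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 0, duration = 8)
  cfg <- fit_config(fit_dt = 1e-4)
  # noiseless data generated from the same parameters: cost ~ 0
  expect_lt(model_cost(p, tr, cfg), 1e-4)

  # Gaussian noise of sd sigma: expected cost ~ N * sigma^2
  trn <- synthesize_trace(p, noise_sd = 10, seed = 99, duration = 8)
  N <- sum(trn$t >= trn$stim_on & trn$t <= trn$stim_off)
  expect_equal(model_cost(p, trn, cfg) / (N * 100), 1, tolerance = 0.1)

  # multi-trace cost is order-invariant
  p2 <- default_model_params(k2_max = 0.8)
  tr2 <- synthesize_trace(p2, noise_sd = 10, seed = 7, duration = 8)
  c12 <- model_cost(list(p, p2), list(trn, tr2), cfg)
  c21 <- model_cost(list(p2, p), list(tr2, trn), cfg)
  expect_equal(c12, c21)

  expect_error(model_cost(p, trn, fit_config(fit_window = c(0, 99))),
               "window")
  pbad <- default_model_params(k2_max = 2e6)
  expect_error(model_cost(pbad, trn, cfg), "bounds")
})

test_that("a noiseless synthetic trace returns its generating parameters", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 0)
  fit <- fit_traces(tr, fast_config())
  truth <- c(0.09, 0.16, 3.5, 0.6, 0.2)
  est <- c(fit$k1D, fit$k_minus1, fit$per_trace$k2_max,
           fit$per_trace$t_del, fit$per_trace$tau)
  expect_true(all(abs(est / truth - 1) < 0.01))
  expect_equal(fit$rrp, 0.5625, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("joint fits share priming parameters across concentrations", {
  shared <- list(k1 = 0.09, k_minus1 = 0.16)
  p_lo <- model_params(k1 = shared$k1, k_minus1 = shared$k_minus1,
                       k2_max = 0.6, t_del = 1.2, tau = 0.35)
  p_hi <- model_params(k1 = shared$k1, k_minus1 = shared$k_minus1,
                       k2_max = 3.5, t_del = 0.6, tau = 0.2)
  tr_lo <- synthesize_trace(p_lo, noise_sd = 0, label = "0.25M")
  tr_hi <- synthesize_trace(p_hi, noise_sd = 0, label = "0.5M")
  fit <- fit_traces(list(tr_lo, tr_hi), fast_config())
  expect_equal(fit$k1D, 0.09, tolerance = 0.02)
  expect_equal(fit$k_minus1, 0.16, tolerance = 0.02)
  expect_equal(fit$per_trace$k2_max, c(0.6, 3.5), tolerance = 0.03)
  expect_equal(fit$per_trace$t_del, c(1.2, 0.6), tolerance = 0.03)
})

test_that("fits are deterministic given the seed", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 10, seed = 5, duration = 4)
  cfg <- fit_config(global_method = "none", n_starts = 1, fit_dt = 5e-3,
                    seed = 17)
  f1 <- fit_traces(tr, cfg)
  f2 <- fit_traces(tr, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$sse, f2$sse)
})

test_that("the annealing and evolutionary global stages run and respect bounds", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 10, seed = 31, duration = 4)
  for (gm in c("annealing", "evolutionary")) {
    cfg <- fit_config(global_method = gm, n_starts = 1, fit_dt = 5e-3,
                      max_iter_per_param = 60, seed = 3)
    # the small iteration budget may leave the simplex formally
    # unconverged, which fit_traces flags by warning
    fit <- suppressWarnings(fit_traces(tr, cfg))
    vals <- c(fit$k1D, fit$k_minus1, fit$per_trace$k2_max,
              fit$per_trace$t_del, fit$per_trace$tau)
    expect_true(all(vals >= 1e-5 & vals <= 1e6))
    expect_lt(fit$sse / length(fit$fits[[1]]$t), 400)  # near noise floor
  }
})

test_that("depot refinement separates k1 and D0 only when the refill phase sags", {
  cfg <- fast_config()
  # depletable depot: slow sag of the steady-state phase
  pd <- model_params(k1 = 0.018, D0 = 5, k_minus1 = 0.16, k2_max = 3.5)
  trd <- synthesize_trace(pd, noise_sd = 0, mode = "depletable_D")
  fitd <- fake_fit(model_params(k1 = 0.09, D0 = 1), trd, cfg)
  rd <- refine_depot(fitd, trd, cfg)
  expect_true(rd$identifiable)
  expect_equal(rd$k1, 0.018, tolerance = 0.1)
  expect_equal(rd$D0, 5, tolerance = 0.1)
  # product constrained to the stage-one value
  expect_lt(abs(rd$k1D / fitd$k1D - 1), 0.02)

  # constant priming flux: flat refill, unidentifiable split
  pc <- default_model_params()
  trc <- synthesize_trace(pc, noise_sd = 10, seed = 4)
  fitc <- fake_fit(pc, trc, cfg)
  rc <- refine_depot(fitc, trc, cfg)
  expect_false(rc$identifiable)
})

test_that("the quality screen flags the canonical failure modes", {
  p <- default_model_params()
  tr <- synthesize_trace(p, noise_sd = 10, seed = 12)
  cfg <- fast_config()
  good <- fake_fit(p, tr, cfg)
  good$fits <- fit_grids(p, tr, cfg)
  expect_true(all(quality_screen(good)))

  # onset off by +0.5 s
  p_late <- p; p_late$t_del <- p$t_del + 0.5
  late <- fake_fit(p_late, tr, cfg)
  late$fits <- fit_grids(p_late, tr, cfg)
  expect_false(quality_screen(late)["onset"])

  # halved priming flux misses the steady-state (refill) phase
  p_half <- p; p_half$k1 <- p$k1 / 2
  half <- fake_fit(p_half, tr, cfg)
  half$fits <- fit_grids(p_half, tr, cfg)
  expect_false(quality_screen(half)["steady_state"])
})
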