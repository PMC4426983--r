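test_that("fusion-rate time course has the Gompertz onset shape", {
  p <- default_model_params(t0 = 1)
  # before onset: baseline
  expect_equal(k2_time_course(p, c(0, 0.5, 0.99)), rep(0, 3))
  pb <- default_model_params(t0 = 1, k2_baseline = 2e-4)
  expect_equal(k2_time_course(pb, 0.5), 2e-4)
  # t - t0 = t_del: inner exponent vanishes, k2 = k2_max / e
  expect_equal(k2_time_course(p, 1 + p$t_del), p$k2_max * exp(-1),
               tolerance = 1e-12)
  # printed default set at t - t0 = 0.8 s
  expect_equal(k2_time_course(default_model_params(), 0.5 + 0.8),
               2.4227, tolerance = 1e-4)
  # saturates at k2_max
  expect_equal(k2_time_course(p, 1e3), p$k2_max, tolerance = 1e-12)
  # non-decreasing and bounded after onset
  tt <- seq(1, 20, by = 0.01)
  k2 <- k2_time_course(p, tt)
  expect_true(all(diff(k2) >= 0))
  expect_true(all(k2 <= p$k2_max + 1e-15))
  # instantaneous return to baseline after an explicit offset
  expect_equal(k2_time_course(p, c(5, 8.001), stim_off = 8),
               c(k2_time_course(p, 5), 0))
  expect_error(k2_time_course(p, c(2, 1)), "monotone")
})

test_that("parameter validation enforces the model invariants", {
  expect_error(model_params(k1 = -1), "non-negative")
  expect_error(model_params(k2_max = 1, tau = 0), "tau must be positive")
  expect_error(model_params(t_del = -0.1), "t_del")
  expect_error(model_params(temperature_K = 0), "temperature")
  expect_error(site_params(default_model_params(), 0), "positive")
  # JSON round trip preserves every field
  p <- model_params(k1 = 0.05, k_minus1 = 0.2, k2_max = 1.7, t0 = 0.4,
                    t_del = 0.55, tau = 0.18, D0 = 1.3,
                    k2_baseline = 2e-4, temperature_K = 296)
  q <- params_from_json(params_to_json(p))
  expect_equal(unclass(q), unclass(p))
})

test_that("steady-state RRP follows the priming/unpriming balance", {
  # fitted means: k1D = 0.132 nC/s, k_minus1 = 0.11 1/s -> 1.2 nC
  p <- model_params(k1 = 0.132, D0 = 1, k_minus1 = 0.11)
  expect_equal(steady_state_rrp(p), 1.2, tolerance = 1e-12)
  expect_equal(steady_state_rrp(model_params(k1 = 0, k_minus1 = 0.1)), 0)
  # monotone decreasing in k2
  r <- steady_state_rrp(p, k2 = c(0, 0.5, 5, 500))
  expect_true(all(diff(r) < 0))
  expect_lt(steady_state_rrp(p, k2 = 1e9), 1e-7)
  expect_error(steady_state_rrp(model_params(k1 = 1, k_minus1 = 0)),
               "undefined")
})

test_that("release-site model matches the unconstrained model under the stated transformation", {
  p <- default_model_params()
  sp <- site_params(p, S = 2)
  k1D <- p$k1 * p$D0
  # steady state: k1D <-> k1*D*S and k_minus1 + k2 <-> k1D + k_minus1 + k2
  for (k2 in c(0, 0.5, 3.5)) {
    transformed <- model_params(k1 = k1D * sp$S, D0 = 1,
                                k_minus1 = k1D + p$k_minus1)
    expect_equal(steady_state_rrp_sites(sp, k2),
                 steady_state_rrp(transformed, k2), tolerance = 1e-14)
  }
  # S -> Inf with k1*D*S held constant
  c0 <- 5
  big <- site_params(model_params(k1 = c0 / 1e8, D0 = 1,
                                  k_minus1 = p$k_minus1), S = 1e8)
  expect_equal(steady_state_rrp_sites(big, 0.5),
               c0 / (c0 / 1e8 + p$k_minus1 + 0.5), tolerance = 1e-9)
  # all sites filled when priming dominates
  full <- site_params(model_params(k1 = 1e5, D0 = 1, k_minus1 = 1e-4),
                      S = 3)
  expect_equal(steady_state_rrp_sites(full, 0), 3, tolerance = 1e-6)

  # dynamics: dR/dt = k1D(S - R) - (km1 + k2)R equals the unconstrained
  # equation with transformed parameters, pointwise
  k2f <- function(t) k2_time_course(p, t)
  rhs <- function(t, y, parms)
    list(k1D * (sp$S - y) - (p$k_minus1 + k2f(t)) * y)
  R0 <- steady_state_rrp_sites(sp, 0)
  times <- seq(0, 8, by = 0.01)
  site_sol <- deSolve::ode(y = R0, times = times, func = rhs,
                           parms = NULL, method = "ode45",
                           rtol = 1e-10, atol = 1e-12)[, 2]
  transformed <- model_params(k1 = k1D * sp$S, D0 = 1,
                              k_minus1 = k1D + p$k_minus1,
                              k2_max = p$k2_max, t0 = p$t0,
                              t_del = p$t_del, tau = p$tau)
  equiv <- integrate_pools(transformed, duration = 8, dt = 0.01,
                           k2_fun = k2f, R0 = R0)
  expect_lt(max(abs(site_sol - equiv$R)) / R0, 1e-8)
})

test_that("pool integration preserves equilibria and conserves mass", {
  p <- default_model_params(k2_max = 0)
  traj <- integrate_pools(p, duration = 5, dt = 0.05)
  expect_equal(traj$R, rep(traj$R[1], nrow(traj)), tolerance = 1e-9)

  # steady-state initialization needs k_minus1 > 0 unless R0 is given
  p0 <- model_params(k1 = 0.1, k_minus1 = 0)
  expect_error(integrate_pools(p0, duration = 1), "R0")
  expect_silent(integrate_pools(p0, duration = 1, R0 = 0.5, dt = 0.1))

  # mass conservation in depletable mode over random parameter sets
  for (pp in random_params(20, seed = 42)) {
    traj <- integrate_pools(pp, duration = 20, mode = "depletable_D",
                            dt = 0.1)
    total <- traj$D + traj$R + traj$F
    expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
  }

  # monotone depletion: no priming, constant fusion rate
  pm <- model_params(k1 = 0, k_minus1 = 0, k2_max = 2)
  traj <- integrate_pools(pm, duration = 3, dt = 0.01, R0 = 1,
                          k2_fun = function(t) rep(2, length(t)))
  expect_true(all(diff(traj$R) < 0))

  # fixed-step and adaptive engines agree
  p <- default_model_params()
  a <- integrate_pools(p, duration = 8, dt = 1e-3, engine = "adaptive")
  f <- integrate_pools(p, duration = 8, dt = 1e-3, engine = "fixed")
  expect_lt(max(abs(a$R - f$R)) / max(a$R), 1e-8)
})

test_that("replenishment split is linear and bounded", {
  p <- default_model_params()
  sp <- split_replenishment(p, duration = 7.5, dt = 1e-3)
  full <- integrate_pools(p, duration = 7.5, dt = 1e-3, engine = "fixed")
  expect_lt(max(abs(sp$R_old + sp$R_new - full$R)) / full$R[1], 1e-8)
  # no priming flux: R_new identically zero, R_old is the full solution
  p0 <- model_params(k1 = 0, k_minus1 = 0.16, k2_max = 3.5)
  sp0 <- split_replenishment(p0, duration = 7.5, R0 = 0.5625)
  full0 <- integrate_pools(p0, duration = 7.5, dt = 1e-3, R0 = 0.5625,
                           engine = "fixed")
  expect_equal(sp0$R_new, rep(0, nrow(sp0)))
  expect_lt(max(abs(sp0$R_old - full0$R)), 1e-10)
  # R_new stays positive and below its asymptotic steady state
  n <- nrow(sp)
  expect_gt(sp$R_new[n], 0)
  expect_lt(sp$R_new[n],
            p$k1 * p$D0 / (p$k_minus1 + p$k2_max) * (1 + 1e-6))
  # currents carry the inward-negative sign
  expect_true(all(sp$I_old <= 0) && all(sp$I_new <= 0))
})

test_that("post-stimulus RRP recovery is mono-exponential with rate k_minus1", {
  p <- model_params(k1 = 0.132, D0 = 1, k_minus1 = 0.11)
  Rend <- 0.05
  expect_equal(rrp_recovery(p, Rend, 0), Rend)
  expect_equal(rrp_recovery(p, Rend, 1e6), steady_state_rrp(p))
  # closed form against the ODE with k2 = 0 from the depleted state
  p0 <- model_params(k1 = 0.132, D0 = 1, k_minus1 = 0.11, k2_max = 0)
  traj <- integrate_pools(p0, duration = 30, dt = 0.1, R0 = Rend)
  expect_lt(max(abs(traj$R - rrp_recovery(p, Rend, traj$t))) /
              steady_state_rrp(p), 1e-8)
  expect_error(rrp_recovery(model_params(k1 = 1, k_minus1 = 0), 1, 1),
               "k_minus1")
})
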