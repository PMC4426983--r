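test_that("rate ratios map to barrier changes via the Arrhenius relation", {
  expect_equal(delta_Ea_from_rates(1, exp(1))$value, 1)
  expect_equal(delta_Ea_from_rates(0.37, 0.37)$value, 0)
  # a 10^4-fold rate increase is a ~9.2 RT barrier reduction
  expect_equal(delta_Ea_from_rates(2e-4, 2)$value, log(1e4),
               tolerance = 1e-12)
  expect_equal(round(delta_Ea_from_rates(2e-4, 2)$value, 2), 9.21)
  # antisymmetric under argument swap
  expect_equal(delta_Ea_from_rates(0.3, 1.7)$value,
               -delta_Ea_from_rates(1.7, 0.3)$value)
  expect_error(delta_Ea_from_rates(0, 1), "positive")
})

test_that("RT units convert to kcal/mol with the gas constant", {
  # 9.3 RT at 293 K is the 5.4 kcal/mol barrier reduction
  expect_equal(round(rt_to_kcal(energy_delta(9.3, 293)), 1), 5.4)
  expect_equal(rt_to_kcal(0), 0)
  expect_equal(rt_to_kcal(1, 293), 1.9872e-3 * 293, tolerance = 1e-12)
  expect_equal(round(rt_to_kcal(1, 293), 3), 0.582)
})

test_that("additive energies act multiplicatively and round-trip exactly", {
  expect_equal(apply_energy_deltas(1.3, numeric(0)), 1.3)
  expect_equal(apply_energy_deltas(0.2, c(1.1, -0.4)),
               apply_energy_deltas(0.2, 0.7))
  expect_equal(apply_energy_deltas(2e-4, log(1e4)), 2, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:200) {
    k <- exp(runif(1, -9, 3))
    d <- runif(sample(1:4, 1), -5, 5)
    expect_equal(delta_Ea_from_rates(k, apply_energy_deltas(k, d))$value,
                 sum(d), tolerance = 1e-12)
  }
})

test_that("the allosteric ladder is a geometric rate sequence", {
  lad <- allosteric_ladder(l_plus = 2e-4, f = 31.3)
  r <- allosteric_rates(lad)
  expect_length(r, 6)
  expect_equal(r[1], 2e-4)
  expect_equal(r[6] / r[1], 31.3^5)
  # each binding step applies the same additive barrier reduction
  via_deltas <- vapply(0:5, function(n)
    apply_energy_deltas(2e-4, rep(log(31.3), n)), numeric(1))
  expect_equal(r, via_deltas, tolerance = 1e-14)
  flat <- allosteric_rates(allosteric_ladder(0.1, 1))
  expect_equal(flat, rep(0.1, 6))
  expect_error(allosteric_ladder(1, 0.5), "f")
})

test_that("mono-exponential dose-response fits recover their parameters", {
  M <- c(0.2, 0.3, 0.4, 0.5, 0.75, 1)
  truth <- c(a = -10, b = 3, c = 0)
  f <- fit_energy_dose_response(M, -10 * exp(-3 * M))
  expect_false(f$degenerate)
  expect_equal(c(f$a, f$b, f$c), unname(truth), tolerance = 1e-6)

  fc <- fit_energy_dose_response(M, rep(-2, 6))
  expect_true(fc$degenerate)
  expect_true(is.na(fc$b))
  expect_equal(fc$c, -2)

  expect_error(fit_energy_dose_response(c(0.5, 0.5, 0.5), c(1, 2, 3)),
               "distinct")

  # with sigma = 0.2 RT noise the offset c is recovered without bias
  set.seed(21)
  cs <- replicate(20, {
    fit_energy_dose_response(M, -10 * exp(-3 * M) + rnorm(6, 0, 0.2))$c
  })
  expect_lt(abs(mean(cs) - 0), 3 * sd(cs) / sqrt(length(cs)))

  # back-transformation anchors the rate curve at the reference
  curve <- energy_to_rate_curve(f, c(0.25, 0.5, 1), k2_ref = 1.72,
                                M_ref = 0.5)
  expect_equal(curve$k2_max_s[2], 1.72)
  expect_true(all(diff(curve$k2_max_s) > 0))
})

test_that("rate-domain SEMs map to the larger asymmetric energy error", {
  k2 <- 1.7; sem <- 0.4
  up <- log(k2 + sem) - log(k2)
  down <- log(k2) - log(k2 - sem)
  expect_equal(energy_error_from_rate_sem(k2, sem), max(up, down))
  expect_gt(down, up)  # log transform inflates the lower half
  expect_error(energy_error_from_rate_sem(1, 1), "smaller")
})
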