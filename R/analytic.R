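#' Closed-form RRP depletion without replenishment
#'
#' When replenishment and the onset delay are neglected, release from the
#' RRP obeys \eqn{dR/dt = -k_2(t) R} with the single-exponential rate
#' \eqn{k_2(t) = k_{2,max}(1 - e^{-t/\tau})}, which integrates to
#' \deqn{R(t) = R_0 \, e^{-k_{2,max}(\tau e^{-t/\tau} + t) + k_{2,max}\tau}.}
#' This closed form serves as the independent oracle for the numerical
#' integrator and as a fast predictor of release kinetics.
#'
#' @param R0 initial RRP size (nC).
#' @param k2_max maximal fusion rate constant (1/s).
#' @param tau rise time constant (s), positive.
#' @param t time grid (s), starting at the onset of sucrose action.
#' @return A data frame with columns `t`, `k2` (1/s), `R` (nC, monotone
#'   non-increasing) and `rate` (`k2 * R`, nC/s).
#' @examples
#' sol <- rrp_no_replenishment(1, k2_max = 3, tau = 0.2, t = seq(0, 5, 0.01))
#' sol$R[1] # equals R0
#' @export
rrp_no_replenishment <- function(R0, k2_max, tau, t) {
  stopifnot(is.numeric(R0), R0 >= 0, is.numeric(k2_max), k2_max >= 0)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  stopifnot(is.numeric(t), all(t >= 0))
  k2 <- k2_max * (1 - exp(-t / tau))
  R <- R0 * exp(-k2_max * (tau * exp(-t / tau) + t) + k2_max * tau)
  data.frame(t = t, k2 = k2, R = R, rate = k2 * R)
}

#' Delay-free fusion-rate time course
#'
#' The single-exponential approximation of the fusion-rate onset used by
#' the closed-form solution, `k2(t) = k2_max*(1 - exp(-t/tau))`. Only the
#' oracle path uses it; the Gompertz onset of [k2_time_course()] is
#' canonical elsewhere.
#'
#' @inheritParams rrp_no_replenishment
#' @return Fusion rate constants (1/s).
#' @export
k2_single_exponential <- function(k2_max, tau, t) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  k2_max * (1 - exp(-pmax(t, 0) / tau))
}

#' Analytical approximation of the depleted RRP fraction
#'
#' For a long stimulus the RRP relaxes from its resting steady state to a
#' new steady state, and with a non-depletable depot and negligible
#' resting fusion the depleted fraction reduces to
#' \deqn{1 - \frac{k_{-1}}{k_{-1} + k_{2,max}} =
#'       \frac{k_{2,max}}{k_{-1} + k_{2,max}}.}
#' The expression is strictly increasing in `k2_max` and strictly
#' decreasing in `k_minus1`, and lies in `[0, 1)`.
#'
#' @param k_minus1 unpriming rate constant (1/s).
#' @param k2_max maximal fusion rate constant (1/s).
#' @return Depleted RRP fraction (dimensionless).
#' @examples
#' depleted_fraction_ss(0.11, 1.7233) # ~0.94
#' @export
depleted_fraction_ss <- function(k_minus1, k2_max) {
  stopifnot(is.numeric(k_minus1), is.numeric(k2_max),
            all(k_minus1 >= 0), all(k2_max >= 0))
  if (any(k_minus1 + k2_max <= 0))
    stop("k_minus1 + k2_max must be positive")
  k2_max / (k_minus1 + k2_max)
}

#' Simulated depletion curve over a fusion-rate grid
#'
#' For each `k2_max` on the grid, simulates a sucrose pulse and reports
#' the depleted RRP fraction. Two estimators are available: the
#' steady-state drop `1 - R(end)/R(0)` and the released-charge estimator
#' (fused charge originating from the initially primed pool, normalized
#' to `R(0)`). On a log10 `k2_max` axis the curve is sigmoidal and
#' non-decreasing; for long pulses in `constant_k1D` mode it converges to
#' [depleted_fraction_ss()].
#'
#' @param params a [model_params()] object; its `k2_max` is replaced by
#'   each grid value. The stimulus is applied from `t = 0` (`t0 = 0`).
#' @param k2_grid fusion-rate grid (1/s).
#' @param pulse stimulus duration (s).
#' @param mode pool mode passed to the simulation.
#' @param estimator `"steady_state"` or `"charge"`.
#' @param dt integration step (s).
#' @return A data frame with columns `k2_max`, `fraction`, `estimator`,
#'   `mode`.
#' @export
depletion_curve <- function(params, k2_grid, pulse,
                            mode = c("constant_k1D", "depletable_D"),
                            estimator = c("steady_state", "charge"),
                            dt = 1e-3) {
  stopifnot(inherits(params, "model_params"), pulse > 0,
            length(k2_grid) >= 1L, all(k2_grid >= 0))
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  frac <- vapply(k2_grid, function(k2m) {
    p <- params
    p$k2_max <- k2m
    p$t0 <- 0
    if (k2m > 0 && p$tau <= 0) stop("tau must be positive")
    if (estimator == "steady_state") {
      traj <- integrate_pools(p, duration = pulse, mode = mode, dt = dt,
                              engine = "fixed")
      1 - traj$R[nrow(traj)] / traj$R[1]
    } else {
      sp <- split_replenishment(p, duration = pulse, dt = dt)
      R0 <- sp$R_old[1]
      if (R0 <= 0) 0 else sp$F_old[nrow(sp)] / R0
    }
  }, numeric(1))
  data.frame(k2_max = k2_grid, fraction = frac, estimator = estimator,
             mode = mode)
}

#' Write a depletion curve as two-column text
#'
#' @param curve a data frame from [depletion_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_depletion_curve <- function(curve, path) {
  stopifnot(all(c("k2_max", "fraction") %in% names(curve)))
  write.table(curve[, c("k2_max", "fraction")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
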