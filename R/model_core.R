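#' Time course of the fusion rate constant during a hypertonic challenge
#'
#' The fusion rate constant rises smoothly after the stimulus with a
#' Gompertz-type ("expo-exponential") time course
#' \deqn{k_2(t) = k_{2,max}\,e^{-e^{-(t - t_0 - t_{del})/\tau}}, \quad t \ge t_0,}
#' capturing the delayed onset (`t_del`) and the smooth transition
#' (`tau`) of sucrose action. Before `t0` the rate equals `k2_baseline`.
#' If `stim_off` is given, the rate returns instantaneously to
#' `k2_baseline` after that time; otherwise it holds its course (the
#' model does not prescribe an offset kinetics, see the methods
#' vignette).
#'
#' @param params a [model_params()] object.
#' @param t numeric vector of times (s), monotone increasing.
#' @param stim_off optional stimulus offset time (s).
#' @return Numeric vector of fusion rate constants (1/s), non-decreasing
#'   on `t >= t0` and bounded by `k2_max`.
#' @examples
#' p <- default_model_params(t0 = 0)
#' k2_time_course(p, c(0.6, 0.8, 5)) # t - t0 = t_del gives k2_max/e
#' @export
k2_time_course <- function(params, t, stim_off = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (length(t) > 1L && any(diff(t) < 0))
    stop("time grid must be monotone increasing")
  k2 <- rep(params$k2_baseline, length(t))
  on <- t >= params$t0
  if (any(on)) {
    k2[on] <- params$k2_max *
      exp(-exp(-(t[on] - params$t0 - params$t_del) / params$tau))
  }
  if (!is.null(stim_off)) k2[t > stim_off] <- params$k2_baseline
  k2
}

# k2 series on a uniform half-step grid covering n steps of size dt from t1,
# optionally overridden by a user-supplied rate function.
k2_half_series <- function(params, t1, n_steps, dt, k2_fun = NULL,
                           stim_off = NULL) {
  th <- t1 + seq(0L, 2L * n_steps) * (dt / 2)
  if (is.null(k2_fun)) k2_time_course(params, th, stim_off = stim_off)
  else k2_fun(th)
}

resolve_R0 <- function(params, R0) {
  if (!is.null(R0)) {
    stopifnot(is.numeric(R0), length(R0) == 1L, R0 >= 0)
    return(R0)
  }
  if (params$k_minus1 <= 0)
    stop("steady-state initialization requires k_minus1 > 0; ",
         "supply R0 explicitly")
  params$k1 * params$D0 / params$k_minus1
}

#' Integrate the vesicle pool dynamics
#'
#' Integrates the coupled pool equations
#' \deqn{dD/dt = -k_1 D + k_{-1} R, \qquad
#'       dR/dt = k_1 D - (k_{-1} + k_2(t)) R,}
#' with the cumulative fused charge \eqn{dF/dt = k_2(t) R} tracked for
#' charge bookkeeping. In `constant_k1D` mode the depot is frozen so the
#' priming flux `k1*D0` is constant and only the RRP equation is
#' integrated (the regime assumed during the initial fit of a trace); in
#' `depletable_D` mode both pools run and `D + R + F` is conserved.
#'
#' The initial condition is the resting steady state with `k2 = 0`:
#' `D(0) = D0`, `R(0) = k1*D0/k_minus1`. With `k_minus1 = 0` this is
#' undefined and `R0` must be supplied.
#'
#' @param params a [model_params()] object.
#' @param duration simulated interval (s), starting at `t = 0`.
#' @param mode `"constant_k1D"` (frozen depot) or `"depletable_D"`.
#' @param dt output sampling interval (s).
#' @param times optional explicit output grid (overrides `duration`/`dt`);
#'   must be uniform when `engine = "fixed"`.
#' @param R0 optional initial RRP (nC); required when `k_minus1 = 0`.
#' @param k2_fun optional function of time overriding [k2_time_course()].
#' @param stim_off optional stimulus offset passed to [k2_time_course()].
#' @param engine `"adaptive"` for the variable-step explicit Runge-Kutta
#'   4(5) solver (deSolve's `ode45`, interpolated onto the output grid) or
#'   `"fixed"` for the fast fixed-step RK4 integrator used inside the
#'   fitting loop.
#' @param rtol,atol relative and absolute integration tolerances for the
#'   adaptive engine.
#' @return A data frame of class `pool_trajectory` with columns `t`, `D`,
#'   `R`, `F` (cumulative fused charge, from 0).
#' @examples
#' traj <- integrate_pools(default_model_params(), duration = 8, dt = 0.01)
#' max(traj$R)
#' @export
integrate_pools <- function(params, duration,
                            mode = c("constant_k1D", "depletable_D"),
                            dt = 1e-3, times = NULL, R0 = NULL,
                            k2_fun = NULL, stim_off = NULL,
                            engine = c("adaptive", "fixed"),
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (is.null(times)) {
    stopifnot(duration > 0)
    times <- seq(0, duration, by = dt)
  } else {
    if (length(times) < 2L || any(diff(times) <= 0))
      stop("times must be increasing with at least two points")
  }
  R0 <- resolve_R0(params, R0)
  depletable <- mode == "depletable_D"

  if (engine == "fixed") {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-9)
      stop("fixed engine requires a uniform time grid")
    h <- dts[1]
    k2h <- k2_half_series(params, times[1], length(times) - 1L, h,
                          k2_fun = k2_fun, stim_off = stim_off)
    sol <- pool_rk4_cpp(params$k1, params$k_minus1, params$D0, R0,
                        k2h, h, depletable)
    out <- data.frame(t = times, D = sol$D, R = sol$R, F = sol$F)
  } else {
    k2_at <- if (is.null(k2_fun)) {
      function(t) k2_time_course(params, t, stim_off = stim_off)
    } else {
      k2_fun
    }
    prime_const <- params$k1 * params$D0
    rhs <- function(t, y, parms) {
      k2 <- k2_at(t)
      if (depletable) {
        dD <- -params$k1 * y[1] + params$k_minus1 * y[2]
        dR <- params$k1 * y[1] - (params$k_minus1 + k2) * y[2]
      } else {
        dD <- 0
        dR <- prime_const - (params$k_minus1 + k2) * y[2]
      }
      list(c(dD, dR, k2 * y[2]))
    }
    sol <- deSolve::ode(y = c(D = params$D0, R = R0, F = 0), times = times,
                        func = rhs, parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    out <- data.frame(t = sol[, "time"], D = sol[, "D"], R = sol[, "R"],
                      F = sol[, "F"])
  }
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  class(out) <- c("pool_trajectory", "data.frame")
  out
}

#' Steady-state RRP size
#'
#' The RRP at dynamic equilibrium between priming, unpriming and fusion:
#' \deqn{R_\infty = \frac{k_1 D_0}{k_{-1} + k_2}.}
#' With `k2 = 0` (the default) this is the resting RRP used for RRP
#' reporting; the pre-stimulus fusion rate is neglected because it is
#' orders of magnitude smaller than the unpriming rate constant.
#'
#' @param params a [model_params()] object.
#' @param k2 fusion rate constant (1/s) at which to evaluate the steady
#'   state.
#' @return Steady-state RRP (nC).
#' @examples
#' # fitted means k1*D = 0.132 nC/s, k_minus1 = 0.11 1/s give a 1.2 nC RRP
#' steady_state_rrp(model_params(k1 = 0.132, D0 = 1, k_minus1 = 0.11))
#' @export
steady_state_rrp <- function(params, k2 = 0) {
  stopifnot(inherits(params, "model_params"), is.numeric(k2), all(k2 >= 0))
  if (any(params$k_minus1 + k2 <= 0))
    stop("steady state undefined: k_minus1 + k2 must be positive")
  params$k1 * params$D0 / (params$k_minus1 + k2)
}

#' Steady-state RRP with a limited number of release sites
#'
#' Steady state of the release-site variant,
#' \deqn{R_\infty = \frac{k_1 D_0 S}{k_1 D_0 + k_{-1} + k_2},}
#' which coincides with [steady_state_rrp()] under the parameter
#' transformation `k1*D <-> k1*D*S` and `k_minus1 + k2 <-> k1*D +
#' k_minus1 + k2` between the two systems.
#'
#' @param params a [site_params()] object.
#' @param k2 fusion rate constant (1/s).
#' @return Steady-state RRP (nC).
#' @export
steady_state_rrp_sites <- function(params, k2 = 0) {
  stopifnot(inherits(params, "site_params"), is.numeric(k2), all(k2 >= 0))
  den <- params$k1 * params$D0 + params$k_minus1 + k2
  if (any(den <= 0)) stop("steady state undefined: degenerate denominator")
  params$k1 * params$D0 * params$S / den
}

#' Split the RRP into initially primed and newly primed components
#'
#' During the stimulus the RRP consists of vesicles already primed at
#' onset (`R_old`, draining as \eqn{dR_{old}/dt = -(k_{-1}+k_2)R_{old}})
#' and vesicles primed during the stimulus (`R_new`, with
#' \eqn{dR_{new}/dt = k_1 D - (k_{-1}+k_2)R_{new}} from 0). Their sum
#' equals the full solution by linearity, and the recorded current is
#' `I = -k2*(R_old + R_new)` (inward currents are negative while pools
#' are positive charge). The fused charge from each component is
#' accumulated as `F_old`, `F_new`; `F_old` is the replenishment-free
#' released charge used by the model-corrected RRP estimator.
#'
#' @inheritParams integrate_pools
#' @return A data frame of class `replenishment_split` with columns `t`,
#'   `R_old`, `R_new`, `I_old`, `I_new` (nA, negative), `F_old`, `F_new`.
#' @export
split_replenishment <- function(params, duration, dt = 1e-3, R0 = NULL,
                                k2_fun = NULL, stim_off = NULL) {
  stopifnot(inherits(params, "model_params"), duration > 0)
  R0 <- resolve_R0(params, R0)
  times <- seq(0, duration, by = dt)
  n <- length(times) - 1L
  k2h <- k2_half_series(params, 0, n, dt, k2_fun = k2_fun,
                        stim_off = stim_off)
  old <- pool_rk4_cpp(0, params$k_minus1, 0, R0, k2h, dt, FALSE)
  new <- pool_rk4_cpp(params$k1, params$k_minus1, params$D0, 0, k2h, dt,
                      FALSE)
  k2 <- k2h[seq(1L, 2L * n + 1L, by = 2L)]
  out <- data.frame(t = times, R_old = old$R, R_new = new$R,
                    I_old = -k2 * old$R, I_new = -k2 * new$R,
                    F_old = old$F, F_new = new$F)
  attr(out, "params") <- params
  class(out) <- c("replenishment_split", "data.frame")
  out
}

#' RRP recovery after a depleting stimulus
#'
#' After the stimulus (`k2` back to ~0) the RRP relaxes mono-exponentially
#' to its resting steady state:
#' \deqn{R(t) = (R_{end} - R_\infty)e^{-k_{-1} t} + R_\infty,}
#' with recovery time constant `1/k_minus1` (9.1 s for the fitted
#' `k_minus1 = 0.11` 1/s).
#'
#' @param params a [model_params()] object with `k_minus1 > 0`.
#' @param R_end RRP size at the end of the depleting stimulus (nC).
#' @param t time after stimulus end (s); vectorized.
#' @return RRP size (nC) at `t`.
#' @export
rrp_recovery <- function(params, R_end, t) {
  stopifnot(inherits(params, "model_params"), is.numeric(R_end),
            is.numeric(t), all(t >= 0))
  if (params$k_minus1 <= 0) stop("recovery requires k_minus1 > 0")
  Rinf <- steady_state_rrp(params, k2 = 0)
  (R_end - Rinf) * exp(-params$k_minus1 * t) + Rinf
}
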