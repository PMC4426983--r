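#' Estimate RRP size from a trace by three methods
#'
#' Quantifies the readily releasable pool from a fitted HS response by
#' the three estimators in common use:
#' \describe{
#'   \item{`baseline_subtraction` (A)}{subtracts the steady-state
#'     current at the end of the response as a baseline and integrates;
#'     underestimates, because replenishment grows gradually rather than
#'     running at its steady rate from onset.}
#'   \item{`integrate_to_timepoint` (B)}{integrates the total charge to
#'     a configurable time point after the peak, neglecting
#'     replenishment entirely; overestimates.}
#'   \item{`model_replenishment` (C)}{subtracts the reconstructed
#'     replenishment current (release from vesicles primed during the
#'     stimulus, from the fitted model) and integrates; the accurate,
#'     model-corrected estimator.}
#' }
#' On traces with ongoing replenishment, C <= A <= B: method B keeps all
#' replenishment, method A removes the end-steady replenishment current
#' over the window but misses the extra charge from vesicles primed
#' during the onset delay (whose later fusion makes the replenishment
#' current transiently overshoot its steady level), and method C removes
#' the full reconstructed replenishment. The model steady-state RRP
#' `k1D/k_minus1` is reported alongside (`model_steady_state`); it is
#' the quantity reported as "the RRP" and the unbiased estimator of the
#' resting pool. Method C integrates the fused charge originating from
#' the initially primed pool, which sits below the resting pool by the
#' charge lost to unpriming while the fusion rate builds up (about 15%
#' with the default simulation set).
#'
#' @param trace an [hs_trace()] object.
#' @param fit the `hs_fit` for that trace (used by method C and for the
#'   steady-state value).
#' @param t_after_peak integration endpoint of method B, seconds after
#'   the response peak (default 2 s).
#' @param steady_frac final fraction of the stimulus window averaged for
#'   the method-A baseline (default 0.1).
#' @param mepsc_charge quantal charge (nC) used to convert nC to a
#'   vesicle count; defaults to the fit kernel's charge.
#' @return A data frame with columns `method`, `value` (nC),
#'   `vesicles`, and `flag` (character, "" when clean).
#' @export
rrp_estimates <- function(trace, fit, t_after_peak = 2,
                          steady_frac = 0.1,
                          mepsc_charge = fit$config$kernel$charge) {
  stopifnot(inherits(trace, "hs_trace"), inherits(fit, "hs_fit"))
  dt <- trace$dt
  pre <- trace$I_pA[trace$t < trace$stim_on]
  base <- if (length(pre) >= 10L) mean(pre) else 0
  win <- trace$t >= trace$stim_on & trace$t <= trace$stim_off
  t <- trace$t[win]
  y <- -(trace$I_pA[win] - base) / 1000   # positive release current, nA
  n <- length(y)
  flagA <- ""

  # A: steady current at the end of the response as baseline
  ns <- max(5L, as.integer(steady_frac * n))
  iss <- mean(y[seq.int(n - ns + 1L, n)])
  qa <- sum(y - iss) * dt
  if (iss <= 0 || n < 20L) flagA <- "no steady phase detected"

  # B: integrate to a fixed time after the peak
  tpk <- t[which.max(y)]
  qb <- sum(y[t <= tpk + t_after_peak]) * dt

  # C: subtract the reconstructed replenishment current
  p <- model_params(k1 = fit$k1D, D0 = 1, k_minus1 = fit$k_minus1,
                    k2_max = fit$per_trace$k2_max[1],
                    t0 = fit$per_trace$t0[1],
                    t_del = fit$per_trace$t_del[1],
                    tau = fit$per_trace$tau[1])
  sp <- split_replenishment(p, duration = trace$stim_off, dt = dt)
  repl <- approx(sp$t, -sp$I_new, xout = t, rule = 2)$y  # nA, positive
  qc <- sum(y - repl) * dt

  qss <- fit$rrp
  out <- data.frame(
    method = c("baseline_subtraction", "integrate_to_timepoint",
               "model_replenishment", "model_steady_state"),
    value = c(qa, qb, qc, qss),
    vesicles = c(qa, qb, qc, qss) / mepsc_charge,
    flag = c(flagA, "", "", ""))
  out
}

#' Depleted RRP fraction
#'
#' Fraction of the readily releasable pool depleted by a stimulus,
#' normalized to a reference RRP (the pool measured with a maximally
#' depleting stimulus). For a simulated pool trajectory the steady-state
#' estimator `(R(0) - R(end)) / reference` is used; for a
#' `replenishment_split` the released-charge estimator (fused charge
#' from the initially primed pool over the reference). The fraction may
#' exceed 1 when the reference stimulus itself under-depletes.
#'
#' @param x a `pool_trajectory` from [integrate_pools()] or a
#'   `replenishment_split` from [split_replenishment()].
#' @param reference_rrp reference RRP (nC), positive.
#' @return The depleted fraction (dimensionless).
#' @export
depleted_fraction <- function(x, reference_rrp) {
  stopifnot(is.numeric(reference_rrp), reference_rrp > 0)
  if (inherits(x, "replenishment_split"))
    return(x$F_old[nrow(x)] / reference_rrp)
  if (inherits(x, "pool_trajectory"))
    return((x$R[1] - x$R[nrow(x)]) / reference_rrp)
  stop("x must be a pool_trajectory or replenishment_split")
}

#' Peak release rate and time-to-peak
#'
#' Maximum of the fusion-rate trajectory `k2(t) * R(t)` and the time at
#' which it occurs. Reported in nC/s and, when a reference RRP is given,
#' in pool fractions per second.
#'
#' @param traj a `pool_trajectory` from [integrate_pools()].
#' @param reference_rrp optional reference RRP (nC) for pool-fraction
#'   units; defaults to `R(0)` of the trajectory.
#' @return A list with `peak_rate` (nC/s), `t_peak` (s),
#'   `peak_pool_frac` (1/s) and `flat` (`TRUE` when no peak exists, all
#'   other entries `NA`).
#' @export
peak_release_rate <- function(traj, reference_rrp = NULL) {
  stopifnot(inherits(traj, "pool_trajectory"))
  params <- attr(traj, "params")
  rate <- k2_time_course(params, traj$t) * traj$R
  if (max(rate) <= 0 || diff(range(rate)) < 1e-15 * max(1, max(rate)))
    return(list(peak_rate = NA_real_, t_peak = NA_real_,
                peak_pool_frac = NA_real_, flat = TRUE))
  i <- which.max(rate)
  ref <- reference_rrp %||% traj$R[1]
  list(peak_rate = rate[i], t_peak = traj$t[i],
       peak_pool_frac = rate[i] / ref, flat = FALSE)
}

#' Spontaneous fusion rate constant from mEPSC statistics
#'
#' The fusion rate constant in the absence of sucrose is estimated by
#' dividing the frequency of spontaneous miniature events by the number
#' of vesicles in the RRP (total RRP charge over the quantal charge).
#' Note this overestimates the calcium-independent component: most
#' spontaneous events are driven by spontaneous calcium fluctuations,
#' which contribute a constant ~2-4e-4 1/s to the apparent resting rate
#' constant.
#'
#' @param mepsc_freq spontaneous event frequency (Hz).
#' @param rrp_charge RRP size (nC).
#' @param mepsc_charge quantal charge of one miniature event (nC).
#' @return The resting fusion rate constant (1/s).
#' @examples
#' spontaneous_rate_constant(2, 1.31, 1.31e-4) # 2e-4 1/s
#' @export
spontaneous_rate_constant <- function(mepsc_freq, rrp_charge,
                                      mepsc_charge) {
  stopifnot(is.numeric(mepsc_freq), is.numeric(rrp_charge),
            is.numeric(mepsc_charge))
  if (any(mepsc_freq <= 0) || any(rrp_charge <= 0))
    stop("frequency and RRP charge must be positive")
  if (any(mepsc_charge <= 0)) stop("mepsc_charge must be positive")
  mepsc_freq / (rrp_charge / mepsc_charge)
}

#' Nonparametric bootstrap of a sample mean
#'
#' Resamples the per-cell values with replacement, computes the mean of
#' each resample, and summarizes the distribution of those sample means
#' with its mean, standard deviation and percentile 95% confidence
#' interval. Values are sorted before resampling so the summary is
#' invariant to input order for a fixed seed.
#'
#' @param values numeric vector of per-cell parameter values, length
#'   >= 2.
#' @param n_resamples number of bootstrap resamples (default 10000).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list of class `bootstrap_summary` with `n`, `n_resamples`,
#'   `mean`, `sd` and `ci95` (`c(low, high)`).
#' @export
bootstrap_means <- function(values, n_resamples = 10000, seed = NULL) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least 2 values to bootstrap")
  stopifnot(n_resamples >= 2)
  values <- sort(values)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  n <- length(values)
  idx <- sample.int(n, n * n_resamples, replace = TRUE)
  means <- colMeans(matrix(values[idx], nrow = n))
  ci <- unname(quantile(means, c(0.025, 0.975), type = 7))
  structure(list(n = n, n_resamples = as.integer(n_resamples),
                 mean = mean(means), sd = sd(means), ci95 = ci),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of the mean (n = %d, %d resamples): %.4g +/- %.4g, 95%% CI [%.4g, %.4g]\n",
    x$n, x$n_resamples, x$mean, x$sd, x$ci95[1], x$ci95[2]))
  invisible(x)
}
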