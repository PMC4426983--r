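#' Activation-energy change as an energy-delta object
#'
#' Carries a change in the activation energy for vesicle fusion as a
#' dimensionless multiple of \eqn{\bar{R}T} together with the temperature
#' it was computed at, plus the derived value in kcal/mol
#' (`value * 1.9872e-3 * T`). Sign convention: positive values mean the
#' fusion barrier is lowered and the rate increases.
#'
#' @param value energy change in units of \eqn{\bar{R}T}.
#' @param temperature_K absolute temperature (K), default 293.
#' @return An object of class `energy_delta`.
#' @export
energy_delta <- function(value, temperature_K = 293) {
  stopifnot(is.numeric(value), is.numeric(temperature_K),
            all(temperature_K > 0))
  structure(list(value = value, temperature_K = temperature_K,
                 kcal_per_mol = value * .RBAR * temperature_K),
            class = "energy_delta")
}

#' @export
print.energy_delta <- function(x, ...) {
  cat(sprintf("Activation-energy change: %s RT (%s kcal/mol at %g K)\n",
              paste(signif(x$value, 4), collapse = ", "),
              paste(signif(x$kcal_per_mol, 4), collapse = ", "),
              x$temperature_K[1]))
  invisible(x)
}

#' Infer an activation-energy change from two fusion rate constants
#'
#' With a constant Arrhenius prefactor, a change of the fusion rate
#' constant from `k2_a` to `k2_b` corresponds to a barrier change
#' \deqn{\Delta E_a = \bar{R}T\,\ln(k_{2,b}/k_{2,a}),}
#' returned in \eqn{\bar{R}T} units (so the numeric value is simply the
#' log rate ratio). The function is antisymmetric under swapping its
#' arguments. A 10^4-fold rate increase corresponds to ~9.2 RT.
#'
#' @param k2_a,k2_b fusion rate constants (1/s), both positive;
#'   vectorized.
#' @param temperature_K absolute temperature (K).
#' @return An [energy_delta()] object.
#' @examples
#' delta_Ea_from_rates(2e-4, 2)$value # log(1e4) = 9.21
#' @export
delta_Ea_from_rates <- function(k2_a, k2_b, temperature_K = 293) {
  stopifnot(is.numeric(k2_a), is.numeric(k2_b))
  if (any(k2_a <= 0) || any(k2_b <= 0))
    stop("rate constants must be positive")
  energy_delta(log(k2_b / k2_a), temperature_K)
}

#' Convert an energy change from RT units to kcal/mol
#'
#' Uses the gas constant 1.9872e-3 kcal/(mol K); at 293 K one RT unit is
#' 0.582 kcal/mol, so a 9.3 RT barrier reduction corresponds to
#' 5.4 kcal/mol.
#'
#' @param delta an [energy_delta()] object, or a numeric value in RT
#'   units.
#' @param temperature_K temperature used when `delta` is numeric.
#' @return Energy change in kcal/mol.
#' @export
rt_to_kcal <- function(delta, temperature_K = 293) {
  if (inherits(delta, "energy_delta")) return(delta$kcal_per_mol)
  stopifnot(is.numeric(delta))
  delta * .RBAR * temperature_K
}

#' Apply additive barrier changes to a fusion rate constant
#'
#' Independent reductions of the activation energy act multiplicatively
#' on the fusion rate:
#' \deqn{k_{2,new} = k_{2,0} \prod_i e^{\Delta E_i},}
#' with each \eqn{\Delta E_i} in RT units. The result is
#' order-independent and equals a single application of the summed
#' delta, the additive/multiplicative duality at the core of supralinear
#' modulation.
#'
#' @param k2_0 starting fusion rate constant (1/s), non-negative.
#' @param deltas numeric vector of energy changes (RT units) or an
#'   [energy_delta()] object.
#' @return The modulated rate constant (1/s).
#' @examples
#' apply_energy_deltas(2e-4, log(1e4)) # 2 1/s
#' @export
apply_energy_deltas <- function(k2_0, deltas) {
  stopifnot(is.numeric(k2_0), all(k2_0 >= 0))
  if (inherits(deltas, "energy_delta")) deltas <- deltas$value
  stopifnot(is.numeric(deltas))
  k2_0 * exp(sum(deltas))
}

#' Allosteric calcium-sensor rate ladder
#'
#' @param l_plus basal fusion rate constant (1/s).
#' @param f multiplication factor per bound calcium ion (>= 1).
#' @param n_max number of binding states beyond the empty sensor
#'   (default 5, i.e. states n = 0..5).
#' @return An object of class `allosteric_ladder`.
#' @seealso [allosteric_rates()]
#' @export
allosteric_ladder <- function(l_plus, f, n_max = 5) {
  stopifnot(is.numeric(l_plus), l_plus >= 0, is.numeric(f), f >= 1,
            is.numeric(n_max), n_max >= 0, n_max == round(n_max))
  structure(list(l_plus = l_plus, f = f, n_max = as.integer(n_max)),
            class = "allosteric_ladder")
}

#' Fusion rate constants of the allosteric sensor states
#'
#' A vesicle whose calcium sensor has `n` ions bound fuses with rate
#' constant \deqn{k_{2,n} = l_+ f^n, \quad n = 0,\dots,n_{max},}
#' where `l_plus` is the basal (spontaneous) fusion rate constant and
#' `f = exp(dE_Ca/RT)` the multiplication factor contributed by each
#' bound ion. Equivalently, each binding step applies the same additive
#' barrier reduction `log(f)` via [apply_energy_deltas()]; the two
#' computations agree exactly.
#'
#' @param ladder an [allosteric_ladder()] object.
#' @return Numeric vector of rate constants for `n = 0..n_max` (1/s).
#' @export
allosteric_rates <- function(ladder) {
  stopifnot(inherits(ladder, "allosteric_ladder"))
  ladder$l_plus * ladder$f^(0:ladder$n_max)
}

#' Fit a mono-exponential activation-energy dose-response
#'
#' Fits \eqn{\Delta E(M) = a\,e^{-bM} + c} to activation-energy changes
#' measured at several sucrose concentrations, by Levenberg-Marquardt
#' least squares. Constant data leave `b` unidentifiable; the fit is then
#' flagged degenerate instead of erroring.
#'
#' @param concentrations sucrose concentrations (M), at least three
#'   distinct values.
#' @param deltas energy changes (RT units) at those concentrations, as a
#'   numeric vector or [energy_delta()] object.
#' @param start optional named list of starting values `a`, `b`, `c`.
#' @return A list of class `energy_dose_fit` with elements `a`, `b`, `c`,
#'   `fitted`, `residuals`, `degenerate` and the underlying `nls` object
#'   (`NULL` when degenerate).
#' @export
fit_energy_dose_response <- function(concentrations, deltas, start = NULL) {
  if (inherits(deltas, "energy_delta")) deltas <- deltas$value
  stopifnot(is.numeric(concentrations), is.numeric(deltas),
            length(concentrations) == length(deltas))
  if (length(unique(concentrations)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (sd(deltas) < 1e-10) {
    return(structure(list(a = 0, b = NA_real_, c = mean(deltas),
                          fitted = rep(mean(deltas), length(deltas)),
                          residuals = deltas - mean(deltas),
                          degenerate = TRUE, fit = NULL),
                     class = "energy_dose_fit"))
  }
  if (is.null(start)) {
    c0 <- deltas[which.max(concentrations)]
    a0 <- deltas[which.min(concentrations)] - c0
    if (abs(a0) < 1e-8) a0 <- -sign(c0 + 1e-8)
    start <- list(a = a0, b = 2, c = c0)
  }
  df <- data.frame(M = concentrations, dE = deltas)
  fit <- tryCatch(
    minpack.lm::nlsLM(dE ~ a * exp(-b * M) + c, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                          c = unname(cf["c"]), fitted = fitted(fit),
                          residuals = residuals(fit), degenerate = FALSE,
                          fit = fit),
                     class = "energy_dose_fit"))
  }
  # nlsLM can fail to wrap an exact (zero-residual) optimum in an nls
  # object; the raw Levenberg-Marquardt solver still converges there.
  lm_fit <- minpack.lm::nls.lm(
    par = unlist(start[c("a", "b", "c")]),
    fn = function(p) deltas - (p[1] * exp(-p[2] * concentrations) + p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (lm_fit$info %in% c(0, 5))
    stop("mono-exponential fit failed: ", lm_fit$message)
  p <- unname(lm_fit$par)
  fitted_v <- p[1] * exp(-p[2] * concentrations) + p[3]
  structure(list(a = p[1], b = p[2], c = p[3], fitted = fitted_v,
                 residuals = deltas - fitted_v, degenerate = FALSE,
                 fit = NULL),
            class = "energy_dose_fit")
}

#' Transform an energy dose-response into a fusion-rate dose-response
#'
#' Inverts the Arrhenius relation around a stated reference: given the
#' fitted \eqn{\Delta E(M)} curve and a reference rate `k2_ref` measured
#' at concentration `M_ref`, the predicted fusion rate at concentration
#' `M` is \eqn{k_2(M) = k_{2,ref}\, e^{\Delta E(M) - \Delta E(M_{ref})}}.
#' The reference rate anchors the absolute scale and is a configuration
#' input.
#'
#' @param fit an `energy_dose_fit` from [fit_energy_dose_response()].
#' @param M concentrations (M) at which to evaluate the curve.
#' @param k2_ref reference fusion rate constant (1/s).
#' @param M_ref concentration (M) at which `k2_ref` was measured.
#' @return A data frame with columns `concentration_M`, `delta_Ea_RT`,
#'   `k2_max_s`.
#' @export
energy_to_rate_curve <- function(fit, M, k2_ref, M_ref) {
  stopifnot(inherits(fit, "energy_dose_fit"), k2_ref > 0)
  dE <- function(m) {
    if (fit$degenerate) rep(fit$c, length(m))
    else fit$a * exp(-fit$b * m) + fit$c
  }
  data.frame(concentration_M = M, delta_Ea_RT = dE(M),
             k2_max_s = k2_ref * exp(dE(M) - dE(M_ref)))
}

#' Map a symmetric rate-domain error into the energy domain
#'
#' Log-transforming a symmetric standard error on a rate constant yields
#' asymmetric errors on the energy scale; the larger of the two halves is
#' reported as the conservative symmetric error.
#'
#' @param k2 rate constant (1/s), positive.
#' @param sem standard error of `k2` (1/s), non-negative and smaller
#'   than `k2`.
#' @return The energy-domain error (RT units).
#' @export
energy_error_from_rate_sem <- function(k2, sem) {
  stopifnot(is.numeric(k2), all(k2 > 0), is.numeric(sem), all(sem >= 0))
  if (any(sem >= k2))
    stop("sem must be smaller than k2 for a log transform")
  pmax(log(k2 + sem) - log(k2), log(k2) - log(k2 - sem))
}
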