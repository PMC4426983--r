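#' Kinetic parameters of the vesicle-state model
#'
#' Container for the rate constants and stimulus-shape parameters of the
#' vesicle-state model. The depot pool `D0` feeds the readily releasable
#' pool with priming rate constant `k1` (so the priming flux is
#' `k1 * D0` nC/s), vesicles unprime with rate constant `k_minus1`, and
#' fuse with the time-dependent rate constant `k2(t)` that rises from
#' `k2_baseline` to `k2_max` after stimulus onset `t0` with delay `t_del`
#' and rise time constant `tau` (see [k2_time_course()]).
#'
#' @param k1 priming rate constant (1/s).
#' @param k_minus1 unpriming rate constant (1/s).
#' @param k2_max maximal fusion rate constant during the stimulus (1/s).
#' @param t0 stimulus onset time (s).
#' @param t_del delay of fusion-rate onset relative to `t0` (s).
#' @param tau rise time constant of the fusion rate (s).
#' @param D0 depot pool size (nC).
#' @param k2_baseline pre-stimulus fusion rate constant (1/s); the RRP at
#'   rest is computed neglecting it (see [steady_state_rrp()]).
#' @param temperature_K absolute temperature (K) used for energy
#'   conversions.
#' @return An object of class `model_params` (a validated named list).
#' @seealso [default_model_params()], [site_params()], [integrate_pools()]
#' @examples
#' p <- model_params(k1 = 0.09, k_minus1 = 0.16, k2_max = 3.5)
#' steady_state_rrp(p)
#' @export
model_params <- function(k1 = 0.09, k_minus1 = 0.16, k2_max = 3.5,
                         t0 = 0.5, t_del = 0.6, tau = 0.2, D0 = 1,
                         k2_baseline = 0, temperature_K = 293) {
  p <- list(k1 = k1, k_minus1 = k_minus1, k2_max = k2_max, t0 = t0,
            t_del = t_del, tau = tau, D0 = D0, k2_baseline = k2_baseline,
            temperature_K = temperature_K)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("k1", "k_minus1", "k2_max", "t0", "t_del", "tau", "D0",
               "k2_baseline", "temperature_K")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number")
  }
  if (p$k1 < 0 || p$k_minus1 < 0 || p$k2_max < 0 || p$k2_baseline < 0)
    stop("rate constants must be non-negative")
  if (p$tau < 0 || p$D0 < 0) stop("tau and D0 must be non-negative")
  if (p$k2_max > 0 && p$tau <= 0)
    stop("tau must be positive when k2_max > 0")
  if (p$t_del < 0) stop("t_del must be non-negative")
  if (p$temperature_K <= 0) stop("temperature_K must be positive")
  invisible(p)
}

#' Default simulation parameter set
#'
#' The canonical parameter set used throughout for simulated HS responses:
#' `k1 = 0.09` 1/s, `k_minus1 = 0.16` 1/s, `k2_max = 3.5` 1/s,
#' `t_del = 0.60` s, `tau = 0.20` s and a depot pool of 1 nC (1000 pC),
#' which gives a resting RRP of `0.09/0.16 = 0.5625` nC and peak currents
#' near 1 nA, a realistic scale for autaptic HS responses.
#'
#' @param ... overrides passed on to [model_params()].
#' @return A `model_params` object.
#' @export
default_model_params <- function(...) {
  do.call(model_params, modifyList(list(), list(...)))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Vesicle-state model parameters\n")
  cat(sprintf("  k1        %.4g 1/s   (priming; k1*D0 = %.4g nC/s)\n",
              x$k1, x$k1 * x$D0))
  cat(sprintf("  k_minus1  %.4g 1/s   (unpriming)\n", x$k_minus1))
  cat(sprintf("  k2_max    %.4g 1/s   (maximal fusion rate)\n", x$k2_max))
  cat(sprintf("  t0 = %.3g s, t_del = %.3g s, tau = %.3g s\n",
              x$t0, x$t_del, x$tau))
  cat(sprintf("  D0 = %.4g nC, k2_baseline = %.3g 1/s, T = %g K\n",
              x$D0, x$k2_baseline, x$temperature_K))
  invisible(x)
}

#' Release-site variant of the model parameters
#'
#' Extends [model_params()] with a fixed number of instantaneously
#' available release sites `S` (in nC-equivalent capacity). Priming is
#' hampered when fewer free sites remain: `dR/dt = k1*D*(S - R) -
#' (k_minus1 + k2)*R`.
#'
#' @param params a `model_params` object.
#' @param S release-site capacity (nC); must be positive.
#' @return An object of class `site_params`.
#' @seealso [steady_state_rrp_sites()]
#' @export
site_params <- function(params, S) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0)
    stop("S must be a positive number")
  structure(c(unclass(params), list(S = S)),
            class = c("site_params", "model_params"))
}

#' Serialize model parameters to JSON
#'
#' Writes the parameter set with stable field names (`k1`, `k_minus1`,
#' `k2_max`, `t0`, `t_del`, `tau`, `D0`, `temperature_K`, plus
#' `k2_baseline`).
#'
#' @param params a `model_params` object.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_params"))
  fields <- c("k1", "k_minus1", "k2_max", "t0", "t_del", "tau", "D0",
              "temperature_K", "k2_baseline")
  if (!is.null(params$S)) fields <- c(fields, "S")
  x <- unclass(params)[fields]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read model parameters from JSON
#'
#' @param path file path or a JSON string produced by [params_to_json()].
#' @return A `model_params` (or `site_params`) object.
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  p <- model_params(k1 = x$k1, k_minus1 = x$k_minus1, k2_max = x$k2_max,
                    t0 = x$t0, t_del = x$t_del, tau = x$tau, D0 = x$D0,
                    k2_baseline = x$k2_baseline %||% 0,
                    temperature_K = x$temperature_K %||% 293)
  if (!is.null(x$S)) p <- site_params(p, x$S)
  p
}
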