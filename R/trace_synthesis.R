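#' Canonical miniature-EPSC convolution kernel
#'
#' Difference-of-exponentials waveform
#' \eqn{h(t) \propto e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}} used to
#' turn release rates into postsynaptic currents. The discrete waveform
#' is normalized so that its integral equals `charge` (the quantal
#' charge of one miniature event); convolution uses the unit-charge
#' shape, so pool units (nC) flow through unchanged.
#'
#' The default quantal charge of 1.1e-4 nC (110 fC) follows from a
#' ~1.3 nC RRP containing ~1.2e4 vesicles.
#'
#' @param rise_tau rise time constant (s); default 0.5 ms.
#' @param decay_tau decay time constant (s), larger than `rise_tau`;
#'   default 3 ms.
#' @param charge quantal charge (nC).
#' @param sample_dt sampling interval (s); default 1e-4 (10 kHz).
#' @param length_factor kernel support as a multiple of `decay_tau`.
#' @return An object of class `mepsc_kernel` with the sampled unit-charge
#'   shape in `$shape` (units 1/s; `sum(shape) * sample_dt == 1`).
#' @export
mepsc_kernel <- function(rise_tau = 5e-4, decay_tau = 3e-3,
                         charge = 1.1e-4, sample_dt = 1e-4,
                         length_factor = 10) {
  if (!(decay_tau > rise_tau && rise_tau > 0))
    stop("need decay_tau > rise_tau > 0")
  stopifnot(charge > 0, sample_dt > 0, length_factor > 0)
  tk <- seq(0, length_factor * decay_tau, by = sample_dt)
  if (length(tk) < 2L) tk <- c(0, sample_dt)
  raw <- exp(-tk / decay_tau) - exp(-tk / rise_tau)
  shape <- raw / (sum(raw) * sample_dt)
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 charge = charge, sample_dt = sample_dt, t = tk,
                 shape = shape),
            class = "mepsc_kernel")
}

#' Unit-charge delta kernel (identity convolution)
#'
#' A single-sample kernel whose convolution leaves a rate series
#' unchanged (up to sign); useful for tests and deconvolution-free
#' analyses.
#'
#' @inheritParams mepsc_kernel
#' @return An `mepsc_kernel` object with one sample.
#' @export
delta_kernel <- function(charge = 1.1e-4, sample_dt = 1e-4) {
  structure(list(rise_tau = NA_real_, decay_tau = NA_real_,
                 charge = charge, sample_dt = sample_dt, t = 0,
                 shape = 1 / sample_dt),
            class = "mepsc_kernel")
}

#' Convert a release-rate series into a postsynaptic current
#'
#' Convolves the fusion-rate series `k2(t) * R(t)` (nC/s) with the
#' unit-charge miniature-EPSC shape and negates the result, since inward
#' EPSCs are recorded as negative currents while pools are positive
#' charge. Because the kernel is unit-charge normalized, the total
#' charge of the output equals the total released charge (up to the
#' kernel tail at the record end).
#'
#' @param rate release-rate series (nC/s), sampled at the kernel's
#'   `sample_dt`.
#' @param kernel an [mepsc_kernel()] object.
#' @param dt sampling interval of `rate` (s); must match the kernel's.
#' @return Current series (nA, inward-negative), same length as `rate`.
#' @export
release_rate_to_current <- function(rate, kernel,
                                    dt = kernel$sample_dt) {
  stopifnot(inherits(kernel, "mepsc_kernel"), is.numeric(rate))
  if (abs(dt - kernel$sample_dt) > 1e-12)
    stop("rate sampling interval does not match the kernel sample_dt")
  n <- length(rate)
  if (length(kernel$shape) == 1L) return(-rate * kernel$shape * dt)
  conv <- stats::convolve(rate, rev(kernel$shape), type = "open") * dt
  -conv[seq_len(n)]
}

#' Uniformly sampled current trace
#'
#' @param t time grid (s), uniform.
#' @param I_pA current (pA, inward-negative).
#' @param stim_on,stim_off stimulus window (s), `stim_on < stim_off`,
#'   within the record.
#' @param label condition label, e.g. a sucrose concentration tag ("0.5M").
#' @param meta named list of cell/condition identifiers.
#' @return An object of class `hs_trace`.
#' @export
hs_trace <- function(t, I_pA, stim_on, stim_off, label = "",
                     meta = list()) {
  stopifnot(is.numeric(t), is.numeric(I_pA), length(t) == length(I_pA),
            length(t) >= 2L)
  dts <- diff(t)
  if (any(dts <= 0) || (max(dts) - min(dts)) > 1e-9)
    stop("trace must be uniformly sampled (jitter tolerance 1e-9 s)")
  stopifnot(is.numeric(stim_on), is.numeric(stim_off))
  if (!(stim_on < stim_off))
    stop("stim_on must precede stim_off")
  if (stim_on < t[1] - 1e-9 || stim_off > t[length(t)] + 1e-9)
    stop("stimulus window must lie within the record")
  structure(list(t = t, I_pA = I_pA, dt = median(dts), stim_on = stim_on,
                 stim_off = stim_off, label = label, meta = meta),
            class = "hs_trace")
}

#' @export
print.hs_trace <- function(x, ...) {
  cat(sprintf(
    "HS current trace%s: %d samples at %.4g kHz, %.3g-%.3g s, stimulus %.3g-%.3g s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$t), 1e-3 / x$dt, x$t[1], x$t[length(x$t)], x$stim_on,
    x$stim_off))
  cat(sprintf("  peak %.4g pA, baseline %.4g pA\n", min(x$I_pA),
              mean(x$I_pA[x$t < x$stim_on])))
  invisible(x)
}

#' Synthesize an HS-evoked EPSC trace from model parameters
#'
#' Integrates the pool dynamics, convolves the release rate with the
#' miniature-EPSC kernel, and adds Gaussian white recording noise (mean
#' 0) after convolution. With the default parameter set and
#' `noise_sd = 10` pA the traces emulate simulated HS responses with
#' ~1 nA peaks and visible baseline noise. Deterministic given `seed`.
#'
#' @param params a [model_params()] object; stimulus onset is
#'   `params$t0`.
#' @param kernel an [mepsc_kernel()]; its `sample_dt` must equal `dt`.
#' @param noise_sd Gaussian noise standard deviation (pA).
#' @param seed integer seed for the noise; `NULL` leaves the RNG state
#'   alone.
#' @param duration record duration (s).
#' @param dt sampling interval (s), default 1e-4 (10 kHz).
#' @param stim_duration stimulus duration (s), default 7.
#' @param mode pool mode, see [integrate_pools()].
#' @param label,meta annotations stored on the trace.
#' @return An [hs_trace()] object; the noiseless pool trajectory is
#'   attached as attribute `"trajectory"` and the noiseless current (pA)
#'   as attribute `"I_clean_pA"`.
#' @export
synthesize_trace <- function(params, kernel = mepsc_kernel(),
                             noise_sd = 10, seed = NULL, duration = 8,
                             dt = 1e-4, stim_duration = 7,
                             mode = "constant_k1D", label = "",
                             meta = list()) {
  stopifnot(inherits(params, "model_params"), noise_sd >= 0,
            duration > 0)
  if (abs(dt - kernel$sample_dt) > 1e-12)
    stop("kernel sample_dt must match the trace dt")
  traj <- integrate_pools(params, duration = duration, mode = mode,
                          dt = dt, engine = "fixed")
  k2 <- k2_time_course(params, traj$t)
  rate <- k2 * traj$R
  I_nA <- release_rate_to_current(rate, kernel, dt = dt)
  I_clean <- 1000 * I_nA
  noise <- 0
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    noise <- rnorm(length(I_clean), mean = 0, sd = noise_sd)
  }
  tr <- hs_trace(traj$t, I_clean + noise, stim_on = params$t0,
                 stim_off = min(params$t0 + stim_duration,
                                traj$t[length(traj$t)]),
                 label = label, meta = meta)
  attr(tr, "trajectory") <- traj
  attr(tr, "I_clean_pA") <- I_clean
  attr(tr, "params") <- params
  tr
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Family of noiseless traces varying only the maximal fusion rate
#'
#' Synthesizes one trace per `k2_max` value, all other parameters
#' shared. Raising `k2_max` increases the peak amplitude and shortens
#' the time to peak, the signature of increasing hypertonicity.
#'
#' @param params a [model_params()] object (its `k2_max` is replaced).
#' @param k2_values vector of maximal fusion rate constants (1/s).
#' @param kernel an [mepsc_kernel()].
#' @param ... further arguments to [synthesize_trace()] (noise is off).
#' @return A list of [hs_trace()] objects, one per `k2_max`, with
#'   labels `"k2max=<value>"`.
#' @export
sweep_k2max <- function(params, k2_values, kernel = mepsc_kernel(), ...) {
  stopifnot(length(k2_values) >= 1L)
  lapply(k2_values, function(k2m) {
    p <- params
    p$k2_max <- k2m
    synthesize_trace(p, kernel = kernel, noise_sd = 0,
                     label = paste0("k2max=", k2m), ...)
  })
}

#' Peak amplitude and time-to-peak of a trace
#'
#' @param trace an [hs_trace()] object.
#' @return A list with `peak_pA` (most negative current) and `t_peak`
#'   (s).
#' @export
trace_peak <- function(trace) {
  stopifnot(inherits(trace, "hs_trace"))
  i <- which.min(trace$I_pA)
  list(peak_pA = trace$I_pA[i], t_peak = trace$t[i])
}
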