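# Shared fixtures: all synthetic, generated in code.

fast_config <- function(...) {
  fit_config(global_method = "none", n_starts = 2, ...)
}

# hs_fit skeleton holding known parameters, for operations that consume a
# completed fit (depot refinement, quality screen) without re-fitting.
fake_fit <- function(params, trace, config = fast_config()) {
  structure(list(
    k1D = params$k1 * params$D0, k_minus1 = params$k_minus1,
    rrp = params$k1 * params$D0 / params$k_minus1,
    per_trace = data.frame(trace = 1, label = trace$label,
                           k2_max = params$k2_max, t_del = params$t_del,
                           tau = params$tau, t0 = trace$stim_on, sse = 0,
                           baseline_pA = 0),
    sse = 0, n_evaluations = 0L, converged = TRUE, config = config),
    class = "hs_fit")
}

# model current and residual grids for a parameter set on a trace, in the
# layout fit_traces() stores (used to probe the quality screen).
fit_grids <- function(params, trace, config = fast_config()) {
  prep <- vesiclefit:::prep_trace(trace, config)
  mod <- vesiclefit:::forward_current_pA(
    params$k1 * params$D0, params$k_minus1, params$k2_max, params$t_del,
    params$tau, prep$t0, prep)
  list(list(t = prep$t, data_pA = prep$y, model_pA = mod))
}

random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    model_params(k1 = exp(runif(1, log(0.01), log(1))),
                 k_minus1 = exp(runif(1, log(0.01), log(1))),
                 k2_max = exp(runif(1, log(0.1), log(20))),
                 t0 = 0.2, t_del = runif(1, 0.1, 1),
                 tau = runif(1, 0.05, 0.5), D0 = runif(1, 0.5, 2)))
}
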