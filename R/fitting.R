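#' Configuration for trace fitting
#'
#' @param fit_window optional `c(start, end)` window (s) for the cost
#'   function; defaults to the stimulus window of each trace, i.e. up to
#'   the time the sucrose concentration starts to decay.
#' @param fit_dt grid spacing (s) on which the cost is evaluated; the
#'   data are subsampled to this spacing (default 1 ms). Use the trace's
#'   own `dt` to fit every sample.
#' @param bounds lower/upper bounds applied to every fitted parameter on
#'   the natural scale, default `c(1e-5, 1e6)`.
#' @param max_iter_per_param iteration/function-evaluation budget per
#'   fitted parameter for each optimizer stage (default 400).
#' @param global_method global stage before the simplex: `"annealing"`
#'   (simulated annealing, the default), `"evolutionary"` (differential
#'   evolution) or `"none"`.
#' @param n_starts number of independent multi-starts of the
#'   global+local pipeline (default 10); the best solution is kept.
#' @param seed integer seed controlling the multi-start jitter and
#'   stochastic optimizers; identical inputs and seed give identical
#'   results.
#' @param kernel miniature-EPSC kernel used for the model current; it is
#'   resampled to `fit_dt` internally.
#' @param baseline_correct subtract the mean pre-stimulus current from
#'   each trace before fitting (default `TRUE`).
#' @param free_per_trace parameters free per trace in joint fits
#'   (default `k2_max`, `t_del`, `tau`); `k1D` and `k_minus1` are always
#'   shared.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(fit_window = NULL, fit_dt = 1e-3,
                       bounds = c(1e-5, 1e6), max_iter_per_param = 400,
                       global_method = c("annealing", "evolutionary",
                                         "none"),
                       n_starts = 10, seed = 1,
                       kernel = mepsc_kernel(),
                       baseline_correct = TRUE,
                       free_per_trace = c("k2_max", "t_del", "tau")) {
  global_method <- match.arg(global_method)
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[1] < bounds[2],
            max_iter_per_param >= 1, n_starts >= 1, fit_dt > 0)
  bad <- setdiff(free_per_trace, c("k2_max", "t_del", "tau"))
  if (length(bad))
    stop("free_per_trace may only contain k2_max, t_del, tau")
  structure(list(fit_window = fit_window, fit_dt = fit_dt,
                 bounds = bounds,
                 max_iter_per_param = as.integer(max_iter_per_param),
                 global_method = global_method,
                 n_starts = as.integer(n_starts),
                 seed = as.integer(seed), kernel = kernel,
                 baseline_correct = baseline_correct,
                 free_per_trace = free_per_trace),
            class = "fit_config")
}

kernel_at_dt <- function(kernel, dt) {
  if (abs(dt - kernel$sample_dt) < 1e-12) return(kernel)
  if (is.na(kernel$rise_tau)) return(delta_kernel(kernel$charge, dt))
  mepsc_kernel(kernel$rise_tau, kernel$decay_tau, kernel$charge,
               sample_dt = dt)
}

# Extract the fitting grid and baseline-corrected data from a trace.
prep_trace <- function(trace, config) {
  stopifnot(inherits(trace, "hs_trace"))
  w <- config$fit_window %||% c(trace$stim_on, trace$stim_off)
  if (w[1] < trace$t[1] - 1e-9 || w[2] > trace$t[length(trace$t)] + 1e-9)
    stop("fit window lies outside the trace")
  idx <- which(trace$t >= w[1] - 1e-12 & trace$t <= w[2] + 1e-12)
  if (length(idx) < 10L) stop("fit window contains too few samples")
  step <- max(1L, as.integer(round(config$fit_dt / trace$dt)))
  idx <- idx[seq(1L, length(idx), by = step)]
  baseline <- 0
  if (config$baseline_correct) {
    pre <- trace$I_pA[trace$t < trace$stim_on]
    if (length(pre) >= 10L) baseline <- mean(pre)
  }
  list(t = trace$t[idx], y = trace$I_pA[idx] - baseline,
       dt = trace$dt * step, t0 = trace$stim_on, baseline = baseline,
       kernel = kernel_at_dt(config$kernel, trace$dt * step))
}

# Model EPSC (pA) on a uniform grid for one parameter set, constant-k1D
# mode; the hot loop of the fit.
forward_current_pA <- function(k1D, km1, k2max, tdel, tau, t0, prep) {
  t <- prep$t
  dt <- prep$dt
  n <- length(t) - 1L
  th <- t[1] + seq(0L, 2L * n) * (dt / 2)
  k2h <- numeric(length(th))
  on <- th >= t0
  if (any(on)) k2h[on] <- k2max * exp(-exp(-(th[on] - t0 - tdel) / tau))
  R0 <- k1D / km1
  sol <- pool_rk4_cpp(k1D, km1, 1, R0, k2h, dt, FALSE)
  rate <- k2h[seq(1L, 2L * n + 1L, by = 2L)] * sol$R
  1000 * release_rate_to_current(rate, prep$kernel, dt = dt)
}

# theta layout: c(log k1D, log k_minus1, then per trace the log of each
# free_per_trace parameter). Shared k2_max/t_del/tau (when not free per
# trace) follow the shared block.
theta_layout <- function(n_traces, free_per_trace) {
  shared <- c("k1D", "k_minus1",
              setdiff(c("k2_max", "t_del", "tau"), free_per_trace))
  list(shared = shared, free = free_per_trace,
       n = length(shared) + n_traces * length(free_per_trace))
}

theta_unpack <- function(theta, layout, i) {
  nms <- c(layout$shared, layout$free)
  vals <- exp(c(theta[seq_along(layout$shared)],
                theta[length(layout$shared) +
                        (i - 1L) * length(layout$free) +
                        seq_along(layout$free)]))
  as.list(setNames(vals, nms))
}

sse_traces <- function(theta, layout, preps) {
  s <- 0
  for (i in seq_along(preps)) {
    p <- theta_unpack(theta, layout, i)
    mod <- forward_current_pA(p$k1D, p$k_minus1, p$k2_max, p$t_del,
                              p$tau, preps[[i]]$t0, preps[[i]])
    s <- s + sum((preps[[i]]$y - mod)^2)
  }
  s
}

#' Sum-of-squared-errors cost of a parameter set on one or more traces
#'
#' Evaluates the model current for `params` on each trace's fitting
#' window (constant-`k1D` mode, model interpolated at the data samples)
#' and returns the summed squared error in pA^2. For several traces the
#' per-trace costs are computed separately and added, so the total is
#' invariant to trace order.
#'
#' @param params a [model_params()] object, or a list with one per
#'   trace (shared parameters equal across entries).
#' @param traces an [hs_trace()] or list of traces.
#' @param config a [fit_config()].
#' @return The summed squared error (pA^2).
#' @export
model_cost <- function(params, traces, config = fit_config()) {
  if (inherits(traces, "hs_trace")) traces <- list(traces)
  if (inherits(params, "model_params"))
    params <- rep(list(params), length(traces))
  stopifnot(length(params) == length(traces))
  s <- 0
  for (i in seq_along(traces)) {
    prep <- prep_trace(traces[[i]], config)
    p <- params[[i]]
    lo <- config$bounds[1]; hi <- config$bounds[2]
    vals <- c(p$k1 * p$D0, p$k_minus1, p$k2_max, p$t_del, p$tau)
    if (any(vals < lo | vals > hi))
      stop("parameters outside the configured bounds")
    mod <- forward_current_pA(p$k1 * p$D0, p$k_minus1, p$k2_max,
                              p$t_del, p$tau, prep$t0, prep)
    s <- s + sum((prep$y - mod)^2)
  }
  s
}

# Data-driven starting values for one trace (log scale).
heuristic_init <- function(prep) {
  y <- -prep$y                       # positive release current, pA
  n <- length(y)
  k <- max(3L, min(101L, 2L * as.integer(0.025 / prep$dt) + 1L))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  peak <- max(ys)
  tpk <- prep$t[which.max(ys)]
  iss <- mean(ys[seq.int(max(1L, n - max(10L, n %/% 10L)), n)])
  k1D <- max(iss / 1000, 1e-4)      # nC/s from steady current
  Q <- sum(y) * prep$dt / 1000      # nC released in the window
  Tw <- prep$t[n] - prep$t[1]
  rrp <- max(Q - k1D * (Tw - (tpk - prep$t[1])) * 0.8, 0.3 * Q, 1e-3)
  km1 <- min(max(k1D / rrp, 1e-3), 10)
  onset <- prep$t[which(ys > 0.2 * peak)[1]]
  if (is.na(onset)) onset <- tpk
  tau <- min(max((tpk - onset) / 3, 0.03), 1)
  tdel <- min(max(onset - prep$t0 - tau, 0.05), 3)
  k2max <- min(max(peak / (1000 * 0.5 * rrp), 0.05), 100)
  log(c(k1D = k1D, k_minus1 = km1, k2_max = k2max, t_del = tdel,
        tau = tau))
}

# Minimal differential evolution (rand/1/bin) within box bounds.
de_optimize <- function(fn, x0, lower, upper, budget) {
  d <- length(x0)
  np <- max(10L, 5L * d)
  gens <- max(2L, budget %/% np)
  pop <- matrix(runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  pop[1, ] <- pmin(pmax(x0, lower), upper)
  cost <- apply(pop, 1, fn)
  Fw <- 0.7; CR <- 0.9
  for (g in seq_len(gens)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3L)
      trial <- pop[idx[1], ] + Fw * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
  }
  b <- which.min(cost)
  list(par = pop[b, ], value = cost[b])
}

#' Fit the vesicle-state model to one or several traces
#'
#' Least-squares estimation of the model parameters from HS-evoked EPSC
#' traces. The initial fit treats the priming flux `k1*D` as one
#' constant (only the RRP equation is integrated), optimizes in log
#' parameter space within the configured bounds, and runs an optional
#' global stage (simulated annealing or differential evolution) followed
#' by a Nelder-Mead simplex from the global optimum, restarted from
#' `n_starts` jittered initial conditions until no further improvement.
#' Every simulation starts from the resting steady state. For joint fits
#' of several concentrations from one cell, `k1D` and `k_minus1` are
#' shared while `k2_max`, `t_del` and `tau` are free per trace (see
#' [fit_config()]). The RRP is not a fit parameter: it is derived
#' post hoc as `k1D / k_minus1`.
#'
#' @param traces an [hs_trace()] or a list of traces (joint fit).
#' @param config a [fit_config()].
#' @return An object of class `hs_fit` with elements `k1D`, `k_minus1`,
#'   `per_trace` (data frame of per-trace `k2_max`, `t_del`, `tau`,
#'   `t0`, `sse`, `baseline_pA`), `rrp` (nC), `sse`, `n_evaluations`,
#'   `converged`, `fits` (per-trace grids, data and model currents) and
#'   the `config` used. Non-convergence is flagged, never silently
#'   dropped.
#' @examples
#' \donttest{
#' tr <- synthesize_trace(default_model_params(), noise_sd = 0)
#' fit <- fit_traces(tr, fit_config(global_method = "none", n_starts = 2))
#' fit$rrp
#' }
#' @export
fit_traces <- function(traces, config = fit_config()) {
  if (inherits(traces, "hs_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "hs_trace")))
  stopifnot(inherits(config, "fit_config"))
  preps <- lapply(traces, prep_trace, config = config)
  layout <- theta_layout(length(traces), config$free_per_trace)
  lb <- rep(log(config$bounds[1]), layout$n)
  ub <- rep(log(config$bounds[2]), layout$n)

  n_eval <- 0L
  fn <- function(theta) {
    n_eval <<- n_eval + 1L
    if (any(theta < lb) || any(theta > ub)) return(1e12)
    s <- sse_traces(theta, layout, preps)
    if (!is.finite(s)) 1e12 else s
  }

  # reference trace (largest peak) seeds the shared parameters
  peaks <- vapply(preps, function(p) max(-p$y), numeric(1))
  ref <- which.max(peaks)
  inits <- lapply(preps, heuristic_init)
  shared_nms <- layout$shared
  theta0 <- c(inits[[ref]][shared_nms],
              unlist(lapply(inits, function(ini) ini[layout$free])))
  theta0 <- pmin(pmax(theta0, lb), ub)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  budget <- config$max_iter_per_param * layout$n
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    start <- if (s == 1L) theta0 else
      pmin(pmax(theta0 + rnorm(layout$n, 0, 0.3), lb), ub)
    if (config$global_method == "annealing") {
      g <- optim(start, fn, method = "SANN",
                 control = list(maxit = budget))
      start <- g$par
    } else if (config$global_method == "evolutionary") {
      span <- 1.5
      g <- de_optimize(fn, start, pmax(start - span, lb),
                       pmin(start + span, ub), budget)
      start <- g$par
    }
    loc <- optim(start, fn, method = "Nelder-Mead",
                 control = list(maxit = budget, reltol = 1e-10))
    # polish: restart the simplex at the optimum once
    loc2 <- optim(loc$par, fn, method = "Nelder-Mead",
                  control = list(maxit = budget, reltol = 1e-10))
    if (loc2$value < loc$value) loc <- loc2
    if (is.null(best) || loc$value < best$value) best <- loc
  }

  per <- do.call(rbind, lapply(seq_along(traces), function(i) {
    p <- theta_unpack(best$par, layout, i)
    mod <- forward_current_pA(p$k1D, p$k_minus1, p$k2_max, p$t_del,
                              p$tau, preps[[i]]$t0, preps[[i]])
    data.frame(trace = i,
               label = traces[[i]]$label,
               k2_max = p$k2_max, t_del = p$t_del, tau = p$tau,
               t0 = preps[[i]]$t0,
               sse = sum((preps[[i]]$y - mod)^2),
               baseline_pA = preps[[i]]$baseline)
  }))
  p1 <- theta_unpack(best$par, layout, 1L)
  fits <- lapply(seq_along(traces), function(i) {
    p <- theta_unpack(best$par, layout, i)
    list(t = preps[[i]]$t, data_pA = preps[[i]]$y,
         model_pA = forward_current_pA(p$k1D, p$k_minus1, p$k2_max,
                                       p$t_del, p$tau, preps[[i]]$t0,
                                       preps[[i]]))
  })
  res <- structure(list(
    k1D = p1$k1D, k_minus1 = p1$k_minus1, per_trace = per,
    rrp = p1$k1D / p1$k_minus1, sse = best$value,
    n_evaluations = n_eval, converged = best$convergence == 0,
    theta = best$par, layout = layout, fits = fits, config = config),
    class = "hs_fit")
  if (!res$converged)
    warning("simplex did not report convergence; result flagged")
  res
}

#' @export
print.hs_fit <- function(x, ...) {
  cat("Vesicle-state model fit\n")
  cat(sprintf("  k1D = %.4g nC/s, k_minus1 = %.4g 1/s, RRP = %.4g nC\n",
              x$k1D, x$k_minus1, x$rrp))
  for (i in seq_len(nrow(x$per_trace))) {
    r <- x$per_trace[i, ]
    cat(sprintf("  trace %d%s: k2_max = %.4g 1/s, t_del = %.3g s, tau = %.3g s, sse = %.4g pA^2\n",
                r$trace,
                if (nzchar(r$label)) paste0(" [", r$label, "]") else "",
                r$k2_max, r$t_del, r$tau, r$sse))
  }
  cat(sprintf("  total sse %.5g pA^2, %d cost evaluations, converged: %s\n",
              x$sse, x$n_evaluations, x$converged))
  invisible(x)
}

#' Resolve the depot pool and priming rate from the refill phase
#'
#' Second fitting stage: with all other parameters fixed at their
#' initial-fit values, `k1` and `D0` are freed (their product
#' constrained within 2% of the stage-one `k1D`) and the full two-pool
#' dynamics with a depletable depot are refitted. The split is only
#' identifiable when the steady-state (refill) phase sags because the
#' depot depletes; a trace generated with a constant priming flux leaves
#' the split unidentifiable, which is flagged rather than reported as a
#' fit.
#'
#' @param fit an `hs_fit` from [fit_traces()].
#' @param trace the [hs_trace()] the fit was obtained from (first trace
#'   for joint fits).
#' @param config a [fit_config()]; bounds and budgets are reused.
#' @param product_tol allowed relative deviation of `k1*D0` from the
#'   stage-one product (default 0.02).
#' @return A list of class `depot_fit` with `k1`, `D0`, `k1D`, `sse`,
#'   `sse_stage1`, and `identifiable` (FALSE when freeing the depot does
#'   not improve the fit materially).
#' @export
refine_depot <- function(fit, trace, config = fit$config,
                         product_tol = 0.02) {
  stopifnot(inherits(fit, "hs_fit"), inherits(trace, "hs_trace"))
  prep <- prep_trace(trace, config)
  row <- fit$per_trace[1, ]
  k2max <- row$k2_max; tdel <- row$t_del; tau <- row$tau
  km1 <- fit$k_minus1; prod1 <- fit$k1D
  t <- prep$t; dt <- prep$dt
  n <- length(t) - 1L
  th <- t[1] + seq(0L, 2L * n) * (dt / 2)
  k2h <- numeric(length(th))
  on <- th >= prep$t0
  k2h[on] <- k2max * exp(-exp(-(th[on] - prep$t0 - tdel) / tau))
  kidx <- seq(1L, 2L * n + 1L, by = 2L)

  sse_depot <- function(par) {  # par = c(log k1, log prod)
    k1 <- exp(par[1]); prod <- exp(par[2])
    if (abs(prod / prod1 - 1) > product_tol) return(1e12)
    D0 <- prod / k1
    R0 <- prod / km1
    sol <- pool_rk4_cpp(k1, km1, D0, R0, k2h, dt, TRUE)
    mod <- 1000 * release_rate_to_current(k2h[kidx] * sol$R,
                                          prep$kernel, dt = dt)
    s <- sum((prep$y - mod)^2)
    if (!is.finite(s)) 1e12 else s
  }

  sse1 <- sum((prep$y - forward_current_pA(prod1, km1, k2max, tdel, tau,
                                           prep$t0, prep))^2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  budget <- config$max_iter_per_param * 2L
  best <- NULL
  for (lk1 in log(c(prod1 / fit$rrp / 10, prod1, prod1 * 10))) {
    o <- optim(c(lk1, log(prod1)), sse_depot, method = "Nelder-Mead",
               control = list(maxit = budget, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  k1 <- exp(best$par[1]); prod <- exp(best$par[2])
  identifiable <- (sse1 - best$value) / sse1 > 1e-3
  structure(list(k1 = k1, D0 = prod / k1, k1D = prod, sse = best$value,
                 sse_stage1 = sse1, identifiable = identifiable),
            class = "depot_fit")
}

#' Automated fit-quality screen
#'
#' Quantitative surrogate for visual fit inspection, flagging the four
#' canonical failure modes: (1) late/early onset of the fit, (2) wrong
#' peak amplitude and/or time-to-peak, (3) systematic residual runs in
#' the decay towards the steady-state phase, (4) biased steady-state
#' (refill) phase. A flag value of `TRUE` means the feature passes.
#'
#' @param fit an `hs_fit` from [fit_traces()].
#' @param trace_index which trace of the fit to screen (default 1).
#' @param thresholds named list overriding the defaults:
#'   `onset_s` (max onset-time mismatch, 0.15 s), `peak_rel` (max
#'   relative peak-amplitude error, 0.1), `t_peak_s` (max time-to-peak
#'   mismatch, 0.15 s), `run_s` (max duration of a same-sign residual
#'   excursion beyond 2 noise SDs in the decay phase, 0.5 s),
#'   `steady_rel` (max steady-phase bias relative to the peak, 0.02).
#' @return A named logical vector of class `quality_flags` with
#'   attributes carrying the measured features.
#' @export
quality_screen <- function(fit, trace_index = 1, thresholds = NULL) {
  stopifnot(inherits(fit, "hs_fit"))
  th <- modifyList(list(onset_s = 0.15, peak_rel = 0.10,
                        t_peak_s = 0.15, run_s = 0.5,
                        steady_rel = 0.02), thresholds %||% list())
  f <- fit$fits[[trace_index]]
  t <- f$t; y <- -f$data_pA; m <- -f$model_pA
  peak_y <- max(y); peak_m <- max(m)
  tp_y <- t[which.max(y)]; tp_m <- t[which.max(m)]
  onset_of <- function(v, pk) {
    i <- which(v > 0.2 * pk)[1]
    if (is.na(i)) t[length(t)] else t[i]
  }
  on_y <- onset_of(y, peak_y); on_m <- onset_of(m, peak_m)
  resid <- y - m
  pre_n <- max(10L, as.integer(0.1 * length(y)))
  sig <- max(sd(resid[seq_len(min(pre_n, length(resid)))]),
             1e-3 * peak_y, 1e-9)
  # decay phase: peak to 2 s past the peak
  dec <- which(t > tp_y & t <= tp_y + 2)
  run_dur <- 0
  if (length(dec) > 2L) {
    sgn <- sign(resid[dec]) * (abs(resid[dec]) > 2 * sig)
    r <- rle(sgn)
    run_dur <- max(c(0, r$lengths[r$values != 0])) *
      (t[2] - t[1])
  }
  tail_idx <- seq.int(max(1L, length(t) - length(t) %/% 7L), length(t))
  steady_bias <- abs(mean(resid[tail_idx])) / peak_y
  flags <- c(onset = abs(on_y - on_m) <= th$onset_s,
             peak = abs(peak_m - peak_y) / peak_y <= th$peak_rel &
               abs(tp_m - tp_y) <= th$t_peak_s,
             decay = run_dur <= th$run_s,
             steady_state = steady_bias <= th$steady_rel)
  structure(flags, class = "quality_flags",
            features = list(onset_data = on_y, onset_model = on_m,
                            peak_data = peak_y, peak_model = peak_m,
                            t_peak_data = tp_y, t_peak_model = tp_m,
                            decay_run_s = run_dur,
                            steady_bias_rel = steady_bias,
                            noise_sd = sig))
}
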