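#' Parameter-recovery study on synthetic fixture families
#'
#' Generates synthetic HS responses from a ground-truth parameter set in
#' which one model parameter at a time is scaled (halved/doubled by
#' default), adds Gaussian recording noise, refits every trace, and
#' tabulates fitted against true values. This replicates, at reduced
#' scale, the simulation study establishing that the fit discriminates
#' between model parameters: the adapted parameter should track its
#' ground truth with log-log slope 1 while the others stay invariant.
#'
#' Scaling `k1` (or equivalently `D0`) adapts the fitted priming flux
#' `k1D`; the five fitted slots are `k1D`, `k_minus1`, `k2_max`,
#' `t_del`, `tau`.
#'
#' @param params ground-truth [model_params()] set.
#' @param vary parameters to scale, a subset of
#'   `c("k1", "k_minus1", "k2_max", "t_del", "tau")`.
#' @param factors scale factors applied one at a time (default 0.5
#'   and 2); the unscaled baseline is always included.
#' @param n_seeds noise realizations per condition.
#' @param noise_sd recording noise (pA), default 10.
#' @param config [fit_config()] used for every fit; default is a
#'   runtime-scaled configuration (multi-start simplex, 1 ms cost grid).
#' @param seed base seed; trace noise and fits derive from it.
#' @param duration,dt trace synthesis arguments.
#' @return A data frame with one row per (condition, seed, fitted slot):
#'   columns `condition`, `factor`, `seed`, `param`, `truth`, `fitted`.
#' @seealso [recovery_summary()]
#' @export
recovery_study <- function(params = default_model_params(),
                           vary = c("k1", "k_minus1", "k2_max", "t_del",
                                    "tau"),
                           factors = c(0.5, 2), n_seeds = 2,
                           noise_sd = 10, config = NULL, seed = 1,
                           duration = 8, dt = 1e-4) {
  vary <- match.arg(vary, several.ok = TRUE)
  if (is.null(config))
    config <- fit_config(global_method = "none", n_starts = 4,
                         fit_dt = 1e-3)
  slots <- c("k1D", "k_minus1", "k2_max", "t_del", "tau")
  truth_of <- function(p) c(k1D = p$k1 * p$D0, k_minus1 = p$k_minus1,
                            k2_max = p$k2_max, t_del = p$t_del,
                            tau = p$tau)
  conds <- c(list(list(name = "baseline", factor = 1)),
             unlist(lapply(vary, function(nm)
               lapply(factors, function(f) list(name = nm, factor = f))),
               recursive = FALSE))
  rows <- list()
  cid <- 0L
  for (cond in conds) {
    cid <- cid + 1L
    p <- params
    if (cond$name != "baseline")
      p[[cond$name]] <- p[[cond$name]] * cond$factor
    tru <- truth_of(p)
    for (s in seq_len(n_seeds)) {
      tr_seed <- seed * 10000L + cid * 100L + s
      tr <- synthesize_trace(p, noise_sd = noise_sd, seed = tr_seed,
                             duration = duration, dt = dt)
      cfg <- config
      cfg$seed <- tr_seed + 50L
      fit <- fit_traces(tr, cfg)
      est <- c(k1D = fit$k1D, k_minus1 = fit$k_minus1,
               k2_max = fit$per_trace$k2_max[1],
               t_del = fit$per_trace$t_del[1],
               tau = fit$per_trace$tau[1])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond$name, factor = cond$factor, seed = s,
        param = slots, truth = unname(tru[slots]),
        fitted = unname(est[slots]))
    }
  }
  do.call(rbind, rows)
}

#' Summarize a parameter-recovery study
#'
#' For each fitted slot, regresses log fitted on log true values over
#' the conditions in which that parameter was adapted (plus the
#' baseline), giving the recovery slope; and over all other conditions
#' computes the worst relative deviation of the slot from its (constant)
#' ground truth, the invariance of non-adapted parameters.
#'
#' @param study a data frame from [recovery_study()].
#' @return A list with `slopes` (named vector, one per adapted slot)
#'   and `max_other_dev` (named vector of worst relative deviations of
#'   each slot when it was not the adapted one).
#' @export
recovery_summary <- function(study) {
  stopifnot(all(c("condition", "param", "truth", "fitted") %in%
                  names(study)))
  cond_of_slot <- c(k1D = "k1", k_minus1 = "k_minus1",
                    k2_max = "k2_max", t_del = "t_del", tau = "tau")
  slots <- intersect(names(cond_of_slot), unique(study$param))
  slopes <- sapply(slots, function(sl) {
    d <- study[study$param == sl &
                 study$condition %in% c(cond_of_slot[[sl]], "baseline"), ]
    if (length(unique(d$truth)) < 2L) return(NA_real_)
    unname(coef(lm(log(fitted) ~ log(truth), data = d))[2])
  })
  max_dev <- sapply(slots, function(sl) {
    d <- study[study$param == sl &
                 !(study$condition %in% cond_of_slot[[sl]]), ]
    max(abs(d$fitted / d$truth - 1))
  })
  list(slopes = slopes, max_other_dev = max_dev)
}
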