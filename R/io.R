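#' Write a current trace as CSV with a JSON sidecar
#'
#' The canonical on-disk format: a two-column CSV (`time_s`,
#' `current_pA`, period decimal separator) plus a JSON sidecar
#' (same path with extension `.json`) holding the stimulus metadata.
#'
#' @param trace an [hs_trace()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hs_trace"))
  df <- data.frame(time_s = trace$t, current_pA = trace$I_pA)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(stim_on = trace$stim_on, stim_off = trace$stim_off,
               label = trace$label, meta = trace$meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Read a current trace from CSV
#'
#' Reads a two-column numeric file (time in s, current in pA) and its
#' JSON sidecar with stimulus metadata. Validates uniform sampling
#' (jitter tolerance 1e-9 s) and rejects non-numeric rows and
#' single-row files. Stimulus metadata must come from the sidecar or
#' the `stim_on`/`stim_off` arguments.
#'
#' @param path CSV path.
#' @param stim_on,stim_off stimulus window (s); overrides the sidecar.
#' @param label,meta annotations; override the sidecar.
#' @return An [hs_trace()] object.
#' @export
read_trace <- function(path, stim_on = NULL, stim_off = NULL,
                       label = NULL, meta = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- read.csv(path, header = TRUE)
  if (ncol(df) < 2L)
    stop("trace file must have two columns (time_s, current_pA): ", path)
  if (nrow(df) < 2L)
    stop("trace file has fewer than 2 rows; cannot establish dt: ", path)
  t <- suppressWarnings(as.numeric(df[[1]]))
  I <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(t) || anyNA(I))
    stop("non-numeric rows in trace file: ", path)
  dts <- diff(t)
  if (any(dts <= 0) || (max(dts) - min(dts)) > 1e-9)
    stop("non-uniform sampling in trace file: ", path)
  side <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp) && sp != path) side <- jsonlite::fromJSON(sp)
  stim_on <- stim_on %||% side$stim_on
  stim_off <- stim_off %||% side$stim_off
  if (is.null(stim_on) || is.null(stim_off))
    stop("missing stimulus metadata for ", path,
         ": provide a JSON sidecar or stim_on/stim_off")
  hs_trace(t, I, stim_on = stim_on, stim_off = stim_off,
           label = label %||% side$label %||% "",
           meta = meta %||% as.list(side$meta %||% list()))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

pipeline_kernel <- function(cfg) {
  k <- cfg$kernel %||% list()
  mepsc_kernel(rise_tau = k$rise_tau %||% 5e-4,
               decay_tau = k$decay_tau %||% 3e-3,
               charge = k$charge %||% 1.1e-4,
               sample_dt = k$sample_dt %||% 1e-4)
}

#' Run the simulate/fit/analyze/bootstrap pipeline
#'
#' Executes the configured stages and writes all outputs (trace CSVs,
#' fit JSONs, a per-trace summary CSV, a bootstrap JSON and a run log)
#' into the output directory. Every artifact records the seed and a
#' hash of the configuration, so a rerun with the same configuration and
#' seed is reproducible.
#'
#' The configuration is a named list (or path to a JSON file) with
#' elements:
#' \describe{
#'   \item{outdir}{output directory (created if needed).}
#'   \item{seed}{integer seed for all stochastic stages.}
#'   \item{simulate}{optional list with `params` (a list of
#'     [model_params()] argument lists, one per trace), `noise_sd`,
#'     `duration`, `dt`; generates the input traces.}
#'   \item{inputs}{alternatively, character vector of trace CSV paths.}
#'   \item{kernel}{optional kernel settings (`rise_tau`, `decay_tau`,
#'     `charge`, `sample_dt`).}
#'   \item{fit}{optional [fit_config()] argument list.}
#'   \item{bootstrap}{optional list with `n_resamples` (default
#'     10000); runs across traces when there are at least 2.}
#' }
#'
#' @param config configuration list or path to a JSON file.
#' @return Invisibly, a list with the per-trace `summary` data frame,
#'   the `bootstrap` summaries, the output `files`, and the config
#'   `hash`. Any stage failure aborts with a stage-labelled error.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  stopifnot(is.list(config))
  outdir <- config$outdir %||% stop("pipeline config needs 'outdir'")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", file = logf,
                               append = TRUE, sep = "")
  cat(sprintf("vesiclefit %s | seed %d | config %s\n",
              as.character(utils::packageVersion("vesiclefit")), seed,
              hash),
      file = logf)

  kernel <- pipeline_kernel(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  traces <- stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      stopifnot(is.list(sim$params), length(sim$params) >= 1L)
      sim_dt <- sim$dt %||% kernel$sample_dt
      sim_kernel <- kernel_at_dt(kernel, sim_dt)
      lapply(seq_along(sim$params), function(i) {
        p <- do.call(model_params, sim$params[[i]])
        tr <- synthesize_trace(p, kernel = sim_kernel,
                               noise_sd = sim$noise_sd %||% 10,
                               seed = seed + i,
                               duration = sim$duration %||% 8,
                               dt = sim_dt,
                               label = sim$labels[[i]] %||%
                                 paste0("sim", i))
        write_trace(tr, file.path(outdir,
                                  paste0("trace_", tr$label, ".csv")))
        tr
      })
    } else if (!is.null(config$inputs)) {
      lapply(unlist(config$inputs), read_trace)
    } else {
      stop("config needs either 'simulate' or 'inputs'")
    }
  })
  logline("simulate: %d trace(s)", length(traces))

  fits <- stage("fit", {
    fargs <- config$fit %||% list()
    fargs$kernel <- kernel
    fargs$seed <- fargs$seed %||% seed
    cfg <- do.call(fit_config, fargs)
    lapply(traces, fit_traces, config = cfg)
  })
  logline("fit: done (%s)",
          paste(sprintf("sse=%.4g", vapply(fits, `[[`, 0, "sse")),
                collapse = ", "))

  summary_df <- stage("analyze", {
    ref_k2 <- max(vapply(fits, function(f) f$per_trace$k2_max[1],
                         numeric(1)))
    ref_rrp <- max(vapply(fits, `[[`, 0, "rrp"))
    do.call(rbind, lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      tr <- traces[[i]]
      est <- rrp_estimates(tr, f)
      p <- model_params(k1 = f$k1D, D0 = 1, k_minus1 = f$k_minus1,
                        k2_max = f$per_trace$k2_max[1], t0 = tr$stim_on,
                        t_del = f$per_trace$t_del[1],
                        tau = f$per_trace$tau[1])
      traj <- integrate_pools(p, duration = tr$stim_off, dt = 1e-3,
                              engine = "fixed")
      pk <- peak_release_rate(traj, reference_rrp = ref_rrp)
      data.frame(
        label = tr$label, k1D = f$k1D, k_minus1 = f$k_minus1,
        rrp_nC = f$rrp, k2_max = f$per_trace$k2_max[1],
        t_del = f$per_trace$t_del[1], tau = f$per_trace$tau[1],
        delta_Ea_RT = log(f$per_trace$k2_max[1] / ref_k2),
        depleted_fraction = depleted_fraction(traj, ref_rrp),
        peak_rate_nC_s = pk$peak_rate,
        rrp_model_corrected_nC = est$value[est$method ==
                                             "model_replenishment"],
        sse_pA2 = f$sse, converged = f$converged,
        seed = seed, config_hash = hash)
    }))
  })
  sum_path <- file.path(outdir, "summary.csv")
  write.csv(summary_df, sum_path, row.names = FALSE)
  logline("analyze: wrote %s", sum_path)

  boot <- stage("bootstrap", {
    if (length(fits) >= 2L) {
      nb <- (config$bootstrap %||% list())$n_resamples %||% 10000
      vals <- list(k2_max = summary_df$k2_max,
                   k1D = summary_df$k1D,
                   k_minus1 = summary_df$k_minus1,
                   rrp_nC = summary_df$rrp_nC)
      lapply(vals, function(v)
        unclass(bootstrap_means(v, n_resamples = nb, seed = seed)))
    } else {
      NULL
    }
  })
  boot_path <- NULL
  if (!is.null(boot)) {
    boot_path <- file.path(outdir, "bootstrap.json")
    writeLines(jsonlite::toJSON(c(list(seed = seed, config_hash = hash),
                                  boot),
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), boot_path)
    logline("bootstrap: wrote %s", boot_path)
  }

  fit_path <- file.path(outdir, "fits.json")
  writeLines(jsonlite::toJSON(
    list(seed = seed, config_hash = hash,
         fits = lapply(fits, function(f)
           list(k1D = f$k1D, k_minus1 = f$k_minus1, rrp = f$rrp,
                per_trace = f$per_trace, sse = f$sse,
                converged = f$converged))),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE),
    fit_path)

  invisible(list(summary = summary_df, fits = fits, bootstrap = boot,
                 files = c(summary = sum_path, fits = fit_path,
                           bootstrap = boot_path, log = logf),
                 hash = hash))
}
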