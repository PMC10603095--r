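#' Write traces to a delimited text file
#'
#' Long format, one row per sample, with header
#' `scenario,observable,timescale,replicate,is_control,E0_uM,S0_uM,t_s,value,trace_id`.
#' The `trace_id` column keys each trace uniquely (short- and long-timescale
#' traces can otherwise share all condition fields).
#'
#' @param traces list of `kin_trace` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    cond <- tr$condition
    data.frame(scenario = tr$scenario_id, observable = tr$observable,
               timescale = tr$timescale, replicate = tr$replicate,
               is_control = tr$is_control,
               E0_uM = if (!is.null(cond)) cond$E0 else NA_real_,
               S0_uM = if (!is.null(cond)) cond$S0 else NA_real_,
               t_s = tr$times, value = tr$values,
               trace_id = sprintf("%s|%s|%s|%g|r%d%s", tr$scenario_id,
                                  tr$observable, tr$timescale,
                                  if (!is.null(cond)) cond$S0 else NA,
                                  tr$replicate,
                                  if (tr$is_control) "|ctrl" else ""))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traces from a delimited text file
#'
#' Inverse of [write_traces()]; validates the schema and per-trace time
#' monotonicity.
#'
#' @param path file written by [write_traces()] (or conforming to its
#'   schema; `timescale` and `trace_id` are optional).
#' @return List of `kin_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("scenario", "observable", "replicate", "is_control",
                "E0_uM", "S0_uM", "t_s", "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trace file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"timescale" %in% names(df)) df$timescale <- ""
  key <- if ("trace_id" %in% names(df)) df$trace_id
  else interaction(df$scenario, df$observable, df$timescale, df$replicate,
                   df$is_control, df$E0_uM, df$S0_uM, drop = TRUE)
  df$.row <- seq_len(nrow(df))
  lapply(split(df, key), function(g) {
    if (is.unsorted(g$t_s, strictly = TRUE))
      stop(sprintf("non-monotonic times in trace group starting at row %d",
                   g$.row[1]))
    cond <- assay_condition(E0 = g$E0_uM[1], S0 = g$S0_uM[1],
                            duration = max(g$t_s),
                            sample_interval = min(diff(g$t_s)),
                            replicate_count = 1)
    kin_trace(g$observable[1], g$t_s, g$value, condition = cond,
              scenario_id = g$scenario[1], replicate = g$replicate[1],
              is_control = as.logical(g$is_control[1]),
              timescale = g$timescale[1])
  })
}

#' Stopped-flow analysis of one scenario's trace set
#'
#' Reproduces the transient-fitting chain: replicates are averaged per
#' condition, long-timescale traces are photobleaching-corrected against the
#' no-substrate control, short-timescale averages are fitted with both the
#' single-exponential-plus-linear and double-exponential models, each
#' concentration is phase-classified, and the per-concentration observed
#' rates are tabulated for the secondary plots.
#'
#' @param traces list of fluorescence `kin_trace` objects as produced by
#'   [generate_stopped_flow_dataset()] (must include short-timescale traces
#'   and may include long-timescale traces plus controls).
#' @param short name of the short timescale (default `"short"`).
#' @param ... thresholds passed to [classify_phases()].
#' @return A list with `classification` (majority phase call), `per_S0`
#'   (named list of single/double fits and phase call per concentration) and
#'   rate tables `kobs_fast`, `kobs_slow`, `kobs_total` (data.frames with
#'   S0, kobs, se).
#' @export
analyse_stopped_flow <- function(traces, short = "short", ...) {
  is_ctl <- vapply(traces, `[[`, logical(1), "is_control")
  controls <- traces[is_ctl]
  signal <- traces[!is_ctl]
  ts_of <- vapply(signal, `[[`, character(1), "timescale")
  S0_of <- vapply(signal, function(tr) tr$condition$S0, numeric(1))
  ctl_ts <- vapply(controls, `[[`, character(1), "timescale")
  short_traces <- signal[ts_of == short]
  short_S0 <- S0_of[ts_of == short]
  if (length(short_traces) == 0) stop("no short-timescale traces found")
  per_S0 <- list()
  for (S0 in sort(unique(short_S0))) {
    avg <- average_replicates(short_traces[short_S0 == S0])
    fs <- fit_single_exp_linear(avg)
    fd <- fit_double_exp(avg)
    per_S0[[as.character(S0)]] <-
      list(S0 = S0, single = fs, double = fd,
           phase = classify_phases(fs, fd, ...))
  }
  calls <- vapply(per_S0, `[[`, character(1), "phase")
  short_biphasic <- mean(calls == "biphasic") > 0.5
  # corrected long-timescale averages: photobleaching removed by control
  # subtraction; used to find or re-estimate slow phases that barely evolve
  # on the short timescale
  long_corrected <- NULL
  long_ts <- setdiff(unique(ts_of), short)
  if (length(long_ts) == 1 && any(ctl_ts == long_ts)) {
    ctl <- controls[[which(ctl_ts == long_ts)[1]]]
    long_traces <- signal[ts_of == long_ts]
    long_S0 <- S0_of[ts_of == long_ts]
    long_corrected <- lapply(sort(unique(long_S0)), function(S0)
      correct_photobleaching(average_replicates(long_traces[long_S0 == S0]),
                             ctl))
    names(long_corrected) <- as.character(sort(unique(long_S0)))
  }
  # slow-phase fit on a corrected long trace, after discarding the fast
  # binding transient (single exponential + linear drift on the remainder)
  fit_long_slow <- function(p, kobs_fast_p) {
    lc <- long_corrected[[as.character(p$S0)]]
    if (is.null(lc)) return(NULL)
    keep <- lc$times > 5 / kobs_fast_p
    lc$times <- lc$times[keep]; lc$values <- lc$values[keep]
    list(fit = fit_single_exp_linear(lc),
         fast_amp = abs(p$single$coefficients[["a"]]))
  }
  tab <- function(fast) {
    do.call(rbind, lapply(per_S0, function(p) {
      if (fast == "double")
        data.frame(S0 = p$S0, kobs = p$double$coefficients[["kobs1"]],
                   se = p$double$se[["kobs1"]])
      else data.frame(S0 = p$S0, kobs = p$single$coefficients[["kobs"]],
                      se = p$single$se[["kobs"]])
    }))
  }
  classification <- if (short_biphasic) "biphasic" else "monophasic"
  slow_source <- if (short_biphasic) "short_double_exp" else "none"
  kobs_slow <- NULL
  if (short_biphasic) {
    kobs_fast <- tab("double")
    kobs_slow <- do.call(rbind, lapply(per_S0, function(p)
      data.frame(S0 = p$S0, kobs = p$double$coefficients[["kobs2"]],
                 se = p$double$se[["kobs2"]])))
    short_dur <- max(short_traces[[1]]$times)
    if (!is.null(long_corrected) &&
        stats::median(kobs_slow$kobs) * short_dur < 3) {
      # slow phase under-resolved on the short timescale
      slow_source <- "long_single_exp"
      kobs_slow <- do.call(rbind, lapply(per_S0, function(p) {
        ls <- fit_long_slow(p, p$double$coefficients[["kobs1"]])
        if (is.null(ls)) return(NULL)
        data.frame(S0 = p$S0, kobs = ls$fit$coefficients[["kobs"]],
                   se = ls$fit$se[["kobs"]])
      }))
    }
  } else {
    kobs_fast <- tab("single")
    if (!is.null(long_corrected)) {
      # a second phase may be too slow for the short window entirely: look
      # for a genuine slow relaxation on the corrected long traces
      long_rows <- lapply(per_S0, function(p) {
        ls <- fit_long_slow(p, p$single$coefficients[["kobs"]])
        if (is.null(ls)) return(NULL)
        f <- ls$fit
        k <- f$coefficients[["kobs"]]
        real <- length(f$degenerate) == 0 && is.finite(k) &&
          k * f$trace_info$t_max >= 1 &&
          abs(f$coefficients[["a"]]) >= 0.05 * ls$fast_amp
        list(row = data.frame(S0 = p$S0, kobs = k, se = f$se[["kobs"]]),
             real = real)
      })
      long_rows <- Filter(Negate(is.null), long_rows)
      if (length(long_rows) > 0 &&
          mean(vapply(long_rows, `[[`, logical(1), "real")) > 0.5) {
        classification <- "biphasic"
        slow_source <- "long_single_exp"
        kobs_slow <- do.call(rbind, lapply(long_rows, `[[`, "row"))
      }
    }
  }
  kobs_total <- if (classification == "biphasic") {
    fast <- kobs_fast[order(kobs_fast$S0), ]
    slow <- kobs_slow[order(kobs_slow$S0), ]
    data.frame(S0 = fast$S0, kobs = fast$kobs + slow$kobs,
               se = sqrt(fast$se^2 + slow$se^2))
  } else NULL
  list(classification = classification, per_S0 = per_S0,
       kobs_fast = kobs_fast, kobs_slow = kobs_slow, kobs_total = kobs_total,
       slow_source = slow_source, long_corrected = long_corrected)
}

#' Full staged analysis of one scenario
#'
#' Runs the complete inference chain on one scenario's synthetic (or
#' imported) datasets: stopped-flow fitting and classification, the binding
#' secondary plot (total-rate variant for biphasic enzymes), the catalytic
#' secondary plot when biphasic, initial rates and Michaelis-Menten fitting
#' of the turnover data (skipped when no activity is measurable), the burst
#' fit, and the assembled mechanism estimate.
#'
#' @param sf_traces stopped-flow trace list.
#' @param turnover_traces absorbance trace list (or NULL).
#' @param burst_trace product `kin_trace` (or NULL).
#' @param turnover_E0,burst_E0 enzyme concentrations of those assays (uM).
#' @param delta_eps_ell absorbance conversion factor (AU/uM).
#' @param rate_window_s initial-rate window (s).
#' @return A list with the intermediate results (`stopped_flow`, `binding`,
#'   `catalytic`, `rates`, `mm`, `burst`) and the final `estimate`
#'   (a `mechanism_estimate`).
#' @export
analyse_scenario <- function(sf_traces, turnover_traces = NULL,
                             burst_trace = NULL, turnover_E0 = NULL,
                             burst_E0 = NULL, delta_eps_ell = 0.01,
                             rate_window_s = 30) {
  sf <- analyse_stopped_flow(sf_traces)
  biphasic <- sf$classification == "biphasic"
  binding <- if (biphasic)
    secondary_plot_binding(sf$kobs_total, mode = "total")
  else secondary_plot_binding(sf$kobs_fast, mode = "fast")
  catalytic <- if (biphasic) secondary_plot_catalytic(sf$kobs_slow) else NULL
  rates <- NULL; mm <- NULL
  if (!is.null(turnover_traces)) {
    if (is.null(turnover_E0))
      turnover_E0 <- turnover_traces[[1]]$condition$E0
    S0s <- vapply(turnover_traces, function(tr) tr$condition$S0, numeric(1))
    v <- vapply(turnover_traces, function(tr)
      initial_rate(tr, window_s = rate_window_s,
                   delta_eps_ell = delta_eps_ell)$v, numeric(1))
    rates <- do.call(rbind, lapply(sort(unique(S0s)), function(S0)
      data.frame(S0 = S0, v = mean(v[S0s == S0]))))
    if (max(rates$v) > 1e-4 * turnover_E0)
      mm <- fit_michaelis_menten(rates, E0 = turnover_E0)
  }
  burst <- if (!is.null(burst_trace)) {
    if (is.null(burst_E0)) burst_E0 <- burst_trace$condition$E0
    fit_burst(burst_trace, E0 = burst_E0)
  } else NULL
  estimate <- assemble_mechanism(binding, catalytic, mm, burst,
                                 phases = sf$classification)
  list(stopped_flow = sf, binding = binding, catalytic = catalytic,
       rates = rates, mm = mm, burst = burst, estimate = estimate)
}

#' Pipeline run configuration
#'
#' One configuration object fully determines a pipeline run (scenario set,
#' assay designs, noise, seed, output directory).
#'
#' @param scenarios character vector of preset names (see
#'   [scenario_presets()]).
#' @param seed base seed for all generated noise.
#' @param outdir output directory (created if needed).
#' @param noise_frac noise fraction of dynamic range (0 = noiseless).
#' @param sf_S0 stopped-flow substrate concentrations (uM).
#' @param sf_timescales named stopped-flow durations (s).
#' @param replicates technical replicates.
#' @param turnover_S0 turnover-assay substrate grid (uM).
#' @param turnover_E0 named vector of per-scenario turnover enzyme
#'   concentrations (uM); unnamed scenarios fall back to `1`.
#' @param burst_E0,burst_S0 burst-assay concentrations (uM).
#' @param delta_eps_ell absorbance conversion factor (AU/uM).
#' @return A `run_config` object.
#' @export
run_config <- function(scenarios = names(scenario_presets()), seed = 1,
                       outdir = tempfile("kinrun"), noise_frac = 0.01,
                       sf_S0 = c(20, 50, 100, 200),
                       sf_timescales = c(short = 2, long = 50),
                       replicates = 3,
                       turnover_S0 = c(1, 2, 5, 10, 20, 50, 100, 200),
                       turnover_E0 = c(WT = 0.1, E104Q = 1, H56A = 1,
                                       E55Q = 1, E55A = 1, E55A_H56A = 1),
                       burst_E0 = 1, burst_S0 = 200, delta_eps_ell = 0.01) {
  presets <- scenario_presets()
  unknown <- setdiff(scenarios, names(presets))
  if (length(unknown))
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "))
  if (noise_frac > 0 && is.null(seed))
    stop("a seed is required when noise is generated")
  structure(list(scenarios = scenarios, seed = seed, outdir = outdir,
                 noise_frac = noise_frac, sf_S0 = sf_S0,
                 sf_timescales = sf_timescales, replicates = replicates,
                 turnover_S0 = turnover_S0, turnover_E0 = turnover_E0,
                 burst_E0 = burst_E0, burst_S0 = burst_S0,
                 delta_eps_ell = delta_eps_ell),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys are the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$turnover_E0)) cfg$turnover_E0 <- unlist(cfg$turnover_E0)
  if (!is.null(cfg$sf_timescales)) cfg$sf_timescales <- unlist(cfg$sf_timescales)
  do.call(run_config, cfg)
}

fit_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  if (inherits(f, "exp_fit"))
    list(model = f$model, coefficients = as.list(f$coefficients),
         se = as.list(f$se), rss = f$rss, n_points = f$n_points,
         aicc = f$aicc, degenerate = f$degenerate)
  else lapply(unclass(f), function(x) if (is.data.frame(x)) NULL else x)
}

#' Run the end-to-end pipeline
#'
#' generate -> correct -> fit -> analyse -> report, for every configured
#' scenario. Writes per-scenario trace files under `traces/`, fit summaries
#' under `fits/`, a deterministic numeric `report.json` (identical config +
#' seed reproduce it byte-for-byte) and a human-readable `log.txt` recording
#' the thresholds applied.
#'
#' @param config a [run_config()].
#' @return Path of the written `report.json`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  presets <- scenario_presets()
  dir.create(file.path(config$outdir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(config$outdir, "fits"), showWarnings = FALSE)
  log_lines <- c("two-step mechanism inference pipeline",
                 sprintf("seed = %d, noise_frac = %g", config$seed,
                         config$noise_frac),
                 "phase classification: delta AICc > 10, rate separation >= 3, |a2|/|a1| >= 0.05",
                 "initial-rate window: 30 s with quadratic depletion check",
                 sprintf("burst kcat route engaged when A/E0 >= 0.1; inactive below kcat = 1e-4 /s"))
  scen_seeds <- make_subseeds(config$seed, 3 * length(config$scenarios))
  report <- list()
  for (i in seq_along(config$scenarios)) {
    nm <- config$scenarios[i]
    sc <- presets[[nm]]
    s3 <- scen_seeds[(3 * i - 2):(3 * i)]
    sf <- generate_stopped_flow_dataset(sc, S0_list = config$sf_S0,
                                        timescales = config$sf_timescales,
                                        replicates = config$replicates,
                                        noise_frac = config$noise_frac,
                                        seed = s3[1])
    tE0 <- if (nm %in% names(config$turnover_E0))
      config$turnover_E0[[nm]] else 1
    to <- generate_turnover_dataset(sc, S0_grid = config$turnover_S0,
                                    E0 = tE0,
                                    replicates = config$replicates,
                                    delta_eps_ell = config$delta_eps_ell,
                                    noise_frac = config$noise_frac,
                                    seed = s3[2])
    bu <- generate_burst_dataset(sc, E0 = config$burst_E0,
                                 S0 = config$burst_S0,
                                 noise_frac = config$noise_frac,
                                 seed = s3[3])
    write_traces(sf, file.path(config$outdir, "traces",
                               paste0(nm, "_stopped_flow.csv")))
    write_traces(to, file.path(config$outdir, "traces",
                               paste0(nm, "_turnover.csv")))
    write_traces(list(bu), file.path(config$outdir, "traces",
                                     paste0(nm, "_burst.csv")))
    warn <- character()
    ana <- withCallingHandlers(
      analyse_scenario(sf, to, bu, turnover_E0 = tE0,
                       burst_E0 = config$burst_E0,
                       delta_eps_ell = config$delta_eps_ell),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log_lines <- c(log_lines, sprintf("[%s] classification = %s%s", nm,
                                      ana$stopped_flow$classification,
                                      if (length(warn))
                                        paste0("; warnings: ",
                                               paste(unique(warn),
                                                     collapse = " | "))
                                      else ""))
    fits_out <- list(
      classification = ana$stopped_flow$classification,
      per_S0 = lapply(ana$stopped_flow$per_S0, function(p)
        list(S0 = p$S0, phase = p$phase, single = fit_to_list(p$single),
             double = fit_to_list(p$double))),
      binding = fit_to_list(ana$binding),
      catalytic = fit_to_list(ana$catalytic),
      mm = fit_to_list(ana$mm),
      burst = fit_to_list(ana$burst))
    jsonlite::write_json(fits_out,
                         file.path(config$outdir, "fits",
                                   paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    e <- ana$estimate
    report[[nm]] <- list(
      classification = ana$stopped_flow$classification,
      rate_limiting = e$rate_limiting,
      KD_uM = e$KD_est, k_on_per_uM_s = e$k_on_est,
      k_off_per_s = e$k_off_est, k_cleave_per_s = e$k_cleave_est,
      k_hydrolyse_per_s = e$k_hydrolyse_est, kcat_per_s = e$kcat_est,
      Km_uM = e$Km_est, burst_amplitude_ratio = e$burst_amplitude_ratio)
  }
  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(log_lines, file.path(config$outdir, "log.txt"))
  invisible(report_path)
}
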