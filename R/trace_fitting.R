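#' Photobleaching correction by control subtraction
#'
#' Long-timescale fluorescence traces are corrected by subtracting the trace
#' measured in the absence of substrate, which carries only background and
#' photobleaching. If the control grid differs, the control is linearly
#' interpolated onto the trace grid.
#'
#' @param trace a fluorescence `kin_trace`.
#' @param control the matching no-substrate control (`is_control = TRUE`).
#' @return The corrected `kin_trace` (`corrected = TRUE`).
#' @export
correct_photobleaching <- function(trace, control) {
  stopifnot(inherits(trace, "kin_trace"), inherits(control, "kin_trace"))
  if (!control$is_control) stop("second argument must be a control trace")
  if (trace$observable != control$observable)
    stop("trace and control observables differ")
  ctl <- if (length(control$times) == length(trace$times) &&
             all(control$times == trace$times)) control$values
  else stats::approx(control$times, control$values, xout = trace$times,
                     rule = 2)$y
  trace$values <- trace$values - ctl
  trace$corrected <- TRUE
  trace
}

#' Pointwise average of replicate traces
#'
#' Replicate traces acquired under one condition are averaged before fitting.
#'
#' @param traces non-empty list of `kin_trace` objects on identical grids and
#'   conditions.
#' @return A single averaged `kin_trace` (replicate index 0).
#' @export
average_replicates <- function(traces) {
  if (length(traces) == 0) stop("no traces to average")
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    if (tr$observable != ref$observable ||
        length(tr$times) != length(ref$times) ||
        any(tr$times != ref$times))
      stop("replicates must share observable and time grid")
    if (!is.null(ref$condition) && !is.null(tr$condition) &&
        (tr$condition$E0 != ref$condition$E0 ||
         tr$condition$S0 != ref$condition$S0))
      stop("replicates must share assay condition")
  }
  vals <- rowMeans(vapply(traces, `[[`, numeric(length(ref$times)), "values"))
  ref$values <- vals
  ref$replicate <- 0L
  ref
}

# ---- deterministic variable-projection exponential fitting -----------------

# Residual sum of squares and linear coefficients for a design matrix built
# from fixed rate constants; the linear parameters are profiled out exactly.
varpro_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients,
       residuals = fit$residuals)
}

# Log-spaced candidate rate grid covering [lo_frac/duration, 1/(2 dt)].
kobs_grid <- function(times, n = 40, lo_frac = 0.5) {
  dur <- max(times) - min(times)
  dt <- min(diff(times))
  exp(seq(log(lo_frac / dur), log(1 / (2 * dt)), length.out = n))
}

aicc_from_rss <- function(rss, n, p) {
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

exp_fit_result <- function(model, coef, se, rss, n, trace, flags = character()) {
  p <- length(coef)
  tss <- sum((trace$values - mean(trace$values))^2)
  structure(list(model = model, coefficients = coef, se = se, rss = rss,
                 tss = tss, n_points = n, aicc = aicc_from_rss(rss, n, p),
                 degenerate = flags,
                 trace_info = list(observable = trace$observable,
                                   scenario_id = trace$scenario_id,
                                   timescale = trace$timescale,
                                   t_max = max(trace$times),
                                   S0 = if (!is.null(trace$condition))
                                     trace$condition$S0 else NA_real_)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> model %s, RSS %.3g over %d points\n",
              x$model, x$rss, x$n_points))
  est <- rbind(estimate = x$coefficients, se = x$se)
  print(signif(est, 4))
  if (length(x$degenerate))
    cat("flags:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

# Jacobian-based standard errors at the optimum.
fit_se <- function(J, rss, n) {
  p <- ncol(J)
  sigma2 <- rss / max(n - p, 1)
  cov <- tryCatch(chol2inv(chol(crossprod(J))) * sigma2,
                  error = function(e) matrix(NA_real_, p, p))
  sqrt(pmax(diag(cov), 0))
}

#' Fit a single exponential plus a linear drift
#'
#' Least-squares fit of F(t) = a * exp(-kobs * t) + m * t + c, the model used
#' for mono-exponential stopped-flow decays where the linear term absorbs the
#' small residual photobleaching on short timescales. The decay rate is
#' profiled on a deterministic log-spaced grid (variable projection: for each
#' candidate kobs the linear parameters a, m, c are solved exactly), then
#' refined by one-dimensional optimisation, so the fit is deterministic and
#' needs no starting guesses.
#'
#' @param trace a `kin_trace` with at least 10 points.
#' @param kobs_range optional length-2 vector bounding the rate search
#'   (per s); defaults to the grid spanning the trace resolution.
#' @return An `exp_fit` with coefficients `a, kobs, m, c`, Jacobian-based
#'   standard errors, RSS and AICc. A fit whose amplitude is negligible
#'   relative to the signal spread is flagged `"degenerate_amplitude"` and its
#'   kobs is reported as NA rather than a spurious rate.
#' @export
fit_single_exp_linear <- function(trace, kobs_range = NULL) {
  stopifnot(inherits(trace, "kin_trace"))
  t <- trace$times; y <- trace$values
  n <- length(t)
  if (n < 10) stop("need at least 10 points for a single-exponential fit")
  grid <- if (is.null(kobs_range)) kobs_grid(t)
  else exp(seq(log(kobs_range[1]), log(kobs_range[2]), length.out = 40))
  rss_k <- function(k) varpro_rss(cbind(exp(-k * t), t, 1), y)$rss
  rss_grid <- vapply(grid, rss_k, numeric(1))
  ib <- which.min(rss_grid)
  lo <- grid[max(ib - 1, 1)]; hi <- grid[min(ib + 1, length(grid))]
  opt <- stats::optimize(function(lk) rss_k(exp(lk)), c(log(lo), log(hi)),
                         tol = 1e-10)
  k <- exp(opt$minimum)
  vp <- varpro_rss(cbind(exp(-k * t), t, 1), y)
  a <- vp$coef[1]; m <- vp$coef[2]; c0 <- vp$coef[3]
  coef <- c(a = unname(a), kobs = k, m = unname(m), c = unname(c0))
  e <- exp(-k * t)
  J <- cbind(a = e, kobs = -a * t * e, m = t, c = rep(1, n))
  se <- stats::setNames(fit_se(J, vp$rss, n), names(coef))
  flags <- character()
  spread <- stats::sd(y)
  if (!is.finite(a) || abs(a) <= max(1e-12, 1e-3 * spread)) {
    flags <- "degenerate_amplitude"
    coef[["kobs"]] <- NA_real_
  }
  if (ib %in% c(1L, length(grid))) flags <- c(flags, "rate_at_search_bound")
  exp_fit_result("single_exp_linear", coef, se, vp$rss, n, trace, flags)
}

#' Fit a double exponential
#'
#' Least-squares fit of
#' F(t) = a1 * exp(-kobs1 * t) + a2 * exp(-kobs2 * t) + c with kobs1 > kobs2,
#' the model for biphasic stopped-flow traces (rapid binding quench followed
#' by slower recovery as the covalent intermediate accumulates; opposite-sign
#' amplitudes are expected and allowed). Both rates are profiled on a
#' deterministic log-spaced grid and refined by Nelder-Mead on the log rates,
#' with the amplitudes and offset solved exactly at each step.
#'
#' @param trace a `kin_trace` with at least 20 points.
#' @param kobs_range optional length-2 vector bounding the rate search.
#' @param min_separation rates closer than this ratio are flagged
#'   `"rate_collapse"` (degenerate, nearly single-exponential).
#' @return An `exp_fit` with coefficients `a1, kobs1, a2, kobs2, c` (fast
#'   phase first).
#' @export
fit_double_exp <- function(trace, kobs_range = NULL, min_separation = 1.5) {
  stopifnot(inherits(trace, "kin_trace"))
  t <- trace$times; y <- trace$values
  n <- length(t)
  if (n < 20) stop("need at least 20 points for a double-exponential fit")
  grid <- if (is.null(kobs_range)) kobs_grid(t, n = 16)
  else exp(seq(log(kobs_range[1]), log(kobs_range[2]), length.out = 16))
  rss_kk <- function(k1, k2)
    varpro_rss(cbind(exp(-k1 * t), exp(-k2 * t), 1), y)$rss
  best <- list(rss = Inf)
  for (i in seq_along(grid)) for (j in seq_len(i - 1L)) {
    r <- rss_kk(grid[i], grid[j])
    if (r < best$rss) best <- list(rss = r, k = c(grid[i], grid[j]))
  }
  obj <- function(lk) {
    k <- exp(lk)
    if (any(!is.finite(k))) return(Inf)
    rss_kk(k[1], k[2])
  }
  opt <- stats::optim(log(best$k), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  k <- sort(exp(opt$par), decreasing = TRUE)
  vp <- varpro_rss(cbind(exp(-k[1] * t), exp(-k[2] * t), 1), y)
  a1 <- vp$coef[1]; a2 <- vp$coef[2]; c0 <- vp$coef[3]
  coef <- c(a1 = unname(a1), kobs1 = k[1], a2 = unname(a2), kobs2 = k[2],
            c = unname(c0))
  e1 <- exp(-k[1] * t); e2 <- exp(-k[2] * t)
  J <- cbind(a1 = e1, kobs1 = -a1 * t * e1, a2 = e2, kobs2 = -a2 * t * e2,
             c = rep(1, n))
  se <- stats::setNames(fit_se(J, vp$rss, n), names(coef))
  flags <- character()
  if (k[1] / k[2] < min_separation) flags <- "rate_collapse"
  exp_fit_result("double_exp", coef, se, vp$rss, n, trace, flags)
}

#' Model value of a fitted trace at given times
#'
#' @param object an `exp_fit`.
#' @param times evaluation times (s).
#' @param ... unused.
#' @return Fitted signal values.
#' @export
predict.exp_fit <- function(object, times, ...) {
  cf <- object$coefficients
  if (object$model == "double_exp")
    cf[["a1"]] * exp(-cf[["kobs1"]] * times) +
      cf[["a2"]] * exp(-cf[["kobs2"]] * times) + cf[["c"]]
  else {
    k <- cf[["kobs"]]
    decay <- if (is.na(k)) 0 else cf[["a"]] * exp(-k * times)
    decay + cf[["m"]] * times + cf[["c"]]
  }
}

# Fitted signal at t = 0 (exponential amplitudes plus offset).
fit_intercept <- function(fit) {
  cf <- fit$coefficients
  if (fit$model == "double_exp") cf[["a1"]] + cf[["a2"]] + cf[["c"]]
  else (if (is.na(cf[["kobs"]])) 0 else cf[["a"]]) + cf[["c"]]
}

#' Normalise a trace to the fitted Y-intercept
#'
#' Divides the signal by the fitted model value at t = 0, so normalised
#' traces start at ~1 and are comparable across conditions.
#'
#' @param trace the fitted `kin_trace`.
#' @param fit the `exp_fit` obtained on that trace.
#' @return The normalised `kin_trace`.
#' @export
normalise_to_intercept <- function(trace, fit) {
  stopifnot(inherits(trace, "kin_trace"), inherits(fit, "exp_fit"))
  f0 <- fit_intercept(fit)
  if (!is.finite(f0) || f0 <= 0)
    stop("fitted intercept is not positive; cannot normalise")
  trace$values <- trace$values / f0
  trace
}

#' Classify a stopped-flow trace as monophasic or biphasic
#'
#' Operationalises the by-eye phase call: the trace is biphasic only if the
#' double-exponential model is decisively preferred (AICc improvement over
#' the single-exponential-plus-linear fit larger than `delta_aicc`), the two
#' rates are separated by at least `min_rate_ratio`, the slow-phase
#' amplitude is at least `min_amp_frac` of the fast-phase amplitude, and the
#' slow phase completes at least `min_efolds` e-folds within the observation
#' window (a "phase" slower than that is indistinguishable from residual
#' photobleaching drift and does not count as a kinetic phase). A
#' single-exponential fit that already explains essentially all signal
#' variance short-circuits to monophasic.
#'
#' @param fit_single the single-exponential-plus-linear `exp_fit` of the
#'   trace.
#' @param fit_double the double-exponential `exp_fit` of the same trace.
#' @param delta_aicc required AICc advantage of the double model (default 10).
#' @param min_rate_ratio required kobs1/kobs2 separation (default 3).
#' @param min_amp_frac required |a2|/|a1| (default 0.05).
#' @param min_efolds required kobs2 * duration (default 1).
#' @return `"monophasic"` or `"biphasic"`.
#' @export
classify_phases <- function(fit_single, fit_double, delta_aicc = 10,
                            min_rate_ratio = 3, min_amp_frac = 0.05,
                            min_efolds = 1) {
  stopifnot(inherits(fit_single, "exp_fit"), inherits(fit_double, "exp_fit"))
  cf <- fit_double$coefficients
  if (length(fit_double$degenerate) > 0) return("monophasic")
  # single model already explains essentially all signal variance
  if (fit_single$rss <= 1e-10 * max(fit_single$tss, 1e-300))
    return("monophasic")
  amp_ok <- is.finite(cf[["a1"]]) && abs(cf[["a1"]]) > 0 &&
    abs(cf[["a2"]]) >= min_amp_frac * abs(cf[["a1"]])
  sep_ok <- cf[["kobs1"]] / cf[["kobs2"]] >= min_rate_ratio
  aicc_ok <- (fit_single$aicc - fit_double$aicc) > delta_aicc
  relax_ok <- cf[["kobs2"]] * fit_double$trace_info$t_max >= min_efolds
  if (aicc_ok && sep_ok && amp_ok && relax_ok) "biphasic" else "monophasic"
}
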