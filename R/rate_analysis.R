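#' Secondary plot of binding-phase rates versus substrate concentration
#'
#' Under pseudo-first-order conditions the binding relaxation obeys
#' kobs = k_on * S0 + k_off; a (weighted) linear regression of the fast-phase
#' rates against substrate concentration yields k_on from the slope, k_off
#' from the intercept and KD = k_off/k_on. Weights are 1/SE^2 from the trace
#' fits when standard errors are available, unweighted otherwise.
#'
#' For biphasic enzymes the fast-phase intercept is inflated by the catalytic
#' rate constants; `mode = "total"` instead regresses the sum of the two
#' fitted relaxation rates, which by the trace identity of the linearised
#' scheme equals k_on * S0 + k_off + k2 + k3 exactly. The catalytic
#' contribution to that intercept is then removed downstream by
#' [assemble_mechanism()], which knows k2 and k3 estimates.
#'
#' @param points data.frame with columns `S0` (uM), `kobs` (per s) and
#'   optionally `se`; at least 3 distinct concentrations.
#' @param mode `"fast"` (fast-phase rates, the default) or `"total"` (sum of
#'   both phase rates from double-exponential fits).
#' @return A `secondary_plot` object with `k_on_est`, `k_off_est` (the raw
#'   intercept), `KD_est`, standard errors and R^2.
#' @export
secondary_plot_binding <- function(points, mode = c("fast", "total")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points), all(c("S0", "kobs") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("S0", "kobs")]), ]
  if (length(unique(points$S0)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else NULL
  fit <- stats::lm(kobs ~ S0, data = points, weights = w)
  cf <- stats::coef(fit)
  # vcov warns on numerically exact fits; the SEs are still what we report
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  k_on <- unname(cf["S0"]); icpt <- unname(cf["(Intercept)"])
  if (icpt < -2 * se["(Intercept)"])
    warning("binding plot intercept is negative beyond 2 SE (unphysical)")
  wts <- if (is.null(w)) rep(1, nrow(points)) else w
  tss <- sum(wts * (points$kobs - stats::weighted.mean(points$kobs, wts))^2)
  r2 <- 1 - sum(wts * stats::residuals(fit)^2) / max(tss, 1e-300)
  structure(list(points = points, model = "linear", mode = mode,
                 k_on_est = k_on, k_off_est = icpt,
                 KD_est = icpt / k_on,
                 se = c(k_on = unname(se["S0"]),
                        k_off = unname(se["(Intercept)"])),
                 r_squared = r2),
            class = "secondary_plot")
}

# One-dimensional variable projection for v = vmax * S/(K + S): for fixed K
# the scale vmax is solved exactly, so only K is searched. Deterministic.
hyperbola_varpro <- function(S, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  sw <- sqrt(w)
  sc <- function(K) {
    x <- S / (K + S)
    b <- sum(w * x * y) / sum(w * x^2)
    list(b = b, rss = sum((sw * (y - b * x))^2))
  }
  Ks <- exp(seq(log(max(min(S) * 1e-4, 1e-8)), log(max(S) * 100),
                length.out = 60))
  rss <- vapply(Ks, function(K) sc(K)$rss, numeric(1))
  ib <- which.min(rss)
  lo <- Ks[max(ib - 1, 1)]; hi <- Ks[min(ib + 1, length(Ks))]
  opt <- stats::optimize(function(lK) sc(exp(lK))$rss, c(log(lo), log(hi)),
                         tol = 1e-12)
  K <- exp(opt$minimum)
  res <- sc(K)
  at_bound <- ib %in% c(1L, length(Ks))
  list(K = K, vmax = res$b, rss = res$rss, at_lower = ib == 1L,
       at_upper = ib == length(Ks), at_bound = at_bound)
}

#' Secondary plot of slow-phase rates: hyperbolic fit for k2
#'
#' The slow catalytic relaxation saturates with substrate,
#' kobs2(S0) ~ k_max * S0/(K_half + S0), and its plateau estimates the
#' non-limiting first catalytic rate constant k2. The small additive k3
#' contribution to kobs2 is neglected (k3 << k2 in the scenarios where this
#' plot is informative), a documented bias source.
#'
#' @param points data.frame with columns `S0`, `kobs` and optionally `se`;
#'   slow-phase rates at >= 3 distinct concentrations.
#' @return A `secondary_plot` object with `k_max_est` (-> k2), `K_half_est`,
#'   approximate SEs and R^2; `degenerate = "saturated"` flags
#'   concentration-independent rates (K_half ~ 0), and a warning is issued
#'   when the data do not reach saturation (K_half beyond the data range).
#' @export
secondary_plot_catalytic <- function(points) {
  stopifnot(is.data.frame(points), all(c("S0", "kobs") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("S0", "kobs")]), ]
  if (length(unique(points$S0)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else NULL
  hv <- hyperbola_varpro(points$S0, points$kobs, w)
  degenerate <- character()
  if (hv$at_lower || hv$K < 1e-3 * min(points$S0)) degenerate <- "saturated"
  if (hv$K > max(points$S0))
    warning("slow-phase rates do not saturate over the data range; ",
            "k_max is extrapolated (wide confidence)")
  # Jacobian-based SEs at the optimum
  x <- points$S0 / (hv$K + points$S0)
  J <- cbind(k_max = x, K_half = -hv$vmax * points$S0 / (hv$K + points$S0)^2)
  se <- fit_se(J, hv$rss, nrow(points))
  tss <- sum((points$kobs - mean(points$kobs))^2)
  structure(list(points = points, model = "hyperbolic",
                 k_max_est = hv$vmax, K_half_est = hv$K,
                 se = c(k_max = se[1], K_half = se[2]),
                 r_squared = 1 - hv$rss / max(tss, 1e-300),
                 degenerate = degenerate),
            class = "secondary_plot")
}

#' @export
print.secondary_plot <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("<secondary_plot linear (%s rates)> k_on = %.4g /uM/s, intercept = %.4g /s, KD = %.4g uM, R2 = %.4f\n",
                x$mode, x$k_on_est, x$k_off_est, x$KD_est, x$r_squared))
  else
    cat(sprintf("<secondary_plot hyperbolic> k_max = %.4g /s, K_half = %.4g uM, R2 = %.4f\n",
                x$k_max_est, x$K_half_est, x$r_squared))
  invisible(x)
}

#' Initial turnover rate from a progress trace
#'
#' Linear-regression slope over the opening window (default ~30 s, chosen to
#' minimise depletion effects), converted to uM product per second. For
#' absorbance traces the slope is divided by `-delta_eps_ell`. When the
#' window shows significant curvature (substrate depletion bending the
#' progress line), a quadratic fit is used and its t = 0 slope reported, with
#' a `depletion` flag.
#'
#' @param trace an absorbance or product `kin_trace`.
#' @param window_s analysis window (s), default 30.
#' @param delta_eps_ell conversion factor for absorbance traces (AU/uM).
#' @return A list with `v` (uM/s), `flagged_depletion` (logical) and
#'   `n_points`.
#' @export
initial_rate <- function(trace, window_s = 30, delta_eps_ell = NULL) {
  stopifnot(inherits(trace, "kin_trace"))
  if (!trace$observable %in% c("absorbance", "product"))
    stop("initial_rate expects an absorbance or product trace")
  sel <- trace$times <= window_s
  if (sum(sel) < 5) stop("fewer than 5 points in the rate window")
  t <- trace$times[sel]; y <- trace$values[sel]
  lin <- stats::lm(y ~ t)
  quad <- stats::lm(y ~ t + I(t^2))
  b_lin <- stats::coef(lin)[["t"]]
  b_quad <- stats::coef(quad)[["t"]]
  c_quad <- stats::coef(quad)[["I(t^2)"]]
  # curvature changes the local slope by >20% across the window -> depletion
  curved <- is.finite(c_quad) && abs(b_quad) > 0 &&
    abs(2 * c_quad * diff(range(t))) > 0.2 * abs(b_quad)
  slope <- if (curved) b_quad else b_lin
  v <- if (trace$observable == "absorbance") {
    if (is.null(delta_eps_ell))
      stop("delta_eps_ell is required to convert an absorbance slope")
    -slope / delta_eps_ell
  } else slope
  list(v = v, flagged_depletion = curved, n_points = sum(sel))
}

#' Michaelis-Menten fit of initial rates
#'
#' Nonlinear least-squares fit of v = Vmax * S0/(Km + S0) to initial rates
#' across a substrate grid; kcat = Vmax/E0.
#'
#' @param rates data.frame with columns `S0` (uM) and `v` (uM/s); at least 4
#'   distinct concentrations.
#' @param E0 enzyme concentration (uM) used in the assay.
#' @return An `mm_fit` object with `Vmax`, `Km`, `kcat`, SEs and R^2. A
#'   warning is issued when the fitted Km lies outside the substrate range.
#' @export
fit_michaelis_menten <- function(rates, E0) {
  stopifnot(is.data.frame(rates), all(c("S0", "v") %in% names(rates)), E0 > 0)
  rates <- rates[stats::complete.cases(rates[, c("S0", "v")]), ]
  if (length(unique(rates$S0)) < 4)
    stop("need at least 4 distinct substrate concentrations")
  start <- list(Vmax = max(rates$v),
                Km = max(min(rates$S0), stats::median(rates$S0) / 2))
  fit <- minpack.lm::nlsLM(v ~ Vmax * S0 / (Km + S0), data = rates,
                           start = start,
                           lower = c(Vmax = 0, Km = 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  if (cf[["Km"]] > max(rates$S0) || cf[["Km"]] < min(rates$S0) / 10)
    warning("fitted Km lies outside the substrate range; poorly constrained")
  tss <- sum((rates$v - mean(rates$v))^2)
  rss <- sum(stats::residuals(fit)^2)
  structure(list(Vmax = unname(cf[["Vmax"]]), Km = unname(cf[["Km"]]),
                 kcat = unname(cf[["Vmax"]]) / E0, E0 = E0,
                 se = c(Vmax = unname(se[["Vmax"]]), Km = unname(se[["Km"]])),
                 r_squared = 1 - rss / max(tss, 1e-300), n = nrow(rates)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g uM/s, Km = %.4g uM, kcat = %.4g /s (E0 = %g uM), R2 = %.4f\n",
              x$Vmax, x$Km, x$kcat, x$E0, x$r_squared))
  invisible(x)
}

#' Burst fit of a product time course
#'
#' Fits P(t) = A * (1 - exp(-lambda * t)) + v_ss * t: an exponential burst of
#' amplitude A (the t = 0 extrapolation of the late linear steady state)
#' followed by linear turnover. The burst rate lambda is profiled on a
#' deterministic grid (variable projection). When the sampled points cannot
#' resolve the burst exponential (lambda at the search bound, i.e. the burst
#' is complete before the first point), the fit falls back to a linear
#' regression of the late points whose intercept is the burst amplitude -
#' the classic extrapolation. A non-positive fitted amplitude is reported as
#' a no-burst outcome (A = 0, pure linear).
#'
#' @param trace a product `kin_trace` spanning burst and steady-state
#'   regimes.
#' @param E0 enzyme concentration (uM), for the amplitude ratio A/E0.
#' @return A `burst_fit` with `amplitude` (uM), `burst_rate` (per s; NA when
#'   extrapolated), `v_ss` (uM/s), `amplitude_ratio` = A/E0 and `method`.
#' @export
fit_burst <- function(trace, E0) {
  stopifnot(inherits(trace, "kin_trace"), E0 > 0)
  if (trace$observable != "product")
    stop("fit_burst expects a product trace")
  t <- trace$times; y <- trace$values
  if (length(t) < 6) stop("too few points for a burst fit")
  lam_grid <- exp(seq(log(0.1 / max(t)), log(10 / min(t[t > 0])),
                      length.out = 50))
  sc <- function(lam) {
    X <- cbind(1 - exp(-lam * t), t)
    vp <- varpro_rss(X, y)
    vp$rss
  }
  rss <- vapply(lam_grid, sc, numeric(1))
  ib <- which.min(rss)
  lo <- lam_grid[max(ib - 1, 1)]; hi <- lam_grid[min(ib + 1, length(lam_grid))]
  opt <- stats::optimize(function(ll) sc(exp(ll)), c(log(lo), log(hi)),
                         tol = 1e-12)
  lam <- exp(opt$minimum)
  vp <- varpro_rss(cbind(1 - exp(-lam * t), t), y)
  A <- vp$coef[1]; vss <- vp$coef[2]
  method <- "exponential_burst"
  if (ib == length(lam_grid) || lam * min(t[t > 0]) > 5) {
    # burst complete before the first sample: extrapolate the linear regime
    late <- t >= stats::median(t)
    lf <- stats::lm(y[late] ~ t[late])
    A <- stats::coef(lf)[[1]]
    vss <- stats::coef(lf)[[2]]
    lam <- NA_real_
    method <- "linear_extrapolation"
  }
  if (!is.finite(A) || A <= 0) {
    lf <- stats::lm(y ~ t)
    return(structure(list(amplitude = 0, burst_rate = NA_real_,
                          v_ss = max(stats::coef(lf)[[2]], 0),
                          amplitude_ratio = 0, E0 = E0, method = "no_burst"),
                     class = "burst_fit"))
  }
  structure(list(amplitude = unname(A), burst_rate = lam,
                 v_ss = max(unname(vss), 0),
                 amplitude_ratio = unname(A) / E0, E0 = E0, method = method),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("<burst_fit (%s)> A = %.4g uM (A/E0 = %.3f), lambda = %.4g /s, v_ss = %.4g uM/s\n",
              x$method, x$amplitude, x$amplitude_ratio, x$burst_rate, x$v_ss))
  invisible(x)
}

#' Assemble a mechanism estimate from the staged analyses
#'
#' Combines the binding secondary plot, the catalytic secondary plot (if
#' biphasic), the Michaelis-Menten fit and/or the burst fit into estimates of
#' KD, k_on, k_off, k2 and k3, and calls the rate-limiting catalytic step:
#' \itemize{
#'   \item kcat comes from the burst fit steady-state velocity when a
#'     substantial burst is present (A/E0 >= 0.1; the progress-curve route,
#'     immune to the burst inflating the opening-window rate), otherwise from
#'     the Michaelis-Menten fit.
#'   \item biphasic: the saturating plateau of the catalytic secondary plot
#'     estimates the limiting slow relaxation rate lambda = k2 + k3; with
#'     kcat = k2 k3/(k2 + k3) known, k2 and k3 are the two roots of
#'     x^2 - lambda x + kcat lambda = 0 (k2 the larger); the second step is
#'     rate-limiting. When k3 << k2 this reduces to k2 ~ lambda and the
#'     kcat-inversion k3 = kcat k2/(k2 - kcat).
#'   \item monophasic with retained activity: the first step is rate-limiting
#'     and k2 ~ kcat; k3 is not identifiable (reported NA).
#'   \item no measurable activity: binding-only estimate with k2 = 0.
#' }
#' k_off is recovered from the binding-plot intercept after removing the
#' catalytic contribution to the observed relaxation rates: for `"total"`
#' mode plots the intercept is k_off + k2 + k3, for monophasic single-phase
#' plots it is k_off + k2.
#'
#' @param binding a linear `secondary_plot`.
#' @param catalytic a hyperbolic `secondary_plot`, or NULL.
#' @param mm an `mm_fit`, or NULL.
#' @param burst a `burst_fit`, or NULL.
#' @param phases `"monophasic"` or `"biphasic"` (from [classify_phases()]).
#' @param activity_threshold kcat (per s) below which the enzyme is called
#'   inactive.
#' @param consistency_tol relative tolerance for the requirement kcat <= k2;
#'   a kcat exceeding the catalytic-plot k2 by more than this is an error.
#' @return A `mechanism_estimate` with fields `KD_est`, `k_on_est`,
#'   `k_off_est`, `k_cleave_est`, `k_hydrolyse_est`, `kcat_est`,
#'   `rate_limiting` (`"first_step"`, `"second_step"` or `"inactive"`) and
#'   per-estimate `provenance` notes.
#' @export
assemble_mechanism <- function(binding, catalytic = NULL, mm = NULL,
                               burst = NULL, phases,
                               activity_threshold = 1e-4,
                               consistency_tol = 0.2) {
  stopifnot(inherits(binding, "secondary_plot"))
  phases <- match.arg(phases, c("monophasic", "biphasic"))
  prov <- list(k_on = "slope of binding secondary plot")
  k_on <- binding$k_on_est
  icpt <- binding$k_off_est
  kcat <- NA_real_
  if (!is.null(burst) && burst$amplitude_ratio >= 0.1 && burst$v_ss > 0) {
    kcat <- burst$v_ss / burst$E0
    prov$kcat <- "steady-state velocity of burst fit"
  } else if (!is.null(mm)) {
    kcat <- mm$kcat
    prov$kcat <- "Vmax/E0 from Michaelis-Menten fit"
  }
  active <- is.finite(kcat) && kcat > activity_threshold
  if (!active) {
    k2 <- 0; k3 <- NA_real_; kcat <- 0
    rate_limiting <- "inactive"
    koff <- icpt
    prov$k_cleave <- "no measurable turnover (inactive enzyme)"
    prov$k_off <- "intercept of binding secondary plot"
  } else if (phases == "biphasic") {
    if (is.null(catalytic))
      stop("biphasic classification requires a catalytic secondary plot")
    lambda <- catalytic$k_max_est
    # kcat = k2 k3/(k2+k3) caps at lambda/4 (k2 = k3 = lambda/2)
    if (kcat > (lambda / 4) * (1 + consistency_tol))
      stop(sprintf(
        "inconsistent estimates: kcat (%.3g/s) exceeds lambda/4 (%.3g/s)",
        kcat, lambda / 4))
    disc <- lambda^2 - 4 * kcat * lambda
    if (disc <= 0) {
      k2 <- k3 <- lambda / 2
      prov$k_cleave <- prov$k_hydrolyse <-
        "catalytic steps indistinguishable (kcat ~ lambda/4)"
    } else {
      k2 <- (lambda + sqrt(disc)) / 2
      k3 <- lambda - k2
      prov$k_cleave <-
        "larger root of x^2 - lambda x + kcat lambda (slow-phase plateau)"
      prov$k_hydrolyse <- "smaller root (equivalent to kcat inversion)"
    }
    koff <- if (binding$mode == "total") icpt - lambda else icpt - k2
    prov$k_off <- sprintf(
      "binding intercept minus catalytic relaxation contribution (%s-rate plot)",
      binding$mode)
    rate_limiting <- "second_step"
  } else {
    k2 <- kcat; k3 <- NA_real_
    prov$k_cleave <- "kcat (first step rate-limiting, monophasic signature)"
    prov$k_hydrolyse <- "not identifiable when the first step limits"
    koff <- icpt - k2
    prov$k_off <- "single-phase intercept minus kcat"
    rate_limiting <- "first_step"
  }
  koff <- max(koff, 0)
  est <- structure(list(KD_est = koff / k_on, k_on_est = k_on,
                        k_off_est = koff, k_cleave_est = k2,
                        k_hydrolyse_est = k3, kcat_est = kcat,
                        rate_limiting = rate_limiting,
                        burst_amplitude_ratio = if (!is.null(burst))
                          burst$amplitude_ratio else NA_real_,
                        Km_est = if (!is.null(mm)) mm$Km else NA_real_,
                        provenance = prov),
                   class = "mechanism_estimate")
  # invariant: second step limiting iff k3 < k2 (when both are estimated)
  if (!is.na(k3)) {
    if (rate_limiting == "second_step" && k3 > k2)
      stop("internal inconsistency in rate-limiting call")
    if (rate_limiting == "first_step" && k3 < k2)
      stop("internal inconsistency in rate-limiting call")
  }
  est
}

#' @export
print.mechanism_estimate <- function(x, ...) {
  cat("<mechanism_estimate>\n")
  cat(sprintf("  KD = %.4g uM (k_on = %.4g /uM/s, k_off = %.4g /s)\n",
              x$KD_est, x$k_on_est, x$k_off_est))
  cat(sprintf("  k2 (cleavage)   = %.4g /s\n  k3 (hydrolysis) = %.4g /s\n",
              x$k_cleave_est, x$k_hydrolyse_est))
  cat(sprintf("  kcat = %.4g /s; rate-limiting: %s\n", x$kcat_est,
              x$rate_limiting))
  invisible(x)
}
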