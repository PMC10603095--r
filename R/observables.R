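#' Tryptophan-fluorescence observation model
#'
#' The intrinsic fluorescence of an active-site-adjacent tryptophan reports on
#' the enzyme's ligation state: binding quenches the signal and formation of
#' the covalent intermediate partially restores it. The observed signal is a
#' linear combination of the enzyme species,
#' F(t) = (f_E*E + f_ES*ES + f_EI*EI + background) * exp(-bleach_rate * t),
#' with a multiplicative exponential photobleaching term. The defaults
#' (f_ES < f_EI < f_E) reproduce the biphasic quench-then-partial-recovery
#' signature of the wild-type enzyme; absolute magnitudes are arbitrary
#' instrument units.
#'
#' @param f_E,f_ES,f_EI fluorescence yields (signal per uM) of free enzyme,
#'   Michaelis complex and glycosyl-enzyme intermediate; all >= 0.
#' @param background constant signal offset.
#' @param bleach_rate photobleaching rate (per s); on a 2 s timescale the
#'   default loses ~0.4% of signal, near-linear, matching a small linear
#'   correction term; over 50 s it is a ~10% exponential decay.
#' @return An object of class `fluorescence_model`.
#' @export
fluorescence_model <- function(f_E = 1.0, f_ES = 0.6, f_EI = 0.85,
                               background = 0, bleach_rate = 0.002) {
  if (any(c(f_E, f_ES, f_EI) < 0)) stop("fluorescence yields must be >= 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(list(f_E = f_E, f_ES = f_ES, f_EI = f_EI,
                 background = background, bleach_rate = bleach_rate),
            class = "fluorescence_model")
}

#' Construct a kinetic trace
#'
#' A trace is one observable time series (fluorescence, absorbance or discrete
#' product amounts) with its assay metadata.
#'
#' @param observable one of `"fluorescence"`, `"absorbance"`, `"product"`.
#' @param times sampling times (s), strictly increasing.
#' @param values signal values, same length as `times`.
#' @param condition the [assay_condition()] under which the trace was
#'   acquired (may be `NULL` for bare traces).
#' @param scenario_id label of the enzyme scenario.
#' @param replicate replicate index.
#' @param is_control logical; `TRUE` marks a no-substrate photobleaching
#'   control (then S0 must be 0).
#' @param timescale optional label (e.g. `"short"`, `"long"`).
#' @param corrected logical; `TRUE` once photobleaching-corrected.
#' @return An object of class `kin_trace`.
#' @export
kin_trace <- function(observable, times, values, condition = NULL,
                      scenario_id = "", replicate = 1L, is_control = FALSE,
                      timescale = "", corrected = FALSE) {
  observable <- match.arg(observable, c("fluorescence", "absorbance", "product"))
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is_control && !is.null(condition) && condition$S0 != 0)
    stop("a control trace must have S0 = 0")
  structure(list(observable = observable, times = as.numeric(times),
                 values = as.numeric(values), condition = condition,
                 scenario_id = scenario_id, replicate = as.integer(replicate),
                 is_control = isTRUE(is_control), timescale = timescale,
                 corrected = isTRUE(corrected)),
            class = "kin_trace")
}

#' @export
print.kin_trace <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("<kin_trace> %s%s, %d points over %g s",
              x$observable, if (x$is_control) " (control)" else "",
              length(x$times), max(x$times)))
  if (!is.null(cond))
    cat(sprintf(", E0 = %g uM, S0 = %g uM", cond$E0, cond$S0))
  if (nzchar(x$scenario_id))
    cat(sprintf(", scenario %s rep %d", x$scenario_id, x$replicate))
  cat("\n")
  invisible(x)
}

#' Fluorescence trace from a trajectory
#'
#' Applies the linear species-to-signal map of a [fluorescence_model()] with
#' its multiplicative photobleaching term. Noiseless; add measurement noise
#' with [add_noise()].
#'
#' @param traj a `kin_trajectory`.
#' @param fm a [fluorescence_model()].
#' @param ... metadata passed to [kin_trace()] (scenario_id, replicate, ...).
#' @return A `kin_trace` with observable `"fluorescence"`.
#' @export
fluorescence_from_trajectory <- function(traj, fm = fluorescence_model(), ...) {
  stopifnot(inherits(traj, "kin_trajectory"), inherits(fm, "fluorescence_model"))
  sig <- (fm$f_E * traj$E + fm$f_ES * traj$ES + fm$f_EI * traj$EI +
            fm$background) * exp(-fm$bleach_rate * traj$t)
  kin_trace("fluorescence", traj$t, sig, condition = attr(traj, "condition"), ...)
}

#' Absorbance trace from a trajectory
#'
#' Liberation of the nucleobase shifts the substrate's UV absorbance; turnover
#' is followed as a decrease at 275 nm, A(t) = A0 - delta_eps_ell * P1(t).
#' The effective extinction change per uM of released base (times path
#' length), `delta_eps_ell`, is a free configuration parameter; it is not a
#' published constant.
#'
#' @param traj a `kin_trajectory`.
#' @param delta_eps_ell absorbance change per uM product (AU/uM), > 0.
#' @param A0 starting absorbance; default `2 * delta_eps_ell * S0`
#'   (proportional to substrate, and large enough that the full turnover drop
#'   `delta_eps_ell * S0` keeps A positive).
#' @param ... metadata passed to [kin_trace()].
#' @return A `kin_trace` with observable `"absorbance"`.
#' @export
absorbance_from_trajectory <- function(traj, delta_eps_ell = 0.01, A0 = NULL,
                                       ...) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (delta_eps_ell <= 0) stop("delta_eps_ell must be > 0")
  cond <- attr(traj, "condition")
  if (is.null(A0)) A0 <- 2 * delta_eps_ell * cond$S0
  kin_trace("absorbance", traj$t, A0 - delta_eps_ell * traj$P1,
            condition = cond, ...)
}

#' Discrete product time course from a trajectory
#'
#' Samples released base P1 at the requested times, emulating sparse
#' quench-and-measure (HPLC-like) product quantification.
#'
#' @param traj a `kin_trajectory`.
#' @param times sampling times (s); must lie within the trajectory span.
#'   Values between grid points are linearly interpolated.
#' @param ... metadata passed to [kin_trace()].
#' @return A `kin_trace` with observable `"product"` (uM of released base).
#' @export
sample_product_timecourse <- function(traj, times, ...) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (any(times < min(traj$t)) || any(times > max(traj$t)))
    stop("requested times fall outside the trajectory span")
  vals <- stats::approx(traj$t, traj$P1, xout = times)$y
  kin_trace("product", times, vals, condition = attr(traj, "condition"), ...)
}

#' Add Gaussian measurement noise to a trace
#'
#' Adds independent, homoscedastic Gaussian noise, reproducibly under `seed`.
#' The calling RNG state is left untouched.
#'
#' @param trace a `kin_trace`.
#' @param sigma noise standard deviation (signal units), >= 0; 0 returns the
#'   trace unchanged.
#' @param seed integer seed.
#' @return The noisy `kin_trace`.
#' @export
add_noise <- function(trace, sigma, seed) {
  stopifnot(inherits(trace, "kin_trace"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(trace)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  trace$values <- trace$values +
    stats::rnorm(length(trace$values), mean = 0, sd = sigma)
  trace
}

#' Default noise level for a set of clean traces
#'
#' One sigma per dataset: a fraction (default 1%) of the largest dynamic
#' range among the clean traces, mimicking a fixed instrument noise floor.
#'
#' @param traces a list of clean `kin_trace` objects.
#' @param frac fraction of the maximum dynamic range.
#' @return sigma in signal units.
#' @export
default_noise_sigma <- function(traces, frac = 0.01) {
  rng <- vapply(traces, function(tr) diff(range(tr$values)), numeric(1))
  frac * max(rng)
}
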