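#' Rate constants of the two-step covalent-intermediate mechanism
#'
#' DNPH1-type retaining N-glycosidases hydrolyse their nucleotide substrate
#' through reversible binding followed by two irreversible chemical steps:
#'
#' \deqn{E + S \rightleftharpoons ES \rightarrow EI + P_1 \rightarrow E + P_2}
#'
#' Binding of enzyme (E) and substrate (S) forms the Michaelis complex (ES)
#' with association rate constant k1 and dissociation rate constant k-1.
#' Glycosidic-bond cleavage (k2) releases the nucleobase (P1, hmU) and leaves
#' a covalent glycosyl-enzyme intermediate (EI); hydrolysis of the glycosyl
#' ester (k3) releases the sugar phosphate (P2, dRP) and resets the enzyme.
#' Release of the cleaved base is not modelled as a separate step, and product
#' release after ester cleavage is lumped into k3.
#'
#' Units are fixed internally to micromolar and seconds; convert nanomolar
#' inputs at the boundary (see [nM_to_uM()]).
#'
#' @param k_on association rate constant k1 (per uM per s); must be > 0.
#' @param k_off dissociation rate constant k-1 (per s).
#' @param k_cleave first catalytic rate constant k2 (per s), base cleavage and
#'   EI formation. Zero is permitted and encodes a chemically inactive enzyme
#'   (an E104Q-type mutant that binds substrate but cannot cleave it).
#' @param k_hydrolyse second catalytic rate constant k3 (per s), hydrolysis of
#'   the glycosyl-ester linkage.
#' @return An object of class `rate_constants` (a named list of the four
#'   parameters).
#' @examples
#' wt <- rate_constants(k_on = 1, k_off = 5, k_cleave = 8, k_hydrolyse = 1)
#' equilibrium_affinity(wt)      # KD = 5 uM
#' steady_state_parameters(wt)   # kcat = 8/9 /s, Km = 13/9 uM
#' @export
rate_constants <- function(k_on, k_off, k_cleave, k_hydrolyse) {
  vals <- c(k_on = k_on, k_off = k_off, k_cleave = k_cleave,
            k_hydrolyse = k_hydrolyse)
  if (!is.numeric(vals) || length(vals) != 4L || anyNA(vals))
    stop("all four rate constants must be single finite numbers")
  if (any(vals < 0))
    stop("rate constants must be non-negative")
  if (k_on <= 0)
    stop("k_on must be strictly positive")
  structure(as.list(vals), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Two-step mechanism rate constants (uM, s):\n")
  cat(sprintf("  k_on  (k1)  = %g /uM/s\n  k_off (k-1) = %g /s\n", x$k_on, x$k_off))
  cat(sprintf("  k_cleave   (k2) = %g /s\n  k_hydrolyse (k3) = %g /s\n",
              x$k_cleave, x$k_hydrolyse))
  invisible(x)
}

#' Equilibrium dissociation constant of the Michaelis complex
#'
#' The ratio k-1 : k1 sets the affinity of enzyme for substrate,
#' KD = k_off / k_on (uM).
#'
#' @param rc a [rate_constants()] object.
#' @return KD in uM.
#' @export
equilibrium_affinity <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_on == 0) stop("undefined affinity: k_on is zero")
  rc$k_off / rc$k_on
}

#' Steady-state Michaelis-Menten parameters of the two-step scheme
#'
#' The standard steady-state treatment of the scheme gives
#' \deqn{k_{cat} = \frac{k_2 k_3}{k_2 + k_3}, \qquad
#'       K_m = \frac{k_3}{k_2 + k_3}\cdot\frac{k_{-1} + k_2}{k_1}.}
#' In the limit k3 -> Inf these reduce to the Briggs-Haldane forms
#' kcat -> k2, Km -> (k_off + k_cleave)/k_on.
#'
#' @param rc a [rate_constants()] object with k_cleave + k_hydrolyse > 0.
#' @return A list with elements `kcat` (per s) and `Km` (uM).
#' @export
steady_state_parameters <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  k2 <- rc$k_cleave; k3 <- rc$k_hydrolyse
  if (k2 + k3 <= 0) stop("no turnover: both catalytic rate constants are zero")
  kcat <- k2 * k3 / (k2 + k3)
  Km <- (k3 / (k2 + k3)) * (rc$k_off + k2) / rc$k_on
  list(kcat = kcat, Km = Km)
}

#' Pseudo-first-order observed binding rate constant
#'
#' Under substrate excess (S0 >> E0) the binding relaxation of the scheme is
#' mono-exponential with observed rate kobs = k_on * S0 + k_off. This is the
#' analytic oracle for the fast stopped-flow phase; when E0 is supplied and
#' S0 < 10 * E0 the pseudo-first-order approximation is flagged with a
#' warning (the approximation degrades, it does not fail outright).
#'
#' @param rc a [rate_constants()] object.
#' @param S0 substrate concentration (uM).
#' @param E0 optional enzyme concentration (uM) used only to check the
#'   pseudo-first-order condition.
#' @return kobs in per s.
#' @export
analytic_binding_kobs <- function(rc, S0, E0 = NULL) {
  stopifnot(inherits(rc, "rate_constants"), is.numeric(S0), all(S0 >= 0))
  if (!is.null(E0) && any(S0 < 10 * E0))
    warning("S0 < 10 * E0: pseudo-first-order kobs is approximate")
  rc$k_on * S0 + rc$k_off
}

#' Analytic burst-kinetics parameters at saturating substrate
#'
#' When the second catalytic step is slower than the first, product P1
#' accumulates in a rapid stoichiometric burst before settling into the
#' steady state. Under saturation (S0 >> Km, negligible depletion over the
#' burst) the classic algebra gives
#' amplitude A = E0 * (k2/(k2 + k3))^2, burst rate lambda = k2 + k3, and
#' steady-state velocity v_ss = kcat * E0. With k2/k3 large the amplitude
#' approaches E0, i.e. the burst titrates the active-enzyme concentration.
#'
#' @param rc a [rate_constants()] object.
#' @param E0 total enzyme (uM).
#' @return A list with `amplitude` (uM), `burst_rate` (per s) and `v_ss`
#'   (uM/s).
#' @export
analytic_burst_parameters <- function(rc, E0) {
  stopifnot(inherits(rc, "rate_constants"), E0 > 0)
  k2 <- rc$k_cleave; k3 <- rc$k_hydrolyse
  if (k2 + k3 <= 0) stop("no turnover: both catalytic rate constants are zero")
  list(amplitude = E0 * (k2 / (k2 + k3))^2,
       burst_rate = k2 + k3,
       v_ss = steady_state_parameters(rc)$kcat * E0)
}

#' Convert nanomolar to micromolar
#'
#' All package internals work in uM and seconds; use this at the input
#' boundary for conditions quoted in nM (e.g. 100 nM enzyme).
#'
#' @param x concentration in nM.
#' @return concentration in uM.
#' @export
nM_to_uM <- function(x) x / 1000
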