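---
title: "Inferring two-step hydrolysis kinetics from transient and steady-state data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring two-step hydrolysis kinetics from transient and steady-state data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnph1kin)
```

## The mechanism

Retaining N-glycosidases of the DNPH1 family hydrolyse their nucleotide
substrate through a double-displacement mechanism. After reversible binding,
the nucleobase is cleaved off and a covalent glycosyl-enzyme intermediate
forms; a second hydrolytic step then releases the sugar phosphate and resets
the enzyme:

$$E + S \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} ES
  \overset{k_2}{\longrightarrow} EI + P_1
  \overset{k_3}{\longrightarrow} E + P_2$$

The package works with exactly this four-parameter scheme. Its assumptions,
all standard for this enzyme family, are:

* both chemical steps are irreversible;
* release of the cleaved base ($P_1$, the modified uracil) is not a separate
  kinetic step;
* product release after ester cleavage is faster than the cleavage itself
  and is lumped into $k_3$.

From the scheme follow the closed forms used as test oracles throughout:
$K_D = k_{-1}/k_1$;
$k_{cat} = k_2 k_3/(k_2+k_3)$ and
$K_m = \frac{k_3}{k_2+k_3}\cdot\frac{k_{-1}+k_2}{k_1}$
(standard steady-state treatment);
the pseudo-first-order binding relaxation $k_{obs} = k_1 S_0 + k_{-1}$; and
the burst algebra at saturation — amplitude $E_0\,(k_2/(k_2+k_3))^2$, burst
rate $k_2+k_3$, steady velocity $k_{cat} E_0$.

Units are fixed internally to µM and seconds. Inputs quoted in nM are
converted at the boundary (`nM_to_uM()`).

## Simulation

`simulate_mechanism()` integrates the mass-action equations with a
stiff-capable solver (`deSolve::lsoda`) at relative tolerance $10^{-8}$ and
absolute tolerance $10^{-10}$ µM. The tolerances are deliberately tight:
binding relaxes at $10$–$200\,\mathrm{s^{-1}}$ while the slow mutants
hydrolyse the intermediate at $10^{-2}\,\mathrm{s^{-1}}$, so both timescales
must be resolved in one trajectory. Sub-tolerance negative concentrations
from round-off are clamped to zero; anything worse raises an error. Every
trajectory is checked against three conservation laws (enzyme, base, sugar)
to $10^{-6}$ relative error in the test suite.

```{r sim-example}
wt <- rate_constants(k_on = 1, k_off = 5, k_cleave = 8, k_hydrolyse = 1)
traj <- simulate_mechanism(wt, assay_condition(E0 = 2, S0 = 50,
                                               duration = 2,
                                               sample_interval = 1e-3))
conservation_error(traj)
```

## What the synthetic data emulate — and what they do not

The generators reproduce the three assay families used to characterise this
enzyme system, with the designs the original experiments used:

* **Stopped-flow tryptophan fluorescence** (`generate_stopped_flow_dataset()`):
  2 µM enzyme, substrate in pseudo-first-order excess, short (2 s) and long
  (50 s) timescales, three technical replicates per condition, plus one
  no-substrate photobleaching control per timescale. Sampling is 1 kHz
  (short) and 100 Hz (long), resolving a $55\,\mathrm{s^{-1}}$ binding
  transient with well over 10 points per e-fold. The signal model is linear
  in the enzyme species with yields $f_{ES} < f_{EI} < f_E$
  (binding quenches, the intermediate partially recovers; defaults 0.6,
  0.85, 1.0 in arbitrary units) times a multiplicative photobleaching
  exponential (default $0.002\,\mathrm{s^{-1}}$ — about 0.4 % signal loss
  over 2 s, i.e. near-linear, and ~10 % over 50 s).
* **Continuous UV turnover assays** (`generate_turnover_dataset()`):
  absorbance decreasing in proportion to released base, 1–200 µM substrate,
  1 s sampling for 300 s, triplicate. The extinction change per µM product
  (`delta_eps_ell`, default 0.01 AU/µM) is a free configuration parameter;
  no published value exists for it, and it cancels out of every kinetic
  conclusion.
* **Discrete product time courses** (`generate_burst_dataset()`): sparse
  HPLC-like sampling of released base at saturating substrate, dense in the
  first seconds to resolve the burst.

Noise is additive, Gaussian and homoscedastic — one sigma per dataset,
defaulting to 1 % of the largest clean dynamic range, mimicking a fixed
instrument noise floor. Seeds propagate deterministically, so every dataset
is bit-for-bit reproducible.

Real instruments add features this model omits deliberately: dead time,
inner-filter effects, heteroscedastic shot noise, drift that is not a clean
exponential, pipetting error across replicates, and day-to-day enzyme
activity variation. Passing the recovery tests therefore demonstrates that
the *inference chain is correct and unbiased under its own assumptions*, not
that it is robust to every artefact of real stopped-flow data.

## Scenario presets

The wild-type and mutant scenarios encode relative kinetic structure, not
absolute rates: the slow hydrolytic step is fixed at $k_3 = 1\,
\mathrm{s^{-1}}$ as the unit scale and the established fold changes are
applied to it — $k_2/k_3 = 8$ for the wild type, a 120-fold reduction of
$k_2$ for H56A, a 150-fold reduction of $k_3$ (and 6-fold of $k_2$) for the
E55 mutants, $k_2 = 0$ for the dead E104Q enzyme, and a uniform 2-fold
affinity loss for every mutant. The affinity change is applied through
$k_{-1}$ with $k_1$ held at $1\,\mathrm{µM^{-1}s^{-1}}$, since nothing in
the underlying measurements decomposes a 2-fold $K_D$ shift between on- and
off-rates. Wild-type binding uses $K_D = 5$ µM, a mid-range value for a
nucleotide-monophosphate enzyme of this class.

```{r presets}
sapply(scenario_presets(), function(s) unlist(s$rc))
```

## The fitting chain and its numerical choices

The analysis deliberately mirrors the staged, phenomenological procedure a
kineticist would apply, rather than a global ODE fit:

1. **Replicate averaging, control subtraction** — replicates are averaged
   pointwise; 50 s traces are corrected by subtracting the no-substrate
   control (interpolated if grids differ). On the 2 s timescale the residual
   bleaching is near-linear and is absorbed by the linear term of the
   single-exponential model instead.
2. **Exponential fits** — `fit_single_exp_linear()` fits
   $a e^{-k_{obs}t} + mt + c$ and `fit_double_exp()` fits
   $a_1 e^{-k_{obs,1}t} + a_2 e^{-k_{obs,2}t} + c$ (opposite-sign amplitudes
   allowed: quench then recovery). Both use variable projection: the decay
   rates are profiled on a deterministic log-spaced grid spanning
   [0.5/duration, 1/(2·interval)] with the linear parameters solved exactly
   at each candidate, then refined by local optimisation. This makes every
   fit deterministic — no random restarts — and immune to poor starting
   guesses. Standard errors come from the Jacobian-based covariance at the
   optimum. A fit whose amplitude is below 0.1 % of the signal spread is
   flagged degenerate rather than reporting a spurious rate.
3. **Phase classification** — `classify_phases()` calls a trace biphasic
   only if the double-exponential model wins by more than 10 AICc units,
   the rates are separated at least 3-fold, the slow amplitude is at least
   5 % of the fast one, *and* the slow phase completes at least one e-fold
   within the observation window. The last rule exists because the
   multiplicative bleach model makes even a binding-only trace formally
   double-exponential with a second rate equal to the bleach rate; a
   "phase" slower than the window is indistinguishable from drift.
   The original classification was by inspection; these thresholds
   operationalise it and are recorded in the run log.
4. **Slow phases and the long timescale** — when the slow relaxation
   completes fewer than ~3 e-folds on the short trace, or is invisible there
   entirely (both steps slowed, as in the E55A/H56A double mutant), the slow
   phase is re-fitted from the bleach-corrected 50 s trace after discarding
   the fast binding transient ($t > 5/k_{obs,1}$). This is the long-timescale
   estimation route used experimentally for slow second phases.
5. **Secondary plots** — the fast-phase rates regress linearly on substrate.
   For a biphasic enzyme the fast-phase intercept is *not* $k_{-1}$: the
   linearised two-variable system has eigenvalue sum
   $k_{obs,1}+k_{obs,2} = k_1 S_0 + k_{-1} + k_2 + k_3$ exactly, so the
   pipeline regresses the sum of the two fitted rates (`mode = "total"`) and
   removes the catalytic contribution downstream. The slow-phase rates
   follow a saturating hyperbola whose plateau estimates the limiting slow
   relaxation $\lambda = k_2 + k_3$; the hyperbolic fit is again a
   one-dimensional variable projection. The additive low-concentration
   offset ($k_3$ at $S_0 = 0$) is neglected by the through-origin hyperbola,
   a documented bias source of a few per cent.
6. **Steady-state turnover** — initial rates are linear-regression slopes
   over the first 30 s; when the progress line bends by more than 20 %
   across the window (depletion at low substrate), a quadratic is fitted and
   its $t = 0$ slope used, with a depletion flag. Rates below
   $10^{-4}\,\mathrm{s^{-1}}\times E_0$ mark the enzyme inactive and skip
   the Michaelis–Menten fit.
7. **Burst route for $k_{cat}$** — for enzymes with a substantial burst
   ($A/E_0 \ge 0.1$) the opening-window rate of a turnover trace is inflated
   by the burst itself, so $k_{cat}$ is taken from the steady-state velocity
   of the burst fit ($v_{ss}/E_0$) instead of the Michaelis–Menten $V_{max}$.
   `fit_burst()` profiles the burst rate deterministically and falls back to
   the classic late-linear extrapolation when the burst is complete before
   the first sample; a non-positive amplitude is reported as a no-burst
   outcome.
8. **Assembly** — `assemble_mechanism()` combines the pieces. For a biphasic
   enzyme, $k_2$ and $k_3$ are the roots of
   $x^2 - \lambda x + k_{cat}\lambda = 0$ (from $\lambda = k_2+k_3$ and
   $k_{cat} = k_2k_3/\lambda$), which degrades gracefully to the familiar
   $k_2 \approx \lambda$, $k_3 = k_{cat}k_2/(k_2-k_{cat})$ when
   $k_3 \ll k_2$. A $k_{cat}$ exceeding $\lambda/4$ (the algebraic maximum)
   by more than 20 % raises a consistency error. $k_{-1}$ is the binding
   intercept minus the catalytic contribution ($\lambda$ for total-rate
   plots; $k_{cat}$ for monophasic enzymes, whose single-phase intercept is
   $k_{-1}+k_2$). The rate-limiting call follows the phase logic: biphasic
   means the intermediate accumulates, so the second step limits; a
   monophasic signature with retained activity means the first step limits
   and $k_3$ is not identifiable; no measurable activity yields a
   binding-only estimate.

```{r chain-example}
sc <- scenario_presets()$WT
sf <- generate_stopped_flow_dataset(sc, seed = 1)
to <- generate_turnover_dataset(sc, E0 = 0.1, seed = 2)
bu <- generate_burst_dataset(sc, seed = 3)
ana <- suppressWarnings(analyse_scenario(sf, to, bu, turnover_E0 = 0.1))
ana$estimate
```

## Degenerate inputs and tie-breaks

Concentration-independent slow rates collapse the hyperbola to
$K_{1/2}\to 0$ and are flagged `saturated`; slow rates that never saturate
trigger a wide-confidence warning. Rates closer than 1.5-fold in the double
exponential are flagged `rate_collapse` and force a monophasic call. Exactly
flat traces are flagged rather than fitted. Negative binding-plot intercepts
beyond 2 SE warn as unphysical. Where the AICc comparison is meaningless
because the single model already explains all variance (noiseless
single-exponential data), classification short-circuits to monophasic.

## Problem sizes

The default designs were chosen as the smallest that exercise every code
path with comfortable statistical margin: four substrate concentrations ×
two timescales × three replicates for stopped flow (2 000 and 5 000 points
per trace), eight concentrations × three replicates × 300 s for turnover,
and a 43-point product time course for the burst assay. A full six-scenario
pipeline run completes in well under a minute on one CPU; the recovery and
classification test suites run ten noisy seeds per scenario.

## Known limitations

* The binding secondary plot assumes pseudo-first-order conditions; at
  $S_0 < 10\,E_0$ the analytic oracle is flagged approximate rather than
  refused (experimental designs of this kind use ≥ 10-fold excess).
* $k_3$ is structurally unidentifiable from these assays when the first
  step is rate-limiting; it is reported as `NA`, never guessed.
* The Michaelis constant of very slow mutants (apparent $K_m$ far below
  the lowest assayed substrate concentration) is poorly constrained and is
  flagged by a warning; the kinetic conclusions never depend on it.
* No global multi-trace ODE fitting is attempted: the package reproduces
  the staged procedure, and its estimates inherit that procedure's biases
  (quantified in the recovery tests at 5–30 % depending on the parameter).
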