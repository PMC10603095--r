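# dnph1kin

Simulation and inference toolkit for enzyme mechanisms with a covalent
glycosyl-enzyme intermediate, modelled on the human nucleotide-pool
sanitiser DNPH1 and its active-site mutants.

## The problem

DNPH1 removes hydroxymethyl-dUMP from the nucleotide pool by a
double-displacement mechanism: reversible substrate binding, cleavage of the
glycosidic bond (releasing the hydroxymethyl-uracil base and leaving a
covalent sugar–enzyme ester), then hydrolysis of that ester (releasing
deoxyribose-5′-phosphate):

    E + S  <=>[k1][k-1]  ES  -->[k2]  EI + P1  -->[k3]  E + P2

Which of the two catalytic steps limits turnover — and how active-site
mutations shift that balance — is read out from three classic experiments:
stopped-flow tryptophan-fluorescence transients (binding and intermediate
formation), continuous UV turnover assays (Michaelis–Menten kinetics), and
discrete product time courses (burst kinetics). This package provides:

* a mass-action simulator of the scheme with analytic oracles
  (`KD = k-1/k1`, `kcat = k2·k3/(k2+k3)`,
  `Km = k3/(k2+k3) · (k-1+k2)/k1`, pseudo-first-order
  `kobs = k1·S0 + k-1`, burst amplitude `E0·(k2/(k2+k3))²`);
* observation models for the three assays (fluorescence with
  photobleaching, 275 nm absorbance, HPLC-like product sampling) and
  scenario presets encoding the wild type and the E104Q, H56A, E55Q, E55A
  and E55A/H56A mutants;
* the staged inference chain: deterministic exponential transient fits,
  phase classification, secondary plots of observed rates versus substrate,
  Michaelis–Menten regression of initial rates, burst fitting, and an
  assembled mechanism estimate with the rate-limiting-step call.

For whom: enzymologists who want to sanity-check a transient-kinetics
analysis against simulated ground truth, and method developers who need a
reproducible, fully synthetic test bed for pre-steady-state fitting chains.

## Worked example

```r
library(dnph1kin)

sc <- scenario_presets()$WT                     # k1=1, k-1=5, k2=8, k3=1
sf <- generate_stopped_flow_dataset(sc, seed = 1)
to <- generate_turnover_dataset(sc, E0 = 0.1, seed = 2)
bu <- generate_burst_dataset(sc, seed = 3)
ana <- analyse_scenario(sf, to, bu, turnover_E0 = 0.1)
ana$estimate
```

prints

```
<mechanism_estimate>
  KD = 4.923 uM (k_on = 0.9776 /uM/s, k_off = 4.813 /s)
  k2 (cleavage)   = 8.462 /s
  k3 (hydrolysis) = 0.9746 /s
  kcat = 0.8739 /s; rate-limiting: second_step
```

i.e. from noisy synthetic data alone the chain recovers the wild-type
ground truth (KD = 5 µM, k2 = 8/s, k3 = 1/s, kcat = 8/9 /s) and concludes
that ester hydrolysis, not base cleavage, limits steady-state turnover —
the biphasic fluorescence signature (rapid quench, partial recovery as the
intermediate accumulates) is what licenses that call. Running the same
chain on the `H56A` preset yields a monophasic signature, a ~120-fold
reduced k2 and a first-step-limiting call; the `E55Q`/`E55A` presets show
burst amplitudes ≈ the enzyme concentration and a ~150-fold reduced k3.

The end-to-end pipeline (`run_pipeline(run_config())`) writes trace files,
fit summaries, a deterministic `report.json` and a log; a thin command-line
wrapper with `generate`/`fit`/`analyse`/`run` subcommands is installed at
`inst/scripts/kinetics_pipeline.R`.

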