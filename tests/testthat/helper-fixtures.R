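# Shared fixtures: everything is generated in code at test time.

wt_rc <- function() rate_constants(k_on = 1, k_off = 5, k_cleave = 8,
                                   k_hydrolyse = 1)

dead_rc <- function() rate_constants(k_on = 1, k_off = 5, k_cleave = 0,
                                     k_hydrolyse = 1)

# deterministic pool of valid random rate constants / conditions
random_mechanisms <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    rc <- rate_constants(k_on = stats::runif(1, 0.1, 5),
                         k_off = stats::runif(1, 0.5, 20),
                         k_cleave = stats::runif(1, 0, 20),
                         k_hydrolyse = stats::runif(1, 0.01, 5))
    cond <- assay_condition(E0 = stats::runif(1, 0.5, 5),
                            S0 = stats::runif(1, 1, 200),
                            duration = stats::runif(1, 5, 40),
                            sample_interval = 0.05)
    list(rc = rc, cond = cond)
  })
}

# noiseless clean fluorescence trace for a scenario at one condition
clean_fluor_trace <- function(scenario, E0, S0, duration, dt = 1e-3) {
  cond <- assay_condition(E0, S0, duration, dt)
  fluorescence_from_trajectory(simulate_mechanism(scenario$rc, cond),
                               scenario$fm)
}
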