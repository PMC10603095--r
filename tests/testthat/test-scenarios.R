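test_that("presets encode the mutant fold changes", {
  p <- scenario_presets()
  expect_equal(p$WT$rc$k_cleave / p$WT$rc$k_hydrolyse, 8)
  expect_equal(p$E104Q$rc$k_cleave, 0)
  expect_equal(p$WT$rc$k_cleave / p$H56A$rc$k_cleave, 120)
  expect_equal(p$WT$rc$k_hydrolyse / p$E55Q$rc$k_hydrolyse, 150)
  expect_equal(p$WT$rc$k_cleave / p$E55Q$rc$k_cleave, 6)
  expect_equal(p$E55A$rc[], p$E55Q$rc[])
  expect_equal(p$E55A_H56A$rc$k_cleave, p$H56A$rc$k_cleave)
  expect_equal(p$E55A_H56A$rc$k_hydrolyse, p$E55Q$rc$k_hydrolyse)
  # every mutant binds 2-fold weaker than wild type
  kd_wt <- equilibrium_affinity(p$WT$rc)
  for (nm in setdiff(names(p), "WT"))
    expect_equal(equilibrium_affinity(p[[nm]]$rc), 2 * kd_wt)
})

test_that("steady-state turnover of H56A is an order of magnitude down", {
  p <- scenario_presets()
  ratio <- steady_state_parameters(p$WT$rc)$kcat /
    steady_state_parameters(p$H56A$rc)$kcat
  expect_equal(ratio, 14.2, tolerance = 0.01)
})

test_that("stopped-flow generator produces the designed trace count", {
  sc <- scenario_presets()$E104Q
  ds <- generate_stopped_flow_dataset(sc, S0_list = c(20, 50),
                                      timescales = c(short = 2, long = 50),
                                      replicates = 3, seed = 5)
  # |S0| * |timescales| * replicates + one control per timescale
  expect_length(ds, 2 * 2 * 3 + 2)
  ctl <- Filter(function(tr) tr$is_control, ds)
  expect_length(ctl, 2)
  expect_true(all(vapply(ctl, function(tr) tr$condition$S0, numeric(1)) == 0))
  expect_error(generate_stopped_flow_dataset(sc, S0_list = numeric(0)),
               "empty")
})

test_that("generated datasets are bit-for-bit reproducible under a seed", {
  sc <- scenario_presets()$WT
  a <- generate_stopped_flow_dataset(sc, S0_list = 50, replicates = 3,
                                     seed = 9)
  b <- generate_stopped_flow_dataset(sc, S0_list = 50, replicates = 3,
                                     seed = 9)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  c_ <- generate_stopped_flow_dataset(sc, S0_list = 50, replicates = 3,
                                      seed = 10)
  expect_false(identical(a[[1]]$values, c_[[1]]$values))
})

test_that("turnover dataset matches the assay design", {
  sc <- scenario_presets()$WT
  grid <- c(1, 2, 5, 10, 20, 50, 100, 200)
  ds <- generate_turnover_dataset(sc, S0_grid = grid, E0 = 0.1, seed = 3)
  expect_length(ds, 8 * 3)
  expect_true(all(vapply(ds, function(tr) max(tr$times), numeric(1)) >= 300))
  expect_true(all(vapply(ds, function(tr) min(diff(tr$times)), numeric(1)) == 1))
  # noiseless initial rates rise hyperbolically with substrate
  clean <- generate_turnover_dataset(sc, S0_grid = grid, E0 = 0.1,
                                     noise_frac = 0, seed = 3,
                                     replicates = 1)
  v <- vapply(clean, function(tr)
    initial_rate(tr, delta_eps_ell = 0.01)$v, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_lt(v[8] / v[7], v[2] / v[1])  # saturating, not linear
  ss <- steady_state_parameters(sc$rc)
  expect_equal(v[8], ss$kcat * 0.1 * 200 / (ss$Km + 200), tolerance = 0.03)
})

test_that("dead-enzyme stopped-flow traces are monophasic decays", {
  sc <- scenario_presets()$E104Q
  ds <- generate_stopped_flow_dataset(sc, S0_list = c(20, 50, 100),
                                      replicates = 3, seed = 21)
  ana <- analyse_stopped_flow(ds)
  expect_identical(ana$classification, "monophasic")
  expect_true(all(vapply(ana$per_S0, `[[`, character(1), "phase") ==
                    "monophasic"))
})

test_that("wild-type recovery is retarded at higher substrate", {
  sc <- scenario_presets()$WT
  ds <- generate_stopped_flow_dataset(sc, S0_list = c(20, 50), noise_frac = 0,
                                      seed = 1)
  ana <- suppressWarnings(analyse_stopped_flow(ds))
  t_half <- vapply(ana$long_corrected, function(tr) {
    i_min <- which.min(tr$values)
    target <- (tr$values[i_min] + tr$values[length(tr$values)]) / 2
    tr$times[which(tr$values[i_min:length(tr$values)] >= target)[1] + i_min - 1]
  }, numeric(1))
  expect_lt(t_half[["20"]], t_half[["50"]])
})

test_that("burst dataset shows the single-turnover signature of E55 mutants", {
  p <- scenario_presets()
  bu <- generate_burst_dataset(p$E55Q, E0 = 1, noise_frac = 0, seed = 2)
  fit <- fit_burst(bu, E0 = 1)
  expect_gte(fit$amplitude_ratio, 0.9)
  # H56A shows no burst at all
  bu2 <- generate_burst_dataset(p$H56A, E0 = 1, noise_frac = 0, seed = 2)
  fit2 <- fit_burst(bu2, E0 = 1)
  expect_lt(fit2$amplitude_ratio, 0.01)
})
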