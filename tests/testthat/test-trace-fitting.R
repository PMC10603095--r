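test_that("single exponential plus drift is recovered exactly", {
  t <- seq(0, 2, by = 1e-3)
  tr <- kin_trace("fluorescence", t, 2 * exp(-55 * t) + 0.001 * t + 1)
  f <- fit_single_exp_linear(tr)
  expect_equal(f$coefficients[["a"]], 2, tolerance = 1e-3)
  expect_equal(f$coefficients[["kobs"]], 55, tolerance = 1e-3)
  expect_equal(f$coefficients[["m"]], 0.001, tolerance = 1e-3)
  expect_equal(f$coefficients[["c"]], 1, tolerance = 1e-3)
  expect_lt(f$rss, 1e-10 * f$tss)
})

test_that("flat-plus-drift input is flagged, not given a spurious rate", {
  t <- seq(0, 2, by = 1e-3)
  tr <- kin_trace("fluorescence", t, 0.5 + 0.02 * t)
  f <- fit_single_exp_linear(tr)
  expect_true("degenerate_amplitude" %in% f$degenerate)
  expect_true(is.na(f$coefficients[["kobs"]]))
})

test_that("double exponential with opposite-sign amplitudes is exact", {
  t <- seq(0, 3, by = 1e-3)
  tr <- kin_trace("fluorescence", t,
                  1.5 * exp(-50 * t) - 0.4 * exp(-2 * t) + 1)
  f <- fit_double_exp(tr)
  expect_equal(f$coefficients[["a1"]], 1.5, tolerance = 1e-3)
  expect_equal(f$coefficients[["kobs1"]], 50, tolerance = 1e-3)
  expect_equal(f$coefficients[["a2"]], -0.4, tolerance = 1e-3)
  expect_equal(f$coefficients[["kobs2"]], 2, tolerance = 1e-3)
  expect_gt(f$coefficients[["kobs1"]], f$coefficients[["kobs2"]])  # sorted
})

test_that("simulated dead-enzyme trace yields the binding oracle kobs", {
  sc <- scenario_presets()$E104Q
  tr <- clean_fluor_trace(sc, E0 = 2, S0 = 50, duration = 2)
  f <- fit_single_exp_linear(tr)
  expect_equal(f$coefficients[["kobs"]],
               analytic_binding_kobs(sc$rc, 50), tolerance = 0.02)
})

test_that("fitted rates are invariant to positive rescaling of the signal", {
  t <- seq(0, 2, by = 1e-3)
  y <- 1.5 * exp(-30 * t) - 0.3 * exp(-3 * t) + 1
  f1 <- fit_double_exp(kin_trace("fluorescence", t, y))
  f2 <- fit_double_exp(kin_trace("fluorescence", t, 7.3 * y))
  expect_equal(f1$coefficients[["kobs1"]], f2$coefficients[["kobs1"]],
               tolerance = 1e-6)
  expect_equal(f1$coefficients[["kobs2"]], f2$coefficients[["kobs2"]],
               tolerance = 1e-6)
})

test_that("control subtraction cancels the bleaching envelope", {
  sc <- scenario_presets()$WT
  ds <- generate_stopped_flow_dataset(sc, S0_list = 20, noise_frac = 0,
                                      seed = 1)
  is_long <- vapply(ds, function(tr) tr$timescale == "long", logical(1))
  is_ctl <- vapply(ds, `[[`, logical(1), "is_control")
  trace <- ds[is_long & !is_ctl][[1]]
  ctl <- ds[is_long & is_ctl][[1]]
  corr <- correct_photobleaching(trace, ctl)
  expect_true(corr$corrected)
  # self-subtraction gives the zero trace
  zero <- correct_photobleaching(ctl, ctl)
  expect_equal(zero$values, rep(0, length(zero$values)))
  # after full turnover the corrected trace is flat (bleach term cancels)
  tail_vals <- corr$values[corr$times > 45]
  expect_lt(abs(stats::coef(stats::lm(tail_vals ~ seq_along(tail_vals)))[[2]]),
            1e-5)
  expect_error(correct_photobleaching(trace, trace), "control")
})

test_that("control interpolation handles mismatched grids", {
  t1 <- seq(0, 10, by = 0.1)
  t2 <- seq(0, 10, by = 0.13)
  decay <- function(t) 3 * exp(-0.05 * t)
  tr <- kin_trace("fluorescence", t1, decay(t1) + 1)
  ctl <- kin_trace("fluorescence", t2, decay(t2), is_control = TRUE)
  corr <- correct_photobleaching(tr, ctl)
  expect_equal(corr$values, rep(1, length(t1)), tolerance = 1e-3)
})

test_that("replicate averaging is exact and reduces noise as sqrt(n)", {
  t <- seq(0, 1, by = 1e-3)
  clean <- kin_trace("fluorescence", t, exp(-3 * t))
  expect_identical(average_replicates(list(clean))$values, clean$values)
  noisy1 <- lapply(1:9, function(i) add_noise(clean, 0.1, i))
  avg9 <- average_replicates(noisy1)
  sd1 <- stats::sd(noisy1[[1]]$values - clean$values)
  sd9 <- stats::sd(avg9$values - clean$values)
  expect_equal(sd1 / sd9, 3, tolerance = 0.25)
  other <- kin_trace("fluorescence", t, exp(-3 * t),
                     condition = assay_condition(1, 5, 1, 1e-3))
  first <- kin_trace("fluorescence", t, exp(-3 * t),
                     condition = assay_condition(1, 9, 1, 1e-3))
  expect_error(average_replicates(list(first, other)), "condition")
})

test_that("normalisation rescales to the fitted intercept", {
  t <- seq(0, 2, by = 1e-3)
  tr <- kin_trace("fluorescence", t, 1 * exp(-20 * t) + 1)
  f <- fit_single_exp_linear(tr)
  norm <- normalise_to_intercept(tr, f)
  expect_equal(norm$values[1], 1, tolerance = 1e-6)
  expect_equal(norm$values, tr$values / 2, tolerance = 1e-4)
})

test_that("phase classification separates the preset signatures", {
  p <- scenario_presets()
  phase_of <- function(nm, seed) {
    ds <- generate_stopped_flow_dataset(p[[nm]], S0_list = c(20, 50, 100),
                                        seed = seed)
    analyse_stopped_flow(ds)$classification
  }
  expect_identical(phase_of("E104Q", 31), "monophasic")
  expect_identical(phase_of("H56A", 32), "monophasic")
  expect_identical(phase_of("WT", 33), "biphasic")
  expect_identical(phase_of("E55Q", 34), "biphasic")
})

test_that("slow phases invisible on the short timescale are found on long", {
  sc <- scenario_presets()$E55A_H56A
  ds <- generate_stopped_flow_dataset(sc, S0_list = c(20, 50, 100), seed = 35)
  ana <- analyse_stopped_flow(ds)
  expect_identical(ana$classification, "biphasic")
  expect_identical(ana$slow_source, "long_single_exp")
  expect_equal(stats::median(ana$kobs_slow$kobs),
               sc$rc$k_cleave * 50 / (50 + 10) + sc$rc$k_hydrolyse,
               tolerance = 0.3)
})
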