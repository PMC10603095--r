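test_that("exact linear secondary plot recovers binding constants", {
  pts <- data.frame(S0 = c(10, 25, 50, 100), kobs = 1 * c(10, 25, 50, 100) + 5)
  sp <- secondary_plot_binding(pts)
  expect_equal(sp$k_on_est, 1, tolerance = 1e-10)
  expect_equal(sp$k_off_est, 5, tolerance = 1e-10)
  expect_equal(sp$KD_est, 5, tolerance = 1e-10)
  expect_error(secondary_plot_binding(pts[1:2, ]), "3 distinct")
  expect_warning(
    secondary_plot_binding(
      data.frame(S0 = c(10, 25, 50, 100),
                 kobs = c(10, 25, 50, 100) - 8,
                 se = rep(0.1, 4))),
    "negative")
})

test_that("exact hyperbola recovers the catalytic plateau", {
  S0 <- c(1, 5, 25, 100)
  pts <- data.frame(S0 = S0, kobs = 8 * S0 / (5 + S0))
  sp <- secondary_plot_catalytic(pts)
  expect_equal(sp$k_max_est, 8, tolerance = 1e-6)
  expect_equal(sp$K_half_est, 5, tolerance = 1e-4)
  # concentration-independent rates collapse to K_half ~ 0, flagged
  flat <- secondary_plot_catalytic(data.frame(S0 = S0, kobs = rep(2, 4)))
  expect_equal(flat$k_max_est, 2, tolerance = 1e-3)
  expect_true("saturated" %in% flat$degenerate)
})

test_that("initial rate handles exact lines and flags depletion", {
  tr <- kin_trace("product", 0:100, 0.05 * (0:100))
  ir <- initial_rate(tr)
  expect_equal(ir$v, 0.05, tolerance = 1e-12)
  expect_false(ir$flagged_depletion)
  # low-substrate wild-type assay bends within 30 s; quadratic slope corrects
  sc <- scenario_presets()$WT
  traj <- simulate_mechanism(sc$rc, assay_condition(0.1, 1, 300, 1))
  tra <- absorbance_from_trajectory(traj, delta_eps_ell = 0.01)
  ir2 <- initial_rate(tra, window_s = 30, delta_eps_ell = 0.01)
  ss <- steady_state_parameters(sc$rc)
  expect_true(ir2$flagged_depletion)
  expect_equal(ir2$v, ss$kcat * 0.1 * 1 / (ss$Km + 1), tolerance = 0.05)
  expect_error(initial_rate(tra, window_s = 30), "delta_eps_ell")
  expect_error(initial_rate(kin_trace("product", 0:20, 0:20 * 0.1),
                            window_s = 2), "5 points")
})

test_that("Michaelis-Menten regression recovers exact parameters", {
  S0 <- c(0.5, 1, 2, 5, 10, 50)
  rates <- data.frame(S0 = S0, v = 0.09 * S0 / (1.5 + S0))
  mm <- fit_michaelis_menten(rates, E0 = 0.1)
  expect_equal(mm$Vmax, 0.09, tolerance = 1e-6)
  expect_equal(mm$Km, 1.5, tolerance = 1e-5)
  expect_equal(mm$kcat, 0.9, tolerance = 1e-5)
  expect_error(fit_michaelis_menten(rates[1:3, ], E0 = 0.1), "4 distinct")
})

test_that("wild-type turnover assay recovers kcat and Km", {
  sc <- scenario_presets()$WT
  ds <- generate_turnover_dataset(sc, E0 = 0.1, noise_frac = 0,
                                  replicates = 1, seed = 1)
  v <- vapply(ds, function(tr) initial_rate(tr, delta_eps_ell = 0.01)$v,
              numeric(1))
  S0 <- vapply(ds, function(tr) tr$condition$S0, numeric(1))
  mm <- fit_michaelis_menten(data.frame(S0 = S0, v = v), E0 = 0.1)
  expect_equal(mm$Km, 13 / 9, tolerance = 0.10)
  expect_equal(mm$kcat, 8 / 9, tolerance = 0.05)
})

test_that("slowed-binding mutant raises the Michaelis constant", {
  p <- scenario_presets()
  km <- vapply(c("WT", "H56A"), function(nm) {
    E0 <- if (nm == "WT") 0.1 else 1
    ds <- generate_turnover_dataset(p[[nm]], E0 = E0, noise_frac = 0,
                                    replicates = 1, seed = 1)
    v <- vapply(ds, function(tr) initial_rate(tr, delta_eps_ell = 0.01)$v,
                numeric(1))
    S0 <- vapply(ds, function(tr) tr$condition$S0, numeric(1))
    fit_michaelis_menten(data.frame(S0 = S0, v = v), E0 = E0)$Km
  }, numeric(1))
  expect_gt(km[["H56A"]], km[["WT"]])
})

test_that("burst fit recovers exact burst parameters and no-burst cases", {
  t <- c(seq(0.1, 5, by = 0.1), seq(6, 60, by = 1))
  tr <- kin_trace("product", t, 1 * (1 - exp(-2 * t)) + 0.01 * t)
  bf <- fit_burst(tr, E0 = 1)
  expect_equal(bf$amplitude, 1, tolerance = 1e-6)
  expect_equal(bf$burst_rate, 2, tolerance = 1e-4)
  expect_equal(bf$v_ss, 0.01, tolerance = 1e-6)
  # pure linear accumulation: amplitude collapses to the no-burst outcome
  lin <- kin_trace("product", t, 0.02 * t)
  bl <- fit_burst(lin, E0 = 1)
  expect_equal(bl$amplitude, 0)
  expect_equal(bl$v_ss, 0.02, tolerance = 1e-6)
})

test_that("burst amplitude ratio follows (k2/(k2+k3))^2 across ratios", {
  for (ratio in c(0.5, 1, 8)) {
    rc <- rate_constants(1, 5, ratio, 1)
    ab <- analytic_burst_parameters(rc, 1)
    ss <- steady_state_parameters(rc)
    times <- c(seq(0.1, 8, by = 0.1), seq(8.5, 60, by = 0.5)) / ab$burst_rate
    cond <- assay_condition(1, max(500 * ss$Km, 50), max(times),
                            max(times) / 2000)
    tr <- sample_product_timecourse(simulate_mechanism(rc, cond), times)
    bf <- fit_burst(tr, E0 = 1)
    expect_equal(bf$amplitude_ratio, ab$amplitude, tolerance = 0.1)
  }
})

test_that("assembled estimates respect the kcat composition law", {
  sc <- scenario_presets()$WT
  sf <- generate_stopped_flow_dataset(sc, noise_frac = 0, seed = 1)
  to <- generate_turnover_dataset(sc, E0 = 0.1, noise_frac = 0, seed = 1)
  bu <- generate_burst_dataset(sc, noise_frac = 0, seed = 1)
  e <- suppressWarnings(analyse_scenario(sf, to, bu, turnover_E0 = 0.1))$estimate
  k2 <- e$k_cleave_est; k3 <- e$k_hydrolyse_est
  expect_equal(e$kcat_est, k2 * k3 / (k2 + k3), tolerance = 0.2)
  expect_identical(e$rate_limiting, "second_step")
})

test_that("inactive enzyme yields a binding-only estimate", {
  sc <- scenario_presets()$E104Q
  sf <- generate_stopped_flow_dataset(sc, noise_frac = 0, seed = 1)
  to <- generate_turnover_dataset(sc, E0 = 1, noise_frac = 0, seed = 1)
  bu <- generate_burst_dataset(sc, noise_frac = 0, seed = 1)
  e <- suppressWarnings(analyse_scenario(sf, to, bu, turnover_E0 = 1))$estimate
  expect_identical(e$rate_limiting, "inactive")
  expect_equal(e$k_cleave_est, 0)
  expect_true(is.na(e$k_hydrolyse_est))
  expect_equal(e$KD_est, 10, tolerance = 0.05)
})

test_that("inconsistent kcat versus relaxation plateau raises an error", {
  binding <- secondary_plot_binding(
    data.frame(S0 = c(10, 25, 50), kobs = c(10, 25, 50) + 14), mode = "total")
  catalytic <- secondary_plot_catalytic(
    data.frame(S0 = c(10, 25, 50), kobs = 2 * c(10, 25, 50) / (5 + c(10, 25, 50))))
  mm <- structure(list(Vmax = 0.9, Km = 1.4, kcat = 1.8, E0 = 0.5,
                       se = c(Vmax = 0.01, Km = 0.1), r_squared = 0.99,
                       n = 8), class = "mm_fit")
  expect_error(
    assemble_mechanism(binding, catalytic, mm, NULL, phases = "biphasic"),
    "inconsistent")
})
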