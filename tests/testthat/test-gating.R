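test_that("Boltzmann fits recover exact parameters in both directions", {
  v <- seq(-120, 20, 10)
  act <- 1 / (1 + exp(-(v + 40) / 8))
  f <- fit_boltzmann(v, act, "activation")
  expect_true(f$ok)
  expect_equal(f$v_half_mV, -40, tolerance = 1e-3)
  expect_equal(f$k_mV, 8, tolerance = 1e-3)
  inact <- 1 / (1 + exp((v + 70) / 6))
  fi <- fit_boltzmann(v, inact, "inactivation")
  expect_equal(fi$v_half_mV, -70, tolerance = 1e-3)
  expect_equal(fi$k_mV, 6, tolerance = 1e-3)
})

test_that("Boltzmann recovery holds across the parameter grid", {
  v <- seq(-140, 0, 10)
  for (vh in c(-120, -80, -20)) {
    for (k in c(4, 15)) {
      vv <- seq(vh - 60, vh + 60, 8)
      y <- 1 / (1 + exp(-(vv - vh) / k))
      f <- fit_boltzmann(vv, y, "activation")
      expect_equal(f$v_half_mV, vh, tolerance = 1e-3)
      expect_equal(f$k_mV, k, tolerance = 1e-3)
    }
  }
})

test_that("linear data are flagged as non-sigmoidal", {
  v <- seq(-100, 0, 10)
  expect_false(fit_boltzmann(v, 0.5 + 0.002 * v, "activation")$ok)
})

test_that("pH 7.4 vs 9.4 G-V midpoints shift by -28 to -34 mV", {
  for (nm in c("nsvba", "nachbac")) {
    ch <- channel_preset(nm)
    vh <- vapply(c(7.4, 9.4), function(ph) {
      chm <- apply_modulation(ch, 22, ph)
      v <- seq(chm$gating$v_half_act - 60, chm$gating$v_half_act + 60, 10)
      g <- 1 / (1 + exp(-(v - chm$gating$v_half_act) / chm$gating$slope_act))
      fit_boltzmann(v, g, "activation")$v_half_mV
    }, 0)
    shift <- vh[2] - vh[1]
    expect_gte(shift, -34); expect_lte(shift, -28)
  }
})

test_that("conductance transform linearizes an ohmic I-V", {
  v <- seq(-80, 20, 10)
  pk <- data.frame(voltage_mV = v, peak_pA = 2 * (v - 50))
  gv <- conductance_transform(pk, 50)
  expect_equal(gv$g_norm, rep(1, length(v)))
  expect_warning(conductance_transform(
    data.frame(voltage_mV = c(0, 50), peak_pA = c(-100, 0)), 50), "V = Erev")
})

test_that("G-V from simulated sweeps recovers the preset midpoint", {
  # symmetric Na (pipette = bath recipe) makes the open-pore GHK flux exactly
  # ohmic, so chord conductance carries no rectification bias
  ch <- channel_preset("nsvba")
  sym <- solution_composition(c(NaCl = 150, HEPES = 10, EGTA = 5,
                                CaCl2 = 0.5))
  prot <- step_protocol(levels = seq(-95, 15, 10), dur_ms = 250,
                        holding = -160)
  ss <- simulate_whole_cell(ch, prot, sym, bath_monovalent("Na"),
                            quiet_conditions(), p4 = TRUE)
  pk <- measure_peaks(p4_subtract(ss), polarity = "auto")
  gv <- conductance_transform(pk, 0)
  f <- fit_boltzmann(gv$voltage_mV, gv$g_norm, "activation")
  expect_true(f$ok)
  expect_equal(f$v_half_mV, ch$gating$v_half_act, tolerance = 2 / 43.5)
  # the conductance route and the I-V fit's gating factor are two readings
  # of the same activation curve
  ivf <- fit_iv(pk)
  expect_lt(abs(f$v_half_mV - ivf$v_half_mV), 0.5)
})

test_that("single-channel conductance slope handles exact and flat data", {
  v <- c(-120, -100, -80, -60)
  exact <- single_channel_conductance(v, 0.030 * v)
  expect_equal(exact$conductance_pS, 30, tolerance = 1e-9)
  flat <- single_channel_conductance(v, rep(-2, 4))
  expect_equal(flat$conductance_pS, 0, tolerance = 1e-9)
  expect_error(single_channel_conductance(v[1:2], c(-3, -2)), "at least 3")
})

test_that("Q10 two-point form follows the printed definition", {
  expect_equal(q10_analysis(c(20, 30), c(1, 4))$q10_two_point, 4)
  expect_equal(q10_analysis(c(20, 25), c(1, 2))$q10_two_point, 4)
  # two-point and regression forms agree exactly for n = 2
  q <- q10_analysis(c(22, 31), c(3, 7))
  expect_equal(q$q10, q$q10_two_point, tolerance = 1e-12)
  expect_error(q10_analysis(c(20, 22), c(1, 2)), "spanning")
  expect_error(q10_analysis(c(20, 30), c(1, -2)), "positive")
})

test_that("Q10 regression recovers the generating coefficient exactly", {
  temps <- seq(18, 38, 4)
  for (q in c(1, 1.7, 3, 5)) {
    r <- 2.5 * q^((temps - 20) / 10)
    expect_equal(q10_analysis(temps, r)$q10, q, tolerance = 1e-4)
  }
})

test_that("depolarization work evaluates to the printed barrier", {
  b <- activation_energy_barrier(140, 1)
  expect_equal(b$magnitude_kcal_mol, 3.23, tolerance = 0.002)
  expect_equal(b$work_kcal_mol, -3.2, tolerance = 0.02)
  expect_equal(activation_energy_barrier(0, 1)$work_kcal_mol, 0)
  expect_equal(activation_energy_barrier(100, 1)$magnitude_kcal_mol,
               96485 * 0.1 / 4184, tolerance = 1e-12)
})
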