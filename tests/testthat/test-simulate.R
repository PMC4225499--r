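test_that("identical seeds give bit-identical sweep sets", {
  ch <- channel_preset("nsvba")
  prot <- step_protocol(levels = c(-40, 0), dur_ms = 100)
  cond <- recording_conditions(seed = 42)
  a <- simulate_whole_cell(ch, prot, pipette_standard(), bath_monovalent("Na"),
                           cond, p4 = TRUE)
  b <- simulate_whole_cell(ch, prot, pipette_standard(), bath_monovalent("Na"),
                           cond, p4 = TRUE)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- recording_conditions(seed = 43)
  d <- simulate_whole_cell(ch, prot, pipette_standard(), bath_monovalent("Na"),
                           c2, p4 = TRUE)
  expect_false(identical(a$current_pA, d$current_pA))
})

test_that("simulation leaves the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_whole_cell(
    channel_preset("nsvba"), step_protocol(levels = 0, dur_ms = 50),
    pipette_standard(), bath_monovalent("Na"),
    recording_conditions(seed = 7)))
  expect_identical(before, .Random.seed)
})

test_that("p_max -> 0 leaves only leak and capacitance", {
  ch <- channel_preset("nsvba")
  ch$p_max <- 1e-12
  prot <- step_protocol(levels = 0, dur_ms = 100)
  cond <- quiet_conditions()
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), cond)
  v <- sweep_voltage(prot, 1)
  leak <- cond$leak_nS * v
  # away from the step edges the trace is pure leak
  mid <- which(ss$time_ms > 60 & ss$time_ms < 100)
  expect_equal(ss$current_pA[mid, 1], leak[mid], tolerance = 1e-6)
})

test_that("NsvBa current decay at 0 mV refits to ~42 ms", {
  ch <- channel_preset("nsvba")
  prot <- step_protocol(levels = 0, dur_ms = 500)
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), quiet_conditions(),
                            p4 = TRUE)
  tf <- sweep_inactivation_tau(p4_subtract(ss), 1, polarity = "inward")
  expect_true(tf$ok)
  expect_equal(tf$tau_ms, 42, tolerance = 0.02)
})

test_that("temperature/pH modulation is additive and matches the presets", {
  for (nm in c("nsvba", "nachbac", "navbp")) {
    ch <- channel_preset(nm)
    dT <- apply_modulation(ch, 37, 7.4)$gating$v_half_act -
      apply_modulation(ch, 20, 7.4)$gating$v_half_act
    expect_gte(dT, -24); expect_lte(dT, -19)
    dpH <- apply_modulation(ch, ch$reference_temperature, 9.4)$gating$v_half_act -
      ch$gating$v_half_act
    expect_gte(dpH, -34); expect_lte(dpH, -28)
    # additivity is exact in the linear model
    both <- apply_modulation(ch, 37, 9.4)$gating$v_half_act -
      ch$gating$v_half_act
    dT15 <- apply_modulation(ch, 37, ch$reference_pH)$gating$v_half_act -
      ch$gating$v_half_act
    expect_equal(both, dT15 + dpH, tolerance = 1e-12)
  }
  conv <- vapply(c("nsvba", "nachbac", "navbp"), function(nm) {
    apply_modulation(channel_preset(nm), 37, 9.4)$gating$v_half_act
  }, 0)
  expect_equal(unname(conv), c(-95, -102, -100))
})

test_that("modulation at reference conditions is the identity", {
  ch <- channel_preset("nachbac")
  same <- apply_modulation(ch, ch$reference_temperature, ch$reference_pH)
  expect_equal(same$gating, ch$gating)
  expect_equal(same$p_max, ch$p_max)
  expect_warning(apply_modulation(ch, 50, 7.4), "clamped")
})

test_that("drug block scales p_max by the Hill factor", {
  ch <- channel_preset("nsvba")
  expect_equal(apply_drug(ch, "tamoxifen", 30)$p_max, ch$p_max / 2)
  expect_equal(apply_drug(ch, "tamoxifen", 0)$p_max, ch$p_max)
  expect_equal(apply_drug(ch, "tamoxifen", 3000)$p_max, ch$p_max / 101)
  expect_error(apply_drug(ch, "unobtainium", 10), "unknown drug")
})

test_that("single-channel amplitudes are ohmic and rates behave", {
  ch <- channel_preset("nsvba")
  r <- simulate_single_channel(ch, "Na", -100, 500,
                               quiet_conditions(seed = 3), erev_mV = 0)
  opens <- r$current_pA[r$open]
  expect_true(length(opens) > 0)
  expect_equal(unique(round(opens, 12)), -3) # 30 pS * -100 mV
  ch0 <- ch
  ch0$sc_open_rate <- 0
  flat <- simulate_single_channel(ch0, "Na", -100, 200,
                                  quiet_conditions(seed = 3))
  expect_equal(unique(flat$current_pA), 0)
  expect_error(simulate_single_channel(ch, "Sr", -100, 10,
                                       quiet_conditions()), "available")
})

test_that("slope conductance of simulated Na and K records is ~30 and ~36 pS", {
  ch <- channel_preset("nsvba")
  for (ion in c("Na", "K")) {
    rec <- simulate_single_channel(
      ch, ion, levels_mV = seq(-120, -60, 20), duration_ms = 3000,
      conditions = recording_conditions(seed = 5, noise_sd_pA = 0.3),
      erev_mV = 0)
    am <- measure_open_amplitudes(rec)
    expect_gte(nrow(am), 3)
    sc <- single_channel_conductance(am$level_mV, am$amplitude_pA)
    expect_equal(sc$conductance_pS, ch$single_channel_conductance[[ion]],
                 tolerance = 0.1)
  }
})

test_that("ramp integration refuses an oversized step", {
  prot <- build_protocol("ramp", dur_ms = 100, dt_ms = 0.5)
  expect_error(
    simulate_whole_cell(channel_preset("hnav1.1"), prot, pipette_thermo(),
                        bath_monovalent("Na"), quiet_conditions()),
    "integration step")
})
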