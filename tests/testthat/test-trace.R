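test_that("P/4 subtraction cancels pure linear leak and capacitance", {
  ch <- channel_preset("nsvba")
  ch$p_max <- 1e-12 # channel-free cell
  prot <- step_protocol(levels = c(-40, 0, 40), dur_ms = 100)
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), quiet_conditions(),
                            p4 = TRUE)
  sub <- p4_subtract(ss)
  leak_amp <- max(abs(ss$current_pA))
  expect_lt(max(abs(sub$current_pA)), 1e-6 * leak_amp)
  # idempotence-scale residual: RMS tiny relative to input RMS
  expect_lt(sqrt(mean(sub$current_pA^2)),
            1e-9 * sqrt(mean(ss$current_pA^2)))
})

test_that("P/4-subtracted sweeps match a leak-free simulation", {
  ch <- channel_preset("nsvba")
  prot <- step_protocol(levels = c(-30, 0), dur_ms = 200)
  cond <- quiet_conditions(seed = 2)
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), cond, p4 = TRUE)
  sub <- p4_subtract(ss)
  clean_cond <- cond
  clean_cond$leak_nS <- 0
  clean_cond$access_MOhm <- 0
  clean <- simulate_whole_cell(ch, prot, pipette_standard(),
                               bath_monovalent("Na"), clean_cond)
  peak <- max(abs(clean$current_pA))
  expect_lt(max(abs(sub$current_pA - clean$current_pA)), 0.01 * peak)
})

test_that("residual holding current beyond -100 pA is QC-flagged", {
  ch <- channel_preset("nsvba")
  prot <- step_protocol(levels = 0, dur_ms = 50)
  leaky <- recording_conditions(seed = 1, leak_nS = 1.2, noise_sd_pA = 0)
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), leaky, p4 = TRUE)
  qc <- p4_subtract(ss)$qc
  expect_lt(qc$residual_holding_pA[1], -100) # 1.2 nS * -140 mV = -168 pA
  expect_true(qc$flagged[1])
  tight <- simulate_whole_cell(ch, prot, pipette_standard(),
                               bath_monovalent("Na"),
                               quiet_conditions(), p4 = TRUE)
  expect_false(p4_subtract(tight)$qc$flagged[1])
})

test_that("p4_subtract refuses sweep sets without subsweeps", {
  ch <- channel_preset("nsvba")
  ss <- simulate_whole_cell(ch, step_protocol(levels = 0, dur_ms = 20),
                            pipette_standard(), bath_monovalent("Na"),
                            quiet_conditions())
  expect_error(p4_subtract(ss), "p4 = TRUE|unsubtracted")
})

test_that("measure_peaks finds the signed extremum per sweep", {
  ch <- channel_preset("nsvba")
  ch$p_max <- 1e-12
  prot <- step_protocol(levels = c(-20, 0, 20), dur_ms = 100)
  cond <- quiet_conditions()
  ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                            bath_monovalent("Na"), cond, p4 = TRUE)
  sub <- p4_subtract(ss)
  pk <- measure_peaks(sub, polarity = "auto")
  expect_equal(nrow(pk), 3)
  expect_equal(pk$peak_pA, c(0, 0, 0), tolerance = 1e-9)
  # synthetic decaying sweep: peak at window start
  sub$current_pA[, 1] <- -5 * exp(-sub$time_ms / 40)
  pk1 <- measure_peaks(sub, window = c(0, 50), polarity = "inward")
  expect_equal(pk1$peak_pA[1], -5, tolerance = 1e-6)
  expect_equal(pk1$tpeak_ms[1], 0)
  expect_error(measure_peaks(sub, window = c(900, 999)), "empty")
})

test_that("peak location is stable under integer-factor resampling", {
  ch <- channel_preset("nsvba")
  prot1 <- step_protocol(levels = 0, dur_ms = 200, dt_ms = 0.05)
  prot2 <- step_protocol(levels = 0, dur_ms = 200, dt_ms = 0.1)
  pk1 <- measure_peaks(simulate_whole_cell(ch, prot1, pipette_standard(),
                                           bath_monovalent("Na"),
                                           quiet_conditions(), p4 = TRUE) |>
                         p4_subtract(), polarity = "inward")
  pk2 <- measure_peaks(simulate_whole_cell(ch, prot2, pipette_standard(),
                                           bath_monovalent("Na"),
                                           quiet_conditions(), p4 = TRUE) |>
                         p4_subtract(), polarity = "inward")
  expect_lt(abs(pk1$tpeak_ms - pk2$tpeak_ms), 0.1 + 1e-9)
  expect_equal(pk1$peak_pA, pk2$peak_pA, tolerance = 1e-3)
})

test_that("NsvBa peak current density is ~119 pA/pF in 150 mM Na", {
  ch <- channel_preset("nsvba")
  ss <- simulate_whole_cell(ch, step_protocol(), pipette_standard(),
                            bath_monovalent("Na"), quiet_conditions(),
                            p4 = TRUE)
  pk <- measure_peaks(p4_subtract(ss), polarity = "auto")
  expect_equal(min(pk$density_pA_per_pF), -119, tolerance = 0.02)
})

test_that("exponential decay recovery is exact on exact data", {
  t <- seq(0, 300, 0.5)
  for (tau in c(7, 42, 78)) {
    f <- fit_inactivation_tau(t, 10 * exp(-t / tau))
    expect_true(f$ok)
    expect_equal(f$tau_ms, tau, tolerance = 1e-4)
    expect_equal(f$A_pA, 10, tolerance = 1e-4)
    expect_equal(f$B_pA, 0, tolerance = 1e-4)
  }
  withB <- fit_inactivation_tau(t, 3 - 8 * exp(-t / 25))
  expect_equal(withB$tau_ms, 25, tolerance = 1e-4)
  expect_equal(withB$B_pA, 3, tolerance = 1e-4)
})

test_that("degenerate decays are flagged, not silently fit", {
  t <- seq(0, 100, 1)
  expect_false(fit_inactivation_tau(t, rep(2, length(t)))$ok)
  expect_false(fit_inactivation_tau(t[1:2], c(1, 0))$ok)
  # near-linear data imply tau >> segment -> flagged
  slow <- fit_inactivation_tau(t, 100 * exp(-t / 1e5))
  expect_false(slow$ok)
})

test_that("noisy tau estimates average to 42 ms within 5%", {
  ch <- channel_preset("nsvba")
  prot <- step_protocol(levels = 0, dur_ms = 500)
  taus <- vapply(1:10, function(seed) {
    ss <- simulate_whole_cell(ch, prot, pipette_standard(),
                              bath_monovalent("Na"),
                              recording_conditions(seed = seed,
                                                   noise_sd_pA = 2),
                              p4 = TRUE)
    sweep_inactivation_tau(p4_subtract(ss), 1, polarity = "inward")$tau_ms
  }, 0)
  expect_equal(mean(taus), 42, tolerance = 0.05)
})
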