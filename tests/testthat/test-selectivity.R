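test_that("fit_iv recovers parameters of model-generated data", {
  v <- seq(-100, 80, 5)
  g <- 2; erev <- 40; vh <- -30; k <- 8
  i <- g * (v - erev) / (1 + exp(-(v - vh) / k))
  f <- fit_iv(data.frame(voltage_mV = v, peak_pA = i))
  expect_true(f$ok)
  expect_equal(f$g_nS, 2, tolerance = 1e-3)
  expect_equal(f$erev_mV, 40, tolerance = 1e-3)
  expect_equal(f$v_half_mV, -30, tolerance = 1e-3)
  expect_equal(f$k_mV, 8, tolerance = 1e-3)
})

test_that("fit_iv flags degenerate inputs", {
  v <- seq(-60, 60, 10)
  expect_false(fit_iv(data.frame(voltage_mV = v, peak_pA = 1.5 * v))$ok)
  expect_false(fit_iv(data.frame(voltage_mV = v[1:4],
                                 peak_pA = v[1:4]))$ok)
})

test_that("erev_linear finds the zero crossing and subtracts LJP", {
  pk <- data.frame(voltage_mV = seq(0, 60, 10),
                   peak_pA = 1.5 * (seq(0, 60, 10) - 43))
  expect_equal(erev_linear(pk)$erev_mV, 43, tolerance = 1e-10)
  expect_equal(erev_linear(pk, ljp = 3.4)$erev_mV, 39.6, tolerance = 1e-10)
  bad <- data.frame(voltage_mV = seq(0, 60, 10),
                    peak_pA = -2 * seq(0, 60, 10))
  expect_false(erev_linear(bad)$ok)
})

test_that("monovalent permeability equation evaluates the printed cases", {
  # equal activities, equal Erev -> 1
  expect_equal(perm_ratio_monovalent(0, 111, 111, 22)$px_pna, 1)
  # K vs Na at 34 degC from Erev 43 vs 40 mV: ~1.15
  b_na <- bath_monovalent("Na"); b_k <- bath_monovalent("K")
  pr <- perm_ratio_monovalent(43 - 40, effective_activity("Na", b_na),
                              effective_activity("K", b_k), temp_c = 34,
                              erev_mV = 43)
  expect_equal(pr$px_pna, 1.15, tolerance = 0.02)
  expect_error(perm_ratio_monovalent(0, -1, 10, 22), "positive")
})

test_that("detection floor engages only without inward current", {
  fl <- perm_ratio_monovalent(-60, 111, 104, 22, erev_mV = -6,
                              has_inward_current = FALSE)
  expect_true(fl$floored)
  expect_equal(fl$px_pna, 0.1)
  ok <- perm_ratio_monovalent(-60, 111, 104, 22, erev_mV = -6,
                              has_inward_current = TRUE)
  expect_false(ok$floored)
  nofloor <- perm_ratio_monovalent(-20, 111, 104, 22, erev_mV = 10,
                                   has_inward_current = FALSE)
  expect_false(nofloor$floored)
})

test_that("divalent permeability equation evaluates the printed cases", {
  # Erev = 0: exp terms are 1 -> 2 a_Na,i / (4 a_x,e)
  expect_equal(perm_ratio_divalent(0, 11.3, 31.9, 34)$px_pna,
               2 * 11.3 / (4 * 31.9))
  # Ca at 34 degC, Erev 41 mV, alpha_Na,i ~11.3 mM, alpha_Ca,e = 0.29 * 110
  pr <- perm_ratio_divalent(41, 11.3, 0.29 * 110, 34)
  expect_equal(pr$px_pna, 2.4, tolerance = 0.02)
  expect_gt(pr$px_pna, 2); expect_lt(pr$px_pna, 3)
})

test_that("permeability ratios increase monotonically with Erev", {
  de <- seq(-40, 40, 5)
  mono <- vapply(de, function(d) {
    perm_ratio_monovalent(d, 111, 104, 22)$px_pna
  }, 0)
  expect_true(all(diff(mono) > 0))
  ev <- seq(-30, 50, 5)
  div <- vapply(ev, function(e) perm_ratio_divalent(e, 11.3, 31.9, 22)$px_pna,
                0)
  expect_true(all(diff(div) > 0))
})

test_that("closed-form equations match the numeric GHK zero-current root", {
  # monovalent: every permeant monovalent ion of every preset, < 0.5%
  pip <- pipette_standard()
  a_na_int <- effective_activity("Na", pip)
  for (nm in c("nsvba", "nachbac", "navbp", "hnav1.1")) {
    ch <- channel_preset(nm)
    na_bath <- bath_monovalent("Na")
    erev_na <- ghk_erev(ch, pip, na_bath, 22)
    for (ion in c("Li", "K", "Rb", "Cs")) {
      one <- ch
      one$permeabilities <- ch$permeabilities[c("Na", ion)]
      bath <- bath_monovalent(ion)
      erev_x <- ghk_erev(one, pip, bath, 22)
      rec <- perm_ratio_monovalent(
        erev_x - erev_na, effective_activity("Na", na_bath),
        effective_activity(ion, bath), 22)$px_pna
      expect_equal(rec, unname(ch$permeabilities[ion]), tolerance = 0.005,
                   label = paste(nm, ion))
    }
    # divalent, < 5%
    for (ion in c("Ca", "Sr", "Ba")) {
      one <- ch
      one$permeabilities <- ch$permeabilities[c("Na", ion)]
      bath <- bath_divalent(ion)
      erev_x <- ghk_erev(one, pip, bath, 22)
      rec <- perm_ratio_divalent(erev_x, a_na_int,
                                 effective_activity(ion, bath), 22)$px_pna
      expect_equal(rec, unname(ch$permeabilities[ion]), tolerance = 0.05,
                   label = paste(nm, ion))
    }
  }
})

test_that("the full pipeline recovers a known permeability ratio", {
  ch <- channel_preset("nsvba")
  ch$permeabilities[["K"]] <- 0.5
  tab <- selectivity_panel(ch, ions = c("Na", "K"),
                          conditions = quiet_conditions(seed = 3))
  expect_equal(tab$px_pna[tab$ion == "K"], 0.5, tolerance = 0.05)
})

test_that("NsvBa panel floors Cs and Mg and passes the alkali ions", {
  tab <- selectivity_panel(channel_preset("nsvba"),
                           ions = c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca"),
                           conditions = recording_conditions(seed = 11))
  expect_true(tab$floored[tab$ion == "Cs"])
  expect_true(tab$floored[tab$ion == "Mg"])
  expect_equal(tab$px_pna[tab$ion == "Cs"], 0.1)
  for (ion in c("Li", "K", "Rb")) {
    expect_false(tab$floored[tab$ion == ion])
    expect_gt(tab$px_pna[tab$ion == ion], 0.7)
    expect_lt(tab$px_pna[tab$ion == ion], 1.5)
  }
  expect_false(tab$floored[tab$ion == "Ca"])
})
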