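# Ion-selectivity inference: I-V fits, reversal potentials, and conversion of
# bi-ionic reversal potentials to relative permeabilities with effective
# activities.
#
# Monovalent: Px/PNa = (a_Na,e / a_x,e) * exp(dErev F / RT), with
# dErev = Erev_x - Erev_Na measured in the same configuration.
# Divalent (Fatt-Ginsborg form):
# Px/PNa = a_Na,i * exp(E F/RT) * (exp(E F/RT) + 1) / (4 a_x,e).
# Both are the exact zero-current solutions of the GHK flux model when Na+ is
# the only permeant internal ion (the pseudo-bi-ionic configuration with
# impermeant internal NMDG+).
#
# Detection floor: conditions with no activatable inward current and a
# measured Erev <= -4 mV report the floor value Px/PNa = 0.1, flagged.

PX_PNA_FLOOR <- 0.1

#' Fit a current-voltage relationship
#'
#' Least-squares fit of \eqn{I(V) = g (V - E_{rev}) / (1 + \exp(-(V -
#' V_{1/2})/k))}: an ohmic driving term gated by a Boltzmann activation
#' factor. `Erev` is the extrapolated reversal potential.
#'
#' @param peaks A `peak_table` from [measure_peaks()] (or any data frame with
#'   `voltage_mV` and `peak_pA`).
#' @return Object of class `iv_fit`: `g_nS`, `erev_mV`, `v_half_mV`, `k_mV`,
#'   `rms_pA`, `ok`, `reason`.
#' @export
fit_iv <- function(peaks) {
  v <- peaks$voltage_mV
  i <- peaks$peak_pA
  fail <- function(reason) {
    structure(list(g_nS = NA_real_, erev_mV = NA_real_, v_half_mV = NA_real_,
                   k_mV = NA_real_, rms_pA = NA_real_, ok = FALSE,
                   reason = reason), class = "iv_fit")
  }
  if (length(v) < 5) return(fail("fewer than 5 points"))
  # a straight line (pure leak) carries no gating information: flag rather
  # than return an unconstrained sigmoid
  line <- stats::lm(i ~ v)
  r2_line <- suppressWarnings(summary(line))$r.squared
  if (stats::var(i) == 0 || r2_line > 0.999) {
    return(fail("no curvature beyond a straight line"))
  }
  erev0 <- zero_crossing(v, i)
  if (is.na(erev0)) erev0 <- max(v) + 10
  hi <- v >= stats::median(v)
  g0 <- tryCatch(abs(stats::coef(stats::lm(i[hi] ~ v[hi]))[[2]]),
                 error = function(e) 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      i ~ g * (v - erev) / (1 + exp(-(v - vh) / k)),
      start = list(g = max(g0, 1e-3), erev = erev0,
                   vh = stats::median(v) - 10, k = 8),
      lower = c(1e-6, min(v) - 200, min(v) - 200, 0.5),
      upper = c(Inf, max(v) + 200, max(v) + 100, 100),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("fit did not converge"))
  p <- stats::coef(fit)
  # degenerate: activation factor essentially constant over the data range
  # (straight line carries no gating information)
  gate <- 1 / (1 + exp(-(range(v) - p[["vh"]]) / p[["k"]]))
  if (diff(gate) < 0.05) return(fail("no voltage-dependent activation"))
  # when the measured I-V brackets zero current, the interpolated crossing is
  # a better-conditioned Erev than the least-squares parameter (which is
  # dominated by the large-current limb); keep the fit value only for true
  # extrapolation beyond the sampled range
  if (!is.na(erev0) && erev0 >= min(v) && erev0 <= max(v)) {
    p[["erev"]] <- refine_crossing(v, i, erev0)
  }
  structure(
    list(g_nS = unname(p[["g"]]), erev_mV = unname(p[["erev"]]),
         v_half_mV = unname(p[["vh"]]), k_mV = unname(p[["k"]]),
         rms_pA = sqrt(mean(stats::resid(fit)^2)), ok = TRUE, reason = NULL),
    class = "iv_fit"
  )
}

# local straight-line refinement of a zero crossing: averages measurement
# noise over the points nearest the coarse crossing
refine_crossing <- function(v, i, v0, window_mV = 15) {
  sel <- abs(v - v0) <= window_mV
  if (sum(sel) < 2) return(v0)
  co <- stats::coef(stats::lm(i[sel] ~ v[sel]))
  if (!is.finite(co[[2]]) || co[[2]] == 0) return(v0)
  -co[[1]] / co[[2]]
}

# linear interpolation of the zero crossing of i(v); NA when no sign change
zero_crossing <- function(v, i) {
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  s <- which(i[-1] * i[-length(i)] <= 0 & i[-1] != i[-length(i)])
  if (!length(s)) return(NA_real_)
  k <- s[length(s)]
  v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Reversal potential from a linear fit of the outward limb
#'
#' Straight-line fit of peak current over a voltage range (default 0 to
#' 60 mV); the zero-current potential, corrected by subtracting the
#' liquid-junction potential.
#'
#' @param peaks A `peak_table`.
#' @param v_range Voltage range used for the fit, mV.
#' @param ljp Liquid-junction potential to subtract, mV.
#' @return List: `erev_mV` (LJP-corrected), `slope_nS`, `ok`, `reason`.
#' @export
#' @examples
#' pk <- data.frame(voltage_mV = seq(0, 60, 10),
#'                  peak_pA = 1.5 * (seq(0, 60, 10) - 43))
#' erev_linear(pk)$erev_mV # 43
erev_linear <- function(peaks, v_range = c(0, 60), ljp = 0) {
  sel <- peaks$voltage_mV >= v_range[1] & peaks$voltage_mV <= v_range[2]
  if (sum(sel) < 2) {
    return(list(erev_mV = NA_real_, slope_nS = NA_real_, ok = FALSE,
                reason = "fewer than 2 points in range"))
  }
  co <- stats::coef(stats::lm(peak_pA ~ voltage_mV, data = peaks[sel, ]))
  if (co[[2]] <= 0) {
    return(list(erev_mV = NA_real_, slope_nS = co[[2]], ok = FALSE,
                reason = "non-positive slope"))
  }
  list(erev_mV = -co[[1]] / co[[2]] - ljp, slope_nS = co[[2]], ok = TRUE,
       reason = NULL)
}

# shared floor logic
apply_floor <- function(px_pna, erev_mV, has_inward_current) {
  floored <- !has_inward_current && !is.na(erev_mV) && erev_mV <= -4
  if (floored) px_pna <- PX_PNA_FLOOR
  list(px_pna = px_pna, floored = floored)
}

#' Relative permeability of a monovalent cation from bi-ionic Erev
#'
#' \eqn{P_x/P_{Na} = (\alpha_{Na,e}/\alpha_{x,e}) \exp(\Delta E_{rev} F/RT)}
#' with \eqn{\Delta E_{rev} = E_{rev,x} - E_{rev,Na}}. When the test condition
#' shows no activatable inward current and its measured Erev is <= -4 mV, the
#' detection floor (0.1) is reported with `floored = TRUE`.
#'
#' @param delta_erev_mV Erev difference (test - Na reference), mV,
#'   LJP-corrected.
#' @param alpha_na_ext,alpha_x_ext External effective activities of Na+ and
#'   the test ion, mM.
#' @param temp_c Bath temperature for RT/F, degC.
#' @param erev_mV Absolute Erev of the test condition (floor trigger), mV.
#' @param has_inward_current Was a clear voltage-activated inward current
#'   seen in the test condition?
#' @param ion Test-ion label carried into the result.
#' @return Object of class `permeability_result`.
#' @export
#' @examples
#' perm_ratio_monovalent(0, 111, 111, 22)$px_pna # 1
perm_ratio_monovalent <- function(delta_erev_mV, alpha_na_ext, alpha_x_ext,
                                  temp_c = 22, erev_mV = NA_real_,
                                  has_inward_current = TRUE, ion = "X") {
  if (alpha_na_ext <= 0 || alpha_x_ext <= 0) {
    stop("activities must be positive")
  }
  px <- (alpha_na_ext / alpha_x_ext) *
    exp(delta_erev_mV / rt_over_f(temp_c))
  fl <- apply_floor(px, erev_mV, has_inward_current)
  structure(
    list(ion = ion, valence = 1, erev_mV = erev_mV,
         delta_erev_mV = delta_erev_mV, alpha_external_mM = alpha_x_ext,
         alpha_internal_mM = NA_real_, px_pna = fl$px_pna,
         floored = fl$floored),
    class = "permeability_result"
  )
}

#' Relative permeability of a divalent cation from bi-ionic Erev
#'
#' Fatt-Ginsborg form: \eqn{P_x/P_{Na} = \alpha_{Na,i}\, e^{u}(e^{u}+1) /
#' (4 \alpha_{x,e})} with \eqn{u = E_{rev} F/RT}. Floor logic as in
#' [perm_ratio_monovalent()].
#'
#' @param erev_mV Absolute (LJP-corrected) reversal potential in the divalent
#'   bath, mV.
#' @param alpha_na_int Internal Na+ effective activity, mM.
#' @param alpha_x_ext External effective activity of the divalent ion, mM.
#' @inheritParams perm_ratio_monovalent
#' @return Object of class `permeability_result`.
#' @export
perm_ratio_divalent <- function(erev_mV, alpha_na_int, alpha_x_ext,
                                temp_c = 22, has_inward_current = TRUE,
                                ion = "X") {
  if (alpha_na_int <= 0 || alpha_x_ext <= 0) {
    stop("activities must be positive")
  }
  eu <- exp(erev_mV / rt_over_f(temp_c))
  px <- alpha_na_int * eu * (eu + 1) / (4 * alpha_x_ext)
  fl <- apply_floor(px, erev_mV, has_inward_current)
  structure(
    list(ion = ion, valence = 2, erev_mV = erev_mV, delta_erev_mV = NA_real_,
         alpha_external_mM = alpha_x_ext, alpha_internal_mM = alpha_na_int,
         px_pna = fl$px_pna, floored = fl$floored),
    class = "permeability_result"
  )
}

#' Full selectivity pipeline for one channel
#'
#' Simulates the ion-substitution panel (bi-ionic baths against the standard
#' NMDG/Na pipette), P/4-subtracts, measures peaks, extracts each condition's
#' reversal potential from the I-V fit, and converts to Px/PNa against the
#' Na+ reference condition. The panel's "no inward current" criterion is a
#' peak inward current smaller in magnitude than `inward_threshold_pA`.
#'
#' @param channel A [channel_model()].
#' @param ions Character vector of test cations (monovalent and/or divalent).
#' @param conditions A [recording_conditions()].
#' @param levels Step levels of the activation protocol, mV.
#' @param inward_threshold_pA Minimum peak inward current magnitude counting
#'   as an activatable inward current, pA.
#' @param ljp Named numeric of per-bath liquid-junction potentials, mV
#'   (default all 0).
#' @return Data frame (`ion`, `z`, `erev_mV`, `dErev_mV`, `alpha_ext_mM`,
#'   `px_pna`, `floored`), one row per test ion: the per-channel selectivity
#'   summary table.
#' @export
selectivity_panel <- function(channel, ions = c("Li", "Na", "K", "Rb", "Cs"),
                              conditions = recording_conditions(seed = 1),
                              levels = seq(-100, 80, 10),
                              inward_threshold_pA = 100, ljp = NULL) {
  pip <- pipette_standard()
  alpha_na_int <- effective_activity("Na", pip)
  measure_one <- function(ion) {
    z <- ion_valence(ion)
    bath <- if (z == 1) bath_monovalent(ion) else bath_divalent(ion)
    if (!is.null(ljp) && ion %in% names(ljp)) bath$ljp <- ljp[[ion]]
    lv <- levels
    repeat {
      pr <- build_protocol("step", holding = -140, levels = lv,
                           dur_ms = 250, dt_ms = 0.05)
      ss <- simulate_whole_cell(channel, pr, pip, bath, conditions, p4 = TRUE)
      pk <- measure_peaks(p4_subtract(ss), polarity = "auto")
      # extend the step family until the I-V brackets zero current (or the
      # command limit is reached), as one would at the rig
      if (!is.na(zero_crossing(pk$voltage_mV, pk$peak_pA)) ||
          max(lv) >= 140) break
      lv <- c(lv, seq(max(lv) + 10, min(max(lv) + 30, 140), 10))
    }
    ivf <- fit_iv(pk)
    erev <- if (ivf$ok) ivf$erev_mV - bath$ljp else
      erev_linear(pk, ljp = bath$ljp)$erev_mV
    list(ion = ion, z = z, erev = erev,
         has_inward = min(pk$peak_pA) < -abs(inward_threshold_pA),
         alpha_ext = effective_activity(ion, bath))
  }
  na_ref <- measure_one("Na")
  rows <- lapply(ions, function(ion) {
    m <- if (ion == "Na") na_ref else measure_one(ion)
    if (m$z == 1) {
      pr <- perm_ratio_monovalent(
        m$erev - na_ref$erev, na_ref$alpha_ext, m$alpha_ext,
        temp_c = conditions$temperature, erev_mV = m$erev,
        has_inward_current = m$has_inward, ion = ion)
    } else {
      pr <- perm_ratio_divalent(
        m$erev, alpha_na_int, m$alpha_ext,
        temp_c = conditions$temperature,
        has_inward_current = m$has_inward, ion = ion)
    }
    data.frame(ion = ion, z = m$z, erev_mV = m$erev,
               dErev_mV = m$erev - na_ref$erev, alpha_ext_mM = m$alpha_ext,
               px_pna = pr$px_pna, floored = pr$floored)
  })
  do.call(rbind, rows)
}

#' Write a selectivity summary table as delimited text
#' @param table Output of [selectivity_panel()].
#' @param path Output file.
#' @export
write_selectivity_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
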