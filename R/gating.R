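# Voltage dependence and thermodynamics: Boltzmann fits, single-channel
# conductance, Q10/Arrhenius analysis, depolarization energy barrier.

#' Fit a Boltzmann (two-asymptote sigmoid) to voltage-response data
#'
#' \eqn{y(V) = I_{min} + (I_{max} - I_{min}) / (1 + \exp(s (V - V_{1/2})/k))}
#' with \eqn{s = -1} for activation (rising with depolarization) and
#' \eqn{s = +1} for inactivation (falling). Data without a plateau on either
#' side (e.g. strictly linear responses) are flagged as failures.
#'
#' @param v Voltages, mV.
#' @param y Normalized responses (conductance or current).
#' @param direction `"activation"` or `"inactivation"`.
#' @return Object of class `boltzmann_fit`: `imax`, `imin`, `v_half_mV`,
#'   `k_mV`, `direction`, `rms`, `ok`, `reason`.
#' @export
#' @examples
#' v <- seq(-120, 20, 10)
#' fit_boltzmann(v, 1 / (1 + exp(-(v + 40) / 8)), "activation")$v_half_mV
fit_boltzmann <- function(v, y, direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  s <- if (direction == "activation") -1 else 1
  fail <- function(reason) {
    structure(list(imax = NA_real_, imin = NA_real_, v_half_mV = NA_real_,
                   k_mV = NA_real_, direction = direction, rms = NA_real_,
                   ok = FALSE, reason = reason), class = "boltzmann_fit")
  }
  if (length(v) < 5) return(fail("fewer than 5 points"))
  vh0 <- tryCatch(zero_crossing(v, y - (max(y) + min(y)) / 2),
                  error = function(e) NA_real_)
  if (is.na(vh0)) vh0 <- stats::median(v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ imin + (imax - imin) / (1 + exp(s * (v - vh) / k)),
      start = list(imax = max(y), imin = min(y), vh = vh0, k = 8),
      lower = c(-Inf, -Inf, min(v) - 150, 0.1),
      upper = c(Inf, Inf, max(v) + 150, 200),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("fit did not converge"))
  p <- stats::coef(fit)
  if (p[["imax"]] <= p[["imin"]]) return(fail("inverted asymptotes"))
  # sigmoid must actually turn over inside (or near) the sampled range
  gate <- 1 / (1 + exp(s * (range(v) - p[["vh"]]) / p[["k"]]))
  if (abs(diff(gate)) < 0.2) return(fail("no sigmoidal saturation in range"))
  structure(
    list(imax = unname(p[["imax"]]), imin = unname(p[["imin"]]),
         v_half_mV = unname(p[["vh"]]), k_mV = unname(p[["k"]]),
         direction = direction, rms = sqrt(mean(stats::resid(fit)^2)),
         ok = TRUE, reason = NULL),
    class = "boltzmann_fit"
  )
}

#' Convert peak currents to normalized chord conductance
#'
#' \eqn{G = I / (V - E_{rev})}, normalized to its maximum. Rows with
#' \eqn{V = E_{rev}} are dropped with a warning.
#'
#' @param peaks A `peak_table`.
#' @param erev_mV Reversal potential, mV.
#' @return Data frame with `voltage_mV` and `g_norm`.
#' @export
conductance_transform <- function(peaks, erev_mV) {
  keep <- peaks$voltage_mV != erev_mV
  if (any(!keep)) warning("dropping row(s) at V = Erev")
  v <- peaks$voltage_mV[keep]
  g <- peaks$peak_pA[keep] / (v - erev_mV)
  data.frame(voltage_mV = v, g_norm = g / max(g))
}

#' Single-channel conductance from open-level amplitudes
#'
#' Ordinary least-squares slope of mean open amplitude (pA) versus holding
#' potential (mV), converted to pS.
#'
#' @param level_mV Holding potentials, mV (at least 3).
#' @param amplitude_pA Mean open-level amplitudes, pA.
#' @return List: `conductance_pS`, `se_pS`, `erev_mV` (extrapolated zero-
#'   amplitude potential, NA for a flat fit).
#' @export
#' @examples
#' single_channel_conductance(c(-100, -80, -60), c(-3, -2.4, -1.8))
single_channel_conductance <- function(level_mV, amplitude_pA) {
  if (length(level_mV) < 3) stop("need at least 3 voltages")
  fit <- stats::lm(amplitude_pA ~ level_mV)
  co <- suppressWarnings(summary(fit))$coefficients # exact fits are fine here
  slope <- co[2, 1]
  list(conductance_pS = 1000 * slope, se_pS = 1000 * co[2, 2],
       erev_mV = if (slope != 0) -co[1, 1] / slope else NA_real_)
}

#' Q10 temperature coefficient of peak rates or currents
#'
#' Arrhenius-style analysis: a linear regression of \eqn{\log_{10} R} on
#' temperature gives \eqn{Q_{10} = 10^{10\,\mathrm{slope}}} (the default,
#' matching Arrhenius plots); the two-point form
#' \eqn{(R_2/R_1)^{10/(T_2-T_1)}} between the series extremes is reported
#' alongside and is identical for a two-point series.
#'
#' @param temp_c Temperatures, degC (at least 2 spanning >= 5 degC).
#' @param rate Peak rates or peak current magnitudes (> 0).
#' @param label Optional condition label (e.g. the pH) carried through.
#' @return Object of class `q10_result`: `q10` (regression), `q10_two_point`,
#'   `slope_log10_per_C`, `n`, `label`.
#' @export
#' @examples
#' q10_analysis(c(20, 30), c(1, 4))$q10 # 4
q10_analysis <- function(temp_c, rate, label = NULL) {
  stopifnot(length(temp_c) == length(rate))
  if (any(rate <= 0)) stop("rates must be positive")
  if (length(temp_c) < 2 || diff(range(temp_c)) < 5) {
    stop("need >= 2 temperatures spanning at least 5 degC")
  }
  ord <- order(temp_c)
  temp_c <- temp_c[ord]; rate <- rate[ord]
  slope <- stats::coef(stats::lm(log10(rate) ~ temp_c))[[2]]
  n <- length(rate)
  q2 <- (rate[n] / rate[1])^(10 / (temp_c[n] - temp_c[1]))
  structure(
    list(q10 = 10^(10 * slope), q10_two_point = q2,
         slope_log10_per_C = slope, n = n, label = label,
         temp_c = temp_c, rate = rate),
    class = "q10_result"
  )
}

#' Electrical work to depolarize a gating charge across a potential gap
#'
#' \eqn{W = z F \Delta\Psi}, converted to kcal/mol. The signed value follows
#' the convention that the barrier separating the resting potential from the
#' activation threshold is reported as negative; the magnitude is also
#' returned. For a 140 mV gap and unit charge the magnitude is 3.23 kcal/mol.
#'
#' @param delta_psi_mV Potential gap, mV.
#' @param z Charge number.
#' @return Object of class `barrier_result`: `delta_psi_mV`, `z`,
#'   `work_kcal_mol` (signed), `magnitude_kcal_mol`.
#' @export
#' @examples
#' activation_energy_barrier(140, 1)$magnitude_kcal_mol # ~3.23
activation_energy_barrier <- function(delta_psi_mV, z = 1) {
  k <- phys_constants()
  mag <- abs(z) * k$F * abs(delta_psi_mV) / 1000 / k$J_per_kcal
  structure(
    list(delta_psi_mV = delta_psi_mV, z = z,
         work_kcal_mol = -mag * sign(delta_psi_mV) * sign(z),
         magnitude_kcal_mol = mag),
    class = "barrier_result"
  )
}

#' Gating summary for a channel under one condition
#'
#' Simulates the activation family, converts peaks to conductance, fits the
#' activation Boltzmann and the inactivation time constant at 0 mV.
#'
#' @param channel A [channel_model()].
#' @param conditions A [recording_conditions()].
#' @param pH External pH of the bath.
#' @param levels Step levels, mV.
#' @return One-row data frame: `channel`, `temp_c`, `pH`, `v_half_act_mV`,
#'   `k_mV`, `tau_inact_ms`.
#' @export
gating_summary <- function(channel, conditions = recording_conditions(seed = 1),
                           pH = 7.4, levels = seq(-140, 20, 10)) {
  prot <- build_protocol("step", holding = -160, levels = levels,
                         dur_ms = 300, dt_ms = 0.05)
  bath <- bath_monovalent("Na", pH = pH)
  ss <- simulate_whole_cell(channel, prot, pipette_standard(), bath,
                            conditions, p4 = TRUE)
  pk <- measure_peaks(p4_subtract(ss), polarity = "inward")
  erev <- ghk_erev(apply_modulation(channel, conditions$temperature, pH),
                   pipette_standard(), bath, conditions$temperature)
  gv <- conductance_transform(pk, erev)
  bf <- fit_boltzmann(gv$voltage_mV, gv$g_norm, "activation")
  # tau at a 0 mV step
  prot0 <- build_protocol("step", holding = -140, levels = 0, dur_ms = 500,
                          dt_ms = 0.05)
  ss0 <- simulate_whole_cell(channel, prot0, pipette_standard(), bath,
                             conditions, p4 = TRUE)
  tf <- sweep_inactivation_tau(p4_subtract(ss0), 1, polarity = "inward")
  data.frame(channel = channel$name, temp_c = conditions$temperature,
             pH = pH, v_half_act_mV = bf$v_half_mV, k_mV = bf$k_mV,
             tau_inact_ms = tf$tau_ms)
}
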