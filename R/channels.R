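# Channel models: gating parameters, permeabilities, modulation and block.
#
# A channel_model is the simulator's ground truth and the recovery target for
# every analysis stage. Gating follows a one-activation-gate x one-
# inactivation-gate (m1h) scheme with Boltzmann steady states; time constants
# are bell-shaped in voltage (sech curves) anchored to their value at 0 mV.
# Temperature and pH act linearly and additively on the activation midpoint,
# and temperature scales the permeability through a Q10 factor.

#' Gating parameters for the two-gate (m1h) scheme
#'
#' @param v_half_act,slope_act Activation midpoint (mV) and slope factor (mV).
#' @param v_half_inact,slope_inact Inactivation midpoint and slope (mV).
#' @param tau_act_ms Activation time constant at 0 mV (ms).
#' @param tau_inact_ms Inactivation time constant at 0 mV (ms).
#' @param tau_act_width,tau_inact_width Voltage width (mV) of the sech-shaped
#'   tau(V) bell, centred at 0 mV.
#' @param tau_floor_ms Lower bound on both time constants (ms).
#' @param q10_gating Q10 applied to gating rates (time constants shrink with
#'   warming).
#' @param dvhalf_dT Linear shift of the activation midpoint, mV per degC.
#' @param dvhalf_dpH Linear shift of the activation midpoint, mV per external
#'   pH unit.
#' @return Object of class `gating_params`.
#' @export
gating_params <- function(v_half_act, slope_act, v_half_inact, slope_inact,
                          tau_act_ms = 2, tau_inact_ms = 50,
                          tau_act_width = 60, tau_inact_width = 80,
                          tau_floor_ms = 0.5, q10_gating = 3,
                          dvhalf_dT = 0, dvhalf_dpH = 0) {
  stopifnot(slope_act > 0, slope_inact > 0, tau_act_ms > 0, tau_inact_ms > 0,
            tau_act_width > 0, tau_inact_width > 0, tau_floor_ms > 0,
            q10_gating > 0)
  structure(
    list(v_half_act = v_half_act, slope_act = slope_act,
         v_half_inact = v_half_inact, slope_inact = slope_inact,
         tau_act_ms = tau_act_ms, tau_inact_ms = tau_inact_ms,
         tau_act_width = tau_act_width, tau_inact_width = tau_inact_width,
         tau_floor_ms = tau_floor_ms, q10_gating = q10_gating,
         dvhalf_dT = dvhalf_dT, dvhalf_dpH = dvhalf_dpH),
    class = "gating_params"
  )
}

#' Define a channel model
#'
#' @param name Channel label.
#' @param gating A [gating_params()] object.
#' @param permeabilities Named numeric vector of relative permeabilities
#'   Px/PNa (PNa = 1). Ions absent from the map are impermeant.
#' @param p_max Maximal permeability scale; arbitrary units chosen so that
#'   currents are in pA at the standard solution activities.
#' @param single_channel_conductance Named numeric vector, pS per ion.
#' @param drug_sensitivity Named list of `c(ic50_uM, hill_n)` per drug.
#' @param q10_permeation Q10 applied to `p_max` (peak-current temperature
#'   sensitivity).
#' @param reference_temperature Reference temperature, degC.
#' @param reference_pH Reference external pH.
#' @return Object of class `channel_model`.
#' @export
channel_model <- function(name, gating, permeabilities, p_max,
                          single_channel_conductance = numeric(0),
                          drug_sensitivity = list(),
                          q10_permeation = 1,
                          reference_temperature = 22, reference_pH = 7.4) {
  stopifnot(inherits(gating, "gating_params"), p_max > 0,
            all(permeabilities >= 0), q10_permeation > 0)
  if (length(single_channel_conductance)) {
    stopifnot(all(single_channel_conductance > 0))
  }
  for (d in drug_sensitivity) stopifnot(length(d) == 2, all(d > 0))
  structure(
    list(name = name, gating = gating, permeabilities = permeabilities,
         p_max = p_max,
         single_channel_conductance = single_channel_conductance,
         drug_sensitivity = drug_sensitivity,
         q10_permeation = q10_permeation,
         reference_temperature = reference_temperature,
         reference_pH = reference_pH,
         sc_open_rate = 0.1, sc_close_rate = 0.3),
    class = "channel_model"
  )
}

#' Built-in channel presets
#'
#' Presets emulating the alkaliphilic Bacillus channels NsvBa (nonselective),
#' NaChBac and NavBp (Na+-selective), plus an hNav1.1-like control with low
#' temperature and pH sensitivity. Selectivity ratios, inactivation time
#' constants at 0 mV (42/78 ms), single-channel conductances (30/36 pS),
#' temperature shifts (-19 to -24 mV over 20-37 degC), pH shifts (-28 to
#' -34 mV over pH 7.4-9.4) and the combined-modulation midpoints
#' (-95/-102/-100 mV at 37 degC + pH 9.4) follow the reported biophysics of
#' these channels; activation kinetics and drug IC50s (tamoxifen 30 uM,
#' nifedipine 100 uM, lidocaine 300 uM, Hill n = 1) are round simulator
#' defaults, not measured values.
#'
#' @param name One of `"nsvba"`, `"nachbac"`, `"navbp"`, `"hnav1.1"`.
#' @return A [channel_model()].
#' @export
#' @examples
#' channel_preset("nsvba")$gating$v_half_act
channel_preset <- function(name = c("nsvba", "nachbac", "navbp", "hnav1.1")) {
  name <- match.arg(name)
  drugs <- list(tamoxifen = c(ic50_uM = 30, hill_n = 1),
                nifedipine = c(ic50_uM = 100, hill_n = 1),
                lidocaine = c(ic50_uM = 300, hill_n = 1))
  switch(
    name,
    nsvba = channel_model(
      name = "NsvBa",
      gating = gating_params(
        v_half_act = -43.5, slope_act = 8,
        v_half_inact = -60, slope_inact = 6,
        tau_act_ms = 2, tau_inact_ms = 42,
        dvhalf_dT = -1.3, dvhalf_dpH = -16),
      permeabilities = c(Na = 1, Li = 0.9, K = 1.15, Rb = 0.9,
                         Cs = 0.02, Mg = 0.02, Ca = 0.8, Sr = 0.6, Ba = 0.6),
      p_max = 18.7,
      single_channel_conductance = c(Na = 30, K = 36),
      drug_sensitivity = drugs,
      q10_permeation = 4.0),
    nachbac = channel_model(
      name = "NaChBac",
      gating = gating_params(
        v_half_act = -51, slope_act = 8,
        v_half_inact = -65, slope_inact = 6,
        tau_act_ms = 2, tau_inact_ms = 78,
        dvhalf_dT = -1.2, dvhalf_dpH = -16.5),
      permeabilities = c(Na = 1, Li = 0.9, K = 0.02, Rb = 0.02, Cs = 0.02,
                         Mg = 0.02, Ca = 0.05, Sr = 0.05, Ba = 0.05),
      p_max = 16,
      single_channel_conductance = c(Na = 30),
      drug_sensitivity = drugs,
      q10_permeation = 4.0),
    navbp = channel_model(
      name = "NavBp",
      gating = gating_params(
        v_half_act = -51.25, slope_act = 8,
        v_half_inact = -65, slope_inact = 6,
        tau_act_ms = 3, tau_inact_ms = 150,
        dvhalf_dT = -1.25, dvhalf_dpH = -15),
      permeabilities = c(Na = 1, Li = 0.9, K = 0.02, Rb = 0.02, Cs = 0.02,
                         Mg = 0.02, Ca = 0.05, Sr = 0.05, Ba = 0.05),
      p_max = 16,
      single_channel_conductance = c(Na = 30),
      drug_sensitivity = drugs,
      q10_permeation = 3.8),
    "hnav1.1" = channel_model(
      name = "hNav1.1",
      gating = gating_params(
        v_half_act = -25, slope_act = 6,
        v_half_inact = -55, slope_inact = 6,
        tau_act_ms = 0.3, tau_inact_ms = 1,
        tau_floor_ms = 0.1,
        dvhalf_dT = -0.2, dvhalf_dpH = -3),
      permeabilities = c(Na = 1, Li = 0.9, K = 0.05, Rb = 0.02, Cs = 0.02,
                         Mg = 0.02, Ca = 0.02, Sr = 0.02, Ba = 0.02),
      p_max = 16,
      single_channel_conductance = c(Na = 17),
      drug_sensitivity = drugs,
      q10_permeation = 1.3)
  )
}

#' Apply temperature and pH modulation to a channel
#'
#' Pure function: returns a copy with the activation midpoint shifted by
#' `dvhalf_dT * (T - T_ref) + dvhalf_dpH * (pH - pH_ref)` (the linear additive
#' model), `p_max` scaled by `q10_permeation^((T - T_ref)/10)`, and gating
#' time constants scaled by `q10_gating^(-(T - T_ref)/10)`. Inputs outside the
#' simulator's validity ranges (15-45 degC, pH 5-12) are clamped with a
#' warning.
#'
#' @param channel A [channel_model()].
#' @param temp_c Bath temperature, degC.
#' @param pH External pH.
#' @return A modified copy of `channel`.
#' @export
#' @examples
#' ch <- apply_modulation(channel_preset("nsvba"), temp_c = 37, pH = 9.4)
#' ch$gating$v_half_act # -95 mV
apply_modulation <- function(channel, temp_c, pH) {
  stopifnot(inherits(channel, "channel_model"))
  if (temp_c < 15 || temp_c > 45) {
    warning("temperature clamped to [15, 45] degC")
    temp_c <- min(max(temp_c, 15), 45)
  }
  if (pH < 5 || pH > 12) {
    warning("pH clamped to [5, 12]")
    pH <- min(max(pH, 5), 12)
  }
  g <- channel$gating
  dT <- temp_c - channel$reference_temperature
  dpH <- pH - channel$reference_pH
  g$v_half_act <- g$v_half_act + g$dvhalf_dT * dT + g$dvhalf_dpH * dpH
  kin_scale <- g$q10_gating^(-dT / 10)
  g$tau_act_ms <- g$tau_act_ms * kin_scale
  g$tau_inact_ms <- g$tau_inact_ms * kin_scale
  g$tau_floor_ms <- g$tau_floor_ms * kin_scale
  out <- channel
  out$gating <- g
  out$p_max <- channel$p_max * channel$q10_permeation^(dT / 10)
  out$modulated_at <- c(temp_c = temp_c, pH = pH)
  out
}

#' Apply open-pore block by a drug
#'
#' Scales `p_max` by `1 / (1 + (C / IC50)^n)`. Pure function.
#'
#' @param channel A [channel_model()].
#' @param drug Drug name present in the channel's `drug_sensitivity` map.
#' @param concentration_uM Drug concentration in uM.
#' @return A modified copy of `channel`.
#' @export
#' @examples
#' half <- apply_drug(channel_preset("nsvba"), "tamoxifen", 30)
#' half$p_max / channel_preset("nsvba")$p_max # 0.5
apply_drug <- function(channel, drug, concentration_uM) {
  stopifnot(inherits(channel, "channel_model"), concentration_uM >= 0)
  if (!drug %in% names(channel$drug_sensitivity)) {
    stop("unknown drug '", drug, "'; available: ",
         paste(names(channel$drug_sensitivity), collapse = ", "))
  }
  d <- channel$drug_sensitivity[[drug]]
  block <- 1 / (1 + (concentration_uM / d[[1]])^d[[2]])
  out <- channel
  out$p_max <- channel$p_max * block
  out$drug_applied <- list(drug = drug, concentration_uM = concentration_uM,
                           fraction_unblocked = block)
  out
}

# gate steady states and time constants ------------------------------------

m_inf <- function(v, gating) {
  1 / (1 + exp(-(v - gating$v_half_act) / gating$slope_act))
}

h_inf <- function(v, gating) {
  1 / (1 + exp((v - gating$v_half_inact) / gating$slope_inact))
}

# bell-shaped tau(V) anchored at its 0 mV value; sech falls off smoothly on
# both flanks, floored to keep the ODE well-conditioned
tau_bell <- function(v, tau0, width, floor) {
  pmax(floor, tau0 / cosh(v / width))
}

tau_m <- function(v, gating) {
  tau_bell(v, gating$tau_act_ms, gating$tau_act_width, gating$tau_floor_ms)
}

tau_h <- function(v, gating) {
  tau_bell(v, gating$tau_inact_ms, gating$tau_inact_width, gating$tau_floor_ms)
}

#' @export
print.channel_model <- function(x, ...) {
  cat("<channel_model>", x$name, "\n")
  cat("  V1/2 act", x$gating$v_half_act, "mV, k", x$gating$slope_act,
      "mV; tau_inact(0 mV)", x$gating$tau_inact_ms, "ms\n")
  cat("  Px/PNa:", paste(names(x$permeabilities), signif(x$permeabilities, 3),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
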