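# Goldman-Hodgkin-Katz constant-field permeation.
#
# The simulator's open-pore current is the GHK flux summed over permeant
# ions, using effective activities (gamma-corrected free concentrations) on
# each side. Working in the reduced voltage u = F V / (R T), each ion
# contributes
#
#   phi_x = z^2 u (a_i - a_e exp(-z u)) / (1 - exp(-z u))
#
# (activities in mM), and the whole-cell open-pore current is
# I = p_max * sum_x Px/PNa * phi_x, in pA. Zero-current potentials of this
# model are exactly the bi-ionic permeability equations used by the
# selectivity module, which is what makes selectivity round-trips exact.

# per-ion activity table for a channel/solution pairing
ghk_activity_table <- function(channel, internal, external) {
  ions <- names(channel$permeabilities)
  rows <- lapply(ions, function(ion) {
    p <- channel$permeabilities[[ion]]
    ci <- ion_conc(internal, ion)
    ce <- ion_conc(external, ion)
    if (p <= 0 || (ci == 0 && ce == 0)) return(NULL)
    data.frame(
      ion = ion, z = ion_valence(ion), p = p,
      alpha_i = if (ci > 0) effective_activity(ion, internal) else 0,
      alpha_e = if (ce > 0) effective_activity(ion, external) else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# GHK flux factor for one ion, vectorized over u = F V / RT
ghk_phi <- function(u, z, alpha_i, alpha_e) {
  zu <- z * u
  small <- abs(zu) < 1e-6
  out <- numeric(length(u))
  if (any(!small)) {
    ezu <- exp(-zu[!small])
    out[!small] <- z^2 * u[!small] * (alpha_i - alpha_e * ezu) / (1 - ezu)
  }
  if (any(small)) {
    # series limit at u -> 0: z (a_i - a_e) + O(u)
    out[small] <- z * (alpha_i - alpha_e) +
      zu[small] * (alpha_e + (alpha_i - alpha_e) / 2) * z
  }
  out
}

#' Open-pore GHK current of a channel
#'
#' Constant-field flux summed over the channel's permeant ions, scaled by
#' `p_max`. Gating is not applied; this is the fully open pore.
#'
#' @param v_mV Membrane potential(s), mV (vectorized).
#' @param channel A [channel_model()].
#' @param internal,external [solution_composition()] objects.
#' @param temp_c Temperature for RT/F, degC.
#' @return Current(s) in pA.
#' @export
#' @examples
#' ghk_current(0, channel_preset("nsvba"), pipette_standard(),
#'             bath_monovalent("Na"), 22)
ghk_current <- function(v_mV, channel, internal, external, temp_c = 22) {
  tab <- ghk_activity_table(channel, internal, external)
  if (is.null(tab)) {
    warning("no permeant species on either side; current is zero")
    return(rep(0, length(v_mV)))
  }
  u <- v_mV / rt_over_f(temp_c)
  i <- numeric(length(v_mV))
  for (r in seq_len(nrow(tab))) {
    i <- i + tab$p[r] * ghk_phi(u, tab$z[r], tab$alpha_i[r], tab$alpha_e[r])
  }
  channel$p_max * i
}

#' Zero-current (reversal) potential of the GHK model
#'
#' Numeric root of [ghk_current()] over voltage, by bisection-based
#' root-finding. This is the simulator-side ground truth that the
#' selectivity module's closed-form permeability equations are checked
#' against.
#'
#' @inheritParams ghk_current
#' @param interval Search interval in mV.
#' @return Reversal potential in mV.
#' @export
ghk_erev <- function(channel, internal, external, temp_c = 22,
                     interval = c(-250, 250)) {
  f <- function(v) ghk_current(v, channel, internal, external, temp_c)
  lo <- f(interval[1])
  hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    stop("GHK current does not reverse within [", interval[1], ", ",
         interval[2], "] mV")
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}
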