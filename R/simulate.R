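# Synthetic voltage-clamp recordings.
#
# Whole-cell sweeps integrate the m1h gate pair (exponential-Euler; the
# per-step update is exact for piecewise-constant commands), drive the GHK
# open-pore current, and add a linear leak (reversal 0 mV), an RC capacitive
# transient (tau = Ra * Cm) and Gaussian noise. All stochastic output is
# governed by an explicit seed; no global RNG state leaks.

#' Recording conditions for a simulated experiment
#'
#' @param temperature Bath temperature, degC (15 to 45).
#' @param leak_nS Linear leak conductance, nS (reversal at 0 mV).
#' @param capacitance_pF Whole-cell membrane capacitance, pF.
#' @param access_MOhm Access resistance, MOhm (sets the capacitive
#'   time constant tau = Ra * Cm).
#' @param noise_sd_pA Gaussian current-noise standard deviation, pA.
#' @param seed Integer RNG seed; mandatory for any simulation.
#' @return Object of class `recording_conditions`.
#' @export
recording_conditions <- function(temperature = 22, leak_nS = 0.5,
                                 capacitance_pF = 20, access_MOhm = 5,
                                 noise_sd_pA = 2, seed = 1L) {
  stopifnot(temperature >= 15, temperature <= 45, capacitance_pF > 0,
            access_MOhm >= 0, noise_sd_pA >= 0, is.numeric(seed))
  structure(
    list(temperature = temperature, leak_nS = leak_nS,
         capacitance_pF = capacitance_pF, access_MOhm = access_MOhm,
         noise_sd_pA = noise_sd_pA, seed = as.integer(seed)),
    class = "recording_conditions"
  )
}

# exact-per-step gate integration along a voltage trace; returns m*h
integrate_gates <- function(v, dt, gating) {
  nt <- length(v)
  m <- numeric(nt)
  h <- numeric(nt)
  m_prev <- m_inf(v[1], gating)
  h_prev <- h_inf(v[1], gating)
  # vectorized targets/rates, sequential relaxation
  mi <- m_inf(v, gating); hi <- h_inf(v, gating)
  am <- exp(-dt / tau_m(v, gating)); ah <- exp(-dt / tau_h(v, gating))
  for (t in seq_len(nt)) {
    m_prev <- mi[t] + (m_prev - mi[t]) * am[t]
    h_prev <- hi[t] + (h_prev - hi[t]) * ah[t]
    m[t] <- m_prev
    h[t] <- h_prev
  }
  m * h
}

# RC capacitive current response to a command-voltage trace
capacitive_current <- function(v, dt, capacitance_pF, access_MOhm) {
  if (access_MOhm <= 0) return(numeric(length(v)))
  tau <- access_MOhm * capacitance_pF / 1000 # MOhm * pF = us -> ms
  dv <- c(0, diff(v))
  x <- capacitance_pF * dv / tau
  as.numeric(stats::filter(x, exp(-dt / tau), method = "recursive"))
}

# one sweep of raw current for an arbitrary command trace
simulate_trace <- function(v, dt, channel, act_tab, rtf, conditions,
                           leak = TRUE) {
  u <- v / rtf
  ipore <- numeric(length(v))
  if (!is.null(act_tab)) {
    for (r in seq_len(nrow(act_tab))) {
      ipore <- ipore + act_tab$p[r] *
        ghk_phi(u, act_tab$z[r], act_tab$alpha_i[r], act_tab$alpha_e[r])
    }
    ipore <- channel$p_max * ipore * integrate_gates(v, dt, channel$gating)
  }
  i <- ipore +
    capacitive_current(v, dt, conditions$capacitance_pF,
                       conditions$access_MOhm)
  if (leak) i <- i + conditions$leak_nS * v
  if (conditions$noise_sd_pA > 0) {
    i <- i + stats::rnorm(length(v), sd = conditions$noise_sd_pA)
  }
  i
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Integrates the channel's activation/inactivation gates along each command
#' sweep, sums the gated GHK pore current with linear leak and capacitive
#' transients, and adds seeded Gaussian noise. Temperature and external-pH
#' modulation of the channel (midpoint shifts, Q10 scaling of `p_max` and of
#' the gating time constants) is applied automatically from `conditions` and
#' the bath pH. With `p4 = TRUE`, four quarter-amplitude opposite-polarity
#' subsweeps delivered from holding are recorded alongside each sweep for
#' offline P/4 leak subtraction.
#'
#' @param channel A [channel_model()].
#' @param protocol A [build_protocol()] object.
#' @param internal,external [solution_composition()] objects.
#' @param conditions A [recording_conditions()] object (carries the seed).
#' @param p4 Record P/4 subsweeps?
#' @return Object of class `sweep_set`: time base (ms), one current trace
#'   (pA) per sweep, the protocol/solutions/conditions metadata and, when
#'   requested, the subsweeps.
#' @export
#' @examples
#' ss <- simulate_whole_cell(
#'   channel_preset("nsvba"),
#'   build_protocol("step", holding = -140, levels = c(-40, -20, 0)),
#'   pipette_standard(), bath_monovalent("Na"),
#'   recording_conditions(seed = 7, noise_sd_pA = 0))
simulate_whole_cell <- function(channel, protocol, internal, external,
                                conditions, p4 = FALSE) {
  stopifnot(inherits(channel, "channel_model"),
            inherits(protocol, "voltage_protocol"),
            inherits(conditions, "recording_conditions"))
  ch <- apply_modulation(channel, conditions$temperature, external$pH)
  dt <- protocol$dt_ms
  # accuracy guard: the exponential-Euler gate update is exact while the
  # command is constant, so the step-size constraint only binds where the
  # voltage changes within a step (ramp epochs)
  ramps <- Filter(function(e) e$type == "ramp", protocol$epochs)
  if (length(ramps)) {
    vspan <- range(unlist(lapply(ramps, function(e) c(e$v_start, e$v_end))))
    vgrid <- seq(vspan[1], vspan[2], length.out = 200)
    min_tau <- min(tau_m(vgrid, ch$gating), tau_h(vgrid, ch$gating))
    if (dt > 0.2 * min_tau) {
      stop("integration step ", dt, " ms exceeds 0.2 * min(tau) = ",
           signif(0.2 * min_tau, 3), " ms over the ramp; reduce dt_ms")
    }
  }
  act_tab <- if (ch$p_max > 0) ghk_activity_table(ch, internal, external)
             else NULL
  rtf <- rt_over_f(conditions$temperature)
  ns <- protocol$n_sweeps
  local_seed(conditions$seed, {
    tr <- lapply(seq_len(ns), function(s) {
      v <- sweep_voltage(protocol, s)
      main <- simulate_trace(v, dt, ch, act_tab, rtf, conditions)
      subs <- NULL
      if (p4) {
        vsub <- protocol$holding - (v - protocol$holding) / 4
        subs <- vapply(1:4, function(k) {
          simulate_trace(vsub, dt, ch, act_tab, rtf, conditions)
        }, numeric(length(v)))
      }
      list(main = main, subs = subs)
    })
    current <- vapply(tr, `[[`, numeric(length(tr[[1]]$main)), "main")
    colnames(current) <- sprintf("sw%02d", seq_len(ns))
    structure(
      list(time_ms = protocol_time(protocol), current_pA = current,
           protocol = protocol, internal = internal, external = external,
           conditions = conditions, drug = ch$drug_applied,
           channel_name = channel$name,
           subsweeps = if (p4) lapply(tr, `[[`, "subs") else NULL,
           p4_subtracted = FALSE),
      class = "sweep_set"
    )
  })
}

#' Simulate a single-channel record
#'
#' Two-state (closed/open) continuous-time Markov gating at the channel's
#' single-channel opening/closing rates, rendered on the sampling grid. The
#' open-level current is ohmic: conductance x (V - Erev), plus Gaussian
#' noise. Segments at each holding potential are concatenated on one time
#' base.
#'
#' @param channel A [channel_model()] whose `single_channel_conductance`
#'   includes `ion`.
#' @param ion Charge-carrier name (selects the conductance preset).
#' @param levels_mV Holding potential of each segment, mV.
#' @param duration_ms Duration of each segment, ms.
#' @param conditions A [recording_conditions()] (seed, noise, sampling via
#'   `dt_ms`).
#' @param erev_mV Reversal potential of the charge carrier under the
#'   recording solutions, mV.
#' @param dt_ms Sampling interval, ms.
#' @return Object of class `single_channel_record` with the time base,
#'   current (pA), per-sample segment index and open/closed state, and the
#'   true conductance (pS).
#' @export
simulate_single_channel <- function(channel, ion, levels_mV, duration_ms,
                                    conditions, erev_mV = 0, dt_ms = 0.1) {
  stopifnot(inherits(channel, "channel_model"), duration_ms > 0, dt_ms > 0)
  if (!ion %in% names(channel$single_channel_conductance)) {
    stop("no single-channel conductance for ion '", ion, "'; available: ",
         paste(names(channel$single_channel_conductance), collapse = ", "))
  }
  g_pS <- channel$single_channel_conductance[[ion]]
  kon <- channel$sc_open_rate   # per ms
  koff <- channel$sc_close_rate
  n_per_seg <- max(1L, round(duration_ms / dt_ms))
  local_seed(conditions$seed, {
    seg_state <- list()
    for (seg in seq_along(levels_mV)) {
      state <- logical(n_per_seg) # FALSE = closed
      cur <- FALSE
      t_next <- if (kon > 0) stats::rexp(1, kon) else Inf
      t_now <- 0
      for (k in seq_len(n_per_seg)) {
        t_now <- t_now + dt_ms
        while (t_now >= t_next) {
          cur <- !cur
          rate <- if (cur) koff else kon
          t_next <- t_next + if (rate > 0) stats::rexp(1, rate) else Inf
        }
        state[k] <- cur
      }
      seg_state[[seg]] <- state
    }
    open <- unlist(seg_state)
    seg_idx <- rep(seq_along(levels_mV), each = n_per_seg)
    v <- levels_mV[seg_idx]
    i <- open * g_pS * (v - erev_mV) / 1000 # pS * mV = fA -> pA
    if (conditions$noise_sd_pA > 0) {
      i <- i + stats::rnorm(length(i), sd = conditions$noise_sd_pA)
    }
    structure(
      list(time_ms = (seq_along(i) - 1) * dt_ms, current_pA = i,
           segment = seg_idx, level_mV = v, open = open,
           conductance_pS = g_pS, erev_mV = erev_mV,
           conditions = conditions, ion = ion),
      class = "single_channel_record"
    )
  })
}

#' Mean open-level amplitude per holding potential
#'
#' Threshold-crossing idealization: within each segment, samples beyond half
#' of the robust open-level estimate count as open; their mean is the open
#' amplitude. Requires a visible open level (reasonable signal-to-noise).
#'
#' @param record A [simulate_single_channel()] record.
#' @param min_events Minimum open-sample count for a segment to be reported.
#' @return Data frame with `level_mV`, `amplitude_pA`, `n_open_samples`.
#' @export
measure_open_amplitudes <- function(record, min_events = 20) {
  out <- lapply(unique(record$segment), function(seg) {
    sel <- record$segment == seg
    x <- record$current_pA[sel]
    v <- record$level_mV[sel][1]
    amp_est <- stats::quantile(abs(x), 0.999, names = FALSE)
    open <- abs(x) > amp_est / 2
    if (sum(open) < min_events) return(NULL)
    data.frame(level_mV = v, amplitude_pA = mean(x[open]),
               n_open_samples = sum(open))
  })
  do.call(rbind, out)
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set>", x$channel_name, "-", ncol(x$current_pA), "sweep(s) x",
      nrow(x$current_pA), "samples,", x$protocol$kind, "protocol\n")
  cat("  T", x$conditions$temperature, "degC, bath pH", x$external$pH,
      if (!is.null(x$subsweeps)) ", with P/4 subsweeps" else "", "\n")
  invisible(x)
}

#' Peak ramp currents across a temperature series
#'
#' Simulates the ramp protocol at each bath temperature (P/4-subtracted,
#' noise and modulation as configured) and reports the peak inward current
#' magnitude: the input series for Q10/Arrhenius analysis.
#'
#' @param channel A [channel_model()].
#' @param temps_c Bath temperatures, degC.
#' @param pH External pH.
#' @param conditions A [recording_conditions()] template (its temperature is
#'   overridden per point; the seed is offset per temperature).
#' @param ramp_ms Ramp duration, ms.
#' @param v_from,v_to Ramp limits, mV.
#' @return Data frame `temp_c`, `peak_pA_abs`.
#' @export
simulate_ramp_series <- function(channel, temps_c, pH = 7.4,
                                 conditions = recording_conditions(seed = 1),
                                 ramp_ms = 100, v_from = -140, v_to = 60) {
  # step size that satisfies the ramp accuracy guard at the warmest point
  hot <- apply_modulation(channel, max(temps_c), pH)
  vgrid <- seq(min(v_from, v_to), max(v_from, v_to), length.out = 200)
  min_tau <- min(tau_m(vgrid, hot$gating), tau_h(vgrid, hot$gating))
  dt <- min(0.02, 0.15 * min_tau)
  prot <- build_protocol("ramp", holding = -140, v_from = v_from,
                         v_to = v_to, dur_ms = ramp_ms, rate_hz = 0.5,
                         dt_ms = dt)
  pip <- pipette_thermo()
  bath <- bath_monovalent("Na", pH = pH)
  rows <- lapply(seq_along(temps_c), function(k) {
    cond <- conditions
    cond$temperature <- temps_c[k]
    cond$seed <- conditions$seed + k
    ss <- simulate_whole_cell(channel, prot, pip, bath, cond, p4 = TRUE)
    sub <- p4_subtract(ss)
    w <- epoch_window(prot, 2)
    data.frame(temp_c = temps_c[k],
               peak_pA_abs = abs(min(sub$current_pA[w[1]:w[2], 1])))
  })
  do.call(rbind, rows)
}

#' Peak step currents across a temperature series
#'
#' Simulates a fixed depolarizing step (default 0 mV, where activation is
#' saturated for all presets and the GHK driving term is temperature-neutral)
#' at each bath temperature and reports the peak inward current magnitude.
#' Unlike ramp peaks, whose Arrhenius slope compounds the thermal shift of
#' activation with inactivation kinetics, the fixed-step series isolates the
#' permeation Q10 of the channel.
#'
#' @inheritParams simulate_ramp_series
#' @param level_mV Step potential, mV.
#' @param dur_ms Step duration, ms.
#' @return Data frame `temp_c`, `peak_pA_abs`.
#' @export
simulate_step_series <- function(channel, temps_c, pH = 7.4,
                                 conditions = recording_conditions(seed = 1),
                                 level_mV = 0, dur_ms = 400) {
  prot <- build_protocol("step", holding = -140, levels = level_mV,
                         dur_ms = dur_ms, dt_ms = 0.05)
  pip <- pipette_thermo()
  bath <- bath_monovalent("Na", pH = pH)
  rows <- lapply(seq_along(temps_c), function(k) {
    cond <- conditions
    cond$temperature <- temps_c[k]
    cond$seed <- conditions$seed + k
    ss <- simulate_whole_cell(channel, prot, pip, bath, cond, p4 = TRUE)
    pk <- measure_peaks(p4_subtract(ss), polarity = "inward")
    data.frame(temp_c = temps_c[k], peak_pA_abs = abs(pk$peak_pA[1]))
  })
  do.call(rbind, rows)
}
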