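# Voltage-command protocols: families of sweeps built from step, prepulse and
# ramp epochs on a shared time base. Every sweep of a protocol has the same
# epoch layout; one epoch (the "varying" one) changes level across sweeps.

#' Build a voltage protocol
#'
#' @param kind `"step"` (holding, then a family of depolarizing steps),
#'   `"prepulse_test"` (variable prepulse followed by a fixed test pulse), or
#'   `"ramp"` (repeated voltage ramps at a fixed repetition rate).
#' @param holding Holding potential, mV.
#' @param levels Step or prepulse levels, mV (strictly increasing). Ignored
#'   for `"ramp"`.
#' @param dur_ms Duration of the step/prepulse/ramp epoch, ms.
#' @param test_mV,test_ms Test-pulse level and duration for `"prepulse_test"`.
#' @param v_from,v_to Ramp start and end potentials, mV.
#' @param rate_hz Sweep repetition rate for `"ramp"` (sets the sweep period).
#' @param n_sweeps Number of ramp repetitions.
#' @param pre_ms,post_ms Holding segments before and after the active epochs.
#' @param dt_ms Sampling interval, ms.
#' @return Object of class `voltage_protocol`.
#' @export
#' @examples
#' p <- build_protocol("step", holding = -140, levels = seq(-10, 70, 10))
#' n_sweeps(p) # 9
build_protocol <- function(kind = c("step", "prepulse_test", "ramp"),
                           holding = -140, levels = NULL, dur_ms = 500,
                           test_mV = -20, test_ms = 100,
                           v_from = -140, v_to = 60, rate_hz = 0.5,
                           n_sweeps = 1, pre_ms = 10, post_ms = 20,
                           dt_ms = 0.05) {
  kind <- match.arg(kind)
  if (any(c(dur_ms, pre_ms, post_ms, dt_ms) <= 0) ||
      (kind == "prepulse_test" && test_ms <= 0)) {
    stop("invalid protocol: all durations must be > 0")
  }
  if (kind %in% c("step", "prepulse_test")) {
    if (is.null(levels) || length(levels) == 0) {
      stop("invalid protocol: empty level list")
    }
    if (any(diff(levels) <= 0)) {
      stop("invalid protocol: levels must be strictly increasing")
    }
  }
  epochs <- switch(
    kind,
    step = list(
      list(type = "step", dur_ms = pre_ms, v_start = holding, v_end = holding),
      list(type = "step", dur_ms = dur_ms, v_start = levels, v_end = levels,
           varying = TRUE),
      list(type = "step", dur_ms = post_ms, v_start = holding, v_end = holding)
    ),
    prepulse_test = list(
      list(type = "step", dur_ms = pre_ms, v_start = holding, v_end = holding),
      list(type = "step", dur_ms = dur_ms, v_start = levels, v_end = levels,
           varying = TRUE),
      list(type = "step", dur_ms = test_ms, v_start = test_mV, v_end = test_mV),
      list(type = "step", dur_ms = post_ms, v_start = holding, v_end = holding)
    ),
    ramp = list(
      list(type = "step", dur_ms = pre_ms, v_start = holding, v_end = holding),
      list(type = "ramp", dur_ms = dur_ms, v_start = v_from, v_end = v_to),
      list(type = "step", dur_ms = post_ms, v_start = holding, v_end = holding)
    )
  )
  ns <- if (kind == "ramp") n_sweeps else length(levels)
  structure(
    list(kind = kind, holding = holding, epochs = epochs, n_sweeps = ns,
         dt_ms = dt_ms,
         sweep_period_ms = if (kind == "ramp") 1000 / rate_hz else NA_real_,
         levels = if (kind == "ramp") NULL else levels),
    class = "voltage_protocol"
  )
}

#' Number of sweeps in a protocol
#' @param protocol A [build_protocol()] object.
#' @return Integer sweep count.
#' @export
n_sweeps <- function(protocol) protocol$n_sweeps

# epoch level for a given sweep (vector-valued epochs vary across sweeps)
epoch_bounds <- function(epoch, sweep) {
  vs <- if (length(epoch$v_start) > 1) epoch$v_start[sweep] else epoch$v_start
  ve <- if (length(epoch$v_end) > 1) epoch$v_end[sweep] else epoch$v_end
  c(vs, ve)
}

#' Command-voltage trace for one sweep
#'
#' @param protocol A [build_protocol()] object.
#' @param sweep Sweep index.
#' @return Numeric vector of command potentials (mV) on the protocol's time
#'   base (`dt_ms` spacing).
#' @export
sweep_voltage <- function(protocol, sweep = 1) {
  stopifnot(sweep >= 1, sweep <= protocol$n_sweeps)
  dt <- protocol$dt_ms
  v <- numeric(0)
  for (ep in protocol$epochs) {
    n <- max(1L, round(ep$dur_ms / dt))
    b <- epoch_bounds(ep, sweep)
    seg <- if (ep$type == "ramp" && b[1] != b[2]) {
      b[1] + (b[2] - b[1]) * (seq_len(n) - 0.5) / n
    } else {
      rep(b[1], n)
    }
    v <- c(v, seg)
  }
  v
}

#' Time base of a protocol
#' @param protocol A [build_protocol()] object.
#' @return Time in ms at each sample (left edge of each sampling interval).
#' @export
protocol_time <- function(protocol) {
  nt <- length(sweep_voltage(protocol, 1))
  (seq_len(nt) - 1) * protocol$dt_ms
}

#' Per-sweep level of the varying epoch
#' @param protocol A [build_protocol()] object.
#' @return Numeric vector (mV), one entry per sweep; for ramp protocols the
#'   ramp end potential.
#' @export
sweep_levels <- function(protocol) {
  if (protocol$kind == "ramp") {
    rep(protocol$epochs[[2]]$v_end, protocol$n_sweeps)
  } else {
    protocol$levels
  }
}

# start/end sample indices of epoch `i`
epoch_window <- function(protocol, i) {
  dt <- protocol$dt_ms
  lens <- vapply(protocol$epochs,
                 function(ep) max(1L, as.integer(round(ep$dur_ms / dt))), 1L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  c(starts[i], ends[i])
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("<voltage_protocol>", x$kind, "-", x$n_sweeps, "sweep(s), holding",
      x$holding, "mV, dt", x$dt_ms, "ms\n")
  invisible(x)
}
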