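# Raw-sweep processing: P/4 leak subtraction, peak measurement, inactivation
# kinetics.

#' P/4 leak and capacitance subtraction
#'
#' The four quarter-amplitude opposite-polarity subsweeps are baseline-
#' referenced to the holding current, averaged, scaled by -4 (the linear
#' leak/capacitance estimate of the full-amplitude command) and subtracted
#' from the baseline-referenced main sweep. Each sweep's residual holding
#' current is recorded; sweeps with residual leak more negative than -100 pA
#' are QC-flagged (flagged, not excluded).
#'
#' @param raw A [simulate_whole_cell()] `sweep_set` recorded with `p4 = TRUE`
#'   (or read back from disk with its subsweeps).
#' @param qc_limit_pA Residual-holding-current QC threshold, pA.
#' @return The `sweep_set` with leak-subtracted traces, `p4_subtracted =
#'   TRUE`, and a `qc` data frame (`sweep`, `residual_holding_pA`, `flagged`).
#' @export
p4_subtract <- function(raw, qc_limit_pA = -100) {
  stopifnot(inherits(raw, "sweep_set"))
  if (is.null(raw$subsweeps)) {
    stop("no P/4 subsweeps present; re-simulate with p4 = TRUE or analyze ",
         "unsubtracted traces")
  }
  w <- epoch_window(raw$protocol, 1) # pre-step holding segment
  base_idx <- w[1]:w[2]
  ns <- ncol(raw$current_pA)
  corrected <- raw$current_pA
  qc <- data.frame(sweep = seq_len(ns), residual_holding_pA = NA_real_,
                   flagged = FALSE)
  for (s in seq_len(ns)) {
    main <- raw$current_pA[, s]
    subs <- raw$subsweeps[[s]]
    if (is.null(subs) || nrow(subs) != length(main)) {
      stop("subsweeps for sweep ", s, " missing or not aligned to time base")
    }
    b_main <- mean(main[base_idx])
    template <- rowMeans(subs)
    template <- -4 * (template - mean(template[base_idx]))
    corrected[, s] <- (main - b_main) - template
    qc$residual_holding_pA[s] <- b_main
    qc$flagged[s] <- b_main < qc_limit_pA
  }
  out <- raw
  out$current_pA <- corrected
  out$subsweeps <- NULL
  out$p4_subtracted <- TRUE
  out$qc <- qc
  out
}

#' Peak currents of each sweep
#'
#' @param sweeps A `sweep_set`.
#' @param window Analysis window `c(from_ms, to_ms)`; default the varying
#'   (test) epoch of the protocol.
#' @param polarity `"inward"` (most negative), `"outward"` (most positive) or
#'   `"auto"` (larger absolute extremum).
#' @return A `peak_table` data frame: `voltage_mV`, `peak_pA`, `tpeak_ms` and
#'   `density_pA_per_pF`.
#' @export
measure_peaks <- function(sweeps, window = NULL,
                          polarity = c("auto", "inward", "outward")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  polarity <- match.arg(polarity)
  prot <- sweeps$protocol
  t <- sweeps$time_ms
  if (is.null(window)) {
    vary <- which(vapply(prot$epochs, function(e) isTRUE(e$varying), TRUE))
    vary <- if (length(vary)) vary[1] else 2L
    w <- epoch_window(prot, vary)
    idx <- w[1]:w[2]
  } else {
    idx <- which(t >= window[1] & t <= window[2])
    if (!length(idx)) stop("empty analysis window")
  }
  levels <- sweep_levels(prot)
  cm <- sweeps$conditions$capacitance_pF
  out <- lapply(seq_len(ncol(sweeps$current_pA)), function(s) {
    x <- sweeps$current_pA[idx, s]
    k <- switch(polarity,
                inward = which.min(x),
                outward = which.max(x),
                auto = if (abs(min(x)) >= abs(max(x))) which.min(x)
                       else which.max(x))
    data.frame(voltage_mV = levels[s], peak_pA = x[k],
               tpeak_ms = t[idx[k]], density_pA_per_pF = x[k] / cm)
  })
  out <- do.call(rbind, out)
  class(out) <- c("peak_table", class(out))
  out
}

#' Fit a single-exponential inactivation decay
#'
#' Least-squares fit of \eqn{f(t) = B + A \exp(-t/\tau)} to the decaying
#' phase of a trace, reported from the time of peak current onward. Fits
#' that do not converge, or whose time constant exceeds 10x the fitted
#' segment length, are flagged as failures rather than returned silently.
#'
#' @param time_ms,current_pA The trace segment (equal-length vectors). The
#'   fit is referenced to the first sample (t = 0 at segment start).
#' @return Object of class `tau_fit`: `A_pA`, `B_pA`, `tau_ms`, `rms_pA`,
#'   `ok` (logical) and `reason` when flagged.
#' @export
#' @examples
#' t <- seq(0, 200, 0.5)
#' fit_inactivation_tau(t, 10 * exp(-t / 42))$tau_ms
fit_inactivation_tau <- function(time_ms, current_pA) {
  stopifnot(length(time_ms) == length(current_pA))
  fail <- function(reason) {
    structure(list(A_pA = NA_real_, B_pA = NA_real_, tau_ms = NA_real_,
                   rms_pA = NA_real_, ok = FALSE, reason = reason),
              class = "tau_fit")
  }
  if (length(time_ms) < 3) return(fail("fewer than 3 samples"))
  t <- time_ms - time_ms[1]
  y <- current_pA
  span <- max(t)
  a0 <- y[1] - y[length(y)]
  if (abs(a0) < 10 * .Machine$double.eps * max(1, abs(y[1])) ||
      stats::sd(y) == 0) {
    return(fail("no decay amplitude"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ B + A * exp(-t / tau),
      start = list(B = y[length(y)], A = a0, tau = max(span / 5, 1e-3)),
      lower = c(-Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("fit did not converge"))
  p <- stats::coef(fit)
  if (p[["tau"]] > 10 * span) return(fail("tau exceeds 10x segment length"))
  structure(
    list(A_pA = unname(p[["A"]]), B_pA = unname(p[["B"]]),
         tau_ms = unname(p[["tau"]]),
         rms_pA = sqrt(mean(stats::resid(fit)^2)), ok = TRUE, reason = NULL),
    class = "tau_fit"
  )
}

#' Inactivation time constant of one sweep, from its peak onward
#'
#' Convenience wrapper: locates the peak inside the test epoch and fits the
#' decay from the peak to the end of the epoch.
#'
#' @param sweeps A `sweep_set`.
#' @param sweep Sweep index.
#' @param polarity Passed to [measure_peaks()].
#' @return A `tau_fit` (see [fit_inactivation_tau()]).
#' @export
sweep_inactivation_tau <- function(sweeps, sweep = 1, polarity = "auto") {
  prot <- sweeps$protocol
  vary <- which(vapply(prot$epochs, function(e) isTRUE(e$varying), TRUE))
  vary <- if (length(vary)) vary[1] else 2L
  w <- epoch_window(prot, vary)
  x <- sweeps$current_pA[w[1]:w[2], sweep]
  t <- sweeps$time_ms[w[1]:w[2]]
  k <- if (polarity == "outward") which.max(x) else
       if (polarity == "inward") which.min(x) else
       if (abs(min(x)) >= abs(max(x))) which.min(x) else which.max(x)
  fit_inactivation_tau(t[k:length(t)], x[k:length(x)])
}

#' Write a peak table as delimited text
#' @param peaks A `peak_table`.
#' @param path Output file.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
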