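# Hill dose-response analysis: channel block, bacterial growth inhibition,
# and the current-block vs growth-block potency comparison.

#' Percent growth inhibition from absorbance readings
#'
#' \eqn{100 (Ab_{control} - Ab_{drug}) / Ab_{control}} using the maximum
#' 600-nm absorbance of untreated and drug-treated cultures. Negative values
#' (drug-enhanced growth) are reported as-is with a warning.
#'
#' @param ab_control Maximum absorbance of the untreated culture (> 0).
#' @param ab_drug Maximum absorbance of the drug-treated culture (>= 0).
#' @return List: `ab_control`, `ab_drug`, `percent`.
#' @export
#' @examples
#' percent_growth_inhibition(1.0, 0.25)$percent # 75
percent_growth_inhibition <- function(ab_control, ab_drug) {
  if (ab_control <= 0) stop("ab_control must be > 0")
  if (ab_drug < 0) stop("ab_drug must be >= 0")
  pct <- 100 * (ab_control - ab_drug) / ab_control
  if (pct < 0) warning("negative inhibition: drug-enhanced growth")
  list(ab_control = ab_control, ab_drug = ab_drug, percent = pct)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of \eqn{y(C) = 100 / (1 + (EC_{50}/C)^n)} to percent
#' responses (block or inhibition, increasing with dose). Doses flagged as
#' assay artifacts (e.g. drug autofluorescence at the absorbance wavelength)
#' are excluded by default. Fits lacking both a low and a high plateau are
#' flagged low-confidence; all-zero responses are failures.
#'
#' @param dose_uM Doses, uM (at least 4).
#' @param response_pct Responses, percent of maximal effect.
#' @param flagged Logical vector of per-dose artifact flags.
#' @param exclude_flagged Drop flagged points before fitting?
#' @return Object of class `dose_response`: `ec50_uM`, `hill_n`, `rms_pct`,
#'   `ok`, `low_confidence`, `reason`.
#' @export
#' @examples
#' d <- c(10, 30, 100, 300, 1000)
#' fit_hill(d, 100 / (1 + (70 / d)))$ec50_uM # 70
fit_hill <- function(dose_uM, response_pct, flagged = NULL,
                     exclude_flagged = TRUE) {
  stopifnot(length(dose_uM) == length(response_pct))
  if (!is.null(flagged) && exclude_flagged) {
    dose_uM <- dose_uM[!flagged]
    response_pct <- response_pct[!flagged]
  }
  fail <- function(reason) {
    structure(list(ec50_uM = NA_real_, hill_n = NA_real_, rms_pct = NA_real_,
                   ok = FALSE, low_confidence = TRUE, reason = reason),
              class = "dose_response")
  }
  if (length(dose_uM) < 4) return(fail("fewer than 4 dose points"))
  if (any(dose_uM <= 0)) stop("doses must be positive")
  if (all(response_pct <= 0)) return(fail("no response at any dose"))
  mid <- zero_crossing(log10(dose_uM), response_pct - 50)
  ec0 <- if (is.na(mid)) stats::median(dose_uM) else 10^mid
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_pct ~ 100 / (1 + (ec50 / dose_uM)^n),
      start = list(ec50 = ec0, n = 1),
      lower = c(1e-6, 0.05), upper = c(1e9, 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("fit did not converge"))
  p <- stats::coef(fit)
  low_conf <- min(response_pct) > 25 || max(response_pct) < 75
  structure(
    list(ec50_uM = unname(p[["ec50"]]), hill_n = unname(p[["n"]]),
         rms_pct = sqrt(mean(stats::resid(fit)^2)), ok = TRUE,
         low_confidence = low_conf,
         reason = if (low_conf) "plateau coverage incomplete" else NULL),
    class = "dose_response"
  )
}

#' Compare current-block and growth-inhibition potencies
#'
#' Absolute log10 ratio of the two IC50s; potencies within half a log unit
#' flag as concordant (on-target pharmacology).
#'
#' @param ic50_current_uM IC50 for channel current block, uM.
#' @param ic50_growth_uM IC50 for bacterial growth inhibition, uM.
#' @return List: `log10_ratio`, `within_half_log`.
#' @export
#' @examples
#' block_vs_growth_comparison(100, 316)$within_half_log # TRUE (boundary)
block_vs_growth_comparison <- function(ic50_current_uM, ic50_growth_uM) {
  stopifnot(ic50_current_uM > 0, ic50_growth_uM > 0)
  r <- abs(log10(ic50_current_uM / ic50_growth_uM))
  list(log10_ratio = r, within_half_log = r <= 0.5 + 1e-9)
}

#' Simulated dose-response of peak-current block
#'
#' Applies the channel's drug sensitivity at each dose, simulates a 0 mV
#' test pulse, and expresses the reduction of peak inward current as percent
#' block: the voltage-clamp arm of the pharmacology assay.
#'
#' @param channel A [channel_model()].
#' @param drug Drug name in the channel's sensitivity map.
#' @param doses_uM Dose series, uM.
#' @param conditions A [recording_conditions()].
#' @return Data frame `drug`, `dose_uM`, `response_pct`.
#' @export
simulate_block_dose_response <- function(channel, drug, doses_uM,
                                         conditions =
                                           recording_conditions(seed = 1)) {
  prot <- build_protocol("step", holding = -140, levels = 0, dur_ms = 500,
                         dt_ms = 0.05)
  pip <- pipette_standard()
  bath <- bath_monovalent("Na")
  peak_at <- function(ch, seed_offset) {
    cond <- conditions
    cond$seed <- conditions$seed + seed_offset
    ss <- simulate_whole_cell(ch, prot, pip, bath, cond, p4 = TRUE)
    min(measure_peaks(p4_subtract(ss), polarity = "inward")$peak_pA)
  }
  i0 <- peak_at(channel, 0)
  resp <- vapply(seq_along(doses_uM), function(k) {
    ik <- peak_at(apply_drug(channel, drug, doses_uM[k]), k)
    100 * (1 - ik / i0)
  }, 0)
  data.frame(drug = drug, dose_uM = doses_uM, response_pct = resp)
}
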