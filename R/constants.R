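#' Physical constants used throughout the package
#'
#' Gas constant, Faraday constant and the joule/kilocalorie conversion, fixed
#' at their CODATA values. `RT/F` at 22 degC evaluates to about 25.4 mV.
#'
#' @return Named list with elements `R` (J/(mol K)), `F` (C/mol) and
#'   `J_per_kcal` (4184 J).
#' @export
#' @examples
#' phys_constants()$F
phys_constants <- function() {
  list(R = 8.314, F = 96485, J_per_kcal = 4184)
}

#' Thermal voltage RT/F in millivolts
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return RT/F in mV.
#' @export
#' @examples
#' rt_over_f(22) # ~25.4 mV
rt_over_f <- function(temp_c) {
  k <- phys_constants()
  1000 * k$R * (temp_c + 273.15) / k$F
}

# internal: local, restorable seeding so no function leaks global RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
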