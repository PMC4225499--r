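# shared fixtures: quiet noise-free conditions and small standard protocols

quiet_conditions <- function(seed = 1, temperature = 22, noise_sd_pA = 0) {
  recording_conditions(temperature = temperature, noise_sd_pA = noise_sd_pA,
                       seed = seed)
}

step_protocol <- function(levels = seq(-100, 80, 10), dur_ms = 250,
                          holding = -140, dt_ms = 0.05) {
  build_protocol("step", holding = holding, levels = levels, dur_ms = dur_ms,
                 dt_ms = dt_ms)
}

# closed-form bi-ionic zero-current potentials used as independent oracles
# (written directly from the permeability equations, not via package code)
erev_biionic_mono <- function(p_x, alpha_x_ext, alpha_na_int, temp_c) {
  rtf <- 1000 * 8.314 * (temp_c + 273.15) / 96485
  rtf * log(p_x * alpha_x_ext / alpha_na_int)
}

erev_biionic_div <- function(p_x, alpha_x_ext, alpha_na_int, temp_c) {
  rtf <- 1000 * 8.314 * (temp_c + 273.15) / 96485
  # solve e^u (e^u + 1) = 4 p alpha_e / alpha_i for u
  rhs <- 4 * p_x * alpha_x_ext / alpha_na_int
  x <- (-1 + sqrt(1 + 4 * rhs)) / 2
  rtf * log(x)
}
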