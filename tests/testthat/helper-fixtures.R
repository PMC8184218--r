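## shared fixture builders; everything is generated in code, no stored data

## minimal single-step protocol for fast unit tests
tiny_protocol <- function(step_mV = -100, hold_mV = 0, pre_ms = 10,
                          step_ms = 50, tail_ms = 10, post_ms = 10,
                          rate_kHz = 2) {
  vcf_protocol(hold_mV = hold_mV, steps_mV = step_mV, pre_ms = pre_ms,
               step_ms = step_ms, tail_ms = tail_ms, post_ms = post_ms,
               tail_mV = -60, rate_kHz = rate_kHz)
}

## voltage-independent-tau gating with unit occupancy (ligand-free sensor)
const_tau_gating <- function(Vhalf = -60, z = 1, tau_ms = 50) {
  gating_params(Vhalf_ref_mV = Vhalf, z = z, Pmin = 0, Pmax = 1,
                atp_shift_mV_per_decade = 0, atp_ec50_uM = 0, hill_n = 1,
                tau_ref_ms = tau_ms, tau_V_slope_mV = 1e12, tau_atp_exp = 0)
}

quiet_fluorophore <- function(...) {
  fluorophore_params(F0 = 1000, s_ec_pct_per_mV = 0, c_slow_pct = 0,
                     bleach_R_per_sample = 0, noise_sd_pct = 0, ...)
}

## F/(R*T) per mV computed from first principles, independent of the package
f_per_mV_oracle <- function(T_K = 297.15) 96485 / (8.314 * T_K * 1000)

## averaged noiseless-equivalent run of a preset
run_noiseless <- function(preset, stages = c("simulate", "preprocess",
                                             "decompose"), ...) {
  run_vcf(vcf_config(preset, seed = 1L, noise = FALSE, stages = stages, ...))
}
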