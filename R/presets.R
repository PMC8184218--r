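## Preset registry: generator configurations matched to published recording
## conditions. Electrochromic sensitivities come from printed F-V fits or
## printed delta-F/F magnitudes divided by the voltage excursion; the slow
## coupling gain is always solved from the preset's own gating so that the
## steady-state value is composed (fast + slow), never configured directly.

## shared gating surface of the hyperpolarization-activated P2X2 branch.
## V1/2(300 uM) and z are unpublished; chosen so the slow component
## equilibrates within an 800 ms step at every activating voltage while
## barely contaminating the first 5 ms (tau(-160 mV, 300 uM) ~ 151 ms, and a
## deliberately mild voltage dependence so tau stays well below the step
## duration across the range); see the methods vignette.
p2x2_gating <- function() {
  gating_params(Vhalf_ref_mV = -100, z = 1, Pmin = 0, Pmax = 1,
                atp_shift_mV_per_decade = -30, atp_ec50_uM = 30, hill_n = 1.5,
                atp_ref_uM = 300, tau_ref_ms = 175, tau_V_slope_mV = 400,
                tau_atp_exp = 0.5, T_K = 297.15)
}

## slow-coupling gain giving `slow_pct` at steady state for the most extreme
## step of `protocol` at `atp_uM`
solve_c_slow <- function(slow_pct, protocol, atp_uM, g, at_mV = NULL) {
  if (is.null(at_mV)) {
    ex <- protocol$steps_mV[which.max(abs(protocol$steps_mV -
                                            protocol$hold_mV))]
  } else {
    ex <- at_mV
  }
  dpo <- open_probability(ex, atp_uM, g) -
    open_probability(protocol$hold_mV, atp_uM, g)
  slow_pct / dpo
}

## 1% total bleach over one sweep, expressed per sample
default_bleach <- function(protocol) 0.01 / protocol_n_samples(protocol)

preset_builders <- list(
  ## A337Anap electrochromic probe: fast-only, slope 0.011 %/mV, 10 uM ATP
  P2X2_A337_EC_FIT = function() {
    proto <- vcf_protocol(hold_mV = 20, steps_mV = seq(40, -140, by = -20),
                          pre_ms = 100, step_ms = 500, tail_ms = 100,
                          post_ms = 100, tail_mV = -60, rate_kHz = 20)
    list(protocol = proto, gating = p2x2_gating(),
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 0.011, c_slow_pct = 0,
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 50, Erev_mV = 0),
         atp_uM = 10, n_repeats = 20L, channel = "F440")
  },
  ## I341Anap electrochromic probe: fast-only, slope 0.007 %/mV, hold -40 mV
  P2X2_I341_EC_FIT = function() {
    proto <- vcf_protocol(hold_mV = -40, steps_mV = seq(40, -160, by = -20),
                          pre_ms = 100, step_ms = 500, tail_ms = 100,
                          post_ms = 100, tail_mV = -60, rate_kHz = 20)
    list(protocol = proto, gating = p2x2_gating(),
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 0.007, c_slow_pct = 0,
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 50, Erev_mV = 0),
         atp_uM = 10, n_repeats = 20L, channel = "F440")
  },
  ## K308R/A337Anap in 300 uM ATP: fast 3.9% at -160 mV plus a slow
  ## gating-coupled component of 0.5% at steady state
  K308R_A337_300ATP = function() {
    proto <- vcf_protocol(hold_mV = 20, steps_mV = seq(40, -160, by = -20),
                          pre_ms = 100, step_ms = 800, tail_ms = 100,
                          post_ms = 100, tail_mV = -60, rate_kHz = 20)
    g <- p2x2_gating()
    list(protocol = proto, gating = g,
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 3.9 / 180,
           c_slow_pct = solve_c_slow(0.5, proto, 300, g, at_mV = -160),
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 50, Erev_mV = 0),
         atp_uM = 300, n_repeats = 20L, channel = "F440")
  },
  ## same construct without agonist: slow coupling inert (Po stays ~ 0),
  ## fast magnitude 4.4% at -160 mV
  K308R_A337_0ATP = function() {
    proto <- vcf_protocol(hold_mV = 20, steps_mV = seq(40, -160, by = -20),
                          pre_ms = 100, step_ms = 800, tail_ms = 100,
                          post_ms = 100, tail_mV = -60, rate_kHz = 20)
    g <- p2x2_gating()
    list(protocol = proto, gating = g,
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 4.4 / 180,
           c_slow_pct = solve_c_slow(0.5, proto, 300, g, at_mV = -160),
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 50, Erev_mV = 0),
         atp_uM = 0, n_repeats = 5L, channel = "F440")
  },
  ## same-cell comparison variant: fast 1.7% at -160 mV, slow 0.25%
  K308R_A337_300ATP_FIG6 = function() {
    proto <- vcf_protocol(hold_mV = 20, steps_mV = seq(40, -160, by = -20),
                          pre_ms = 100, step_ms = 800, tail_ms = 100,
                          post_ms = 100, tail_mV = -60, rate_kHz = 20)
    g <- p2x2_gating()
    list(protocol = proto, gating = g,
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 1.7 / 180,
           c_slow_pct = solve_c_slow(0.25, proto, 300, g, at_mV = -160),
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 50, Erev_mV = 0),
         atp_uM = 300, n_repeats = 20L, channel = "F440")
  },
  ## Ci-VSP voltage-sensor control: ligand-independent, depolarization-
  ## activated, slow-only, 10.6% at +160 mV on the 500 nm channel
  CiVSP_F401 = function() {
    proto <- vcf_protocol(hold_mV = -60, steps_mV = seq(-80, 160, by = 20),
                          pre_ms = 100, step_ms = 500, tail_ms = 0,
                          post_ms = 100, tail_mV = -60, rate_kHz = 10,
                          inter_sweep_s = 3)
    g <- gating_params(Vhalf_ref_mV = 50, z = -1, Pmin = 0, Pmax = 1,
                       atp_shift_mV_per_decade = 0, atp_ec50_uM = 0,
                       hill_n = 1, atp_ref_uM = 300, tau_ref_ms = 30,
                       tau_V_slope_mV = 1e6, tau_atp_exp = 0, T_K = 297.15)
    list(protocol = proto, gating = g,
         fluorophore = fluorophore_params(
           F0 = 1000, s_ec_pct_per_mV = 0,
           c_slow_pct = solve_c_slow(10.6, proto, 0, g, at_mV = 160),
           bleach_R_per_sample = default_bleach(proto), noise_sd_pct = 0.4),
         conductance = conductance_params(N_gamma_uS = 0, Erev_mV = 0),
         atp_uM = 0, n_repeats = 3L, channel = "F500")
  }
)

#' List registered simulation presets
#' @return character vector of preset names.
#' @export
list_presets <- function() names(preset_builders)

#' Retrieve a fully specified generator configuration
#'
#' Each preset bundles a protocol, gating/fluorophore/conductance parameters,
#' the agonist concentration, the repeat count used for averaging (20 in ATP,
#' 5 in 0 ATP, 3 for the voltage-sensor control) and the detection channel.
#'
#' @param name one of [list_presets()].
#' @return an object of class `vcf_preset`: a named list with elements
#'   `name`, `protocol`, `gating`, `fluorophore`, `conductance`, `atp_uM`,
#'   `n_repeats`, `channel`.
#' @examples
#' get_preset("P2X2_A337_EC_FIT")$fluorophore$s_ec_pct_per_mV
#' @export
get_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(preset_builders)) {
    stop("unknown preset '", paste(name, collapse = ","), "'; available: ",
         paste(list_presets(), collapse = ", "), call. = FALSE)
  }
  out <- preset_builders[[name]]()
  out <- c(list(name = name), out)
  class(out) <- "vcf_preset"
  out
}

#' Simulate all repeats of a preset
#'
#' @param preset preset name or a `vcf_preset` object.
#' @param seed integer seed for the noise substreams.
#' @param noise logical; `FALSE` zeroes the noise sd (deterministic run).
#' @param n_repeats,atp_uM optional overrides of the preset condition.
#' @return list of `vcf_sweep` objects.
#' @export
simulate_preset <- function(preset, seed = 1L, noise = TRUE,
                            n_repeats = NULL, atp_uM = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "vcf_preset"))
  fl <- preset$fluorophore
  if (!noise) fl$noise_sd_pct <- 0
  simulate_experiment(preset$protocol,
                      if (is.null(atp_uM)) preset$atp_uM else atp_uM,
                      preset$gating, fl, preset$conductance,
                      n_repeats = if (is.null(n_repeats)) preset$n_repeats
                                  else n_repeats,
                      seed = seed, channel = preset$channel,
                      meta = list(preset = preset$name))
}

#' Export the preset registry as a JSON configuration file
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preset_registry <- function(path) {
  reg <- lapply(list_presets(), function(nm) {
    p <- get_preset(nm)
    lapply(p[setdiff(names(p), "name")],
           function(x) if (is.list(x)) unclass(x) else x)
  })
  names(reg) <- list_presets()
  jsonlite::write_json(reg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.vcf_preset <- function(x, ...) {
  cat("Preset", x$name, "-", x$channel, "channel,", x$atp_uM, "uM agonist,",
      x$n_repeats, "repeats\n")
  print(x$protocol)
  invisible(x)
}
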