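#' Gating parameters of the generative channel model
#'
#' The steady-state open probability is a two-state Boltzmann surface over
#' voltage scaled by agonist occupancy,
#' \deqn{P_\infty(V, A) = h(A)\,[P_{min} + (P_{max}-P_{min}) /
#'   (1 + e^{zF(V - V_{1/2}(A))/RT})],}
#' with Hill occupancy \eqn{h(A) = A^n / (EC_{50}^n + A^n)} and a log-linear
#' agonist-dependent half-activation voltage
#' \eqn{V_{1/2}(A) = V_{1/2,ref} + s \log_{10}(A/A_{ref})}. With `z > 0` the
#' open probability increases on hyperpolarisation. Relaxation after a voltage
#' step is mono-exponential with
#' \eqn{\tau(V, A) = \tau_{ref}\, e^{(V - V_{1/2}(A))/s_\tau}\,(A_{ref}/A)^q},
#' so lower agonist gives slower kinetics when `q > 0`.
#'
#' @param Vhalf_ref_mV half-activation voltage at the reference agonist
#'   concentration (mV).
#' @param z effective gating charge (dimensionless; `z > 0` means activation
#'   by hyperpolarisation, `z < 0` by depolarisation).
#' @param Pmin,Pmax open-probability bounds, `0 <= Pmin < Pmax <= 1`.
#' @param atp_shift_mV_per_decade shift of V1/2 per tenfold agonist change (mV).
#' @param atp_ec50_uM,hill_n Hill occupancy parameters; `atp_ec50_uM = 0`
#'   declares a ligand-independent sensor (occupancy fixed at 1).
#' @param atp_ref_uM reference agonist concentration (uM) anchoring
#'   `Vhalf_ref_mV` and the tau law.
#' @param tau_ref_ms relaxation time constant at `V = V1/2` and the reference
#'   concentration (ms).
#' @param tau_V_slope_mV e-fold voltage dependence of tau (mV).
#' @param tau_atp_exp exponent q of the agonist dependence of tau.
#' @param T_K temperature (K); default 297.15 (room temperature).
#' @return an object of class `gating_params`.
#' @export
gating_params <- function(Vhalf_ref_mV = -100, z = 1, Pmin = 0, Pmax = 1,
                          atp_shift_mV_per_decade = -30, atp_ec50_uM = 30,
                          hill_n = 1.5, atp_ref_uM = 300, tau_ref_ms = 50,
                          tau_V_slope_mV = 80, tau_atp_exp = 0.5,
                          T_K = 297.15) {
  g <- structure(as.list(environment()), class = "gating_params")
  stopifnot(is.numeric(g$Pmin), is.numeric(g$Pmax),
            g$Pmin >= 0, g$Pmin < g$Pmax, g$Pmax <= 1,
            g$tau_ref_ms > 0, g$T_K > 0, g$atp_ec50_uM >= 0,
            g$atp_ref_uM > 0, g$tau_V_slope_mV != 0, g$z != 0)
  g
}

#' Fluorophore and photodetection parameters
#'
#' The recorded fluorescence of one sweep is
#' \deqn{F_k = F_0 (1 - R_b k)\,[1 + \frac{s_{ec}}{100}(V_k - V_{hold})
#'  + \frac{c_{slow}}{100}(Po_k - Po_{hold})] + \epsilon_k,}
#' with `k` the 0-based sample index, `R_b` the per-sample linear bleach rate
#' and iid Gaussian noise of sd `noise_sd_pct` percent of `F0`.
#'
#' @param F0 baseline fluorescence (arbitrary photodetector units), > 0.
#' @param s_ec_pct_per_mV electrochromic sensitivity (percent of F0 per mV,
#'   signed; positive means fluorescence decreases on hyperpolarisation).
#' @param c_slow_pct slow-component gain (percent of F0 per unit increase in
#'   open probability).
#' @param bleach_R_per_sample fractional bleach per sample, >= 0; the bleach
#'   envelope must stay positive over the sweep.
#' @param noise_sd_pct Gaussian noise sd (percent of F0), >= 0.
#' @return an object of class `fluorophore_params`.
#' @export
fluorophore_params <- function(F0 = 1000, s_ec_pct_per_mV = 0.011,
                               c_slow_pct = 0, bleach_R_per_sample = 0,
                               noise_sd_pct = 0.4) {
  fl <- structure(as.list(environment()), class = "fluorophore_params")
  stopifnot(fl$F0 > 0, fl$bleach_R_per_sample >= 0, fl$noise_sd_pct >= 0)
  fl
}

#' Lumped conductance parameters
#'
#' Current is ohmic through the open channels:
#' `I_uA = N_gamma_uS * Po * (V - Erev_mV) / 1000`.
#'
#' @param N_gamma_uS maximal (all-open) conductance (uS), >= 0.
#' @param Erev_mV reversal potential (mV); 0 for a non-selective cation
#'   conductance in a sodium bath.
#' @return an object of class `conductance_params`.
#' @export
conductance_params <- function(N_gamma_uS = 50, Erev_mV = 0) {
  co <- structure(as.list(environment()), class = "conductance_params")
  stopifnot(co$N_gamma_uS >= 0, is.finite(co$Erev_mV))
  co
}

#' Hill occupancy of the agonist site
#' @param atp_uM agonist concentration (uM), >= 0.
#' @param g a [gating_params()].
#' @return occupancy in \[0, 1\]; identically 1 for ligand-independent
#'   sensors (`atp_ec50_uM = 0`).
#' @export
hill_occupancy <- function(atp_uM, g) {
  stopifnot(inherits(g, "gating_params"), all(is.finite(atp_uM)),
            all(atp_uM >= 0))
  if (g$atp_ec50_uM <= 0) return(rep(1, length(atp_uM)))
  an <- atp_uM^g$hill_n
  an / (g$atp_ec50_uM^g$hill_n + an)
}

#' Agonist-dependent half-activation voltage
#' @inheritParams hill_occupancy
#' @return V1/2 at `atp_uM` (mV); at zero agonist the reference value is
#'   returned (the occupancy term already closes the channel).
#' @export
vhalf_at <- function(atp_uM, g) {
  stopifnot(inherits(g, "gating_params"))
  ifelse(atp_uM > 0,
         g$Vhalf_ref_mV +
           g$atp_shift_mV_per_decade * log10(atp_uM / g$atp_ref_uM),
         g$Vhalf_ref_mV)
}

#' Relaxation time constant of gating
#' @param V_mV membrane potential (mV).
#' @inheritParams hill_occupancy
#' @return tau (ms); `Inf` at zero agonist for agonist-dependent kinetics
#'   (`tau_atp_exp > 0`), where the occupancy is zero and no relaxation occurs.
#' @export
gating_tau <- function(V_mV, atp_uM, g) {
  stopifnot(inherits(g, "gating_params"))
  fac <- if (g$tau_atp_exp == 0 || g$atp_ec50_uM <= 0) {
    1
  } else if (atp_uM <= 0) {
    Inf
  } else {
    (g$atp_ref_uM / atp_uM)^g$tau_atp_exp
  }
  tau <- g$tau_ref_ms *
    exp((V_mV - vhalf_at(atp_uM, g)) / g$tau_V_slope_mV) * fac
  if (any(tau <= 0, na.rm = TRUE)) stop("tau must be positive", call. = FALSE)
  tau
}
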