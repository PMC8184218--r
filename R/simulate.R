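#' Steady-state open probability
#'
#' Evaluates the Boltzmann open-probability surface
#' `P(V, A) = h(A) * [Pmin + (Pmax - Pmin) / (1 + exp(z F (V - V1/2(A)) / RT))]`
#' with `F/(RT)` evaluated per mV (about 0.03905 1/mV at 297.15 K).
#'
#' @param V_mV membrane potential (mV); vectorised.
#' @param atp_uM agonist concentration (uM), scalar >= 0.
#' @param g a [gating_params()].
#' @return open probability in \[0, 1\], same length as `V_mV`.
#' @examples
#' g <- gating_params(Vhalf_ref_mV = -100, z = 1)
#' open_probability(-100, 300, g)  # midpoint: half of occupancy-scaled Pmax
#' @export
open_probability <- function(V_mV, atp_uM, g) {
  stopifnot(inherits(g, "gating_params"))
  if (!all(is.finite(V_mV)) || length(atp_uM) != 1L || !is.finite(atp_uM) ||
      atp_uM < 0) {
    stop("'V_mV' must be finite and 'atp_uM' a finite scalar >= 0",
         call. = FALSE)
  }
  f <- boltzmann_factor_per_mV(g$T_K)
  h <- hill_occupancy(atp_uM, g)
  vh <- vhalf_at(atp_uM, g)
  p <- h * (g$Pmin + (g$Pmax - g$Pmin) /
              (1 + exp(g$z * f * (V_mV - vh))))
  pmin(pmax(p, 0), 1)
}

#' Open-probability time course over a protocol
#'
#' Within each constant-voltage segment the open probability relaxes
#' mono-exponentially towards its steady state,
#' `Po(t) = Pinf + (Po_start - Pinf) exp(-t / tau(V, A))`, continuously across
#' segment boundaries within an episode. Each episode starts from the
#' holding-state steady value (the un-sampled inter-episode rest is taken to
#' be much longer than tau).
#'
#' @param protocol a [vcf_protocol()].
#' @param atp_uM agonist concentration (uM).
#' @param g a [gating_params()].
#' @return numeric vector of open probability, one value per sample.
#' @export
simulate_gating_trace <- function(protocol, atp_uM, g) {
  stopifnot(inherits(protocol, "vcf_protocol"), inherits(g, "gating_params"))
  segs <- protocol_segments(protocol)
  rate <- protocol$rate_kHz
  po <- numeric(sum(segs$n))
  p_hold <- open_probability(protocol$hold_mV, atp_uM, g)
  po0 <- p_hold
  for (i in seq_len(nrow(segs))) {
    if (segs$segment[i] == "pre") po0 <- p_hold  # episode onset: rested state
    pinf <- open_probability(segs$v_mV[i], atp_uM, g)
    tau <- gating_tau(segs$v_mV[i], atp_uM, g)
    idx <- segs$start[i] + seq_len(segs$n[i]) - 1L
    t_rel <- (seq_len(segs$n[i]) - 1) / rate
    po[idx] <- pinf + (po0 - pinf) * exp(-t_rel / tau)
    po0 <- pinf + (po0 - pinf) * exp(-segs$duration_ms[i] / tau)
  }
  po
}

new_vcf_sweep <- function(t_ms, V_cmd_mV, I_uA, F_channels, meta, protocol) {
  n <- length(t_ms)
  if (n < 1L) stop("sweep must contain at least one sample", call. = FALSE)
  lens <- c(length(V_cmd_mV), length(I_uA), vapply(F_channels, length, 1L))
  if (any(lens != n)) {
    stop("all per-sample arrays must share one length", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(t_ms)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
      stop("time base must be strictly increasing and uniform", call. = FALSE)
    }
  }
  structure(list(t_ms = t_ms, V_cmd_mV = V_cmd_mV, I_uA = I_uA,
                 F_channels = F_channels, meta = meta, protocol = protocol),
            class = "vcf_sweep")
}

#' Simulate one VCF sweep
#'
#' Generates current and fluorescence for one protocol repeat. Current is
#' ohmic, `I = N_gamma * Po * (V - Erev)`. Fluorescence follows the
#' electrochromic-plus-gating model with a linear bleach envelope over the
#' 0-based sample index and additive iid Gaussian noise (see
#' [fluorophore_params()]).
#'
#' @param protocol a [vcf_protocol()].
#' @param atp_uM agonist concentration (uM).
#' @param gating a [gating_params()].
#' @param fluorophore a [fluorophore_params()].
#' @param conductance a [conductance_params()].
#' @param seed integer fixing the noise stream; identical seeds reproduce
#'   identical sweeps. `NULL` draws from the current RNG state.
#' @param channel fluorescence channel label (e.g. `"F440"`).
#' @param meta named list of extra metadata (preset name, repeat index, ...).
#' @return an object of class `vcf_sweep` with fields `t_ms`, `V_cmd_mV`,
#'   `I_uA`, `F_channels` (named list), `meta`, `protocol`.
#' @export
simulate_sweep <- function(protocol, atp_uM, gating, fluorophore, conductance,
                           seed = NULL, channel = "F440", meta = list()) {
  stopifnot(inherits(fluorophore, "fluorophore_params"),
            inherits(conductance, "conductance_params"))
  v <- protocol_voltage(protocol)
  t_ms <- protocol_time(protocol)
  po <- simulate_gating_trace(protocol, atp_uM, gating)
  po_hold <- open_probability(protocol$hold_mV, atp_uM, gating)
  n <- length(v)
  k <- seq_len(n) - 1  # 0-based sample index
  envelope <- 1 - fluorophore$bleach_R_per_sample * k
  if (any(envelope <= 0)) {
    stop("bleach envelope reaches zero within the sweep", call. = FALSE)
  }
  signal <- 1 +
    (fluorophore$s_ec_pct_per_mV / 100) * (v - protocol$hold_mV) +
    (fluorophore$c_slow_pct / 100) * (po - po_hold)
  f <- fluorophore$F0 * envelope * signal
  if (fluorophore$noise_sd_pct > 0) {
    sd_abs <- fluorophore$noise_sd_pct * fluorophore$F0 / 100
    eps <- if (is.null(seed)) {
      stats::rnorm(n, sd = sd_abs)
    } else {
      withr::with_seed(as.integer(seed), stats::rnorm(n, sd = sd_abs))
    }
    f <- f + eps
  }
  i_uA <- conductance$N_gamma_uS * po * (v - conductance$Erev_mV) / 1000
  meta <- utils::modifyList(
    list(atp_uM = atp_uM, seed = seed, repeat_index = 1L, channel = channel),
    meta)
  new_vcf_sweep(t_ms, v, i_uA, stats::setNames(list(f), channel), meta,
                protocol)
}

#' Simulate a repeat-averaged experiment
#'
#' Runs [simulate_sweep()] `n_repeats` times with distinct noise substreams
#' derived deterministically from `seed`; the deterministic signal components
#' are identical across repeats.
#'
#' @inheritParams simulate_sweep
#' @param n_repeats number of protocol repeats (>= 1).
#' @return list of `vcf_sweep` objects, one per repeat.
#' @export
simulate_experiment <- function(protocol, atp_uM, gating, fluorophore,
                                conductance, n_repeats, seed = 1L,
                                channel = "F440", meta = list()) {
  stopifnot(n_repeats >= 1)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, n_repeats))
  lapply(seq_len(n_repeats), function(i) {
    simulate_sweep(protocol, atp_uM, gating, fluorophore, conductance,
                   seed = sub_seeds[i], channel = channel,
                   meta = utils::modifyList(meta, list(repeat_index = i)))
  })
}

#' @export
print.vcf_sweep <- function(x, ...) {
  cat("VCF sweep:", length(x$t_ms), "samples @",
      x$protocol$rate_kHz, "kHz;", length(x$protocol$steps_mV), "episodes\n")
  cat("  channels:", paste(names(x$F_channels), collapse = ", "),
      "| [ATP]:", x$meta$atp_uM, "uM\n")
  if (!is.null(x$meta$preset)) cat("  preset:", x$meta$preset, "\n")
  invisible(x)
}
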