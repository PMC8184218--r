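#' Fast (instantaneous) fluorescence component of one step
#'
#' Delta-F/F over the first `window_ms` of the step, referenced to the episode
#' baseline. For an electrochromic fluorophore this window captures the
#' voltage-linear component before the gating-coupled component has grown.
#'
#' @param norm a [normalize_baseline()] result covering the step.
#' @param step_onset_ms time of the command transition (ms, on `norm$t_ms`).
#' @param window_ms extraction window (ms), default 5.
#' @param step_ms optional step duration for window validation.
#' @return signed delta-F/F in percent.
#' @export
extract_fast <- function(norm, step_onset_ms, window_ms = 5, step_ms = NULL) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (!is.null(step_ms) && window_ms > step_ms) {
    stop("fast window exceeds step duration", call. = FALSE)
  }
  window_dff(norm, step_onset_ms, step_onset_ms + window_ms)
}

#' Steady-state fluorescence component of one step
#'
#' Delta-F/F over the last `window_ms` of the step (the window ends at the
#' command transition back off the step).
#'
#' @param norm a [normalize_baseline()] result covering the step.
#' @param step_end_ms time of the end-of-step transition (ms).
#' @param window_ms extraction window (ms); 50 for agonist recordings, 100 for
#'   agonist-free ones by convention.
#' @param step_ms optional step duration for window validation.
#' @return signed delta-F/F in percent.
#' @export
extract_steady <- function(norm, step_end_ms, window_ms = 50, step_ms = NULL) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (!is.null(step_ms) && window_ms > step_ms) {
    stop("steady window exceeds step duration", call. = FALSE)
  }
  window_dff(norm, step_end_ms - window_ms, step_end_ms)
}

## mean delta-F/F over the half-open time window [t0, t1)
window_dff <- function(norm, t0_ms, t1_ms) {
  t <- norm$t_ms
  tol <- if (length(t) > 1L) (t[2] - t[1]) * 1e-6 else 1e-9
  idx <- which(t >= t0_ms - tol & t < t1_ms - tol)
  if (!length(idx)) stop("window contains no samples", call. = FALSE)
  delta_f_over_f(norm, c(min(idx), max(idx)))
}

#' Slow component by decomposition
#'
#' The steady-state change is the sum of the instantaneous (fast) and
#' gating-coupled (slow) components, so `slow = steady - fast`, exactly.
#'
#' @param steady_pct,fast_pct signed percent values from the same step and
#'   baseline.
#' @return signed slow component in percent.
#' @export
split_components <- function(steady_pct, fast_pct) steady_pct - fast_pct

#' Decompose every step of a sweep into fast/steady/slow components
#'
#' Runs the full per-sweep analysis: bleach estimation over the pre-step
#' holding segments, compensation, per-episode baseline normalisation, and
#' windowed extraction of the fast and steady components; the slow component
#' is their difference.
#'
#' @param sweep a `vcf_sweep` (typically repeat-averaged).
#' @param channel fluorescence channel label; default first.
#' @param fast_window_ms fast window (ms), default 5.
#' @param steady_window_ms steady window (ms); default 50 when agonist is
#'   present, 100 when `meta$atp_uM == 0`.
#' @param compensation bleach compensation mode, see [preprocess_sweep()].
#' @return a data.frame of class `vcf_decomposition` with columns `step_mV`,
#'   `dV_mV`, `dF_fast_pct`, `dF_steady_pct`, `dF_slow_pct` plus window
#'   metadata in attributes (`fast_window_ms`, `steady_window_ms`, `bleach`,
#'   `channel`).
#' @export
decompose_sweep <- function(sweep, channel = NULL, fast_window_ms = 5,
                            steady_window_ms = NULL,
                            compensation = c("first_order",
                                             "exact_division", "additive")) {
  compensation <- match.arg(compensation)
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (is.null(channel)) channel <- names(sweep$F_channels)[1L]
  if (is.null(steady_window_ms)) {
    atp <- sweep$meta$atp_uM
    steady_window_ms <- if (!is.null(atp) && atp == 0) 100 else 50
  }
  pp <- preprocess_sweep(sweep, channel, compensation)
  f <- pp$sweep$F_channels[[channel]]
  segs <- protocol_segments(sweep$protocol)
  rate <- sweep$protocol$rate_kHz
  rows <- lapply(unique(segs$episode), function(ep) {
    e <- segs[segs$episode == ep, , drop = FALSE]
    pre <- e[e$segment == "pre", ]
    stp <- e[e$segment == "step", ]
    if (nrow(pre) == 0L) stop("episode lacks a baseline segment",
                              call. = FALSE)
    norm <- normalize_baseline(f, c(pre$start, pre$start + pre$n - 1L),
                               t_ms = sweep$t_ms,
                               compensation_mode = compensation)
    onset <- stp$t_start_ms
    end <- onset + stp$duration_ms
    fast <- extract_fast(norm, onset, fast_window_ms,
                         step_ms = stp$duration_ms)
    steady <- extract_steady(norm, end, steady_window_ms,
                             step_ms = stp$duration_ms)
    data.frame(step_mV = stp$v_mV,
               dV_mV = stp$v_mV - sweep$protocol$hold_mV,
               dF_fast_pct = fast, dF_steady_pct = steady,
               dF_slow_pct = split_components(steady, fast))
  })
  out <- do.call(rbind, rows)
  attr(out, "fast_window_ms") <- fast_window_ms
  attr(out, "steady_window_ms") <- steady_window_ms
  attr(out, "bleach") <- pp$bleach
  attr(out, "channel") <- channel
  class(out) <- c("vcf_decomposition", "data.frame")
  out
}

#' Build an F-V curve from a decomposition
#'
#' The voltage axis is the excursion from the holding potential
#' (`dV = step - holding`). Optional normalisation divides by the value at the
#' most hyperpolarised step (the convention for slow-component curves, whose
#' maximum sits at the most negative step).
#'
#' @param decomp a [decompose_sweep()] result.
#' @param component `"fast"`, `"steady"` or `"slow"`.
#' @param normalize `"none"` or `"max_hyperpol"`.
#' @return an object of class `fv_curve` with fields `step_mV`, `dV_mV`,
#'   `dFF_pct`, `component`, `normalization`.
#' @export
build_fv <- function(decomp, component = c("fast", "steady", "slow"),
                     normalize = c("none", "max_hyperpol")) {
  component <- match.arg(component)
  normalize <- match.arg(normalize)
  stopifnot(inherits(decomp, "vcf_decomposition") || is.data.frame(decomp))
  if (nrow(decomp) < 2L) stop("need >= 2 steps", call. = FALSE)
  if (anyDuplicated(decomp$dV_mV)) stop("duplicate dV values", call. = FALSE)
  y <- decomp[[paste0("dF_", component, "_pct")]]
  if (normalize == "max_hyperpol") {
    ref <- y[which.min(decomp$dV_mV)]
    if (ref == 0) stop("normalisation reference is zero", call. = FALSE)
    y <- y / ref
  }
  structure(list(step_mV = decomp$step_mV, dV_mV = decomp$dV_mV, dFF_pct = y,
                 component = component, normalization = normalize),
            class = "fv_curve")
}

#' @export
print.fv_curve <- function(x, ...) {
  cat("F-V curve (", x$component, " component, normalization: ",
      x$normalization, ")\n", sep = "")
  print(data.frame(dV_mV = x$dV_mV, dFF = x$dFF_pct))
  invisible(x)
}

#' Ordinary least-squares line through an F-V curve
#'
#' @param curve an [build_fv()] result (or any list with `dV_mV`, `dFF_pct`).
#' @return an object of class `linear_fit`: `slope_pct_per_mV`,
#'   `intercept_pct`, `r_squared`.
#' @export
fit_linear <- function(curve) {
  x <- curve$dV_mV; y <- curve$dFF_pct
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  if (length(unique(x)) < 2L) stop("degenerate: all dV equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope_pct_per_mV = unname(stats::coef(fit)[2L]),
                 intercept_pct = unname(stats::coef(fit)[1L]),
                 r_squared = max(0, min(1, r2)),
                 residuals = unname(stats::residuals(fit))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g x + %.4g; R^2 = %.4f\n",
              x$slope_pct_per_mV, x$intercept_pct, x$r_squared))
  invisible(x)
}

#' Classify an F-V curve as linear or nonlinear
#'
#' A curve is called linear when the OLS fit explains it (`R^2 >=
#' r2_threshold`) and the residual signs show no systematic run: a same-sign
#' run reaching half the points (`ceiling(n/2)`) flags curvature that a high
#' R^2 can mask when one component dominates. Residuals smaller than
#' `resid_tol_frac` of the curve's spread carry no sign, so negligible
#' systematic structure (e.g. second-order bleach-compensation residue on
#' noiseless data) cannot drive the run count.
#'
#' @param curve an [build_fv()] result with >= 4 points.
#' @param r2_threshold R^2 cutoff, default 0.98.
#' @param resid_tol_frac sign-free residual band, as a fraction of the
#'   standard deviation of the curve values; default 1e-3.
#' @return list with `label` (`"linear"`/`"nonlinear"`), `r_squared`,
#'   `max_sign_run`, `run_limit`, `fit` (the `linear_fit`).
#' @export
classify_linearity <- function(curve, r2_threshold = 0.98,
                               resid_tol_frac = 1e-3) {
  n <- length(curve$dV_mV)
  if (n < 4L) stop("need >= 4 points", call. = FALSE)
  fit <- fit_linear(curve)
  res <- fit$residuals
  tol <- max(resid_tol_frac * stats::sd(curve$dFF_pct),
             .Machine$double.eps)
  s <- sign(res[abs(res) > tol])
  max_run <- if (length(s)) max(rle(s)$lengths) else 0L
  run_limit <- ceiling(n / 2)
  linear <- fit$r_squared >= r2_threshold && max_run < run_limit
  list(label = if (linear) "linear" else "nonlinear",
       r_squared = fit$r_squared, max_sign_run = max_run,
       run_limit = run_limit, fit = fit)
}

#' Time for the fast component to reach 90% of its amplitude
#'
#' Measures, on the compensated and baseline-normalised trace of the step with
#' the largest voltage excursion, the elapsed time from the command transition
#' to the first sample at which the deflection reaches `frac` of the fast
#' amplitude. For the model's instantaneous electrochromic response this is
#' one sample period.
#'
#' @param sweep a `vcf_sweep`.
#' @param channel channel label; default first.
#' @param frac completion fraction, default 0.9.
#' @param fast_window_ms window defining the fast amplitude, default 5.
#' @return elapsed time (ms).
#' @export
fast_rise_time <- function(sweep, channel = NULL, frac = 0.9,
                           fast_window_ms = 5) {
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (is.null(channel)) channel <- names(sweep$F_channels)[1L]
  pp <- preprocess_sweep(sweep, channel)
  f <- pp$sweep$F_channels[[channel]]
  segs <- protocol_segments(sweep$protocol)
  stp <- segs[segs$segment == "step", , drop = FALSE]
  ep <- stp$episode[which.max(abs(stp$v_mV - sweep$protocol$hold_mV))]
  e <- segs[segs$episode == ep, , drop = FALSE]
  pre <- e[e$segment == "pre", ]
  stp <- e[e$segment == "step", ]
  norm <- normalize_baseline(f, c(pre$start, pre$start + pre$n - 1L),
                             t_ms = sweep$t_ms)
  amp <- extract_fast(norm, stp$t_start_ms, fast_window_ms,
                      step_ms = stp$duration_ms) / 100
  dt <- 1 / sweep$protocol$rate_kHz
  step_idx <- stp$start + seq_len(stp$n) - 1L
  dev <- norm$F_norm[step_idx] - 1
  hit <- which(sign(dev) == sign(amp) & abs(dev) >= frac * abs(amp))
  if (!length(hit)) stop("deflection never reaches the threshold",
                         call. = FALSE)
  ## transition falls between the last pre sample and the first step sample
  (hit[1L] - 1L) * dt + dt
}
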