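#' Tail-current amplitude after one step
#'
#' Mean current over a short window at the fixed tail potential,
#' `[tail_start + settle, tail_start + settle + window)`. Because the tail
#' voltage is the same after every step, the amplitude indexes the open
#' probability reached at the end of the preceding step.
#'
#' @param sweep a `vcf_sweep`.
#' @param tail_start_ms time of the step-to-tail transition (ms).
#' @param settle_ms settle time skipped after the transition (ms), default 1.
#' @param window_ms averaging window (ms), default 3.
#' @param tail_ms optional tail duration for window validation.
#' @return mean current (uA).
#' @export
extract_tail <- function(sweep, tail_start_ms, settle_ms = 1, window_ms = 3,
                         tail_ms = NULL) {
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (!is.null(tail_ms) && settle_ms + window_ms > tail_ms) {
    stop("tail window outside tail segment", call. = FALSE)
  }
  t <- sweep$t_ms
  tol <- (t[2] - t[1]) * 1e-6
  t0 <- tail_start_ms + settle_ms
  idx <- which(t >= t0 - tol & t < t0 + window_ms - tol)
  if (!length(idx)) stop("tail window contains no samples", call. = FALSE)
  mean(sweep$I_uA[idx])
}

#' Tail-current amplitudes for every step of a sweep
#'
#' @inheritParams extract_tail
#' @return data.frame with `step_mV` and `amplitude_uA`.
#' @export
tail_currents <- function(sweep, settle_ms = 1, window_ms = 3) {
  segs <- protocol_segments(sweep$protocol)
  tails <- segs[segs$segment == "tail", , drop = FALSE]
  if (nrow(tails) == 0L) stop("protocol has no tail segment", call. = FALSE)
  steps <- segs[segs$segment == "step", , drop = FALSE]
  amp <- vapply(seq_len(nrow(tails)), function(i) {
    extract_tail(sweep, tails$t_start_ms[i], settle_ms, window_ms,
                 tail_ms = tails$duration_ms[i])
  }, numeric(1))
  data.frame(step_mV = steps$v_mV, amplitude_uA = amp)
}

#' Normalised conductance-voltage curve from tail amplitudes
#'
#' Divides the tail amplitudes by a reference maximum: by default the
#' amplitude of largest magnitude in the supplied set, or an externally
#' supplied reference (e.g. the maximum from the highest-agonist dataset when
#' several concentrations share one normalisation).
#'
#' @param amplitudes tail amplitudes (uA), one per step.
#' @param step_voltages step potentials (mV), same length.
#' @param ref_amplitude optional signed reference amplitude; default the
#'   element of `amplitudes` with the largest magnitude.
#' @return an object of class `gv_curve` with fields `V_mV`, `G_norm`,
#'   `ref_amplitude`.
#' @export
gv_from_tails <- function(amplitudes, step_voltages, ref_amplitude = NULL) {
  stopifnot(length(amplitudes) == length(step_voltages),
            length(amplitudes) >= 4L)
  if (is.null(ref_amplitude)) {
    ref_amplitude <- amplitudes[which.max(abs(amplitudes))]
  }
  if (ref_amplitude == 0) stop("zero reference maximum", call. = FALSE)
  structure(list(V_mV = as.numeric(step_voltages),
                 G_norm = amplitudes / ref_amplitude,
                 ref_amplitude = ref_amplitude),
            class = "gv_curve")
}

#' @export
print.gv_curve <- function(x, ...) {
  cat("G-V curve (reference amplitude", format(x$ref_amplitude, digits = 4),
      "uA)\n")
  print(data.frame(V_mV = x$V_mV, G_norm = x$G_norm))
  invisible(x)
}

#' Two-state Boltzmann fit
#'
#' Nonlinear least squares of
#' \deqn{I(V) = I_{min} + (I_{max} - I_{min}) / (1 + e^{ZF(V - V_{1/2})/RT}),}
#' the two-state (single transition) voltage dependence. Because
#' `(Imin, Imax, Z)` and `(Imax, Imin, -Z)` describe the same curve, the
#' reported parameters are canonicalised to `Imax >= Imin`; `Z > 0` then means
#' the response approaches `Imax` towards hyperpolarised potentials, and the
#' fit accepts either sign and reports it. Initialisation is deterministic:
#' amplitude limits from the data extrema, V1/2 from the voltage nearest the
#' half-range crossing, Z from the local slope there.
#'
#' @param V_mV voltages (mV) or a `gv_curve`.
#' @param response response values (normalised conductance or current); not
#'   needed when `V_mV` is a `gv_curve`.
#' @param T_K temperature (K), default 297.15.
#' @return an object of class `boltzmann_fit`: `Imin`, `Imax`, `Z`,
#'   `Vhalf_mV`, `T_K`, `se` (named standard errors), `rss`.
#' @export
fit_boltzmann <- function(V_mV, response = NULL, T_K = 297.15) {
  if (inherits(V_mV, "gv_curve")) {
    response <- V_mV$G_norm
    V_mV <- V_mV$V_mV
  }
  stopifnot(length(V_mV) == length(response), length(V_mV) >= 4L)
  f <- boltzmann_factor_per_mV(T_K)
  ord <- order(V_mV)
  v <- V_mV[ord]; y <- response[ord]
  ## deterministic initialisation
  i_lo <- y[1L]; i_hi <- y[length(y)]       # limits at most hyper/depolarised V
  half <- (i_lo + i_hi) / 2
  cross <- which.min(abs(y - half))
  vh0 <- v[cross]
  j <- max(2L, min(cross, length(v) - 1L))
  slope_at <- (y[j + 1L] - y[j - 1L]) / (v[j + 1L] - v[j - 1L])
  dr <- i_lo - i_hi                          # Imax - Imin for Z > 0
  z0 <- if (dr != 0 && slope_at != 0) -4 * slope_at / (dr * f) else 1
  if (!is.finite(z0) || z0 == 0) z0 <- 1
  model <- function(p) {
    p[["Imin"]] + (p[["Imax"]] - p[["Imin"]]) /
      (1 + exp(p[["Z"]] * f * (v - p[["Vhalf"]])))
  }
  out <- minpack.lm::nls.lm(
    par = c(Imin = i_hi, Imax = i_lo, Z = z0, Vhalf = vh0),
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (out$info == 0L || out$info == 5L) {
    stop("Boltzmann fit did not converge: ", out$message, call. = FALSE)
  }
  co <- out$par
  dof <- length(y) - 4L
  s2 <- if (dof > 0L) out$deviance / dof else 0
  se <- tryCatch(sqrt(pmax(diag(solve(out$hessian)) * s2, 0)),
                 error = function(e) rep(NA_real_, 4L))
  names(se) <- names(co)
  if (co[["Imax"]] < co[["Imin"]]) {  # canonicalise the mirror solution
    co[c("Imin", "Imax")] <- co[c("Imax", "Imin")]
    se[c("Imin", "Imax")] <- se[c("Imax", "Imin")]
    co[["Z"]] <- -co[["Z"]]
  }
  if (co[["Vhalf"]] < min(v) || co[["Vhalf"]] > max(v)) {
    warning("fitted V1/2 lies outside the data span", call. = FALSE)
  }
  structure(list(Imin = unname(co[["Imin"]]), Imax = unname(co[["Imax"]]),
                 Z = unname(co[["Z"]]), Vhalf_mV = unname(co[["Vhalf"]]),
                 T_K = T_K, se = se, rss = out$deviance),
            class = "boltzmann_fit")
}

#' Evaluate a Boltzmann fit
#' @param fit a [fit_boltzmann()] result.
#' @param V_mV voltages (mV).
#' @return fitted response values.
#' @export
predict_boltzmann <- function(fit, V_mV) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  f <- boltzmann_factor_per_mV(fit$T_K)
  fit$Imin + (fit$Imax - fit$Imin) /
    (1 + exp(fit$Z * f * (V_mV - fit$Vhalf_mV)))
}

#' Normalise a fitted Boltzmann to conductance units
#'
#' Divides the fitted curve by its saturating limit (the fitted limit of
#' larger magnitude), giving the normalised G-V parameterisation; identical to
#' refitting the normalised data.
#'
#' @param fit a [fit_boltzmann()] result.
#' @param V_mV voltages (mV) at which to evaluate.
#' @return normalised conductance values.
#' @export
normalize_boltzmann <- function(fit, V_mV) {
  ref <- if (abs(fit$Imax) >= abs(fit$Imin)) fit$Imax else fit$Imin
  if (ref == 0) stop("degenerate fit: zero saturating limit", call. = FALSE)
  predict_boltzmann(fit, V_mV) / ref
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit: V1/2 = %.2f mV, Z = %.3f, limits [%.4g, %.4g] (T = %.2f K)\n",
    x$Vhalf_mV, x$Z, x$Imin, x$Imax, x$T_K))
  invisible(x)
}

#' Overlap between a normalised F-V curve and a G-V curve
#'
#' Root-mean-square pointwise difference of the two normalised curves on a
#' common voltage grid (union of both curves' points, linear interpolation,
#' intersection of ranges). Values near zero mean the slow fluorescence
#' component tracks the conductance.
#'
#' @param fslow a normalised `fv_curve` (the `step_mV` axis is used) or a
#'   list with `x`/`y`.
#' @param gv a `gv_curve` or a list with `x`/`y`.
#' @return RMS deviation (dimensionless).
#' @export
overlap_score <- function(fslow, gv) {
  as_xy <- function(obj) {
    if (inherits(obj, "fv_curve")) list(x = obj$step_mV, y = obj$dFF_pct)
    else if (inherits(obj, "gv_curve")) list(x = obj$V_mV, y = obj$G_norm)
    else list(x = obj$x, y = obj$y)
  }
  a <- as_xy(fslow); b <- as_xy(gv)
  lo <- max(min(a$x), min(b$x)); hi <- min(max(a$x), max(b$x))
  if (lo >= hi) stop("empty overlap range", call. = FALSE)
  grid <- sort(unique(c(a$x, b$x)))
  grid <- grid[grid >= lo & grid <= hi]
  ya <- stats::approx(a$x, a$y, xout = grid)$y
  yb <- stats::approx(b$x, b$y, xout = grid)$y
  sqrt(mean((ya - yb)^2))
}
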