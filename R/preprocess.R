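#' Estimate the linear photobleaching rate
#'
#' Fits an ordinary least-squares line to fluorescence against the 0-based
#' sample index over the union of the supplied windows and expresses the
#' (negated) slope as a fraction of the fitted intercept per sample, so that a
#' decaying trace yields `R_per_sample > 0`.
#'
#' @param trace numeric fluorescence series.
#' @param windows list of inclusive 1-based index ranges `c(start, end)`, or a
#'   single range. Defaults to the whole trace.
#' @return an object of class `bleach_estimate` with fields `R_per_sample`
#'   (fractional, signed-positive for decay), `slope` (signed, trace units per
#'   sample), `intercept` (trace units at sample 0), `fit_window`,
#'   `residual_rms`.
#' @export
estimate_bleach_rate <- function(trace, windows = NULL) {
  n <- length(trace)
  if (is.null(windows)) windows <- list(c(1L, n))
  if (!is.list(windows)) windows <- list(windows)
  idx <- sort(unique(unlist(lapply(windows, function(w) {
    if (length(w) != 2L || w[1] < 1 || w[2] > n || w[1] > w[2]) {
      stop("invalid fit window", call. = FALSE)
    }
    seq.int(w[1], w[2])
  }))))
  if (length(idx) < 2L) {
    stop("singular design: need >= 2 distinct samples across windows",
         call. = FALSE)
  }
  k <- idx - 1  # 0-based sample number
  y <- trace[idx]
  kbar <- mean(k); ybar <- mean(y)
  slope <- sum((k - kbar) * (y - ybar)) / sum((k - kbar)^2)
  intercept <- ybar - slope * kbar
  if (intercept == 0) stop("fitted intercept is zero", call. = FALSE)
  resid <- y - (intercept + slope * k)
  structure(list(R_per_sample = -slope / intercept, slope = slope,
                 intercept = intercept, fit_window = windows,
                 residual_rms = sqrt(mean(resid^2))),
            class = "bleach_estimate")
}

#' @export
print.bleach_estimate <- function(x, ...) {
  cat(sprintf("Bleach estimate: R = %.4g / sample (intercept %.4g, rms %.3g)\n",
              x$R_per_sample, x$intercept, x$residual_rms))
  invisible(x)
}

bleach_R <- function(bleach) {
  if (inherits(bleach, "bleach_estimate")) bleach$R_per_sample
  else as.numeric(bleach)
}

#' Additive bleach compensation
#'
#' Adds back the expected linear loss, `out[k] = in[k] + R_abs * k` with `k`
#' the 0-based sample index. The fractional rate of a [estimate_bleach_rate()]
#' result is converted to absolute units via its fitted intercept; a bare
#' number is taken as the absolute loss per sample. Exactly inverts a linear
#' decay of a constant-baseline (gap-free) trace.
#'
#' @param trace numeric fluorescence series.
#' @param bleach a `bleach_estimate` or a numeric absolute rate (trace units
#'   per sample).
#' @return compensated numeric series.
#' @export
compensate_additive <- function(trace, bleach) {
  R_abs <- if (inherits(bleach, "bleach_estimate")) {
    bleach$R_per_sample * bleach$intercept
  } else {
    as.numeric(bleach)
  }
  trace + R_abs * (seq_along(trace) - 1)
}

#' Multiplicative bleach compensation
#'
#' Divides out (exactly or to first order) the linear bleach envelope
#' `1 - R * k`. `first_order` multiplies by `(1 - s * k)` where `s` is
#' the signed fractional slope (negative for a decaying trace, so the factor
#' is `1 + R * k`); the residual of this first-order inverse is bounded by
#' `(R * k_max)^2` relative. `exact_division` divides by `(1 - R * k)` and is
#' exact for the linear bleach model.
#'
#' @param trace numeric fluorescence series.
#' @param bleach a `bleach_estimate` or numeric fractional rate per sample
#'   (positive for decay).
#' @param mode `"first_order"` or `"exact_division"`.
#' @return compensated numeric series.
#' @export
compensate_multiplicative <- function(trace, bleach,
                                      mode = c("first_order",
                                               "exact_division")) {
  mode <- match.arg(mode)
  R <- bleach_R(bleach)
  k <- seq_along(trace) - 1
  if (mode == "first_order") {
    s <- -R  # signed slope convention: negative for decay
    trace * (1 - s * k)
  } else {
    denom <- 1 - R * k
    if (any(denom <= 0)) {
      stop("exact_division undefined: bleach envelope reaches zero",
           call. = FALSE)
    }
    trace / denom
  }
}

#' Average repeated sweeps
#'
#' Per-sample arithmetic mean of current and every fluorescence channel across
#' protocol repeats. All sweeps must share the protocol and channel set.
#'
#' @param sweeps list of `vcf_sweep` objects.
#' @return a `vcf_sweep` whose metadata records `n_averaged`.
#' @export
average_repeats <- function(sweeps) {
  stopifnot(length(sweeps) >= 1L,
            all(vapply(sweeps, inherits, TRUE, "vcf_sweep")))
  ref <- sweeps[[1L]]
  for (s in sweeps[-1L]) {
    if (!identical(unclass(ref$protocol), unclass(s$protocol)) ||
        !identical(names(ref$F_channels), names(s$F_channels))) {
      stop("protocol or channel mismatch across repeats", call. = FALSE)
    }
  }
  nrep <- length(sweeps)
  avg <- function(get) Reduce(`+`, lapply(sweeps, get)) / nrep
  f_avg <- lapply(names(ref$F_channels), function(ch) {
    avg(function(s) s$F_channels[[ch]])
  })
  names(f_avg) <- names(ref$F_channels)
  meta <- ref$meta
  meta$n_averaged <- nrep
  meta$repeat_index <- NULL
  new_vcf_sweep(ref$t_ms, ref$V_cmd_mV, avg(function(s) s$I_uA), f_avg,
                meta, ref$protocol)
}

#' Normalise a fluorescence trace to its baseline
#'
#' Divides the trace by the mean over the baseline window so the baseline
#' level becomes 1, the reference for delta-F/F.
#'
#' @param trace numeric fluorescence series (typically bleach-compensated).
#' @param baseline_window inclusive 1-based index range `c(start, end)`.
#' @param t_ms optional time base carried along.
#' @param compensation_mode label recording how the trace was compensated.
#' @return an object of class `normalized_trace` with fields `t_ms`, `F_norm`,
#'   `baseline_window`, `compensation_mode`.
#' @export
normalize_baseline <- function(trace, baseline_window, t_ms = NULL,
                               compensation_mode = "none") {
  n <- length(trace)
  w <- baseline_window
  if (length(w) != 2L || w[1] < 1 || w[2] > n || w[1] > w[2]) {
    stop("baseline window outside trace", call. = FALSE)
  }
  b <- mean(trace[w[1]:w[2]])
  if (!is.finite(b) || b <= 0) {
    stop("non-positive baseline mean", call. = FALSE)
  }
  structure(list(t_ms = if (is.null(t_ms)) (seq_len(n) - 1) else t_ms,
                 F_norm = trace / b, baseline_window = c(w[1], w[2]),
                 compensation_mode = compensation_mode),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat("Normalized fluorescence trace:", length(x$F_norm), "samples;",
      "baseline samples", x$baseline_window[1], "-", x$baseline_window[2],
      "; compensation:", x$compensation_mode, "\n")
  invisible(x)
}

#' Fractional fluorescence change over a window
#'
#' `100 * (mean(F_norm over window) - 1)`, signed: negative for a downward
#' deflection. Reporting layers may convert to magnitude plus direction.
#'
#' @param norm a [normalize_baseline()] result.
#' @param window inclusive 1-based index range `c(start, end)`.
#' @return delta-F/F in percent (signed).
#' @export
delta_f_over_f <- function(norm, window) {
  stopifnot(inherits(norm, "normalized_trace"))
  w <- window
  if (length(w) != 2L || w[1] < 1 || w[2] > length(norm$F_norm) ||
      w[1] > w[2]) {
    stop("empty or out-of-range window", call. = FALSE)
  }
  100 * (mean(norm$F_norm[w[1]:w[2]]) - 1)
}

## pre-segment (resting baseline) windows of a sweep, used for bleach fitting
holding_windows <- function(sweep, segment = "pre") {
  segs <- protocol_segments(sweep$protocol)
  segs <- segs[segs$segment %in% segment, , drop = FALSE]
  lapply(seq_len(nrow(segs)), function(i) {
    c(segs$start[i], segs$start[i] + segs$n[i] - 1L)
  })
}

#' Bleach-compensate one fluorescence channel of a sweep
#'
#' Estimates the bleach rate over the pre-step holding segments (the resting
#' baseline of every episode, uncontaminated by voltage-evoked signal) and
#' applies the requested compensation to the whole channel.
#'
#' @param sweep a `vcf_sweep`.
#' @param channel channel label; default first channel.
#' @param mode `"first_order"`, `"exact_division"` or `"additive"`.
#' @return list with `sweep` (compensated copy) and `bleach`
#'   (the `bleach_estimate`).
#' @export
preprocess_sweep <- function(sweep, channel = NULL,
                             mode = c("first_order", "exact_division",
                                      "additive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (is.null(channel)) channel <- names(sweep$F_channels)[1L]
  f <- sweep$F_channels[[channel]]
  if (is.null(f)) stop("unknown channel '", channel, "'", call. = FALSE)
  est <- estimate_bleach_rate(f, holding_windows(sweep))
  comp <- switch(mode,
    additive = compensate_additive(f, est),
    compensate_multiplicative(f, est, mode))
  sweep$F_channels[[channel]] <- comp
  list(sweep = sweep, bleach = est, mode = mode, channel = channel)
}
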