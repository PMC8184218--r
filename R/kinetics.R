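#' Mono-exponential fit of a relaxation segment
#'
#' Least-squares fit of `y(t) = offset + amplitude * exp(-(t - t0)/tau)`.
#' Initialisation is deterministic: the offset from the final tenth of the
#' segment, the amplitude from the first residual, tau from a log-linear
#' regression of the residual magnitude; the fit is then refined by
#' Levenberg-Marquardt.
#'
#' @param t_ms time base (ms), >= 10 samples.
#' @param y signal values.
#' @param t0_ms segment origin; default the first time point.
#' @return an object of class `exp_fit`: `tau_ms`, `amplitude`, `offset`,
#'   `rss`, `converged`. Non-convergence yields `converged = FALSE` with
#'   `tau_ms = NA` and a `diagnostics` message; a flat segment is an error.
#' @export
fit_monoexponential <- function(t_ms, y, t0_ms = NULL) {
  stopifnot(length(t_ms) == length(y))
  if (length(y) < 10L) stop("need >= 10 samples", call. = FALSE)
  if (is.null(t0_ms)) t0_ms <- t_ms[1L]
  rng <- diff(range(y))
  if (rng == 0 || rng < 1e-12 * max(abs(y), 1)) {
    stop("degenerate input: flat segment", call. = FALSE)
  }
  tt <- t_ms - t0_ms
  n <- length(y)
  tail_idx <- seq.int(max(1L, floor(0.9 * n)), n)
  offset0 <- mean(y[tail_idx])
  resid0 <- y - offset0
  amp0 <- resid0[1L]
  if (amp0 == 0) amp0 <- rng * sign(y[1L] - offset0 + .Machine$double.eps)
  use <- which(sign(resid0) == sign(amp0) & abs(resid0) > 1e-3 * abs(amp0))
  tau0 <- if (length(use) >= 3L) {
    sl <- stats::coef(stats::lm(log(abs(resid0[use])) ~ tt[use]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tt)) / 5
  } else {
    diff(range(tt)) / 5
  }
  dat <- data.frame(tt = tt, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * exp(-tt / tau), data = dat,
                      start = list(offset = offset0, amplitude = amp0,
                                   tau = max(tau0, 1e-6)),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(tau_ms = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "exp_fit"))
  }
  co <- stats::coef(fit)
  structure(list(tau_ms = unname(co[["tau"]]),
                 amplitude = unname(co[["amplitude"]]),
                 offset = unname(co[["offset"]]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = TRUE, diagnostics = NULL),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Exponential fit: tau = %.3g ms, amplitude = %.4g, offset = %.4g\n",
                x$tau_ms, x$amplitude, x$offset))
  } else {
    cat("Exponential fit did not converge:", x$diagnostics, "\n")
  }
  invisible(x)
}

#' Activation time constant of the slow fluorescence component
#'
#' Compensates and normalises the episode of the requested step, then fits a
#' mono-exponential from just after the fast window (default 5 ms past the
#' transition, excluding the instantaneous component) to the end of the step.
#'
#' @param sweep a `vcf_sweep`.
#' @param step_mV which step to analyse (default the most hyperpolarised).
#' @param channel channel label; default first.
#' @param skip_ms dead time after the transition excluded from the fit.
#' @param compensation bleach compensation mode.
#' @return an `exp_fit`.
#' @export
fit_slow_kinetics <- function(sweep, step_mV = NULL, channel = NULL,
                              skip_ms = 5,
                              compensation = "first_order") {
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (is.null(channel)) channel <- names(sweep$F_channels)[1L]
  if (is.null(step_mV)) step_mV <- min(sweep$protocol$steps_mV)
  pp <- preprocess_sweep(sweep, channel, compensation)
  f <- pp$sweep$F_channels[[channel]]
  segs <- protocol_segments(sweep$protocol)
  stp <- segs[segs$segment == "step" & segs$v_mV == step_mV, , drop = FALSE]
  if (nrow(stp) != 1L) stop("no unique step at ", step_mV, " mV",
                            call. = FALSE)
  pre <- segs[segs$segment == "pre" & segs$episode == stp$episode, ]
  norm <- normalize_baseline(f, c(pre$start, pre$start + pre$n - 1L),
                             t_ms = sweep$t_ms)
  rate <- sweep$protocol$rate_kHz
  i0 <- stp$start + as.integer(round(skip_ms * rate))
  i1 <- stp$start + stp$n - 1L
  fit_monoexponential(sweep$t_ms[i0:i1], norm$F_norm[i0:i1],
                      t0_ms = sweep$t_ms[i0])
}

#' Compare time constants (or any scalar summaries) across conditions
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param design `"two_sample_t"` (unpaired, equal variances), `"paired_t"`,
#'   or `"anova_tukey"` (one-way ANOVA followed by Tukey's HSD).
#' @return an object of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `groups` (mean/sem/n per condition), and for the ANOVA design
#'   `tukey`, a data.frame of honest-significant-difference pairs.
#' @export
compare_tau <- function(groups, design = c("two_sample_t", "paired_t",
                                           "anova_tukey")) {
  design <- match.arg(design)
  stopifnot(is.list(groups), !is.null(names(groups)))
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L)) stop("insufficient n: every group needs >= 2 values",
                         call. = FALSE)
  summ <- data.frame(group = names(groups),
                     mean = vapply(groups, mean, 1),
                     sem = vapply(groups, function(g) {
                       stats::sd(g) / sqrt(length(g))
                     }, 1),
                     n = ns, row.names = NULL)
  tukey <- NULL
  if (design == "anova_tukey") {
    if (length(groups) < 3L) stop("ANOVA design needs >= 3 groups",
                                  call. = FALSE)
    df <- data.frame(y = unlist(groups, use.names = FALSE),
                     g = factor(rep(names(groups), ns)))
    fit <- stats::aov(y ~ g, data = df)
    an <- summary(fit)[[1L]]
    statistic <- an[["F value"]][1L]
    p_value <- an[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    if (length(groups) != 2L) stop("t-test designs need exactly 2 groups",
                                   call. = FALSE)
    if (design == "paired_t" && ns[1L] != ns[2L]) {
      stop("paired design needs equal group lengths", call. = FALSE)
    }
    ht <- stats::t.test(groups[[1L]], groups[[2L]],
                        paired = design == "paired_t",
                        var.equal = design == "two_sample_t")
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  }
  structure(list(test = design, statistic = statistic, p_value = p_value,
                 groups = summ, tukey = tukey),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  print(x$groups)
  if (!is.null(x$tukey)) print(x$tukey)
  invisible(x)
}
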