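#' Pipeline run configuration
#'
#' A single validated configuration drives the whole chain
#' simulate -> preprocess -> decompose -> conductance -> kinetics. It is
#' echoed verbatim into the report so every number is reproducible from
#' config + seed.
#'
#' @param preset preset name, see [list_presets()].
#' @param seed integer seed for all randomness.
#' @param noise logical; `FALSE` runs the generator noiselessly.
#' @param n_repeats,atp_uM optional overrides of the preset condition.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "decompose", "conductance", "kinetics")`;
#'   later stages require the earlier ones.
#' @param fast_window_ms,steady_window_ms extraction windows (ms);
#'   `steady_window_ms = NULL` picks 50/100 ms by agonist condition.
#' @param compensation bleach compensation mode for step protocols.
#' @param tail_settle_ms,tail_window_ms tail-current window (ms).
#' @param r2_threshold linearity classification cutoff.
#' @return an object of class `vcf_config`.
#' @export
vcf_config <- function(preset, seed = 1L, noise = TRUE, n_repeats = NULL,
                       atp_uM = NULL,
                       stages = c("simulate", "preprocess", "decompose",
                                  "conductance", "kinetics"),
                       fast_window_ms = 5, steady_window_ms = NULL,
                       compensation = "first_order",
                       tail_settle_ms = 1, tail_window_ms = 3,
                       r2_threshold = 0.98) {
  all_stages <- c("simulate", "preprocess", "decompose", "conductance",
                  "kinetics")
  stages <- as.character(stages)
  if (length(setdiff(stages, all_stages))) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "), call. = FALSE)
  }
  idx <- sort(match(stages, all_stages))
  if (length(idx) && !identical(idx, seq_len(max(idx)))) {
    stop("stages must form a prefix of the pipeline (later stages need ",
         "the earlier ones)", call. = FALSE)
  }
  get_preset(preset)  # validates the name
  structure(list(preset = preset, seed = as.integer(seed), noise = noise,
                 n_repeats = n_repeats, atp_uM = atp_uM, stages = stages,
                 fast_window_ms = fast_window_ms,
                 steady_window_ms = steady_window_ms,
                 compensation = compensation,
                 tail_settle_ms = tail_settle_ms,
                 tail_window_ms = tail_window_ms,
                 r2_threshold = r2_threshold),
            class = "vcf_config")
}

#' Run the full analysis pipeline on one configuration
#'
#' Executes the enabled stages in order, deterministically for a given seed,
#' and assembles a structured report: the per-step decomposition table, F-V
#' curves with linear fits and linearity classification, the tail-current G-V
#' curve with its two-state Boltzmann fit, the slow-component/conductance
#' overlap score, and the slow-component activation kinetics at the most
#' hyperpolarised step.
#'
#' @param config a [vcf_config()].
#' @return an object of class `vcf_report`; stage timings are recorded in
#'   `timings_s`.
#' @export
run_vcf <- function(config) {
  stopifnot(inherits(config, "vcf_config"))
  report <- list(config = unclass(config),
                 version = as.character(utils::packageVersion("fluorovolt")),
                 timings_s = list())
  class(report) <- "vcf_report"
  preset <- get_preset(config$preset)
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    report$timings_s[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  on_stage <- function(s) s %in% config$stages
  if (!on_stage("simulate")) return(report)

  sweeps <- tic("simulate", simulate_preset(
    preset, seed = config$seed, noise = config$noise,
    n_repeats = config$n_repeats, atp_uM = config$atp_uM))
  report$n_repeats <- length(sweeps)
  report$n_samples <- length(sweeps[[1L]]$t_ms)
  if (!on_stage("preprocess")) return(report)

  avg <- tic("preprocess", average_repeats(sweeps))
  pp <- preprocess_sweep(avg, preset$channel, config$compensation)
  report$bleach <- pp$bleach
  if (!on_stage("decompose")) return(report)

  decomp <- tic("decompose", decompose_sweep(
    avg, channel = preset$channel, fast_window_ms = config$fast_window_ms,
    steady_window_ms = config$steady_window_ms,
    compensation = config$compensation))
  report$decomposition <- decomp
  report$fv_fast <- build_fv(decomp, "fast")
  report$fv_steady <- build_fv(decomp, "steady")
  report$linear_fit_fast <- fit_linear(report$fv_fast)
  report$linear_fit_steady <- fit_linear(report$fv_steady)
  report$classification_steady <-
    classify_linearity(report$fv_steady, config$r2_threshold)
  if (!on_stage("conductance")) return(report)

  report <- tic("conductance", {
    has_tail <- preset$protocol$tail_ms > 0
    if (has_tail && preset$conductance$N_gamma_uS > 0) {
      tails <- tail_currents(avg, config$tail_settle_ms,
                             config$tail_window_ms)
      report$tail_currents <- tails
      report$gv <- gv_from_tails(tails$amplitude_uA, tails$step_mV)
      report$boltzmann <- tryCatch(fit_boltzmann(report$gv),
                                   error = function(e) NULL)
      slow_ref <- decomp$dF_slow_pct[which.min(decomp$dV_mV)]
      if (abs(slow_ref) > 0) {
        report$fv_slow_norm <- build_fv(decomp, "slow",
                                        normalize = "max_hyperpol")
        report$overlap_rms <- overlap_score(report$fv_slow_norm, report$gv)
      }
    }
    report
  })
  if (!on_stage("kinetics")) return(report)

  report$slow_kinetics <- tic("kinetics", tryCatch(
    fit_slow_kinetics(avg, channel = preset$channel,
                      skip_ms = config$fast_window_ms,
                      compensation = config$compensation),
    error = function(e) structure(
      list(tau_ms = NA_real_, amplitude = NA_real_, offset = NA_real_,
           rss = NA_real_, converged = FALSE,
           diagnostics = conditionMessage(e)), class = "exp_fit")))
  report
}

#' @export
print.vcf_report <- function(x, ...) {
  cat("VCF pipeline report (preset ", x$config$preset, ", seed ",
      x$config$seed, ")\n", sep = "")
  if (!is.null(x$decomposition)) {
    cat("\nPer-step decomposition (percent delta-F/F):\n")
    print(as.data.frame(x$decomposition), row.names = FALSE)
    cat("\nFast F-V: ")
    print(x$linear_fit_fast)
    cat("Steady F-V classified:", x$classification_steady$label, "\n")
  }
  if (!is.null(x$boltzmann)) {
    cat("\nG-V ")
    print(x$boltzmann)
  }
  if (!is.null(x$overlap_rms)) {
    cat(sprintf("Slow F-V / G-V overlap RMS: %.4f\n", x$overlap_rms))
  }
  if (!is.null(x$slow_kinetics) && x$slow_kinetics$converged) {
    cat(sprintf("Slow-component tau at %g mV: %.1f ms\n",
                min(get_preset(x$config$preset)$protocol$steps_mV),
                x$slow_kinetics$tau_ms))
  }
  invisible(x)
}

#' Compare two pipeline reports step by step
#'
#' Per-voltage differences of the decomposition components (A minus B), plus
#' a paired t-test across voltages for each component.
#'
#' @param report_a,report_b [run_vcf()] reports from the same protocol.
#' @return list with `differences` (data.frame) and `tests` (named list of
#'   `group_comparison` objects).
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "vcf_report"), inherits(report_b, "vcf_report"))
  da <- report_a$decomposition; db <- report_b$decomposition
  if (is.null(da) || is.null(db)) {
    stop("both reports need a decomposition stage", call. = FALSE)
  }
  if (!identical(da$step_mV, db$step_mV) ||
      !identical(da$dV_mV, db$dV_mV)) {
    stop("protocol mismatch between reports", call. = FALSE)
  }
  comp <- c("dF_fast_pct", "dF_steady_pct", "dF_slow_pct")
  diffs <- data.frame(step_mV = da$step_mV, dV_mV = da$dV_mV)
  for (cc in comp) diffs[[paste0("d_", cc)]] <- da[[cc]] - db[[cc]]
  tests <- lapply(comp, function(cc) {
    compare_tau(list(A = da[[cc]], B = db[[cc]]), design = "paired_t")
  })
  names(tests) <- comp
  list(differences = diffs, tests = tests)
}
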