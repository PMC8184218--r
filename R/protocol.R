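#' Step-pulse protocol description
#'
#' A protocol defines one family of voltage-step episodes. Each episode is the
#' concatenation of a pre segment at the holding potential (the baseline), the
#' test step, an optional tail segment at a fixed tail potential (for tail
#' current G-V analysis), and a post segment back at holding. A sweep holds
#' all episodes back to back, one per entry of `steps_mV`.
#'
#' @param hold_mV holding potential (mV).
#' @param steps_mV ordered vector of step potentials (mV); must be non-empty
#'   with no duplicates.
#' @param pre_ms,step_ms,tail_ms,post_ms segment durations (ms); all >= 0,
#'   `tail_ms = 0` drops the tail segment.
#' @param tail_mV tail potential (mV), conventionally -60.
#' @param rate_kHz sampling rate (kHz).
#' @param inter_sweep_s rest between protocol repeats (s); metadata only, the
#'   rest is not sampled (the excitation shutter is closed between episodes,
#'   so neither bleaching nor acquisition advances during it).
#' @return an object of class `vcf_protocol`.
#' @examples
#' vcf_protocol(hold_mV = 20, steps_mV = seq(40, -160, by = -20))
#' @export
vcf_protocol <- function(hold_mV, steps_mV, pre_ms = 100, step_ms = 500,
                         tail_ms = 100, post_ms = 100, tail_mV = -60,
                         rate_kHz = 20, inter_sweep_s = 1) {
  p <- structure(list(
    hold_mV = as.numeric(hold_mV), steps_mV = as.numeric(steps_mV),
    pre_ms = as.numeric(pre_ms), step_ms = as.numeric(step_ms),
    tail_ms = as.numeric(tail_ms), post_ms = as.numeric(post_ms),
    tail_mV = as.numeric(tail_mV), rate_kHz = as.numeric(rate_kHz),
    inter_sweep_s = as.numeric(inter_sweep_s)
  ), class = "vcf_protocol")
  problems <- validate_protocol(p)
  if (length(problems)) {
    stop("invalid protocol: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  p
}

#' Validate a protocol, returning problems by field
#'
#' @param p a list with the fields of [vcf_protocol()].
#' @return character vector of problems, each naming the offending field;
#'   empty when valid.
#' @export
validate_protocol <- function(p) {
  problems <- character()
  need <- c("hold_mV", "steps_mV", "pre_ms", "step_ms", "tail_ms", "post_ms",
            "tail_mV", "rate_kHz")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    return(paste0("missing field '", missing, "'"))
  }
  chk_num <- function(field, n = 1L) {
    v <- p[[field]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      problems <<- c(problems, paste0("'", field, "' must be finite numeric"))
      FALSE
    } else TRUE
  }
  for (f in need) chk_num(f)
  if (!length(problems)) {
    for (f in c("pre_ms", "step_ms", "tail_ms", "post_ms")) {
      if (p[[f]] < 0) problems <- c(problems, paste0("'", f, "' must be >= 0"))
    }
    if (p$rate_kHz <= 0) problems <- c(problems, "'rate_kHz' must be > 0")
    if (length(p$steps_mV) < 1) {
      problems <- c(problems, "'steps_mV' must be non-empty")
    } else if (anyDuplicated(p$steps_mV)) {
      problems <- c(problems, "'steps_mV' must not contain duplicates")
    }
    if (p$step_ms == 0) problems <- c(problems, "'step_ms' must be > 0")
  }
  problems
}

## samples in a segment: round(duration * rate), first sample at segment onset
segment_samples <- function(duration_ms, rate_kHz) {
  as.integer(round(duration_ms * rate_kHz))
}

#' Per-segment sample layout of a protocol
#'
#' @param protocol a [vcf_protocol()].
#' @return data.frame with one row per segment: `episode`, `segment`
#'   (pre/step/tail/post), `v_mV`, `start` (1-based first sample), `n`
#'   (sample count), `t_start_ms`, `duration_ms`.
#' @export
protocol_segments <- function(protocol) {
  stopifnot(inherits(protocol, "vcf_protocol"))
  rate <- protocol$rate_kHz
  seg_def <- data.frame(
    segment = c("pre", "step", "tail", "post"),
    duration_ms = c(protocol$pre_ms, protocol$step_ms, protocol$tail_ms,
                    protocol$post_ms),
    stringsAsFactors = FALSE
  )
  seg_def <- seg_def[seg_def$duration_ms > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(protocol$steps_mV), function(i) {
    v <- c(pre = protocol$hold_mV, step = protocol$steps_mV[i],
           tail = protocol$tail_mV, post = protocol$hold_mV)
    data.frame(episode = i, segment = seg_def$segment,
               v_mV = unname(v[seg_def$segment]),
               n = segment_samples(seg_def$duration_ms, rate),
               duration_ms = seg_def$duration_ms,
               stringsAsFactors = FALSE)
  }))
  out$start <- cumsum(c(1L, out$n[-nrow(out)]))
  out$t_start_ms <- (out$start - 1L) / rate
  out[, c("episode", "segment", "v_mV", "start", "n", "t_start_ms",
          "duration_ms")]
}

#' Total number of samples in one sweep of a protocol
#' @param protocol a [vcf_protocol()].
#' @return integer sample count.
#' @export
protocol_n_samples <- function(protocol) {
  sum(protocol_segments(protocol)$n)
}

#' Command-voltage trace of a protocol
#' @param protocol a [vcf_protocol()].
#' @return numeric vector, one command voltage (mV) per sample.
#' @export
protocol_voltage <- function(protocol) {
  segs <- protocol_segments(protocol)
  rep(segs$v_mV, segs$n)
}

#' Time base of a protocol
#' @param protocol a [vcf_protocol()].
#' @return numeric vector of sample times (ms), starting at 0.
#' @export
protocol_time <- function(protocol) {
  (seq_len(protocol_n_samples(protocol)) - 1) / protocol$rate_kHz
}

#' @export
print.vcf_protocol <- function(x, ...) {
  cat("Step protocol: hold", x$hold_mV, "mV;", length(x$steps_mV), "steps",
      max(x$steps_mV), "to", min(x$steps_mV), "mV\n")
  cat("  segments (ms): pre", x$pre_ms, "| step", x$step_ms, "| tail",
      x$tail_ms, "@", x$tail_mV, "mV | post", x$post_ms, "\n")
  cat("  sampling:", x$rate_kHz, "kHz;", protocol_n_samples(x),
      "samples per sweep\n")
  invisible(x)
}
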