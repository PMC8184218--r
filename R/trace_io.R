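## Plain-text interchange formats: sweeps as CSV with a commented ("#") header
## block, protocols as JSON. All voltages mV, times ms, currents uA,
## fluorescence arbitrary units; not configurable.

SWEEP_SCHEMA_VERSION <- "1"

#' Write a sweep recording to CSV
#'
#' Columnar text: `t_ms`, `V_cmd_mV`, `I_uA`, then one column per fluorescence
#' channel, preceded by a commented header block carrying the schema version,
#' rate, channel labels, metadata and the full protocol (as embedded JSON).
#' Numbers round-trip to at least 12 significant digits.
#'
#' @param sweep a `vcf_sweep`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "vcf_sweep"))
  if (length(sweep$t_ms) == 0L) stop("empty sweep", call. = FALSE)
  meta <- sweep$meta
  hdr <- c(
    paste0("# fluorovolt_sweep"),
    paste0("# schema_version: ", SWEEP_SCHEMA_VERSION),
    paste0("# rate_kHz: ", format(sweep$protocol$rate_kHz, digits = 15)),
    paste0("# channels: ", paste(names(sweep$F_channels), collapse = ",")),
    paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                        digits = NA, null = "null")),
    paste0("# protocol: ", jsonlite::toJSON(unclass(sweep$protocol),
                                            auto_unbox = TRUE, digits = NA))
  )
  df <- data.frame(t_ms = sweep$t_ms, V_cmd_mV = sweep$V_cmd_mV,
                   I_uA = sweep$I_uA)
  for (ch in names(sweep$F_channels)) df[[ch]] <- sweep$F_channels[[ch]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    formatC(col, digits = 15, format = "g")
  }), sep = ","))
  writeLines(body, con)
  invisible(path)
}

parse_sweep_header <- function(lines) {
  hdr <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# ([A-Za-z_]+): (.*)$", ln))[[1L]]
    if (length(m) == 3L) hdr[[m[2L]]] <- m[3L]
  }
  hdr
}

#' Read a sweep recording written by [write_sweep()]
#'
#' @param path CSV path.
#' @return a validated `vcf_sweep`. Missing columns, a malformed header and a
#'   non-uniform time base each raise a distinct error.
#' @export
read_sweep <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  n_hdr <- match(FALSE, is_hdr, nomatch = length(lines) + 1L) - 1L
  hdr <- parse_sweep_header(lines[seq_len(n_hdr)])
  if (is.null(hdr$rate_kHz) || is.null(hdr$channels) ||
      is.null(hdr$schema_version)) {
    stop("malformed header: need schema_version, rate_kHz and channels",
         call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(hdr$rate_kHz))
  if (!is.finite(rate) || rate <= 0) {
    stop("malformed header: invalid rate_kHz", call. = FALSE)
  }
  channels <- strsplit(hdr$channels, ",", fixed = TRUE)[[1L]]
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_ms", "V_cmd_mV", "I_uA", channels)
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- diff(df$t_ms)
  if (nrow(df) > 1L &&
      (any(dt <= 0) || max(abs(dt - 1 / rate)) > 1e-6 / rate)) {
    stop("non-uniform time base", call. = FALSE)
  }
  meta <- if (!is.null(hdr$meta)) {
    jsonlite::fromJSON(hdr$meta, simplifyVector = TRUE)
  } else {
    list()
  }
  protocol <- if (!is.null(hdr$protocol)) {
    pl <- jsonlite::fromJSON(hdr$protocol, simplifyVector = TRUE)
    do.call(vcf_protocol, pl)
  } else {
    NULL
  }
  f <- lapply(channels, function(ch) df[[ch]])
  names(f) <- channels
  new_vcf_sweep(df$t_ms, df$V_cmd_mV, df$I_uA, f, meta, protocol)
}

#' Write a protocol to JSON
#' @param protocol a [vcf_protocol()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "vcf_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a protocol from JSON
#'
#' @param path JSON path.
#' @return a [vcf_protocol()]. Schema violations are reported with the names
#'   of the offending fields.
#' @export
read_protocol <- function(path) {
  pl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(vcf_protocol))
  extra <- setdiff(names(pl), known)
  if (length(extra)) {
    stop("unknown protocol fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(vcf_protocol, pl)
}
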