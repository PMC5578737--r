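#' Recording metadata
#'
#' Describes the conditions of a single bilayer recording: holding potential,
#' KCl concentration on each side of the membrane, temperature and sampling.
#' Pure KCl buffers are assumed throughout, so the chloride concentration on
#' each side equals the potassium concentration.
#'
#' Sign convention: `voltage_mV` is the potential of the trans (IMS-facing)
#' side relative to cis, chosen so that a cation-selective channel under a
#' cis-high (e.g. 250:20 mM) KCl gradient has a positive reversal potential.
#'
#' @param voltage_mV applied holding potential (mV, convention above).
#' @param cis_K_mM,trans_K_mM KCl concentration in the cis / trans chamber
#'   (mM); must be positive.
#' @param temperature_K absolute temperature, in `[273, 320]` K.
#' @param sample_rate_Hz samples per second (> 0).
#' @param duration_s recording length in seconds (> 0).
#' @param label free-text label (variant, condition, substrate concentration).
#' @param u_rev_mV optional known reversal potential (mV) under these buffers;
#'   used by [extract_events()] to compute the driving force. `NULL` means
#'   unknown (treated as 0 mV, appropriate for symmetric buffers).
#' @return an object of class `recording_meta`.
#' @export
recording_meta <- function(voltage_mV, cis_K_mM, trans_K_mM,
                           temperature_K = 298.15, sample_rate_Hz,
                           duration_s, label = "", u_rev_mV = NULL) {
  meta <- structure(
    list(voltage_mV = as.numeric(voltage_mV),
         cis_K_mM = as.numeric(cis_K_mM),
         trans_K_mM = as.numeric(trans_K_mM),
         temperature_K = as.numeric(temperature_K),
         sample_rate_Hz = as.numeric(sample_rate_Hz),
         duration_s = as.numeric(duration_s),
         label = as.character(label),
         u_rev_mV = if (is.null(u_rev_mV)) NULL else as.numeric(u_rev_mV)),
    class = "recording_meta")
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  ok <- function(x) length(x) == 1L && is.finite(x)
  if (!ok(meta$cis_K_mM) || meta$cis_K_mM <= 0 ||
      !ok(meta$trans_K_mM) || meta$trans_K_mM <= 0)
    stop_tim23("KCl concentrations must be positive", "tim23_invalid_meta")
  if (!ok(meta$sample_rate_Hz) || meta$sample_rate_Hz <= 0)
    stop_tim23("sample_rate_Hz must be positive", "tim23_invalid_meta")
  if (!ok(meta$duration_s) || meta$duration_s <= 0)
    stop_tim23("duration_s must be positive", "tim23_invalid_meta")
  if (!ok(meta$temperature_K) ||
      meta$temperature_K < 273 || meta$temperature_K > 320)
    stop_tim23("temperature_K must lie in [273, 320]", "tim23_invalid_meta")
  if (!ok(meta$voltage_mV))
    stop_tim23("voltage_mV must be a finite scalar", "tim23_invalid_meta")
  invisible(meta)
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(sprintf(
    "<recording_meta> %s\n  V = %g mV (trans rel. cis), KCl %g:%g mM cis:trans, T = %g K\n  %g Hz x %g s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$voltage_mV, x$cis_K_mM, x$trans_K_mM, x$temperature_K,
    x$sample_rate_Hz, x$duration_s))
  invisible(x)
}

#' Sampled current trace
#'
#' A uniformly sampled single-channel current recording. Sample `i` is taken
#' at time `(i - 1) / sample_rate_Hz`.
#'
#' @param samples numeric vector of currents (pA); all finite.
#' @param meta a [recording_meta()]; `length(samples)` must equal
#'   `round(duration_s * sample_rate_Hz)`.
#' @return object of class `channel_trace` with elements `samples` and `meta`.
#' @export
channel_trace <- function(samples, meta) {
  validate_meta(meta)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop_tim23("trace samples must all be finite", "tim23_invalid_trace")
  n_expect <- round(meta$duration_s * meta$sample_rate_Hz)
  if (length(samples) != n_expect)
    stop_tim23(sprintf(
      "trace has %d samples but meta implies %d", length(samples), n_expect),
      "tim23_invalid_trace")
  structure(list(samples = samples, meta = meta), class = "channel_trace")
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace> %d samples (%g s at %g Hz), V = %g mV\n",
              length(x$samples), x$meta$duration_s, x$meta$sample_rate_Hz,
              x$meta$voltage_mV))
  invisible(x)
}

trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$meta$sample_rate_Hz
}

#' Idealized (piecewise-constant) trace
#'
#' @param segments data.frame with columns `start_s`, `duration_s`,
#'   `level_pA`; segments must be contiguous, non-overlapping and adjacent
#'   segments must have distinct levels.
#' @param meta the [recording_meta()] of the underlying recording.
#' @return object of class `idealized_trace`.
#' @export
idealized_trace <- function(segments, meta) {
  validate_meta(meta)
  stopifnot(is.data.frame(segments),
            all(c("start_s", "duration_s", "level_pA") %in% names(segments)))
  if (nrow(segments) == 0L)
    stop_tim23("idealized trace needs at least one segment",
               "tim23_invalid_idealization")
  if (any(segments$duration_s <= 0))
    stop_tim23("segment durations must be positive",
               "tim23_invalid_idealization")
  ends <- segments$start_s + segments$duration_s
  if (nrow(segments) > 1L) {
    gap <- abs(segments$start_s[-1L] - ends[-nrow(segments)])
    if (any(gap > 1e-9 * meta$duration_s))
      stop_tim23("segments must be contiguous", "tim23_invalid_idealization")
    if (any(diff(segments$level_pA) == 0))
      stop_tim23("adjacent segments must have distinct levels",
                 "tim23_invalid_idealization")
  }
  structure(list(segments = segments, meta = meta),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("<idealized_trace> %d segments over %g s, levels %g to %g pA\n",
              nrow(x$segments), x$meta$duration_s,
              min(x$segments$level_pA), max(x$segments$level_pA)))
  invisible(x)
}

#' Table of gating events
#'
#' One row per transition of an idealized trace that passes the amplitude
#' floor. `amplitude_pA` is the signed level difference (new minus old),
#' `conductance_pS` the absolute conductance change given the driving force,
#' and `direction` is `"opening"` or `"closing"`.
#'
#' @param events data.frame with columns `time_s`, `amplitude_pA`,
#'   `conductance_pS`, `direction`.
#' @param meta [recording_meta()] of the source recording.
#' @return object of class `event_table`.
#' @export
event_table <- function(events, meta) {
  validate_meta(meta)
  need <- c("time_s", "amplitude_pA", "conductance_pS", "direction")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop_tim23(paste("event table needs columns", paste(need, collapse = ", ")),
               "tim23_schema")
  if (nrow(events) > 0L) {
    if (any(events$conductance_pS <= 0))
      stop_tim23("conductance_pS must be positive", "tim23_schema")
    if (!all(events$direction %in% c("opening", "closing")))
      stop_tim23("direction must be 'opening' or 'closing'", "tim23_schema")
  }
  structure(list(events = events[, need], meta = meta),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events over %g s (%s)\n",
              nrow(x$events), x$meta$duration_s,
              if (nzchar(x$meta$label)) x$meta$label else "unlabelled"))
  invisible(x)
}

meta_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

write_meta_json <- function(meta, path) {
  fields <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
}

read_meta_json <- function(path) {
  if (!file.exists(path))
    stop_tim23(paste("metadata sidecar not found:", path), "tim23_io")
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("voltage_mV", "cis_K_mM", "trans_K_mM", "temperature_K",
            "sample_rate_Hz", "duration_s")
  missing <- setdiff(need, names(fields))
  if (length(missing))
    stop_tim23(paste("sidecar missing fields:", paste(missing, collapse = ", ")),
               "tim23_invalid_meta")
  recording_meta(voltage_mV = fields$voltage_mV,
                 cis_K_mM = fields$cis_K_mM,
                 trans_K_mM = fields$trans_K_mM,
                 temperature_K = fields$temperature_K,
                 sample_rate_Hz = fields$sample_rate_Hz,
                 duration_s = fields$duration_s,
                 label = if (is.null(fields$label)) "" else fields$label,
                 u_rev_mV = fields$u_rev_mV)
}

# Full-precision numeric formatting: %.17g round-trips IEEE doubles exactly.
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a trace to delimited text plus a JSON metadata sidecar
#'
#' The trace file is a tab-separated table with header
#' `time_s<TAB>current_pA`; numbers are written at full precision so that
#' [read_trace()] reproduces the samples bit-identically. Metadata is written
#' to `<name>.meta.json` next to the trace file.
#'
#' @param trace a [channel_trace()].
#' @param path output file path (e.g. `"rec.tsv"`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "channel_trace"))
  lines <- c("time_s\tcurrent_pA",
             paste(fmt_full(trace_times(trace)),
                   fmt_full(trace$samples), sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tim23(paste("cannot write trace to", path), "tim23_io")
  write_meta_json(trace$meta, meta_sidecar_path(path))
  invisible(path)
}

#' Read a trace from delimited text plus its JSON metadata sidecar
#'
#' @param path trace file with columns `time_s`, `current_pA` (TSV or CSV).
#' @param sidecar_path metadata JSON; defaults to `<name>.meta.json`.
#' @return a validated [channel_trace()]. Uniform sampling is verified to
#'   within 1 ppm of the nominal sample interval.
#' @export
read_trace <- function(path, sidecar_path = meta_sidecar_path(path)) {
  if (!file.exists(path))
    stop_tim23(paste("trace file not found:", path), "tim23_io")
  meta <- read_meta_json(sidecar_path)
  tab <- data.table::fread(path, sep = "auto", header = TRUE,
                           data.table = FALSE)
  need <- c("time_s", "current_pA")
  if (!all(need %in% names(tab)))
    stop_tim23(paste("trace file missing column(s):",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
               "tim23_missing_column")
  dt_nominal <- 1 / meta$sample_rate_Hz
  if (nrow(tab) > 1L) {
    dev <- abs(diff(tab$time_s) - dt_nominal) / dt_nominal
    if (max(dev) > 1e-6)
      stop_tim23(sprintf(
        "non-uniform sampling: max interval deviation %.3g ppm exceeds 1 ppm",
        max(dev) * 1e6), "tim23_nonuniform_sampling")
  }
  channel_trace(tab$current_pA, meta)
}

#' Write / read an event table (TSV plus JSON metadata sidecar)
#'
#' The event file is tab-separated with header
#' `time_s amplitude_pA conductance_pS direction`; floats are written at full
#' precision so the round-trip is lossless.
#'
#' @param events an [event_table()].
#' @param path output file path.
#' @return `path` invisibly (`write_events`); an [event_table()]
#'   (`read_events`).
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  ev <- events$events
  lines <- c("time_s\tamplitude_pA\tconductance_pS\tdirection",
             if (nrow(ev)) paste(fmt_full(ev$time_s), fmt_full(ev$amplitude_pA),
                                 fmt_full(ev$conductance_pS), ev$direction,
                                 sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tim23(paste("cannot write events to", path), "tim23_io")
  write_meta_json(events$meta, meta_sidecar_path(path))
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, sidecar_path = meta_sidecar_path(path)) {
  if (!file.exists(path))
    stop_tim23(paste("event file not found:", path), "tim23_io")
  meta <- read_meta_json(sidecar_path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("time_s", "amplitude_pA", "conductance_pS", "direction")
  if (nrow(tab) == 0L && ncol(tab) == 4L) names(tab) <- names(tab)  # keep
  if (!all(need %in% names(tab)))
    stop_tim23(paste("event file missing column(s):",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
               "tim23_schema")
  if (nrow(tab) == 0L) {
    tab <- data.frame(time_s = numeric(), amplitude_pA = numeric(),
                      conductance_pS = numeric(), direction = character())
  } else {
    for (col in c("time_s", "amplitude_pA", "conductance_pS"))
      tab[[col]] <- as.numeric(tab[[col]])
    tab$direction <- as.character(tab$direction)
  }
  event_table(tab, meta)
}
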