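#' Idealization parameters
#'
#' @param penalty model-selection penalty per change point (squared-pA units).
#'   `NULL` (default) uses `3 * sigma^2 * log(n)` with `sigma` estimated
#'   robustly from the median absolute deviation of successive differences
#'   divided by `sqrt(2)` — a BIC-like choice, stated so results are
#'   reproducible.
#' @param min_dwell_s shortest retained segment (s). Default 0.5 ms: five
#'   samples at the 10 kHz default acquisition rate, short enough not to
#'   censor substrate-induced flickering.
#' @param min_step_pA smallest level difference kept after merging (pA).
#' @return object of class `idealize_params`.
#' @export
idealize_params <- function(penalty = NULL, min_dwell_s = 5e-4,
                            min_step_pA = 1.5) {
  if (!is.null(penalty) && penalty <= 0)
    stop_tim23("penalty must be strictly positive", "tim23_invalid_params")
  if (min_dwell_s <= 0 || min_step_pA <= 0)
    stop_tim23("min_dwell_s and min_step_pA must be strictly positive",
               "tim23_invalid_params")
  structure(list(penalty = penalty, min_dwell_s = min_dwell_s,
                 min_step_pA = min_step_pA), class = "idealize_params")
}

#' Idealize a current trace by penalized change-point detection
#'
#' Fits a piecewise-constant least-squares model with a per-change-point
#' penalty, solved exactly by functionally pruned dynamic programming (FPOP;
#' identical optimum to exhaustive optimal partitioning), then applies two
#' merge passes: first every segment shorter than
#' `min_dwell_s` is merged into the neighbour whose level is closer
#' (durations filtered before amplitudes — output depends on this order),
#' then adjacent segments whose levels differ by less than `min_step_pA` are
#' merged, smallest difference first. Merged levels are recomputed as the
#' mean of the underlying samples, so the residual mean per segment is ~0.
#'
#' @param trace a [channel_trace()] with at least 10 samples and duration at
#'   least `2 * min_dwell_s`.
#' @param params an [idealize_params()].
#' @return an [idealized_trace()].
#' @export
idealize <- function(trace, params = idealize_params()) {
  stopifnot(inherits(trace, "channel_trace"))
  x <- trace$samples
  n <- length(x)
  fs <- trace$meta$sample_rate_Hz
  if (n < 10L)
    stop_tim23("trace must have at least 10 samples", "tim23_trace_too_short")
  if (trace$meta$duration_s < 2 * params$min_dwell_s)
    stop_tim23("trace shorter than twice the minimum dwell",
               "tim23_trace_too_short")

  penalty <- params$penalty
  if (is.null(penalty)) {
    sigma_hat <- mad(diff(x)) / sqrt(2)
    penalty <- 3 * sigma_hat^2 * log(n)
  }
  # numeric floor: a zero/near-zero penalty (noiseless traces) must still
  # exceed the rounding error of the cumulative-sum cost, or exact ties
  # would split arbitrarily
  penalty <- max(penalty,
                 64 * .Machine$double.eps * n * max(1, max(abs(x)))^2)

  cps <- .fpop_mean(x, penalty)
  bounds <- c(0L, cps, n)            # segment i covers (bounds[i], bounds[i+1]]
  cs <- c(0, cumsum(x))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  lens <- ends - starts + 1L
  sums <- cs[ends + 1L] - cs[starts]

  min_len <- max(1L, as.integer(round(params$min_dwell_s * fs)))

  # duration filter: repeatedly merge the shortest offending segment into
  # the neighbour with the closer level (ties and boundaries -> the only /
  # earlier neighbour)
  repeat {
    if (length(lens) <= 1L) break
    short <- which(lens < min_len)
    if (!length(short)) break
    i <- short[which.min(lens[short])]
    lev <- sums / lens
    left_ok <- i > 1L
    right_ok <- i < length(lens)
    to <- if (left_ok && right_ok) {
      if (abs(lev[i] - lev[i - 1L]) <= abs(lev[i] - lev[i + 1L])) i - 1L
      else i + 1L
    } else if (left_ok) i - 1L else i + 1L
    a <- min(i, to); b <- max(i, to)
    sums[a] <- sums[a] + sums[b]
    lens[a] <- lens[a] + lens[b]
    starts[a] <- starts[a]
    ends[a] <- ends[b]
    keep <- -b
    sums <- sums[keep]; lens <- lens[keep]
    starts <- starts[keep]; ends <- ends[keep]
  }

  # amplitude filter: merge the closest adjacent pair until all level
  # differences reach min_step_pA
  repeat {
    if (length(lens) <= 1L) break
    lev <- sums / lens
    d <- abs(diff(lev))
    j <- which.min(d)
    if (d[j] >= params$min_step_pA) break
    sums[j] <- sums[j] + sums[j + 1L]
    lens[j] <- lens[j] + lens[j + 1L]
    ends[j] <- ends[j + 1L]
    keep <- -(j + 1L)
    sums <- sums[keep]; lens <- lens[keep]
    starts <- starts[keep]; ends <- ends[keep]
  }

  segments <- data.frame(start_s = (starts - 1L) / fs,
                         duration_s = lens / fs,
                         level_pA = sums / lens)
  idealized_trace(segments, trace$meta)
}

# Per-sample reconstruction of an idealized trace on the acquisition grid.
idealized_levels <- function(idealized, n = NULL) {
  fs <- idealized$meta$sample_rate_Hz
  if (is.null(n)) n <- round(idealized$meta$duration_s * fs)
  reps <- round(idealized$segments$duration_s * fs)
  lev <- rep(idealized$segments$level_pA, times = reps)
  length(lev) <- n
  lev
}

#' Residual noise level of an idealization
#'
#' Standard deviation of the trace minus its piecewise-constant
#' reconstruction; an estimate of the recording's noise amplitude.
#'
#' @param trace the original [channel_trace()].
#' @param idealized the matching [idealized_trace()].
#' @return residual standard deviation in pA.
#' @export
residual_sd <- function(trace, idealized) {
  stopifnot(inherits(trace, "channel_trace"),
            inherits(idealized, "idealized_trace"))
  m1 <- trace$meta; m2 <- idealized$meta
  if (m1$sample_rate_Hz != m2$sample_rate_Hz ||
      m1$duration_s != m2$duration_s || m1$voltage_mV != m2$voltage_mV)
    stop_tim23("trace and idealization metadata do not match",
               "tim23_meta_mismatch")
  lev <- idealized_levels(idealized, n = length(trace$samples))
  res <- trace$samples - lev
  sqrt(max(0, mean(res^2) - mean(res)^2))
}
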