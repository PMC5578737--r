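#' Extract gating events from an idealized trace
#'
#' One event per segment boundary. The signed amplitude is the level
#' difference (new minus old); the conductance change is
#' `|amplitude_pA| / |V - U_rev| * 1000` pS, using the reversal potential
#' stored in the metadata (`u_rev_mV`, 0 if absent — appropriate for
#' symmetric buffers). Events whose conductance change falls below
#' `floor_pS` are excluded from the table (and hence from gating frequency
#' and amplitude histograms).
#'
#' Polarity: recordings at negative driving force give negative open levels;
#' direction is assigned from the change in conductance magnitude
#' (`"opening"` if the new level carries more current magnitude).
#'
#' @param idealized an [idealized_trace()].
#' @param floor_pS smallest conductance change counted as a gating event
#'   (default 20 pS).
#' @return an [event_table()] (possibly empty for a single-segment trace).
#' @export
extract_events <- function(idealized, floor_pS = 20) {
  stopifnot(inherits(idealized, "idealized_trace"))
  meta <- idealized$meta
  seg <- idealized$segments
  u_rev <- if (is.null(meta$u_rev_mV)) 0 else meta$u_rev_mV
  driving <- meta$voltage_mV - u_rev
  if (nrow(seg) < 2L) {
    return(event_table(data.frame(time_s = numeric(),
                                  amplitude_pA = numeric(),
                                  conductance_pS = numeric(),
                                  direction = character()), meta))
  }
  if (abs(driving) < .Machine$double.eps^0.5)
    stop_tim23("zero driving force: voltage equals the reversal potential",
               "tim23_zero_driving_force")
  amp <- diff(seg$level_pA)
  ev <- data.frame(
    time_s = seg$start_s[-1L],
    amplitude_pA = amp,
    conductance_pS = abs(amp) / abs(driving) * 1000,
    direction = ifelse(abs(seg$level_pA[-1L]) > abs(seg$level_pA[-nrow(seg)]),
                       "opening", "closing"))
  ev <- ev[ev$conductance_pS >= floor_pS, , drop = FALSE]
  rownames(ev) <- NULL
  event_table(ev, meta)
}

#' Gating frequency in events per minute
#'
#' All gating events of a recording divided by the recording duration,
#' scaled to events per minute.
#'
#' @param events an [event_table()].
#' @return events per minute.
#' @export
gating_frequency <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (events$meta$duration_s <= 0)
    stop_tim23("recording duration must be positive", "tim23_invalid_meta")
  nrow(events$events) / events$meta$duration_s * 60
}

#' Gaussian-mixture fit of conductance-change classes
#'
#' Decomposes the distribution of gating-event conductance changes into `k`
#' Gaussian classes by maximum likelihood (EM). Initialization is
#' deterministic: k-means seeded with the `(2i - 1) / (2k)` quantiles of the
#' amplitudes, so repeated fits of the same data are identical. Components
#' are reported sorted by descending mean.
#'
#' @param events an [event_table()] or a numeric vector of conductance
#'   changes (pS).
#' @param k number of classes (default 3, the three most prominent classes
#'   of a Tim23 gating-event histogram).
#' @param max_iter,tol EM stopping controls.
#' @param sd_floor_pS lower bound on class standard deviations (degenerate,
#'   e.g. identical, amplitudes are held at this floor).
#' @return object of class `conductance_classes`: `k`, `means_pS`, `sds_pS`,
#'   `weights`, `n_events`, `loglik`, `iterations`.
#' @export
fit_conductance_classes <- function(events, k = 3, max_iter = 500,
                                    tol = 1e-8, sd_floor_pS = 1e-3) {
  x <- if (inherits(events, "event_table")) events$events$conductance_pS
       else as.numeric(events)
  n <- length(x)
  if (n < 10 * k)
    stop_tim23(sprintf("need at least %d events to fit %d classes (got %d)",
                       10 * k, k, n), "tim23_too_few_events")
  if (any(x <= 0))
    stop_tim23("conductance changes must be positive", "tim23_schema")

  # deterministic initialization: k-means from interior quantiles
  centers <- unique(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7))
  if (length(centers) < k)
    centers <- centers + seq(0, by = sd_floor_pS, length.out = length(centers))
  km <- if (length(unique(x)) > k) {
    tryCatch(kmeans(x, centers = matrix(centers, ncol = 1)),
             error = function(e) NULL)
  } else NULL
  if (!is.null(km)) {
    mu <- as.numeric(km$centers)
    grp <- km$cluster
    sdv <- vapply(seq_len(k), function(j) {
      xi <- x[grp == j]
      if (length(xi) > 1) sd(xi) else 0
    }, numeric(1))
    w <- tabulate(grp, k) / n
  } else {
    mu <- centers[seq_len(k)]
    sdv <- rep(0, k)
    w <- rep(1 / k, k)
  }
  sdv <- pmax(sdv, sd_floor_pS, sd(x) / 100)

  loglik <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sdv[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / pmax(nk, .Machine$double.xmin)
    sdv <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) /
                  pmax(nk, .Machine$double.xmin))
    sdv <- pmax(sdv, sd_floor_pS)
    if (is.finite(loglik) && ll - loglik < tol * abs(ll)) { loglik <- ll; break }
    loglik <- ll
    if (it >= max_iter)
      stop_tim23("EM did not converge within max_iter", "tim23_no_convergence")
  }
  if (any(w < 0.01))
    stop_tim23(sprintf(
      "degenerate mixture component (weight %.2g%% < 1%%)", 100 * min(w)),
      "tim23_degenerate_component")
  ord <- order(mu, decreasing = TRUE)
  structure(list(k = k, means_pS = mu[ord], sds_pS = sdv[ord],
                 weights = w[ord], n_events = n, loglik = loglik,
                 iterations = it),
            class = "conductance_classes")
}

#' @export
print.conductance_classes <- function(x, ...) {
  cat(sprintf("<conductance_classes> %d classes from %d events\n",
              x$k, x$n_events))
  for (j in seq_len(x$k))
    cat(sprintf("  %6.1f pS (sd %5.1f, weight %4.1f%%)\n",
                x$means_pS[j], x$sds_pS[j], 100 * x$weights[j]))
  invisible(x)
}

#' Open probability of an idealized recording
#'
#' Mean current divided by maximum current, the standard single-channel
#' definition, computed on the idealized levels: the time-weighted mean of
#' the fitted levels divided by the fully open level. Using idealized rather
#' than raw values keeps sample noise out of the denominator; in addition,
#' the open level is estimated by pooling (duration-weighted) all segments
#' whose level lies within `tol_pA` of the largest fitted level, because the
#' plain maximum over many noisy per-segment estimates is biased upward by
#' selection. Negative-going recordings are handled by magnitude.
#'
#' @param idealized an [idealized_trace()].
#' @param tol_pA pooling tolerance for the open level; default the larger of
#'   1.5 pA and 5% of the fitted level range (below the smallest
#'   sub-conductance separation at typical driving forces).
#' @return fraction in `[0, 1]`.
#' @export
open_probability <- function(idealized, tol_pA = NULL) {
  stopifnot(inherits(idealized, "idealized_trace"))
  lev <- abs(idealized$segments$level_pA)
  dur <- idealized$segments$duration_s
  if (max(lev) <= 0)
    stop_tim23("all idealized levels are zero", "tim23_all_closed")
  if (is.null(tol_pA)) tol_pA <- max(1.5, 0.05 * diff(range(lev)))
  top <- lev >= max(lev) - tol_pA
  open_level <- weighted.mean(lev[top], dur[top])
  min(1, weighted.mean(lev, dur) / open_level)
}
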