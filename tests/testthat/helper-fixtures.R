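# Shared fixtures and independent oracles, all built in code.

meta_sym <- function(voltage_mV = 80, duration_s = 1, rate = 1e4) {
  recording_meta(voltage_mV, 250, 250, 298.15, rate, duration_s)
}

meta_asym <- function(voltage_mV = 0, duration_s = 1, rate = 1e4) {
  recording_meta(voltage_mV, 250, 20, 298.15, rate, duration_s)
}

# Two-state (open/closed) model without flicker sub-states; open->closed is
# Boltzmann-tied, closed->open = rc.
two_state_model <- function(rc = 10, v_half = 140, v_slope = 12,
                            noise_sd_pA = 2, g_open = 460) {
  channel_model(levels_pS = c(closed = 0, open = g_open),
                rate_matrix = matrix(c(0, rc, rc * exp(-v_half / v_slope), 0),
                                     2, 2, byrow = TRUE),
                v_half_mV = v_half, v_slope_mV = v_slope,
                noise_sd_pA = noise_sd_pA)
}

# Frozen model with zero transition rates: constant conductance.
frozen_model <- function(g_open = 460, noise_sd_pA = 0, pk_over_pcl = 1) {
  channel_model(levels_pS = c(closed = 0, open = g_open),
                rate_matrix = matrix(0, 2, 2),
                pk_over_pcl = pk_over_pcl, noise_sd_pA = noise_sd_pA)
}

# Build a channel_trace directly from a piecewise-constant level sequence
# (level value per segment, equal-length segments unless lengths given).
pwc_trace <- function(levels_pA, lengths, rate = 1e4, voltage_mV = 80,
                      noise_sd = 0) {
  x <- rep(levels_pA, times = lengths)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  channel_trace(x, meta_sym(voltage_mV, duration_s = length(x) / rate,
                            rate = rate))
}

# Independent oracle: exhaustive O(n^2) optimal-partitioning dynamic program
# for penalized least-squares segmentation. Returns change-point indices
# (last sample of each segment but the final one), like the package solver.
dp_segment_oracle <- function(x, beta) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  F <- c(-beta, rep(Inf, n))
  last <- integer(n + 1)
  for (t in seq_len(n)) {
    i <- seq_len(t)                      # candidate segment starts (1-based)
    vals <- F[i] + (css[t + 1] - css[i]) -
      (cs[t + 1] - cs[i])^2 / (t - i + 1) + beta
    j <- which.min(vals)
    F[t + 1] <- vals[j]
    last[t + 1] <- j - 1L                # change point before sample j
  }
  cps <- integer(0)
  t <- n
  while (last[t + 1] > 0L) {
    cps <- c(last[t + 1], cps)
    t <- last[t + 1]
  }
  cps
}

# The penalty actually used by idealize() for a given trace, reproduced so
# oracle comparisons run at the identical value.
default_penalty <- function(x) {
  sigma_hat <- mad(diff(x)) / sqrt(2)
  max(3 * sigma_hat^2 * log(length(x)),
      64 * .Machine$double.eps * length(x) * max(1, max(abs(x)))^2)
}

# Time-weighted state occupancy of a simulated state path.
path_occupancy <- function(path, k) {
  dwell <- diff(c(path$times, path$duration_s))
  occ <- vapply(seq_len(k), function(s) sum(dwell[path$states == s]),
                numeric(1))
  occ / sum(occ)
}

meta_sidecar_path_for_test <- function(path) {
  tim23ephys:::meta_sidecar_path(path)
}
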