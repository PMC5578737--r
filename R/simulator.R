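#' Channel gating model
#'
#' Parameterization of a continuous-time Markov gating model for a
#' Tim23-like channel. The default topology is a star around the fully open
#' state: two partial closures ("flicker" sub-states) and one full closure.
#' With the default levels `c(closed = 0, sub290 = 290, sub400 = 400,
#' open = 460)` pS the transition amplitudes seen from the open level are
#' 460 pS (full closure), 170 pS and 60 pS (partial closures) — the three
#' conductance-change classes of a Tim23 gating-event histogram.
#'
#' Voltage dependence: the open-to-closed rate is
#' `Q[closed_from_open] = Q[closed->open] * exp((|V| - v_half) / v_slope)`,
#' which makes the stationary open probability of the open/closed pair a
#' Boltzmann function of `|V|` with midpoint `v_half_mV` and slope
#' `v_slope_mV`.
#'
#' Substrate dependence: `flicker_amax`, `ec50_uM` and `hill_h` define the
#' target fold-increase of the stationary gating-event frequency,
#' `fold(c) = 1 + (flicker_amax - 1) * c^h / (c^h + ec50^h)`. At simulation
#' time the open-to-substate ("flicker") rates are multiplied by the factor
#' that achieves exactly this event-frequency fold (see
#' [flicker_rate_multiplier()]); the substate-to-open return rates are left
#' untouched so flicker dwell times do not depend on substrate.
#'
#' @param levels_pS named numeric vector of state conductances (pS); distinct,
#'   non-negative. The largest is the open state; a zero entry (if any) is the
#'   fully closed state; the rest are flicker sub-states.
#' @param rate_matrix square matrix of transition rates (1/s) at 0 mV and no
#'   substrate; non-negative off-diagonal, diagonal ignored (completed to zero
#'   row sums). Row/column order follows `levels_pS`. The open-to-closed
#'   entry is recomputed from `v_half_mV` / `v_slope_mV` at simulation time.
#' @param pk_over_pcl cation/anion permeability ratio P_K/P_Cl (> 0; `Inf`
#'   allowed for an ideally cation-selective channel).
#' @param v_half_mV,v_slope_mV Boltzmann voltage-closure parameters (mV).
#' @param tim50_shift_mV shift applied to `v_half_mV` when the soluble Tim50
#'   IMS domain is present (negative = closure promoted at lower voltage).
#' @param flicker_amax saturating fold-increase of the gating-event frequency
#'   under substrate (>= 1).
#' @param ec50_uM,hill_h substrate dose-response parameters.
#' @param noise_sd_pA standard deviation of additive Gaussian current noise.
#' @param filter_cutoff_Hz optional single-pole low-pass corner frequency;
#'   `NULL` disables filtering (the default: noise stays white, which matches
#'   the idealizer's noise-scale estimator).
#' @return object of class `channel_model`.
#' @export
channel_model <- function(levels_pS = c(closed = 0, sub290 = 290,
                                        sub400 = 400, open = 460),
                          rate_matrix = default_rate_matrix(levels_pS),
                          pk_over_pcl = 15,
                          v_half_mV = 140, v_slope_mV = 12,
                          tim50_shift_mV = -40,
                          flicker_amax = 50, ec50_uM = 1, hill_h = 1.5,
                          noise_sd_pA = 2, filter_cutoff_Hz = NULL) {
  nm <- names(levels_pS)
  levels_pS <- as.numeric(levels_pS)
  names(levels_pS) <- nm
  k <- length(levels_pS)
  if (k < 2L || anyDuplicated(levels_pS) || any(levels_pS < 0))
    stop_tim23("levels_pS must be >= 2 distinct non-negative conductances",
               "tim23_invalid_model")
  if (is.null(names(levels_pS)) || any(!nzchar(names(levels_pS))))
    names(levels_pS) <- paste0("s", seq_len(k))
  rate_matrix <- as.matrix(rate_matrix)
  if (!all(dim(rate_matrix) == k))
    stop_tim23("rate_matrix dimension must match levels_pS",
               "tim23_invalid_model")
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0))
    stop_tim23("off-diagonal rates must be non-negative",
               "tim23_invalid_model")
  diag(rate_matrix) <- 0
  diag(rate_matrix) <- -rowSums(rate_matrix)
  dimnames(rate_matrix) <- list(names(levels_pS), names(levels_pS))
  if (pk_over_pcl <= 0)
    stop_tim23("pk_over_pcl must be positive", "tim23_invalid_model")
  if (flicker_amax < 1)
    stop_tim23("flicker_amax must be >= 1", "tim23_invalid_model")
  structure(list(levels_pS = levels_pS, rate_matrix = rate_matrix,
                 pk_over_pcl = pk_over_pcl,
                 v_half_mV = v_half_mV, v_slope_mV = v_slope_mV,
                 tim50_shift_mV = tim50_shift_mV,
                 flicker_amax = flicker_amax, ec50_uM = ec50_uM,
                 hill_h = hill_h, noise_sd_pA = noise_sd_pA,
                 filter_cutoff_Hz = filter_cutoff_Hz),
            class = "channel_model")
}

# Baseline transition rates (1/s) at 0 mV, no substrate, for the default
# star topology. Absolute gating rates are not reported for this channel;
# these defaults are calibrated so a constant-voltage recording at +80 mV
# accumulates >= 2000 detectable gating events in ~15 minutes of trace while
# keeping sub-state occupancy low. The open->closed entry is a placeholder:
# it is recomputed from (v_half, v_slope) for the applied voltage.
default_rate_matrix <- function(levels_pS) {
  k <- length(levels_pS)
  q <- matrix(0, k, k, dimnames = list(names(levels_pS), names(levels_pS)))
  io <- which.max(levels_pS)
  ic <- which(levels_pS == 0)
  flick <- setdiff(seq_len(k), c(io, ic))
  k_fwd <- c(1.2, 0.35)    # open -> sub, larger-amplitude class first
  k_ret <- c(600, 280)     # sub -> open (mean dwells 1.7 ms and 3.6 ms)
  for (j in seq_along(flick)) {
    idx <- min(j, length(k_fwd))
    q[io, flick[j]] <- k_fwd[idx]
    q[flick[j], io] <- k_ret[idx]
  }
  if (length(ic)) {
    q[ic[1], io] <- 10                       # closed -> open
    q[io, ic[1]] <- 10 * exp(-140 / 12)      # 0 mV value of Boltzmann tie
  }
  q
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(
    "<channel_model> states %s pS; P_K/P_Cl = %g; v_half = %g mV, v_slope = %g mV\n  flicker_amax = %g (EC50 %g uM, h %g); noise %g pA\n",
    paste(x$levels_pS, collapse = "/"), x$pk_over_pcl, x$v_half_mV,
    x$v_slope_mV, x$flicker_amax, x$ec50_uM, x$hill_h, x$noise_sd_pA))
  invisible(x)
}

#' Default channel models for the wild-type and N150A variants
#'
#' Both variants share conductance levels, baseline rate matrix, voltage
#' dependence and noise; they differ only in ion selectivity (the mutant's
#' P_K/P_Cl is 33% of wild type) and in the saturating substrate activation
#' (fold 50 for wild type, fold 6 for N150A).
#'
#' @param variant `"wildtype"` or `"N150A"`.
#' @return a [channel_model()].
#' @export
default_model <- function(variant = c("wildtype", "N150A")) {
  variant <- match.arg(variant)
  wt_ratio <- 15
  switch(variant,
         wildtype = channel_model(pk_over_pcl = wt_ratio, flicker_amax = 50),
         N150A = channel_model(pk_over_pcl = 0.33 * wt_ratio,
                               flicker_amax = 6))
}

#' Recording protocol for the simulator
#'
#' @param voltage_mV holding potential (mV, trans relative to cis).
#' @param duration_s recording length (> 0).
#' @param sample_rate_Hz sampling rate (default 10 kHz).
#' @param substrate_uM presequence-peptide concentration (0 = unstimulated).
#' @param tim50_present if `TRUE`, `v_half` is shifted by the model's
#'   `tim50_shift_mV`.
#' @param cis_K_mM,trans_K_mM chamber KCl concentrations (default symmetric
#'   250 mM).
#' @param temperature_K absolute temperature.
#' @param label free-text label stored in the trace metadata.
#' @return object of class `recording_protocol`.
#' @export
recording_protocol <- function(voltage_mV, duration_s,
                               sample_rate_Hz = 1e4, substrate_uM = 0,
                               tim50_present = FALSE,
                               cis_K_mM = 250, trans_K_mM = 250,
                               temperature_K = 298.15, label = "") {
  if (duration_s <= 0)
    stop_tim23("duration_s must be positive", "tim23_invalid_protocol")
  if (substrate_uM < 0)
    stop_tim23("substrate_uM must be non-negative", "tim23_invalid_protocol")
  structure(list(voltage_mV = voltage_mV, duration_s = duration_s,
                 sample_rate_Hz = sample_rate_Hz, substrate_uM = substrate_uM,
                 tim50_present = isTRUE(tim50_present),
                 cis_K_mM = cis_K_mM, trans_K_mM = trans_K_mM,
                 temperature_K = temperature_K, label = label),
            class = "recording_protocol")
}

state_roles <- function(model) {
  io <- which.max(model$levels_pS)
  ic <- which(model$levels_pS == 0)
  ic <- if (length(ic)) ic[1] else integer()
  list(open = io, closed = ic,
       flicker = setdiff(seq_along(model$levels_pS), c(io, ic)))
}

#' Substrate dose-response fold of the gating-event frequency
#'
#' `1 + (flicker_amax - 1) * c^h / (c^h + ec50^h)`.
#'
#' @param model a [channel_model()].
#' @param substrate_uM substrate concentration(s), uM.
#' @return target fold-increase of the stationary gating-event frequency.
#' @export
substrate_fold <- function(model, substrate_uM) {
  c_ <- substrate_uM
  h <- model$hill_h
  1 + (model$flicker_amax - 1) * ifelse(
    c_ <= 0, 0, c_^h / (c_^h + model$ec50_uM^h))
}

#' Flicker-rate multiplier realizing a target event-frequency fold
#'
#' For the star gating topology (all transitions via the open state), solves
#' in closed form for the factor `B` by which the open-to-substate rates must
#' be multiplied so that the stationary total gating-event frequency
#' increases by exactly `fold` relative to `B = 1`. With forward rates
#' `K = sum(k_i)`, substate occupancy ratio `S = sum(k_i / r_i)`, closure
#' rate `kc` and closed occupancy ratio `c0 = kc / rc`, the event frequency
#' is `E(B) = 2 (B K + kc) / (1 + B S + c0)` and
#' `B = (D (1 + c0) - kc) / (K - D S)` with `D = fold (K + kc) / (1 + S + c0)`.
#'
#' @param q effective generator matrix before substrate scaling.
#' @param roles state roles as returned internally (open/closed/flicker).
#' @param fold target fold-increase (>= 1).
#' @return scalar multiplier `B >= 1`.
#' @keywords internal
flicker_rate_multiplier <- function(q, roles, fold) {
  if (fold == 1 || length(roles$flicker) == 0L) return(1)
  io <- roles$open
  k_fwd <- q[io, roles$flicker]
  k_ret <- q[cbind(roles$flicker, io)]
  if (any(k_ret <= 0 & k_fwd > 0))
    stop_tim23("flicker return rates must be positive", "tim23_invalid_model")
  # star topology required for the closed form
  off <- q; diag(off) <- 0
  allowed <- matrix(FALSE, nrow(q), ncol(q))
  allowed[io, ] <- TRUE; allowed[, io] <- TRUE
  if (any(off[!allowed] != 0))
    stop_tim23("substrate scaling requires a star gating topology",
               "tim23_invalid_model")
  K <- sum(k_fwd)
  S <- sum(ifelse(k_fwd > 0, k_fwd / k_ret, 0))
  if (length(roles$closed)) {
    kc <- q[io, roles$closed]
    rc <- q[roles$closed, io]
    c0 <- if (rc > 0) kc / rc else 0
  } else kc <- c0 <- 0
  D <- fold * (K + kc) / (1 + S + c0)
  if (K - D * S <= 0)
    stop_tim23(sprintf(
      "event-frequency fold %.3g is unattainable (ceiling %.3g)",
      fold, (K / S) * (1 + S + c0) / (K + kc)), "tim23_invalid_model")
  (D * (1 + c0) - kc) / (K - D * S)
}

#' Effective generator matrix at given voltage and substrate
#'
#' Applies the Boltzmann voltage tie to the open-to-closed rate and the
#' substrate scaling of the flicker rates to the model's baseline rate
#' matrix.
#'
#' @param model a [channel_model()].
#' @param voltage_mV applied potential.
#' @param substrate_uM substrate concentration (uM).
#' @param tim50_present shift `v_half` by the model's `tim50_shift_mV`.
#' @return generator matrix (zero row sums).
#' @export
effective_generator <- function(model, voltage_mV, substrate_uM = 0,
                                tim50_present = FALSE) {
  q <- model$rate_matrix
  diag(q) <- 0
  roles <- state_roles(model)
  if (length(roles$closed)) {
    v_half <- model$v_half_mV + if (tim50_present) model$tim50_shift_mV else 0
    rc <- q[roles$closed, roles$open]
    q[roles$open, roles$closed] <-
      rc * exp((abs(voltage_mV) - v_half) / model$v_slope_mV)
  }
  fold <- substrate_fold(model, substrate_uM)
  if (fold > 1) {
    B <- flicker_rate_multiplier(q, roles, fold)
    q[roles$open, roles$flicker] <- B * q[roles$open, roles$flicker]
  }
  diag(q) <- -rowSums(q)
  q
}

#' Stationary distribution of a generator matrix
#'
#' @param q generator matrix (zero row sums).
#' @return probability vector `pi` with `pi %*% q = 0`.
#' @export
stationary_distribution <- function(q) {
  k <- nrow(q)
  if (all(q == 0)) return(rep(1 / k, k))  # frozen chain: every state invariant
  a <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(a, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat / sum(pi_hat)
}

#' Reversal potential implied by a channel model under given buffers
#'
#' Delegates to [ghk_reversal()] with the model's permeability ratio.
#'
#' @param model a [channel_model()].
#' @param meta a [recording_meta()] (buffers and temperature are used).
#' @return reversal potential in mV.
#' @export
reversal_potential <- function(model, meta) {
  ghk_reversal(model$pk_over_pcl, meta)
}

#' Simulate the gating state path (exact continuous-time jumps)
#'
#' Gillespie-style simulation of the gating Markov chain: exponential
#' holding times with the state's total exit rate, jump destinations by
#' relative rates. Used by [simulate_trace()]; exposed for occupancy and
#' dwell-time studies.
#'
#' @param model a [channel_model()].
#' @param voltage_mV applied potential (mV).
#' @param duration_s stop after this much simulated time (`NULL` to stop by
#'   `n_jumps`).
#' @param n_jumps stop after this many jumps (`NULL` to stop by time).
#' @param substrate_uM,tim50_present protocol modifiers, see
#'   [effective_generator()].
#' @param initial_state state index or name; default the open state.
#' @param seed integer seed for reproducibility (`NULL` = use current RNG
#'   state).
#' @return list with `times` (entry time of each visited state, starting at
#'   0), `states` (state indices), `duration_s` (total simulated time) and
#'   `generator`.
#' @export
simulate_state_path <- function(model, voltage_mV, duration_s = NULL,
                                n_jumps = NULL, substrate_uM = 0,
                                tim50_present = FALSE,
                                initial_state = NULL, seed = NULL) {
  if (is.null(duration_s) && is.null(n_jumps))
    stop_tim23("one of duration_s or n_jumps is required", "tim23_invalid_protocol")
  q <- effective_generator(model, voltage_mV, substrate_uM, tim50_present)
  k <- nrow(q)
  roles <- state_roles(model)
  s0 <- if (is.null(initial_state)) roles$open
        else if (is.character(initial_state)) match(initial_state, rownames(q))
        else as.integer(initial_state)
  if (is.na(s0) || s0 < 1L || s0 > k)
    stop_tim23("invalid initial state", "tim23_invalid_protocol")
  exit_rate <- -diag(q)
  jump_prob <- q
  diag(jump_prob) <- 0
  for (i in seq_len(k))
    if (exit_rate[i] > 0) jump_prob[i, ] <- jump_prob[i, ] / exit_rate[i]

  run <- function() {
    cap <- if (!is.null(n_jumps)) n_jumps + 1L else 1024L
    times <- numeric(cap); states <- integer(cap)
    times[1L] <- 0; states[1L] <- s0
    m <- 1L; t_now <- 0; s <- s0
    repeat {
      if (!is.null(n_jumps) && m >= n_jumps + 1L) break
      if (exit_rate[s] <= 0) { t_now <- Inf; break }
      t_now <- t_now + rexp(1L, exit_rate[s])
      if (!is.null(duration_s) && t_now >= duration_s) break
      s <- sample.int(k, 1L, prob = jump_prob[s, ])
      m <- m + 1L
      if (m > length(times)) {
        times <- c(times, numeric(length(times)))
        states <- c(states, integer(length(states)))
      }
      times[m] <- t_now; states[m] <- s
    }
    total <- if (!is.null(duration_s)) duration_s else
      if (is.finite(t_now)) t_now else times[m]
    list(times = times[seq_len(m)], states = states[seq_len(m)],
         duration_s = total, generator = q)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a Tim23-like current recording with ground truth
#'
#' Exact-jump continuous-time Markov simulation of the gating state path,
#' sampled onto the uniform acquisition grid. The instantaneous current is
#' `level_pS * (V - U_rev) / 1000 + noise`, with a common GHK reversal
#' potential for all conducting states and additive white Gaussian noise
#' (optionally low-pass filtered with a single pole at
#' `model$filter_cutoff_Hz`). Identical `(model, protocol, seed)` give
#' bit-identical output.
#'
#' @param model a [channel_model()].
#' @param protocol a [recording_protocol()].
#' @param seed integer seed.
#' @param initial_state passed to [simulate_state_path()] (default: open).
#' @return list with elements `trace` (a [channel_trace()]) and `truth`
#'   (list: `times`, `states`, `levels_pA`, `events` data.frame of true
#'   transition times/amplitudes, `n_events`, `u_rev_mV`, `stationary`,
#'   `generator`, `model`, `protocol`).
#' @export
simulate_trace <- function(model, protocol, seed = NULL,
                           initial_state = NULL) {
  stopifnot(inherits(model, "channel_model"),
            inherits(protocol, "recording_protocol"))
  meta <- recording_meta(voltage_mV = protocol$voltage_mV,
                         cis_K_mM = protocol$cis_K_mM,
                         trans_K_mM = protocol$trans_K_mM,
                         temperature_K = protocol$temperature_K,
                         sample_rate_Hz = protocol$sample_rate_Hz,
                         duration_s = protocol$duration_s,
                         label = protocol$label)
  u_rev <- reversal_potential(model, meta)
  meta$u_rev_mV <- u_rev
  run <- function() {
    path <- simulate_state_path(model, protocol$voltage_mV,
                                duration_s = protocol$duration_s,
                                substrate_uM = protocol$substrate_uM,
                                tim50_present = protocol$tim50_present,
                                initial_state = initial_state, seed = NULL)
    n <- round(protocol$duration_s * protocol$sample_rate_Hz)
    t_grid <- (seq_len(n) - 1) / protocol$sample_rate_Hz
    idx <- findInterval(t_grid, path$times)
    levels_pA <- model$levels_pS *
      (protocol$voltage_mV - u_rev) / 1000
    x <- levels_pA[path$states][idx]
    if (model$noise_sd_pA > 0)
      x <- x + rnorm(n, 0, model$noise_sd_pA)
    if (!is.null(model$filter_cutoff_Hz)) {
      a <- exp(-2 * pi * model$filter_cutoff_Hz / protocol$sample_rate_Hz)
      x <- as.numeric(stats::filter(x * (1 - a), filter = a,
                                    method = "recursive"))
    }
    m <- length(path$states)
    events <- if (m > 1L) {
      amp <- diff(levels_pA[path$states])
      data.frame(time_s = path$times[-1L], amplitude_pA = amp,
                 from = path$states[-m], to = path$states[-1L])
    } else data.frame(time_s = numeric(), amplitude_pA = numeric(),
                      from = integer(), to = integer())
    truth <- list(times = path$times, states = path$states,
                  levels_pA = levels_pA, events = events,
                  n_events = nrow(events), u_rev_mV = u_rev,
                  stationary = stationary_distribution(path$generator),
                  generator = path$generator,
                  model = model, protocol = protocol)
    list(trace = channel_trace(x, meta), truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a current-voltage dataset
#'
#' Mean open-level current per voltage under the model's selectivity: the
#' noiseless mean is `g_open * (V - U_rev) / 1000` pA, to which zero-mean
#' Gaussian error with the standard error of a `per_voltage_duration_s`
#' recording average is added. The zero crossing of the noiseless means is
#' exactly [reversal_potential()].
#'
#' @param model a [channel_model()].
#' @param voltages_mV strictly increasing vector of holding potentials (>= 2).
#' @param meta [recording_meta()] carrying buffers/temperature (its voltage
#'   and duration fields are ignored).
#' @param seed integer seed.
#' @param per_voltage_duration_s averaging time per voltage (default 5 s).
#' @return an [iv_dataset()].
#' @export
simulate_iv <- function(model, voltages_mV, meta, seed = NULL,
                        per_voltage_duration_s = 5) {
  if (length(voltages_mV) < 2L || is.unsorted(voltages_mV, strictly = TRUE))
    stop_tim23("voltages must be >= 2, sorted and distinct", "tim23_invalid_iv")
  u_rev <- reversal_potential(model, meta)
  g_open <- max(model$levels_pS)
  n_avg <- max(1, round(per_voltage_duration_s * meta$sample_rate_Hz))
  se <- model$noise_sd_pA / sqrt(n_avg)
  run <- function() {
    mean_pA <- g_open * (voltages_mV - u_rev) / 1000 +
      if (se > 0) rnorm(length(voltages_mV), 0, se) else 0
    iv_dataset(data.frame(voltage_mV = voltages_mV, mean_current_pA = mean_pA,
                          sd_pA = rep(se, length(voltages_mV)),
                          n = rep(n_avg, length(voltages_mV))),
               meta)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
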