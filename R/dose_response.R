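#' Presequence titration series
#'
#' Gating frequency as a function of substrate (presequence peptide)
#' concentration, with the unstimulated baseline frequency of the same
#' channel.
#'
#' @param concentration_uM non-negative, strictly increasing concentrations.
#' @param freq_per_min gating frequency at each concentration (events/min).
#' @param baseline_freq_per_min unstimulated gating frequency (> 0).
#' @param label variant / condition label.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(concentration_uM, freq_per_min,
                             baseline_freq_per_min, label = "") {
  if (length(concentration_uM) != length(freq_per_min))
    stop_tim23("concentration and frequency vectors must match",
               "tim23_invalid_titration")
  if (any(concentration_uM < 0) ||
      is.unsorted(concentration_uM, strictly = TRUE))
    stop_tim23("concentrations must be non-negative and strictly increasing",
               "tim23_invalid_titration")
  if (baseline_freq_per_min <= 0)
    stop_tim23("baseline frequency must be positive", "tim23_zero_baseline")
  structure(list(points = data.frame(concentration_uM = concentration_uM,
                                     freq_per_min = freq_per_min),
                 baseline_freq_per_min = baseline_freq_per_min,
                 label = label),
            class = "titration_series")
}

#' Relative activation of gating by substrate
#'
#' Fold-increase of the gating frequency over the unstimulated baseline.
#'
#' @param freq_stim stimulated gating frequency (events/min).
#' @param freq_baseline unstimulated gating frequency (> 0).
#' @return fold-increase (1 = no response).
#' @export
relative_activation <- function(freq_stim, freq_baseline) {
  if (any(freq_baseline <= 0))
    stop_tim23("baseline gating frequency must be positive",
               "tim23_zero_baseline")
  freq_stim / freq_baseline
}

#' Percent reduction of substrate activation between two channels
#'
#' `100 * (1 - fold_variant / fold_reference)`: e.g. saturating activation
#' folds of 50 (reference) and 6 (variant) give an 88% reduction.
#'
#' @param fold_wt reference (wild-type) fold-activation (> 0).
#' @param fold_mut variant fold-activation.
#' @return percent reduction.
#' @export
activation_reduction_percent <- function(fold_wt, fold_mut) {
  if (any(fold_wt <= 0))
    stop_tim23("reference fold-activation must be positive",
               "tim23_invalid_fold")
  100 * (1 - fold_mut / fold_wt)
}

#' Hill fit of a gating-activation titration
#'
#' Least-squares fit of
#' `fold(c) = 1 + (a_max - 1) * c^h / (c^h + ec50^h)` to the relative
#' activation computed from a [titration_series()]. The Hill form is a
#' declared modelling choice for the saturating concentration response.
#'
#' @param series a [titration_series()] with at least 4 concentrations
#'   spanning baseline to near-saturation.
#' @return list with `a_max`, `ec50_uM`, `hill_h`, standard errors, a
#'   `plateau_identifiable` flag (`FALSE` when the largest tested
#'   concentration is below the fitted EC50, or when the series is flat) and
#'   the `nls` fit object (`NULL` for a flat series).
#' @export
fit_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$points
  if (nrow(p) < 4L)
    stop_tim23("need at least 4 titration points", "tim23_too_few_points")
  fold <- relative_activation(p$freq_per_min, series$baseline_freq_per_min)
  conc <- p$concentration_uM
  if (diff(range(fold)) < 0.25) {
    # flat series: no measurable response, EC50 meaningless
    return(list(a_max = mean(fold), ec50_uM = NA_real_, hill_h = NA_real_,
                se_a_max = sd(fold) / sqrt(length(fold)),
                se_ec50_uM = NA_real_, se_hill_h = NA_real_,
                plateau_identifiable = FALSE, fit = NULL))
  }
  pos <- conc > 0
  start <- list(a_max = max(fold),
                ec50 = exp(mean(log(conc[pos]))),
                h = 1)
  dat <- data.frame(conc = conc, fold = fold)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fold ~ 1 + (a_max - 1) * ifelse(conc <= 0, 0,
                                      conc^h / (conc^h + ec50^h)),
      data = dat, start = start,
      lower = c(a_max = 1, ec50 = 1e-9, h = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      stop_tim23(paste("titration fit did not converge:",
                       conditionMessage(e)), "tim23_no_convergence"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  list(a_max = unname(est["a_max"]), ec50_uM = unname(est["ec50"]),
       hill_h = unname(est["h"]),
       se_a_max = unname(se[1]), se_ec50_uM = unname(se[2]),
       se_hill_h = unname(se[3]),
       plateau_identifiable = max(conc) >= unname(est["ec50"]),
       fit = fit)
}

#' Simulate a presequence titration through the full analysis pipeline
#'
#' For each concentration (and the unstimulated baseline), simulates a
#' constant-voltage recording, idealizes it, extracts gating events and
#' computes the gating frequency — the in-silico analogue of a bilayer
#' titration where current is recorded after each addition of peptide.
#'
#' @param model a [channel_model()].
#' @param concentrations_uM substrate concentrations (uM); strictly
#'   increasing, excluding the baseline 0 (added automatically).
#' @param voltage_mV holding potential (default +80 mV, where the channel
#'   stays primarily open but responds to presequence).
#' @param duration_s recording length per titration point (default 60 s,
#'   one-minute constant-voltage recordings).
#' @param sample_rate_Hz acquisition rate.
#' @param seed integer seed; each titration point uses an offset sub-seed.
#' @param params [idealize_params()] used for all points.
#' @param floor_pS event amplitude floor passed to [extract_events()].
#' @return a [titration_series()].
#' @export
simulate_titration <- function(model, concentrations_uM, voltage_mV = 80,
                               duration_s = 60, sample_rate_Hz = 1e4,
                               seed = NULL, params = idealize_params(),
                               floor_pS = 20) {
  freq_at <- function(conc, sub_seed) {
    prot <- recording_protocol(voltage_mV, duration_s,
                               sample_rate_Hz = sample_rate_Hz,
                               substrate_uM = conc,
                               label = sprintf("titration %g uM", conc))
    sim <- simulate_trace(model, prot, seed = sub_seed)
    gating_frequency(extract_events(idealize(sim$trace, params),
                                    floor_pS = floor_pS))
  }
  seeds <- if (is.null(seed)) vector("list", length(concentrations_uM) + 1)
           else as.list(seed + seq_len(length(concentrations_uM) + 1) - 1)
  baseline <- freq_at(0, seeds[[1]])
  freqs <- vapply(seq_along(concentrations_uM),
                  function(i) freq_at(concentrations_uM[i], seeds[[i + 1]]),
                  numeric(1))
  titration_series(concentrations_uM, freqs, baseline)
}
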