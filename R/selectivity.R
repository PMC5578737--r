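#' Current-voltage dataset
#'
#' @param points data.frame with columns `voltage_mV` (strictly increasing),
#'   `mean_current_pA`, `sd_pA`, `n` (>= 1 each).
#' @param meta [recording_meta()] carrying the buffer concentrations and
#'   temperature under which the curve was recorded.
#' @return object of class `iv_dataset`.
#' @export
iv_dataset <- function(points, meta) {
  validate_meta(meta)
  need <- c("voltage_mV", "mean_current_pA", "sd_pA", "n")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop_tim23(paste("IV points need columns", paste(need, collapse = ", ")),
               "tim23_invalid_iv")
  if (nrow(points) >= 2L && is.unsorted(points$voltage_mV, strictly = TRUE))
    stop_tim23("voltages must be strictly increasing", "tim23_invalid_iv")
  if (any(points$n < 1))
    stop_tim23("each IV point needs n >= 1", "tim23_invalid_iv")
  structure(list(points = points[, need], meta = meta), class = "iv_dataset")
}

#' @export
print.iv_dataset <- function(x, ...) {
  cat(sprintf("<iv_dataset> %d voltages from %g to %g mV, KCl %g:%g mM\n",
              nrow(x$points), min(x$points$voltage_mV),
              max(x$points$voltage_mV), x$meta$cis_K_mM, x$meta$trans_K_mM))
  invisible(x)
}

ghk_concentrations <- function(meta) {
  # pure KCl buffers: [Cl] on each side equals [K]
  list(k_cis = meta$cis_K_mM, k_trans = meta$trans_K_mM,
       cl_cis = meta$cis_K_mM, cl_trans = meta$trans_K_mM)
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' For a channel permeable to K+ and Cl- with permeability ratio
#' `x = P_K / P_Cl` under pure KCl buffers,
#' `U_rev = (RT/F) * ln((x * [K]cis + [Cl]trans) / (x * [K]trans + [Cl]cis))`.
#' With the package's sign convention (trans relative to cis) a
#' cation-selective channel under a cis-high gradient has a positive
#' reversal potential. `pk_over_pcl = Inf` gives the K+ Nernst potential.
#'
#' @param pk_over_pcl permeability ratio (>= 0; `Inf` = ideally
#'   cation-selective, `0` = ideally anion-selective).
#' @param meta [recording_meta()] with buffer concentrations and temperature.
#' @return reversal potential in mV.
#' @export
ghk_reversal <- function(pk_over_pcl, meta) {
  validate_meta(meta)
  if (any(pk_over_pcl < 0))
    stop_tim23("pk_over_pcl must be non-negative", "tim23_invalid_ratio")
  cc <- ghk_concentrations(meta)
  rt_f <- rt_over_f_mV(meta$temperature_K)
  ifelse(is.infinite(pk_over_pcl),
         rt_f * log(cc$k_cis / cc$k_trans),
         rt_f * log((pk_over_pcl * cc$k_cis + cc$cl_trans) /
                      (pk_over_pcl * cc$k_trans + cc$cl_cis)))
}

#' Invert the GHK equation: permeability ratio from a reversal potential
#'
#' Closed-form inversion
#' `x = (r * [Cl]cis - [Cl]trans) / ([K]cis - r * [K]trans)` with
#' `r = exp(U_rev * F / (R * T))`; the exact inverse of [ghk_reversal()].
#' The reversal potential must lie strictly inside the Nernst bounds
#' `(-(RT/F) ln([Cl]cis/[Cl]trans), (RT/F) ln([K]cis/[K]trans))`.
#'
#' @param u_rev_mV measured reversal potential (mV, package sign convention).
#' @param meta [recording_meta()].
#' @return `P_K / P_Cl`.
#' @export
ghk_permeability_ratio <- function(u_rev_mV, meta) {
  validate_meta(meta)
  cc <- ghk_concentrations(meta)
  rt_f <- rt_over_f_mV(meta$temperature_K)
  upper <- rt_f * log(cc$k_cis / cc$k_trans)
  lower <- -rt_f * log(cc$cl_cis / cc$cl_trans)
  if (any(u_rev_mV >= pmax(upper, lower)) || any(u_rev_mV <= pmin(upper, lower)))
    stop_tim23(sprintf(
      "reversal potential %.4g mV at/outside the Nernst bounds (%.4g, %.4g) mV: permeability ratio infinite or undefined",
      u_rev_mV[1], min(upper, lower), max(upper, lower)),
      "tim23_nernst_bound")
  r <- exp(u_rev_mV / rt_f)
  (r * cc$cl_cis - cc$cl_trans) / (cc$k_cis - r * cc$k_trans)
}

#' Estimate the reversal potential from an I-V dataset
#'
#' Zero crossing of a local linear fit through the sign-change bracket plus
#' up to two neighbours on each side; the standard error is propagated from
#' the per-point standard deviations (delta method on the intercept/slope
#' ratio).
#'
#' @param iv an [iv_dataset()] whose mean currents change sign.
#' @return list with `u_rev_mV`, `se_mV`, `n_points` (points used).
#' @export
estimate_reversal <- function(iv) {
  stopifnot(inherits(iv, "iv_dataset"))
  p <- iv$points
  s <- sign(p$mean_current_pA)
  cross <- which(s[-1] * s[-length(s)] <= 0 &
                   !(s[-1] == 0 & s[-length(s)] == 0))
  if (all(s > 0) || all(s < 0) || !length(cross))
    stop_tim23("mean currents do not change sign across the voltage range",
               "tim23_no_sign_change")
  i <- cross[1]
  idx <- max(1, i - 2):min(nrow(p), i + 3)
  use <- p[idx, ]
  wts <- if (all(use$sd_pA > 0)) 1 / use$sd_pA^2 else NULL
  fit <- lm(mean_current_pA ~ voltage_mV, data = use, weights = wts)
  a <- coef(fit)[1]; b <- coef(fit)[2]
  if (b == 0)
    stop_tim23("flat I-V: cannot locate zero crossing", "tim23_no_sign_change")
  u <- -a / b
  # summary.lm warns on exactly collinear (noiseless) points; the zero
  # covariance it returns is the correct propagated uncertainty there
  vc <- tryCatch(suppressWarnings(vcov(fit)), error = function(e) matrix(0, 2, 2))
  if (any(!is.finite(vc))) vc <- matrix(0, 2, 2)
  # delta method for -a/b
  grad <- c(-1 / b, a / b^2)
  se <- sqrt(max(0, t(grad) %*% vc %*% grad))
  list(u_rev_mV = unname(u), se_mV = as.numeric(se), n_points = nrow(use))
}

#' Selectivity as percent of a reference channel
#'
#' `100 * x_variant / x_reference`, the declared normalization for
#' "percent of wild type" selectivity: the ratio of P_K/P_Cl values.
#'
#' @param x_variant,x_reference permeability ratios (> 0).
#' @return percent.
#' @export
selectivity_percent <- function(x_variant, x_reference) {
  if (any(x_variant <= 0) || any(x_reference <= 0))
    stop_tim23("permeability ratios must be positive", "tim23_invalid_ratio")
  100 * x_variant / x_reference
}

#' Boltzmann fit of open probability versus voltage
#'
#' Least-squares fit of `Po(V) = 1 / (1 + exp((|V| - v_half) / v_slope))`.
#'
#' @param po_points data.frame with columns `voltage_mV` and `po` (at least
#'   4 points spanning the transition, `po` in `[0, 1]`).
#' @return list with `v_half_mV`, `v_slope_mV`, standard errors and the
#'   `nls` fit object.
#' @export
fit_po_voltage <- function(po_points) {
  stopifnot(is.data.frame(po_points),
            all(c("voltage_mV", "po") %in% names(po_points)))
  if (nrow(po_points) < 4L)
    stop_tim23("need at least 4 (voltage, Po) points", "tim23_too_few_points")
  if (any(po_points$po < 0 | po_points$po > 1))
    stop_tim23("Po values must lie in [0, 1]", "tim23_invalid_po")
  if (diff(range(po_points$po)) < 0.05)
    stop_tim23("Po does not vary across the voltage range: v_half/v_slope not identifiable",
               "tim23_not_identifiable")
  v <- abs(po_points$voltage_mV)
  po <- po_points$po
  # start values: midpoint from the Po closest to 0.5, generic slope
  start <- list(v_half = v[which.min(abs(po - 0.5))], v_slope = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(po ~ 1 / (1 + exp((v - v_half) / v_slope)),
                      data = data.frame(v = v, po = po), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_tim23(paste("Boltzmann fit did not converge:", conditionMessage(e)),
                 "tim23_no_convergence"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  list(v_half_mV = unname(est["v_half"]), v_slope_mV = unname(est["v_slope"]),
       se_v_half_mV = unname(se[1]), se_v_slope_mV = unname(se[2]), fit = fit)
}
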