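#' Drift-corrected oxygen consumption per vial
#'
#' The concentration drawdown in each aggregate vial is corrected by the
#' mean drawdown of the aggregate-free control vials (which capture, e.g.,
#' temperature-driven shifts), converted to an absolute O2 consumption via
#' the vial volume, and normalised to per day. Corrected rates below zero
#' are flagged and clipped to zero with a warning rather than propagated.
#'
#' @param assays tibble as from [generate_o2_assays()]: columns
#'   `is_control`, `o2_start_umol_L`, `o2_end_umol_L`, `vial_volume_mL`,
#'   `duration_h` (and `poc_ug`, `vial_id` carried through).
#' @return tibble of aggregate vials with `o2_rate_umol_d` (umol O2 d^-1)
#'   and `clipped` (logical) appended.
#' @examples
#' a <- tibble::tibble(vial_id = 1:2, is_control = c(FALSE, TRUE),
#'                     o2_start_umol_L = 300, o2_end_umol_L = c(270, 300),
#'                     vial_volume_mL = 5.9, duration_h = 24, poc_ug = c(8, NA))
#' o2_consumption(a)$o2_rate_umol_d # 0.177
#' @export
o2_consumption <- function(assays) {
  need <- c("is_control", "o2_start_umol_L", "o2_end_umol_L",
            "vial_volume_mL", "duration_h")
  if (!all(need %in% names(assays))) {
    abort_config("`assays` must have columns ",
                 paste(need, collapse = ", "))
  }
  controls <- dplyr::filter(assays, .data$is_control)
  if (nrow(controls) == 0) {
    abort_config("at least one control vial is required for drift correction")
  }
  drift <- mean(controls$o2_start_umol_L - controls$o2_end_umol_L)
  out <- assays %>%
    dplyr::filter(!.data$is_control) %>%
    mutate(
      delta_umol_L = .data$o2_start_umol_L - .data$o2_end_umol_L - drift,
      o2_rate_umol_d = .data$delta_umol_L * .data$vial_volume_mL / 1000 /
        (.data$duration_h / 24),
      clipped = .data$o2_rate_umol_d < 0
    ) %>%
    select(-"delta_umol_L")
  if (any(out$clipped)) {
    rlang::warn(sprintf(
      "o2_consumption: %d corrected rate(s) below zero were clipped to 0",
      sum(out$clipped)))
    out$o2_rate_umol_d[out$clipped] <- 0
  }
  out
}

#' Carbon-specific respiration rate
#'
#' Converts an O2 consumption rate to a carbon-specific respiration rate
#' using the respiratory quotient (mol O2 per mol CO2, default 1.2) and the
#' aggregate's POC content (ug C, converted to umol with a carbon molar
#' mass of 12.011 g mol^-1):
#' k = (O2 rate / RQ) / (POC / 12.011), in d^-1. A rate of 0.1 d^-1 means
#' 10% of the aggregate POC is respired per day.
#'
#' @param o2_rate_umol_d O2 consumption in umol O2 d^-1, >= 0.
#' @param poc_ug aggregate POC in ug C, > 0.
#' @param rq respiratory quotient, default 1.2.
#' @return carbon-specific rate k in d^-1.
#' @examples
#' c_specific_rate(0.177, 8) # ~0.22 d^-1
#' @export
c_specific_rate <- function(o2_rate_umol_d, poc_ug, rq = 1.2) {
  if (any(!is.finite(o2_rate_umol_d)) || any(o2_rate_umol_d < 0)) {
    abort_config("`o2_rate_umol_d` must be finite and >= 0")
  }
  if (any(!is.finite(poc_ug)) || any(poc_ug <= 0)) {
    abort_config("`poc_ug` must be positive and finite")
  }
  check_number(rq, "rq", function(v) v > 0, "> 0")
  (o2_rate_umol_d / rq) / (poc_ug / 12.011)
}

#' Remineralization length scale
#'
#' L = k / U: the fraction of aggregate carbon respired per meter settled,
#' from the carbon-specific respiration rate (d^-1) and settling velocity
#' (m d^-1). Reported as a fraction per meter; multiply by 100 for % m^-1
#' (0.16 d^-1 at 160 m d^-1 gives 0.1% m^-1).
#'
#' @param k_d carbon-specific respiration rate, d^-1, >= 0.
#' @param u_m_d settling velocity, m d^-1, > 0.
#' @return L in m^-1 (fraction per meter).
#' @examples
#' 100 * remineralization_length(0.16, 160) # 0.1 % per m
#' @export
remineralization_length <- function(k_d, u_m_d) {
  if (any(!is.finite(k_d)) || any(k_d < 0)) {
    abort_config("`k_d` must be finite and >= 0")
  }
  if (any(!is.finite(u_m_d)) || any(u_m_d <= 0)) {
    abort_config("`u_m_d` must be positive and finite")
  }
  k_d / u_m_d
}

#' Fraction of aggregate carbon lost over a settling depth
#'
#' Linear mode accumulates L per meter settled, capped at 1 (matches the
#' % m^-1 framing of the length scale); exponential mode treats L as a
#' continuous attenuation coefficient, 1 - exp(-L z).
#'
#' @param k_d carbon-specific respiration rate, d^-1.
#' @param u_m_d settling velocity, m d^-1.
#' @param depth_m settling depth in m, >= 0.
#' @param mode `"linear"` (default) or `"exponential"`.
#' @return fraction of initial POC lost, in \[0, 1\].
#' @examples
#' carbon_loss(0.24, 100, 50)                       # 0.12
#' carbon_loss(1, 100, 50, mode = "exponential")    # 1 - exp(-0.5)
#' @export
carbon_loss <- function(k_d, u_m_d, depth_m,
                        mode = c("linear", "exponential")) {
  mode <- match.arg(mode)
  if (any(!is.finite(depth_m)) || any(depth_m < 0)) {
    abort_config("`depth_m` must be finite and >= 0")
  }
  L <- remineralization_length(k_d, u_m_d)
  switch(mode,
         linear = pmin(L * depth_m, 1),
         exponential = 1 - exp(-L * depth_m))
}

#' Remineralization and depth loss across the fitted size range
#'
#' For a grid of diameters, predicts the settling velocity from a fitted
#' size~velocity power law, then the remineralization length scale and the
#' carbon loss over a settling depth. Diameters outside the fitted range
#' trigger an extrapolation warning.
#'
#' @param fit an `agg_powerfit` from [fit_power_law()].
#' @param k_d carbon-specific respiration rate, d^-1.
#' @param d_range diameter range (mm) to tabulate, default c(1, 5).
#' @param depth_m settling depth for the loss column, default 50.
#' @param n grid size, default 50.
#' @param mode passed to [carbon_loss()].
#' @return tibble with `d_mm`, `u_m_d`, `L_per_m`, `L_pct_per_m`,
#'   `loss_frac`.
#' @export
loss_curve <- function(fit, k_d, d_range = c(1, 5), depth_m = 50, n = 50,
                       mode = c("linear", "exponential")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "agg_powerfit")) {
    abort_config("`fit` must be an agg_powerfit")
  }
  check_number(k_d, "k_d", function(v) v >= 0, ">= 0")
  fitted_range <- range(fit$data$d)
  if (d_range[1] < fitted_range[1] || d_range[2] > fitted_range[2]) {
    rlang::warn(sprintf(
      "loss_curve: requested diameters [%g, %g] extrapolate beyond the fitted range [%g, %g]",
      d_range[1], d_range[2], fitted_range[1], fitted_range[2]))
  }
  d <- seq(d_range[1], d_range[2], length.out = n)
  u <- predict(fit, d = d)
  L <- remineralization_length(k_d, u)
  tibble(d_mm = d, u_m_d = u, L_per_m = L, L_pct_per_m = 100 * L,
         loss_frac = carbon_loss(k_d, u, depth_m, mode = mode))
}
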