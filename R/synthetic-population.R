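#' Parameters of a synthetic aggregate population
#'
#' Defines the generating truth for a treatment's aggregate population. The
#' defaults mirror the culture experiment's non-infected treatment: twelve
#' individually picked aggregates of 1-5 mm, settling as U = a d^(D3 - 1)
#' with D3 = 2.37 and a velocity prefactor chosen so a 2.4 mm aggregate
#' sinks at ~201 m d^-1, a solid hydrated density of 1.284 g cm^-3, POC in
#' proportion to solid (non-porous) volume such that a 2.4 mm aggregate
#' carries ~6.7 ug C, and a carbon-specific respiration rate of 0.16 d^-1.
#'
#' @param n_aggregates number of aggregates.
#' @param d_range diameter range (min, max) in mm, min > 0.
#' @param size_dist `"power_law"` (number spectrum ~ d^exponent) or
#'   `"log_uniform"`.
#' @param size_exponent exponent of the power-law size distribution
#'   (ignored for `"log_uniform"`).
#' @param d3_true generating three-dimensional fractal number, in \[1, 3\].
#' @param velocity_scale_a prefactor a in U = a d^(D3-1), m d^-1 mm^-(D3-1).
#' @param velocity_noise_sd sd (log scale) of multiplicative lognormal noise
#'   on U; 0 gives a noiseless power law.
#' @param mass_density solid hydrated density rho_s, g cm^-3.
#' @param poc_per_solid_volume POC per solid aggregate volume, ug C mm^-3.
#' @param resp_rate carbon-specific respiration rate k, d^-1 (expected
#'   value across aggregates).
#' @param resp_rate_cv sd (log scale) of mean-preserving lognormal
#'   between-aggregate variability in k; 0 gives every aggregate the same
#'   rate.
#' @param seed integer RNG seed; the generators are pure functions of
#'   (params, seed).
#' @return a validated list of class `agg_population_params`.
#' @export
population_params <- function(n_aggregates = 12,
                              d_range = c(1, 5),
                              size_dist = c("power_law", "log_uniform"),
                              size_exponent = -3,
                              d3_true = 2.37,
                              velocity_scale_a = 60,
                              velocity_noise_sd = 0.1,
                              mass_density = 1.284,
                              poc_per_solid_volume = 1480,
                              resp_rate = 0.16,
                              resp_rate_cv = 0,
                              seed = 1L) {
  size_dist <- match.arg(size_dist)
  check_number(n_aggregates, "n_aggregates",
               function(v) v >= 0 && v == round(v), "non-negative integer")
  if (!is.numeric(d_range) || length(d_range) != 2 || any(!is.finite(d_range)) ||
      d_range[1] <= 0 || d_range[2] < d_range[1]) {
    abort_config("`d_range` must be (min, max) with 0 < min <= max")
  }
  check_number(size_exponent, "size_exponent")
  check_number(d3_true, "d3_true", function(v) v >= 1 && v <= 3, "in [1, 3]")
  check_number(velocity_scale_a, "velocity_scale_a", function(v) v > 0, "> 0")
  check_number(velocity_noise_sd, "velocity_noise_sd", function(v) v >= 0, ">= 0")
  check_number(mass_density, "mass_density", function(v) v > 0, "> 0")
  check_number(poc_per_solid_volume, "poc_per_solid_volume",
               function(v) v > 0, "> 0")
  check_number(resp_rate, "resp_rate", function(v) v >= 0, ">= 0")
  check_number(resp_rate_cv, "resp_rate_cv", function(v) v >= 0, ">= 0")
  check_number(seed, "seed", function(v) v == round(v), "integer")
  structure(list(
    n_aggregates = as.integer(n_aggregates), d_range = d_range,
    size_dist = size_dist, size_exponent = size_exponent, d3_true = d3_true,
    velocity_scale_a = velocity_scale_a, velocity_noise_sd = velocity_noise_sd,
    mass_density = mass_density, poc_per_solid_volume = poc_per_solid_volume,
    resp_rate = resp_rate, resp_rate_cv = resp_rate_cv,
    seed = as.integer(seed)
  ), class = "agg_population_params")
}

# Inverse-CDF sampler for a truncated power-law (pdf ~ d^e on [dmin, dmax]).
sample_power_law <- function(n, dmin, dmax, exponent) {
  u <- runif(n)
  if (abs(exponent + 1) < 1e-12) {
    exp(log(dmin) + u * (log(dmax) - log(dmin)))
  } else {
    e1 <- exponent + 1
    (dmin^e1 + u * (dmax^e1 - dmin^e1))^(1 / e1)
  }
}

#' Generate a synthetic aggregate population with ground truth
#'
#' Draws diameters from the configured size distribution, assigns settling
#' velocities U = a d^(D3-1) * eps with multiplicative lognormal noise eps,
#' and records the Stokes-consistent ground truth per aggregate: excess
#' density from (U, d), porosity from the excess and solid hydrated density,
#' and POC proportional to the solid volume V (1 - phi). The same seed
#' always reproduces the identical table.
#'
#' @param params a [population_params()] object.
#' @return tibble with one row per aggregate: `id`, `d_mm`, `v_mm3`,
#'   `u_m_d`, `u_expected_m_d`, `drho_mg_cm3`, `phi`, `solid_v_mm3`,
#'   `poc_ug`, `resp_k_d`.
#' @examples
#' generate_aggregate_population(population_params(n_aggregates = 5))
#' @export
generate_aggregate_population <- function(params = population_params()) {
  if (!inherits(params, "agg_population_params")) {
    abort_config("`params` must come from population_params()")
  }
  withr::with_seed(params$seed, {
    n <- params$n_aggregates
    d <- switch(params$size_dist,
      power_law = sample_power_law(n, params$d_range[1], params$d_range[2],
                                   params$size_exponent),
      log_uniform = sample_power_law(n, params$d_range[1], params$d_range[2], -1)
    )
    d <- sort(d)
    u_expected <- params$velocity_scale_a * d^(params$d3_true - 1)
    eps <- if (params$velocity_noise_sd > 0) {
      exp(rnorm(n, mean = 0, sd = params$velocity_noise_sd))
    } else {
      rep(1, n)
    }
    u <- u_expected * eps
    v <- sphere_volume(d)
    drho <- excess_density(u, d)
    phi <- porosity(drho, params$mass_density)
    solid_v <- v * (1 - phi)
    k <- if (params$resp_rate_cv > 0) {
      # mean-preserving lognormal between-aggregate variability
      params$resp_rate * exp(rnorm(n, 0, params$resp_rate_cv) -
                               params$resp_rate_cv^2 / 2)
    } else {
      rep(params$resp_rate, n)
    }
    tibble(
      id = seq_len(n),
      d_mm = d, v_mm3 = v,
      u_m_d = u, u_expected_m_d = u_expected,
      drho_mg_cm3 = drho, phi = phi,
      solid_v_mm3 = solid_v,
      poc_ug = params$poc_per_solid_volume * solid_v,
      resp_k_d = k
    )
  })
}

#' Generate timed settling trials for a population
#'
#' Each aggregate settles a fixed distance; the stopwatch time is
#' distance / U plus optional Gaussian timing noise, truncated (by redraw)
#' so that times stay positive.
#'
#' @param population table from [generate_aggregate_population()].
#' @param distance_cm settling distance in cm, default 15.
#' @param timing_noise_sd_s sd of timing noise in seconds, default 0.
#' @param seed integer RNG seed.
#' @return tibble with `id`, `distance_cm`, `time_s`, `u_true_m_d`.
#' @export
generate_settling_trials <- function(population, distance_cm = 15,
                                     timing_noise_sd_s = 0, seed = 1L) {
  check_number(distance_cm, "distance_cm", function(v) v > 0, "> 0")
  check_number(timing_noise_sd_s, "timing_noise_sd_s", function(v) v >= 0, ">= 0")
  check_number(seed, "seed", function(v) v == round(v), "integer")
  u_cm_s <- population$u_m_d / physical_constants()$m_per_day_per_cm_s
  t0 <- distance_cm / u_cm_s
  withr::with_seed(seed, {
    time_s <- t0
    if (timing_noise_sd_s > 0) {
      for (i in seq_along(time_s)) {
        repeat {
          cand <- t0[i] + rnorm(1, sd = timing_noise_sd_s)
          if (cand > 0) break
        }
        time_s[i] <- cand
      }
    }
    tibble(id = population$id, distance_cm = distance_cm,
           time_s = time_s, u_true_m_d = population$u_m_d)
  })
}

#' Generate paired oxygen-drawdown assays for a population
#'
#' Each aggregate is incubated in a gas-tight vial (default 5.9 mL, 24 h);
#' the end concentration is the start minus the drawdown implied by the
#' aggregate's true carbon-specific respiration rate (via the respiratory
#' quotient), minus a common drift shared with aggregate-free control vials,
#' plus optional measurement noise. Controls carry drift and noise only.
#'
#' @param population table from [generate_aggregate_population()].
#' @param vial_volume_mL vial volume in mL, default 5.9.
#' @param duration_h incubation duration in hours, default 24.
#' @param o2_start_umol_L starting O2 concentration, umol L^-1.
#' @param control_drift_frac fractional concentration drift over the
#'   incubation shared by all vials (positive = O2 loss), default 0.
#' @param noise_sd_umol_L sd of end-concentration measurement noise.
#' @param n_controls number of aggregate-free control vials, default 3.
#' @param rq respiratory quotient, mol O2 per mol CO2, default 1.2.
#' @param seed integer RNG seed.
#' @return tibble of assays: `vial_id`, `is_control`, `vial_volume_mL`,
#'   `o2_start_umol_L`, `o2_end_umol_L`, `duration_h`, `poc_ug`, `true_k_d`.
#' @export
generate_o2_assays <- function(population, vial_volume_mL = 5.9,
                               duration_h = 24, o2_start_umol_L = 300,
                               control_drift_frac = 0, noise_sd_umol_L = 0,
                               n_controls = 3, rq = 1.2, seed = 1L) {
  check_number(vial_volume_mL, "vial_volume_mL", function(v) v > 0, "> 0")
  check_number(duration_h, "duration_h", function(v) v > 0, "> 0")
  check_number(o2_start_umol_L, "o2_start_umol_L", function(v) v > 0, "> 0")
  check_number(control_drift_frac, "control_drift_frac")
  check_number(noise_sd_umol_L, "noise_sd_umol_L", function(v) v >= 0, ">= 0")
  check_number(n_controls, "n_controls",
               function(v) v >= 1 && v == round(v), "positive integer")
  check_number(rq, "rq", function(v) v > 0, "> 0")
  check_number(seed, "seed", function(v) v == round(v), "integer")

  dur_d <- duration_h / 24
  vol_L <- vial_volume_mL / 1000
  # O2 consumed (umol) = RQ * k * POC(umol C) * duration
  o2_umol <- rq * population$resp_k_d * (population$poc_ug / 12.011) * dur_d
  drawdown <- o2_umol / vol_L
  drift <- control_drift_frac * o2_start_umol_L

  withr::with_seed(seed, {
    n_agg <- nrow(population)
    noise <- if (noise_sd_umol_L > 0) {
      rnorm(n_agg + n_controls, sd = noise_sd_umol_L)
    } else {
      rep(0, n_agg + n_controls)
    }
    end_agg <- o2_start_umol_L - drawdown - drift + noise[seq_len(n_agg)]
    if (any(end_agg < 0)) {
      abort_config("O2 drawdown exceeds the starting concentration (anoxia) ",
                   "for aggregate(s) ",
                   paste(population$id[end_agg < 0], collapse = ", "))
    }
    end_ctl <- o2_start_umol_L - drift + noise[n_agg + seq_len(n_controls)]
    bind_rows(
      tibble(vial_id = population$id, is_control = FALSE,
             vial_volume_mL = vial_volume_mL,
             o2_start_umol_L = o2_start_umol_L, o2_end_umol_L = end_agg,
             duration_h = duration_h, poc_ug = population$poc_ug,
             true_k_d = population$resp_k_d),
      tibble(vial_id = n_agg + seq_len(n_controls), is_control = TRUE,
             vial_volume_mL = vial_volume_mL,
             o2_start_umol_L = o2_start_umol_L, o2_end_umol_L = end_ctl,
             duration_h = duration_h, poc_ug = NA_real_, true_k_d = NA_real_)
    )
  })
}
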