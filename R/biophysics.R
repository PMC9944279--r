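#' Physical constants for settling calculations
#'
#' Internal computations run in cgs units. Defaults are for freshwater at
#' 17 degrees C: kinematic viscosity 1.085e-2 cm^2 s^-1 and gravitational
#' acceleration 981 cm s^-2. Velocities cross the package boundary in
#' m d^-1 (1 cm s^-1 = 864 m d^-1) and diameters in mm.
#'
#' @param nu kinematic viscosity, cm^2 s^-1.
#' @param g gravitational acceleration, cm s^-2.
#' @return a list of class `agg_constants`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(nu = 1.085e-2, g = 981) {
  check_number(nu, "nu", function(v) v > 0, "> 0")
  check_number(g, "g", function(v) v > 0, "> 0")
  structure(list(nu = nu, g = g, m_per_day_per_cm_s = 864),
            class = "agg_constants")
}

#' Equivalent circular diameter from cross-sectional area
#'
#' The diameter of a circle with the same area as the detected particle,
#' assuming spherical geometry: d = 2 * sqrt(A / pi). Unit-consistent: the
#' result carries the square root of the area unit.
#'
#' @param area cross-sectional area (any squared length unit), > 0.
#' @return diameter in the corresponding length unit.
#' @examples
#' ecd_from_area(pi)        # 2
#' ecd_from_area(c(3, 12))  # ~1.95 and ~3.91 um for areas in um^2
#' @export
ecd_from_area <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    abort_config("`area` must be positive and finite")
  }
  2 * sqrt(area / pi)
}

#' Sphere volume from diameter
#'
#' V = (pi/6) d^3, used to assign a volume to each aggregate from its ECD.
#'
#' @param d diameter (any length unit), > 0.
#' @return volume in the cubed unit.
#' @examples
#' sphere_volume(1) # 0.5236
#' @export
sphere_volume <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    abort_config("`d` must be positive and finite")
  }
  pi / 6 * d^3
}

#' Settling velocity from a timed settling trial
#'
#' Aggregates are timed while sinking a fixed distance (default 15 cm) in a
#' settling column; velocity is distance/time converted to m d^-1.
#'
#' @param time_s settling time in seconds, > 0.
#' @param distance_cm settling distance in cm, default 15.
#' @param constants see [physical_constants()].
#' @return settling velocity U in m d^-1.
#' @examples
#' settling_velocity(60)  # 216 m/d
#' settling_velocity(150) # 86.4 m/d
#' @export
settling_velocity <- function(time_s, distance_cm = 15,
                              constants = physical_constants()) {
  if (!is.numeric(time_s) || any(!is.finite(time_s)) || any(time_s <= 0)) {
    abort_config("`time_s` must be positive and finite")
  }
  check_number(distance_cm, "distance_cm", function(v) v > 0, "> 0")
  distance_cm / time_s * constants$m_per_day_per_cm_s
}

#' Stokes-law excess density of a settling aggregate
#'
#' delta_rho = 18 U nu / (g d^2), evaluated in cgs and reported in mg cm^-3
#' (the bulk density of the aggregate in excess of the ambient water).
#'
#' @param u_m_d settling velocity in m d^-1.
#' @param d_mm diameter (ECD) in mm.
#' @param constants see [physical_constants()].
#' @return excess density in mg cm^-3.
#' @examples
#' excess_density(201, 2.4) # ~0.8 mg cm^-3
#' excess_density(144, 2.4) # ~0.6 mg cm^-3
#' @export
excess_density <- function(u_m_d, d_mm, constants = physical_constants()) {
  if (any(!is.finite(u_m_d)) || any(u_m_d < 0)) {
    abort_config("`u_m_d` must be finite and >= 0")
  }
  if (any(!is.finite(d_mm)) || any(d_mm <= 0)) {
    abort_config("`d_mm` must be positive and finite")
  }
  u_cm_s <- u_m_d / constants$m_per_day_per_cm_s
  d_cm <- d_mm / 10
  1000 * 18 * u_cm_s * constants$nu / (constants$g * d_cm^2)
}

#' Stokes settling velocity implied by an excess density
#'
#' Inverse of [excess_density()]: U = delta_rho g d^2 / (18 nu), reported in
#' m d^-1. Used for internal-consistency checks and for predicting how a
#' density change translates into a velocity change.
#'
#' @param drho_mg_cm3 excess density in mg cm^-3.
#' @param d_mm diameter in mm.
#' @param constants see [physical_constants()].
#' @return velocity in m d^-1.
#' @export
stokes_velocity <- function(drho_mg_cm3, d_mm,
                            constants = physical_constants()) {
  if (any(!is.finite(drho_mg_cm3)) || any(drho_mg_cm3 < 0)) {
    abort_config("`drho_mg_cm3` must be finite and >= 0")
  }
  if (any(!is.finite(d_mm)) || any(d_mm <= 0)) {
    abort_config("`d_mm` must be positive and finite")
  }
  d_cm <- d_mm / 10
  u_cm_s <- (drho_mg_cm3 / 1000) * constants$g * d_cm^2 / (18 * constants$nu)
  u_cm_s * constants$m_per_day_per_cm_s
}

#' Aggregate porosity from excess and solid hydrated density
#'
#' phi = 1 - delta_rho / rho_s: the aggregate volume fraction occupied by
#' water. delta_rho is accepted in mg cm^-3 (as reported) and rho_s in
#' g cm^-3 (density-gradient measurement); the mg-to-g conversion is applied
#' internally. The aggregate volume cancels algebraically.
#'
#' @param drho_mg_cm3 excess density in mg cm^-3, >= 0.
#' @param rho_s_g_cm3 solid hydrated density in g cm^-3, > 0.
#' @return porosity in \[0, 1\].
#' @examples
#' porosity(0.6, 1.258) # 0.9995
#' @export
porosity <- function(drho_mg_cm3, rho_s_g_cm3) {
  if (any(!is.finite(drho_mg_cm3)) || any(drho_mg_cm3 < 0)) {
    abort_config("`drho_mg_cm3` must be finite and >= 0")
  }
  if (any(!is.finite(rho_s_g_cm3)) || any(rho_s_g_cm3 <= 0)) {
    abort_config("`rho_s_g_cm3` must be positive and finite")
  }
  drho_g <- drho_mg_cm3 / 1000
  if (any(drho_g > rho_s_g_cm3)) {
    abort_config("excess density exceeds solid hydrated density; ",
                 "porosity would be negative")
  }
  1 - drho_g / rho_s_g_cm3
}

#' Particle Reynolds number
#'
#' Re = d U / nu with d and U converted to cgs.
#'
#' @param d_mm diameter in mm.
#' @param u_m_d settling velocity in m d^-1.
#' @param constants see [physical_constants()].
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(2.4, 201) # ~5.15
#' @export
reynolds_number <- function(d_mm, u_m_d, constants = physical_constants()) {
  if (any(!is.finite(d_mm)) || any(d_mm <= 0)) {
    abort_config("`d_mm` must be positive and finite")
  }
  if (any(!is.finite(u_m_d)) || any(u_m_d < 0)) {
    abort_config("`u_m_d` must be finite and >= 0")
  }
  (d_mm / 10) * (u_m_d / constants$m_per_day_per_cm_s) / constants$nu
}

#' Drag coefficient of a settling particle
#'
#' C_D = 24/Re + 6/(1 + sqrt(Re)) + 0.4, the standard intermediate-Reynolds
#' interpolation (tends to 0.4 as Re grows, to Stokes drag 24/Re as Re -> 0).
#'
#' @param re Reynolds number, > 0.
#' @return dimensionless drag coefficient.
#' @examples
#' drag_coefficient(1) # 27.4
#' @export
drag_coefficient <- function(re) {
  if (any(!is.finite(re)) || any(re <= 0)) {
    abort_config("`re` must be positive and finite")
  }
  24 / re + 6 / (1 + sqrt(re)) + 0.4
}

#' Density gradient for solid-hydrated-density assignment
#'
#' Cells or aggregates are centrifuged onto a stack of viscous layers of
#' increasing density; they come to rest in the layer matching the density
#' of their hydrated particulate material. The default six layers span
#' 1.18-1.38 g cm^-3.
#'
#' @param layer_densities strictly increasing densities in g cm^-3, top to
#'   bottom.
#' @return an object of class `agg_density_gradient`.
#' @export
density_gradient <- function(layer_densities = seq(1.18, 1.38, length.out = 6)) {
  if (!is.numeric(layer_densities) || length(layer_densities) < 2 ||
      any(!is.finite(layer_densities)) || any(diff(layer_densities) <= 0)) {
    abort_config("`layer_densities` must be strictly increasing")
  }
  structure(list(layer_densities = layer_densities),
            class = "agg_density_gradient")
}

#' Assign a mass density from the density layer an item settled into
#'
#' Returns the measured density of the layer in which the item came to rest
#' (its solid hydrated density). If the item settled through the densest
#' layer, its density exceeds the gradient and cannot be assigned.
#'
#' @param layer_index 1-based index of the layer the item settled into.
#' @param gradient an [density_gradient()] object (or its numeric layers).
#' @param measured_layer_density optional directly measured density of that
#'   layer (density meter reading); used in preference to the nominal value.
#' @return mass density rho_s in g cm^-3.
#' @examples
#' g <- density_gradient()
#' assign_density_layer(3, g)
#' assign_density_layer(3, g, measured_layer_density = 1.284)
#' @export
assign_density_layer <- function(layer_index, gradient = density_gradient(),
                                 measured_layer_density = NULL) {
  layers <- if (inherits(gradient, "agg_density_gradient")) {
    gradient$layer_densities
  } else {
    density_gradient(gradient)$layer_densities
  }
  check_number(layer_index, "layer_index", function(v) v >= 1 && v == round(v),
               "positive integer")
  if (layer_index > length(layers)) {
    rlang::abort(
      sprintf("item settled below the densest layer (index %d of %d): exceeds gradient",
              as.integer(layer_index), length(layers)),
      class = "aggsink_exceeds_gradient")
  }
  if (!is.null(measured_layer_density)) {
    check_number(measured_layer_density, "measured_layer_density",
                 function(v) v > 0, "> 0")
    return(measured_layer_density)
  }
  layers[[layer_index]]
}

#' Derive the full set of per-aggregate biophysical quantities
#'
#' Takes a table with measured diameter and settling velocity and appends
#' the derived columns used in single-aggregate summaries: sphere volume,
#' Stokes excess density, porosity (given a solid hydrated density),
#' Reynolds number, and drag coefficient.
#'
#' @param records data frame with columns `d_mm` and `u_m_d`.
#' @param rho_s_g_cm3 solid hydrated density used for porosity (scalar or
#'   per-row vector), g cm^-3.
#' @param constants see [physical_constants()].
#' @return the input tibble with columns `v_mm3`, `drho_mg_cm3`, `phi`,
#'   `re`, `c_d`, `rho_s_g_cm3` appended.
#' @examples
#' aggregate_biophysics(tibble::tibble(d_mm = 2.4, u_m_d = 201), 1.284)
#' @export
aggregate_biophysics <- function(records, rho_s_g_cm3,
                                 constants = physical_constants()) {
  if (!is.data.frame(records) || !all(c("d_mm", "u_m_d") %in% names(records))) {
    abort_config("`records` must be a data frame with columns `d_mm` and `u_m_d`")
  }
  records %>%
    as_tibble() %>%
    mutate(
      v_mm3 = sphere_volume(.data$d_mm),
      drho_mg_cm3 = excess_density(.data$u_m_d, .data$d_mm, constants),
      rho_s_g_cm3 = rho_s_g_cm3,
      phi = porosity(.data$drho_mg_cm3, rho_s_g_cm3),
      re = reynolds_number(.data$d_mm, .data$u_m_d, constants),
      c_d = drag_coefficient(.data$re)
    )
}
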