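#' Speed of sound in water from temperature
#'
#' Quadratic approximation `v_water(t) = 1404.3 + 4.7 t - 0.04 t^2` with
#' `t` in degrees Celsius, used to calibrate the through-transmission
#' water path.
#'
#' @param temp_c Water temperature in Celsius, within \[0, 100\].
#' @return Speed of sound in m/s.
#' @export
water_sound_speed <- function(temp_c) {
  if (!is.numeric(temp_c) || any(!is.finite(temp_c))) {
    stop("water_sound_speed: 'temp_c' must be finite numeric", call. = FALSE)
  }
  if (any(temp_c < 0 | temp_c > 100)) {
    stop("water_sound_speed: temperature outside [0, 100] C", call. = FALSE)
  }
  1404.3 + 4.7 * temp_c - 0.04 * temp_c^2
}

#' Acoustic velocity of a material from a through-transmission time shift
#'
#' With a sample of height `h` inserted into a water path, the onset of
#' the received ultrasonic burst shifts by `delta_t = t_material -
#' t_water_baseline` (negative when the material is faster than water).
#' The material velocity follows from `v = h / (delta_t + h / v_water)`.
#'
#' @param height_m Sample height in metres (> 0).
#' @param delta_t_s Time shift in seconds (material onset minus
#'   water-only baseline onset).
#' @param v_water_ms Speed of sound in the water bath, m/s.
#' @return Material acoustic velocity in m/s.
#' @export
material_velocity <- function(height_m, delta_t_s, v_water_ms) {
  if (!is.numeric(height_m) || any(height_m <= 0)) {
    stop("material_velocity: 'height_m' must be positive", call. = FALSE)
  }
  if (!is.numeric(v_water_ms) || any(v_water_ms <= 0)) {
    stop("material_velocity: 'v_water_ms' must be positive", call. = FALSE)
  }
  transit <- delta_t_s + height_m / v_water_ms
  if (any(transit <= 0)) {
    stop("material_velocity: non-positive effective transit time (delta_t + h/v_water <= 0)",
         call. = FALSE)
  }
  height_m / transit
}

#' Specific characteristic acoustic impedance
#'
#' `z = rho * v` in kg m^-2 s^-1 (Rayl). Impedance mismatch across an
#' interface governs how much of an acoustic wave reflects rather than
#' transmits.
#'
#' @param density_kg_m3 Volumetric mass density, kg/m^3 (> 0).
#' @param velocity_ms Acoustic velocity, m/s (> 0).
#' @return Impedance in kg m^-2 s^-1.
#' @export
acoustic_impedance <- function(density_kg_m3, velocity_ms) {
  if (!is.numeric(density_kg_m3) || any(density_kg_m3 <= 0) ||
      !is.numeric(velocity_ms) || any(velocity_ms <= 0)) {
    stop("acoustic_impedance: density and velocity must be positive",
         call. = FALSE)
  }
  density_kg_m3 * velocity_ms
}

#' One through-transmission impedance measurement
#'
#' @param material Material identifier.
#' @param sample_height_m Sample height in metres (> 0).
#' @param delta_t_s Onset time shift in seconds (see
#'   [material_velocity()]); may be `NA` when a velocity is supplied
#'   directly to [impedance_table()].
#' @param water_temp_c Bath temperature in Celsius.
#' @param density_kg_m3 Measured density, kg/m^3 (> 0). Density is an
#'   input: the suspension-technique protocol that produces it is a lab
#'   procedure outside this package.
#' @return An `impedance_measurement` object.
#' @export
impedance_measurement <- function(material, sample_height_m, delta_t_s,
                                  water_temp_c, density_kg_m3) {
  if (!is.numeric(sample_height_m) || sample_height_m <= 0) {
    stop("impedance_measurement: sample_height_m must be positive",
         call. = FALSE)
  }
  if (!is.numeric(density_kg_m3) || density_kg_m3 <= 0) {
    stop("impedance_measurement: density_kg_m3 must be positive",
         call. = FALSE)
  }
  structure(list(material = as.character(material),
                 sample_height_m = as.numeric(sample_height_m),
                 delta_t_s = as.numeric(delta_t_s),
                 water_temp_c = as.numeric(water_temp_c),
                 density_kg_m3 = as.numeric(density_kg_m3)),
            class = "impedance_measurement")
}

# z display convention: 3 significant figures in units of 1e6, except
# values below 0.01e6 which round to 1 significant figure (the air row).
format_z <- function(z) {
  ze6 <- z / 1e6
  shown <- ifelse(ze6 >= 0.01, signif(ze6, 3), signif(ze6, 1))
  sprintf("%ge6", shown)
}

#' Impedance report table
#'
#' Builds rows (material, density, velocity, impedance) from a list of
#' measurements. Velocity per material either comes from the supplied
#' `velocities` map (e.g. the mean of several bath measurements) or is
#' derived from the measurement's time shift and bath temperature via
#' [water_sound_speed()] and [material_velocity()]. The displayed
#' impedance is rounded to 3 significant figures in units of 1e6
#' (1 significant figure below 0.01e6); full precision is kept in the
#' `z_kg_m2_s` column.
#'
#' @param measurements List of [impedance_measurement()]s (one per
#'   material).
#' @param velocities Optional named numeric vector, material -> velocity
#'   in m/s.
#' @return data.frame with columns `material`, `density_kg_m3`,
#'   `velocity_ms`, `z_kg_m2_s`, `z_display`.
#' @export
impedance_table <- function(measurements, velocities = NULL) {
  if (length(measurements) == 0L) {
    stop("impedance_table: empty input", call. = FALSE)
  }
  rows <- lapply(measurements, function(m) {
    if (!inherits(m, "impedance_measurement")) {
      stop("impedance_table: all elements must be impedance_measurement objects",
           call. = FALSE)
    }
    v <- if (!is.null(velocities) && m$material %in% names(velocities)) {
      as.numeric(velocities[[m$material]])
    } else if (is.finite(m$delta_t_s)) {
      vw <- water_sound_speed(m$water_temp_c)
      material_velocity(m$sample_height_m, m$delta_t_s, vw)
    } else {
      stop(sprintf(
        "impedance_table: no velocity available for material '%s'",
        m$material), call. = FALSE)
    }
    z <- acoustic_impedance(m$density_kg_m3, v)
    data.frame(material = m$material, density_kg_m3 = m$density_kg_m3,
               velocity_ms = v, z_kg_m2_s = z, z_display = format_z(z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
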