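# One-compartment constant-clearance lung-burden kinetics.
#
# dB/dt = D - k B  with deposition rate D and first-order clearance rate
# k = ln(2)/t_half, giving the steady state B_ss = D / k and the analytic
# trajectory B(t) = (D/k)(1 - exp(-k t)) from an empty lung.  The clearance
# rate is always computed exactly as ln(2)/t_half: the rounded "0.01/day"
# sometimes quoted for a 60-day rat half-time would shift every derived
# NOAEC by about 15%.

#' Clearance rate from half-time
#'
#' @param half_time [quantity()] in days (or numeric days), strictly
#'   positive.
#' @return Rate `ln(2)/t_half` as a [quantity()] in 1/day.
#' @export
rate_from_half_time <- function(half_time) {
  half_time <- as_quantity(half_time, "day")
  if (base_magnitude(half_time) <= 0) {
    stop("half-time must be strictly positive", call. = FALSE)
  }
  quantity(log(2), "1") / half_time
}

#' First-order clearance specification
#'
#' Couples a half-time and rate with the exact identity
#' `rate x half_time = ln(2)`.
#'
#' @param half_time [quantity()] in days, or numeric days.
#' @return Object of class `clearance_spec` with elements `half_time` and
#'   `rate`.
#' @export
clearance_spec <- function(half_time) {
  half_time <- convert(as_quantity(half_time, "day"), "day")
  rate <- rate_from_half_time(half_time)
  structure(list(half_time = half_time, rate = convert(rate, "1/day")),
            class = "clearance_spec")
}

#' @export
print.clearance_spec <- function(x, ...) {
  cat("<clearance_spec> t1/2 =", format(x$half_time), "  k =",
      format(x$rate), "\n")
  invisible(x)
}

as_clearance <- function(x) {
  if (inherits(x, "clearance_spec")) x else clearance_spec(x)
}

#' Alveolar deposition rate
#'
#' Mass rate `C x F_a x VE`; when a particle density is supplied the
#' deposited mass is re-expressed as particle volume (`/ rho`) and the rate
#' is returned in ul/day.  All ventilation is the daily exposure-period
#' volume (tidal volume x respiratory rate folded in), so per-kg ventilation
#' yields a per-kg deposition rate.
#'
#' @param concentration Dust concentration in inhaled air ([quantity()],
#'   mg/m^3, or numeric in those units).
#' @param alveolar_fraction Dimensionless fraction in `(0, 1)`.
#' @param ventilation Daily ventilation volume ([quantity()], m^3/day or
#'   m^3/(day kg)).
#' @param density Optional particle density ([quantity()], g/cm^3) switching
#'   the output from mass to volume rate.
#' @param schedule_factor Dimensionless exposure-schedule adjustment,
#'   default 1 (the daily ventilation volumes already encode the exposure
#'   schedule).
#' @return [quantity()] in mg/day (mass) or ul/day (volume), possibly per
#'   kg, following the dimension of `ventilation`.
#' @export
deposition_rate <- function(concentration, alveolar_fraction, ventilation,
                            density = NULL, schedule_factor = 1) {
  concentration <- as_quantity(concentration, "mg/m^3")
  ventilation <- as_quantity(ventilation, "m^3/day")
  if (base_magnitude(concentration) > 0 &&
      (alveolar_fraction <= 0 || alveolar_fraction >= 1)) {
    stop("alveolar_fraction must lie in (0, 1)", call. = FALSE)
  }
  rate <- concentration * quantity(alveolar_fraction) * ventilation *
    quantity(schedule_factor)
  if (!is.null(density)) {
    density <- as_quantity(density, "g/cm^3")
    rate <- rate / density
    per_kg <- abs(rate$dim[["mass"]] + 1) < 1e-9   # volume rate per kg
    return(convert(rate, if (per_kg) "ul/kg/day" else "ul/day"))
  }
  per_kg <- abs(rate$dim[["mass"]]) < 1e-9         # mass rate per kg
  convert(rate, if (per_kg) "mg/kg/day" else "mg/day")
}

#' Steady-state alveolar burden
#'
#' Steady-state lung load equals mean deposition rate over clearance rate.
#'
#' @param dep_rate Deposition rate ([quantity()], mg/day or ul/day,
#'   optionally per kg).
#' @param clearance A [clearance_spec()] or half-time in days.
#' @return Burden [quantity()] (mg or ul, matching `dep_rate`).
#' @export
steady_state_burden <- function(dep_rate, clearance) {
  clearance <- as_clearance(clearance)
  dep_rate <- as_quantity(dep_rate, "mg/day")
  if (base_magnitude(clearance$rate) <= 0) {
    stop("zero clearance rate: no steady state exists", call. = FALSE)
  }
  dep_rate / clearance$rate
}

#' Analytic burden trajectory of the one-compartment model
#'
#' `B(t) = (D/k)(1 - exp(-k t))` from an empty lung; non-decreasing and
#' bounded above by the steady state.
#'
#' @param dep_rate Deposition rate ([quantity()] or numeric mg/day).
#' @param clearance A [clearance_spec()] or half-time in days.
#' @param times Non-negative, strictly increasing vector of times
#'   ([quantity()] vectors are not supported; numeric days).
#' @return Object of class `burden_state`: list with `deposition_rate`,
#'   `clearance`, `steady_state_burden` and a data.frame `trajectory`
#'   (`time_days`, `burden`), burdens in the unit of
#'   `steady_state_burden`.
#' @export
burden_trajectory <- function(dep_rate, clearance, times) {
  clearance <- as_clearance(clearance)
  dep_rate <- as_quantity(dep_rate, "mg/day")
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  bss <- steady_state_burden(dep_rate, clearance)
  k <- magnitude(clearance$rate, "1/day")
  burden <- bss$magnitude * (1 - exp(-k * times))
  structure(
    list(deposition_rate = dep_rate, clearance = clearance,
         steady_state_burden = bss,
         trajectory = data.frame(time_days = times, burden = burden),
         burden_unit = bss$unit_label),
    class = "burden_state")
}

#' @export
print.burden_state <- function(x, ...) {
  cat("<burden_state> D =", format(x$deposition_rate), " t1/2 =",
      format(x$clearance$half_time), "\n  steady state:",
      format(x$steady_state_burden), "\n  trajectory:",
      nrow(x$trajectory), "points in [", min(x$trajectory$time_days), ",",
      max(x$trajectory$time_days), "] days\n")
  invisible(x)
}

#' Invert a threshold burden to a NOAEC
#'
#' The inverse of steady-state burden composed with deposition rate: the air
#' concentration at which the steady-state burden equals the threshold.  For
#' a volumetric threshold (ul, with a density) this is
#' `threshold x rho x k / (VE x F_a)`; without density the threshold is a
#' mass and the density term drops.
#'
#' @param threshold_burden [quantity()] (ul/kg, ul, mg/kg or mg).
#' @param clearance A [clearance_spec()] or half-time in days.
#' @param ventilation Daily ventilation volume ([quantity()], m^3/day,
#'   per kg if the threshold is per kg).
#' @param alveolar_fraction Dimensionless in `(0, 1)`.
#' @param density Optional particle density ([quantity()], g/cm^3); required
#'   when the threshold is a volume.
#' @return NOAEC as a [quantity()] in mg/m^3.
#' @examples
#' noaec_from_threshold(quantity(1, "ul/kg"), 60,
#'                      quantity(0.29, "m^3/kg/day"), 0.075,
#'                      quantity(1, "g/cm^3"))   # 0.531 mg/m^3
#' @export
noaec_from_threshold <- function(threshold_burden, clearance, ventilation,
                                 alveolar_fraction, density = NULL) {
  clearance <- as_clearance(clearance)
  threshold_burden <- as_quantity(threshold_burden, "ul/kg")
  ventilation <- as_quantity(ventilation, "m^3/day")
  if (base_magnitude(threshold_burden) < 0) {
    stop("threshold burden must be non-negative", call. = FALSE)
  }
  if (base_magnitude(threshold_burden) > 0 &&
      (alveolar_fraction <= 0 || alveolar_fraction >= 1)) {
    stop("alveolar_fraction must lie in (0, 1)", call. = FALSE)
  }
  num <- threshold_burden
  if (!is.null(density)) num <- num * as_quantity(density, "g/cm^3")
  num <- num * clearance$rate
  convert(num / (ventilation * quantity(alveolar_fraction)), "mg/m^3")
}
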