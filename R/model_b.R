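# Model B: retained particle volume per alveolar macrophage pool volume.
#
# The overload threshold is a critical retained particle *volume* relative
# to the macrophage pool volume (Morrow's criterion: 6% of the pool).  A rat
# NOAEC follows by inverting the one-compartment steady state,
#
#   NOAEC = threshold [ul/kg] * rho * k_rat / (VE_rat [m^3/(day kg)] * F_rat),
#
# and the HEC follows from two adjustment factors,
#
#   AF_lungburden = (VE_rat F_rat) / (VE_human F_human)   (per-kg ventilation)
#   AF_clearance  = (t_half_human / t_half_rat) * (pool_rat / pool_human)
#   HEC = NOAEC * AF_lungburden / AF_clearance.
#
# The AF closed forms are the unique two-factor decomposition of the full
# steady-state burden-per-pool equivalence ratio; hec_volumetric()
# cross-checks the decomposition against the full ratio on every call and
# aborts on disagreement.  All quantities are normalised per kg body weight
# on both species (the classical formulation mixed a per-g-lung threshold
# with per-kg-rat ventilation; restating the threshold per kg raises it from
# 1 to 4.2 ul/kg, and both are first-class scenarios here).

#' Construct a Model B scenario
#'
#' @param rat,human [species_physiology()] records; defaults are the 1 kg
#'   reference rat and the 70 kg reference human with a 400-day clearance
#'   half-time.
#' @param rat_alveolar_fraction,human_alveolar_fraction Dimensionless
#'   alveolar deposition fractions in `(0, 1)` (or [deposition_profile()]
#'   records).
#' @param threshold_volume_per_kg Critical steady-state particle volume
#'   burden ([quantity()], ul/kg, or numeric).
#' @param particle_density [quantity()], g/cm^3, or numeric.
#' @param fvi Dimensionless divisor of undocumented origin in the classical
#'   NOAEC formula; all published sensitivity results are reproduced with
#'   the default 1.
#' @param mppd_version_label Text recording which deposition program version
#'   produced the fractions.
#' @param label Scenario label used in grids and reports.
#' @return Object of class `model_b_scenario`.
#' @export
model_b_scenario <- function(rat = load_physiology("rat_MAK"),
                             human = load_physiology("human_MAK_Brown"),
                             rat_alveolar_fraction,
                             human_alveolar_fraction,
                             threshold_volume_per_kg = quantity(1, "ul/kg"),
                             particle_density = quantity(1, "g/cm^3"),
                             fvi = 1,
                             mppd_version_label = "",
                             label = "") {
  stopifnot(inherits(rat, "species_physiology"),
            inherits(human, "species_physiology"))
  f_r <- alveolar_fraction_of(rat_alveolar_fraction)
  f_h <- alveolar_fraction_of(human_alveolar_fraction)
  if (f_r <= 0 || f_r >= 1 || f_h <= 0 || f_h >= 1) {
    stop("alveolar fractions must lie in (0, 1)", call. = FALSE)
  }
  threshold_volume_per_kg <- as_quantity(threshold_volume_per_kg, "ul/kg")
  particle_density <- as_quantity(particle_density, "g/cm^3")
  if (base_magnitude(threshold_volume_per_kg) <= 0 ||
      base_magnitude(particle_density) <= 0 || fvi <= 0) {
    stop("threshold, density and fvi must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(rat = rat, human = human,
         rat_alveolar_fraction = f_r, human_alveolar_fraction = f_h,
         threshold_volume_per_kg = threshold_volume_per_kg,
         particle_density = particle_density, fvi = fvi,
         mppd_version_label = mppd_version_label, label = label),
    class = "model_b_scenario")
}

#' Morrow overload threshold
#'
#' The critical retained particle volume is a fixed fraction (classically
#' 6%) of the alveolar macrophage pool volume.
#'
#' @param pool_per_kg Macrophage pool volume ([quantity()], ul/kg, or
#'   numeric).
#' @param fraction Dimensionless in `[0, 1)`, default 0.06.
#' @return Threshold as a [quantity()] in ul/kg; 6% of the 70 ul/kg rat pool
#'   is 4.2 ul/kg.
#' @export
morrow_threshold <- function(pool_per_kg, fraction = 0.06) {
  pool_per_kg <- as_quantity(pool_per_kg, "ul/kg")
  if (base_magnitude(pool_per_kg) <= 0) {
    stop("pool volume must be strictly positive", call. = FALSE)
  }
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  convert(pool_per_kg * quantity(fraction), "ul/kg")
}

#' Re-express a per-kg-body-weight threshold per gram of lung
#'
#' @param threshold_per_kg [quantity()], ul/kg body weight.
#' @param lung_mass_per_kg [quantity()], g lung per kg body weight.
#' @return Threshold as a [quantity()] in ul per g lung; 4.2 ul/kg over
#'   4.5 g lung/kg gives 0.933 ul/g.
#' @export
threshold_per_gram_lung <- function(threshold_per_kg, lung_mass_per_kg) {
  threshold_per_kg <- as_quantity(threshold_per_kg, "ul/kg")
  lung_mass_per_kg <- as_quantity(lung_mass_per_kg, "g/kg")
  if (base_magnitude(threshold_per_kg) <= 0 ||
      base_magnitude(lung_mass_per_kg) <= 0) {
    stop("inputs must be strictly positive", call. = FALSE)
  }
  convert(threshold_per_kg / lung_mass_per_kg, "ul/g")
}

#' Rat NOAEC from the volumetric overload threshold
#'
#' Inverts the one-compartment steady state for the scenario's threshold,
#' density, rat half-time, per-kg ventilation and rat alveolar fraction,
#' divided by the scenario's `fvi`.
#'
#' @param s A [model_b_scenario()].
#' @return NOAEC as a [quantity()] in mg/m^3.
#' @export
noaec_eq7 <- function(s) {
  stopifnot(inherits(s, "model_b_scenario"))
  noaec <- noaec_from_threshold(
    threshold_burden = s$threshold_volume_per_kg,
    clearance = clearance_spec(pv_quantity(s$rat$clearance_half_time)),
    ventilation = pv_quantity(s$rat$ventilation_rate_per_kg),
    alveolar_fraction = s$rat_alveolar_fraction,
    density = s$particle_density)
  convert(noaec / quantity(s$fvi), "mg/m^3")
}

#' Lung-burden adjustment factor
#'
#' Ratio of rat to human alveolar volume deposition per kg body weight at
#' equal air concentration: `(VE_rat F_rat) / (VE_human F_human)` with per-kg
#' daily ventilation volumes.
#'
#' @param s A [model_b_scenario()].
#' @return Dimensionless numeric.
#' @export
af_lungburden <- function(s) {
  stopifnot(inherits(s, "model_b_scenario"))
  ve_r <- convert(pv_quantity(s$rat$ventilation_rate_per_kg), "m^3/kg/day")
  ve_h <- convert(pv_quantity(s$human$ventilation_rate_per_kg), "m^3/kg/day")
  den <- ve_h$magnitude * s$human_alveolar_fraction
  if (den == 0) stop("zero human deposition", call. = FALSE)
  ve_r$magnitude * s$rat_alveolar_fraction / den
}

#' Clearance adjustment factor
#'
#' `(t_half_human / t_half_rat) x (pool_rat / pool_human)`: the human
#' retains each deposited volume longer (slower clearance) but dilutes it in
#' a larger macrophage pool per kg.
#'
#' @param s A [model_b_scenario()].
#' @return Dimensionless numeric; 400/60 days x 70/500 ul/kg = 0.933.
#' @export
af_clearance <- function(s) {
  stopifnot(inherits(s, "model_b_scenario"))
  t_r <- magnitude(pv_quantity(s$rat$clearance_half_time), "day")
  t_h <- magnitude(pv_quantity(s$human$clearance_half_time), "day")
  pool_r <- magnitude(pv_quantity(s$rat$macrophage_pool_volume_per_kg),
                      "ul/kg")
  pool_h <- magnitude(pv_quantity(s$human$macrophage_pool_volume_per_kg),
                      "ul/kg")
  if (min(t_r, t_h, pool_r, pool_h) <= 0) {
    stop("half-times and pool volumes must be strictly positive",
         call. = FALSE)
  }
  (t_h / t_r) * (pool_r / pool_h)
}

#' Volume-per-macrophage-pool HEC (Model B translation)
#'
#' Computes the NOAEC via [noaec_eq7()] and the HEC as
#' `NOAEC x AF_lungburden / AF_clearance`, then cross-checks that this
#' two-factor decomposition equals the full steady-state burden-per-pool
#' equivalence ratio `[VE_r F_r/(k_r pool_r)] / [VE_h F_h/(k_h pool_h)]`
#' to 1e-10 relative; disagreement aborts with a consistency error.
#'
#' @param s A [model_b_scenario()].
#' @return A [translation_result()] with adjustment factors and a full
#'   calculation ledger.
#' @export
hec_volumetric <- function(s) {
  stopifnot(inherits(s, "model_b_scenario"))
  noaec <- noaec_eq7(s)
  af_lb <- af_lungburden(s)
  af_cl <- af_clearance(s)
  hec <- convert(noaec * quantity(af_lb / af_cl), "mg/m^3")

  # independent full-ratio route: burden per pool at unit concentration
  k_r <- magnitude(rate_from_half_time(
    pv_quantity(s$rat$clearance_half_time)), "1/day")
  k_h <- magnitude(rate_from_half_time(
    pv_quantity(s$human$clearance_half_time)), "1/day")
  ve_r <- magnitude(pv_quantity(s$rat$ventilation_rate_per_kg), "m^3/kg/day")
  ve_h <- magnitude(pv_quantity(s$human$ventilation_rate_per_kg),
                    "m^3/kg/day")
  pool_r <- magnitude(pv_quantity(s$rat$macrophage_pool_volume_per_kg),
                      "ul/kg")
  pool_h <- magnitude(pv_quantity(s$human$macrophage_pool_volume_per_kg),
                      "ul/kg")
  full_ratio <- (ve_r * s$rat_alveolar_fraction / (k_r * pool_r)) /
    (ve_h * s$human_alveolar_fraction / (k_h * pool_h))
  if (abs(af_lb / af_cl - full_ratio) > 1e-10 * abs(full_ratio)) {
    stop("AF decomposition inconsistent with the full steady-state ",
         "burden-per-pool ratio (", af_lb / af_cl, " vs ", full_ratio, ")",
         call. = FALSE)
  }

  led <- new_ledger()
  led <- ledger_add(led, "overload threshold", s$threshold_volume_per_kg,
                    "critical steady-state particle volume per kg")
  led <- ledger_add(led, "particle density", s$particle_density,
                    s$mppd_version_label)
  led <- ledger_add(led, "NOAEC (rat)", noaec,
                    "threshold x rho x k_rat / (VE_rat x F_rat) / fvi")
  led <- ledger_add(led, "AF_lungburden", quantity(af_lb),
                    "(VE_rat F_rat)/(VE_human F_human), per kg")
  led <- ledger_add(led, "AF_clearance", quantity(af_cl),
                    "(t_half_human/t_half_rat) x (pool_rat/pool_human)")
  led <- ledger_add(led, "HEC", hec, "NOAEC x AF_lungburden / AF_clearance")

  clean <- assert_dimension(noaec, "concentration")$pass &&
    assert_dimension(hec, "concentration")$pass
  translation_result("B", noaec_rat = noaec, hec = hec,
                     af_lungburden = af_lb, af_clearance = af_cl,
                     translation_factor = af_lb / af_cl,
                     ledger = led, dimension_audit_clean = clean)
}

#' Density-proportional rule-of-thumb HEC
#'
#' The published volumetric shortcut `HEC [mg/m^3] = 0.5 x density
#' [g/cm^3]`, kept as a labelled reference line for comparisons; it is not
#' produced by this package's own translation.
#'
#' @param density Particle density ([quantity()], g/cm^3, or numeric).
#' @return HEC as a [quantity()] in mg/m^3.
#' @export
hec_simple_rule <- function(density) {
  density <- as_quantity(density, "g/cm^3")
  if (base_magnitude(density) <= 0) {
    stop("density must be strictly positive", call. = FALSE)
  }
  quantity(0.5 * magnitude(density, "g/cm^3"), "mg/m^3")
}
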