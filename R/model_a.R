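# Model A: retained particle mass per alveolar surface area.
#
# The working assumption is that rats and humans are equally sensitive at
# the same retained mass per m^2 of alveolar surface.  Equating the
# steady-state mass burden per surface across species at their respective
# air concentrations and solving for the human concentration gives
#
#   HEC = NOAEC * [F_r VE_r / (k_r S_r)] / [F_h VE_h / (k_h S_h)]
#
# with absolute (per-animal / per-person) daily ventilation volumes VE.
# Under these assumptions the HEC is density-independent by construction:
# deposition fractions barely vary with density (and in the wrong
# direction), and identical clearance half-times are applied to substances
# of different density, so dividing a finished HEC by a density in g/cm^3
# is dimensionally invalid -- the audit below makes that mechanical.

#' Construct a Model A scenario
#'
#' @param rat,human [species_physiology()] records.
#' @param rat_deposition,human_deposition [deposition_profile()] records (or
#'   bare alveolar fractions in `(0,1)`).
#' @param noaec_rat Rat NOAEC ([quantity()], mg/m^3, or numeric).
#' @param substance_label Text.
#' @param substance_density Particle density ([quantity()], g/cm^3).
#'   Metadata only: the mass-per-surface translation must not use it.
#' @param rat_body_weight Optional override of the rat body weight used to
#'   absolutise the per-kg ventilation ([quantity()], kg).  Defaults to the
#'   rat record's own body weight.
#' @return Object of class `model_a_scenario`.
#' @export
model_a_scenario <- function(rat, human, rat_deposition, human_deposition,
                             noaec_rat, substance_label = "",
                             substance_density = quantity(1, "g/cm^3"),
                             rat_body_weight = NULL) {
  stopifnot(inherits(rat, "species_physiology"),
            inherits(human, "species_physiology"))
  noaec_rat <- as_quantity(noaec_rat, "mg/m^3")
  if (base_magnitude(noaec_rat) <= 0) {
    stop("noaec_rat must be strictly positive", call. = FALSE)
  }
  structure(
    list(rat = rat, human = human,
         rat_deposition = rat_deposition,
         human_deposition = human_deposition,
         noaec_rat = noaec_rat, substance_label = substance_label,
         substance_density = as_quantity(substance_density, "g/cm^3"),
         rat_body_weight = rat_body_weight),
    class = "model_a_scenario")
}

alveolar_fraction_of <- function(x) {
  if (inherits(x, "deposition_profile")) x$alveolar_fraction else as.numeric(x)
}

#' Mass-per-alveolar-surface HEC (Model A forward translation)
#'
#' @param s A [model_a_scenario()].
#' @return A [translation_result()] whose ledger records every intermediate
#'   with units and provenance.  The output is independent of
#'   `substance_density` by construction.
#' @export
hec_mass_per_surface <- function(s) {
  stopifnot(inherits(s, "model_a_scenario"))
  f_r <- alveolar_fraction_of(s$rat_deposition)
  f_h <- alveolar_fraction_of(s$human_deposition)
  if (is.null(f_r) || is.null(f_h) || is.na(f_r) || is.na(f_h)) {
    stop("scenario is missing a deposition profile", call. = FALSE)
  }
  bw_r <- pv_quantity(s$rat_body_weight %||% s$rat$body_weight)
  ve_r <- convert(pv_quantity(s$rat$ventilation_rate_per_kg) * bw_r,
                  "m^3/day")
  ve_h <- convert(pv_quantity(s$human$ventilation_rate_per_kg) *
                    pv_quantity(s$human$body_weight), "m^3/day")
  k_r <- clearance_spec(pv_quantity(s$rat$clearance_half_time))
  k_h <- clearance_spec(pv_quantity(s$human$clearance_half_time))
  s_r <- pv_quantity(s$rat$alveolar_surface_area)
  s_h <- pv_quantity(s$human$alveolar_surface_area)

  # steady-state mass burden per surface at unit air concentration, each side
  per_conc_r <- (quantity(f_r) * ve_r) / (k_r$rate * s_r)
  per_conc_h <- (quantity(f_h) * ve_h) / (k_h$rate * s_h)
  tf <- convert(per_conc_r / per_conc_h, "1")
  hec <- convert(s$noaec_rat * tf, "mg/m^3")

  led <- new_ledger()
  led <- ledger_add(led, "NOAEC (rat)", s$noaec_rat, s$substance_label)
  led <- ledger_add(led, "rat ventilation (absolute)", ve_r,
                    s$rat$species_strain)
  led <- ledger_add(led, "human ventilation (absolute)", ve_h,
                    s$human$species_strain)
  led <- ledger_add(led, "rat clearance rate", k_r$rate, "ln(2)/t_half")
  led <- ledger_add(led, "human clearance rate", k_h$rate, "ln(2)/t_half")
  led <- ledger_add(led, "rat burden/surface per unit concentration",
                    per_conc_r, "F_r VE_r / (k_r S_r)")
  led <- ledger_add(led, "human burden/surface per unit concentration",
                    per_conc_h, "F_h VE_h / (k_h S_h)")
  led <- ledger_add(led, "translation factor", tf, "rat/human ratio")
  led <- ledger_add(led, "HEC", hec, "NOAEC x translation factor")

  clean <- assert_dimension(hec, "concentration")$pass &&
    assert_dimension(tf, "dimensionless")$pass
  translation_result("A", noaec_rat = s$noaec_rat, hec = hec,
                     translation_factor = magnitude(tf, "1"),
                     ledger = led, dimension_audit_clean = clean)
}

#' Recalculate a reference HEC under revised surface and clearance data
#'
#' Applies two multiplicative corrections to a reference mass-per-surface
#' HEC: a revised human/rat alveolar surface ratio (the HEC is proportional
#' to the surface translation factor) and a revised human clearance
#' half-time (the HEC is proportional to the human clearance rate, i.e.
#' inversely proportional to the half-time).
#'
#' @param hec_reference Reference HEC ([quantity()], mg/m^3, or numeric).
#' @param surface_ratio_old,surface_ratio_new Dimensionless human/rat
#'   surface ratios.
#' @param half_time_old,half_time_new Human clearance half-times
#'   ([quantity()], days, or numeric days).
#' @return Corrected HEC as a [quantity()] in mg/m^3:
#'   `hec_reference x (new/old surface ratio) x (old/new half-time)`.
#'   E.g. 0.134 mg/m^3 under 193 -> 349 and 400 -> 255 days becomes
#'   0.380 mg/m^3.
#' @export
corrected_hec <- function(hec_reference, surface_ratio_old,
                          surface_ratio_new, half_time_old, half_time_new) {
  hec_reference <- as_quantity(hec_reference, "mg/m^3")
  half_time_old <- as_quantity(half_time_old, "day")
  half_time_new <- as_quantity(half_time_new, "day")
  vals <- c(base_magnitude(hec_reference), surface_ratio_old,
            surface_ratio_new, base_magnitude(half_time_old),
            base_magnitude(half_time_new))
  if (any(vals <= 0)) {
    stop("all correction inputs must be strictly positive", call. = FALSE)
  }
  out <- hec_reference *
    quantity(surface_ratio_new / surface_ratio_old) *
    (half_time_old / half_time_new)
  convert(out, "mg/m^3")
}

#' Audit the division of a finished HEC by a particle density
#'
#' Performs the division through the unit layer and reports (i) the honest
#' result -- a dimensionless number of order 1e-10, failing the
#' concentration-dimension check -- and (ii) the unit-dropping value obtained
#' by dividing bare magnitudes and silently keeping "mg/m^3", which is what
#' a post-hoc density "correction" actually computes.
#'
#' @param hec [quantity()] in mg/m^3 (or numeric).
#' @param density [quantity()] in g/cm^3 (or numeric).
#' @return Object of class `density_audit`: list with `value` (dimensionless
#'   [quantity()]), `dimension_check` (failed [assert_dimension()] report),
#'   `dimension_ok` (FALSE), and `unit_dropping_value` (bare magnitude
#'   ratio).
#' @examples
#' density_division_audit(quantity(1.06, "mg/m^3"), quantity(4.3, "g/cm^3"))
#' @export
density_division_audit <- function(hec, density) {
  hec <- as_quantity(hec, "mg/m^3")
  density <- as_quantity(density, "g/cm^3")
  if (base_magnitude(hec) <= 0 || base_magnitude(density) <= 0) {
    stop("audit inputs must be strictly positive", call. = FALSE)
  }
  value <- combine(hec, "divide", density)
  chk <- assert_dimension(value, "concentration")
  structure(
    list(value = value,
         dimension_check = chk,
         dimension_ok = chk$pass,
         unit_dropping_value = hec$magnitude / density$magnitude),
    class = "density_audit")
}

#' @export
print.density_audit <- function(x, ...) {
  cat("<density_audit>\n  honest value: ", format(x$value),
      "  (dimension check: ", if (x$dimension_ok) "pass" else "FAIL",
      ")\n", sep = "")
  cat("  ", x$dimension_check$message, "\n", sep = "")
  cat("  unit-dropping magnitude ratio: ",
      format(x$unit_dropping_value, digits = 4),
      "  (units silently kept as mg/m^3)\n", sep = "")
  invisible(x)
}
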