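# Tabulated MPPD alveolar deposition fractions plus extrathoracic
# corrections.  The deposition physics is *not* modelled here: fractions are
# program outputs whose provenance (MPPD version, breathing pattern,
# inhalability setting) materially changes the result, so they are kept as
# keyed data rows and unknown scenarios fail loudly -- no interpolation.
# Percentages are stored as fractions in (0,1); rendering multiplies by 100.

deposition_table_cache <- function() {
  tab <- get0("deposition_table", envir = .dustdose_env)
  if (is.null(tab)) {
    path <- system.file("extdata", "deposition_fractions.csv",
                        package = "dustdose", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    assign("deposition_table", tab, envir = .dustdose_env)
  }
  tab
}

#' The bundled deposition-fraction table
#'
#' @param file Optional path to a user-supplied CSV with the same columns as
#'   the bundled table (`program_version`, `species`, `breathing_pattern`,
#'   `inhalability_adjustment`, `substance`, `mmad_um`, `gsd`,
#'   `density_g_cm3`, `alveolar_fraction`, `head_tb_fraction`, `source`).
#' @return A data.frame; fractions are stored in `(0, 1)`.
#' @export
deposition_table <- function(file = NULL) {
  if (is.null(file)) deposition_table_cache() else
    utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Construct a deposition profile record
#'
#' @param program_version,species,breathing_pattern,inhalability_adjustment,substance
#'   Key labels.
#' @param particle_mmad Mass median aerodynamic diameter ([quantity()], um),
#'   or `NA`.
#' @param particle_gsd Geometric standard deviation, or `NA`.
#' @param particle_density [quantity()], g/cm^3.
#' @param alveolar_fraction Dimensionless fraction in `(0, 1)`.
#' @param head_tb_fraction Head plus tracheo-bronchial fraction in `[0, 1)`,
#'   or `NA`.
#' @param source Provenance string.
#' @return An object of class `deposition_profile`.
#' @export
deposition_profile <- function(program_version, species, breathing_pattern,
                               inhalability_adjustment, substance = "generic",
                               particle_mmad = NA, particle_gsd = NA,
                               particle_density = NA,
                               alveolar_fraction, head_tb_fraction = NA,
                               source = "") {
  if (!is.numeric(alveolar_fraction) || alveolar_fraction <= 0 ||
      alveolar_fraction >= 1) {
    stop("alveolar_fraction must lie in (0, 1); percentages are stored as ",
         "fractions", call. = FALSE)
  }
  if (!is.na(head_tb_fraction)) {
    if (head_tb_fraction < 0 || head_tb_fraction >= 1) {
      stop("head_tb_fraction must lie in [0, 1)", call. = FALSE)
    }
    if (alveolar_fraction + head_tb_fraction > 1) {
      stop("alveolar_fraction + head_tb_fraction must not exceed 1",
           call. = FALSE)
    }
  }
  structure(
    list(program_version = program_version, species = species,
         breathing_pattern = breathing_pattern,
         inhalability_adjustment = inhalability_adjustment,
         substance = substance, particle_mmad = particle_mmad,
         particle_gsd = particle_gsd, particle_density = particle_density,
         alveolar_fraction = alveolar_fraction,
         head_tb_fraction = head_tb_fraction, source = source),
    class = "deposition_profile")
}

#' @export
print.deposition_profile <- function(x, ...) {
  cat("<deposition_profile> ", x$program_version, ", ", x$species, ", ",
      x$breathing_pattern, ", IA ", x$inhalability_adjustment, ", ",
      x$substance, "\n", sep = "")
  cat(sprintf("  alveolar fraction: %.4g%%", 100 * x$alveolar_fraction))
  if (!is.na(x$head_tb_fraction)) {
    cat(sprintf(";  head+TB fraction: %.4g%%", 100 * x$head_tb_fraction))
  }
  cat("\n  ", x$source, "\n", sep = "")
  invisible(x)
}

#' Look up a tabulated deposition profile by exact key
#'
#' No interpolation is performed: a scenario absent from the table is an
#' error that lists the nearest keyed rows, because deposition fractions are
#' program outputs, not smooth functions of the keys.
#'
#' @param program_version e.g. `"MPPD 2.0"`, `"MPPD 2.11"`.
#' @param species `"rat"` or `"human"`.
#' @param breathing_pattern e.g. `"nasal"`, `"Oronasal-Mouth Breather"`,
#'   `"Oronasal-Normal Augmenter"`.  `NULL` matches any.
#' @param inhalability_adjustment `"on"`, `"off"` or `"na"`.  `NULL` matches
#'   any.
#' @param substance `"generic"` (MMAD 1.8 um, GSD 2), `"toner"` or `"TiO2"`.
#' @param density_g_cm3 Particle density key, g/cm^3.  `NULL` matches any.
#' @param table Optional alternative table from [deposition_table()].
#' @return A [deposition_profile()].
#' @examples
#' lookup_deposition("MPPD 2.0", "rat", inhalability_adjustment = "off")
#' lookup_deposition("MPPD 2.0", "human",
#'                   breathing_pattern = "Oronasal-Mouth Breather")
#' @export
lookup_deposition <- function(program_version, species,
                              breathing_pattern = NULL,
                              inhalability_adjustment = NULL,
                              substance = "generic",
                              density_g_cm3 = NULL,
                              table = NULL) {
  tab <- if (is.null(table)) deposition_table() else table
  keep <- tab$program_version == program_version &
    tab$species == species & tab$substance == substance
  if (!is.null(breathing_pattern)) {
    keep <- keep & tab$breathing_pattern == breathing_pattern
  }
  if (!is.null(inhalability_adjustment)) {
    keep <- keep & tab$inhalability_adjustment == inhalability_adjustment
  }
  if (!is.null(density_g_cm3)) {
    keep <- keep & !is.na(tab$density_g_cm3) &
      abs(tab$density_g_cm3 - density_g_cm3) < 1e-9
  }
  hit <- tab[keep, , drop = FALSE]
  if (nrow(hit) == 0) {
    near <- tab[tab$species == species, , drop = FALSE]
    stop("no tabulated deposition profile for (", program_version, ", ",
         species, ", ", breathing_pattern %||% "*", ", IA ",
         inhalability_adjustment %||% "*", ", ", substance,
         "); nearest keyed rows for this species:\n",
         paste(utils::capture.output(print(
           near[, c("program_version", "breathing_pattern",
                    "inhalability_adjustment", "substance",
                    "density_g_cm3", "alveolar_fraction")])),
           collapse = "\n"),
         call. = FALSE)
  }
  if (nrow(hit) > 1) {
    stop("ambiguous deposition key: ", nrow(hit), " rows match; add ",
         "breathing_pattern / inhalability_adjustment / density_g_cm3 keys",
         call. = FALSE)
  }
  deposition_profile(
    program_version = hit$program_version, species = hit$species,
    breathing_pattern = hit$breathing_pattern,
    inhalability_adjustment = hit$inhalability_adjustment,
    substance = hit$substance,
    particle_mmad = if (is.na(hit$mmad_um)) NA else
      quantity(hit$mmad_um, "um"),
    particle_gsd = hit$gsd,
    particle_density = if (is.na(hit$density_g_cm3)) NA else
      quantity(hit$density_g_cm3, "g/cm^3"),
    alveolar_fraction = hit$alveolar_fraction,
    head_tb_fraction = hit$head_tb_fraction,
    source = hit$source)
}

#' Extrathoracic deposition correction factor
#'
#' Converts an alveolar-space concentration to the inhaled-air concentration
#' that produces it: a fraction `f` of the inhaled dust deposits in the head
#' and tracheo-bronchial region, so the factor is `1 / (1 - f)`.  A head+TB
#' fraction of 1/3 (MPPD 2.0 default, inhalability adjustment off) gives 3/2;
#' 25% (adjustment on) gives 4/3.
#'
#' @param head_tb_fraction Dimensionless fraction in `[0, 1)`.
#' @return Dimensionless factor `>= 1`.
#' @export
extrathoracic_correction <- function(head_tb_fraction) {
  if (!is.numeric(head_tb_fraction) || head_tb_fraction < 0 ||
      head_tb_fraction >= 1) {
    stop("head_tb_fraction must lie in [0, 1)", call. = FALSE)
  }
  1 / (1 - head_tb_fraction)
}

#' Volumetric NOAEC from the critical alveolar particle-volume rate
#'
#' The first volumetric derivation chain: a critical daily particle volume in
#' the alveolar space (per kg body weight) is divided by the alveolar
#' ventilation volume (total ventilation minus physiological dead space) to
#' give a critical concentration in alveolar air, then corrected for
#' extrathoracic deposition to give the critical concentration in inhaled
#' air -- the volumetric NOAEC.
#'
#' @param ventilation_per_kg Daily ventilation volume per kg ([quantity()],
#'   m^3/(day kg), or numeric in those units).
#' @param dead_space_fraction Dimensionless in `[0, 1)`.
#' @param critical_alveolar_volume_rate Critical particle volume deposited
#'   per day and kg ([quantity()], ul/(day kg), or numeric in those units).
#' @param head_tb_fraction Head plus tracheo-bronchial deposition fraction in
#'   `[0, 1)`.
#' @return Volumetric NOAEC as a [quantity()] displayed in ul/m^3 (a
#'   volume-per-volume ratio).  The reference chain (0.29 m^3/(day kg), dead
#'   space 1/3, 0.069 ul/(day kg), head+TB 1/3) gives 0.535 ul/m^3.
#' @export
first_derivation_chain <- function(ventilation_per_kg, dead_space_fraction,
                                   critical_alveolar_volume_rate,
                                   head_tb_fraction) {
  ventilation_per_kg <- as_quantity(ventilation_per_kg, "m^3/kg/day")
  critical_alveolar_volume_rate <-
    as_quantity(critical_alveolar_volume_rate, "ul/kg/day")
  if (base_magnitude(ventilation_per_kg) <= 0) {
    stop("ventilation must be strictly positive", call. = FALSE)
  }
  if (base_magnitude(critical_alveolar_volume_rate) < 0) {
    stop("critical volume rate must be non-negative", call. = FALSE)
  }
  if (dead_space_fraction < 0 || dead_space_fraction >= 1) {
    stop("dead_space_fraction must lie in [0, 1)", call. = FALSE)
  }
  alveolar_ventilation <- ventilation_per_kg * quantity(1 - dead_space_fraction)
  in_alveolar_air <- critical_alveolar_volume_rate / alveolar_ventilation
  in_inhaled_air <- in_alveolar_air *
    quantity(extrathoracic_correction(head_tb_fraction))
  convert(in_inhaled_air, "ul/m^3")
}
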