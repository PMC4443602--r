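# Provenance-tagged registry of species physiological parameters, plus the
# surface-ratio and quarter-power allometric derivations built on them.

#' Construct a provenance-tagged parameter value
#'
#' @param quantity A [quantity()].
#' @param source Citation string (must be non-empty: every constant in the
#'   registry is traceable).
#' @param method Free text, e.g. the measurement technique.
#' @param notes Free text.
#' @return An object of class `parameter_value`.
#' @export
parameter_value <- function(quantity, source, method = "", notes = "") {
  stopifnot(is_quantity(quantity))
  if (!is.character(source) || !nzchar(trimws(source))) {
    stop("every registry entry needs a non-empty 'source'", call. = FALSE)
  }
  structure(list(quantity = quantity, source = source,
                 method = method, notes = notes),
            class = "parameter_value")
}

#' @export
print.parameter_value <- function(x, ...) {
  cat(format(x$quantity), " [", x$source, "]\n", sep = "")
  invisible(x)
}

pv_quantity <- function(x) if (inherits(x, "parameter_value")) x$quantity else x

#' Assemble and validate a species physiology record
#'
#' @param species_strain Label.
#' @param body_weight [quantity()] or [parameter_value()], kg.
#' @param ventilation_rate_per_kg Daily exposure-period ventilation volume per
#'   kg body weight, m^3/(day kg).  For rats this already encodes the 6 h/day
#'   chamber schedule; for humans, one work shift.
#' @param alveolar_surface_area m^2 per animal/person.
#' @param dead_space_fraction Dimensionless in `[0, 1)`.
#' @param macrophage_count_per_kg Count per kg body weight, or `NULL`.
#' @param macrophage_cell_volume Single-cell volume, um^3, or `NULL`.
#' @param macrophage_pool_volume_per_kg ul per kg body weight.
#' @param clearance_half_time Alveolar clearance half-time, days.
#' @param lung_mass_per_kg g lung per kg body weight.
#' @return An object of class `species_physiology`.  When both macrophage
#'   count and cell volume are supplied, their product must agree with the
#'   stated pool volume within 1%.
#' @export
species_physiology <- function(species_strain,
                               body_weight,
                               ventilation_rate_per_kg,
                               alveolar_surface_area,
                               dead_space_fraction,
                               macrophage_count_per_kg = NULL,
                               macrophage_cell_volume = NULL,
                               macrophage_pool_volume_per_kg,
                               clearance_half_time,
                               lung_mass_per_kg) {
  obj <- structure(
    list(species_strain = species_strain,
         body_weight = body_weight,
         ventilation_rate_per_kg = ventilation_rate_per_kg,
         alveolar_surface_area = alveolar_surface_area,
         dead_space_fraction = dead_space_fraction,
         macrophage_count_per_kg = macrophage_count_per_kg,
         macrophage_cell_volume = macrophage_cell_volume,
         macrophage_pool_volume_per_kg = macrophage_pool_volume_per_kg,
         clearance_half_time = clearance_half_time,
         lung_mass_per_kg = lung_mass_per_kg),
    class = "species_physiology")
  validate_species_physiology(obj)
  obj
}

validate_species_physiology <- function(p) {
  pos_fields <- c("body_weight", "ventilation_rate_per_kg",
                  "alveolar_surface_area", "macrophage_pool_volume_per_kg",
                  "clearance_half_time", "lung_mass_per_kg")
  for (f in pos_fields) {
    q <- pv_quantity(p[[f]])
    if (!is_quantity(q) || base_magnitude(q) <= 0) {
      stop("physiology field '", f, "' must be a strictly positive quantity",
           call. = FALSE)
    }
  }
  ds <- pv_quantity(p$dead_space_fraction)
  ds <- if (is_quantity(ds)) magnitude(ds, "1") else as.numeric(ds)
  if (ds < 0 || ds >= 1) {
    stop("dead_space_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(p$macrophage_count_per_kg) &&
      !is.null(p$macrophage_cell_volume)) {
    derived <- macrophage_pool_volume(pv_quantity(p$macrophage_count_per_kg),
                                      pv_quantity(p$macrophage_cell_volume))
    stated <- convert(pv_quantity(p$macrophage_pool_volume_per_kg), "ul/kg")
    rel <- abs(magnitude(derived, "ul/kg") - stated$magnitude) /
      stated$magnitude
    if (rel > 0.01) {
      stop("macrophage pool inconsistency: count x cell volume = ",
           signif(magnitude(derived, "ul/kg"), 5), " ul/kg but stated pool is ",
           stated$magnitude, " ul/kg (", signif(100 * rel, 3),
           "% apart; > 1% tolerated)", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.species_physiology <- function(x, ...) {
  cat("<species_physiology> ", x$species_strain, "\n", sep = "")
  for (f in setdiff(names(x), "species_strain")) {
    v <- x[[f]]
    if (is.null(v)) next
    q <- pv_quantity(v)
    lab <- if (is_quantity(q)) format(q) else format(q)
    cat(sprintf("  %-32s %s\n", f, lab))
  }
  invisible(x)
}

#' Alveolar macrophage pool volume from cell count and cell volume
#'
#' @param count_per_kg Macrophage count per kg body weight ([quantity()] with
#'   unit `"1/kg"`, or bare numeric interpreted as per kg).
#' @param cell_volume Single-cell volume ([quantity()], um^3).
#' @return Pool volume as a [quantity()] in ul/kg.  The rat reference values
#'   (6e7 cells/kg of 1166 um^3 each) give 69.96, i.e. the conventional
#'   70 ul/kg.
#' @export
macrophage_pool_volume <- function(count_per_kg, cell_volume) {
  count_per_kg <- as_quantity(count_per_kg, "1/kg")
  cell_volume <- as_quantity(cell_volume, "um^3")
  if (base_magnitude(count_per_kg) <= 0 || base_magnitude(cell_volume) <= 0) {
    stop("count and cell volume must be strictly positive", call. = FALSE)
  }
  convert(count_per_kg * cell_volume, "ul/kg")
}

#' Quarter-power allometric scaling of a clearance half-time
#'
#' Cross-species extrapolation of first-order rates proportional to body
#' weight to the power -1/4 (West et al.): `k_human = k_rat *
#' (bw_rat/bw_human)^(1/4)`.  Half-times are inversely proportional to rates,
#' so `t_half_human = t_half_rat / (bw_rat/bw_human)^(1/4)`.
#'
#' @param t_half_rat Rat clearance half-time ([quantity()], days, or numeric
#'   days).
#' @param bw_rat,bw_human Body weights ([quantity()], kg, or numeric kg).
#' @return Scaled human half-time as a [quantity()] in days.  With 60 days
#'   and 0.25/70 kg this yields 245.5 days.
#' @export
allometric_half_time <- function(t_half_rat, bw_rat, bw_human) {
  t_half_rat <- as_quantity(t_half_rat, "day")
  bw_rat <- as_quantity(bw_rat, "kg")
  bw_human <- as_quantity(bw_human, "kg")
  if (base_magnitude(t_half_rat) <= 0 || base_magnitude(bw_rat) <= 0 ||
      base_magnitude(bw_human) <= 0) {
    stop("allometric scaling needs strictly positive inputs", call. = FALSE)
  }
  ratio <- magnitude(bw_rat / bw_human, "1")
  quantity(magnitude(t_half_rat, "day") / ratio^(1 / 4), "day")
}

#' Interspecies alveolar surface-area translation factor
#'
#' @param s_human,s_rat Alveolar surface areas ([quantity()], m^2, or numeric
#'   m^2).
#' @return Dimensionless ratio human/rat as a [quantity()].  Reference-method
#'   morphometry (143 m^2 human, 0.41 m^2 F344 rat) gives 348.8; the cast-
#'   derived values (57.22/0.2972 m^2) give 192.5.
#' @export
surface_translation_factor <- function(s_human, s_rat) {
  s_human <- as_quantity(s_human, "m^2")
  s_rat <- as_quantity(s_rat, "m^2")
  if (base_magnitude(s_rat) <= 0 || base_magnitude(s_human) <= 0) {
    stop("surface areas must be strictly positive", call. = FALSE)
  }
  convert(s_human / s_rat, "1")
}

load_presets <- function() {
  presets <- get0("physiology_presets", envir = .dustdose_env)
  if (is.null(presets)) {
    path <- system.file("extdata", "physiology_presets.json",
                        package = "dustdose", mustWork = TRUE)
    presets <- jsonlite::read_json(path)$presets
    assign("physiology_presets", presets, envir = .dustdose_env)
  }
  presets
}

field_to_pv <- function(x) {
  if (is.null(x)) return(NULL)
  parameter_value(quantity(x$value, x$unit), source = x$source,
                  method = x$method %||% "", notes = x$notes %||% "")
}

#' Load a species physiology preset
#'
#' @param preset_name One of the bundled preset names; see
#'   [list_physiology_presets()].
#' @param file Optional path to a user-supplied JSON preset file with the
#'   same layout as the bundled one.
#' @return A validated [species_physiology()] record with per-field
#'   provenance.
#' @examples
#' load_physiology("rat_MAK")
#' load_physiology("human_Gehr")
#' @export
load_physiology <- function(preset_name, file = NULL) {
  presets <- if (is.null(file)) load_presets() else
    jsonlite::read_json(file)$presets
  entry <- presets[[preset_name]]
  if (is.null(entry)) {
    stop("unknown physiology preset '", preset_name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  species_physiology(
    species_strain = entry$species_strain,
    body_weight = field_to_pv(entry$body_weight),
    ventilation_rate_per_kg = field_to_pv(entry$ventilation_rate_per_kg),
    alveolar_surface_area = field_to_pv(entry$alveolar_surface_area),
    dead_space_fraction = field_to_pv(entry$dead_space_fraction),
    macrophage_count_per_kg = field_to_pv(entry$macrophage_count_per_kg),
    macrophage_cell_volume = field_to_pv(entry$macrophage_cell_volume),
    macrophage_pool_volume_per_kg =
      field_to_pv(entry$macrophage_pool_volume_per_kg),
    clearance_half_time = field_to_pv(entry$clearance_half_time),
    lung_mass_per_kg = field_to_pv(entry$lung_mass_per_kg))
}

#' List bundled physiology presets
#'
#' @return Character vector of preset names.
#' @export
list_physiology_presets <- function() names(load_presets())
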