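# Sensitivity-grid execution and table rendering.  The bundled nine-row
# grid varies the deposition program version and settings (hence the
# alveolar fractions), the overload threshold (1 vs 4.2 ul/kg) and the
# human clearance half-time (400 vs 250 days), and carries the published
# reference cells so a run can be compared cell by cell.

# printed reference cells of the nine-scenario sensitivity grid
.sensitivity_reference <- data.frame(
  label = paste0("row", 1:9),
  mppd = c("MPPD 2.0 IA off OMB", "MPPD 2.0 IA on ONA", "MPPD 2.11 ONA",
           "MPPD 2.0 IA on ONA", "MPPD 2.11 ONA", "MPPD 2.0 IA on ONA",
           "MPPD 2.11 ONA", "MPPD 2.0 IA on ONA", "MPPD 2.11 ONA"),
  f_rat = c(0.075, 0.063, 0.033, 0.063, 0.033, 0.063, 0.033, 0.063, 0.033),
  f_human = c(0.164, 0.084, 0.088, 0.084, 0.088, 0.084, 0.088, 0.084, 0.088),
  threshold_ul_kg = c(1, 1, 1, 4.2, 4.2, 1, 1, 4.2, 4.2),
  t_half_human_d = c(400, 400, 400, 400, 400, 250, 250, 250, 250),
  noaec = c(0.53, 0.63, 1.21, 2.66, 5.07, 0.63, 1.21, 2.66, 5.07),
  af_lungburden = c(0.93, 1.52, 0.76, 1.52, 0.76, 1.52, 0.76, 1.52, 0.76),
  af_clearance = c(0.93, 0.93, 0.93, 0.93, 0.93, 0.58, 0.58, 0.58, 0.58),
  hec = c(0.53, 1.03, 0.98, 4.33, 4.14, 1.65, 1.58, 6.93, 6.62),
  stringsAsFactors = FALSE)

# printed reference for the toner density sweep (alveolar fraction vs density)
.density_sweep_reference <- data.frame(
  density_g_cm3 = c(1, 1.2, 2, 3, 4, 4.3, 5),
  alveolar_fraction_pct = c(4.0, 4.0, 4.1, 4.2, 4.2, 4.25, 4.2))

#' Half-up rounding
#'
#' Rounds halves away from zero (0.005 -> 0.01 at 2 digits), matching the
#' convention of the published tables; base R's banker's rounding would
#' silently flip cells such as 1.575 -> 1.57.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The bundled nine-scenario sensitivity grid
#'
#' @param human_template Physiology preset name for the human side (the
#'   grid overrides its clearance half-time row by row).
#' @return Named list of [model_b_scenario()] objects, one per grid row, in
#'   published order.
#' @export
sensitivity_scenarios <- function(human_template = "human_MAK_Brown") {
  rat <- load_physiology("rat_MAK")
  lapply(seq_len(nrow(.sensitivity_reference)), function(i) {
    row <- .sensitivity_reference[i, ]
    human <- load_physiology(human_template)
    human$clearance_half_time <- parameter_value(
      quantity(row$t_half_human_d, "day"),
      source = if (row$t_half_human_d >= 400) {
        "one-compartment human half-time assumption (400 days)"
      } else {
        "Gregoratto et al. (2010) alveolar-interstitial model (about 250 days)"
      })
    model_b_scenario(
      rat = rat, human = human,
      rat_alveolar_fraction = row$f_rat,
      human_alveolar_fraction = row$f_human,
      threshold_volume_per_kg = quantity(row$threshold_ul_kg, "ul/kg"),
      particle_density = quantity(1, "g/cm^3"),
      mppd_version_label = row$mppd,
      label = row$label)
  })
}

#' Run a list of scenarios as a sensitivity grid
#'
#' @param scenarios Non-empty list of [model_b_scenario()] (dispatched to
#'   [hec_volumetric()]) or [model_a_scenario()] (dispatched to
#'   [hec_mass_per_surface()]) objects.
#' @param reference Optional data.frame of printed reference cells with a
#'   `label` column and any of `noaec`, `af_lungburden`, `af_clearance`,
#'   `hec`; the bundled grid reference is used when `scenarios` is omitted.
#' @param digits Decimal places of the reference cells (comparison rounds
#'   computed values half-up to this precision before differencing).
#' @return Object of class `grid_result`: `rows` (data.frame of computed
#'   values at full precision), `results` (list of
#'   [translation_result()]s), `comparison` (per-cell computed-rounded,
#'   printed and delta; `NULL` without a reference), `errors` (per-row
#'   error messages; a failing row does not abort the others).
#' @export
run_grid <- function(scenarios = sensitivity_scenarios(),
                     reference = if (missing(scenarios))
                       .sensitivity_reference else NULL,
                     digits = 2) {
  if (!is.list(scenarios) || length(scenarios) == 0) {
    stop("scenarios must be a non-empty list", call. = FALSE)
  }
  n <- length(scenarios)
  rows <- vector("list", n)
  results <- vector("list", n)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- scenarios[[i]]
    lab <- if (!is.null(s$label) && nzchar(s$label)) s$label else
      paste0("row", i)
    res <- tryCatch({
      if (inherits(s, "model_b_scenario")) hec_volumetric(s)
      else if (inherits(s, "model_a_scenario")) hec_mass_per_surface(s)
      else stop("unsupported scenario class: ",
                paste(class(s), collapse = "/"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
      rows[[i]] <- data.frame(label = lab, noaec = NA_real_,
                              af_lungburden = NA_real_,
                              af_clearance = NA_real_, hec = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(
        label = lab,
        noaec = magnitude(res$noaec_rat, "mg/m^3"),
        af_lungburden = res$af_lungburden,
        af_clearance = res$af_clearance,
        hec = magnitude(res$hec, "mg/m^3"),
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  comparison <- NULL
  if (!is.null(reference)) {
    cols <- intersect(c("noaec", "af_lungburden", "af_clearance", "hec"),
                      names(reference))
    comp <- list()
    for (col in cols) {
      m <- match(rows$label, reference$label)
      printed <- reference[[col]][m]
      computed <- round_half_up(rows[[col]], digits)
      comp[[col]] <- data.frame(
        label = rows$label, cell = col, computed = computed,
        printed = printed, delta = abs(computed - printed),
        stringsAsFactors = FALSE)
    }
    comparison <- do.call(rbind, comp)
    comparison <- comparison[!is.na(comparison$printed), , drop = FALSE]
    rownames(comparison) <- NULL
  }
  structure(list(rows = rows, results = results, comparison = comparison,
                 errors = errors, digits = digits),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", nrow(x$rows), "scenarios\n")
  print(x$rows, digits = 4)
  if (!is.null(x$comparison)) {
    ndev <- sum(x$comparison$delta != 0)
    cat("comparison against printed reference:", nrow(x$comparison),
        "cells,", ndev, "deviating\n")
  }
  if (any(!is.na(x$errors))) {
    cat("errors:\n")
    for (i in which(!is.na(x$errors))) cat("  row", i, ":", x$errors[i], "\n")
  }
  invisible(x)
}

#' Render a grid result as text
#'
#' @param result A [run_grid()] result.
#' @param format `"csv"`, `"markdown"` or `"json"`.
#' @param digits Decimal places for markdown rendering (csv and json carry
#'   full precision so that render/parse round-trips are exact).
#' @return A character scalar (single document).
#' @export
render_grid <- function(result, format = c("csv", "markdown", "json"),
                        digits = 2) {
  format <- match.arg(format)
  rows <- result$rows
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(rows = rows, comparison = result$comparison),
      dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)))
  }
  # markdown
  fmt <- function(x) formatC(round_half_up(x, digits), format = "f",
                             digits = digits)
  header <- "| scenario | NOAEC/mg/m^3 | AF_lungburden | AF_clearance | HEC/mg/m^3 |"
  sep <- "|---|---|---|---|---|"
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste0("| ", rows$label[i], " | ", fmt(rows$noaec[i]), " | ",
           fmt(rows$af_lungburden[i]), " | ", fmt(rows$af_clearance[i]),
           " | ", fmt(rows$hec[i]), " |")
  }, character(1))
  paste(c(header, sep, body), collapse = "\n")
}

#' Regenerate a published reference table
#'
#' @param table `"deposition-density"` (alveolar fraction vs particle
#'   density sweep), `"volumetric-chain"` (first volumetric NOAEC
#'   derivation), `"sensitivity"` (the nine-scenario grid) or
#'   `"corrected-hec"` (revised mass-per-surface HECs).
#' @return A data.frame (`"sensitivity"` returns a [run_grid()]
#'   `grid_result`).
#' @export
reproduce_table <- function(table = c("sensitivity", "volumetric-chain",
                                      "deposition-density",
                                      "corrected-hec")) {
  table <- match.arg(table)
  if (table == "sensitivity") {
    return(run_grid())
  }
  if (table == "deposition-density") {
    tab <- deposition_table()
    sweep <- tab[tab$substance == "toner" & tab$species == "rat", ,
                 drop = FALSE]
    out <- data.frame(density_g_cm3 = sweep$density_g_cm3,
                      alveolar_fraction_pct = 100 * sweep$alveolar_fraction)
    out$printed_pct <- .density_sweep_reference$alveolar_fraction_pct[
      match(out$density_g_cm3, .density_sweep_reference$density_g_cm3)]
    return(out)
  }
  if (table == "volumetric-chain") {
    rat <- load_physiology("rat_MAK")
    ve <- pv_quantity(rat$ventilation_rate_per_kg)
    ds <- magnitude(pv_quantity(rat$dead_space_fraction), "1")
    crit <- quantity(0.069, "ul/kg/day")  # critical alveolar volume rate
    head_tb <- lookup_deposition("MPPD 2.0", "rat",
                                 inhalability_adjustment = "off")$head_tb_fraction
    alv_vent <- convert(ve * quantity(1 - ds), "m^3/kg/day")
    in_alv <- convert(crit / alv_vent, "ul/m^3")
    noaec <- first_derivation_chain(ve, ds, crit, head_tb)
    return(data.frame(
      step = c("ventilation volume per day and kg",
               "dead space fraction",
               "alveolar ventilation volume per day and kg",
               "critical particle alveolar volume per day and kg",
               "critical particle volume concentration, alveolar air",
               "head + tracheo-bronchial deposition fraction",
               "critical particle volume concentration, inhaled air (NOAEC)"),
      value = c(magnitude(ve, "m^3/kg/day"), ds,
                magnitude(alv_vent, "m^3/kg/day"),
                magnitude(crit, "ul/kg/day"), magnitude(in_alv, "ul/m^3"),
                head_tb, magnitude(noaec, "ul/m^3")),
      unit = c("m^3/kg/day", "1", "m^3/kg/day", "ul/kg/day", "ul/m^3", "1",
               "ul/m^3"),
      stringsAsFactors = FALSE))
  }
  # corrected-hec
  toner <- corrected_hec(0.134, 193, 349, 400, 255)
  tio2 <- corrected_hec(1.07, 193, 349, 400, 255)
  data.frame(
    substance = c("toner", "TiO2"),
    hec_reference = c(0.134, 1.07),
    surface_ratio_old = 193, surface_ratio_new = 349,
    half_time_old_d = 400, half_time_new_d = 255,
    hec_corrected = c(magnitude(toner, "mg/m^3"), magnitude(tio2, "mg/m^3")),
    stringsAsFactors = FALSE)
}
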