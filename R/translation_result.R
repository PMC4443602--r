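# Shared result container for the interspecies translations.  The ledger
# records every intermediate as a dimensioned quantity with provenance, so a
# result doubles as an audit trail; `dimension_audit_clean` is FALSE if any
# ledger step failed its dimension check (no raw unitless arithmetic leaks
# into a reported HEC).

new_ledger <- function() {
  data.frame(step = character(0), value = numeric(0), unit = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

ledger_add <- function(ledger, step, q, provenance = "") {
  stopifnot(is_quantity(q))
  rbind(ledger,
        data.frame(step = step, value = q$magnitude, unit = q$unit_label,
                   provenance = provenance, stringsAsFactors = FALSE))
}

#' Construct a translation result
#'
#' @param model `"A"` (mass per alveolar surface) or `"B"` (volume per
#'   macrophage pool).
#' @param noaec_rat Rat NOAEC ([quantity()], mg/m^3).
#' @param hec Human equivalent concentration ([quantity()], mg/m^3).
#' @param af_lungburden,af_clearance Dimensionless adjustment factors
#'   (`NA` for model A, which uses a single translation factor).
#' @param translation_factor Overall dimensionless NOAEC-to-HEC factor.
#' @param ledger Data.frame of (step, value, unit, provenance) rows.
#' @param dimension_audit_clean Logical: all ledger steps passed their
#'   dimension checks.
#' @return Object of class `translation_result`.  For model B the identity
#'   `hec = noaec_rat * af_lungburden / af_clearance` holds to 1e-10
#'   relative.
#' @export
translation_result <- function(model, noaec_rat, hec,
                               af_lungburden = NA_real_,
                               af_clearance = NA_real_,
                               translation_factor = NA_real_,
                               ledger = new_ledger(),
                               dimension_audit_clean = TRUE) {
  stopifnot(is_quantity(noaec_rat), is_quantity(hec))
  if (!is.na(af_lungburden) && !is.na(af_clearance)) {
    lhs <- magnitude(hec, "mg/m^3")
    rhs <- magnitude(noaec_rat, "mg/m^3") * af_lungburden / af_clearance
    if (abs(lhs - rhs) > 1e-10 * max(abs(rhs), 1e-300)) {
      stop("translation_result invariant violated: hec != ",
           "noaec * AF_lungburden / AF_clearance", call. = FALSE)
    }
  }
  structure(list(model = model, noaec_rat = noaec_rat, hec = hec,
                 af_lungburden = af_lungburden, af_clearance = af_clearance,
                 translation_factor = translation_factor, ledger = ledger,
                 dimension_audit_clean = dimension_audit_clean),
            class = "translation_result")
}

#' @export
print.translation_result <- function(x, digits = 4, ...) {
  cat("<translation_result> model ", x$model, "\n", sep = "")
  cat("  NOAEC (rat): ", format(x$noaec_rat, digits = digits), "\n", sep = "")
  if (!is.na(x$af_lungburden)) {
    cat(sprintf("  AF_lungburden: %.*g   AF_clearance: %.*g\n",
                digits, x$af_lungburden, digits, x$af_clearance))
  }
  if (!is.na(x$translation_factor)) {
    cat(sprintf("  translation factor: %.*g\n", digits,
                x$translation_factor))
  }
  cat("  HEC: ", format(x$hec, digits = digits), "\n", sep = "")
  cat("  dimension audit:",
      if (x$dimension_audit_clean) "clean" else "FLAGGED", "\n")
  cat("  ledger:", nrow(x$ledger), "steps\n")
  invisible(x)
}
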