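# Dimension-aware scalar arithmetic.
#
# Every downstream number (deposition rates, burdens, NOAECs, HECs) is carried
# as a `quantity`: a magnitude plus a signed exponent vector over the base
# dimensions mass, length, time.  Canonical internal base units are mg, m,
# day, which renders every quantity the models print (mg/m^3, ul, g/cm^3,
# m^2, days) without scale surprises.  "Breaths" and "cells" are treated as
# dimensionless counts: tidal volume x respiratory rate is always folded into
# a daily ventilation volume before it reaches this layer.

.dustdose_env <- new.env(parent = emptyenv())

.base_dims <- c("mass", "length", "time")

unit_registry <- function() {
  reg <- get0("unit_registry", envir = .dustdose_env)
  if (is.null(reg)) {
    path <- system.file("extdata", "units.json", package = "dustdose",
                        mustWork = TRUE)
    raw <- jsonlite::read_json(path)$units
    reg <- lapply(raw, function(u) {
      list(dim = c(mass = u$mass, length = u$length, time = u$time),
           scale = u$scale)
    })
    assign("unit_registry", reg, envir = .dustdose_env)
  }
  reg
}

zero_dim <- function() c(mass = 0, length = 0, time = 0)

# Parse a compound unit label such as "mg/m^3", "m^3/kg/day", "um^3" or "1".
# Grammar: "/"-separated factors, the first in the numerator and every later
# one in the denominator; "*" (or a space) multiplies within a factor; "^"
# attaches an integer power to an atomic unit.
parse_unit <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  label <- gsub("µ|μ", "u", label)   # accept micro signs
  label <- gsub("\\s+", "", label)
  if (label == "" || label == "1") {
    return(list(dim = zero_dim(), scale = 1))
  }
  reg <- unit_registry()
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  dim <- zero_dim()
  scale <- 1
  for (i in seq_along(parts)) {
    sgn <- if (i == 1L) 1 else -1
    atoms <- strsplit(parts[i], "*", fixed = TRUE)[[1]]
    for (atom in atoms) {
      if (atom == "") next
      pow <- 1
      if (grepl("^", atom, fixed = TRUE)) {
        bits <- strsplit(atom, "^", fixed = TRUE)[[1]]
        atom <- bits[1]
        pow <- as.numeric(bits[2])
      }
      u <- reg[[atom]]
      if (is.null(u)) {
        stop("unknown unit '", atom, "' in label '", label, "'; known units: ",
             paste(names(reg), collapse = ", "), call. = FALSE)
      }
      dim <- dim + sgn * pow * u$dim
      scale <- scale * u$scale^(sgn * pow)
    }
  }
  list(dim = dim, scale = scale)
}

#' Create a dimensioned quantity
#'
#' A `quantity` is a magnitude tied to a physical dimension (signed exponents
#' over mass, length, time) and a display unit.  All model arithmetic in the
#' package flows through this class so that unit errors surface as dimension
#' mismatches instead of silently wrong numbers.
#'
#' @param magnitude Numeric scalar, the value expressed in `unit`.
#' @param unit Unit label, e.g. `"mg/m^3"`, `"ul/kg"`, `"g/cm^3"`, `"day"`,
#'   `"um^3"`, or `"1"` for a dimensionless number.  Compound labels are
#'   `"/"`-separated (first factor numerator, later factors denominators)
#'   with `"^"` powers, e.g. `"m^3/kg/day"`.
#' @return An object of class `quantity`.
#' @examples
#' quantity(1.06, "mg/m^3")
#' quantity(4.3, "g/cm^3")
#' @export
quantity <- function(magnitude, unit = "1") {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, is.finite(magnitude))
  p <- parse_unit(unit)
  structure(
    list(magnitude = as.numeric(magnitude), dim = p$dim,
         unit_label = unit, scale = p$scale),
    class = "quantity")
}

is_quantity <- function(x) inherits(x, "quantity")

as_quantity <- function(x, unit = "1") {
  if (is_quantity(x)) x else quantity(x, unit)
}

# magnitude in canonical base units (mg, m, day)
base_magnitude <- function(q) q$magnitude * q$scale

same_dim <- function(a, b, tol = 1e-9) all(abs(a - b) < tol)

dim_label <- function(dim) {
  if (all(dim == 0)) return("dimensionless")
  num <- character(0); den <- character(0)
  base_units <- c(mass = "mg", length = "m", time = "day")
  for (d in .base_dims) {
    e <- dim[[d]]
    if (e > 0) num <- c(num, if (e == 1) base_units[[d]] else
      paste0(base_units[[d]], "^", e))
    if (e < 0) den <- c(den, if (e == -1) base_units[[d]] else
      paste0(base_units[[d]], "^", -e))
  }
  if (length(num) == 0) num <- "1"
  paste(c(paste(num, collapse = "*"),
          if (length(den)) paste(den, collapse = "/")),
        collapse = "/")
}

# Preferred display units by dimension, so combine() renders results in the
# units the dosimetry literature prints rather than raw mg-m-day powers.
.canonical_display <- list(
  "0,0,0"   = "1",
  "1,0,0"   = "mg",
  "0,1,0"   = "m",
  "0,2,0"   = "m^2",
  "0,3,0"   = "m^3",
  "0,0,1"   = "day",
  "0,0,-1"  = "1/day",
  "1,-3,0"  = "mg/m^3",
  "1,0,-1"  = "mg/day",
  "0,3,-1"  = "m^3/day",
  "-1,3,0"  = "ul/kg",
  "-1,3,-1" = "m^3/kg/day",
  "-1,0,0"  = "1/kg"
)

canonical_unit_for <- function(dim) {
  key <- paste(dim, collapse = ",")
  .canonical_display[[key]] %||% dim_label(dim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a quantity to another unit of the same dimension
#'
#' @param q A [quantity()].
#' @param target_unit Unit label with the same physical dimension as `q`.
#' @return A `quantity` expressed in `target_unit`; the underlying physical
#'   magnitude is unchanged (round-trip conversion is identity to machine
#'   precision).
#' @examples
#' convert(quantity(1, "um^3"), "ul")    # 1e-9 ul
#' convert(quantity(288, "l"), "m^3")    # 0.288 m^3
#' @export
convert <- function(q, target_unit) {
  stopifnot(is_quantity(q))
  p <- parse_unit(target_unit)
  if (!same_dim(q$dim, p$dim)) {
    stop("cannot convert '", q$unit_label, "' [", dim_label(q$dim),
         "] to '", target_unit, "' [", dim_label(p$dim),
         "]: dimensions differ", call. = FALSE)
  }
  structure(
    list(magnitude = base_magnitude(q) / p$scale, dim = p$dim,
         unit_label = target_unit, scale = p$scale),
    class = "quantity")
}

#' Multiply or divide two quantities
#'
#' Exponent vectors add (multiply) or subtract (divide); the magnitude is
#' computed in coherent base units and the result is rendered in a canonical
#' derived unit (e.g. `ul * g/cm^3` renders as `mg`).  Division of quantities
#' with unequal dimensions is legal and yields a derived (possibly
#' dimensionless) quantity -- this is deliberate, so that a dimensionally
#' invalid step such as dividing a concentration by a density can be carried
#' through to an audit report instead of aborting.
#'
#' @param a,b [quantity()] objects (bare numerics are promoted to
#'   dimensionless).
#' @param operator `"multiply"` or `"divide"`.
#' @return A `quantity`.
#' @examples
#' combine(quantity(1, "ul"), "multiply", quantity(1, "g/cm^3"))  # 1 mg
#' combine(quantity(1.06, "mg/m^3"), "divide", quantity(4.3, "g/cm^3"))
#' @export
combine <- function(a, operator = c("multiply", "divide"), b) {
  operator <- match.arg(operator)
  a <- as_quantity(a); b <- as_quantity(b)
  if (operator == "divide" && base_magnitude(b) == 0) {
    stop("division by a zero-magnitude quantity", call. = FALSE)
  }
  dim <- if (operator == "multiply") a$dim + b$dim else a$dim - b$dim
  mag <- if (operator == "multiply") {
    base_magnitude(a) * base_magnitude(b)
  } else {
    base_magnitude(a) / base_magnitude(b)
  }
  unit <- canonical_unit_for(dim)
  scale <- parse_unit(unit)$scale
  structure(
    list(magnitude = mag / scale, dim = dim, unit_label = unit, scale = scale),
    class = "quantity")
}

# Named dimension descriptors accepted by assert_dimension().
.dimension_descriptors <- list(
  dimensionless = c(mass = 0, length = 0, time = 0),
  mass          = c(mass = 1, length = 0, time = 0),
  length        = c(mass = 0, length = 1, time = 0),
  area          = c(mass = 0, length = 2, time = 0),
  volume        = c(mass = 0, length = 3, time = 0),
  time          = c(mass = 0, length = 0, time = 1),
  rate          = c(mass = 0, length = 0, time = -1),
  concentration = c(mass = 1, length = -3, time = 0),
  density       = c(mass = 1, length = -3, time = 0),
  volume_per_mass = c(mass = -1, length = 3, time = 0)
)

#' Check that a quantity has an expected dimension
#'
#' Always returns a report (never throws): the Model A audit needs to carry a
#' failed check, e.g. that a density-divided "HEC" is dimensionless and hence
#' not a concentration, into its output.
#'
#' @param q A [quantity()].
#' @param expected A named dimension descriptor (`"concentration"`,
#'   `"volume"`, `"time"`, `"dimensionless"`, ...) or any unit label whose
#'   dimension is the expected one.
#' @return A list of class `dimension_check` with elements `pass`,
#'   `expected`, `actual` and `message`.
#' @examples
#' assert_dimension(quantity(0.53, "mg/m^3"), "concentration")  # pass
#' assert_dimension(quantity(2.5e-10, "1"), "concentration")    # fail
#' @export
assert_dimension <- function(q, expected) {
  stopifnot(is_quantity(q))
  exp_dim <- if (expected %in% names(.dimension_descriptors)) {
    .dimension_descriptors[[expected]]
  } else {
    parse_unit(expected)$dim
  }
  pass <- same_dim(q$dim, exp_dim)
  msg <- if (pass) {
    paste0("dimension check passed: ", dim_label(q$dim))
  } else {
    paste0("dimension check FAILED: ", dim_label(q$dim), " != ",
           dim_label(exp_dim), " (expected '", expected, "')")
  }
  structure(list(pass = pass, expected = exp_dim, actual = q$dim,
                 message = msg),
            class = "dimension_check")
}

#' @export
print.dimension_check <- function(x, ...) {
  cat(x$message, "\n")
  invisible(x)
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x$magnitude, digits = 7), x$unit_label, "\n")
  invisible(x)
}

#' @export
format.quantity <- function(x, digits = 7, ...) {
  paste(format(x$magnitude, digits = digits), x$unit_label)
}

#' Arithmetic operators for quantities
#'
#' `*` and `/` delegate to [combine()]; `+` and `-` require identical
#' dimensions; comparisons compare physical magnitudes after dimension check.
#'
#' @param e1,e2 Quantities or bare numerics.
#' @return A `quantity` or logical.
#' @export
Ops.quantity <- function(e1, e2) {
  if (.Generic %in% c("*", "/")) {
    return(combine(e1, if (.Generic == "*") "multiply" else "divide", e2))
  }
  e1 <- as_quantity(e1); e2 <- as_quantity(e2)
  if (!same_dim(e1$dim, e2$dim)) {
    stop("'", .Generic, "' requires identical dimensions: ",
         dim_label(e1$dim), " vs ", dim_label(e2$dim), call. = FALSE)
  }
  if (.Generic %in% c("+", "-")) {
    mag <- get(.Generic)(base_magnitude(e1), base_magnitude(e2))
    return(convert(structure(list(magnitude = mag, dim = e1$dim,
                                  unit_label = canonical_unit_for(e1$dim),
                                  scale = parse_unit(canonical_unit_for(e1$dim))$scale),
                             class = "quantity"),
                   e1$unit_label))
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    return(get(.Generic)(base_magnitude(e1), base_magnitude(e2)))
  }
  stop("operator '", .Generic, "' not defined for quantities", call. = FALSE)
}

#' Raise a quantity to an integer or rational power
#'
#' @param q A [quantity()].
#' @param power Numeric exponent.
#' @return A `quantity` with all dimension exponents multiplied by `power`.
#' @export
q_pow <- function(q, power) {
  stopifnot(is_quantity(q), is.numeric(power), length(power) == 1L)
  dim <- q$dim * power
  unit <- canonical_unit_for(dim)
  scale <- parse_unit(unit)$scale
  structure(list(magnitude = base_magnitude(q)^power / scale, dim = dim,
                 unit_label = unit, scale = scale),
            class = "quantity")
}

#' Extract the magnitude of a quantity in a given unit
#'
#' @param q A [quantity()].
#' @param unit Unit label; defaults to the quantity's display unit.
#' @return Bare numeric.
#' @export
magnitude <- function(q, unit = NULL) {
  stopifnot(is_quantity(q))
  if (is.null(unit)) return(q$magnitude)
  convert(q, unit)$magnitude
}
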