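#' @keywords internal
"_PACKAGE"

# Conversion constants. 1 mmHg = 133.322 Pa exactly for this package;
# 1 ml = 1e-6 m^3. All internal computation is SI (Pa, m^3/s, Pa.s/m^3);
# user-facing quantities stay in the clinical units (mmHg, ml/s, mmHg.s/ml).
MMHG_PA <- 133.322
ML_M3 <- 1e-6
RES_SI <- MMHG_PA / ML_M3 # 1 mmHg.s/ml in Pa.s/m^3

.unit_table <- function() {
  data.frame(
    unit = c("mmHg", "Pa", "ml/s", "m^3/s", "mmHg.s/ml", "Pa.s/m^3",
             "m^2", "mm^2", "mm", "m"),
    dim = c("pressure", "pressure", "flow", "flow", "resistance",
            "resistance", "area", "area", "length", "length"),
    to_si = c(MMHG_PA, 1, ML_M3, 1, RES_SI, 1, 1, 1e-6, 1e-3, 1),
    stringsAsFactors = FALSE
  )
}

.normalize_unit <- function(u) {
  u <- gsub("·", ".", u)    # middle dot
  u <- gsub("\\s+", ".", trimws(u))
  u <- sub("mmHg\\.?s/ml", "mmHg.s/ml", u)
  u <- sub("Pa\\.?s/m\\^?3", "Pa.s/m^3", u)
  u <- sub("^m3/s$", "m^3/s", u)
  u <- sub("^m2$", "m^2", u)
  u
}

#' Convert a scalar between the supported physical units
#'
#' Exact linear conversion between the units used throughout the package:
#' pressures (`mmHg`, `Pa`), flow rates (`ml/s`, `m^3/s`), hydraulic
#' resistances (`mmHg.s/ml`, `Pa.s/m^3`), areas (`m^2`, `mm^2`) and lengths
#' (`mm`, `m`). Uses 1 mmHg = 133.322 Pa and 1 ml = 1e-6 m^3, so all
#' conversions round-trip to machine precision.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names; a middle dot or space may be used in place of
#'   `.` in the resistance units.
#' @return the converted numeric vector.
#' @examples
#' unit_convert(1, "mmHg", "Pa")           # 133.322
#' unit_convert(0.330, "mmHg.s/ml", "Pa.s/m^3")
#' @export
unit_convert <- function(value, from, to) {
  tab <- .unit_table()
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  i <- match(from, tab$unit)
  j <- match(to, tab$unit)
  if (is.na(i) || is.na(j)) {
    stop("unsupported unit(s): ", if (is.na(i)) from else to, call. = FALSE)
  }
  if (tab$dim[i] != tab$dim[j]) {
    stop("cannot convert ", from, " (", tab$dim[i], ") to ", to,
         " (", tab$dim[j], ")", call. = FALSE)
  }
  value * tab$to_si[i] / tab$to_si[j]
}

#' Blood (or working-fluid) physical properties
#'
#' @param density fluid density in kg/m^3; default 1060 (whole blood).
#' @param viscosity dynamic viscosity in Pa.s; default 4e-3 (blood treated
#'   as Newtonian at the shear rates of a high-flow shunt).
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, viscosity = 4e-3) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("viscosity must be a single positive number", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: density %g kg/m^3, dynamic viscosity %g Pa.s\n",
              x$density, x$viscosity))
  invisible(x)
}
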