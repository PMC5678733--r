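#' Discretized cortical/retinal sheet geometry
#'
#' A square sheet of nodes in abstract sheet coordinates together with the
#' conversion to cortical millimetres. The default conversion maps the unit
#' cortical sheet onto a 3 x 3 mm patch of tissue, so that anatomical radii
#' stated in mm (e.g. astrocyte arbor radii) are directly usable.
#'
#' @param extent Side length of the square sheet, in sheet units.
#' @param density Nodes per sheet unit per axis (>= 8).
#' @param mm_per_unit Millimetres of tissue per sheet unit.
#' @param origin Sheet coordinate of the lower-left corner (the sheet spans
#'   `[origin, origin + extent]` on both axes).
#' @return An object of class `sheet_geometry` with fields `extent`,
#'   `density`, `n` (nodes per axis, `round(extent * density)`),
#'   `mm_per_unit` and `origin`.
#' @examples
#' g <- sheet_geometry(extent = 1, density = 48)
#' g$n                      # 48 nodes per axis
#' units_to_mm(g, 0.22)     # inhibitory radius in mm
#' @export
sheet_geometry <- function(extent = 1, density = 48, mm_per_unit = 3,
                           origin = 0) {
  if (!is.numeric(extent) || extent <= 0) stop("extent must be > 0")
  if (!is.numeric(density) || density < 8) stop("density must be >= 8")
  if (!is.numeric(mm_per_unit) || mm_per_unit <= 0)
    stop("mm_per_unit must be > 0")
  n <- as.integer(round(extent * density))
  structure(list(extent = extent, density = density, n = n,
                 mm_per_unit = mm_per_unit, origin = origin),
            class = "sheet_geometry")
}

#' @export
print.sheet_geometry <- function(x, ...) {
  cat(sprintf("<sheet_geometry> %d x %d nodes, extent %.4g sheet units (%.3g mm), density %g\n",
              x$n, x$n, x$extent, x$extent * x$mm_per_unit, x$density))
  invisible(x)
}

#' Sheet-unit / millimetre conversions
#'
#' @param geometry A [sheet_geometry()].
#' @param x Length(s) to convert.
#' @return Converted length(s).
#' @export
units_to_mm <- function(geometry, x) x * geometry$mm_per_unit

#' @rdname units_to_mm
#' @export
mm_to_units <- function(geometry, x) x / geometry$mm_per_unit

# node-centre coordinates along one axis
sheet_coords <- function(geometry) {
  geometry$origin + (seq_len(geometry$n) - 0.5) / geometry$density
}

# pixels per sheet unit helpers
units_to_px <- function(geometry, x) x * geometry$density
mm_to_px <- function(geometry, x) units_to_px(geometry, mm_to_units(geometry, x))
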