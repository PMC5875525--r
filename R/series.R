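#' Phantom image series
#'
#' In-memory container for one axial HU volume with its physical geometry:
#' the common currency between the synthetic renderer, the DICOM layer and
#' the analyzer.
#'
#' @param hu 3-D numeric array of Hounsfield units, dimensions
#'   rows x cols x slices.
#' @param pixel_spacing in-plane pixel spacing in mm (isotropic).
#' @param slice_thickness slice thickness in mm.
#' @param z numeric vector of slice centre positions in mm, strictly
#'   ascending, one per slice.
#' @param modality "CT" or "CBCT".
#' @param protocol protocol name (free text).
#' @param machine machine identifier.
#' @param date acquisition date, "YYYYMMDD".
#' @return an object of class \code{phantom_series}.
#' @export
phantom_series <- function(hu, pixel_spacing, slice_thickness, z,
                           modality = "CT", protocol = "unknown",
                           machine = "unknown", date = "20000101") {
  if (length(dim(hu)) != 3L)
    stop("hu must be a rows x cols x slices array")
  if (length(z) != dim(hu)[3])
    stop("z must have one position per slice")
  if (any(diff(z) <= 0)) stop("slice z-positions must be strictly ascending")
  if (pixel_spacing <= 0) stop("pixel spacing must be positive")
  if (slice_thickness <= 0) stop("slice thickness must be positive")
  if (!all(is.finite(hu))) stop("HU values must be finite")
  structure(list(hu = hu, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, z = as.numeric(z),
                 modality = modality, protocol = protocol,
                 machine = machine, date = date),
            class = "phantom_series")
}

#' @export
print.phantom_series <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("phantom_series: %d x %d x %d voxels (%s, %s)\n",
              d[1], d[2], d[3], x$modality, x$protocol))
  cat(sprintf("  spacing %.3f mm, thickness %g mm, z %.1f..%.1f mm\n",
              x$pixel_spacing, x$slice_thickness, min(x$z), max(x$z)))
  cat(sprintf("  machine %s, date %s, HU range [%.0f, %.0f]\n",
              x$machine, x$date, min(x$hu), max(x$hu)))
  invisible(x)
}

#' @export
dim.phantom_series <- function(x) dim(x$hu)
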