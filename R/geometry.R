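#' Default ACR-464 phantom geometry
#'
#' Builds the nominal description of the ACR CT accreditation phantom
#' (model 464): a 20 cm diameter cylinder of four 4 cm modules. Module 1
#' holds the five density plugs (air, polyethylene, water, acrylic, bone)
#' and the two wire ramps for slice-thickness measurement; module 2 the
#' low-contrast cylinder and the four 6 mm rods; module 3 the uniform
#' section with the two in-plane distance BBs at a nominal 100.0 mm
#' separation; module 4 the high-contrast bar patterns. Four alignment BBs
#' sit at the phantom periphery on the module-1 and module-4 centre planes.
#'
#' In-plane coordinates are mm relative to the phantom axis with y pointing
#' towards 12 o'clock; z is mm along the axis with the module-1 centre
#' plane at z = 0, so module centre planes lie at 0, 40, 80 and 120 mm.
#'
#' Exact in-plane plug/rod/BB coordinates are not part of the published
#' phantom specification at this level of detail; they are configuration
#' with defaults placing the plugs at 12/3/6/9 o'clock plus the centre.
#' The analyzer and the synthetic renderer share this single description,
#' which is all the measurements require. Accepted per-plug HU ranges
#' default to values per ACR CT Accreditation Program documentation and
#' are plain configuration.
#'
#' @param phantom_diameter phantom diameter in mm.
#' @param module_length axial length of each module in mm.
#' @param distance_nominal nominal distance-BB separation in mm.
#' @param roi_area named numeric: ROI areas in mm^2 for the HU-accuracy,
#'   low-contrast and uniformity ROIs.
#' @param uniformity_edge_margin distance in mm from the phantom edge to
#'   the outer boundary of each edge uniformity ROI.
#' @param plugs data.frame describing the module-1 density plugs
#'   (name, x, y, diameter, nominal_hu, hu_min, hu_max).
#' @param ramp_pitch z-increment per ramp wire in mm.
#' @param bar_lpcm integer vector of bar-pattern frequencies in lp/cm.
#' @return an object of class \code{acr_geometry}.
#' @export
acr_geometry <- function(phantom_diameter = 200,
                         module_length = 40,
                         distance_nominal = 100.0,
                         roi_area = c(hu = 200, low_contrast = 100,
                                      uniformity = 400),
                         uniformity_edge_margin = 10,
                         plugs = NULL,
                         ramp_pitch = 0.5,
                         bar_lpcm = c(4, 5, 6, 7, 8, 9, 10, 12)) {
  if (is.null(plugs)) {
    plugs <- data.frame(
      name = c("air", "bone", "acrylic", "polyethylene", "water"),
      x = c(0, 60, 0, -60, 0),
      y = c(60, 0, -60, 0, 0),
      diameter = 25,
      nominal_hu = c(-1000, 955, 120, -95, 0),
      hu_min = c(-1005, 850, 110, -107, -7),
      hu_max = c(-970, 970, 135, -84, 7),
      stringsAsFactors = FALSE
    )
  }
  geom <- list(
    phantom_diameter = phantom_diameter,
    module_length = module_length,
    n_modules = 4L,
    module_z = module_length * (0:3),
    distance_nominal = distance_nominal,
    roi_area = roi_area,
    uniformity_edge_margin = uniformity_edge_margin,
    plugs = plugs,
    ramps = list(x = c(-30, 30), wire_spacing = 2, n_wires = 15,
                 pitch = ramp_pitch, wire_diameter = 1.2),
    alignment_bbs = list(radius = 90, angles = c(0, 90, 180, 270),
                         diameter = 3, modules = c(1L, 4L)),
    distance_bbs = list(separation = distance_nominal, angle = 0,
                        diameter = 3),
    low_contrast = list(cyl_center = c(0, 45), cyl_diameter = 25,
                        background_center = c(0, 20),
                        rod_diameter = 6, rod_radius = 50,
                        rod_angles = c(225, 255, 285, 315),
                        rod_bg_offset_deg = 12),
    bar_patterns = list(lpcm = bar_lpcm, size = 14, radius = 55,
                        angles = seq(0, by = 45,
                                     length.out = length(bar_lpcm)))
  )
  class(geom) <- "acr_geometry"
  validate_geometry(geom)
  geom
}

#' @export
print.acr_geometry <- function(x, ...) {
  cat("ACR-464 phantom geometry\n")
  cat(sprintf("  diameter %g mm, %d modules of %g mm\n",
              x$phantom_diameter, x$n_modules, x$module_length))
  cat(sprintf("  plugs: %s\n", paste(x$plugs$name, collapse = ", ")))
  cat(sprintf("  distance BBs %g mm apart; bar patterns %s lp/cm\n",
              x$distance_nominal,
              paste(x$bar_patterns$lpcm, collapse = "/")))
  invisible(x)
}

validate_geometry <- function(geom) {
  stopifnot(geom$phantom_diameter > 0, geom$module_length > 0,
            geom$n_modules == 4L, all(geom$roi_area > 0))
  if (!isTRUE(all.equal(geom$module_z,
                        geom$module_length * (0:3))))
    stop("module centre planes must be at 0, 1, 2, 3 module lengths")
  if (geom$distance_bbs$separation != geom$distance_nominal)
    stop("distance BB separation must equal the nominal value")
  p <- geom$plugs
  if (anyDuplicated(p$name)) stop("plug names must be unique")
  if (any(p$diameter <= 0)) stop("plug diameters must be positive")
  if (any(p$nominal_hu < p$hu_min | p$nominal_hu > p$hu_max))
    stop("each accepted HU range must contain its nominal HU")
  invisible(TRUE)
}

#' Circular ROI radius for a target area
#'
#' @param area ROI area in mm^2.
#' @return radius in mm, \code{sqrt(area / pi)}.
#' @export
roi_radius <- function(area) sqrt(area / pi)

#' ROI template for one phantom module
#'
#' Returns the circular ROIs used to analyze one module, in mm relative to
#' the phantom axis: module 1 one HU-accuracy ROI (~200 mm^2) per plug;
#' module 2 the low-contrast cylinder ROI (~100 mm^2), its adjacent
#' background, and per-rod ROIs with flanking local-background ROIs;
#' module 3 one centre plus four edge uniformity ROIs (~400 mm^2) at
#' 12/3/6/9 o'clock; module 4 one ROI inside each bar-pattern region.
#'
#' @param geometry an \code{acr_geometry}.
#' @param module module number, 1 to 4.
#' @return object of class \code{roi_template}: a data.frame with columns
#'   label, x, y, radius and attributes \code{module} and \code{rule} (the
#'   slice-selection rule the template is intended for).
#' @export
roi_template <- function(geometry, module) {
  if (!module %in% 1:4)
    stop("unknown module id: ", module, " (must be 1, 2, 3 or 4)")
  g <- geometry
  r_hu <- roi_radius(g$roi_area[["hu"]])
  r_lc <- roi_radius(g$roi_area[["low_contrast"]])
  r_un <- roi_radius(g$roi_area[["uniformity"]])
  if (module == 1) {
    tpl <- data.frame(label = paste0("hu_", g$plugs$name),
                      x = g$plugs$x, y = g$plugs$y, radius = r_hu,
                      stringsAsFactors = FALSE)
    rule <- "alignment_bbs"
  } else if (module == 2) {
    lc <- g$low_contrast
    ang <- lc$rod_angles * pi / 180
    rods <- data.frame(label = paste0("rod_", seq_along(ang)),
                       x = lc$rod_radius * cos(ang),
                       y = lc$rod_radius * sin(ang),
                       radius = 0.8 * lc$rod_diameter / 2,
                       stringsAsFactors = FALSE)
    off <- lc$rod_bg_offset_deg * pi / 180
    rbg <- do.call(rbind, lapply(seq_along(ang), function(i) {
      a <- ang[i] + c(-off, off)
      data.frame(label = paste0("rod_", i, "_bg", 1:2),
                 x = lc$rod_radius * cos(a), y = lc$rod_radius * sin(a),
                 radius = 0.8 * lc$rod_diameter / 2,
                 stringsAsFactors = FALSE)
    }))
    tpl <- rbind(
      data.frame(label = "low_contrast", x = lc$cyl_center[1],
                 y = lc$cyl_center[2], radius = r_lc,
                 stringsAsFactors = FALSE),
      data.frame(label = "low_contrast_bg", x = lc$background_center[1],
                 y = lc$background_center[2], radius = r_lc,
                 stringsAsFactors = FALSE),
      rods, rbg)
    rule <- "module_midplane"
  } else if (module == 3) {
    re <- g$phantom_diameter / 2 - g$uniformity_edge_margin - r_un
    tpl <- data.frame(
      label = c("center", "edge_12", "edge_3", "edge_6", "edge_9"),
      x = c(0, 0, re, 0, -re),
      y = c(0, re, 0, -re, 0),
      radius = r_un, stringsAsFactors = FALSE)
    rule <- "distance_bbs"
  } else {
    bp <- g$bar_patterns
    ang <- bp$angles * pi / 180
    # ROI kept well inside each pattern square so blur bleeding across
    # the pattern boundary does not masquerade as modulation
    tpl <- data.frame(label = sprintf("bar_%g_lpcm", bp$lpcm),
                      x = bp$radius * cos(ang), y = bp$radius * sin(ang),
                      radius = 0.3 * bp$size, stringsAsFactors = FALSE)
    rule <- "alignment_bbs"
  }
  R <- g$phantom_diameter / 2
  out <- sqrt(tpl$x^2 + tpl$y^2) + tpl$radius > R
  if (any(out))
    stop("ROI outside phantom cross-section: ",
         paste(tpl$label[out], collapse = ", "))
  structure(tpl, module = module, rule = rule,
            class = c("roi_template", "data.frame"))
}

#' Pixel coordinate grids for a slice
#'
#' Physical in-plane coordinates (mm) of every pixel centre of an
#' \code{nrow x ncol} slice with the image centre at (0, 0); x runs along
#' columns, y along rows pointing up (towards 12 o'clock).
#'
#' @param nrow,ncol matrix dimensions.
#' @param spacing pixel spacing in mm (isotropic in-plane).
#' @return list with matrices \code{x} and \code{y}.
#' @export
pixel_grid <- function(nrow, ncol, spacing) {
  cx <- (ncol + 1) / 2
  cy <- (nrow + 1) / 2
  x <- matrix(rep((seq_len(ncol) - cx) * spacing, each = nrow),
              nrow, ncol)
  y <- matrix(rep((cy - seq_len(nrow)) * spacing, times = ncol),
              nrow, ncol)
  list(x = x, y = y)
}

#' Pixels inside a circular ROI
#'
#' A pixel belongs to the ROI when its centre lies inside the circle.
#'
#' @param grid a \code{\link{pixel_grid}}.
#' @param x,y,radius circle centre and radius in mm.
#' @return logical matrix.
#' @export
roi_mask <- function(grid, x, y, radius) {
  (grid$x - x)^2 + (grid$y - y)^2 <= radius^2
}

#' Read / write a phantom geometry as YAML or JSON
#'
#' Configuration round trip for \code{\link{acr_geometry}}: every numeric
#' nominal is overridable by editing the file.
#'
#' @param geometry an \code{acr_geometry}.
#' @param path file path; format chosen from the extension
#'   (.yaml/.yml or .json).
#' @return \code{read_geometry} returns an \code{acr_geometry}.
#' @export
write_geometry <- function(geometry, path) {
  lst <- unclass(geometry)
  lst$plugs <- as.list(geometry$plugs)
  lst$roi_area <- as.list(geometry$roi_area)  # keep names in YAML maps
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @param path file path to read.
#' @export
read_geometry <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lst$plugs <- as.data.frame(lst$plugs, stringsAsFactors = FALSE)
  lst$module_z <- as.numeric(lst$module_z)
  lst$n_modules <- as.integer(lst$n_modules)
  ra <- unlist(lst$roi_area)
  lst$roi_area <- stats::setNames(as.numeric(ra), names(ra))
  lst$alignment_bbs$modules <- as.integer(lst$alignment_bbs$modules)
  geom <- structure(lst, class = "acr_geometry")
  validate_geometry(geom)
  geom
}
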