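#' Simulation configuration for the synthetic phantom renderer
#'
#' Ground-truth parameters for \code{\link{render_phantom}}. The renderer
#' and the analyzer share one \code{\link{acr_geometry}}, so every
#' injected quantity (plug HU, BB separation, slice thickness, artifact
#' amplitudes) has a known truth against which the pipeline can be scored.
#'
#' The image model is deliberately simple: an ideal HU map, a Gaussian
#' point-spread function (resolution), additive artifact fields (parabolic
#' cupping, optional crescent arc), then i.i.d. Gaussian noise in HU,
#' seeded. The cupping amplitude is defined as the HU depression at the
#' phantom axis relative to the uniformity edge-ROI radius (the parabola
#' crosses zero there), so the measured uniformity value tracks the
#' injected amplitude directly.
#'
#' @param geometry an \code{\link{acr_geometry}}.
#' @param matrix_size reconstruction matrix (pixels per side, >= 128).
#' @param fov field of view in mm (sets pixel spacing = fov/matrix_size).
#' @param slice_thickness slice thickness in mm (also the slice interval).
#' @param noise_sigma Gaussian noise standard deviation in HU.
#' @param psf_fwhm Gaussian PSF full width at half maximum in mm.
#' @param cupping cupping amplitude in HU (0 = off).
#' @param crescent list(amplitude, radius, width, angle_deg, span_deg) or
#'   NULL for off; a localized annular-arc HU offset.
#' @param plug_hu named numeric overriding geometry nominal plug HU.
#' @param water_hu background (water) HU of the phantom body.
#' @param bb_hu,wire_hu HU of the metal BBs and ramp wires.
#' @param rod_contrast low-contrast rod and cylinder contrast above water,
#'   in HU (the phantom's nominal 0.6\% contrast is ~6 HU).
#' @param bar_amplitude bar-pattern HU amplitude above water.
#' @param offset in-plane phantom offset (x, y) in mm.
#' @param z_offset z position of the module-1 centre plane in mm.
#' @param roll in-plane phantom roll in degrees (counter-clockwise).
#' @param z_range optional c(zmin, zmax) in mm limiting rendered coverage
#'   (default: the full four-module phantom).
#' @param seed integer random seed; fixes the volume bit-exactly.
#' @param modality,protocol,machine,date session metadata labels.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(geometry = acr_geometry(),
                       matrix_size = 384, fov = 250,
                       slice_thickness = 2.5,
                       noise_sigma = 4, psf_fwhm = 0.7,
                       cupping = 0, crescent = NULL,
                       plug_hu = NULL, water_hu = 0,
                       bb_hu = 3000, wire_hu = 2000,
                       rod_contrast = 6, bar_amplitude = 400,
                       offset = c(0, 0), z_offset = 0, roll = 0,
                       z_range = NULL, seed = 1L,
                       modality = "CT", protocol = "ct-sim",
                       machine = "sim1", date = "20200101") {
  stopifnot(matrix_size >= 128, noise_sigma >= 0, psf_fwhm >= 0)
  hu <- stats::setNames(geometry$plugs$nominal_hu, geometry$plugs$name)
  if (!is.null(plug_hu)) hu[names(plug_hu)] <- plug_hu
  if (geometry$phantom_diameter + 2 * max(abs(offset)) >= fov)
    stop("phantom does not fit in the field of view")
  cfg <- list(geometry = geometry, matrix_size = as.integer(matrix_size),
              fov = fov, pixel_spacing = fov / matrix_size,
              slice_thickness = slice_thickness,
              noise_sigma = noise_sigma, psf_fwhm = psf_fwhm,
              cupping = cupping, crescent = crescent, plug_hu = hu,
              water_hu = water_hu, air_hu = -1000, bb_hu = bb_hu,
              wire_hu = wire_hu, rod_contrast = rod_contrast,
              bar_amplitude = bar_amplitude, offset = offset,
              z_offset = z_offset, roll = roll, z_range = z_range,
              seed = as.integer(seed), modality = modality,
              protocol = protocol, machine = machine, date = date)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulation configurations
#'
#' "ct-sim" emulates a fan-beam CT simulator (low noise, sharp PSF, no
#' cupping); "cbct-head" a linac CBCT head mode (high noise from scatter,
#' wider PSF, cupping), the regime in which the low-contrast rods become
#' indistinguishable from background.
#'
#' @param name "ct-sim" or "cbct-head".
#' @param ... overrides passed on to \code{\link{sim_config}}.
#' @return a \code{\link{sim_config}}.
#' @export
sim_preset <- function(name = c("ct-sim", "cbct-head"), ...) {
  name <- match.arg(name)
  if (name == "ct-sim") {
    sim_config(noise_sigma = 4, psf_fwhm = 0.7, cupping = 0,
               modality = "CT", protocol = "ct-sim", ...)
  } else {
    sim_config(noise_sigma = 30, psf_fwhm = 1.2, cupping = 20,
               modality = "CBCT", protocol = "standard dose head",
               machine = "linac1", ...)
  }
}

# area-weighted (4x4 supersampled) disc: needed for sub-pixel features
# (BBs, ramp wires) whose rendered mass must not depend on where the
# centre falls within a pixel
add_disc_aa <- function(img, grid, x0, y0, r, delta, spacing) {
  sel <- which(abs(grid$x - x0) <= r + spacing &
               abs(grid$y - y0) <= r + spacing)
  if (!length(sel)) return(img)
  sub <- (seq_len(4) - 2.5) / 4 * spacing
  cov <- numeric(length(sel))
  for (dx in sub) for (dy in sub)
    cov <- cov + ((grid$x[sel] + dx - x0)^2 +
                  (grid$y[sel] + dy - y0)^2 <= r^2)
  img[sel] <- img[sel] + delta * cov / 16
  img
}

#' Render a synthetic phantom series
#'
#' Renders an axial HU volume of the full four-module phantom described by
#' the configuration's geometry: module-1 density plugs and wire ramps
#' (wires on a \code{pitch} z-grid, each present in a slice when its z
#' falls inside the slice's half-open thickness window), module-2
#' low-contrast cylinder and rods, module-3 uniform section with the two
#' distance BBs, module-4 bar patterns, and the four peripheral alignment
#' BBs on the module-1 and module-4 centre planes. Pipeline order: ideal
#' map, Gaussian PSF blur, artifact fields, seeded Gaussian noise.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{phantom_series}}.
#' @export
render_phantom <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  ml <- g$module_length
  R <- g$phantom_diameter / 2
  th <- config$slice_thickness
  zr <- config$z_range
  if (is.null(zr)) zr <- config$z_offset + c(-ml / 2, 3.5 * ml)
  z <- seq(zr[1] + th / 2, zr[2], by = th)
  n <- config$matrix_size
  sp <- config$pixel_spacing
  grid <- pixel_grid(n, n, sp)
  # phantom-frame coordinates (undo offset then roll)
  a <- -config$roll * pi / 180
  xs <- grid$x - config$offset[1]
  ys <- grid$y - config$offset[2]
  xp <- cos(a) * xs - sin(a) * ys
  yp <- sin(a) * xs + cos(a) * ys
  inside <- xp^2 + yp^2 <= R^2
  rr2 <- xp^2 + yp^2
  r_un <- roi_radius(g$roi_area[["uniformity"]])
  r_ref <- R - g$uniformity_edge_margin - r_un
  sigma_px <- config$psf_fwhm / (2 * sqrt(2 * log(2))) / sp
  wire_k <- seq_len(g$ramps$n_wires) - (g$ramps$n_wires + 1) / 2
  wire_z <- config$z_offset + g$ramps$pitch / 2 + wire_k * g$ramps$pitch
  wire_y <- wire_k * g$ramps$wire_spacing
  bb_ang <- g$alignment_bbs$angles * pi / 180
  hu <- array(config$air_hu, dim = c(n, n, length(z)))
  set.seed(config$seed)
  for (i in seq_along(z)) {
    img <- matrix(config$air_hu, n, n)
    zp <- z[i] - config$z_offset          # 0 = module-1 centre plane
    mod_id <- findInterval(zp, ml * (0:3) - ml / 2)
    if (zp < -ml / 2 || zp >= 3.5 * ml) mod_id <- 0L
    if (mod_id > 0) img[inside] <- config$water_hu
    win <- z[i] + c(-th / 2, th / 2)      # half-open [lo, hi)
    if (mod_id == 1) {
      for (j in seq_len(nrow(g$plugs)))
        img[(xp - g$plugs$x[j])^2 + (yp - g$plugs$y[j])^2 <=
              (g$plugs$diameter[j] / 2)^2] <- config$plug_hu[g$plugs$name[j]]
      vis <- wire_z >= win[1] & wire_z < win[2]
      for (k in which(vis)) for (rx in g$ramps$x) {
        ctr <- phantom_to_image(rx, wire_y[k], config)
        img <- add_disc_aa(img, grid, ctr[1], ctr[2],
                           g$ramps$wire_diameter / 2,
                           config$wire_hu - config$water_hu, sp)
      }
    } else if (mod_id == 2) {
      lc <- g$low_contrast
      img[(xp - lc$cyl_center[1])^2 + (yp - lc$cyl_center[2])^2 <=
            (lc$cyl_diameter / 2)^2] <-
        config$water_hu + config$rod_contrast
      for (ang in lc$rod_angles * pi / 180) {
        rx <- lc$rod_radius * cos(ang)
        ry <- lc$rod_radius * sin(ang)
        img[(xp - rx)^2 + (yp - ry)^2 <= (lc$rod_diameter / 2)^2] <-
          config$water_hu + config$rod_contrast
      }
    } else if (mod_id == 4) {
      img <- render_bars(img, xp, yp, g, config, sp)
    }
    # metal features (after materials so they overwrite additively)
    if (mod_id == 3) {
      bz <- config$z_offset + 2 * ml
      if (bz >= win[1] && bz < win[2]) {
        sep <- g$distance_bbs$separation / 2
        da <- g$distance_bbs$angle * pi / 180
        for (s in c(-1, 1)) {
          ctr <- phantom_to_image(s * sep * cos(da), s * sep * sin(da),
                                  config)
          img <- add_disc_aa(img, grid, ctr[1], ctr[2],
                             g$distance_bbs$diameter / 2,
                             config$bb_hu - config$water_hu, sp)
        }
      }
    }
    for (m in g$alignment_bbs$modules) {
      bz <- config$z_offset + (m - 1) * ml
      if (bz >= win[1] && bz < win[2]) {
        for (ang in bb_ang) {
          ctr <- phantom_to_image(g$alignment_bbs$radius * cos(ang),
                                  g$alignment_bbs$radius * sin(ang),
                                  config)
          img <- add_disc_aa(img, grid, ctr[1], ctr[2],
                             g$alignment_bbs$diameter / 2,
                             config$bb_hu - config$water_hu, sp)
        }
      }
    }
    if (sigma_px > 0)
      img <- EBImage::gblur(img, sigma = sigma_px)
    if (config$cupping != 0 && mod_id > 0)
      img[inside] <- img[inside] -
        config$cupping * (1 - rr2[inside] / r_ref^2)
    if (!is.null(config$crescent) && mod_id > 0) {
      cr <- config$crescent
      r <- sqrt(rr2)
      ang <- atan2(yp, xp) * 180 / pi
      dang <- ((ang - cr$angle_deg + 180) %% 360) - 180
      sel <- abs(r - cr$radius) <= cr$width / 2 &
        abs(dang) <= cr$span_deg / 2
      img[sel] <- img[sel] + cr$amplitude
    }
    if (config$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
    hu[, , i] <- img
  }
  phantom_series(hu, pixel_spacing = sp, slice_thickness = th, z = z,
                 modality = config$modality, protocol = config$protocol,
                 machine = config$machine, date = config$date)
}

# phantom-frame (x, y) -> image-frame mm (apply roll then offset)
phantom_to_image <- function(x, y, config) {
  a <- config$roll * pi / 180
  c(cos(a) * x - sin(a) * y + config$offset[1],
    sin(a) * x + cos(a) * y + config$offset[2])
}

# square-wave bar patterns rendered by bandlimited Fourier synthesis:
# harmonics above the pixel-grid Nyquist frequency are dropped, as a
# reconstruction kernel would, so under-sampled fine patterns flatten to
# their mean level instead of aliasing into spurious low-frequency moire
render_bars <- function(img, xp, yp, g, config, spacing) {
  bp <- g$bar_patterns
  half <- bp$size / 2
  f_nyq <- 1 / (2 * spacing)              # cycles per mm
  for (j in seq_along(bp$lpcm)) {
    ang <- bp$angles[j] * pi / 180
    cx <- bp$radius * cos(ang)
    cy <- bp$radius * sin(ang)
    sel <- which(abs(xp - cx) <= half & abs(yp - cy) <= half)
    if (!length(sel)) next
    p <- 10 / bp$lpcm[j]                  # line-pair period in mm
    wave <- rep(0.5, length(sel))
    k <- 1
    while (k / p <= f_nyq) {
      wave <- wave + (2 / (pi * k)) *
        sin(2 * pi * k * (xp[sel] - cx) / p)
      k <- k + 2
    }
    img[sel] <- img[sel] + config$bar_amplitude * wave
  }
  img
}

#' Simulate a longitudinal QA programme
#'
#' Renders one phantom series per session with a drift model applied to
#' the true plug HU values: linear per-session drift, step events (e.g., a
#' recalibration or tube change, optionally triggering a baseline reset),
#' and small per-session jitter. Every injected truth is logged so that
#' recovery by the analysis pipeline can be scored.
#'
#' @param config a \code{\link{sim_config}} for the base session.
#' @param drift list with optional elements \code{slopes} (named numeric,
#'   HU per session, names are plug names), \code{steps} (data.frame with
#'   columns session, plug, magnitude, reset), and \code{session_sd}
#'   (scalar HU jitter of true plug values between sessions).
#' @param n_sessions number of quarterly sessions to render.
#' @param seed integer seed for the session-level randomness (per-session
#'   render seeds and truth jitter are derived from it).
#' @return list with elements \code{series} (list of
#'   \code{phantom_series}), \code{truth} (data.frame session, plug,
#'   true_hu, segment) and \code{segments} (segment id per session;
#'   increments after each reset event).
#' @export
simulate_longitudinal <- function(config, drift = list(),
                                  n_sessions = 8, seed = 1L) {
  stopifnot(n_sessions >= 1)
  set.seed(seed)
  render_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  plugs <- config$geometry$plugs$name
  base <- config$plug_hu[plugs]
  slopes <- stats::setNames(numeric(length(plugs)), plugs)
  if (!is.null(drift$slopes))
    slopes[names(drift$slopes)] <- drift$slopes
  sd_s <- drift$session_sd %||% 0
  steps <- drift$steps
  segments <- integer(n_sessions)
  seg <- 1L
  series <- vector("list", n_sessions)
  truth <- NULL
  cum_step <- stats::setNames(numeric(length(plugs)), plugs)
  for (t in seq_len(n_sessions)) {
    if (!is.null(steps)) {
      ev <- steps[steps$session == t, , drop = FALSE]
      for (k in seq_len(nrow(ev)))
        cum_step[ev$plug[k]] <- cum_step[ev$plug[k]] + ev$magnitude[k]
    }
    true_hu <- base + slopes * (t - 1) + cum_step +
      stats::rnorm(length(plugs), 0, sd_s)
    segments[t] <- seg
    cfg_t <- config
    cfg_t$plug_hu[plugs] <- true_hu
    cfg_t$seed <- render_seeds[t]
    cfg_t$date <- format(seq(as.Date("2020-01-01"), by = "quarter",
                             length.out = n_sessions)[t], "%Y%m%d")
    series[[t]] <- render_phantom(cfg_t)
    truth <- rbind(truth, data.frame(session = t, plug = plugs,
                                     true_hu = unname(true_hu),
                                     segment = seg,
                                     stringsAsFactors = FALSE))
    if (!is.null(steps) && any(steps$session == t & as.logical(steps$reset)))
      seg <- seg + 1L
  }
  list(series = series, truth = truth, segments = segments)
}
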