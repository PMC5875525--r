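# The eight image-quality measurements: HU accuracy, CNR, noise,
# uniformity, in-plane distance, slice thickness, low-contrast rod
# visibility and high-contrast bar-pattern resolution.

#' Place an ROI template at the detected phantom position
#'
#' Rotates a phantom-frame \code{\link{roi_template}} by the estimated
#' roll and translates it to the detected phantom centre, giving ROI
#' centres in image-frame mm.
#'
#' @param template a \code{\link{roi_template}}.
#' @param center phantom centre c(x, y) in mm.
#' @param roll roll angle in degrees.
#' @return the template with transformed x, y.
#' @export
place_template <- function(template, center, roll = 0) {
  a <- roll * pi / 180
  x <- cos(a) * template$x - sin(a) * template$y + center[1]
  y <- sin(a) * template$x + cos(a) * template$y + center[2]
  template$x <- x
  template$y <- y
  template
}

#' ROI statistics on one slice
#'
#' Mean and sample standard deviation of the HU values whose pixel centres
#' fall inside the ROI circle, minus any pixels covered by the supplied
#' artifact mask. If more than \code{max_masked} of the ROI pixels are
#' masked the ROI is re-seated by searching small angular offsets about
#' the phantom axis for the placement minimizing the masked fraction, and
#' the result is flagged.
#'
#' @param slice HU matrix.
#' @param spacing pixel spacing in mm.
#' @param roi list or one-row data.frame with label, x, y, radius
#'   (image-frame mm).
#' @param artifact_mask optional logical matrix of pixels to exclude.
#' @param center phantom axis (mm) about which re-seating rotates.
#' @param max_masked masked-fraction threshold triggering re-seating.
#' @return object of class \code{roi_stats}: label, mean, sd, n, area,
#'   center, masked_frac, reseated, flagged.
#' @export
extract_roi_stats <- function(slice, spacing, roi, artifact_mask = NULL,
                              center = c(0, 0), max_masked = 0.3) {
  grid <- pixel_grid(nrow(slice), ncol(slice), spacing)
  seat <- function(x, y) {
    m <- roi_mask(grid, x, y, roi$radius)
    n_all <- sum(m)
    if (n_all == 0)
      stop("ROI '", roi$label, "' fully outside the image")
    masked <- if (is.null(artifact_mask)) 0 else sum(m & artifact_mask)
    list(mask = m & !(if (is.null(artifact_mask))
      matrix(FALSE, nrow(slice), ncol(slice)) else artifact_mask),
      n_all = n_all, frac = masked / n_all, x = x, y = y)
  }
  s <- seat(roi$x, roi$y)
  reseated <- FALSE
  if (s$frac > max_masked) {
    rel <- c(roi$x - center[1], roi$y - center[2])
    best <- s
    for (da in pi / 180 * c(-30, -25, -20, -15, -10, -5, 5, 10, 15,
                            20, 25, 30)) {
      cand <- seat(cos(da) * rel[1] - sin(da) * rel[2] + center[1],
                   sin(da) * rel[1] + cos(da) * rel[2] + center[2])
      if (cand$frac < best$frac) best <- cand
    }
    if (best$frac < s$frac) { s <- best; reseated <- TRUE }
  }
  px <- slice[s$mask]
  structure(list(label = roi$label, mean = mean(px),
                 sd = if (length(px) > 1) stats::sd(px) else 0,
                 n = length(px), area = length(px) * spacing^2,
                 center = c(s$x, s$y), masked_frac = s$frac,
                 reseated = reseated,
                 flagged = reseated || s$frac > max_masked),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI %s: mean %.2f HU, SD %.2f HU, n = %d (%.0f mm^2)%s\n",
              x$label, x$mean, x$sd, x$n, x$area,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Contrast-to-noise ratio
#'
#' CNR = |ROI mean - background mean| / background SD, the ACR formula
#' used for the polyethylene and acrylic plugs against the water-plug
#' background in the same slice, and for the low-contrast cylinder against
#' adjacent background.
#'
#' @param roi,background \code{roi_stats} (or any lists with mean/sd).
#' @return CNR, dimensionless; NA when the background SD is 0 (undefined;
#'   occurs only on noiseless synthetic input).
#' @export
compute_cnr <- function(roi, background) {
  if (background$sd == 0) return(NA_real_)
  abs(roi$mean - background$mean) / background$sd
}

#' Noise (%) with the +1000 HU rescale
#'
#' Noise(\%) = 100 x ROI SD / (ROI mean + 1000 HU). The rescale keeps the
#' denominator away from zero for water-like plugs and makes values
#' comparable across plugs; as a consequence the statistic is
#' deliberately not invariant under global HU offsets.
#'
#' @param roi a \code{roi_stats}.
#' @return noise in percent.
#' @export
compute_noise <- function(roi) {
  if (roi$mean + 1000 <= 0)
    stop("noise undefined: ROI mean ", round(roi$mean, 1),
         " HU <= -1000 HU")
  100 * roi$sd / (roi$mean + 1000)
}

#' HU accuracy for the five density plugs
#'
#' One ~200 mm^2 ROI per plug on the module-1 slice; each mean is checked
#' against the configured accepted HU range.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param loc a \code{\link{localize_phantom}} result.
#' @param geometry an \code{\link{acr_geometry}}.
#' @param artifact_mask optional logical exclusion mask.
#' @return list(table = data.frame(plug, mean, sd, n, nominal, in_range,
#'   flagged), stats = list of \code{roi_stats}).
#' @export
measure_hu_accuracy <- function(series, loc, geometry = acr_geometry(),
                                artifact_mask = NULL) {
  tpl <- place_template(roi_template(geometry, 1), loc$center, loc$roll)
  slice <- series$hu[, , loc$module_slices[["m1"]]]
  stats_l <- lapply(seq_len(nrow(tpl)), function(i)
    extract_roi_stats(slice, series$pixel_spacing, tpl[i, ],
                      artifact_mask, center = loc$center))
  plugs <- sub("^hu_", "", tpl$label)
  g <- geometry$plugs[match(plugs, geometry$plugs$name), ]
  means <- vapply(stats_l, `[[`, 0, "mean")
  data <- data.frame(plug = plugs, mean = means,
                     sd = vapply(stats_l, `[[`, 0, "sd"),
                     n = vapply(stats_l, function(s) s$n, 0L),
                     nominal = g$nominal_hu,
                     in_range = means >= g$hu_min & means <= g$hu_max,
                     flagged = vapply(stats_l, `[[`, TRUE, "flagged"),
                     stringsAsFactors = FALSE)
  list(table = data, stats = stats::setNames(stats_l, plugs))
}

#' Image uniformity on the module-3 slice
#'
#' Centre ROI mean and the four edge ROI means (~400 mm^2 each, at
#' 12/3/6/9 o'clock); the uniformity value is the maximum absolute
#' difference between an edge mean and the centre mean. The centre mean is
#' reported separately for its absolute limit.
#'
#' @inheritParams measure_hu_accuracy
#' @return list(value, center_mean, edge_means, flagged, stats).
#' @export
measure_uniformity <- function(series, loc, geometry = acr_geometry(),
                               artifact_mask = NULL) {
  tpl <- place_template(roi_template(geometry, 3), loc$center, loc$roll)
  slice <- series$hu[, , loc$module_slices[["m3"]]]
  stats_l <- lapply(seq_len(nrow(tpl)), function(i)
    extract_roi_stats(slice, series$pixel_spacing, tpl[i, ],
                      artifact_mask, center = loc$center))
  names(stats_l) <- tpl$label
  ctr <- stats_l$center$mean
  edges <- vapply(stats_l[grep("^edge_", names(stats_l))], `[[`, 0, "mean")
  list(value = max(abs(edges - ctr)), center_mean = ctr,
       edge_means = edges,
       flagged = any(vapply(stats_l, `[[`, TRUE, "flagged")),
       stats = stats_l)
}

#' In-plane distance between the two distance BBs
#'
#' Euclidean distance between the sub-pixel intensity-weighted BB
#' centroids on the module-3 slice, in mm, against the nominal 100.0 mm.
#'
#' @param loc a \code{\link{localize_phantom}} result.
#' @return distance in mm, or NA if either distance BB is missing.
#' @export
measure_inplane_distance <- function(loc) {
  m3 <- loc$module_slices[["m3"]]
  db <- loc$bbs[loc$bbs$slice == m3 & !is.na(loc$bbs$matched) &
                  grepl("^dist_", loc$bbs$matched), , drop = FALSE]
  if (!all(c("dist_1", "dist_2") %in% db$matched)) return(NA_real_)
  p1 <- db[match("dist_1", db$matched), c("x", "y")]
  p2 <- db[match("dist_2", db$matched), c("x", "y")]
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Slice thickness from the module-1 wire ramps
#'
#' ACR wire-count method: a ramp wire is visible when its peak contrast
#' over the local background exceeds half the maximum wire contrast;
#' thickness = ramp z-pitch x mean visible-wire count over the two ramps.
#'
#' @inheritParams measure_hu_accuracy
#' @param min_contrast minimum integrated wire contrast (HU x pixels)
#'   below which the measurement is not evaluable.
#' @return list(value = thickness mm (NA if not evaluable), counts = per
#'   ramp visible-wire counts, contrasts = per-ramp integrated-contrast
#'   vectors).
#' @export
measure_slice_thickness <- function(series, loc,
                                    geometry = acr_geometry(),
                                    min_contrast = 500) {
  slice <- series$hu[, , loc$module_slices[["m1"]]]
  sp <- series$pixel_spacing
  grid <- pixel_grid(nrow(slice), ncol(slice), sp)
  rp <- geometry$ramps
  k <- seq_len(rp$n_wires) - (rp$n_wires + 1) / 2
  wy <- k * rp$wire_spacing
  counts <- numeric(0)
  contrasts <- list()
  for (rx in rp$x) {
    pos <- vapply(wy, function(y) {
      a <- loc$roll * pi / 180
      c(cos(a) * rx - sin(a) * y + loc$center[1],
        sin(a) * rx + cos(a) * y + loc$center[2])
    }, numeric(2))
    box <- abs(grid$x - mean(pos[1, ])) <= 5 &
      grid$y >= min(pos[2, ]) - 4 & grid$y <= max(pos[2, ]) + 4
    bg <- stats::median(slice[box])
    # integrated wire mass within a capture disc: conserved under both
    # the PSF and pixel discretization, unlike a single peak sample
    ctr <- vapply(seq_along(wy), function(j) {
      near <- (grid$x - pos[1, j])^2 + (grid$y - pos[2, j])^2 <= 1.4^2
      sum(slice[near] - bg)
    }, 0)
    contrasts[[length(contrasts) + 1L]] <- ctr
    if (max(ctr) >= min_contrast)
      counts <- c(counts, sum(ctr > 0.5 * max(ctr)))
  }
  if (!length(counts))
    return(list(value = NA_real_, counts = integer(0),
                contrasts = contrasts))
  list(value = rp$pitch * mean(counts), counts = counts,
       contrasts = contrasts)
}

#' Low-contrast scoring on the module-2 slice
#'
#' CNR between the 25 mm low-contrast cylinder (~100 mm^2 ROI) and its
#' adjacent background, plus visibility of the four 6 mm rods: a rod is
#' visible when its ROI mean exceeds the local background mean (two
#' flanking ROIs at the same radius) by more than k x background SD. The
#' SD is taken from the larger adjacent-background ROI, where the same
#' stationary noise field is sampled with less estimator variance. A
#' count of 0 is a legitimate result for CBCT-like noise.
#'
#' @inheritParams measure_hu_accuracy
#' @param k visibility threshold in background-SD units (mirrors the
#'   CNR >= 1.0 criterion).
#' @return list(cnr, n_visible, rods = data.frame, stats).
#' @export
score_low_contrast <- function(series, loc, geometry = acr_geometry(),
                               artifact_mask = NULL, k = 1.0) {
  tpl <- place_template(roi_template(geometry, 2), loc$center, loc$roll)
  slice <- series$hu[, , loc$module_slices[["m2"]]]
  sp <- series$pixel_spacing
  get <- function(lab) {
    i <- match(lab, tpl$label)
    extract_roi_stats(slice, sp, tpl[i, ], artifact_mask,
                      center = loc$center)
  }
  lc <- get("low_contrast")
  bg <- get("low_contrast_bg")
  cnr <- compute_cnr(lc, bg)
  rods <- lapply(1:4, function(i) {
    rod <- get(paste0("rod_", i))
    b1 <- get(paste0("rod_", i, "_bg1"))
    b2 <- get(paste0("rod_", i, "_bg2"))
    local_bg <- (b1$mean * b1$n + b2$mean * b2$n) / (b1$n + b2$n)
    contrast <- rod$mean - local_bg
    data.frame(rod = i, contrast = contrast, threshold = k * bg$sd,
               visible = contrast > k * bg$sd)
  })
  rods <- do.call(rbind, rods)
  list(cnr = cnr, n_visible = sum(rods$visible), rods = rods,
       stats = list(low_contrast = lc, background = bg))
}

#' High-contrast bar-pattern scoring on the module-4 slice
#'
#' The modulation statistic of each bar-pattern region is the HU standard
#' deviation inside its ROI. Scanning from the coarsest to the finest
#' pattern, a pattern is resolvable while its statistic exceeds fraction
#' \code{f} of the coarsest pattern's statistic; the score is the highest
#' resolvable lp/cm (monotone by construction: the scan stops at the first
#' failure). If the coarsest pattern itself does not rise above the noise
#' floor the result is not evaluable.
#'
#' @inheritParams measure_hu_accuracy
#' @param f resolvability fraction of the coarsest-pattern statistic.
#' @param min_modulation minimum noise-corrected modulation of the
#'   coarsest pattern, in HU.
#' @return list(value = lp/cm (NA if not evaluable), stats = data.frame
#'   (lpcm, sd, resolvable), noise_sd).
#' @export
score_high_contrast <- function(series, loc, geometry = acr_geometry(),
                                f = 0.4, min_modulation = 20) {
  tpl <- place_template(roi_template(geometry, 4), loc$center, loc$roll)
  slice <- series$hu[, , loc$module_slices[["m4"]]]
  sp <- series$pixel_spacing
  ord <- order(geometry$bar_patterns$lpcm)
  tpl <- tpl[ord, ]
  lpcm <- geometry$bar_patterns$lpcm[ord]
  sds <- vapply(seq_len(nrow(tpl)), function(i)
    extract_roi_stats(slice, sp, tpl[i, ], center = loc$center)$sd, 0)
  noise <- extract_roi_stats(
    slice, sp, list(label = "noise", x = loc$center[1],
                    y = loc$center[2],
                    radius = roi_radius(geometry$roi_area[["uniformity"]])),
    center = loc$center)$sd
  base <- sds[1]
  mod0 <- sqrt(max(base^2 - noise^2, 0))
  res <- data.frame(lpcm = lpcm, sd = sds, resolvable = FALSE)
  if (mod0 < min_modulation)
    return(list(value = NA_real_, stats = res, noise_sd = noise))
  for (i in seq_along(lpcm)) {
    if (sds[i] > f * base) res$resolvable[i] <- TRUE else break
  }
  list(value = max(res$lpcm[res$resolvable]), stats = res,
       noise_sd = noise)
}
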