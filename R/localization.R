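# Phantom localization: finds the phantom axis, detects the metal BBs,
# estimates in-plane roll and assigns the analysis slice for each module.
# Thresholds are absolute HU with wide margins between the materials
# involved (air ~ -1000, water ~ 0, bone < ~1000, metal BBs >> 1000), so
# localization is insensitive to moderate global HU drift.

#' Find the phantom centre in each slice
#'
#' The phantom is the largest connected region above the body threshold in
#' each slice (holes such as the air plug are filled before taking the
#' centroid, which would otherwise bias it).
#'
#' @param series a \code{\link{phantom_series}}.
#' @param threshold body threshold in HU separating phantom from air.
#' @return list with \code{per_slice} (data.frame slice, z, x, y, found,
#'   area_px) and \code{center} (mean in-plane centre, mm).
#' @export
find_phantom_center <- function(series, threshold = -300) {
  d <- dim(series$hu)
  grid <- pixel_grid(d[1], d[2], series$pixel_spacing)
  min_px <- 0.05 * d[1] * d[2]
  res <- data.frame(slice = seq_len(d[3]), z = series$z, x = NA_real_,
                    y = NA_real_, found = FALSE, area_px = 0)
  for (i in seq_len(d[3])) {
    mask <- series$hu[, , i] > threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(lab[lab > 0])
    big <- which.max(tab)
    if (tab[big] < min_px) next
    comp <- EBImage::fillHull(lab == big) > 0
    res$x[i] <- mean(grid$x[comp])
    res$y[i] <- mean(grid$y[comp])
    res$found[i] <- TRUE
    res$area_px[i] <- sum(comp)
  }
  if (!any(res$found))
    stop("phantom not found: no region above ", threshold, " HU")
  list(per_slice = res,
       center = c(x = mean(res$x[res$found]), y = mean(res$y[res$found])))
}

#' Detect alignment and distance BBs
#'
#' BBs are connected components above the BB threshold with area below a
#' small-object cap, reported as intensity-weighted sub-pixel centroids in
#' mm. Each detection is matched to its nearest expected in-plane position
#' (the four peripheral alignment BBs and the two distance BBs, relative
#' to the detected phantom centre) within a gate; unmatched expected BBs
#' are flagged, not fatal.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param geometry an \code{\link{acr_geometry}}.
#' @param center phantom centre c(x, y) in mm (from
#'   \code{\link{find_phantom_center}}).
#' @param threshold BB threshold in HU.
#' @param gate matching gate in mm.
#' @return data.frame of detections: slice, z, x, y, area_px, weight,
#'   matched (expected-position label or NA).
#' @export
detect_bbs <- function(series, geometry, center, threshold = 800,
                       gate = 5) {
  d <- dim(series$hu)
  sp <- series$pixel_spacing
  grid <- pixel_grid(d[1], d[2], sp)
  cap_px <- 4 * pi * (geometry$alignment_bbs$diameter / 2)^2 / sp^2
  ang <- geometry$alignment_bbs$angles
  exp_xy <- rbind(
    cbind(geometry$alignment_bbs$radius * cos(ang * pi / 180),
          geometry$alignment_bbs$radius * sin(ang * pi / 180)),
    cbind(c(-1, 1) * geometry$distance_bbs$separation / 2 *
            cos(geometry$distance_bbs$angle * pi / 180),
          c(-1, 1) * geometry$distance_bbs$separation / 2 *
            sin(geometry$distance_bbs$angle * pi / 180)))
  exp_lab <- c(paste0("align_", ang), c("dist_1", "dist_2"))
  out <- NULL
  for (i in seq_len(d[3])) {
    img <- series$hu[, , i]
    mask <- img > threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    for (id in seq_len(max(lab))) {
      sel <- lab == id
      npx <- sum(sel)
      if (npx > cap_px) next
      w <- img[sel] - threshold
      cx <- sum(grid$x[sel] * w) / sum(w)
      cy <- sum(grid$y[sel] * w) / sum(w)
      # refine to sub-pixel over a window around the component: the
      # below-threshold skirt of the blurred BB carries the fractional
      # position that the thresholded component quantizes away
      win <- (grid$x - cx)^2 + (grid$y - cy)^2 <= 3^2
      wbg <- stats::median(img[(grid$x - cx)^2 + (grid$y - cy)^2 <= 6^2 &
                                 !win])
      ww <- pmax(img[win] - wbg, 0)
      if (sum(ww) > 0) {
        cx <- sum(grid$x[win] * ww) / sum(ww)
        cy <- sum(grid$y[win] * ww) / sum(ww)
      }
      dd <- sqrt((exp_xy[, 1] + center[1] - cx)^2 +
                 (exp_xy[, 2] + center[2] - cy)^2)
      m <- which.min(dd)
      out <- rbind(out, data.frame(
        slice = i, z = series$z[i], x = cx, y = cy, area_px = npx,
        weight = sum(w),
        matched = if (dd[m] <= gate) exp_lab[m] else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(slice = integer(), z = numeric(), x = numeric(),
                      y = numeric(), area_px = numeric(),
                      weight = numeric(), matched = character(),
                      stringsAsFactors = FALSE)
  out
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Estimate in-plane phantom roll from matched alignment BBs
#'
#' The roll angle is the mean angular offset of the detected alignment-BB
#' centroids from their nominal clock positions about the phantom axis.
#' With fewer than two matched alignment BBs the roll is assumed 0 and
#' flagged.
#'
#' @param bbs detection table from \code{\link{detect_bbs}}.
#' @param geometry an \code{\link{acr_geometry}}.
#' @param center phantom centre c(x, y) in mm.
#' @param max_roll guard in degrees: larger estimates are flagged as
#'   probable setup errors (the templates are still rotated).
#' @return list(roll = degrees in (-180, 180], flagged, n_bbs).
#' @export
estimate_roll <- function(bbs, geometry, center, max_roll = 5) {
  al <- bbs[!is.na(bbs$matched) & grepl("^align_", bbs$matched), ,
            drop = FALSE]
  if (nrow(al) < 2)
    return(list(roll = 0, flagged = TRUE, n_bbs = nrow(al)))
  nominal <- as.numeric(sub("align_", "", al$matched))
  meas <- atan2(al$y - center[2], al$x - center[1]) * 180 / pi
  roll <- mean(wrap_angle(meas - nominal))
  list(roll = wrap_angle(roll), flagged = abs(roll) > max_roll,
       n_bbs = nrow(al))
}

#' Assign the analysis slice for each module
#'
#' Modules 1 and 4 use the slices in which the most alignment BBs are
#' visible (two BB planes ~3 module lengths apart); module 3 the slice
#' containing both distance BBs; module 2 the slice nearest the module-2
#' mid-plane. When BBs are unmatched the assignment falls back to nominal
#' module offsets from the detected phantom longitudinal mid-plane.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param center_info result of \code{\link{find_phantom_center}}.
#' @param bbs detection table from \code{\link{detect_bbs}}.
#' @param geometry an \code{\link{acr_geometry}}.
#' @return list(slices = integer c(m1, m2, m3, m4), method = "bbs" or
#'   "fallback", flags = character vector).
#' @export
assign_module_slices <- function(series, center_info, bbs, geometry) {
  ml <- geometry$module_length
  ps <- center_info$per_slice
  zf <- ps$z[ps$found]
  span <- diff(range(zf)) + series$slice_thickness
  if (span < 3.5 * ml)
    stop("incomplete phantom coverage: z span ", round(span, 1),
         " mm < ", 3.5 * ml, " mm")
  flags <- character()
  nearest_slice <- function(z) which.min(abs(series$z - z))
  al <- bbs[!is.na(bbs$matched) & grepl("^align_", bbs$matched), ,
            drop = FALSE]
  counts <- table(factor(al$slice, levels = seq_along(series$z)))
  method <- "bbs"
  if (nrow(al) >= 1 && max(counts) >= 2) {
    s1 <- which.max(counts)
    far <- abs(series$z - series$z[s1]) > 1.5 * ml
    s4 <- NA_integer_
    if (any(far & counts > 0)) {
      cand <- which(far & counts > 0)
      s4 <- cand[which.max(counts[cand])]
    }
    if (is.na(s4)) {
      flags <- c(flags, "second alignment-BB plane not found")
      s4 <- nearest_slice(series$z[s1] + 3 * ml)
    }
    if (series$z[s1] > series$z[s4]) { tmp <- s1; s1 <- s4; s4 <- tmp }
    m1 <- s1; m4 <- s4
    m2 <- nearest_slice(series$z[m1] + ml)
  } else {
    method <- "fallback"
    flags <- c(flags, "alignment BBs not matched; nominal offsets used")
    zmid <- mean(range(zf))
    m1 <- nearest_slice(zmid - 1.5 * ml)
    m2 <- nearest_slice(zmid - 0.5 * ml)
    m4 <- nearest_slice(zmid + 1.5 * ml)
  }
  db <- bbs[!is.na(bbs$matched) & grepl("^dist_", bbs$matched), ,
            drop = FALSE]
  both <- intersect(db$slice[db$matched == "dist_1"],
                    db$slice[db$matched == "dist_2"])
  if (length(both) >= 1) {
    wsum <- vapply(both, function(s) sum(db$weight[db$slice == s]), 0)
    m3 <- both[which.max(wsum)]
  } else {
    flags <- c(flags, "distance BBs not found in a common slice")
    m3 <- nearest_slice(series$z[m1] + 2 * ml)
  }
  list(slices = c(m1 = as.integer(unname(m1)), m2 = as.integer(unname(m2)),
                  m3 = as.integer(unname(m3)), m4 = as.integer(unname(m4))),
       method = method, flags = flags)
}

#' Localize the phantom in a series
#'
#' Orchestrates \code{\link{find_phantom_center}},
#' \code{\link{detect_bbs}}, \code{\link{estimate_roll}} and
#' \code{\link{assign_module_slices}}.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param geometry an \code{\link{acr_geometry}}.
#' @param body_threshold,bb_threshold HU thresholds.
#' @param gate BB matching gate in mm.
#' @param max_roll roll guard in degrees.
#' @return object of class \code{localization}: centre, per-slice centres,
#'   BB detections with match flags, roll estimate, module slice
#'   assignment and quality flags.
#' @export
localize_phantom <- function(series, geometry = acr_geometry(),
                             body_threshold = -300, bb_threshold = 800,
                             gate = 5, max_roll = 5) {
  ctr <- find_phantom_center(series, threshold = body_threshold)
  bbs <- detect_bbs(series, geometry, ctr$center,
                    threshold = bb_threshold, gate = gate)
  roll <- estimate_roll(bbs, geometry, ctr$center, max_roll = max_roll)
  assign <- assign_module_slices(series, ctr, bbs, geometry)
  expected <- c(paste0("align_", geometry$alignment_bbs$angles),
                "dist_1", "dist_2")
  found <- vapply(expected, function(e) e %in% bbs$matched, TRUE)
  structure(list(center = ctr$center, per_slice = ctr$per_slice,
                 bbs = bbs, roll = roll$roll,
                 roll_flagged = roll$flagged,
                 module_slices = assign$slices, method = assign$method,
                 bbs_found = found,
                 flags = c(assign$flags,
                           if (roll$flagged) "roll estimate flagged")),
            class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat(sprintf("phantom localization: centre (%.2f, %.2f) mm, roll %.2f deg%s\n",
              x$center[1], x$center[2], x$roll,
              if (x$roll_flagged) " [flagged]" else ""))
  cat(sprintf("  module slices: %s (%s)\n",
              paste(x$module_slices, collapse = ", "), x$method))
  cat(sprintf("  BBs matched: %d/%d\n", sum(x$bbs_found),
              length(x$bbs_found)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Export a localization result as JSON for audit
#'
#' @param loc a \code{localization}.
#' @param path output file path.
#' @export
export_localization <- function(loc, path) {
  jsonlite::write_json(
    list(center = as.list(loc$center), roll_deg = loc$roll,
         roll_flagged = loc$roll_flagged,
         module_slices = as.list(loc$module_slices),
         method = loc$method, bbs_found = as.list(loc$bbs_found),
         flags = loc$flags, bbs = loc$bbs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
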