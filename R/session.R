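#' Run a complete QA session on one series
#'
#' Localizes the phantom and computes the full measurement panel: per-plug
#' HU accuracy, CNR and noise for the polyethylene and acrylic plugs
#' against the water-plug background, uniformity, in-plane distance,
#' slice thickness, low-contrast scoring and high-contrast resolution. A
#' single failed metric never aborts the session: it is marked
#' not-evaluable with a reason. If localization itself fails every metric
#' is not-evaluable.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param geometry an \code{\link{acr_geometry}}.
#' @param artifact_mask optional logical matrix (image grid) of pixels to
#'   exclude from HU/uniformity ROIs (e.g., a known crescent artifact).
#' @param k_lowcontrast rod-visibility threshold in background-SD units.
#' @param f_highcontrast bar-pattern resolvability fraction.
#' @return an object of class \code{qa_session}.
#' @export
run_session <- function(series, geometry = acr_geometry(),
                        artifact_mask = NULL, k_lowcontrast = 1.0,
                        f_highcontrast = 0.4) {
  metric_names <- c(paste0("hu_", geometry$plugs$name),
                    "cnr_polyethylene", "cnr_acrylic",
                    "noise_polyethylene", "noise_acrylic",
                    "uniformity", "uniformity_center", "distance",
                    "slice_thickness", "lowcontrast_cnr",
                    "lowcontrast_rods", "highcontrast_lpcm")
  metrics <- data.frame(metric = metric_names, value = NA_real_,
                        evaluable = FALSE, note = "",
                        stringsAsFactors = FALSE)
  set_metric <- function(m, value, note = "") {
    i <- match(m, metrics$metric)
    metrics$value[i] <<- value
    metrics$evaluable[i] <<- is.finite(value)
    metrics$note[i] <<- note
  }
  details <- list()
  loc <- tryCatch(localize_phantom(series, geometry),
                  error = function(e) e)
  if (inherits(loc, "error")) {
    metrics$note <- paste("localization failed:",
                          conditionMessage(loc))
    return(new_qa_session(series, metrics, details, loc = NULL))
  }
  try_metric <- function(expr, on_error_metrics) {
    tryCatch(expr, error = function(e) {
      for (m in on_error_metrics)
        set_metric(m, NA_real_, conditionMessage(e))
      NULL
    })
  }
  hu <- try_metric(
    measure_hu_accuracy(series, loc, geometry, artifact_mask),
    paste0("hu_", geometry$plugs$name))
  if (!is.null(hu)) {
    details$hu <- hu$table
    for (i in seq_len(nrow(hu$table)))
      set_metric(paste0("hu_", hu$table$plug[i]), hu$table$mean[i],
                 if (!hu$table$in_range[i]) "outside accepted HU range"
                 else "")
    for (p in c("polyethylene", "acrylic")) {
      cnr <- compute_cnr(hu$stats[[p]], hu$stats[["water"]])
      set_metric(paste0("cnr_", p), cnr,
                 if (is.na(cnr)) "background SD is 0" else "")
      set_metric(paste0("noise_", p), compute_noise(hu$stats[[p]]))
    }
  }
  un <- try_metric(
    measure_uniformity(series, loc, geometry, artifact_mask),
    c("uniformity", "uniformity_center"))
  if (!is.null(un)) {
    details$uniformity <- un
    set_metric("uniformity", un$value,
               if (un$flagged) "ROI re-seated or masked" else "")
    set_metric("uniformity_center", un$center_mean)
  }
  dist <- try_metric(measure_inplane_distance(loc), "distance")
  if (!is.null(dist))
    set_metric("distance", dist,
               if (is.na(dist)) "distance BB missing" else "")
  st <- try_metric(measure_slice_thickness(series, loc, geometry),
                   "slice_thickness")
  if (!is.null(st)) {
    details$slice_thickness <- st
    set_metric("slice_thickness", st$value,
               if (is.na(st$value)) "no wires above background" else "")
  }
  lc <- try_metric(
    score_low_contrast(series, loc, geometry, artifact_mask,
                       k = k_lowcontrast),
    c("lowcontrast_cnr", "lowcontrast_rods"))
  if (!is.null(lc)) {
    details$low_contrast <- lc
    set_metric("lowcontrast_cnr", lc$cnr,
               if (is.na(lc$cnr)) "background SD is 0" else "")
    set_metric("lowcontrast_rods", lc$n_visible)
  }
  hc <- try_metric(
    score_high_contrast(series, loc, geometry, f = f_highcontrast),
    "highcontrast_lpcm")
  if (!is.null(hc)) {
    details$high_contrast <- hc
    set_metric("highcontrast_lpcm", hc$value,
               if (is.na(hc$value))
                 "coarsest pattern below noise floor" else "")
  }
  new_qa_session(series, metrics, details, loc)
}

new_qa_session <- function(series, metrics, details, loc) {
  structure(list(machine = series$machine, modality = series$modality,
                 protocol = series$protocol, date = series$date,
                 metrics = metrics, details = details,
                 localization = loc),
            class = "qa_session")
}

#' @export
print.qa_session <- function(x, ...) {
  cat(sprintf("QA session: %s / %s / %s (%s)\n", x$machine, x$modality,
              x$protocol, x$date))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$evaluable[i]) {
      cat(sprintf("  %-20s %10.3f  %s\n", m$metric[i], m$value[i],
                  m$note[i]))
    } else {
      cat(sprintf("  %-20s %10s  %s\n", m$metric[i], "n/e", m$note[i]))
    }
  }
  invisible(x)
}

#' @export
summary.qa_session <- function(object, ...) {
  m <- object$metrics
  cat(sprintf("QA session %s/%s/%s: %d of %d metrics evaluable\n",
              object$machine, object$modality, object$protocol,
              sum(m$evaluable), nrow(m)))
  flagged <- m$metric[nzchar(m$note)]
  if (length(flagged)) cat("  noted:", paste(flagged, collapse = ", "),
                           "\n")
  invisible(object)
}

#' @export
as.data.frame.qa_session <- function(x, ...) {
  data.frame(machine = x$machine, modality = x$modality,
             protocol = x$protocol, date = x$date, x$metrics,
             stringsAsFactors = FALSE)
}

#' Serialize a QA session to JSON
#'
#' @param session a \code{qa_session}.
#' @param path output file path.
#' @export
write_session_json <- function(session, path) {
  jsonlite::write_json(
    list(machine = session$machine, modality = session$modality,
         protocol = session$protocol, date = session$date,
         metrics = session$metrics,
         localization = if (is.null(session$localization)) NULL else
           list(center = as.list(session$localization$center),
                roll_deg = session$localization$roll,
                module_slices =
                  as.list(session$localization$module_slices),
                flags = session$localization$flags)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
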