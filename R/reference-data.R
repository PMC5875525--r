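# Bundled reference measurement summaries from a two-year quarterly QA
# programme (one fan-beam CT simulator, five protocols; three linac CBCT
# systems, five protocols each): per-protocol averages and SDs of plug
# CNR and noise, and the maximum observed SDs of the HU, uniformity and
# distance metrics. These drive the shipped default tolerance sets and
# serve as worked-example inputs to the tolerance engine.

#' Bundled two-year QA summary tables
#'
#' \code{qa_summary_tables()} returns the per-protocol CNR/noise averages
#' and standard deviations; \code{qa_max_sd_table()} the maximum observed
#' standard deviations of the HU, uniformity, distance and low-contrast
#' CNR metrics over all machines and protocols.
#'
#' @param modality optional filter, "CT" or "CBCT".
#' @return data.frame.
#' @export
qa_summary_tables <- function(modality = NULL) {
  d <- utils::read.csv(system.file("extdata", "qa_summary_two_year.csv",
                                   package = "acrqa"),
                       stringsAsFactors = FALSE)
  if (!is.null(modality)) d <- d[d$modality == modality, ]
  d
}

#' @rdname qa_summary_tables
#' @export
qa_max_sd_table <- function(modality = NULL) {
  d <- utils::read.csv(system.file("extdata", "qa_max_sd_two_year.csv",
                                   package = "acrqa"),
                       stringsAsFactors = FALSE)
  if (!is.null(modality)) d <- d[d$modality == modality, ]
  d
}

#' Absolute ACR image-quality limits
#'
#' Reads the bundled configuration of absolute limits (uniformity edge
#' difference, uniformity centre, low-contrast CNR minimum) into absolute
#' tolerance rows. These values come from ACR CT Accreditation Program
#' documentation and are plain configuration, editable via \code{path}.
#'
#' @param path YAML file of limits; default the bundled one.
#' @param strict_center use the +/-5 HU variant of the uniformity centre
#'   limit instead of +/-7 HU.
#' @return a \code{tolerance_set} (absolute mode).
#' @export
acr_absolute_limits <- function(path = system.file("extdata",
                                                   "acr_limits.yaml",
                                                   package = "acrqa"),
                                strict_center = FALSE) {
  lim <- yaml::read_yaml(path)
  if (strict_center)
    lim$uniformity_center <- lim$uniformity_center_strict
  lim$uniformity_center_strict <- NULL
  rows <- do.call(rbind, lapply(names(lim), function(m)
    data.frame(metric = m, mode = "absolute", bound = NA_real_,
               lo = as.numeric(lim[[m]]$lo), hi = as.numeric(lim[[m]]$hi),
               units = as.character(lim[[m]]$units),
               provenance = "fixed-ACR", rounding = "none",
               degenerate = FALSE, stringsAsFactors = FALSE)))
  new_tolerance_set(rows)
}

worst_case_rows <- function(metric, bound) {
  new_tolerance_set(data.frame(
    metric = metric, mode = "delta", bound = bound, lo = NA_real_,
    hi = NA_real_, units = units_for(metric), provenance = "worst-case",
    rounding = "none", degenerate = FALSE, stringsAsFactors = FALSE))
}

#' Default tolerance sets derived from the bundled two-year summaries
#'
#' Applies the 2 x maximum-SD rule to the bundled reference summaries:
#' CNR and noise bands come from the per-protocol SD tables, HU and
#' uniformity bands from the recorded maximum SDs. Worst-case bounds
#' (high-contrast resolution +/-1 lp/cm, slice thickness +/-0.5 mm,
#' in-plane distance +/-1.0 mm) are appended, and for the CT set the
#' absolute ACR limits as well.
#'
#' The CBCT bone-plug band is not derivable from the bundled summaries by
#' the same rule (2 x its recorded maximum SD of 29.1 HU is far wider
#' than any band a QA programme would run with); it is excluded unless an
#' explicit \code{bone_bound} is supplied.
#'
#' @param include_absolute append the absolute ACR limits.
#' @return a \code{tolerance_set}.
#' @export
tolerances_ct <- function(include_absolute = TRUE) {
  summ <- qa_summary_tables("CT")
  ms <- qa_max_sd_table("CT")
  ts <- rbind(
    tolerance_from_sds(data.frame(metric = summ$metric, sd = summ$sd)),
    tolerance_from_sds(data.frame(metric = ms$metric, sd = ms$max_sd),
                       provenance = "derived-2xmaxSD (summary)"),
    worst_case_rows(c("distance", "slice_thickness",
                      "highcontrast_lpcm"), c(1.0, 0.5, 1)))
  ts <- new_tolerance_set(ts)
  if (include_absolute) ts <- new_tolerance_set(rbind(
    ts, acr_absolute_limits()))
  ts
}

#' @param bone_bound optional explicit CBCT bone-plug HU band.
#' @rdname tolerances_ct
#' @export
tolerances_cbct <- function(include_absolute = FALSE, bone_bound = NULL) {
  summ <- qa_summary_tables("CBCT")
  ms <- qa_max_sd_table("CBCT")
  ms <- ms[ms$metric != "hu_bone", ]
  ts <- rbind(
    tolerance_from_sds(data.frame(metric = summ$metric, sd = summ$sd)),
    tolerance_from_sds(data.frame(metric = ms$metric, sd = ms$max_sd),
                       provenance = "derived-2xmaxSD (summary)"),
    worst_case_rows(c("slice_thickness", "highcontrast_lpcm"),
                    c(0.5, 1)))
  if (!is.null(bone_bound))
    ts <- rbind(ts, new_tolerance_set(data.frame(
      metric = "hu_bone", mode = "delta", bound = bone_bound,
      lo = NA_real_, hi = NA_real_, units = "HU",
      provenance = "explicit-config", rounding = "none",
      degenerate = FALSE, stringsAsFactors = FALSE)))
  ts <- new_tolerance_set(ts)
  if (include_absolute) ts <- new_tolerance_set(rbind(
    ts, acr_absolute_limits()))
  ts
}
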