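# Baselines, tolerance derivation (2 x maximum SD), session evaluation
# and longitudinal trending.

#' Round half away from zero
#'
#' Tolerance rounding rule: 2 x 3.1 = 6.2 rounds to 6 and 2 x 7.9 = 15.8
#' to 16 at 0 digits.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# decimal places used when rounding a derived tolerance, per metric class
tolerance_digits <- function(metric) {
  ifelse(grepl("^hu_", metric), 0,
    ifelse(grepl("^uniformity", metric), 1,
      ifelse(grepl("cnr", metric), 1,
        ifelse(grepl("^noise", metric), 2,
          ifelse(metric %in% c("distance", "slice_thickness"), 1,
            ifelse(metric == "highcontrast_lpcm", 0, 2))))))
}

new_tolerance_set <- function(df) {
  need <- c("metric", "mode", "bound", "lo", "hi", "units",
            "provenance", "rounding", "degenerate")
  for (m in setdiff(need, names(df)))
    df[[m]] <- switch(m, degenerate = FALSE, bound = NA_real_,
                      lo = NA_real_, hi = NA_real_, NA_character_)
  structure(df[need], class = c("tolerance_set", "data.frame"))
}

#' @export
print.tolerance_set <- function(x, ...) {
  cat("tolerance set (", nrow(x), " bounds)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (x$mode[i] == "delta") {
      cat(sprintf("  %-20s +/- %-8g %-6s [%s]%s\n", x$metric[i],
                  x$bound[i], x$units[i], x$provenance[i],
                  if (isTRUE(x$degenerate[i])) " (degenerate)" else ""))
    } else {
      cat(sprintf("  %-20s in [%g, %g] %-6s [%s]\n", x$metric[i],
                  x$lo[i], x$hi[i], x$units[i], x$provenance[i]))
    }
  }
  invisible(x)
}

units_for <- function(metric) {
  ifelse(grepl("^hu_|^uniformity", metric), "HU",
    ifelse(grepl("^noise", metric), "%",
      ifelse(metric %in% c("distance", "slice_thickness"), "mm",
        ifelse(metric == "highcontrast_lpcm", "lp/cm", ""))))
}

#' Derive delta tolerances from per-group standard deviations
#'
#' The core 2 x maximum-SD rule: for each metric the tolerance band is
#' twice the maximum standard deviation over all groups (machines x
#' protocols, within baseline segments), rounded per the metric's class
#' (nearest HU for HU metrics, one decimal for CNR, two for noise \%).
#'
#' @param sds data.frame with columns \code{metric} and \code{sd} (one
#'   row per group).
#' @param provenance provenance string recorded on each bound.
#' @return a \code{tolerance_set} (delta mode).
#' @export
tolerance_from_sds <- function(sds, provenance = "derived-2xmaxSD") {
  metrics <- unique(sds$metric)
  rows <- lapply(metrics, function(m) {
    s <- sds$sd[sds$metric == m]
    s <- s[is.finite(s)]
    if (!length(s)) return(NULL)
    digits <- tolerance_digits(m)
    data.frame(metric = m, mode = "delta",
               bound = round_half_away(2 * max(s), digits),
               lo = NA_real_, hi = NA_real_, units = units_for(m),
               provenance = provenance,
               rounding = paste0(digits, " decimals, half away from zero"),
               degenerate = max(s) == 0, stringsAsFactors = FALSE)
  })
  new_tolerance_set(do.call(rbind, rows))
}

#' Derive tolerances from a measurement history
#'
#' Computes the sample SD of each metric within every (machine, protocol,
#' segment) group having at least two records, then applies the
#' 2 x maximum-SD rule via \code{\link{tolerance_from_sds}}. Groups with
#' fewer than two records are skipped; metrics with no usable group are
#' dropped with a reason. An all-identical history yields tolerance 0
#' flagged degenerate.
#'
#' @param history data.frame with columns machine, protocol, metric,
#'   value and optionally segment (default one segment).
#' @return a \code{tolerance_set}; skipped metrics are in
#'   \code{attr(, "skipped")}.
#' @export
derive_tolerances <- function(history) {
  if (is.null(history$segment)) history$segment <- 1L
  grp <- interaction(history$machine, history$protocol,
                     history$segment, history$metric, drop = TRUE)
  sds <- do.call(rbind, lapply(split(history, grp), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(metric = d$metric[1], sd = stats::sd(d$value),
               stringsAsFactors = FALSE)
  }))
  skipped <- setdiff(unique(history$metric),
                     if (is.null(sds)) character() else unique(sds$metric))
  if (is.null(sds))
    stop("no group has >= 2 records; SD undefined everywhere")
  ts <- tolerance_from_sds(sds)
  attr(ts, "skipped") <- if (length(skipped))
    data.frame(metric = skipped,
               reason = "fewer than 2 records in every group") else NULL
  ts
}

#' Establish baseline values from a history segment
#'
#' The default baseline is the first session's value per metric; with
#' \code{k > 1} the mean of the first k sessions is used (preliminary
#' mode for a programme's first quarters).
#'
#' @param segment data.frame with columns metric, value and date (one row
#'   per metric per session), all from one baseline segment of one
#'   machine/protocol.
#' @param k number of initial sessions to average.
#' @param reason why this baseline was established.
#' @return data.frame(metric, baseline, date_established, reason, n_used).
#' @export
establish_baseline <- function(segment, k = 1,
                               reason = c("commissioning", "maintenance",
                                          "recalibration",
                                          "tube replacement")) {
  reason <- match.arg(reason)
  if (nrow(segment) == 0) stop("empty history segment")
  segment <- segment[order(segment$date), ]
  out <- do.call(rbind, lapply(split(segment, segment$metric),
                               function(d) {
    dates <- sort(unique(d$date))
    use <- d[d$date %in% dates[seq_len(min(k, length(dates)))], ]
    data.frame(metric = d$metric[1], baseline = mean(use$value),
               date_established = max(use$date), reason = reason,
               n_used = nrow(use), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate a QA session against baselines and tolerances
#'
#' Each tolerance bound is applied in its mode: delta bounds compare
#' |value - baseline| against the band (a deviation exactly equal to the
#' tolerance passes -- only results outside the band warrant action);
#' absolute bounds check the value against [lo, hi] inclusive. Metrics
#' without a baseline (delta mode) or not evaluable in the session get
#' status not-evaluable.
#'
#' @param session a \code{qa_session} (or a data.frame with columns
#'   metric, value, evaluable).
#' @param baselines data.frame(metric, baseline) from
#'   \code{\link{establish_baseline}}; may be NULL if only absolute
#'   bounds are evaluated.
#' @param tolerances a \code{tolerance_set}.
#' @return an object of class \code{qa_report}.
#' @export
evaluate_session <- function(session, baselines, tolerances) {
  m <- if (inherits(session, "qa_session")) session$metrics else session
  rows <- lapply(seq_len(nrow(tolerances)), function(i) {
    tl <- tolerances[i, ]
    j <- match(tl$metric, m$metric)
    val <- if (is.na(j)) NA_real_ else m$value[j]
    ok <- !is.na(j) && isTRUE(m$evaluable[j])
    base <- if (!is.null(baselines) && tl$metric %in% baselines$metric)
      baselines$baseline[match(tl$metric, baselines$metric)] else NA_real_
    if (!ok) {
      status <- "not-evaluable"; dev <- NA_real_
    } else if (tl$mode == "delta") {
      if (is.na(base)) {
        status <- "not-evaluable"; dev <- NA_real_
      } else {
        dev <- val - base
        status <- if (abs(dev) > tl$bound) "action" else "pass"
      }
    } else {
      dev <- NA_real_
      status <- if (val < tl$lo || val > tl$hi) "action" else "pass"
    }
    data.frame(metric = tl$metric, value = val, baseline = base,
               deviation = dev, mode = tl$mode, bound = tl$bound,
               lo = tl$lo, hi = tl$hi, units = tl$units,
               status = status, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("qa_report", "data.frame"))
}

#' @export
print.qa_report <- function(x, ...) {
  n_act <- sum(x$status == "action")
  cat(sprintf("QA report: %d bounds, %d pass, %d action, %d not-evaluable\n",
              nrow(x), sum(x$status == "pass"), n_act,
              sum(x$status == "not-evaluable")))
  for (i in seq_len(nrow(x))) {
    lim <- if (x$mode[i] == "delta")
      sprintf("+/-%g vs %.6g", x$bound[i], x$baseline[i])
    else sprintf("[%g, %g]", x$lo[i], x$hi[i])
    cat(sprintf("  %-20s %10.6g %-5s %-22s %s\n", x$metric[i],
                x$value[i], x$units[i], lim, toupper(x$status[i])))
  }
  invisible(x)
}

# ---- measurement history persistence --------------------------------------

#' Append a QA session to a measurement-history CSV
#'
#' The history store is a flat append-only CSV with one row per metric:
#' machine, modality, protocol, date, metric, value, segment.
#'
#' @param session a \code{qa_session}.
#' @param path CSV path (created with a header if missing).
#' @param segment baseline-segment id for these records.
#' @return invisibly, the rows appended.
#' @export
append_history <- function(session, path, segment = 1L) {
  df <- as.data.frame(session)
  rows <- data.frame(machine = df$machine, modality = df$modality,
                     protocol = df$protocol, date = df$date,
                     metric = df$metric, value = df$value,
                     segment = segment, stringsAsFactors = FALSE)
  rows <- rows[is.finite(rows$value), ]
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append =
                       file.exists(path), qmethod = "double")
  invisible(rows)
}

#' Read a measurement-history CSV
#'
#' Malformed rows (missing fields or non-numeric values) are skipped with
#' a warning reporting the count.
#'
#' @param path CSV path.
#' @return history data.frame.
#' @export
read_history <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("machine", "modality", "protocol", "date", "metric",
            "value", "segment")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("history is missing columns: ",
                         paste(miss, collapse = ", "))
  val <- suppressWarnings(as.numeric(h$value))
  seg <- suppressWarnings(as.integer(h$segment))
  bad <- !is.finite(val) | is.na(seg) | !nzchar(h$metric)
  if (any(bad))
    warning(sum(bad), " malformed history row(s) skipped")
  h <- h[!bad, ]
  h$value <- val[!bad]
  h$segment <- seg[!bad]
  h
}

#' Longitudinal trend report
#'
#' Per-metric time series grouped by machine and protocol, with
#' per-segment mean and SD and baseline-reset boundaries, renderable with
#' \code{plot()} as the classic HU-over-time QA chart (error bars 1 SD,
#' vertical lines at maintenance/recalibration resets).
#'
#' @param history a history data.frame (see \code{\link{read_history}}).
#' @return an object of class \code{trend_report}.
#' @export
trend_report <- function(history) {
  if (nrow(history) == 0) stop("empty history")
  grp <- interaction(history$machine, history$protocol, history$metric,
                     history$segment, drop = TRUE)
  summ <- do.call(rbind, lapply(split(history, grp), function(d) {
    data.frame(machine = d$machine[1], protocol = d$protocol[1],
               metric = d$metric[1], segment = d$segment[1],
               n = nrow(d), mean = mean(d$value),
               sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
               date_start = min(d$date), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(data = history,
                 summary = summ[order(summ$machine, summ$protocol,
                                      summ$metric, summ$segment), ]),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("trend report:", length(unique(x$data$metric)), "metrics,",
      length(unique(paste(x$data$machine, x$data$protocol))),
      "machine/protocol series\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @param x a \code{trend_report}.
#' @param metric metric id to plot.
#' @param machine optional machine filter.
#' @param ... passed to \code{plot}.
#' @rdname trend_report
#' @export
plot.trend_report <- function(x, metric, machine = NULL, ...) {
  d <- x$data[x$data$metric == metric, ]
  if (!is.null(machine)) d <- d[d$machine == machine, ]
  if (nrow(d) == 0) stop("no records for metric ", metric)
  d <- d[order(d$machine, d$protocol, d$date), ]
  keys <- unique(paste(d$machine, d$protocol))
  idx <- seq_len(nrow(d))
  ses <- match(d$date, sort(unique(d$date)))
  graphics::plot(ses, d$value, type = "n",
                 xlab = "session", ylab = paste(metric, units_for(metric)),
                 main = metric, ...)
  for (k in seq_along(keys)) {
    sel <- paste(d$machine, d$protocol) == keys[k]
    graphics::lines(ses[sel], d$value[sel], type = "b", col = k, pch = k)
    sg <- d$segment[sel]
    if (any(diff(sg) != 0)) {
      at <- ses[sel][which(diff(sg) != 0) + 1] - 0.5
      graphics::abline(v = at, lty = 2, col = "grey40")
    }
    for (s in unique(sg)) {
      v <- d$value[sel][sg == s]
      if (length(v) > 1) {
        m <- mean(v); sdev <- stats::sd(v)
        graphics::rect(min(ses[sel][sg == s]) - 0.2, m - sdev,
                       max(ses[sel][sg == s]) + 0.2, m + sdev,
                       border = NA,
                       col = grDevices::adjustcolor(k, alpha.f = 0.12))
      }
    }
  }
  graphics::legend("topleft", legend = keys, col = seq_along(keys),
                   pch = seq_along(keys), bty = "n", cex = 0.8)
  invisible(x)
}

#' Read / write a tolerance set as YAML
#'
#' @param tolerances a \code{tolerance_set}.
#' @param path YAML file path.
#' @return \code{read_tolerances} returns a \code{tolerance_set}.
#' @export
write_tolerances <- function(tolerances, path) {
  rows <- lapply(seq_len(nrow(tolerances)), function(i)
    as.list(tolerances[i, ]))
  yaml::write_yaml(rows, path)
  invisible(path)
}

#' @rdname write_tolerances
#' @export
read_tolerances <- function(path) {
  rows <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(rows, function(r) {
    r$bound <- if (is.null(r$bound)) NA_real_ else as.numeric(r$bound)
    r$lo <- if (is.null(r$lo)) NA_real_ else as.numeric(r$lo)
    r$hi <- if (is.null(r$hi)) NA_real_ else as.numeric(r$hi)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  new_tolerance_set(df)
}
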