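# Minimal DICOM codec for uncompressed axial CT series: explicit VR little
# endian, CT Image Storage, signed 16-bit pixels. Covers exactly the subset
# of the standard this package writes and the attributes the analyzer
# needs; anything else (compressed transfer syntaxes, non-axial
# orientations, mixed series) is rejected with an error naming the
# offending attribute.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.9.7432"

# ---- encoding -------------------------------------------------------------

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                   endian = "little")

dcm_pad <- function(val, pad = as.raw(0x20)) {
  if (length(val) %% 2L == 1L) val <- c(val, pad)
  val
}

# one data element, explicit VR little endian
dcm_element <- function(group, element, vr, value) {
  val <- switch(vr,
    US = dcm_uint16(value),
    UL = dcm_uint32(value),
    OB = as.raw(value),
    OW = value,  # already raw
    dcm_pad(charToRaw(as.character(value)),
            pad = if (vr == "UI") as.raw(0x00) else as.raw(0x20))
  )
  if (vr %in% c("OB", "OW")) val <- dcm_pad(val, as.raw(0x00))
  hdr <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(hdr, as.raw(c(0, 0)), dcm_uint32(length(val)), val)
  } else {
    c(hdr, dcm_uint16(length(val)), val)
  }
}

dcm_ds <- function(x) paste(vapply(x, function(v) sprintf("%.8g", v), ""),
                            collapse = "\\")

#' Write a phantom series as a DICOM series
#'
#' One CT Image Storage file per slice (explicit VR little endian,
#' uncompressed signed 16-bit, rescale slope 1 / intercept 0), carrying the
#' geometry and acquisition metadata \code{\link{read_series}} needs to
#' invert the operation exactly. HU values are rounded to integers on
#' write, which is lossless for CT data on the usual -1024..3071 scale.
#'
#' @param series a \code{\link{phantom_series}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "phantom_series"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  d <- dim(series$hu)
  half <- (c(d[2], d[1]) - 1) / 2 * series$pixel_spacing
  series_uid <- paste0(UID_ROOT, ".1.1")
  study_uid <- paste0(UID_ROOT, ".1.0")
  paths <- character(d[3])
  for (i in seq_len(d[3])) {
    sl <- round(series$hu[, , i])
    if (any(sl < -32768 | sl > 32767))
      stop("HU values outside the signed 16-bit stored range")
    px <- writeBin(as.integer(t(sl)), raw(), size = 2, endian = "little")
    sop_uid <- paste0(UID_ROOT, ".1.2.", i)
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0022, "DA", series$date),
      dcm_element(0x0008, 0x0060, "CS", series$modality),
      dcm_element(0x0008, 0x1010, "SH", series$machine),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(series$slice_thickness)),
      dcm_element(0x0018, 0x1030, "LO", series$protocol),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(i)),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_ds(c(-half[1], -half[2], series$z[i]))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[1]),
      dcm_element(0x0028, 0x0011, "US", d[2]),
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_ds(rep(series$pixel_spacing, 2))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", c(0L, 1L)),
      dcm_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
      dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".0.1"))
    )
    out <- c(raw(128), charToRaw("DICM"),
             dcm_element(0x0002, 0x0000, "UL", length(meta)), meta, body)
    paths[i] <- file.path(dir, sprintf("slice%04d.dcm", i))
    writeBin(out, paths[i])
  }
  invisible(paths)
}

# ---- decoding -------------------------------------------------------------

# parse all data elements of one file; returns named list keyed
# "GGGG,EEEE" with raw values plus parsed VR
dcm_parse <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", basename(path))
  pos <- 133L
  n <- length(buf)
  elems <- list()
  ts_checked <- FALSE
  while (pos + 8L <= n + 1L) {
    grp <- readBin(buf[pos:(pos + 1L)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    ele <- readBin(buf[(pos + 2L):(pos + 3L)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding at tag ",
           sprintf("%04X,%04X", grp, ele), " in ", basename(path))
    if (vr %in% c("OB", "OW", "OF", "UT", "UN", "SQ")) {
      len <- readBin(buf[(pos + 8L):(pos + 11L)], "integer", size = 4,
                     endian = "little")
      val_start <- pos + 12L
    } else {
      len <- readBin(buf[(pos + 6L):(pos + 7L)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      val_start <- pos + 8L
    }
    if (len < 0) stop("undefined-length element not supported in ",
                      basename(path))
    val <- if (len > 0) buf[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", grp, ele)
    elems[[key]] <- list(vr = vr, raw = val)
    if (grp > 0x0002 && !ts_checked) {
      ts <- dcm_string(elems, "0002,0010")
      if (!identical(ts, UID_EXPLICIT_LE))
        stop("unsupported TransferSyntaxUID '", ts, "' in ",
             basename(path))
      ts_checked <- TRUE
    }
    pos <- val_start + len + (len %% 2L == 1L)
  }
  elems
}

dcm_string <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  v <- e$raw
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}

dcm_numeric <- function(elems, key) {
  s <- dcm_string(elems, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_required <- function(x, attr_name, path) {
  if (is.null(x) || (is.character(x) && !nzchar(x)))
    stop("missing required DICOM attribute ", attr_name, " in ",
         basename(path))
  x
}

#' Read an axial DICOM series
#'
#' Reads every DICOM file in a directory as one axial CT/CBCT series:
#' stored values are mapped to HU through RescaleSlope/RescaleIntercept and
#' slices are sorted by ImagePositionPatient z ascending. Mixed matrix
#' sizes or spacings, missing spacing/rescale metadata and non-axial
#' orientations are rejected with an error naming the offending attribute.
#'
#' @param dir directory containing exactly one series.
#' @return a \code{\link{phantom_series}}.
#' @export
read_series <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  dcm <- files[grepl("\\.dcm$", files, ignore.case = TRUE)]
  if (length(dcm)) files <- dcm         # sidecar files are not slices
  if (length(files) == 0) stop("no files in directory: ", dir)
  slices <- lapply(files, function(f) {
    el <- dcm_parse(f)
    rows <- readBin(el[["0028,0010"]]$raw, "integer", size = 2,
                    endian = "little", signed = FALSE)
    cols <- readBin(el[["0028,0011"]]$raw, "integer", size = 2,
                    endian = "little", signed = FALSE)
    spacing <- dcm_required(dcm_numeric(el, "0028,0030"),
                            "PixelSpacing (0028,0030)", f)
    slope <- dcm_required(dcm_numeric(el, "0028,1053"),
                          "RescaleSlope (0028,1053)", f)
    intercept <- dcm_required(dcm_numeric(el, "0028,1052"),
                              "RescaleIntercept (0028,1052)", f)
    ipp <- dcm_required(dcm_numeric(el, "0020,0032"),
                        "ImagePositionPatient (0020,0032)", f)
    iop <- dcm_numeric(el, "0020,0037")
    if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("non-axial ImageOrientationPatient (0020,0037) in ",
           basename(f))
    px_raw <- dcm_required(el[["7FE0,0010"]], "PixelData (7FE0,0010)", f)$raw
    stored <- readBin(px_raw, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = TRUE)
    hu <- matrix(stored * slope[1] + intercept[1], nrow = rows,
                 byrow = TRUE)
    list(hu = hu, rows = rows, cols = cols, spacing = spacing[1],
         z = ipp[3],
         thickness = dcm_numeric(el, "0018,0050"),
         modality = dcm_string(el, "0008,0060"),
         protocol = dcm_string(el, "0018,1030"),
         machine = dcm_string(el, "0008,1010"),
         date = dcm_string(el, "0008,0022"),
         series_uid = dcm_string(el, "0020,000E"))
  })
  uid <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uid) > 1)
    stop("mixed series: multiple SeriesInstanceUID (0020,000E) values")
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols),
                          numeric(2))))
  if (nrow(dims) > 1)
    stop("mixed series: inconsistent Rows/Columns (0028,0010/0011)")
  sp <- unique(vapply(slices, function(s) s$spacing, 0))
  if (length(sp) > 1)
    stop("mixed series: inconsistent PixelSpacing (0028,0030)")
  ord <- order(vapply(slices, function(s) s$z, 0))
  slices <- slices[ord]
  hu <- array(0, dim = c(dims[1, 1], dims[1, 2], length(slices)))
  for (i in seq_along(slices)) hu[, , i] <- slices[[i]]$hu
  s1 <- slices[[1]]
  phantom_series(hu, pixel_spacing = sp,
                 slice_thickness = s1$thickness %||%
                   stats::median(diff(vapply(slices, `[[`, 0, "z"))),
                 z = vapply(slices, function(s) s$z, 0),
                 modality = s1$modality %||% "CT",
                 protocol = s1$protocol %||% "unknown",
                 machine = s1$machine %||% "unknown",
                 date = s1$date %||% "20000101")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
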