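# Readers and writers: NPY stacks, multi-page TIFF, timestamps JSON,
# ROI JSON, report JSON + TDC CSV.
#
# DICOM multiframe input is not supported in this implementation; supply the
# exported frames as a TIFF or NPY stack plus a timestamps JSON.

#' Read / write NPY arrays (version 1.0, numeric dtypes)
#'
#' Minimal NPY support sufficient for frame stacks: C-order or Fortran-order
#' arrays of little-endian float/integer dtypes are read; arrays are written
#' as C-order \code{<f8}.
#'
#' @param path file path.
#' @return \code{readNPY}: a numeric array; \code{writeNPY}: invisibly, path.
#' @export
readNPY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  n <- prod(shape)
  data <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i2" = readBin(con, "integer", n, size = 2, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2, signed = FALSE,
                    endian = "little"),
    "|u1" = as.integer(readBin(con, "raw", n)),
    stop("unsupported NPY dtype: ", descr))
  data <- as.numeric(data)
  if (length(shape) == 1L) return(data)
  if (fortran) array(data, dim = shape)
  else aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
}

#' @rdname readNPY
#' @param x numeric array or vector.
#' @export
writeNPY <- function(x, path) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  shape <- paste0("(", paste(d, collapse = ", "),
                  if (length(d) == 1L) "," else "", ")")
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                  shape)
  # total header (magic..dict+newline) padded with spaces to a multiple of 64
  base <- 10L + nchar(dict) + 1L
  pad <- (64L - base %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  v <- if (is.null(dim(x))) as.numeric(x)
       else as.numeric(aperm(x, rev(seq_along(d))))
  writeBin(v, con, size = 8, endian = "little")
  invisible(path)
}

#' Read / write a timestamps JSON sidecar
#'
#' Format: \code{{"timestamps_s": [0, 0.133, ...]}}.
#' @param path file path.
#' @return numeric vector of seconds.
#' @export
readTimestamps <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$timestamps_s)) stop("no 'timestamps_s' field in ", path)
  as.numeric(obj$timestamps_s)
}

#' @rdname readTimestamps
#' @param timestamps numeric vector of seconds.
#' @export
writeTimestamps <- function(timestamps, path) {
  jsonlite::write_json(list(timestamps_s = timestamps), path, digits = NA)
  invisible(path)
}

#' Read a dynamic DSA series from disk
#'
#' Accepts an NPY stack (T x H x W) or a multi-page TIFF; frame times come
#' from \code{timestamps} (a numeric vector or the path of a timestamps
#' JSON). Pixel values are converted to the canonical density convention:
#' larger value = more contrast, reference frame at t = 0 approximately zero.
#'
#' @param path stack file (.npy, .tif/.tiff).
#' @param timestamps numeric vector, path to a timestamps JSON, or NULL if
#'   \code{path} is an NPY written next to a \code{timestamps.json}.
#' @param view "AP" or "LAT".
#' @param invert invert pixel values on load (sources that render contrast
#'   dark); the flag is recorded in the series.
#' @param subtractBaseline subtract the t = 0 frame (default TRUE).
#' @return A [DSASeries-class].
#' @export
readSeries <- function(path, timestamps = NULL, view = c("AP", "LAT"),
                       invert = FALSE, subtractBaseline = TRUE) {
  view <- match.arg(view)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "npy") {
    a <- readNPY(path)
    if (length(dim(a)) != 3L) stop("NPY stack must be T x H x W")
    a
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    a <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (t in seq_along(pages)) a[t, , ] <- pages[[t]]
    a
  } else stop("unsupported container '", ext, "' (use .npy or .tif; ",
              "DICOM export is not supported, convert to TIFF/NPY first)")
  if (is.character(timestamps)) timestamps <- readTimestamps(timestamps)
  if (is.null(timestamps)) {
    side <- file.path(dirname(path), "timestamps.json")
    if (!file.exists(side))
      stop("timestamps are required (no frame-time vector in the container)")
    timestamps <- readTimestamps(side)
  }
  if (length(timestamps) != dim(arr)[1])
    stop(sprintf("frame count (%d) does not match timestamps (%d)",
                 dim(arr)[1], length(timestamps)))
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (invert) arr <- max(arr) - arr
  if (subtractBaseline) arr <- sweep(arr, 2:3, arr[1, , ])
  DSASeries(arr, timestamps, view = view, polarityInverted = invert,
            baselineSubtracted = subtractBaseline)
}

#' Write a series as an NPY stack plus timestamps JSON
#'
#' @param series a [DSASeries-class].
#' @param path output .npy path; \code{timestamps.json} is written alongside.
#' @export
writeSeriesNPY <- function(series, path) {
  writeNPY(series@frames, path)
  writeTimestamps(series@timestamps,
                  file.path(dirname(path), "timestamps.json"))
  invisible(path)
}

#' Write a series as a multi-page TIFF (16-bit, normalized)
#'
#' Densities are scaled to the unit interval by the global maximum before
#' writing (TDC shapes, TTP and FWHM are invariant to global scaling).
#'
#' @param series a [DSASeries-class].
#' @param path output .tif path.
#' @export
writeSeriesTIFF <- function(series, path) {
  arr <- series@frames
  lo <- min(arr); hi <- max(arr)
  arr <- if (hi > lo) (arr - lo) / (hi - lo) else arr * 0
  pages <- lapply(seq_len(dim(arr)[1]), function(t) arr[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read named ROIs from JSON
#'
#' Each region is \code{{"polygon": [[x, y], ...]}} (0-based pixel
#' coordinates) or \code{{"mask": {"shape": [H, W], "base64": "..."}}} with
#' row-major 0/1 bytes.
#'
#' @param path JSON file.
#' @return An [ROISet-class].
#' @export
readROIs <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  regions <- lapply(obj, function(r) {
    if (!is.null(r$polygon)) {
      xy <- r$polygon
      if (is.list(xy)) xy <- do.call(rbind, xy)
      list(type = "polygon", xy = matrix(as.numeric(xy), ncol = 2))
    } else if (!is.null(r$mask)) {
      raw <- jsonlite::base64_dec(r$mask$base64)
      H <- r$mask$shape[1]; W <- r$mask$shape[2]
      list(type = "mask",
           mask = matrix(as.integer(raw) > 0, nrow = H, ncol = W,
                         byrow = TRUE))
    } else stop("each ROI needs a 'polygon' or 'mask' field")
  })
  new("ROISet", regions = regions)
}

#' @rdname readROIs
#' @param rois an [ROISet-class].
#' @export
writeROIs <- function(rois, path) {
  out <- lapply(rois@regions, function(r) {
    if (r$type == "polygon") list(polygon = unname(r$xy))
    else list(mask = list(shape = dim(r$mask),
                          base64 = jsonlite::base64_enc(
                            as.raw(as.integer(t(r$mask))))))
  })
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Rasterize one ROI to a logical mask
#' @param rois an [ROISet-class].
#' @param name region name.
#' @param H,W frame dimensions.
#' @export
roiMask <- function(rois, name, H, W) {
  if (!(name %in% names(rois@regions))) stop("no ROI named '", name, "'")
  r <- rois@regions[[name]]
  m <- if (r$type == "mask") r$mask else {
    if (any(r$xy[, 1] < 0) || any(r$xy[, 1] > W - 1) ||
        any(r$xy[, 2] < 0) || any(r$xy[, 2] > H - 1))
      stop("ROI '", name, "' lies outside the frame bounds")
    rasterizePolygon(r$xy, H, W)
  }
  if (!all(dim(m) == c(H, W)))
    stop("ROI '", name, "' does not match the frame dimensions")
  if (!any(m)) stop("ROI '", name, "' rasterizes to an empty mask")
  m
}

#' Write a TDC as CSV
#'
#' Columns \code{t_s,density}.
#' @param tdc a [TDC-class].
#' @param path output CSV path.
#' @export
writeTDC <- function(tdc, path) {
  utils::write.csv(data.frame(t_s = tdc@timestamps, density = tdc@density),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTDC
#' @param label label for the curve read back.
#' @export
readTDC <- function(path, label = "tdc") {
  d <- utils::read.csv(path)
  new("TDC", timestamps = d$t_s, density = d$density, label = label,
      nPixels = NA_integer_)
}

fitToList <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(t0 = fit@t0, alpha = fit@alpha, beta = fit@beta, K = fit@K,
       baseline = fit@baseline, r2 = fit@rSquared, ttp_s = fit@ttp,
       fwhm_s = fit@fwhm, converged = fit@converged)
}

#' Write a marker report to JSON (+ TDC CSVs alongside)
#'
#' Emits flat \code{aMTT_AP} / \code{aMTT_Lat} keys (null when the view is
#' absent or invalid), a per-view block with fit parameters, \code{cct_s}
#' (null without ROIs), correlations and provenance. Every TDC held by the
#' report is exported as \code{<stem>_tdc_<label>.csv} next to the JSON.
#'
#' @param report a [MarkerReport-class].
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  amttOf <- function(v) {
    e <- report@views[[v]]
    if (is.null(e) || !isTRUE(e$valid)) NA_real_ else e$aMTT_s
  }
  viewBlock <- function(e) list(
    aMTT_s = if (isTRUE(e$valid)) e$aMTT_s else NA_real_,
    valid = isTRUE(e$valid),
    fit = fitToList(e$fit),
    warnings = if (length(e$warnings)) e$warnings else NULL)
  doc <- list(
    aMTT_AP = amttOf("AP"),
    aMTT_Lat = amttOf("LAT"),
    views = lapply(report@views, viewBlock),
    cct_s = if (is.null(report@cct)) NA_real_ else report@cct@cct,
    cct = if (is.null(report@cct)) NULL else list(
      ttp_artery_s = report@cct@ttpArtery, ttp_vein_s = report@cct@ttpVein,
      cct_s = report@cct@cct, method = report@cct@method),
    correlations = report@correlations,
    provenance = report@provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  stem <- sub("\\.json$", "", path)
  for (v in names(report@views)) {
    e <- report@views[[v]]
    for (tdc in e$tdcs)
      writeTDC(tdc, sprintf("%s_tdc_%s_%s.csv", stem, v, tdc@label))
  }
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) jsonlite::fromJSON(path)
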