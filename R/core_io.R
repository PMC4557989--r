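#' Construct an 8-bit RGB raster image
#'
#' The common currency of all image metrics: an H x W x 3 array of integer
#' intensities in \[0, 255\], optionally carrying an isotropic physical scale.
#' Pixel coordinates are 0-based, row-major, origin at the top-left corner.
#'
#' @param pixels numeric or integer array of dimension H x W x 3 with values
#'   in \[0, 255\]. A matrix (H x W) is replicated to 3 identical channels.
#' @param mm_per_px optional physical scale in millimetres per pixel (> 0).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, mm_per_px = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array (or an H x W matrix)")
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L)
    stop("image too small: need at least 16 x 16 pixels, got ",
         d[1], " x ", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (!is.null(mm_per_px)) {
    mm_per_px <- as.numeric(mm_per_px)
    if (length(mm_per_px) != 1L || !is.finite(mm_per_px) || mm_per_px <= 0)
      stop("mm_per_px must be a single positive number")
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px, bit_depth = 8L),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, 8-bit RGB%s\n", d[1], d[2],
              if (is.null(x$mm_per_px)) ""
              else sprintf(", %.4g mm/px", x$mm_per_px)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Construct a sampled emission spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths in nanometres, all
#'   within \[300, 1400\].
#' @param intensity non-negative intensities, same length as `wavelength_nm`.
#' @param units `"relative"` (arbitrary counts) or `"absolute"`
#'   (W cm^-2 nm^-1 sr^-1); hazard sums require absolute units.
#' @param delta_lambda_nm per-sample bin width in nm; defaults to the median
#'   wavelength spacing.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity,
                              units = c("relative", "absolute"),
                              delta_lambda_nm = NULL) {
  units <- match.arg(units)
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least 2 samples")
  if (length(intensity) != length(wavelength_nm))
    stop("wavelength and intensity lengths differ")
  if (anyNA(wavelength_nm) || anyNA(intensity))
    stop("spectrum contains missing values")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelength_nm) < 300 || max(wavelength_nm) > 1400)
    stop("wavelengths must lie within [300, 1400] nm")
  if (min(intensity) < 0)
    stop("intensities must be non-negative")
  if (is.null(delta_lambda_nm))
    delta_lambda_nm <- stats::median(diff(wavelength_nm))
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 units = units, delta_lambda_nm = as.numeric(delta_lambda_nm)),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d samples, %.0f-%.0f nm, units %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$units))
  invisible(x)
}

#' Construct a normalized luminance map
#'
#' @param values H x W numeric matrix in \[0, 1\], normalized to frame maximum.
#' @param mm_per_px optional physical scale, mm per pixel.
#' @return An object of class `luminance_map`.
#' @export
luminance_map <- function(values, mm_per_px = NULL) {
  if (!is.matrix(values)) stop("values must be an H x W matrix")
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop("luminance values must lie in [0, 1]")
  structure(list(values = values, mm_per_px = mm_per_px),
            class = "luminance_map")
}

# ---- image file I/O ---------------------------------------------------------

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png  = "png",
         jpg  = , jpeg = "jpeg",
         tif  = , tiff = "tiff",
         stop("unsupported image extension '", ext, "' for ", path))
}

#' Read an image file as an 8-bit RGB raster
#'
#' PNG, TIFF (uncompressed baseline) and JPEG are supported. 16-bit sources
#' are down-converted to 8 bits by integer division; grayscale is replicated
#' to three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param mm_per_px optional physical scale to attach, mm per pixel.
#' @return A [raster_image()].
#' @export
read_image <- function(path, mm_per_px = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  fmt <- img_format(path)
  px <- switch(fmt,
    png = {
      x <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e)
                      stop("cannot read PNG '", path, "': ",
                           conditionMessage(e), call. = FALSE))
      info <- attr(x, "info")
      if (!is.null(info) && identical(info$bit.depth, 16L))
        floor(x * 65535) %/% 256L
      else round(x * 255)
    },
    jpeg = {
      x <- tryCatch(jpeg::readJPEG(path),
                    error = function(e)
                      stop("cannot read JPEG '", path, "': ",
                           conditionMessage(e), call. = FALSE))
      round(x * 255)
    },
    tiff = read_tiff_raw(path)
  )
  px <- array(as.vector(px), dim = if (is.matrix(px)) c(dim(px), 1L)
                                   else dim(px))
  if (dim(px)[3] == 1L) px <- array(px, c(dim(px)[1:2], 3L))
  if (dim(px)[3] == 2L) px <- array(px[, , 1L], c(dim(px)[1:2], 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  raster_image(px, mm_per_px = mm_per_px)
}

#' Write an 8-bit RGB raster image
#'
#' @param image a [raster_image()].
#' @param path output path; format chosen by extension (.png/.tif/.tiff/.jpg).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  fmt <- img_format(path)
  switch(fmt,
         png  = png::writePNG(image$pixels / 255, path),
         jpeg = jpeg::writeJPEG(image$pixels / 255, path, quality = 1),
         tiff = write_tiff_raw(image$pixels, path))
  invisible(path)
}

# Minimal baseline TIFF codec (uncompressed, 8-bit gray or RGB, little- or
# big-endian, strip layout). No compression schemes: these files are QA
# fixtures, not archives.
read_tiff_raw <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("cannot read TIFF '", path, "': truncated file")
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("cannot read TIFF '", path, "': bad byte-order mark")
  rd <- function(off, what, n, size)
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = size >= 4)
  if (rd(2, "integer", 1, 2) != 42L)
    stop("cannot read TIFF '", path, "': not a TIFF file")
  ifd <- rd(4, "integer", 1, 4)
  nent <- rd(ifd, "integer", 1, 2)
  tags <- list()
  for (i in seq_len(nent)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd(e, "integer", 1, 2)
    typ <- rd(e + 2, "integer", 1, 2)
    cnt <- rd(e + 4, "integer", 1, 4)
    sz <- c(1, 1, 2, 4, 8)[typ]
    vals <- if (cnt * sz <= 4) {
      rd(e + 8, "integer", cnt, sz)
    } else {
      off <- rd(e + 8, "integer", 1, 4)
      rd(off, "integer", cnt, sz)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default))
        stop("cannot read TIFF '", path, "': missing tag ", tag)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bps <- need(258, 8L); comp <- need(259, 1L); spp <- need(277, 1L)
  if (comp != 1L)
    stop("cannot read TIFF '", path, "': only uncompressed TIFF supported")
  if (any(bps != 8L))
    stop("cannot read TIFF '", path, "': only 8 bits per sample supported")
  offs <- need(273); counts <- need(279, h * w * spp)
  bytes <- unlist(lapply(seq_along(offs), function(i)
    as.integer(raw[(offs[i] + 1):(offs[i] + counts[i])])))
  if (length(bytes) < h * w * spp)
    stop("cannot read TIFF '", path, "': truncated pixel data")
  # stored row-major interleaved; to H x W x C
  a <- aperm(array(bytes[seq_len(h * w * spp)], c(spp, w, h)), c(3, 2, 1))
  if (spp == 1L) a <- array(a, c(h, w, 3L))
  a[, , 1:3, drop = FALSE]
}

write_tiff_raw <- function(px, path) {
  d <- dim(px); h <- d[1]; w <- d[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeBin(charToRaw("II"), con); wr(42, 2); wr(8, 4)      # header, IFD at 8
  entries <- list( # tag, type (3=SHORT, 4=LONG), count, value-or-offset
    c(256, 4, 1, w), c(257, 4, 1, h), c(258, 3, 3, 134),
    c(259, 3, 1, 1), c(262, 3, 1, 2), c(273, 4, 1, 140),
    c(277, 3, 1, 3), c(278, 4, 1, h), c(279, 4, 1, w * h * 3),
    c(284, 3, 1, 1))
  wr(length(entries), 2)
  for (e in entries) { wr(e[1], 2); wr(e[2], 2); wr(e[3], 4); wr(e[4], 4) }
  wr(0, 4)                 # no next IFD -> IFD ends at 8 + 2 + 120 + 4 = 134
  wr(c(8, 8, 8), 2)        # BitsPerSample array at offset 134, data at 140
  inter <- aperm(px, c(3, 2, 1))   # channel-interleaved, row-major
  writeBin(as.raw(as.vector(inter)), con)
  invisible(path)
}

# ---- spectrum file I/O ------------------------------------------------------

#' Read a two-column emission-spectrum CSV
#'
#' Format: `wavelength_nm,intensity`, comma-delimited, optional header line,
#' `#` comment lines permitted. Rows are sorted by wavelength, duplicate
#' wavelengths averaged, and the bin width set to the median spacing.
#'
#' @param path path to the CSV file.
#' @param units unit flag to attach, `"relative"` (default) or `"absolute"`.
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path, units = c("relative", "absolute")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  rowno <- which(keep)
  if (length(lines) == 0L) stop("spectrum file is empty: ", path)
  parts <- strsplit(lines, ",")
  bad_shape <- vapply(parts, length, 1L) < 2L
  if (any(bad_shape))
    stop("spectrum parse error at row ", rowno[which(bad_shape)[1]],
         ": expected two comma-separated columns in ", path)
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  # a single non-numeric first row is a header
  if (is.na(wl[1]) && is.na(it[1]) && length(wl) > 1L) {
    wl <- wl[-1]; it <- it[-1]; rowno <- rowno[-1]
  }
  bad <- is.na(wl) | is.na(it)
  if (any(bad))
    stop("spectrum parse error at row ", rowno[which(bad)[1]],
         ": non-numeric value in ", path)
  if (length(wl) < 2L)
    stop("spectrum needs at least 2 data rows: ", path)
  o <- order(wl)
  wl <- wl[o]; it <- it[o]
  if (anyDuplicated(wl)) {
    it <- as.numeric(tapply(it, wl, mean))
    wl <- sort(unique(wl))
  }
  if (length(wl) < 2L)
    stop("spectrum needs at least 2 distinct wavelengths: ", path)
  emission_spectrum(wl, it, units = units)
}

#' Write an emission spectrum as two-column CSV
#'
#' @param spectrum an [emission_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  writeLines(c("wavelength_nm,intensity",
               paste(spectrum$wavelength_nm, spectrum$intensity, sep = ",")),
             path)
  invisible(path)
}

# ---- luminance --------------------------------------------------------------

# Un-normalized Rec.601 luma on 8-bit values; H x W matrix in [0, 255].
luma8 <- function(image) {
  px <- image$pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Normalized luminance map of an image
#'
#' Per-pixel Rec.601 luma (Y = 0.299 R + 0.587 G + 0.114 B) computed on the
#' 8-bit values, then divided by the frame maximum so the brightest pixel is
#' 1. An all-black frame maps to all zeros.
#'
#' @param image a [raster_image()].
#' @return A [luminance_map()]; inherits the image's `mm_per_px`.
#' @export
luminance <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  y <- luma8(image)
  m <- max(y)
  if (m > 0) y <- y / m
  luminance_map(y, mm_per_px = image$mm_per_px)
}
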