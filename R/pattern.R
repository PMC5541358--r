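#' Construct a SAXS pattern object
#'
#' A `saxs_pattern` holds a 2D grid of scattering intensities (detector
#' counts, arbitrary units) together with a validity mask. Invalid pixels
#' (beamstop flare, detector-module gaps, thresholded outliers) carry `NA`
#' intensity and `FALSE` in the mask; every valid pixel holds a finite value.
#'
#' Pixel coordinates are 1-based `(row, col)`; row increases downward, as the
#' image is displayed. All geometry in the package uses this convention.
#'
#' @param intensity numeric matrix of intensities. `NA`/non-finite entries
#'   are marked invalid.
#' @param valid optional logical matrix of the same shape; pixels flagged
#'   `FALSE` are invalidated in addition to non-finite ones.
#' @param source text identifier (usually the file name).
#' @return An object of class `saxs_pattern`: a list with elements
#'   `intensity` (matrix, `NA` at invalid pixels), `valid` (logical matrix),
#'   `source` and `shape`.
#' @export
saxs_pattern <- function(intensity, valid = NULL, source = "<memory>") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    saxs_validation_error("intensity must be a numeric matrix")
  storage.mode(intensity) <- "double"
  if (is.null(valid)) valid <- is.finite(intensity)
  if (!identical(dim(valid), dim(intensity)))
    saxs_validation_error("intensity and valid mask must have identical shape")
  valid <- valid & is.finite(intensity)
  intensity[!valid] <- NA_real_
  structure(list(intensity = intensity, valid = valid,
                 source = as.character(source), shape = dim(intensity)),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat(sprintf("SAXS pattern %s: %d x %d pixels, %d valid (%.1f%%)\n",
              x$source, x$shape[1], x$shape[2], sum(x$valid),
              100 * mean(x$valid)))
  v <- x$intensity[x$valid]
  if (length(v))
    cat(sprintf("  intensity range [%.6g, %.6g], mean %.6g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

# PNG stores its bit depth in byte 25 (1-based) of the file: 8-byte
# signature, then the IHDR chunk length/type (8) and width/height (8).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) saxs_format_error(paste0("truncated PNG: ", path))
  as.integer(hdr[25L])
}

collapse_channels <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  warning("multi-channel image collapsed to single channel by unweighted mean",
          call. = FALSE)
  apply(arr, c(1L, 2L), mean)
}

#' Load a detector image as a SAXS pattern
#'
#' Reads a TIFF, PNG or JPEG image into a [saxs_pattern()]. Integer pixel
#' types are promoted to real counts without rescaling (an 8/16-bit image
#' yields values on `0..2^bits-1`); float TIFFs are read as stored, with
#' `NaN` pixels marked invalid. Multi-channel (RGB) images are collapsed to
#' one channel by unweighted mean with a warning; scientific detector data
#' is expected to be single-channel.
#'
#' JPEG reading requires the EBImage package.
#'
#' @param path path to a TIFF (8/16/32-bit grayscale, incl. float), PNG or
#'   JPEG file.
#' @return A [saxs_pattern()] with all finite pixels valid.
#' @export
load_pattern <- function(path) {
  if (!file.exists(path)) saxs_io_error(paste0("cannot read file: ", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = {
      img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                      error = function(e)
                        saxs_io_error(paste0("unreadable TIFF ", path, ": ",
                                             conditionMessage(e))))
      fmt <- attr(img, "sample.format")
      bits <- attr(img, "bits.per.sample")
      img <- collapse_channels(unclass(img))
      if (is.null(fmt) || identical(fmt, "uint")) {
        # readTIFF normalizes integer samples to [0,1]; undo it.
        img <- round(img * (2^bits - 1))
      }
      img
    },
    png = {
      img <- tryCatch(png::readPNG(path),
                      error = function(e)
                        saxs_io_error(paste0("unreadable PNG ", path, ": ",
                                             conditionMessage(e))))
      bits <- png_bit_depth(path)
      round(collapse_channels(img) * (2^bits - 1))
    },
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        saxs_format_error("JPEG input requires the EBImage package")
      img <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                      error = function(e)
                        saxs_io_error(paste0("unreadable JPEG ", path, ": ",
                                             conditionMessage(e))))
      # EBImage stores (x, y [, channel]): transpose to (row, col).
      img <- if (length(dim(img)) == 3L) aperm(img, c(2L, 1L, 3L)) else t(img)
      round(collapse_channels(img) * 255)
    },
    saxs_format_error(paste0("unsupported image format: .", ext))
  )
  arr <- matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2])  # drop reader attrs
  saxs_pattern(arr, source = basename(path))
}

#' Write a SAXS pattern as a 32-bit float TIFF
#'
#' Emits an uncompressed little-endian 32-bit floating-point grayscale TIFF,
#' preserving raw intensity values (including values outside \[0, 1\]) at
#' single precision. Invalid pixels are stored as `NaN` and round-trip back
#' to invalid through [load_pattern()].
#'
#' @param p a [saxs_pattern()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(p, path) {
  stopifnot(inherits(p, "saxs_pattern"))
  m <- p$intensity
  m[!p$valid] <- NaN
  con <- tryCatch(file(path, "wb"),
                  error = function(e)
                    saxs_io_error(paste0("cannot write file: ", path)))
  on.exit(close(con))
  nr <- nrow(m); nc <- ncol(m); n <- nr * nc
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  data_off <- 8L
  writeBin(data_off + 4L * n, con, size = 4, endian = "little")  # IFD offset
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")   # scanlines
  tag <- function(id, type, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  writeBin(10L, con, size = 2, endian = "little")  # number of IFD entries
  tag(256, 4, nc)          # ImageWidth
  tag(257, 4, nr)          # ImageLength
  tag(258, 3, 32)          # BitsPerSample
  tag(259, 3, 1)           # Compression: none
  tag(262, 3, 1)           # Photometric: black is zero
  tag(273, 4, data_off)    # StripOffsets
  tag(277, 3, 1)           # SamplesPerPixel
  tag(278, 4, nr)          # RowsPerStrip
  tag(279, 4, 4L * n)      # StripByteCounts
  tag(339, 3, 3)           # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}
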