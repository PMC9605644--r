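#' Time-lapse frame container
#'
#' A frame is one image of a time-lapse sequence: a grayscale `H x W` matrix
#' or an RGB `H x W x 3` array of intensities on the 0-255 scale, together
#' with its non-negative sequence index and a source name. Frames in a
#' sequence must carry strictly increasing indices.
#'
#' @param pixels Numeric `H x W` matrix (grayscale) or `H x W x 3` array
#'   (RGB), intensities in `[0, 255]`.
#' @param index Non-negative integer frame number.
#' @param source_name Text identifier, typically the file name.
#' @return An object of class `gema_frame`.
#' @export
gema_frame <- function(pixels, index = 0L, source_name = "<memory>") {
  if (is.matrix(pixels)) {
    dims_ok <- all(dim(pixels) >= 1L)
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    dims_ok <- all(dim(pixels)[1:2] >= 1L) && dim(pixels)[3] == 3L
  } else {
    abort_gema("`pixels` must be an H x W matrix or an H x W x 3 array.",
               "gemaseg_validation_error")
  }
  if (!dims_ok) {
    abort_gema("Frame dimensions must satisfy H >= 1, W >= 1 (3 channels if RGB).",
               "gemaseg_validation_error")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort_gema("Frame intensities must lie in [0, 255].", "gemaseg_validation_error")
  }
  if (index < 0) {
    abort_gema("Frame index must be non-negative.", "gemaseg_validation_error")
  }
  structure(
    list(pixels = pixels, index = as.integer(index), source_name = source_name),
    class = "gema_frame"
  )
}

#' @export
print.gema_frame <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 2L) "grayscale" else "RGB"
  cat(sprintf("<gema_frame> %s %d x %d, index %d, source '%s'\n",
              kind, d[1], d[2], x$index, x$source_name))
  invisible(x)
}

# EBImage stores images as (x = width, y = height[, channel]); the package
# works row-major (H x W). These two helpers do the transposition once.
ebimage_to_pixels <- function(img) {
  dat <- EBImage::imageData(img)
  nd <- length(dim(dat))
  if (nd == 2L) {
    t(dat) * 255
  } else {
    nch <- dim(dat)[3]
    if (nch >= 4L) dat <- dat[, , 1:3, drop = FALSE] # drop alpha
    aperm(dat, c(2, 1, 3)) * 255
  }
}

pixels_to_ebimage <- function(pixels) {
  if (is.matrix(pixels)) {
    EBImage::Image(t(pixels) / 255)
  } else {
    EBImage::Image(aperm(pixels, c(2, 1, 3)) / 255, colormode = "Color")
  }
}

supported_image_ext <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Read an image file into a frame
#'
#' Decodes a PNG, JPEG or TIFF file (8- or 16-bit) into a [gema_frame()].
#' Intensities are returned on the 0-255 scale; 16-bit inputs are rescaled
#' linearly by the maximum of their sample type (not the per-image maximum,
#' so intensity statistics remain comparable across frames). Grayscale
#' images are kept 2-D.
#'
#' @param path Path to the image file.
#' @param index Frame index to attach (default 0).
#' @return A [gema_frame()].
#' @export
read_frame <- function(path, index = 0L) {
  if (!file.exists(path)) {
    abort_gema(sprintf("Cannot read image: file '%s' does not exist.", path),
               "gemaseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% supported_image_ext) {
    abort_gema(sprintf("Unsupported image format '%s' for '%s' (expected PNG/JPEG/TIFF).",
                       ext, path),
               "gemaseg_format_error")
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      abort_gema(sprintf("Failed to decode image '%s': %s", path, conditionMessage(e)),
                 "gemaseg_io_error")
    }
  )
  px <- ebimage_to_pixels(img)
  px <- clamp(px, 0, 255)
  gema_frame(px, index = index, source_name = basename(path))
}

#' Write a binary mask as a PNG file
#'
#' Foreground (1) pixels are written as 255, background (0) as 0.
#'
#' @param mask Binary `H x W` matrix with values in `{0, 1}`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Pixels above half intensity are foreground. Color PNGs are averaged to
#' grayscale before thresholding.
#'
#' @param path PNG path holding a `{0, 255}` mask.
#' @return Binary `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask_png <- function(path) {
  fr <- read_frame(path)
  px <- if (is.matrix(fr$pixels)) fr$pixels else to_grayscale(fr)
  (px > 127) + 0
}

validate_mask <- function(mask, arg = "mask") {
  assert_gray(mask, arg)
  if (!all(mask %in% c(0, 1))) {
    abort_gema(sprintf("`%s` must be binary with values in {0, 1}.", arg),
               "gemaseg_validation_error")
  }
  invisible(mask)
}
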