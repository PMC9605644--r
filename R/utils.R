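# Shared numeric helpers. All image grids in this package are base-R numeric
# matrices with rows = image rows (y) and columns = image columns (x),
# intensities on the 0-255 scale.

round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort_gema <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gemaseg_error"))
}

is_odd <- function(x) x %% 2 == 1

#' @keywords internal
assert_gray <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || !is.numeric(gray)) {
    abort_gema(sprintf("`%s` must be a numeric matrix (H x W grayscale grid).", arg),
               "gemaseg_validation_error")
  }
  invisible(gray)
}

# Reflective (mirror) padding by r pixels on every side. For r less than the
# image extent this is the classic symmetric border used by all convolutions
# and local filters in the package.
pad_reflect <- function(x, r) {
  if (r == 0) return(x)
  h <- nrow(x); w <- ncol(x)
  if (r >= h || r >= w) {
    # fall back to repeated reflection for very small images
    idx <- function(n) {
      i <- seq(-r + 1L, n + r)
      period <- 2L * n
      i <- ((i - 1L) %% period + period) %% period + 1L
      ifelse(i > n, period - i + 1L, i)
    }
    return(x[idx(h), idx(w), drop = FALSE])
  }
  x2 <- rbind(x[r:1, , drop = FALSE], x, x[h:(h - r + 1L), , drop = FALSE])
  cbind(x2[, r:1, drop = FALSE], x2, x2[, w:(w - r + 1L), drop = FALSE])
}

# Correlation of an image with an odd-sized kernel under a reflective border.
# EBImage::filter2 performs FFT convolution (kernel flipped); flipping the
# kernel once turns it back into correlation.
convolve_reflect <- function(x, kernel) {
  k <- nrow(kernel)
  stopifnot(k == ncol(kernel), is_odd(k))
  r <- (k - 1L) / 2L
  xp <- pad_reflect(x, r)
  flipped <- kernel[k:1, k:1, drop = FALSE]
  out <- EBImage::filter2(xp, flipped, boundary = "circular")
  out[(r + 1L):(r + nrow(x)), (r + 1L):(r + ncol(x)), drop = FALSE]
}

# Normalized 2-D Gaussian kernel of odd side `size` and standard deviation
# `sigma` (pixels). sigma = 0 returns the identity kernel.
gaussian_kernel <- function(size, sigma) {
  stopifnot(is_odd(size), size >= 1)
  r <- (size - 1) / 2
  if (sigma <= 0) {
    k <- matrix(0, size, size)
    k[r + 1, r + 1] <- 1
    return(k)
  }
  d <- seq(-r, r)
  g1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Natural-order sort of file names ("img2" before "img10").
natural_sort <- function(x) stringr::str_sort(x, numeric = TRUE)
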