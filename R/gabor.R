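#' Gabor filter bank configuration
#'
#' Parameterization of the oriented texture filters used by the adaptive
#' engine. A kernel is the real (even) part of a complex Gabor filter
#'
#' \deqn{g(x, y) = \frac{f^2}{\pi \gamma \eta}
#'   \exp\!\left(-\frac{x'^2 f^2}{\gamma^2} - \frac{y'^2 f^2}{\eta^2}\right)
#'   \cos(2 \pi f x')}
#'
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta}, evaluated on a `size x size` grid
#' whose coordinates span `[-1, 1]` along each axis, so `f` counts carrier
#' cycles per kernel half-width. The defaults are the four-orientation,
#' single-scale bank used for brightfield cell texture.
#'
#' @param f Spatial frequency (> 0; default 3.0).
#' @param size Odd kernel side length in pixels (default 21).
#' @param thetas Orientations in degrees, each in `[0, 180)`
#'   (default `c(0, 45, 90, 135)`).
#' @param gamma Sharpness along the major axis (> 0; default 10).
#' @param eta Sharpness along the minor axis (> 0; default 0.5).
#' @param n_scales Number of frequency scales (default 1; the only value
#'   used by the default pipeline).
#' @param combine How orientation responses are fused by
#'   [apply_gabor_bank()]: pixel-wise `"max"` (default) or `"sum"` of
#'   absolute responses.
#' @return A list of class `gema_gabor_config`.
#' @export
gabor_bank_config <- function(f = 3.0, size = 21L,
                              thetas = c(0, 45, 90, 135),
                              gamma = 10, eta = 0.5, n_scales = 1L,
                              combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (!is_odd(size) || size < 3) {
    abort_gema("Gabor kernel size must be odd and >= 3.", "gemaseg_validation_error")
  }
  if (f <= 0 || gamma <= 0 || eta <= 0) {
    abort_gema("Gabor parameters f, gamma, eta must be > 0.", "gemaseg_validation_error")
  }
  if (length(thetas) == 0 || any(thetas < 0 | thetas >= 180)) {
    abort_gema("Orientations must be non-empty and lie in [0, 180) degrees.",
               "gemaseg_validation_error")
  }
  structure(
    list(f = f, size = as.integer(size), thetas = thetas, gamma = gamma,
         eta = eta, n_scales = as.integer(n_scales), combine = combine),
    class = "gema_gabor_config"
  )
}

#' Build one Gabor kernel
#'
#' Evaluates the real part of the Gabor filter (see [gabor_bank_config()])
#' at orientation `theta` and removes the DC component by subtracting the
#' kernel mean, so constant image regions produce zero response. Before DC
#' removal the center value equals `f^2 / (pi * gamma * eta)`.
#'
#' @param config A [gabor_bank_config()].
#' @param theta Orientation in degrees.
#' @param dc_remove Subtract the kernel mean (default TRUE).
#' @return An object of class `gema_gabor_kernel` with fields `real_part`
#'   (`size x size` matrix) and `theta`.
#' @export
build_gabor_kernel <- function(config, theta, dc_remove = TRUE) {
  size <- config$size
  coord <- seq(-1, 1, length.out = size)
  X <- matrix(rep(coord, each = size), size, size)  # x varies along columns
  Y <- matrix(rep(coord, times = size), size, size) # y varies along rows
  th <- theta * pi / 180
  Xp <- X * cos(th) + Y * sin(th)
  Yp <- -X * sin(th) + Y * cos(th)
  f <- config$f
  g <- (f^2 / (pi * config$gamma * config$eta)) *
    exp(-(Xp^2 * f^2 / config$gamma^2 + Yp^2 * f^2 / config$eta^2)) *
    cos(2 * pi * f * Xp)
  if (dc_remove) g <- g - mean(g)
  structure(list(real_part = g, theta = theta), class = "gema_gabor_kernel")
}

#' Build the full Gabor bank
#'
#' One kernel per orientation in `config$thetas`, in the given order.
#'
#' @param config A [gabor_bank_config()].
#' @return List of [build_gabor_kernel()] results.
#' @export
build_gabor_bank <- function(config) {
  lapply(config$thetas, function(th) build_gabor_kernel(config, th))
}

#' Apply a Gabor bank to a grayscale image
#'
#' Correlates each kernel with the image under a reflective border and fuses
#' the orientation responses pixel-wise (maximum of absolute responses by
#' default, emphasizing the orientation with the highest response). The
#' fused response is rescaled linearly to `[0, 255]` by its per-frame
#' maximum; an identically zero response stays zero.
#'
#' @param gray `H x W` intensity matrix (preprocessed).
#' @param bank List of `gema_gabor_kernel` objects from [build_gabor_bank()].
#' @param combine `"max"` (default) or `"sum"` fusion of absolute responses.
#' @return `H x W` response matrix in `[0, 255]`.
#' @export
apply_gabor_bank <- function(gray, bank, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  assert_gray(gray)
  if (length(bank) == 0) {
    abort_gema("Gabor bank must contain at least one kernel.",
               "gemaseg_validation_error")
  }
  responses <- lapply(bank, function(k) abs(convolve_reflect(gray, k$real_part)))
  fused <- purrr::reduce(responses, if (combine == "max") pmax else `+`)
  m <- max(fused)
  # below FFT roundoff the response is indistinguishable from zero; rescaling
  # it would amplify numerical dust to full range
  if (m <= 1e-6) return(matrix(0, nrow(gray), ncol(gray)))
  fused * (255 / m)
}
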