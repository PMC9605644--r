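#' Structuring element
#'
#' Neighborhood shape for the morphological operators.
#'
#' @param size Odd side length / diameter in pixels (>= 3).
#' @param shape `"square"` (box) or `"disk"`.
#' @return A list of class `gema_se` holding a binary EBImage brush.
#' @export
struct_element <- function(size = 5L, shape = c("square", "disk")) {
  shape <- match.arg(shape)
  if (!is_odd(size) || size < 3) {
    abort_gema("Structuring element size must be odd and >= 3.",
               "gemaseg_validation_error")
  }
  brush <- EBImage::makeBrush(as.integer(size),
                              shape = if (shape == "square") "box" else "disc")
  structure(list(size = as.integer(size), shape = shape, brush = brush),
            class = "gema_se")
}

#' GEMA engine parameters
#'
#' Parameters of the adaptive binarization and the morphological cleanup.
#' The scheduled integer in `[5, 11]` is the offset subtracted from the
#' local mean, i.e. the constant of the adaptive threshold (a block size of
#' 5-11 px would be far smaller than a cell); the block size over which the
#' local mean is taken must exceed a cell diameter.
#'
#' @param adaptive_block_size Odd window size in pixels of the local-mean
#'   neighborhood (default 51).
#' @param threshold_c Integer threshold offset in `[5, 11]` (default 8;
#'   overwritten per frame by the controller inside [segment_gema()]).
#' @param closing_se,dilation_se Structuring elements of the binary closing
#'   and the final dilation (defaults 5x5 and 3x3 squares).
#' @param adaptive_method `"gaussian"` (Gaussian-weighted local mean,
#'   default) or `"mean"` (uniform local mean).
#' @param cv_source Whether the controller's CV is computed on the
#'   `"preprocessed"` (default) or `"raw"` grayscale frame.
#' @return A list of class `gema_params`.
#' @export
gema_params <- function(adaptive_block_size = 51L, threshold_c = 8L,
                        closing_se = struct_element(5L, "square"),
                        dilation_se = struct_element(3L, "square"),
                        adaptive_method = c("gaussian", "mean"),
                        cv_source = c("preprocessed", "raw")) {
  adaptive_method <- match.arg(adaptive_method)
  cv_source <- match.arg(cv_source)
  if (!is_odd(adaptive_block_size) || adaptive_block_size < 3) {
    abort_gema("Adaptive block size must be odd and >= 3.",
               "gemaseg_validation_error")
  }
  if (threshold_c < 5 || threshold_c > 11) {
    abort_gema("threshold_c must lie in [5, 11].", "gemaseg_validation_error")
  }
  structure(
    list(adaptive_block_size = as.integer(adaptive_block_size),
         threshold_c = as.integer(threshold_c),
         closing_se = closing_se, dilation_se = dilation_se,
         adaptive_method = adaptive_method, cv_source = cv_source),
    class = "gema_params"
  )
}

#' Morphological gradient
#'
#' The arithmetic difference between the dilation and the erosion of the
#' image under a structuring element: per pixel, local maximum minus local
#' minimum over the neighborhood (reflective border). Highlights local
#' intensity variation; flat regions map to zero.
#'
#' @param gray `H x W` intensity matrix.
#' @param se A [struct_element()] (default 5x5 square).
#' @return Non-negative `H x W` gradient matrix.
#' @export
morphological_gradient <- function(gray, se = struct_element(5L)) {
  assert_gray(gray)
  img <- gray / 255
  g <- EBImage::dilate(img, se$brush) - EBImage::erode(img, se$brush)
  g * 255
}

#' Gradient baseline segmentation
#'
#' The fixed-threshold baseline engine: grayscale conversion, shared
#' preprocessing, 5x5 morphological gradient, and binarization at a fixed
#' gradient threshold of 25 (strict inequality; ties go to background).
#'
#' @param frame A [gema_frame()].
#' @param preprocess A [preprocess_config()], or `NULL` to skip
#'   preprocessing.
#' @param se Structuring element of the gradient (default 5x5 square).
#' @param threshold Fixed gradient threshold (default 25).
#' @return Binary `H x W` mask.
#' @export
segment_gradient <- function(frame, preprocess = preprocess_config(),
                             se = struct_element(5L), threshold = 25) {
  gray <- to_grayscale(frame)
  if (!is.null(preprocess)) gray <- preprocess_frame(gray, preprocess)
  grad <- morphological_gradient(gray, se)
  (grad > threshold) + 0
}

#' Adaptive binarization of a texture response
#'
#' Local thresholding: the threshold at each pixel is the (Gaussian- or
#' uniformly-weighted) mean of the response over an odd `block_size`
#' neighborhood, and a pixel is foreground iff its response exceeds that
#' local mean by more than the integer offset `threshold_c`:
#' `response - local_mean > c`. Cells are the locally bright side of the
#' Gabor response, and a constant response yields an empty mask (an empty
#' chip must segment to 0% cells). The Gaussian window uses
#' `sd = block_size / 6` and a reflective border.
#'
#' @param response `H x W` response matrix in `[0, 255]`.
#' @param params A [gema_params()].
#' @return Binary `H x W` mask.
#' @export
adaptive_binarize <- function(response, params = gema_params()) {
  assert_gray(response, "response")
  k <- params$adaptive_block_size
  kernel <- if (params$adaptive_method == "gaussian") {
    gaussian_kernel(k, k / 6)
  } else {
    matrix(1 / k^2, k, k)
  }
  local_mean <- convolve_reflect(response, kernel)
  (response - local_mean > params$threshold_c) + 0
}

#' Morphological cleanup of a binary mask
#'
#' Binary closing (fill small background holes and bridge gaps between
#' nearby foreground fragments) followed by binary dilation (enlarge the
#' boundaries of foreground regions). Both operations are extensive on
#' binary images, so the input mask is always contained in the result.
#'
#' @param mask Binary `H x W` mask.
#' @param closing_se Structuring element of the closing, or `NULL` to skip.
#' @param dilation_se Structuring element of the dilation, or `NULL` to
#'   skip.
#' @return Binary `H x W` mask.
#' @export
morph_postprocess <- function(mask, closing_se = struct_element(5L),
                              dilation_se = struct_element(3L)) {
  validate_mask(mask)
  out <- mask
  if (!is.null(closing_se)) {
    out <- EBImage::closing(out, closing_se$brush)
  }
  if (!is.null(dilation_se)) {
    out <- EBImage::dilate(out, dilation_se$brush)
  }
  (out > 0.5) + 0
}

#' Adaptive (GEMA) segmentation of one frame
#'
#' Runs the full adaptive pipeline on one frame: grayscale conversion,
#' preprocessing, per-frame CV, controller update (which schedules the
#' integer threshold offset), Gabor-bank texture response, adaptive
#' binarization with the scheduled offset, and morphological cleanup. The
#' pipeline contains no randomness: identical inputs and state give
#' byte-identical masks.
#'
#' @param frame A [gema_frame()]; its index must follow the controller's
#'   history.
#' @param state A [controller()] state.
#' @param preprocess A [preprocess_config()].
#' @param bank Gabor bank from [build_gabor_bank()].
#' @param params A [gema_params()].
#' @param combine Orientation fusion passed to [apply_gabor_bank()].
#' @return A list with elements `mask` (binary matrix), `state` (updated
#'   controller) and `row` (one-row [gema_trace()] tibble).
#' @export
segment_gema <- function(frame, state, preprocess = preprocess_config(),
                         bank = build_gabor_bank(gabor_bank_config()),
                         params = gema_params(),
                         combine = c("max", "sum")) {
  combine <- match.arg(combine)
  gray <- to_grayscale(frame)
  pre <- preprocess_frame(gray, preprocess)
  cv_input <- if (params$cv_source == "preprocessed") pre else gray
  cv <- coefficient_of_variation(cv_input) # undefined-CV error propagates
  state <- update_controller(state, frame$index, cv)
  params$threshold_c <- state$current_threshold
  response <- apply_gabor_bank(pre, bank, combine)
  mask <- adaptive_binarize(response, params)
  mask <- morph_postprocess(mask, params$closing_se, params$dilation_se)
  row <- gema_trace(frame = frame$index, filename = frame$source_name,
                    cv = cv, threshold = state$current_threshold,
                    percent_cells = percent_cells(mask))
  list(mask = mask, state = state, row = row)
}
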