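#' Preprocessing configuration
#'
#' Parameters of the shared preprocessing stage applied by both segmentation
#' engines: contrast-limited adaptive histogram equalization (CLAHE)
#' followed by Gaussian smoothing.
#'
#' @param clahe_clip_limit Positive contrast clip limit, expressed as a
#'   multiple of the mean per-bin count of a tile histogram (default 2.0,
#'   the canonical CLAHE default).
#' @param clahe_tile_grid Integer vector `c(rows, cols)` of contextual tiles
#'   (default `c(8, 8)`).
#' @param gaussian_sigma Non-negative smoothing standard deviation in
#'   pixels (default 1.0); `0` skips smoothing.
#' @return A list of class `gema_preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(8L, 8L),
                              gaussian_sigma = 1.0) {
  if (clahe_clip_limit <= 0) {
    abort_gema("CLAHE clip limit must be > 0.", "gemaseg_validation_error")
  }
  if (length(clahe_tile_grid) != 2 || any(clahe_tile_grid < 1)) {
    abort_gema("CLAHE tile grid must be two integers >= 1.", "gemaseg_validation_error")
  }
  if (gaussian_sigma < 0) {
    abort_gema("Gaussian sigma must be >= 0.", "gemaseg_validation_error")
  }
  structure(
    list(clahe_clip_limit = clahe_clip_limit,
         clahe_tile_grid = as.integer(clahe_tile_grid),
         gaussian_sigma = gaussian_sigma),
    class = "gema_preprocess_config"
  )
}

#' Convert a frame to grayscale
#'
#' RGB frames are mapped pixel-wise to the unweighted channel mean
#' `I = (R + G + B) / 3`, rounded half-up to an integer in `[0, 255]`.
#' Grayscale input is returned unchanged.
#'
#' @param frame A [gema_frame()], or a raw pixel matrix/array.
#' @return `H x W` numeric matrix of intensities in `[0, 255]`.
#' @export
to_grayscale <- function(frame) {
  px <- if (inherits(frame, "gema_frame")) frame$pixels else frame
  if (is.matrix(px)) return(px)
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L) {
    abort_gema("Expected a grayscale matrix or an H x W x 3 RGB array.",
               "gemaseg_validation_error")
  }
  g <- (px[, , 1, drop = TRUE] + px[, , 2, drop = TRUE] +
          px[, , 3, drop = TRUE]) / 3
  matrix(clamp(round_half_up(g), 0, 255), dim(px)[1], dim(px)[2])
}

#' Preprocess a grayscale frame
#'
#' Applies CLAHE first, then Gaussian smoothing with a reflective border.
#' Output is rounded to integers in `[0, 255]` and keeps the input shape.
#'
#' @param gray `H x W` intensity matrix in `[0, 255]`.
#' @param config A [preprocess_config()].
#' @return Preprocessed `H x W` matrix, integers in `[0, 255]`.
#' @export
preprocess_frame <- function(gray, config = preprocess_config()) {
  assert_gray(gray)
  out <- clahe_equalize(gray, grid = config$clahe_tile_grid,
                        clip_limit = config$clahe_clip_limit)
  if (config$gaussian_sigma > 0) {
    out <- gaussian_smooth(out, config$gaussian_sigma)
  }
  clamp(round_half_up(out), 0, 255)
}

#' Gaussian smoothing with a reflective border
#'
#' Convolves with a normalized Gaussian kernel of radius `ceil(3 * sigma)`;
#' the normalized kernel and mirror border preserve the image mean up to
#' quantization.
#'
#' @param gray `H x W` intensity matrix.
#' @param sigma Standard deviation in pixels (> 0).
#' @return Smoothed matrix (not rounded).
#' @export
gaussian_smooth <- function(gray, sigma) {
  assert_gray(gray)
  stopifnot(sigma > 0)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  convolve_reflect(gray, gaussian_kernel(size, sigma))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic tile-based CLAHE on the 0-255 intensity scale: the image is
#' divided into a `rows x cols` grid of contextual tiles, each tile's
#' 256-bin histogram is clipped at `clip_limit` times the mean bin count
#' (the clipped excess is redistributed uniformly over all bins), each
#' clipped histogram defines a histogram-equalization lookup table, and
#' every pixel is remapped by bilinear interpolation between the tables of
#' the four nearest tile centers. With a single tile and a clip limit of at
#' least 256 this reduces to plain global histogram equalization. A
#' constant image maps to a constant image (within one gray level).
#'
#' @param gray `H x W` intensity matrix in `[0, 255]`.
#' @param grid Integer `c(rows, cols)` tile grid.
#' @param clip_limit Clip limit as a multiple of the mean bin count (> 0).
#' @return Equalized matrix, integers in `[0, 255]`.
#' @export
clahe_equalize <- function(gray, grid = c(8L, 8L), clip_limit = 2.0) {
  assert_gray(gray)
  h <- nrow(gray); w <- ncol(gray)
  nty <- min(as.integer(grid[1]), h)
  ntx <- min(as.integer(grid[2]), w)
  v <- floor(clamp(gray, 0, 255)) # bin index - 1
  row_edges <- tile_edges(h, nty)
  col_edges <- tile_edges(w, ntx)
  luts <- clahe_tile_luts(v, row_edges, col_edges, clip_limit)
  # bilinear interpolation between tile-center lookup tables
  ry <- interp_weights(seq_len(h), tile_centers(row_edges))
  rx <- interp_weights(seq_len(w), tile_centers(col_edges))
  tile_id <- function(ty, tx) (tx - 1L) * nty + ty
  V <- v + 1L
  lut_at <- function(ty_idx, tx_idx) {
    ids <- matrix(tile_id(rep(ty_idx, times = w), rep(tx_idx, each = h)), h, w)
    matrix(luts[cbind(as.vector(ids), as.vector(V))], h, w)
  }
  WY <- matrix(rep(ry$w, times = w), h, w)
  WX <- matrix(rep(rx$w, each = h), h, w)
  out <- (1 - WY) * (1 - WX) * lut_at(ry$lo, rx$lo) +
    (1 - WY) * WX * lut_at(ry$lo, rx$hi) +
    WY * (1 - WX) * lut_at(ry$hi, rx$lo) +
    WY * WX * lut_at(ry$hi, rx$hi)
  clamp(round_half_up(out), 0, 255)
}

# split n pixels into k near-equal tiles; returns (k+1) edge positions
tile_edges <- function(n, k) {
  edges <- round(seq(0, n, length.out = k + 1))
  as.integer(edges)
}

tile_centers <- function(edges) {
  (utils::head(edges, -1) + utils::tail(edges, -1) + 1) / 2
}

# per-tile clipped-histogram equalization lookup tables
# returns a (n_tiles x 256) matrix, tiles indexed column-major (ty fastest)
clahe_tile_luts <- function(v, row_edges, col_edges, clip_limit) {
  nty <- length(row_edges) - 1L
  ntx <- length(col_edges) - 1L
  luts <- matrix(0, nty * ntx, 256)
  for (tx in seq_len(ntx)) {
    for (ty in seq_len(nty)) {
      tile <- v[(row_edges[ty] + 1L):row_edges[ty + 1L],
                (col_edges[tx] + 1L):col_edges[tx + 1L], drop = FALSE]
      luts[(tx - 1L) * nty + ty, ] <- hist_equalize_lut(tile, clip_limit)
    }
  }
  luts
}

# histogram-equalization LUT of one tile with contrast clipping
hist_equalize_lut <- function(tile, clip_limit) {
  n <- length(tile)
  counts <- tabulate(as.vector(tile) + 1L, nbins = 256)
  limit <- clip_limit * n / 256
  excess <- sum(pmax(counts - limit, 0))
  counts <- pmin(counts, limit) + excess / 256
  cdf <- cumsum(counts) / n
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) {
    return(0:255) # single occupied bin and no redistribution: identity
  }
  clamp(round_half_up(255 * (cdf - cdf_min) / (1 - cdf_min)), 0, 255)
}

# for each query position, the two bracketing tile centers and the weight of
# the upper one; clamped to the nearest center outside the center range
interp_weights <- function(pos, centers) {
  k <- length(centers)
  if (k == 1L) {
    return(list(lo = rep(1L, length(pos)), hi = rep(1L, length(pos)),
                w = rep(0, length(pos))))
  }
  hi <- findInterval(pos, centers) + 1L
  hi <- clamp(hi, 2L, k)
  lo <- hi - 1L
  w <- (pos - centers[lo]) / (centers[hi] - centers[lo])
  list(lo = lo, hi = hi, w = clamp(w, 0, 1))
}
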