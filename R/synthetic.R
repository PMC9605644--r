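#' Synthetic time-lapse configuration
#'
#' Parameters of the seeded synthetic generator that emulates brightfield
#' frames of an adherent culture in a microfluidic chamber: textured
#' elliptical cells on a flat noisy background, with fractional coverage
#' ramping monotonically up toward confluence (`kind = "growth"`) or down
#' during drug-induced apoptosis (`kind = "apoptosis"`).
#'
#' Three features of real sequences are built in. Cells are rendered
#' brighter than the background, so the raw-frame coefficient of variation
#' declines as the culture approaches confluence (the mean rises faster
#' than the dispersion), reproducing the qualitative CV-versus-time shape
#' of real experiments. Intra-cell texture is a crossed pair of orthogonal
#' sinusoids at a random orientation, so a cell is visible to oriented
#' texture filters regardless of how it is rotated (intracellular granular
#' structure has no single dominant direction). And the texture contrast
#' fades as the monolayer packs: adherent cells flatten on contact
#' inhibition and lose optical contrast, which is what makes fixed-threshold
#' segmentation degrade near confluence while adaptive methods keep
#' working; the fade is a sigmoid in coverage so it acts mainly above the
#' decline midpoint.
#'
#' @param height,width Frame size in pixels (defaults 768 x 768).
#' @param n_frames Number of frames in a sequence (default 20).
#' @param kind `"growth"` or `"apoptosis"`.
#' @param coverage_start,coverage_end Fractional coverage of the first and
#'   last frame, in `[0, 1]` (defaults 0.1 and 0.9; reversed for
#'   apoptosis). Growth requires `start < end`, apoptosis `start > end`.
#' @param cell_radius_range Min/max ellipse semi-axis in pixels (default
#'   `c(75, 90)`): cell diameters well above the 21-px extent of the
#'   default texture filters, as in real fields of view where a cell spans
#'   many filter widths.
#' @param cell_texture_contrast Amplitude of the intra-cell intensity
#'   modulation at zero coverage (default 30).
#' @param cell_brightness Mean intensity offset of cells over the
#'   background (default 80).
#' @param background_level Flat background intensity (default 100).
#' @param noise_sd Additive Gaussian pixel noise, intensity units
#'   (default 2).
#' @param texture_wavelength_range Min/max texture wavelength in pixels
#'   (default `c(4, 8)`).
#' @param confluent_texture_factor Fraction of `cell_texture_contrast`
#'   remaining at full confluence (default 0.05).
#' @param texture_decline_midpoint Coverage at which the contrast fade is
#'   halfway (default 0.7).
#' @param texture_decline_rate Steepness of the sigmoidal fade
#'   (default 14).
#' @param seed Integer RNG seed (default 42).
#' @return A list of class `gema_synthetic_config`.
#' @export
synthetic_config <- function(height = 768L, width = 768L, n_frames = 20L,
                             kind = c("growth", "apoptosis"),
                             coverage_start = NULL, coverage_end = NULL,
                             cell_radius_range = c(75, 90),
                             cell_texture_contrast = 30,
                             cell_brightness = 80,
                             background_level = 100,
                             noise_sd = 2,
                             texture_wavelength_range = c(4, 8),
                             confluent_texture_factor = 0.05,
                             texture_decline_midpoint = 0.7,
                             texture_decline_rate = 14,
                             seed = 42L) {
  kind <- match.arg(kind)
  if (is.null(coverage_start)) coverage_start <- if (kind == "growth") 0.1 else 0.9
  if (is.null(coverage_end)) coverage_end <- if (kind == "growth") 0.9 else 0.1
  if (coverage_start < 0 || coverage_start > 1 ||
      coverage_end < 0 || coverage_end > 1) {
    abort_gema("Coverage fractions must lie in [0, 1].", "gemaseg_config_error")
  }
  if (kind == "growth" && coverage_start >= coverage_end) {
    abort_gema("Growth requires coverage_start < coverage_end.",
               "gemaseg_config_error")
  }
  if (kind == "apoptosis" && coverage_start <= coverage_end) {
    abort_gema("Apoptosis requires coverage_start > coverage_end.",
               "gemaseg_config_error")
  }
  if (min(cell_radius_range) > min(height, width)) {
    abort_gema("Cell radius exceeds the image size; coverage targets unreachable.",
               "gemaseg_config_error")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_frames = as.integer(n_frames), kind = kind,
         coverage_start = coverage_start, coverage_end = coverage_end,
         cell_radius_range = cell_radius_range,
         cell_texture_contrast = cell_texture_contrast,
         cell_brightness = cell_brightness,
         background_level = background_level, noise_sd = noise_sd,
         texture_wavelength_range = texture_wavelength_range,
         confluent_texture_factor = confluent_texture_factor,
         texture_decline_midpoint = texture_decline_midpoint,
         texture_decline_rate = texture_decline_rate,
         seed = as.integer(seed)),
    class = "gema_synthetic_config"
  )
}

# evaluate `code` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# texture contrast multiplier at a given coverage: sigmoidal fade toward the
# confluent floor (cells flatten and lose contrast as the monolayer packs)
contrast_scale <- function(config, coverage) {
  f <- config$confluent_texture_factor
  f + (1 - f) * stats::plogis(-config$texture_decline_rate *
                                (coverage - config$texture_decline_midpoint))
}

# one random textured ellipse; returns pixel indices and a unit-amplitude
# texture field (two orthogonal sinusoids, random orientation and phases)
draw_cell <- function(config) {
  h <- config$height; w <- config$width
  r <- config$cell_radius_range
  wl <- config$texture_wavelength_range
  cx <- stats::runif(1, 0, w - 1)
  cy <- stats::runif(1, 0, h - 1)
  rx <- stats::runif(1, r[1], r[2])
  ry <- stats::runif(1, r[1], r[2])
  ang <- stats::runif(1, 0, pi)
  lambda <- stats::runif(1, wl[1], wl[2])
  tex_ang <- stats::runif(1, 0, pi)
  phase1 <- stats::runif(1, 0, 2 * pi)
  phase2 <- stats::runif(1, 0, 2 * pi)
  rows <- max(1, floor(cy - max(rx, ry))):min(h, ceiling(cy + max(rx, ry)) + 1)
  cols <- max(1, floor(cx - max(rx, ry))):min(w, ceiling(cx + max(rx, ry)) + 1)
  X <- rep(cols - 1, each = length(rows))
  Y <- rep(rows - 1, times = length(cols))
  u <- (X - cx) * cos(ang) + (Y - cy) * sin(ang)
  v <- -(X - cx) * sin(ang) + (Y - cy) * cos(ang)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  ii <- rep(rows, times = length(cols))[inside]
  jj <- rep(cols, each = length(rows))[inside]
  idx <- ii + (jj - 1L) * h
  a1 <- X[inside] * cos(tex_ang) + Y[inside] * sin(tex_ang)
  a2 <- -X[inside] * sin(tex_ang) + Y[inside] * cos(tex_ang)
  tex <- (sin(2 * pi * a1 / lambda + phase1) +
            sin(2 * pi * a2 / lambda + phase2)) / sqrt(2)
  list(idx = idx, tex = tex)
}

# assemble one frame: background + brightness pedestal + scaled texture,
# then per-frame Gaussian noise under its own substream seed
render_frame <- function(mask, texfield, coverage, config, noise_seed) {
  amp <- config$cell_texture_contrast * contrast_scale(config, coverage)
  base <- config$background_level + config$cell_brightness * mask +
    amp * texfield
  noisy <- with_seed(noise_seed, {
    base + stats::rnorm(length(base), 0, config$noise_sd)
  })
  matrix(clamp(round_half_up(noisy), 0, 255), nrow(base), ncol(base))
}

noise_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Generate one synthetic frame at a target coverage
#'
#' Places random textured ellipses on the flat background until the union
#' mask's coverage is as close as possible to `target_coverage` (within
#' about half the area of one cell, inside the 2-percentage-point contract
#' for the default geometry), adds Gaussian pixel noise, and returns the
#' frame together with its exact ground-truth mask. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param target_coverage Fraction in `[0, 1]`; 0 and 1 are hit exactly.
#' @param index Frame index to attach.
#' @return List with `frame` (a [gema_frame()]), `mask` (binary matrix) and
#'   `coverage` (achieved fraction).
#' @export
generate_frame <- function(config, target_coverage, index = 0L) {
  if (target_coverage < 0 || target_coverage > 1) {
    abort_gema("target_coverage must lie in [0, 1].", "gemaseg_config_error")
  }
  with_seed(config$seed, {
    h <- config$height; w <- config$width
    nseed <- noise_seeds(1)
    mask <- matrix(0, h, w)
    texfield <- matrix(0, h, w)
    if (target_coverage >= 1) {
      X <- matrix(rep(0:(w - 1), each = h), h, w)
      Y <- matrix(rep(0:(h - 1), times = w), h, w)
      mask[] <- 1
      texfield <- sin(2 * pi * (X + Y) / 6)
    } else if (target_coverage > 0) {
      cells <- list()
      cov_k <- 0 # coverage after 0, 1, 2, ... cells
      repeat {
        cell <- draw_cell(config)
        cells[[length(cells) + 1L]] <- cell
        mask[cell$idx] <- 1
        cov_k <- c(cov_k, sum(mask) / (h * w))
        if (cov_k[length(cov_k)] >= target_coverage) break
      }
      k <- which.min(abs(cov_k - target_coverage)) - 1L
      mask <- matrix(0, h, w)
      for (i in seq_len(k)) {
        mask[cells[[i]]$idx] <- 1
        texfield[cells[[i]]$idx] <- cells[[i]]$tex
      }
    }
    coverage <- sum(mask) / length(mask)
    frame <- gema_frame(render_frame(mask, texfield, coverage, config, nseed),
                        index = index,
                        source_name = sprintf("synthetic_%04d.png", index))
    list(frame = frame, mask = mask, coverage = coverage)
  })
}

#' Generate a synthetic time-lapse sequence
#'
#' Coverage follows a logistic ramp from `coverage_start` to `coverage_end`
#' over `n_frames`. Cell positions persist from frame to frame: growth adds
#' cells incrementally to a fixed layout, apoptosis removes them, so
#' textures are temporally coherent. Ground-truth masks are exact unions of
#' the placed ellipses. Two runs with the same configuration produce
#' identical sequences.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `gema_synthetic_sequence` with elements
#'   `frames` (list of [gema_frame()]), `masks` (list of binary matrices),
#'   `coverage` (achieved fractions) and `target` (requested fractions).
#' @export
generate_sequence <- function(config) {
  if (config$n_frames < 2) {
    abort_gema("A sequence needs n_frames >= 2.", "gemaseg_config_error")
  }
  targets <- logistic_ramp(config$coverage_start, config$coverage_end,
                           config$n_frames)
  with_seed(config$seed, {
    h <- config$height; w <- config$width; n_px <- h * w
    nseeds <- noise_seeds(config$n_frames)
    cov_max <- max(targets)
    cells <- list()
    cov_k <- numeric(0)
    mask <- matrix(0, h, w)
    guard <- 0L
    while ((if (length(cov_k)) cov_k[length(cov_k)] else 0) < cov_max &&
           guard < 50000L) {
      guard <- guard + 1L
      cell <- draw_cell(config)
      cells[[length(cells) + 1L]] <- cell
      mask[cell$idx] <- 1
      cov_k <- c(cov_k, sum(mask) / n_px)
    }
    # nearest cumulative-cell-count k for each frame target (k = 0 allowed)
    cov_with0 <- c(0, cov_k)
    k_t <- vapply(targets, function(tg) which.min(abs(cov_with0 - tg)) - 1L,
                  integer(1))
    # enforce the monotone direction of the biological stage
    k_t <- if (config$kind == "growth") cummax(k_t) else rev(cummax(rev(k_t)))
    # render in increasing-k order so the layout is built incrementally;
    # growth visits frames first-to-last, apoptosis last-to-first
    order_t <- if (config$kind == "growth") seq_len(config$n_frames) else
      rev(seq_len(config$n_frames))
    frames <- vector("list", config$n_frames)
    masks <- vector("list", config$n_frames)
    coverage <- numeric(config$n_frames)
    mask <- matrix(0, h, w)
    texfield <- matrix(0, h, w)
    ki <- 0L
    for (t in order_t) {
      while (ki < k_t[t]) {
        ki <- ki + 1L
        cell <- cells[[ki]]
        mask[cell$idx] <- 1
        texfield[cell$idx] <- cell$tex
      }
      masks[[t]] <- mask
      coverage[t] <- sum(mask) / n_px
      frames[[t]] <- gema_frame(
        render_frame(mask, texfield, coverage[t], config, nseeds[t]),
        index = t - 1L, source_name = sprintf("synthetic_%04d.png", t - 1L))
    }
    structure(list(frames = frames, masks = masks, coverage = coverage,
                   target = targets, config = config),
              class = "gema_synthetic_sequence")
  })
}

logistic_ramp <- function(from, to, n, steepness = 8) {
  u <- seq(0, 1, length.out = n)
  s <- 1 / (1 + exp(-steepness * (u - 0.5)))
  s <- (s - s[1]) / (s[n] - s[1])
  from + (to - from) * s
}

#' Write a synthetic sequence to disk
#'
#' Frames and ground-truth masks as 8-bit grayscale PNGs
#' (`frame_0000.png`, `mask_0000.png`, masks with values `{0, 255}`) plus a
#' `manifest.csv` with columns `frame`, `filename`, `true_coverage`.
#'
#' @param sequence A [generate_sequence()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(sequence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(sequence$frames)
  fnames <- sprintf("frame_%04d.png", seq_len(n) - 1L)
  for (t in seq_len(n)) {
    EBImage::writeImage(pixels_to_ebimage(sequence$frames[[t]]$pixels),
                        file.path(dir, fnames[t]))
    write_mask_png(sequence$masks[[t]],
                   file.path(dir, sprintf("mask_%04d.png", t - 1L)))
  }
  readr::write_csv(
    tibble::tibble(frame = seq_len(n) - 1L, filename = fnames,
                   true_coverage = sequence$coverage),
    file.path(dir, "manifest.csv")
  )
  invisible(dir)
}
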