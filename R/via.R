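#' Read VIA polygon annotations
#'
#' Parses a VGG Image Annotator (VIA) JSON export and returns the regions
#' recorded for one image as a tibble of polygons. Both circulating dialects
#' are accepted and detected from the top-level keys: the full project file
#' (regions under `_via_img_metadata`) and the plain region-list export
#' (top level keyed by `filename + size`). Non-polygon shapes are converted
#' to polygonal approximations: rectangles to their 4 corners, circles and
#' ellipses to 32-vertex polygons. Coordinates follow VIA's convention:
#' `x` = column, `y` = row, 0-based, origin top-left.
#'
#' @param path Path to a VIA JSON file.
#' @param image_name File name of the annotated image (matched against the
#'   `filename` field).
#' @return A tibble with one row per region: `image_name`, `label`, `shape`,
#'   and a `vertices` list-column of tibbles with columns `x`, `y`. An image
#'   absent from the file yields a zero-row tibble (not an error).
#' @export
read_via_annotations <- function(path, image_name) {
  if (!file.exists(path)) {
    abort_gema(sprintf("VIA annotation file '%s' does not exist.", path),
               "gemaseg_io_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort_gema(sprintf("Malformed VIA JSON in '%s': %s", path, conditionMessage(e)),
                 "gemaseg_parse_error")
    }
  )
  metadata <- if (!is.null(doc[["_via_img_metadata"]])) {
    doc[["_via_img_metadata"]]
  } else {
    doc[!startsWith(names(doc), "_via_")]
  }
  rows <- purrr::map(metadata, function(entry) {
    if (is.null(entry$filename) || !identical(entry$filename, image_name)) return(NULL)
    purrr::map(entry$regions, function(region) {
      sa <- region$shape_attributes
      verts <- via_shape_to_polygon(sa)
      if (is.null(verts)) return(NULL)
      label <- ""
      ra <- region$region_attributes
      if (length(ra) > 0) label <- as.character(ra[[1]])[1]
      tibble::tibble(
        image_name = image_name, label = label,
        shape = sa$name %||% "polygon", vertices = list(verts)
      )
    })
  })
  rows <- purrr::compact(purrr::flatten(rows))
  if (length(rows) == 0) {
    return(tibble::tibble(image_name = character(), label = character(),
                          shape = character(), vertices = list()))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

via_shape_to_polygon <- function(sa, n_approx = 32L) {
  name <- sa$name %||% "polygon"
  if (name %in% c("polygon", "polyline")) {
    tibble::tibble(x = as.numeric(unlist(sa$all_points_x)),
                   y = as.numeric(unlist(sa$all_points_y)))
  } else if (name == "rect") {
    x <- sa$x; y <- sa$y; w <- sa$width; h <- sa$height
    tibble::tibble(x = c(x, x + w, x + w, x),
                   y = c(y, y, y + h, y + h))
  } else if (name %in% c("circle", "ellipse")) {
    rx <- if (name == "circle") sa$r else sa$rx
    ry <- if (name == "circle") sa$r else sa$ry
    theta <- (sa$theta %||% 0)
    t <- 2 * pi * (seq_len(n_approx) - 1) / n_approx
    ex <- rx * cos(t); ey <- ry * sin(t)
    tibble::tibble(x = sa$cx + ex * cos(theta) - ey * sin(theta),
                   y = sa$cy + ex * sin(theta) + ey * cos(theta))
  } else {
    NULL # point and other unsupported shapes carry no area
  }
}

#' Rasterize polygon annotations into a binary mask
#'
#' Fills the union of the given polygons on an `height x width` pixel grid.
#' A pixel belongs to the foreground iff its center lies inside or on the
#' boundary of at least one polygon (center-inside convention, boundary
#' counted as inside); the pixel at row `i`, column `j` (1-based) has its
#' center at the 0-based coordinate `(x = j - 1, y = i - 1)`. Polygons are
#' clipped to the image bounds implicitly.
#'
#' @param annotations Tibble as returned by [read_via_annotations()], or a
#'   list of data frames with columns `x`, `y`.
#' @param height,width Mask dimensions in pixels (>= 1).
#' @return Binary `height x width` matrix with values in `{0, 1}`.
#' @export
rasterize_polygons <- function(annotations, height, width) {
  stopifnot(height >= 1, width >= 1)
  polys <- if (is.data.frame(annotations)) annotations$vertices else annotations
  mask <- matrix(0, height, width)
  for (poly in polys) {
    px <- as.numeric(poly$x); py <- as.numeric(poly$y)
    if (length(px) < 3) {
      abort_gema("A polygon annotation needs at least 3 vertices.",
                 "gemaseg_validation_error")
    }
    mask <- mask | fill_polygon(px, py, height, width)
  }
  mask + 0
}

# Even-odd rule with an explicit on-boundary test, vectorized over the
# polygon's bounding-box pixels.
fill_polygon <- function(px, py, height, width, eps = 1e-9) {
  n <- length(px)
  rows <- max(1L, floor(min(py)) + 1L):min(height, ceiling(max(py)) + 1L)
  cols <- max(1L, floor(min(px)) + 1L):min(width, ceiling(max(px)) + 1L)
  out <- matrix(FALSE, height, width)
  if (min(py) > height - 1 || min(px) > width - 1 || max(py) < 0 || max(px) < 0) {
    return(out)
  }
  X <- matrix(rep(cols - 1, each = length(rows)), length(rows), length(cols))
  Y <- matrix(rep(rows - 1, times = length(cols)), length(rows), length(cols))
  inside <- matrix(FALSE, length(rows), length(cols))
  boundary <- matrix(FALSE, length(rows), length(cols))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # on-segment test: zero cross product and within the segment's box
    cross <- (xj - xi) * (Y - yi) - (yj - yi) * (X - xi)
    on_seg <- abs(cross) <= eps * (abs(xj - xi) + abs(yj - yi) + 1) &
      X >= pmin(xi, xj) - eps & X <= pmax(xi, xj) + eps &
      Y >= pmin(yi, yj) - eps & Y <= pmax(yi, yj) + eps
    boundary <- boundary | on_seg
    crosses <- ((yi > Y) != (yj > Y))
    if (any(crosses)) {
      xint <- xi + (Y - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (X < xint))
    }
    j <- i
  }
  out[rows, cols] <- inside | boundary
  out
}
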