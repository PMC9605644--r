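#' Experiment trace
#'
#' The per-frame record of a segmentation run: one row per processed frame,
#' ordered by frame index, with the frame's coefficient of variation, the
#' threshold parameter the engine used, and the percent of image area
#' classified as cells.
#'
#' @param frame Integer frame indices (strictly increasing).
#' @param filename Source file names.
#' @param cv Coefficient of variation of the frame (dimensionless, >= 0).
#' @param threshold Threshold parameter used (integer; in `[5, 11]` for the
#'   adaptive engine, the fixed gradient threshold for the baseline).
#' @param percent_cells Percent of image area covered by cells, in `[0, 100]`.
#' @return A tibble of class `gema_trace`.
#' @export
gema_trace <- function(frame = integer(), filename = character(),
                       cv = numeric(), threshold = integer(),
                       percent_cells = numeric()) {
  out <- tibble::tibble(
    frame = as.integer(frame), filename = as.character(filename),
    cv = as.numeric(cv), threshold = as.integer(threshold),
    percent_cells = as.numeric(percent_cells)
  )
  class(out) <- c("gema_trace", class(out))
  validate_trace(out)
}

validate_trace <- function(trace) {
  if (nrow(trace) > 0) {
    if (is.unsorted(trace$frame, strictly = TRUE)) {
      abort_gema("Trace frame indices must be strictly increasing.",
                 "gemaseg_validation_error")
    }
    if (any(trace$percent_cells < 0 | trace$percent_cells > 100)) {
      abort_gema("percent_cells must lie in [0, 100].", "gemaseg_validation_error")
    }
  }
  trace
}

as_gema_trace <- function(df) {
  gema_trace(df$frame, df$filename, df$cv, df$threshold, df$percent_cells)
}

#' Write an experiment trace to CSV
#'
#' Columns `frame,filename,cv,threshold,percent_cells`; floating-point
#' values keep full precision so a round-trip read reproduces them.
#'
#' @param trace A [gema_trace()] with at least one row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (nrow(trace) == 0) {
    abort_gema("Refusing to write an empty trace.", "gemaseg_validation_error")
  }
  validate_trace(trace)
  readr::write_csv(as.data.frame(trace), path)
  invisible(path)
}

#' Read an experiment trace from CSV
#'
#' @param path CSV written by [write_trace()].
#' @return A [gema_trace()] tibble.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), filename = readr::col_character(),
    cv = readr::col_double(), threshold = readr::col_integer(),
    percent_cells = readr::col_double()
  ))
  as_gema_trace(df)
}

#' Plot an experiment trace
#'
#' Shows the percent-area-covered-by-cells curve over frames, with the
#' coefficient of variation and the scheduled threshold as companion panels.
#'
#' @param object A [gema_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gema_trace <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~.data$quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL,
                  title = "Segmentation trace") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(trace) {
  dplyr::bind_rows(
    tibble::tibble(frame = trace$frame, quantity = "percent cells",
                   value = trace$percent_cells),
    tibble::tibble(frame = trace$frame, quantity = "coefficient of variation",
                   value = trace$cv),
    tibble::tibble(frame = trace$frame, quantity = "threshold parameter",
                   value = as.numeric(trace$threshold))
  )
}

#' @export
plot.gema_trace <- function(x, ...) print(autoplot.gema_trace(x, ...))
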