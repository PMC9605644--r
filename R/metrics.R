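#' Polygon area by the shoelace (Gaussian area) formula
#'
#' \deqn{A = \tfrac{1}{2} \left| \sum_i x_i y_{i+1} - \sum_i x_{i+1} y_i \right|}
#'
#' Works for convex and concave simple polygons; the absolute value makes
#' the result independent of vertex orientation (clockwise annotations and
#' counterclockwise ones agree).
#'
#' @param vertices Data frame (or list) with numeric `x`, `y` of at least
#'   3 ordered vertices.
#' @return Area in squared pixels.
#' @export
shoelace_area <- function(vertices) {
  x <- as.numeric(vertices$x); y <- as.numeric(vertices$y)
  if (length(x) < 3 || length(x) != length(y)) {
    abort_gema("shoelace_area needs >= 3 (x, y) vertices.",
               "gemaseg_validation_error")
  }
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn) - sum(xn * y)) / 2
}

#' Percent of image area covered by cells
#'
#' `100 * (number of foreground pixels) / (H * W)`.
#'
#' @param mask Binary `H x W` mask.
#' @return Percentage in `[0, 100]`.
#' @export
percent_cells <- function(mask) {
  validate_mask(mask)
  100 * sum(mask) / length(mask)
}

#' Pixel-wise confusion counts
#'
#' Counts true/false positives/negatives between a predicted and a gold
#' mask, with cell (1) as the positive class.
#'
#' @param predicted,gold Binary masks of identical shape.
#' @return A list of class `gema_confusion` with integer fields `tp`, `tn`,
#'   `fp`, `fn`, `n` (with `tp + tn + fp + fn = n`).
#' @export
confusion_counts <- function(predicted, gold) {
  validate_mask(predicted, "predicted")
  validate_mask(gold, "gold")
  if (!identical(dim(predicted), dim(gold))) {
    abort_gema("Predicted and gold masks must have identical shapes.",
               "gemaseg_validation_error")
  }
  tp <- sum(predicted == 1 & gold == 1)
  tn <- sum(predicted == 0 & gold == 0)
  fp <- sum(predicted == 1 & gold == 0)
  fn <- sum(predicted == 0 & gold == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = length(gold)),
            class = "gema_confusion")
}

#' Pixel accuracy
#'
#' `(TP + TN) / n`; counts true negatives, so background-heavy frames can
#' score high even with imperfect cell overlap.
#'
#' @param c A [confusion_counts()] result.
#' @return Accuracy in `[0, 1]`.
#' @export
pixel_accuracy <- function(c) {
  if (c$n == 0) abort_gema("Accuracy undefined for empty masks (n = 0).",
                           "gemaseg_validation_error")
  (c$tp + c$tn) / c$n
}

#' Dice score
#'
#' `2 TP / (2 TP + FP + FN)`, the overlap between predicted and gold
#' foreground. When both masks are empty (`tp = fp = fn = 0`) the score is
#' defined as 1.0 (perfect agreement on an empty frame); this convention is
#' reported with a message when triggered.
#'
#' @param c A [confusion_counts()] result.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) {
    message("Dice: both masks empty; returning 1 by convention.")
    return(1.0)
  }
  2 * c$tp / denom
}

#' Evaluate predicted masks against gold-standard masks
#'
#' Computes per-frame confusion counts, accuracy and Dice for paired mask
#' sequences, plus unweighted means across the evaluated frames.
#'
#' @param predicted,gold Lists of binary masks of equal length (pairwise
#'   identical shapes).
#' @param frames Frame indices to label the rows with (default `0, 1, ...`).
#' @param block If not `NULL`, evaluate only every `block`-th frame
#'   (positions 1, 1 + block, ...), mirroring gold standards annotated
#'   every N-th image.
#' @return A tibble of class `gema_evaluation` with columns `frame`, `tp`,
#'   `tn`, `fp`, `fn`, `accuracy`, `dice`; the unweighted means are stored
#'   in `attr(x, "summary")`.
#' @export
evaluate_masks <- function(predicted, gold, frames = seq_along(predicted) - 1L,
                           block = NULL) {
  if (length(predicted) != length(gold)) {
    abort_gema("Need as many predicted masks as gold masks.",
               "gemaseg_validation_error")
  }
  keep <- seq_along(predicted)
  if (!is.null(block)) keep <- seq(1L, length(predicted), by = as.integer(block))
  rows <- purrr::map(keep, function(i) {
    cc <- confusion_counts(predicted[[i]], gold[[i]])
    tibble::tibble(frame = frames[i], tp = cc$tp, tn = cc$tn, fp = cc$fp,
                   fn = cc$fn, accuracy = pixel_accuracy(cc),
                   dice = dice_score(cc))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- tibble::tibble(
    accuracy_mean = mean(out$accuracy), dice_mean = mean(out$dice),
    n_frames = nrow(out)
  )
  class(out) <- c("gema_evaluation", class(out))
  out
}

#' Write an evaluation report to CSV
#'
#' Per-frame rows followed by a `mean` summary row holding the unweighted
#' accuracy and Dice means.
#'
#' @param evaluation A [evaluate_masks()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  df <- as.data.frame(evaluation)
  s <- attr(evaluation, "summary")
  df$frame <- as.character(df$frame)
  df <- rbind(df, data.frame(frame = "mean", tp = NA, tn = NA, fp = NA, fn = NA,
                             accuracy = s$accuracy_mean, dice = s$dice_mean))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Plot an evaluation report
#'
#' Per-frame accuracy and Dice curves with their means as dashed lines.
#'
#' @param object A [evaluate_masks()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gema_evaluation <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(frame = object$frame, metric = "accuracy",
                   value = object$accuracy),
    tibble::tibble(frame = object$frame, metric = "dice", value = object$dice)
  )
  s <- attr(object, "summary")
  means <- tibble::tibble(metric = c("accuracy", "dice"),
                          value = c(s$accuracy_mean, s$dice_mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value,
                                     color = .data$metric),
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frame", y = "score",
                  title = "Segmentation vs gold standard") +
    ggplot2::theme_minimal()
}

#' @export
plot.gema_evaluation <- function(x, ...) print(autoplot.gema_evaluation(x, ...))
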