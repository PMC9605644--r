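#' Coefficient of variation of an image
#'
#' The ratio of the population standard deviation to the mean of all pixel
#' intensities, `CV = sigma / mu`. A scale-free dispersion measure: it is
#' invariant to positive rescaling of intensities and zero only for
#' constant images. The population (not sample) standard deviation is used:
#' the frame's pixels are the full population of interest.
#'
#' @param gray `H x W` intensity matrix with mean > 0.
#' @return The CV, a non-negative dimensionless number.
#' @export
coefficient_of_variation <- function(gray) {
  assert_gray(gray)
  mu <- mean(gray)
  if (mu <= 0) {
    abort_gema("CV undefined: image mean is not positive.", "gemaseg_undefined_cv")
  }
  sqrt(mean((gray - mu)^2)) / mu
}

#' Fit the CV-versus-frame regression
#'
#' Ordinary least squares of CV values `y` on frame indices `x`,
#' `Y = m X + b`. The fit error recorded with the model is the mean
#' absolute relative error `mean(|predicted - observed| / observed)` over
#' the fitted points (points with observed CV of zero are excluded from the
#' error average).
#'
#' @param points Data frame with numeric columns `x` (frame index) and `y`
#'   (CV value); at least 2 rows with distinct `x`.
#' @return An object of class `gema_cv_fit` with fields `m`, `b`,
#'   `fit_window` (tibble of the points used) and `fit_error`.
#' @export
fit_cv_regression <- function(points) {
  points <- tibble::as_tibble(points)[, c("x", "y")]
  if (nrow(points) < 2 || length(unique(points$x)) < 2) {
    abort_gema("Regression needs >= 2 points with distinct frame indices.",
               "gemaseg_degenerate_fit")
  }
  fit <- stats::lm(y ~ x, data = points)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  structure(
    list(m = m, b = b, fit_window = points,
         fit_error = relative_fit_error(m, b, points)),
    class = "gema_cv_fit"
  )
}

relative_fit_error <- function(m, b, points) {
  obs <- points$y
  keep <- obs > 0
  if (!any(keep)) return(NA_real_)
  pred <- m * points$x[keep] + b
  mean(abs(pred - obs[keep]) / obs[keep])
}

#' @export
print.gema_cv_fit <- function(x, ...) {
  cat(sprintf("<gema_cv_fit> CV = %.6g * frame + %.6g (n = %d, rel. error %.2f%%)\n",
              x$m, x$b, nrow(x$fit_window), 100 * x$fit_error))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CV regression fit
#'
#' @param x A `gema_cv_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.gema_cv_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"), estimate = c(x$b, x$m))
}

#' One-row fit summary of a CV regression
#'
#' @param x A `gema_cv_fit`.
#' @param ... Unused.
#' @return Tibble with columns `m`, `b`, `fit_error`, `n_points`.
#' @export
glance.gema_cv_fit <- function(x, ...) {
  tibble::tibble(m = x$m, b = x$b, fit_error = x$fit_error,
                 n_points = nrow(x$fit_window))
}

#' Create an adaptive-threshold controller
#'
#' The controller observes one CV value per frame, models the CV-vs-frame
#' relation with a (piecewise) linear regression, and schedules the integer
#' threshold parameter of the adaptive binarization in `[5, 11]`. Confluent
#' images binarize well near 5 and apoptotic images near 11; since both
#' regimes minimize the CV, the direction of the CV-to-threshold mapping is
#' an explicit `mode` input.
#'
#' @param mode `"growth"` (culture filling toward confluence; low CV maps
#'   to 5) or `"apoptosis"` (culture dying; low CV maps to 11).
#' @param refit_tolerance Mean absolute relative prediction error (fraction)
#'   above which the regression is refitted (default 0.05, i.e. 5%).
#' @param min_refit_window Minimum number of recent points used when
#'   monitoring the fit and refitting (default 5).
#' @param threshold_min,threshold_max Bounds of the scheduled integer
#'   parameter (defaults 5 and 11).
#' @param min_calibration_spread Minimum relative spread
#'   `(cv_max - cv_min) / cv_max` before the observed CV range counts as
#'   calibration (default 0.1); below it the cold-start endpoint is kept,
#'   so that two CV values differing only by noise do not swing the
#'   schedule to an extreme.
#' @return An object of class `gema_controller`.
#' @export
controller <- function(mode = c("growth", "apoptosis"),
                       refit_tolerance = 0.05, min_refit_window = 5L,
                       threshold_min = 5L, threshold_max = 11L,
                       min_calibration_spread = 0.1) {
  mode <- match.arg(mode)
  state <- structure(
    list(history = tibble::tibble(x = numeric(), y = numeric()),
         model = NULL, mode = mode,
         cv_min = Inf, cv_max = -Inf,
         min_calibration_spread = min_calibration_spread,
         refit_tolerance = refit_tolerance,
         min_refit_window = as.integer(min_refit_window),
         threshold_min = as.integer(threshold_min),
         threshold_max = as.integer(threshold_max),
         last_fit_row = 0L, n_refits = 0L, last_refit_x = NA_real_,
         current_threshold = NA_integer_),
    class = "gema_controller"
  )
  state$current_threshold <- cold_start_threshold(state)
  state
}

# before any calibration: a growth culture starts sparse (apoptotic-looking,
# high CV side), an apoptosis culture starts confluent
cold_start_threshold <- function(state) {
  if (state$mode == "growth") state$threshold_max else state$threshold_min
}

#' Schedule the adaptive-threshold parameter from a CV value
#'
#' Clamps `predicted_cv` to the calibration range `[cv_min, cv_max]`
#' observed so far and maps it linearly onto the integer threshold range,
#' rounding half-up. In growth mode low CV maps to the lower endpoint (5,
#' confluence) and high CV to the upper endpoint (11); in apoptosis mode
#' the direction is reversed. Before any calibration spread is available
#' the mode's cold-start endpoint is returned.
#'
#' @param state A [controller()] state.
#' @param predicted_cv CV value (typically the regression prediction).
#' @return Integer threshold in `[threshold_min, threshold_max]`.
#' @export
schedule_threshold <- function(state, predicted_cv) {
  lo <- state$threshold_min; hi <- state$threshold_max
  spread_ok <- is.finite(state$cv_min) && is.finite(state$cv_max) &&
    state$cv_max > 0 &&
    (state$cv_max - state$cv_min) / state$cv_max >
      (state$min_calibration_spread %||% 0)
  if (!spread_ok) {
    return(cold_start_threshold(state))
  }
  t <- (clamp(predicted_cv, state$cv_min, state$cv_max) - state$cv_min) /
    (state$cv_max - state$cv_min)
  value <- if (state$mode == "growth") lo + t * (hi - lo) else hi - t * (hi - lo)
  as.integer(clamp(round_half_up(value), lo, hi))
}

#' Feed one CV observation to the controller
#'
#' Appends the point to the history and updates the calibration bounds.
#' Once two points are available an initial regression is fitted;
#' afterwards the fit is monitored out-of-sample: the mean absolute
#' relative prediction error over the points that arrived since the model
#' was last fitted (capped at the most recent `min_refit_window` points,
#' and always including the new one). Whenever that error exceeds
#' `refit_tolerance`, the model is refitted on all points since the
#' previous fit, extended to at least `min_refit_window` recent points.
#' A noiseless linear series therefore triggers exactly one fit and no
#' refit, while drift away from the fitted segment (for example a level
#' shift) triggers a refit within a frame or two. The scheduled threshold
#' is then updated from the model's prediction at the new frame index.
#'
#' @param state A [controller()] state.
#' @param x Frame index, strictly greater than all indices seen so far.
#' @param cv Observed CV value (>= 0).
#' @return The updated `gema_controller` state; `state$current_threshold`
#'   holds the threshold to use for this frame.
#' @export
update_controller <- function(state, x, cv) {
  if (nrow(state$history) > 0 && x <= max(state$history$x)) {
    abort_gema("Frame indices fed to the controller must be strictly increasing.",
               "gemaseg_ordering_error")
  }
  if (cv < 0) abort_gema("CV must be >= 0.", "gemaseg_validation_error")
  state$history <- dplyr::bind_rows(state$history, tibble::tibble(x = x, y = cv))
  state$cv_min <- min(state$cv_min, cv)
  state$cv_max <- max(state$cv_max, cv)
  n <- nrow(state$history)
  if (is.null(state$model)) {
    if (n >= 2 && length(unique(state$history$x)) >= 2) {
      state$model <- fit_cv_regression(state$history)
      state$last_fit_row <- n
    }
  } else {
    # out-of-sample monitoring: points arrived since the last (re)fit,
    # capped at the most recent min_refit_window points
    from_mon <- max(state$last_fit_row + 1L, n - state$min_refit_window + 1L)
    monitor <- state$history[from_mon:n, ]
    err <- relative_fit_error(state$model$m, state$model$b, monitor)
    if (!is.na(err) && err > state$refit_tolerance) {
      from <- max(1L, min(state$last_fit_row + 1L,
                          n - state$min_refit_window + 1L))
      window <- state$history[from:n, ]
      if (length(unique(window$x)) >= 2) {
        state$model <- fit_cv_regression(window)
        state$last_fit_row <- n
        state$n_refits <- state$n_refits + 1L
        state$last_refit_x <- x
      }
    } else {
      state$model$fit_error <- err
    }
  }
  state$current_threshold <- if (is.null(state$model)) {
    cold_start_threshold(state)
  } else {
    schedule_threshold(state, state$model$m * x + state$model$b)
  }
  state
}

#' @export
print.gema_controller <- function(x, ...) {
  cat(sprintf(
    "<gema_controller> mode %s, %d point(s), threshold %s, %d refit(s)\n",
    x$mode, nrow(x$history),
    ifelse(is.na(x$current_threshold), "?", x$current_threshold), x$n_refits))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
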