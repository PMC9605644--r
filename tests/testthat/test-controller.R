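test_that("coefficient of variation uses population moments", {
  expect_equal(coefficient_of_variation(matrix(42, 5, 5)), 0)
  img <- matrix(c(2, 4, 4, 4, 5, 5, 7, 9), 2, 4) # mu = 5, population sd = 2
  expect_equal(coefficient_of_variation(img), 0.4, tolerance = 1e-12)
  expect_equal(coefficient_of_variation(img * 3.7),
               coefficient_of_variation(img), tolerance = 1e-12)
  expect_error(coefficient_of_variation(matrix(0, 3, 3)),
               class = "gemaseg_undefined_cv")
})

test_that("OLS fit recovers exact lines and hand-computed degenerate cases", {
  fit <- fit_cv_regression(data.frame(x = 0:2, y = c(1, 3, 5)))
  expect_equal(fit$m, 2, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$fit_error, 0, tolerance = 1e-12)

  fit2 <- fit_cv_regression(data.frame(x = 0:2, y = c(0, 1, 0)))
  expect_equal(fit2$m, 0, tolerance = 1e-12)
  expect_equal(fit2$b, 1 / 3, tolerance = 1e-12)

  expect_error(fit_cv_regression(data.frame(x = 1, y = 1)),
               class = "gemaseg_degenerate_fit")
  expect_error(fit_cv_regression(data.frame(x = c(2, 2, 2), y = 1:3)),
               class = "gemaseg_degenerate_fit")
})

test_that("OLS agrees with a brute-force grid-search oracle", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    x <- sort(runif(n, 0, 10))
    y <- runif(n, 0, 5)
    fit <- fit_cv_regression(data.frame(x = x, y = y))
    oracle <- oracle_grid_ols(x, y)
    expect_equal(fit$m, unname(oracle["m"]), tolerance = 1e-3)
    expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-3)
  }
})

test_that("tidy and glance expose slope and intercept", {
  fit <- fit_cv_regression(data.frame(x = 0:3, y = c(1, 2, 3.1, 3.9)))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- generics::glance(fit)
  expect_named(gl, c("m", "b", "fit_error", "n_points"))
  expect_equal(gl$n_points, 4L)
})

test_that("noisy lines are recovered within 5% in at least 95/100 replicates", {
  m_true <- 0.002; b_true <- 0.25
  set.seed(1234)
  ok <- 0L
  for (rep in 1:100) {
    x <- 0:199
    y <- m_true * x + b_true + rnorm(200, 0, 0.01 * abs(b_true))
    fit <- fit_cv_regression(data.frame(x = x, y = y))
    if (abs(fit$m - m_true) <= 0.05 * abs(m_true) &&
        abs(fit$b - b_true) <= 0.05 * abs(b_true)) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 95L)
})

calibrated_state <- function(mode, cv_min = 0.1, cv_max = 0.3) {
  st <- controller(mode)
  st$cv_min <- cv_min
  st$cv_max <- cv_max
  st
}

test_that("threshold schedule hits the stage endpoints and the midpoint", {
  growth <- calibrated_state("growth")
  expect_equal(schedule_threshold(growth, 0.1), 5L)  # confluence endpoint
  expect_equal(schedule_threshold(growth, 0.3), 11L)
  expect_equal(schedule_threshold(growth, 0.2), 8L)  # linear midpoint
  apo <- calibrated_state("apoptosis")
  expect_equal(schedule_threshold(apo, 0.1), 11L)    # apoptosis endpoint
  expect_equal(schedule_threshold(apo, 0.3), 5L)
})

test_that("the schedule is monotone, integer, bounded, and clamps out-of-range CV", {
  growth <- calibrated_state("growth")
  apo <- calibrated_state("apoptosis")
  cvs <- seq(0, 0.5, by = 0.01)
  tg <- vapply(cvs, function(v) schedule_threshold(growth, v), integer(1))
  ta <- vapply(cvs, function(v) schedule_threshold(apo, v), integer(1))
  expect_true(all(tg %in% 5:11) && all(ta %in% 5:11))
  expect_true(all(diff(tg) >= 0))
  expect_true(all(diff(ta) <= 0))
  expect_equal(tg[1], 5L)   # below cv_min clamps to the low end
  expect_equal(tg[length(tg)], 11L)
})

test_that("before calibration the cold-start endpoint is used", {
  expect_equal(controller("growth")$current_threshold, 11L)
  expect_equal(controller("apoptosis")$current_threshold, 5L)
  # a negligible CV spread is still cold start
  st <- controller("growth")
  st <- update_controller(st, 0, 0.2000)
  st <- update_controller(st, 1, 0.2001)
  expect_equal(st$current_threshold, 11L)
})

test_that("a noiseless linear CV series is fitted once and never refitted", {
  st <- controller("growth", min_calibration_spread = 0)
  for (i in 0:19) st <- update_controller(st, i, 0.3 - 0.01 * i)
  expect_equal(st$n_refits, 0L)
  expect_equal(st$model$m, -0.01, tolerance = 1e-9)
  expect_equal(st$model$b, 0.3, tolerance = 1e-9)
  # predictions follow the line: final frame is the calibration minimum -> 5
  expect_equal(st$current_threshold, 5L)
})

test_that("a level shift triggers a refit within two frames", {
  st <- controller("growth")
  k <- 15L
  first_refit <- NA_integer_
  for (i in 0:29) {
    cv <- 0.2 + 0.001 * i
    if (i >= k) cv <- 2 * (0.2 + 0.001 * i)
    st <- update_controller(st, i, cv)
    if (i < k) expect_equal(st$n_refits, 0L)
    if (is.na(first_refit) && st$n_refits > 0) first_refit <- i
  }
  expect_false(is.na(first_refit))
  expect_lte(first_refit, k + 2)
  # and the model ends up tracking the shifted series
  expect_lt(st$model$fit_error, 0.06)
})

test_that("controller rejects out-of-order frames and negative CV", {
  st <- controller("growth")
  st <- update_controller(st, 5, 0.2)
  expect_error(update_controller(st, 5, 0.2), class = "gemaseg_ordering_error")
  expect_error(update_controller(st, 4, 0.2), class = "gemaseg_ordering_error")
  expect_error(update_controller(st, 6, -0.1),
               class = "gemaseg_validation_error")
})
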