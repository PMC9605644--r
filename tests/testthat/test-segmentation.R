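test_that("morphological gradient matches hand-derived cases", {
  expect_equal(morphological_gradient(matrix(7, 9, 9)), matrix(0, 9, 9))

  img <- matrix(0, 9, 9)
  img[5, 5] <- 255
  g <- morphological_gradient(img, struct_element(3))
  expect_true(all(g[4:6, 4:6] == 255))
  g[4:6, 4:6] <- 0
  expect_true(all(g == 0))
})

test_that("morphological gradient equals the sliding-window oracle", {
  set.seed(51)
  for (rep in 1:8) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    for (k in c(3, 5)) {
      expect_equal(morphological_gradient(img, struct_element(k)),
                   oracle_gradient(img, k), tolerance = 1e-9)
    }
  }
})

test_that("gradient baseline binarizes at a strict fixed threshold", {
  const <- make_gray_frame(matrix(90, 32, 32))
  expect_equal(segment_gradient(const), matrix(0, 32, 32))
  expect_equal(segment_gradient(const, preprocess = NULL), matrix(0, 32, 32))

  img <- matrix(0, 32, 32)
  img[10:22, 10:22] <- 200
  mask <- segment_gradient(make_gray_frame(img), preprocess = NULL)
  expect_equal(mask[16, 16], 0) # flat interior beyond the SE reach
  expect_equal(mask[2, 2], 0)   # flat exterior
  expect_equal(mask[10, 16], 1) # boundary band
  # gradient of an 8-bit image never exceeds 255, so threshold 255 blanks all
  noisy <- make_gray_frame(matrix(sample(0:255, 1024, replace = TRUE), 32, 32))
  expect_equal(segment_gradient(noisy, preprocess = NULL, threshold = 255),
               matrix(0, 32, 32))
})

test_that("adaptive binarization keeps constants empty and is monotone in c", {
  p <- gema_params(adaptive_block_size = 15L)
  expect_equal(adaptive_binarize(matrix(200, 20, 20), p), matrix(0, 20, 20))

  set.seed(61)
  resp <- matrix(runif(400, 0, 255), 20, 20)
  m5 <- adaptive_binarize(resp, gema_params(adaptive_block_size = 15L,
                                            threshold_c = 5L))
  m11 <- adaptive_binarize(resp, gema_params(adaptive_block_size = 15L,
                                             threshold_c = 11L))
  expect_true(all(m11 <= m5)) # mask(c=11) is a subset of mask(c=5)
  expect_error(gema_params(adaptive_block_size = 10L),
               class = "gemaseg_validation_error")
  expect_error(gema_params(threshold_c = 4L),
               class = "gemaseg_validation_error")
})

test_that("a bright blob on a dark background is segmented by the adaptive rule", {
  resp <- matrix(0, 60, 60)
  d2 <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+")
  resp[d2 <= 25] <- 200
  mask <- adaptive_binarize(resp, gema_params(adaptive_block_size = 51L,
                                              threshold_c = 5L))
  expect_true(all(mask[d2 <= 9] == 1))   # blob core is foreground
  expect_true(all(mask[d2 >= 400] == 0)) # far background stays empty
})

test_that("adaptive binarization matches a direct per-pixel oracle", {
  set.seed(71)
  for (rep in 1:4) {
    resp <- matrix(sample(0:255, 196, replace = TRUE), 14, 14)
    p <- gema_params(adaptive_block_size = 7L, threshold_c = 8L)
    expect_equal(adaptive_binarize(resp, p),
                 oracle_adaptive_binarize(resp, 7L, 8L))
  }
})

test_that("uniform-mean adaptive variant uses the box window", {
  set.seed(72)
  resp <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  p <- gema_params(adaptive_block_size = 5L, threshold_c = 6L,
                   adaptive_method = "mean")
  got <- adaptive_binarize(resp, p)
  local_mean <- gemaseg:::convolve_reflect(resp, matrix(1 / 25, 5, 5))
  expect_equal(got, (resp - local_mean > 6) + 0)
})

test_that("morphological cleanup is extensive, idempotent closing, fills gaps", {
  expect_equal(morph_postprocess(matrix(0, 10, 10)), matrix(0, 10, 10))

  strip <- matrix(0, 5, 9)
  strip[3, c(3, 6)] <- 1 # two foreground pixels two apart
  closed <- morph_postprocess(strip, struct_element(3), NULL)
  expect_true(all(closed[3, 3:6] == 1)) # the gap is bridged
  expect_equal(closed, oracle_binary_closing(strip, 3))
  # closing is idempotent
  expect_equal(morph_postprocess(closed, struct_element(3), NULL), closed)

  set.seed(81)
  mask <- matrix(rbinom(400, 1, 0.3), 20, 20)
  out <- morph_postprocess(mask)
  expect_true(all(out >= mask)) # extensivity of closing + dilation
  expect_true(all(out %in% c(0, 1)))
  expect_equal(morph_postprocess(mask, struct_element(5), NULL),
               oracle_binary_closing(mask, 5))
})

test_that("the adaptive pipeline is deterministic and segments mid-coverage frames well", {
  frame50 <- generate_frame(synthetic_config(), target_coverage = 0.5)
  bank <- build_gabor_bank(gabor_bank_config())
  st <- controller("growth")
  res1 <- segment_gema(frame50$frame, st, bank = bank)
  res2 <- segment_gema(frame50$frame, st, bank = bank)
  expect_identical(res1$mask, res2$mask)
  expect_identical(res1$row, res2$row)
  expect_true(all(res1$mask %in% c(0, 1)))
  expect_equal(dim(res1$mask), dim(frame50$mask))
  expect_gte(dice_score(confusion_counts(res1$mask, frame50$mask)), 0.80)
  # trace row carries the scheduled threshold and the area estimate
  expect_true(res1$row$threshold %in% 5:11)
  expect_equal(res1$row$percent_cells, percent_cells(res1$mask))
})
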