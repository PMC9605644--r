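test_that("PNG round-trip is the identity on pixel values", {
  m <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  path <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(m) / 255), path)
  fr <- read_frame(path, index = 3L)
  expect_s3_class(fr, "gema_frame")
  expect_equal(fr$index, 3L)
  expect_equal(round(fr$pixels), m)

  black <- matrix(0, 10, 10)
  p2 <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(black)), p2)
  expect_equal(read_frame(p2)$pixels, black, tolerance = 1e-12)
})

test_that("RGB JPEG decodes within compression tolerance", {
  arr <- array(0, c(8, 8, 3))
  arr[, , 1] <- 100 / 255; arr[, , 2] <- 150 / 255; arr[, , 3] <- 200 / 255
  path <- tempfile(fileext = ".jpg")
  EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color"),
                      path, quality = 98)
  fr <- read_frame(path)
  expect_equal(dim(fr$pixels), c(8L, 8L, 3L))
  expect_true(max(abs(fr$pixels[, , 1] - 100)) <= 3)
  expect_true(max(abs(fr$pixels[, , 2] - 150)) <= 3)
  expect_true(max(abs(fr$pixels[, , 3] - 200)) <= 3)
})

test_that("16-bit TIFF is rescaled by the sample-type maximum", {
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  path <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(t(m) / 255), path, bits.per.sample = 16)
  fr <- read_frame(path)
  expect_equal(fr$pixels, m, tolerance = 0.01)
})

test_that("unreadable or unsupported files raise typed errors naming the path", {
  txt <- write_tempfile("this is not an image", ext = ".png")
  expect_error(read_frame(txt), class = "gemaseg_io_error")
  doc <- write_tempfile("hello", ext = ".txt")
  expect_error(read_frame(doc), class = "gemaseg_format_error")
  expect_error(read_frame(doc), "\\.txt")
  expect_error(read_frame(tempfile(fileext = ".png")), class = "gemaseg_io_error")
})

test_that("frame validation rejects bad dimensions and intensities", {
  expect_error(gema_frame(matrix(-1, 2, 2)), class = "gemaseg_validation_error")
  expect_error(gema_frame(matrix(300, 2, 2)), class = "gemaseg_validation_error")
  expect_error(gema_frame(array(0, c(2, 2, 2))), class = "gemaseg_validation_error")
  expect_error(gema_frame(matrix(0, 2, 2), index = -1),
               class = "gemaseg_validation_error")
})

test_that("VIA polygons parse identically from both export dialects", {
  region <- via_polygon_region(c(0, 4, 4, 0), c(0, 0, 3, 3))
  for (builder in list(via_region_export, via_project_export)) {
    path <- write_tempfile(builder("img.png", region))
    ann <- read_via_annotations(path, "img.png")
    expect_equal(nrow(ann), 1L)
    expect_equal(ann$vertices[[1]]$x, c(0, 4, 4, 0))
    expect_equal(ann$vertices[[1]]$y, c(0, 0, 3, 3))
    expect_equal(ann$label, "cell")
  }
})

test_that("VIA rect/circle shapes become polygon approximations", {
  rect <- '{"shape_attributes":{"name":"rect","x":1,"y":1,"width":2,"height":2},"region_attributes":{}}'
  circ <- '{"shape_attributes":{"name":"circle","cx":5,"cy":5,"r":2},"region_attributes":{}}'
  path <- write_tempfile(via_region_export("img.png", c(rect, circ)))
  ann <- read_via_annotations(path, "img.png")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$vertices[[1]]$x, c(1, 3, 3, 1))
  expect_equal(ann$vertices[[1]]$y, c(1, 1, 3, 3))
  expect_equal(nrow(ann$vertices[[2]]), 32L)
  expect_equal(shoelace_area(ann$vertices[[2]]), pi * 4, tolerance = 0.1)
})

test_that("VIA reader: absent image gives empty tibble, bad JSON errors", {
  path <- write_tempfile(via_region_export("img.png",
                                           via_polygon_region(0:2, c(0, 2, 0))))
  expect_equal(nrow(read_via_annotations(path, "other.png")), 0L)
  empty <- write_tempfile(via_region_export("img.png", character(0)))
  expect_equal(nrow(read_via_annotations(empty, "img.png")), 0L)
  bad <- write_tempfile("{not json")
  expect_error(read_via_annotations(bad, "img.png"),
               class = "gemaseg_parse_error")
})

test_that("rasterization follows the center-inside convention", {
  square <- list(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4))
  mask <- rasterize_polygons(list(square), 10, 10)
  expect_equal(mask, oracle_rasterize(list(square), 10, 10))
  expect_equal(sum(mask), 25) # centers 0..4 in both axes, boundary inside

  expect_equal(rasterize_polygons(list(), 5, 7), matrix(0, 5, 7))
  expect_error(rasterize_polygons(list(list(x = c(0, 1), y = c(0, 1))), 5, 5),
               class = "gemaseg_validation_error")
})

test_that("disjoint polygons rasterize additively", {
  p1 <- list(x = c(0, 3, 3, 0), y = c(0, 0, 3, 3))
  p2 <- list(x = c(6, 9, 9, 6), y = c(6, 6, 9, 9))
  both <- rasterize_polygons(list(p1, p2), 12, 12)
  expect_equal(sum(both),
               sum(rasterize_polygons(list(p1), 12, 12)) +
                 sum(rasterize_polygons(list(p2), 12, 12)))
})

test_that("rasterization matches the brute-force oracle on random polygons", {
  set.seed(11)
  for (rep in 1:25) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    polys <- replicate(sample(1:2, 1), random_polygon(lim = min(h, w) - 1),
                       simplify = FALSE)
    expect_equal(rasterize_polygons(polys, h, w), oracle_rasterize(polys, h, w))
  }
})

test_that("mask PNG writer emits {0,255} values that read back exactly", {
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  path <- tempfile(fileext = ".png")
  write_mask_png(mask, path)
  raw <- round(read_frame(path)$pixels)
  expect_true(all(raw %in% c(0, 255)))
  expect_equal(read_mask_png(path), mask)
})

test_that("trace CSV round-trips within 1e-4 and refuses empty traces", {
  tr <- gema_trace(frame = 0:2, filename = sprintf("f%d.png", 0:2),
                   cv = c(0.21345, 0.220011, 0.2301),
                   threshold = c(11L, 10L, 9L),
                   percent_cells = c(10.1234, 15.5, 22.75))
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  lines <- readLines(path)
  expect_equal(lines[1], "frame,filename,cv,threshold,percent_cells")
  expect_equal(length(lines), 4L)
  back <- read_trace(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$cv, tr$cv, tolerance = 1e-4)
  expect_equal(back$percent_cells, tr$percent_cells, tolerance = 1e-4)

  expect_error(write_trace(gema_trace(), tempfile()),
               class = "gemaseg_validation_error")
  expect_error(gema_trace(frame = c(2, 1), filename = c("a", "b"),
                          cv = c(0.1, 0.1), threshold = c(5L, 5L),
                          percent_cells = c(1, 2)),
               class = "gemaseg_validation_error")
})

test_that("trace autoplot returns a ggplot without error", {
  tr <- gema_trace(frame = 0:4, filename = sprintf("f%d.png", 0:4),
                   cv = seq(0.2, 0.3, length.out = 5),
                   threshold = rep(8L, 5), percent_cells = seq(10, 50, 10))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
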