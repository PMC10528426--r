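test_that("crop window reproduces the native and fractional geometry", {
  native <- matrix(0, 3072, 3900)
  cf <- crop_field(native)
  expect_equal(unname(dim(cf)), c(1800, 1800))
  expect_equal(unname(attr(cf, "origin")), c(900, 800))

  # full-image window is the identity
  full <- crop_window(c(1, 3900), c(1, 3072))
  expect_identical(unclass(crop_field(native, full))[1:length(native)],
                   unclass(native)[1:length(native)])

  # fifth-scale image picks up the same window fractionally
  small <- matrix(0, 614, 780)
  cf5 <- crop_field(small)
  expect_equal(unname(dim(cf5)), c(360, 360))
  # direct arithmetic on the printed fractions
  expect_equal(unname(attr(cf5, "origin")),
               c(round(900 / 3900 * 780), round(800 / 3072 * 614)))
  expect_error(crop_window(c(50, 120), c(10, 90), native_extent = c(100, 100)))
})

test_that("margin report reproduces the printed percentages and sigma margins", {
  r <- crop_margins_report(crop_window())
  expect_equal(unname(r$percent), c(23, 69, 26, 85))
  expect_equal(unname(r$sigma), c(18, 10, 10, 15))
  # a bound exactly at the mean ROI border gives a 0-sigma margin
  r0 <- crop_margins_report(crop_window(x_range = c(1971 - 250, 2700)),
                            c(1971, 1588), c(46, 52), 250)
  expect_equal(unname(r0$sigma[1]), 0)
  expect_error(crop_margins_report(crop_window(), c(1971, 1588), c(0, 52)),
               "> 0")
})

test_that("highest-confidence selection honours threshold and tie-break", {
  a <- bounding_box(100, 100, 50, 50, 0.9)
  b <- bounding_box(0, 0, 50, 50, 0.3)
  expect_equal(unname(select_detection(list(a, b))), c(125, 125))
  expect_null(select_detection(list()))
  expect_null(select_detection(list(b), accept_threshold = 0.5))
  # equal top confidence: first in input order wins
  a2 <- bounding_box(200, 200, 50, 50, 0.9)
  expect_equal(unname(select_detection(list(a, a2))), c(125, 125))
})

test_that("fallback centre is the rounded mean of training ROI centres", {
  ext <- c(100, 100)
  r1 <- roi_from_center(c(10, 10), 5, ext)
  r2 <- roi_from_center(c(20, 20), 5, ext)
  expect_equal(unname(fallback_center(list(r1, r2))), c(15, 15))
  expect_equal(unname(fallback_center(list(r1))), c(10, 10))
  expect_error(fallback_center(list()), "empty")
})

test_that("fallback centre converges on the generator mean", {
  cfg <- tiny_config()
  set.seed(31)
  ctrs <- cbind(rnorm(1000, cfg$center_mean[1], cfg$center_std[1]),
                rnorm(1000, cfg$center_mean[2], cfg$center_std[2]))
  rois <- lapply(seq_len(nrow(ctrs)), function(i) {
    list(center_x = ctrs[i, 1], center_y = ctrs[i, 2])
  })
  fb <- fallback_center(rois)
  for (ax in 1:2) {
    expect_lt(abs(fb[ax] - cfg$center_mean[ax]),
              3 * cfg$center_std[ax] / sqrt(1000) + 0.5)  # + rounding
  }
})

test_that("circular masks match exhaustive lattice enumeration", {
  set.seed(7)
  for (i in 1:8) {
    radius <- runif(1, 1, 50)
    ext <- c(sample(60:120, 1), sample(60:120, 1))
    ctr <- c(runif(1, 0, ext[1] - 1), runif(1, 0, ext[2] - 1))
    roi <- roi_from_center(ctr, radius, ext)
    expect_equal(roi_cardinality(roi), oracle_circle_count(ctr, radius, ext))
  }
  # radius 1 at a safe interior point: the five pixels of the plus shape
  roi1 <- roi_from_center(c(10, 10), 1, c(21, 21))
  expect_equal(roi_cardinality(roi1), 5)
  # corner clipping: about a quarter of the interior mask survives
  rin <- roi_from_center(c(30, 30), 10, c(61, 61))
  rco <- roi_from_center(c(0, 0), 10, c(61, 61))
  expect_equal(roi_cardinality(rco),
               oracle_circle_count(c(0, 0), 10, c(61, 61)))
  expect_lt(abs(roi_cardinality(rco) / roi_cardinality(rin) - 0.25), 0.07)
  expect_error(roi_from_center(c(200, 10), 5, c(100, 100)), "outside")
})

test_that("detect_macula localises synthetic maculae and falls back cleanly", {
  cfg <- tiny_config()
  fb <- c(x = cfg$center_mean[1], y = cfg$center_mean[2])
  det <- matched_filter_detector(cfg$radius)
  ds <- numeric(6)
  for (i in 1:6) {
    rec <- generate_image(cfg, if (i %% 2) "AMD" else "Negative", 400 + i)
    out <- detect_macula(rec$image, det, fb, cfg$radius)
    expect_s3_class(out$roi, "circular_roi")
    expect_equal(out$source, "model")
    truth <- roi_from_center(rec$truth$macula_center, cfg$radius,
                             image_extent(rec$image))
    ds[i] <- dice(out$roi, truth)
  }
  expect_gte(mean(ds), 0.8)

  # determinism
  rec <- generate_image(cfg, "AMD", 401)
  o1 <- detect_macula(rec$image, det, fb, cfg$radius)
  o2 <- detect_macula(rec$image, det, fb, cfg$radius)
  expect_identical(o1$roi$mask, o2$roi$mask)

  # a detector returning nothing triggers the fallback path
  none <- function(image) list()
  out <- detect_macula(rec$image, none, fb, cfg$radius)
  expect_equal(out$source, "fallback")
  expect_equal(c(out$roi$center_x, out$roi$center_y), unname(fb))
  # and a raising detector propagates with context
  bad <- function(image) stop("boom")
  expect_error(detect_macula(rec$image, bad, fb, cfg$radius),
               "detector failed: boom")
})

test_that("ROI files round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  rois <- list(case_a = roi_from_center(c(10.5, 20), 5, c(50, 50)),
               case_b = roi_from_center(c(30, 30), 12, c(50, 50)))
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(names(back), c("case_a", "case_b"))
  expect_equal(back$case_a$center, c(10.5, 20))
  expect_equal(back$case_b$radius, 12)
  expect_error(read_rois("/nonexistent.json"), "not found")
})

test_that("annotation preprocessing halves the radius then rescales", {
  img <- matrix(runif(1800 * 1800) * 255, 1800, 1800)
  roi <- roi_from_center(c(900, 900), 250, c(1800, 1800))
  pp <- preprocess_annotations(list(list(image = img, roi = roi)))[[1]]
  expect_equal(unname(dim(pp$image)), c(300, 300))
  expect_equal(pp$radius, 125 * 300 / 1800)  # ~21 px
  expect_equal(unname(pp$center), c(150, 150))

  # target equal to input side: only the halving applies
  small <- matrix(0, 300, 300)
  roi2 <- roi_from_center(c(100, 100), 60, c(300, 300))
  pp2 <- preprocess_annotations(list(list(image = small, roi = roi2)))[[1]]
  expect_equal(pp2$radius, 30)
  expect_identical(pp2$image, small)
  expect_error(preprocess_annotations(list(list(image = matrix(0, 10, 20),
                                                roi = roi2))),
               "non-square")
})
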