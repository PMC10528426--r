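test_that("grayscale conversion uses the Rec. 601 luma weights", {
  g <- matrix(runif(12) * 255, 3, 4)
  expect_identical(to_grayscale(g), g)
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(100, 100, 100)
  rgb[1, 2, ] <- c(255, 0, 0)
  out <- to_grayscale(rgb)
  expect_equal(out[1, 1], 100)
  expect_equal(out[1, 2], 0.299 * 255)
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "channel")
})

test_that("2:1 down-sampling is 2x2 mean pooling with edge remainders", {
  expect_equal(downsample_2to1(matrix(7, 6, 6)), matrix(7, 3, 3))
  m <- rbind(c(0, 0, 10, 20), c(0, 0, 30, 40))
  expect_equal(downsample_2to1(m), matrix(c(0, 25), 1, 2))
  # 5x5 ramp: trailing row/col blocks average over what exists
  r <- matrix(1:25, 5, 5, byrow = TRUE)
  d <- downsample_2to1(r)
  expect_equal(unname(dim(d)), c(3, 3))
  expect_equal(d[1, 1], mean(c(1, 2, 6, 7)))
  expect_equal(d[3, 1], mean(c(21, 22)))
  expect_equal(d[3, 3], 25)
})

test_that("fixed-bin-number discretisation follows the stated rule", {
  img <- matrix(0:63, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  d <- discretise(img, mask, 64)
  expect_equal(as.vector(d$levels), as.vector(img) + 1L)

  img2 <- matrix(5, 4, 4)
  expect_true(all(discretise(img2, matrix(TRUE, 4, 4), 64)$levels == 1L))

  img3 <- matrix(c(0, 255, 0, 255), 2, 2)
  expect_equal(sort(unique(as.vector(
    discretise(img3, matrix(TRUE, 2, 2), 64)$levels))), c(1L, 64L))
  expect_error(discretise(img, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("GLCM worked examples", {
  lv <- matrix(1L, 2, 2)
  m <- glcm_matrix(lv, 2, directions = list(c(1L, 0L)))[[1]]
  expect_equal(m / sum(m), rbind(c(1, 0), c(0, 0)))

  lv2 <- rbind(c(1L, 2L), c(1L, 2L))
  m2 <- glcm_matrix(lv2, 2, directions = list(c(1L, 0L)))[[1]]
  expect_equal(m2 / sum(m2), rbind(c(0, 0.5), c(0.5, 0)))

  f <- glcm_features(rbind(c(1, 0), c(0, 0)))
  expect_equal(unname(f["joint_average"]), 1)
  f2 <- glcm_features(rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(unname(f2["joint_average"]), 1.5)
  # uniform over 4 levels: joint average is the mean level
  P <- matrix(1 / 16, 4, 4)
  expect_equal(unname(glcm_features(P)["joint_average"]), 2.5)
  expect_error(glcm_features(matrix(0.4, 2, 2)), "normalised")
})

test_that("GLRLM worked examples", {
  lv <- matrix(5L, 3, 3)
  m <- glrlm_matrix(lv, 6, directions = list(c(1L, 0L)))[[1]]
  expect_equal(sum(m), 3)           # 3 horizontal runs
  expect_equal(m[5, 3], 3)          # each of length 3
  f <- rlm_features_for_test(lv, 6)
  expect_equal(unname(f["short_run_low_grey_level_emphasis"]), 1 / 225)

  single <- matrix(4L, 1, 1)
  fs <- rlm_features_for_test(single, 6)
  expect_equal(unname(fs["low_grey_level_run_emphasis"]), 1 / 16)
})

test_that("GLDZM and NGLDM worked examples", {
  single <- matrix(4L, 1, 1)
  f <- gldzm_features(single, 6)
  expect_equal(unname(f["small_distance_high_grey_level_emphasis"]), 16)

  # constant grid: one zone touching the border at distance 1
  const <- matrix(3L, 4, 4)
  fc <- gldzm_features(const, 6)
  expect_equal(unname(fc["small_distance_high_grey_level_emphasis"]), 9)

  s3 <- matrix(3L, 1, 1)
  fn <- ngldm_features(s3, 6)
  expect_equal(unname(fn["low_grey_level_count_emphasis"]), 1 / 9)
  expect_equal(unname(fn["high_dependence_low_grey_level_emphasis"]), 1 / 9)

  # constant 3x3: dependence counts 8 (centre), 5 (edges), 3 (corners)
  m <- ngldm_matrix(matrix(2L, 3, 3), 4)
  expect_equal(sum(m), 9)
  expect_equal(m[2, 9], 1)  # centre: 8 neighbours -> column k+1 = 9
  expect_equal(m[2, 6], 4)
  expect_equal(m[2, 4], 4)
})

test_that("NGTDM worked examples and conventions", {
  const <- matrix(2L, 3, 3)
  f <- ngtdm_features(const, 4)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["strength"]), 0)

  lv <- matrix(1L, 3, 3); lv[2, 2] <- 2L
  f2 <- ngtdm_features(lv, 4)
  o <- oracle_ngtdm(lv, 4)
  n <- sum(o$n); p <- o$n / n
  pres <- which(o$n > 0)
  contrast_hand <- (sum(outer(p[pres], p[pres]) *
                          outer(pres, pres, function(a, b) (a - b)^2)) /
                      (length(pres) * (length(pres) - 1))) * (sum(o$s) / n)
  strength_hand <- sum((outer(p[pres], rep(1, 2)) + outer(rep(1, 2), p[pres])) *
                         outer(pres, pres, function(a, b) (a - b)^2)) /
    (.Machine$double.eps + sum(o$s))
  expect_equal(unname(f2["contrast"]), contrast_hand)
  expect_equal(unname(f2["strength"]), strength_hand)
})

test_that("intensity statistics and histogram examples", {
  f <- intensity_features(c(1, 2, 3, 4))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["energy"]), 30)
  expect_equal(unname(intensity_features(c(-2, -1, 0, 1, 2))["skewness"]), 0)

  cimg <- matrix(9, 3, 3)
  d <- discretise(cimg, matrix(TRUE, 3, 3), 64)
  hv <- histogram_features(d$levels[!is.na(d$levels)], 64)
  expect_equal(unname(hv["entropy"]), 0)
  expect_equal(unname(hv["uniformity"]), 1)
  expect_equal(unname(hv["variance"]), 0)
})

test_that("the default catalogue has 270 uniquely named entries over 8 families", {
  cat_df <- default_catalogue()
  expect_equal(nrow(cat_df), 270)
  expect_equal(length(unique(cat_df$id)), 270)
  expect_setequal(unique(cat_df$family),
                  c("Intensity-Based Statistics", "Intensity Histogram",
                    "Grey-Level Co-Occurrence Matrix",
                    "Grey-Level Run Length Matrix",
                    "Grey-Level Size Zone Matrix",
                    "Grey-Level Distance Zone Matrix",
                    "Neighbourhood Grey Tone Difference Matrix",
                    "Neighbouring Grey Level Dependence Matrix"))
  # the shipped YAML is the same catalogue
  yml <- system.file("extdata", "feature_catalogue_v1.yaml",
                     package = "retinomics")
  expect_identical(read_catalogue(yml), cat_df)
  # full display nomenclature follows the standard family naming
  expect_true("Neighbouring Grey Level Dependence Matrix Low Grey Level Count Emphasis [alpha 0]" %in%
                cat_df$name)
})

test_that("extraction is deterministic, complete and flags failing families", {
  cfg <- tiny_config()
  rec <- generate_image(cfg, "AMD", 12)
  roi <- roi_from_center(rec$truth$macula_center, cfg$radius,
                         image_extent(rec$image))
  fv <- extract_features(rec$image, roi)
  expect_length(fv, 270)
  expect_identical(names(fv), default_catalogue()$id)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(rec$image, roi))

  # constant ROI: variance- and contrast-like entries collapse to zero
  flat <- matrix(100, 64, 64)
  roi_f <- roi_from_center(c(31, 31), 12, c(64, 64))
  fvf <- extract_features(flat, roi_f)
  expect_equal(unname(fvf["stat.variance"]), 0)
  expect_equal(unname(fvf["glcm.d1.avg.contrast"]), 0)
  expect_equal(unname(fvf["ngtdm.d1.contrast"]), 0)
  expect_equal(unname(fvf["hist.entropy"]), 0)
})

test_that("direction-aggregated features are invariant under 90-degree rotation", {
  cfg <- tiny_config()
  rec <- generate_image(cfg, "AMD", 21)
  # odd-sized square patch centred on the macula so the lattice maps to
  # itself under a quarter turn about the centre pixel
  cx <- round(rec$truth$macula_center[["x"]])
  cy <- round(rec$truth$macula_center[["y"]])
  half <- 30
  patch <- rec$image[(cy - half):(cy + half) + 1, (cx - half):(cx + half) + 1]
  rot <- t(patch)[ncol(patch):1, ]  # quarter turn
  roi <- roi_from_center(c(half, half), 25, c(2 * half + 1, 2 * half + 1))
  f1 <- extract_features(patch, roi, downsample = FALSE)
  f2 <- extract_features(rot, roi, downsample = FALSE)
  expect_equal(f1, f2, tolerance = 1e-9)
})
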