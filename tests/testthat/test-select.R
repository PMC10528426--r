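test_that("ICC(1,1) matches the hand ANOVA decomposition and aov oracle", {
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  # hand: MSB = 8, MSW = 0.5 -> (8 - 0.5) / (8 + 0.5) = 15/17
  expect_equal(icc_1_1(m), 15 / 17)
  expect_equal(icc_1_1(m), oracle_icc_aov(m))

  set.seed(11)
  for (i in 1:20) {
    mm <- matrix(rnorm(12 * 3, rep(rnorm(12, sd = 2), 3)), 12, 3)
    expect_equal(icc_1_1(mm), oracle_icc_aov(mm), tolerance = 1e-8)
  }
})

test_that("ICC behaves at the reliability extremes", {
  # identical repeats across differing cases: perfect reliability
  m <- matrix(rep(c(1, 5, 9, 2), 3), 4, 3)
  expect_equal(icc_1_1(m), 1)
  # fully independent draws: ICC concentrates near zero
  set.seed(12)
  m0 <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(icc_1_1(m0)), 0.1)
  # degenerate zero-variance input is undefined
  expect_true(is.na(icc_1_1(matrix(3, 4, 2))))
  expect_error(icc_1_1(matrix(1, 1, 2)), ">= 2")
})

test_that("augmentation is seeded, bounded and identity at zero magnitude", {
  cfg <- tiny_config()
  rec <- generate_image(cfg, "AMD", 31)
  roi <- roi_from_center(rec$truth$macula_center, cfg$radius,
                         image_extent(rec$image))
  id_spec <- augmentation_spec(n_variants = 2, rotation_range = 0,
                               roi_jitter_px = 0, roi_radius_jitter_frac = 0)
  vs <- augment_case(rec$image, roi, id_spec)
  expect_identical(vs[[1]]$image, rec$image)
  expect_equal(vs[[1]]$roi$mask, roi$mask)

  spec <- augmentation_spec(n_variants = 5, seed = 11, scale = cfg$scale)
  v1 <- augment_case(rec$image, roi, spec, case_seed_offset = 3)
  v2 <- augment_case(rec$image, roi, spec, case_seed_offset = 3)
  expect_identical(v1, v2)
  expect_length(v1, 5)
  for (v in v1) {
    expect_lte(abs(v$roi$radius - roi$radius), 0.1 * roi$radius + 1e-9)
  }
})

test_that("a 90-degree rotation maps the ROI centre by the rotation matrix", {
  img <- matrix(runif(101 * 101), 101, 101)
  pt <- c(70, 40)
  rp <- rotate_point(pt, 90, c(101, 101))
  # about centre (50, 50): (dx, dy) = (20, -10) -> (10, 20)
  expect_equal(unname(rp), c(60, 70), tolerance = 1e-12)
  # a bright dot placed at pt lands at the mapped location
  img[pt[2] + 1, pt[1] + 1] <- 10
  rot <- rotate_image(img, 90)
  expect_equal(which(rot == max(rot)) - 1,
               unname(round(rp[2]) + round(rp[1]) * 101))
})

test_that("stability selection keeps reproducible features and drops noise", {
  set.seed(21)
  n <- 40
  base <- rnorm(n, sd = 4)
  tables <- lapply(1:4, function(v) {
    data.frame(case_id = sprintf("c%02d", 1:n),
               stable = base + rnorm(n, sd = 0.1),
               exact = base,
               noise = rnorm(n),
               constant = rep(1, n))
  })
  rep_ <- select_stable(tables, threshold = 0.80)
  expect_true(rep_$retained[rep_$feature == "stable"])
  expect_true(rep_$retained[rep_$feature == "exact"])
  expect_false(rep_$retained[rep_$feature == "noise"])
  expect_lt(abs(rep_$icc[rep_$feature == "noise"]), 0.35)
  # zero-variance feature: undefined ICC, dropped
  expect_true(is.na(rep_$icc[rep_$feature == "constant"]))
  expect_false(rep_$retained[rep_$feature == "constant"])
  # threshold 1.0 retains only exact-ICC-1 features
  rep1 <- select_stable(tables, threshold = 1.0)
  expect_identical(rep1$feature[rep1$retained], "exact")

  bad <- tables
  bad[[2]]$case_id <- rev(bad[[2]]$case_id)
  expect_error(select_stable(bad), "mismatched case sets")
})

test_that("predictor ranking: null behaviour, shift detection, Bonferroni", {
  set.seed(22)
  n <- 20
  x <- rnorm(2 * n)
  perm <- data.frame(f_null = x)
  labs <- sample(rep(c("AMD", "Negative"), n))
  r0 <- rank_predictors(perm, labs)
  expect_gt(r0$p_value[1], 0.05)

  shifted <- data.frame(f_null = x,
                        f_shift = x + ifelse(labs == "AMD", 5, 0))
  r1 <- rank_predictors(shifted, labs)
  expect_lt(r1$p_corrected[r1$feature == "f_shift"], 0.005)
  expect_equal(r1$feature[1], "f_shift")
  expect_gt(r1$median_pos[r1$feature == "f_shift"],
            r1$median_neg[r1$feature == "f_shift"])

  # Bonferroni: multiplication clipped at 1, never decreases p
  many <- as.data.frame(matrix(rnorm(2 * n * 10), 2 * n, 10))
  rm_ <- rank_predictors(many, labs)
  expect_equal(rm_$p_corrected, pmin(1, rm_$p_value * 10))
  expect_true(all(rm_$p_corrected >= rm_$p_value))
})

test_that("rank-sum ranking is invariant to monotone transforms", {
  set.seed(23)
  n <- 15
  labs <- rep(c("AMD", "Negative"), each = n)
  x <- c(rnorm(n, 1), rnorm(n))
  a <- rank_predictors(data.frame(f = x), labs)
  b <- rank_predictors(data.frame(f = exp(x)), labs)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # and a constant feature gets p = 1 by convention
  cc <- rank_predictors(data.frame(f = rep(2, 2 * n)), labs)
  expect_equal(cc$p_value, 1)
})
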