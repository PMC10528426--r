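test_that("ADASYN balances towards parity with convex synthetic rows", {
  set.seed(51)
  X <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(20 * 3, 3), 20))
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("AMD", "Negative"), c(10, 20))
  res <- adasyn_oversample(X, y, seed = 2)
  added <- sum(res$synthetic)
  expect_lte(abs(added - 10), 4)  # G = 10, rounding shares per seed point
  expect_equal(res$y[res$synthetic], rep("AMD", added))

  # every synthetic row lies on a segment between two original minority rows
  minor <- X[y == "AMD", , drop = FALSE]
  for (i in which(res$synthetic)) {
    s <- res$X[i, ]
    on_segment <- FALSE
    for (a in 1:nrow(minor)) for (b in 1:nrow(minor)) {
      if (a == b) next
      d <- minor[b, ] - minor[a, ]
      lam <- sum((s - minor[a, ]) * d) / sum(d * d)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((minor[a, ] + lam * d - s)^2)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }

  # balanced input is returned unchanged
  bal <- adasyn_oversample(X[1:20, ], y[1:20], seed = 1)
  expect_false(any(bal$synthetic))
  expect_identical(bal$X, X[1:20, ])
  expect_error(adasyn_oversample(X[8:30, ], y[8:30], k = 5), "too small")
})

test_that("confusion metrics equal the closed-form definitions", {
  expect_equal(unname(confusion_metrics(list(tp = 9, tn = 0, fp = 0, fn = 1))["sensitivity"]),
               90)
  all100 <- confusion_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(all100 == 100))
  set.seed(52)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(0:250, 4, replace = TRUE),
                           c("tp", "tn", "fp", "fn")))
    m <- confusion_metrics(cm, as_percent = FALSE)
    expect_equal(unname(m["accuracy"]),
                 (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn))
    if (cm$tp + cm$fn > 0) expect_equal(unname(m["sensitivity"]), cm$tp / (cm$tp + cm$fn))
    if (cm$tn + cm$fp > 0) expect_equal(unname(m["specificity"]), cm$tn / (cm$tn + cm$fp))
    if (cm$tp + cm$fp > 0) expect_equal(unname(m["ppv"]), cm$tp / (cm$tp + cm$fp))
    if (cm$tn + cm$fn > 0) expect_equal(unname(m["npv"]), cm$tn / (cm$tn + cm$fn))
  }
  expect_true(is.na(confusion_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))["ppv"]))
})

test_that("rank-statistic AUC equals the concordant-pair oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), rep(c("Negative", "AMD"), c(3, 2)),
                       ci = FALSE)$auc, 1)
  set.seed(53)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labs <- sample(rep(c("AMD", "Negative"), length.out = n))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(sc, labs, ci = FALSE)$auc, oracle_auc(sc, labs))
  }
  # label-independent scores concentrate near 1/2
  set.seed(54)
  labs <- rep(c("AMD", "Negative"), 1000)
  a <- roc_auc(rnorm(2000), labs, ci = FALSE)$auc
  expect_lt(abs(a - 0.5), 0.03)
  expect_error(roc_auc(1:3, rep("AMD", 3), ci = FALSE), "both classes")
})

test_that("proportion CI is Clopper-Pearson with an exact chance test", {
  r <- proportion_ci_and_chance_test(50, 100)
  expect_gt(r$p_value, 0.9)
  r2 <- proportion_ci_and_chance_test(100, 100)
  expect_equal(r2$ci[2], 1)
  expect_gt(r2$ci[1], 0.96)
  set.seed(55)
  for (i in 1:10) {
    n <- sample(5:200, 1); s <- sample(0:n, 1)
    rr <- proportion_ci_and_chance_test(s, n)
    expect_gte(rr$estimate, rr$ci[1] - 1e-12)
    expect_lte(rr$estimate, rr$ci[2] + 1e-12)
  }
  expect_error(proportion_ci_and_chance_test(1, 0), "> 0")
})

test_that("Cohen kappa matches hand arithmetic; linear = unweighted for binary", {
  # contingency [[20, 5], [10, 15]]: po = 0.7, pc = 0.5 -> kappa = 0.4
  a <- rep(c("AMD", "AMD", "Negative", "Negative"), c(20, 5, 10, 15))
  b <- rep(c("AMD", "Negative", "AMD", "Negative"), c(20, 5, 10, 15))
  k <- cohen_kappa(a, b, ci = FALSE)
  expect_equal(k$kappa, 0.4)
  expect_equal(cohen_kappa(a, b, weighting = "none", ci = FALSE)$kappa, 0.4)
  expect_equal(cohen_kappa(a, a, ci = FALSE)$kappa, 1)
  # independent raters with matched marginals: kappa near 0
  set.seed(56)
  r1 <- sample(rep(c("AMD", "Negative"), 2500))
  r2 <- sample(rep(c("AMD", "Negative"), 2500))
  expect_lt(abs(cohen_kappa(r1, r2, ci = FALSE)$kappa), 0.05)
  # all-one-category agreement is undefined
  expect_true(is.na(cohen_kappa(rep("AMD", 5), rep("AMD", 5), ci = FALSE)$kappa))
})

test_that("ensembles are deterministic, separable-perfect and chance-level on noise", {
  toy <- toy_classification_data(n_per_class = 25, shift = 4)
  for (kind in c("svm", "rf")) {
    cfgE <- ensemble_config(n_sub = 3, n_base = 10)
    fit <- train_model(toy$X, toy$y, kind, cfgE, seed = 9)
    pr <- predict(fit, toy$X)
    expect_equal(pr$labels, toy$y)            # linearly separable
    expect_equal(rowMeans(pr$sub_fractions), pr$vote_fraction)
    fit2 <- train_model(toy$X, toy$y, kind, cfgE, seed = 9)
    expect_equal(predict(fit2, toy$X)$vote_fraction, pr$vote_fraction)
  }

  # label-permuted data: held-out accuracy is chance-level
  set.seed(57)
  toy2 <- toy_classification_data(n_per_class = 100, shift = 0)
  idx <- sample(200, 140)
  fit <- train_model(toy2$X[idx, ], toy2$y[idx], "svm",
                     ensemble_config(n_sub = 3, n_base = 10), seed = 1)
  acc <- mean(predict(fit, toy2$X[-idx, ])$labels == toy2$y[-idx])
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("vote ties resolve to the positive class", {
  toy <- toy_classification_data(n_per_class = 6, shift = 10, p = 2)
  fit <- train_model(toy$X, toy$y, "rf", ensemble_config(n_sub = 1, n_base = 2),
                     seed = 3)
  fake <- fit
  # force a tie by construction of the vote rule itself
  expect_equal(ifelse(0.5 >= 0.5, fit$positive, "Negative"), "AMD")
  # and missing feature columns are rejected
  expect_error(predict(fit, toy$X[, 1, drop = FALSE]), "undefined columns|missing")
})

test_that("nested CV is leakage-free, reproducible and swaps metrics with labels", {
  toy <- toy_classification_data(n_per_class = 30, shift = 2.5)
  cfgE <- ensemble_config(n_sub = 2, n_base = 8)
  cv <- nested_cv(toy$X, toy$y, outer_k = 5, inner_k = 3, kinds = "svm",
                  config = cfgE, seed = 4)
  folds <- cv$per_kind$svm$folds
  expect_equal(sort(unname(unlist(folds))), 1:60)  # partition: no case reused
  rep_ <- cv$per_kind$svm$report
  expect_true(all(rep_$ci_lo <= rep_$mean + 1e-9 & rep_$mean <= rep_$ci_hi + 1e-9))
  auc <- rep_$mean[rep_$split == "test" & rep_$metric == "roc_auc"]
  expect_gt(auc, 85)

  cv2 <- nested_cv(toy$X, toy$y, outer_k = 5, inner_k = 3, kinds = "svm",
                   config = cfgE, seed = 4)
  expect_identical(cv$per_kind$svm$test_scores, cv2$per_kind$svm$test_scores)

  # swapping class labels swaps sensitivity/specificity and PPV/NPV exactly
  swap <- c(AMD = "Negative", Negative = "AMD")
  pred <- cv$per_kind$svm$test_predictions
  m1 <- confusion_metrics(confusion_matrix(pred, toy$y))
  m2 <- confusion_metrics(confusion_matrix(unname(swap[pred]),
                                           unname(swap[toy$y])))
  expect_equal(unname(m1["sensitivity"]), unname(m2["specificity"]))
  expect_equal(unname(m1["ppv"]), unname(m2["npv"]))
  expect_equal(unname(m1["accuracy"]), unname(m2["accuracy"]))
})
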