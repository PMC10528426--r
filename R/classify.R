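# Ensemble-of-ensembles classification with ADASYN rebalancing under nested
# stratified cross-validation. Two model kinds: "svm" (each base classifier
# = Fisher-discriminant-ratio feature screen + PCA + linear SVM on a
# bootstrap resample; 3 independently seeded sub-ensembles of 100) and "rf"
# (3 sub-ensembles, each a 100-tree Gini random forest whose trees are the
# base classifiers). Prediction is the majority over all 300 base votes;
# vote ties go to "AMD" (screening favours sensitivity).

#' ADASYN adaptive synthetic oversampling
#'
#' Oversamples the minority class towards balance: each minority case
#' receives a share of the deficit proportional to the fraction of
#' majority-class cases among its k nearest neighbours (borderline cases
#' get more synthetics); each synthetic row is a convex combination of a
#' minority row and one of its k nearest minority neighbours. Neighbour
#' search uses z-scored features; synthesis happens in the original feature
#' space. Already-balanced input is returned unchanged.
#'
#' @param X numeric feature matrix / data.frame.
#' @param y class labels (two classes).
#' @param k neighbour count (default 5).
#' @param seed integer seed.
#' @return list `X` (matrix with synthetic rows appended), `y`,
#'   `synthetic` (logical row flags).
#' @export
adasyn_oversample <- function(X, y, k = 5, seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("ADASYN needs exactly two classes")
  if (tab[1] == tab[2]) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(y == minority)
  if (length(min_idx) < k + 1) {
    stop("minority class too small for ", k, "-neighbourhood ADASYN")
  }
  G <- max(tab) - min(tab)
  sd0 <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, ifelse(sd0 > 0, sd0, 1), `/`)
  D <- as.matrix(stats::dist(Z))
  r <- vapply(min_idx, function(i) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(nrow(X))[-i][nb]
    mean(y[nb] != minority)
  }, numeric(1))
  w <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  g <- round(w * G)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  synth <- list()
  for (q in seq_along(min_idx)) {
    if (g[q] == 0) next
    i <- min_idx[q]
    others <- setdiff(min_idx, i)
    nbm <- others[order(D[i, others])[seq_len(min(k, length(others)))]]
    for (s in seq_len(g[q])) {
      z <- nbm[sample.int(length(nbm), 1)]
      lam <- stats::runif(1)
      synth[[length(synth) + 1]] <- X[i, ] + lam * (X[z, ] - X[i, ])
    }
  }
  Xs <- if (length(synth)) rbind(X, do.call(rbind, synth)) else X
  list(X = Xs,
       y = c(y, rep(minority, length(synth))),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(synth))))
}

#' Default hyperparameters for the ensemble models
#'
#' @param n_sub number of sub-ensembles (default 3).
#' @param n_base base classifiers per sub-ensemble (default 100).
#' @param fisher_k features kept by the Fisher-discriminant-ratio screen
#'   (svm path; capped at the feature count).
#' @param pca_var fraction of variance retained by PCA (svm path).
#' @param svm_cost linear-SVM cost parameter.
#' @param adasyn_k ADASYN neighbour count.
#' @return list of settings.
#' @export
ensemble_config <- function(n_sub = 3, n_base = 100, fisher_k = 20,
                            pca_var = 0.95, svm_cost = 1, adasyn_k = 5) {
  list(n_sub = n_sub, n_base = n_base, fisher_k = fisher_k,
       pca_var = pca_var, svm_cost = svm_cost, adasyn_k = adasyn_k)
}

# Column variances without apply(): one pass of colMeans.
col_variance <- function(X) {
  n <- nrow(X)
  v <- (colMeans(X^2) - colMeans(X)^2) * n / (n - 1)
  pmax(v, 0)
}

fisher_ratio <- function(X, y, positive) {
  a <- y == positive
  mu1 <- colMeans(X[a, , drop = FALSE]); mu0 <- colMeans(X[!a, , drop = FALSE])
  v1 <- col_variance(X[a, , drop = FALSE])
  v0 <- col_variance(X[!a, , drop = FALSE])
  num <- (mu1 - mu0)^2; den <- v1 + v0
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

# Stratified bootstrap resample indices (guarantees both classes present).
boot_indices <- function(y) {
  unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    idx[sample.int(length(idx), length(idx), replace = TRUE)]
  }), use.names = FALSE)
}

#' Train an ensemble-of-ensembles model
#'
#' ADASYN is applied to the training data first (unless `rebalance =
#' FALSE`), then `n_sub` independently seeded sub-ensembles of `n_base`
#' base classifiers are fitted; zero-variance / non-finite feature columns
#' are excluded with a warning. Deterministic per seed.
#'
#' @param X feature matrix / data.frame (named columns).
#' @param y class labels; `positive` defaults to "AMD".
#' @param kind "svm" or "rf".
#' @param config an [ensemble_config()].
#' @param seed master seed.
#' @param rebalance apply ADASYN (default TRUE).
#' @param positive positive class label.
#' @return object of class `radiomic_ensemble`.
#' @export
train_model <- function(X, y, kind = c("svm", "rf"), config = ensemble_config(),
                        seed = 1L, rebalance = TRUE, positive = "AMD") {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < 2) stop("need >= 2 cases per class")
  bad <- apply(X, 2, function(col) any(!is.finite(col)) || stats::sd(col) == 0)
  if (any(bad)) {
    warning("excluding ", sum(bad), " degenerate feature column(s): ",
            paste(utils::head(colnames(X)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", call. = FALSE)
    X <- X[, !bad, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no usable feature columns")
  if (rebalance && length(unique(y)) == 2 && diff(range(table(y))) > 0) {
    # adapt the neighbourhood to what the (possibly small) training fold
    # supports; with a single-case minority rebalancing is skipped
    k_eff <- min(config$adasyn_k, min(table(y)) - 1)
    if (k_eff >= 1) {
      res <- adasyn_oversample(X, y, k = k_eff, seed = derive_seed(seed, 999))
      X <- res$X; y <- res$y
    }
  }
  ylev <- c(positive, setdiff(sort(unique(y)), positive))
  subs <- lapply(seq_len(config$n_sub), function(s) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, s))
    if (kind == "rf") {
      randomForest::randomForest(
        x = X, y = factor(y, ylev), ntree = config$n_base)
    } else {
      lapply(seq_len(config$n_base), function(b) {
        idx <- boot_indices(y)
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        # relative-tolerance variance screen (robust to huge-scale features
        # where naive cancellation leaves non-zero residue)
        keep <- col_variance(Xb) > 1e-12 * pmax(colMeans(Xb^2), 1e-300)
        Xb <- Xb[, keep, drop = FALSE]
        fr <- fisher_ratio(Xb, yb, positive)
        top <- order(fr, decreasing = TRUE)[seq_len(min(config$fisher_k, ncol(Xb)))]
        feats <- colnames(Xb)[top]
        pc <- stats::prcomp(Xb[, feats, drop = FALSE], center = TRUE, scale. = TRUE)
        cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
        ncomp <- max(1L, which(cum >= config$pca_var)[1])
        S <- pc$x[, seq_len(ncomp), drop = FALSE]
        fit <- e1071::svm(x = S, y = factor(yb, ylev), kernel = "linear",
                          cost = config$svm_cost, scale = FALSE)
        list(features = feats, center = pc$center, scale = pc$scale,
             rotation = pc$rotation[, seq_len(ncomp), drop = FALSE], svm = fit)
      })
    }
  })
  structure(list(kind = kind, positive = positive, levels = ylev,
                 features = colnames(X), config = config, seed = seed,
                 subs = subs),
            class = "radiomic_ensemble")
}

#' Predict with an ensemble model (majority vote)
#'
#' @param object a `radiomic_ensemble`.
#' @param newdata feature matrix / data.frame containing the training
#'   feature columns.
#' @param ... unused.
#' @return list: `labels` (majority vote; exact ties go to the positive
#'   class), `vote_fraction` (overall fraction of base votes for the
#'   positive class, usable as a ROC score), `sub_fractions` (cases x
#'   sub-ensembles matrix; rowMeans equal `vote_fraction`).
#' @export
predict.radiomic_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (anyNA(X)) stop("missing features in newdata")
  n <- nrow(X)
  fr <- vapply(object$subs, function(sub) {
    if (object$kind == "rf") {
      votes <- stats::predict(sub, X, type = "vote", norm.votes = TRUE)
      votes[, object$positive]
    } else {
      vote <- rep(0, n)
      for (b in sub) {
        S <- sweep(sweep(X[, b$features, drop = FALSE], 2, b$center),
                   2, b$scale, `/`) %*% b$rotation
        vote <- vote + (as.character(stats::predict(b$svm, S)) == object$positive)
      }
      vote / length(sub)
    }
  }, numeric(n))
  fr <- matrix(fr, nrow = n)
  overall <- rowMeans(fr)
  labels <- ifelse(overall >= 0.5, object$positive,
                   setdiff(object$levels, object$positive))
  list(labels = labels, vote_fraction = overall, sub_fractions = fr)
}

#' Per-feature selection frequency in a trained ensemble
#'
#' For the SVM ensemble: the fraction of base classifiers whose
#' Fisher-discriminant-ratio screen kept the feature. For the random-forest
#' ensemble: the fraction of trees splitting on the feature at least once.
#' Used as the relevance key of the predictor ranking.
#'
#' @param model a trained `radiomic_ensemble`.
#' @return named numeric vector over `model$features`, values in \[0, 1\].
#' @export
selection_frequencies <- function(model) {
  feats <- model$features
  if (model$kind == "svm") {
    bases <- unlist(model$subs, recursive = FALSE)
    cnt <- table(factor(unlist(lapply(bases, `[[`, "features")), feats))
    return(stats::setNames(as.numeric(cnt) / length(bases), feats))
  }
  used <- Reduce(`+`, lapply(model$subs, function(rf) {
    colSums(randomForest::varUsed(rf, by.tree = TRUE, count = TRUE) > 0)
  }))
  ntree <- sum(vapply(model$subs, function(rf) rf$ntree, numeric(1)))
  stats::setNames(used / ntree, feats)
}

# Fold-wise mean and 95% t-interval.
fold_summary <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  m <- mean(v)
  half <- if (n > 1 && stats::sd(v) > 0) {
    stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
  } else 0
  c(mean = m, ci_lo = max(0, m - half), ci_hi = min(100, m + half))
}

#' Nested stratified k-fold cross-validation of both ensemble models
#'
#' Outer stratified folds give internal-test predictions; within each
#' outer-training set an inner stratified k-fold yields validation
#' predictions; training metrics come from the refit on the full
#' outer-training set. ADASYN runs inside training folds only -- synthetic
#' rows never reach validation or test folds. Metrics are aggregated over
#' folds as mean with a 95% t-interval; pooled test predictions additionally
#' give an exact binomial test against chance.
#'
#' @param X feature matrix / data.frame.
#' @param y class labels.
#' @param outer_k,inner_k fold counts (default 10/10).
#' @param kinds model kinds to evaluate (default both).
#' @param config an [ensemble_config()].
#' @param seed master seed (folds, ADASYN, ensembles).
#' @param positive positive class label.
#' @return list: `per_kind` (per kind: `report` data.frame with
#'   metric/split rows, `test_predictions`, `test_scores`, `folds`),
#'   `winner` (kind with highest mean internal-test ROC-AUC).
#' @export
nested_cv <- function(X, y, outer_k = 10, inner_k = 10,
                      kinds = c("svm", "rf"), config = ensemble_config(),
                      seed = 1L, positive = "AMD") {
  X <- as.matrix(X); y <- as.character(y)
  if (min(table(y)) < outer_k) stop("too few cases per class for ", outer_k,
                                    " stratified outer folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 17))
  outer_folds <- caret::createFolds(factor(y), k = outer_k)

  per_kind <- lapply(kinds, function(kind) {
    metr <- c("roc_auc", "accuracy", "sensitivity", "specificity", "ppv", "npv")
    fold_rows <- list()
    test_pred <- character(length(y)); test_score <- numeric(length(y))
    for (f in seq_along(outer_folds)) {
      te <- outer_folds[[f]]
      tr <- setdiff(seq_along(y), te)
      stopifnot(length(intersect(tr, te)) == 0)  # leakage guard
      # inner validation loop
      set.seed(derive_seed(seed, 1000 + f))
      inner <- caret::createFolds(factor(y[tr]), k = inner_k)
      val_pred <- character(length(tr)); val_score <- numeric(length(tr))
      for (g in seq_along(inner)) {
        iv <- inner[[g]]; it <- setdiff(seq_along(tr), iv)
        fit <- train_model(X[tr[it], , drop = FALSE], y[tr[it]], kind, config,
                           seed = derive_seed(seed, f * 100 + g),
                           positive = positive)
        pr <- predict(fit, X[tr[iv], , drop = FALSE])
        val_pred[iv] <- pr$labels; val_score[iv] <- pr$vote_fraction
      }
      # refit on the full outer-training set
      fit <- train_model(X[tr, , drop = FALSE], y[tr], kind, config,
                         seed = derive_seed(seed, 2000 + f),
                         positive = positive)
      pr_tr <- predict(fit, X[tr, , drop = FALSE])
      pr_te <- predict(fit, X[te, , drop = FALSE])
      test_pred[te] <- pr_te$labels; test_score[te] <- pr_te$vote_fraction
      row <- function(split, pred, score, truth) {
        cm <- confusion_matrix(pred, truth, positive)
        auc <- tryCatch(100 * roc_auc(score, truth, positive, ci = FALSE)$auc,
                        error = function(e) NA_real_)
        c(auc, confusion_metrics(cm))
      }
      fold_rows[[f]] <- rbind(
        train = row("train", pr_tr$labels, pr_tr$vote_fraction, y[tr]),
        validation = row("validation", val_pred, val_score, y[tr]),
        test = row("test", pr_te$labels, pr_te$vote_fraction, y[te]))
    }
    report <- do.call(rbind, lapply(c("train", "validation", "test"), function(sp) {
      vals <- vapply(fold_rows, function(fr) fr[sp, ], numeric(6))
      do.call(rbind, lapply(seq_along(metr), function(mi) {
        s <- fold_summary(vals[mi, ])
        data.frame(split = sp, metric = metr[mi], mean = s[1],
                   ci_lo = s[2], ci_hi = s[3])
      }))
    }))
    rownames(report) <- NULL
    # pooled internal-test results + chance test on pooled accuracy
    cm <- confusion_matrix(test_pred, y, positive)
    nir <- max(table(y)) / length(y)
    chance <- proportion_ci_and_chance_test(cm$tp + cm$tn, length(y), nir)
    list(report = report,
         test_predictions = test_pred, test_scores = test_score,
         pooled_test_auc = 100 * roc_auc(test_score, y, positive, ci = FALSE)$auc,
         pooled_test_metrics = confusion_metrics(cm),
         p_vs_chance = chance$p_value,
         folds = outer_folds)
  })
  names(per_kind) <- kinds
  test_auc <- vapply(per_kind, function(pk) {
    pk$report$mean[pk$report$split == "test" & pk$report$metric == "roc_auc"]
  }, numeric(1))
  list(per_kind = per_kind, winner = kinds[which.max(test_auc)],
       test_auc = test_auc)
}
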