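# Classification performance metrics. "AMD" is the positive class
# throughout: Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
# PPV = TP/(TP+FP), NPV = TN/(TN+FN), Accuracy = (TP+TN)/total.

#' Confusion matrix from predicted and true labels
#' @param predicted,truth character vectors of labels.
#' @param positive positive class (default "AMD").
#' @return list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth, positive = "AMD") {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == positive; t <- truth == positive
  list(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Performance metrics from a confusion matrix
#'
#' Zero-denominator metrics are returned as `NA` ("undefined").
#'
#' @param cm list with `tp`, `tn`, `fp`, `fn` (see [confusion_matrix()]).
#' @param as_percent return percentages (default TRUE, matching the usual
#'   reporting scale).
#' @return named numeric vector: accuracy, sensitivity, specificity, ppv, npv.
#' @export
confusion_metrics <- function(cm, as_percent = TRUE) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(
    accuracy = rat(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
    sensitivity = rat(cm$tp, cm$tp + cm$fn),
    specificity = rat(cm$tn, cm$tn + cm$fp),
    ppv = rat(cm$tp, cm$tp + cm$fp),
    npv = rat(cm$tn, cm$tn + cm$fn))
  if (as_percent) out * 100 else out
}

#' ROC-AUC via the rank statistic, with a seeded bootstrap CI
#'
#' AUC equals the probability a positive-class score outranks a
#' negative-class one (ties counted half, i.e. midranks).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels.
#' @param positive positive class (default "AMD").
#' @param ci compute a bootstrap percentile CI (default TRUE).
#' @param n_boot bootstrap replicates. @param seed bootstrap seed.
#' @return list `auc`, `ci` (length-2 or NULL).
#' @export
roc_auc <- function(scores, labels, positive = "AMD", ci = TRUE,
                    n_boot = 2000, seed = 1L) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc_of <- function(sc, ps) {
    r <- rank(sc)  # midranks
    (sum(r[ps]) - sum(ps) * (sum(ps) + 1) / 2) / (sum(ps) * sum(!ps))
  }
  auc <- auc_of(scores, pos)
  ci_out <- NULL
  if (ci) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample(length(scores), replace = TRUE)
      if (length(unique(pos[idx])) < 2) return(NA_real_)
      auc_of(scores[idx], pos[idx])
    }, numeric(1))
    ci_out <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(auc = auc, ci = ci_out)
}

#' Exact binomial CI and test against chance for a proportion
#'
#' Clopper--Pearson 95% CI and an exact binomial test against the
#' no-information rate.
#'
#' @param successes,n counts. @param chance null proportion (default 0.5).
#' @return list `estimate`, `ci`, `p_value`.
#' @export
proportion_ci_and_chance_test <- function(successes, n, chance = 0.5) {
  if (n <= 0) stop("n must be > 0")
  stopifnot(successes >= 0, successes <= n)
  bt <- stats::binom.test(successes, n, p = chance)
  list(estimate = successes / n, ci = as.numeric(bt$conf.int),
       p_value = bt$p.value)
}

#' Cohen's kappa with linear weights and a seeded bootstrap CI
#'
#' `kappa = (po - pc) / (1 - pc)` on weighted agreement, with linear weights
#' `1 - |i - j| / (R - 1)` over the ordered label alphabet; for binary
#' labels this is identical to the unweighted kappa. Undefined (`NA`) when
#' chance agreement is 1.
#'
#' @param a,b equal-length label vectors.
#' @param weighting "linear" or "none".
#' @param ci compute bootstrap percentile CI. @param n_boot,seed bootstrap
#'   controls.
#' @return list `kappa`, `ci`, `table` (the agreement table).
#' @export
cohen_kappa <- function(a, b, weighting = c("linear", "none"), ci = TRUE,
                        n_boot = 2000, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(as.character(a), as.character(b))))
  kap <- function(aa, bb) {
    tab <- table(factor(aa, lev), factor(bb, lev)) / length(aa)
    r <- length(lev)
    w <- if (weighting == "linear" && r > 1) {
      1 - abs(outer(seq_len(r), seq_len(r), `-`)) / (r - 1)
    } else diag(r)
    po <- sum(w * tab)
    pc <- sum(w * outer(rowSums(tab), colSums(tab)))
    if (abs(1 - pc) < 1e-12) return(NA_real_)
    (po - pc) / (1 - pc)
  }
  k <- kap(a, b)
  ci_out <- NULL
  if (ci) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample(length(a), replace = TRUE)
      kap(a[idx], b[idx])
    }, numeric(1))
    ci_out <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(kappa = k, ci = ci_out, table = table(factor(a, lev), factor(b, lev)))
}
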