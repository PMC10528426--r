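# Per-case explanation: each top predictor's value is situated within the
# class-conditional training distribution as an integer percentile (with
# ">100th"/"<1st" marking values outside the training range) and as a
# deviation from the class mean in sigma units.

#' Fit class-conditional reference distributions
#'
#' Stores, per (feature, class), the sorted training values and their
#' moments. Built from training data only; the external/test cases being
#' explained must not enter.
#'
#' @param features data.frame of feature columns (optional `case_id`,
#'   `label` columns ignored).
#' @param labels class labels (each class non-empty).
#' @return object of class `reference_distribution`.
#' @export
fit_reference <- function(features, labels) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 1 || any(table(labels) == 0)) stop("each class must be non-empty")
  feats <- setdiff(colnames(features), c("case_id", "label"))
  per_class <- lapply(cls, function(cl) {
    lapply(stats::setNames(feats, feats), function(f) {
      v <- sort(features[[f]][labels == cl])
      list(values = v, mean = mean(v), sd = stats::sd(v),
           min = v[1], max = v[length(v)])
    })
  })
  structure(list(classes = cls, features = feats,
                 per_class = stats::setNames(per_class, cls)),
            class = "reference_distribution")
}

# Integer percentile of `value` within sorted training values, by the
# inclusive <=-count convention; out-of-range values map to "<1" / ">100".
percentile_string <- function(value, values) {
  if (value > values[length(values)]) return(">100\u00b0")
  if (value < values[1]) return("<1\u00b0")
  paste0(round(100 * sum(values <= value) / length(values)), "\u00b0")
}

#' Explain one case against its predicted class's training distribution
#'
#' For each top predictor: the case value, its percentile within the
#' predicted class's training distribution (integer degrees; values outside
#' the training range print as ">100\u00b0" / "<1\u00b0") and its deviation
#' from the class mean in sigma units, rounded to 0.1. When true labels are
#' available the same comparison against the true class can be requested
#' via `class_label`.
#'
#' @param features named feature vector (or 1-row data.frame) for the case.
#' @param predicted predicted class label.
#' @param ref a [fit_reference()] object.
#' @param top character vector of predictor names in ranking order.
#' @param case_id identifier carried into the report.
#' @param vote_fraction optional overall vote fraction for the case.
#' @param class_label class distribution to compare against (defaults to
#'   `predicted`).
#' @return `case_report` list: `case_id`, `predicted`, `vote_fraction`,
#'   `predictors` data.frame (name, value, percentile, sigma_deviation).
#' @export
explain_case <- function(features, predicted, ref, top, case_id = "case",
                         vote_fraction = NA_real_, class_label = predicted) {
  if (is.data.frame(features)) features <- unlist(features[1, , drop = TRUE])
  if (!class_label %in% ref$classes) stop("class absent from reference: ", class_label)
  missing <- setdiff(top, names(features))
  if (length(missing)) stop("unknown predictor name(s): ",
                            paste(missing, collapse = ", "))
  missing_ref <- setdiff(top, ref$features)
  if (length(missing_ref)) stop("predictor(s) absent from reference: ",
                                paste(missing_ref, collapse = ", "))
  rows <- lapply(top, function(f) {
    rf <- ref$per_class[[class_label]][[f]]
    v <- unname(features[[f]])
    sig <- if (rf$sd > 0) round((v - rf$mean) / rf$sd, 1) else NA_real_
    data.frame(name = f, value = v,
               percentile = percentile_string(v, rf$values),
               sigma_deviation = sig)
  })
  structure(list(case_id = case_id, predicted = predicted,
                 vote_fraction = vote_fraction,
                 class_compared = class_label,
                 predictors = do.call(rbind, rows)),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("Case %s: predicted \"%s\"", x$case_id, x$predicted))
  if (is.finite(x$vote_fraction)) {
    cat(sprintf(" (vote fraction %.2f)", x$vote_fraction))
  }
  cat(sprintf("\nPredictor values (percentile / sigma deviation in the \"%s\" training distribution):\n",
              x$class_compared))
  for (i in seq_len(nrow(x$predictors))) {
    p <- x$predictors[i, ]
    sig <- if (is.na(p$sigma_deviation)) "undefined sigma" else
      sprintf("%+.1f\u03c3", p$sigma_deviation)
    cat(sprintf("  %s: %g (%s/%s)\n", p$name, signif(p$value, 6),
                p$percentile, sig))
  }
  invisible(x)
}

#' Tidy per-class distribution summaries for violin/box visualisation
#'
#' One row per (feature, class): quartiles (default type-7 interpolation),
#' Tukey whiskers and mean/sd, for the listed features.
#'
#' @param ref a [fit_reference()] object.
#' @param features feature names (default: every reference feature).
#' @return data.frame ready for CSV export / plotting.
#' @export
export_distribution_summaries <- function(ref, features = ref$features) {
  rows <- list()
  for (f in features) {
    for (cl in ref$classes) {
      v <- ref$per_class[[cl]][[f]]$values
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, class = cl, n = length(v),
        min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
        whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
        whisker_hi = max(v[v <= q[3] + 1.5 * iqr]),
        mean = mean(v), sd = stats::sd(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
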