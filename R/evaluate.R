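# Segmentation / agreement evaluation: Dice similarity coefficient on
# rasterised circular masks, split summaries with failure breakdown, and the
# manual-vs-automatic ROI agreement analysis.

#' Dice similarity coefficient between two circular ROIs
#'
#' `2 |A intersect B| / (|A| + |B|)` on the rasterised pixel masks (both on
#' the same image extent); symmetric in its arguments.
#'
#' @param a,b `circular_roi` objects on the same extent.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$mask), dim(b$mask)))
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' DSC study: per-case Dice with split and failure breakdown
#'
#' @param predictions named list of `detector_outcome` (or `circular_roi`)
#'   objects keyed by case id.
#' @param references named list of reference `circular_roi` objects with the
#'   same case ids.
#' @param splits optional named character vector of split tags per case.
#' @return list: `per_case` data.frame (case_id, dsc, source, split),
#'   `summaries` (mean/sd by split and by source),
#'   `failure_percent` = round(100 * fallbacks / total).
#' @export
dsc_study <- function(predictions, references, splits = NULL) {
  ids <- names(predictions)
  if (!setequal(ids, names(references))) stop("case id mismatch between predictions and references")
  per_case <- do.call(rbind, lapply(ids, function(id) {
    p <- predictions[[id]]
    roi <- if (inherits(p, "detector_outcome")) p$roi else p
    src <- if (inherits(p, "detector_outcome")) p$source else "model"
    data.frame(case_id = id, dsc = dice(roi, references[[id]]), source = src,
               split = if (is.null(splits)) "all" else splits[[id]])
  }))
  summarise <- function(key) {
    do.call(rbind, lapply(split(per_case, per_case[[key]]), function(s) {
      data.frame(group = s[[key]][1], n = nrow(s),
                 mean_dsc = mean(s$dsc), sd_dsc = stats::sd(s$dsc))
    }))
  }
  list(per_case = per_case,
       summaries = list(by_split = summarise("split"),
                        by_source = summarise("source")),
       failure_percent = fallback_percent(sum(per_case$source == "fallback"),
                                          nrow(per_case)))
}

#' Detector failure percentage
#' @param n_fallback,n_total counts.
#' @return `round(100 * n_fallback / n_total)`.
#' @export
fallback_percent <- function(n_fallback, n_total) {
  round(100 * n_fallback / n_total)
}

#' Manual-vs-automatic ROI classification agreement
#'
#' Linear-weighted Cohen kappa (identical to unweighted for binary labels)
#' between predictions obtained on manual and on automatically detected
#' ROIs for the same cases, plus the 2x2 agreement table.
#'
#' @param predictions_manual,predictions_auto equal-length label vectors
#'   over the same cases (same order).
#' @param seed bootstrap seed for the CI.
#' @return output of [cohen_kappa()].
#' @export
agreement_study <- function(predictions_manual, predictions_auto, seed = 1L) {
  if (length(predictions_manual) != length(predictions_auto)) {
    stop("mismatched case sets")
  }
  cohen_kappa(predictions_manual, predictions_auto, weighting = "linear",
              seed = seed)
}
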