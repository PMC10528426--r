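# Stability-based feature selection: features are re-extracted under random
# rotations of the image plus ROI-centre/radius perturbations (emulating
# segmentation variability and test-retest), kept only when their one-way
# random-effects single-rater ICC across variants exceeds a threshold
# (default 0.80). Univariate predictor ranking uses the Wilcoxon rank-sum
# test with Bonferroni correction at the 0.05 / 0.005 significance levels.

#' Augmentation specification for the stability study
#'
#' Defaults (magnitudes are package choices; the perturbation protocol is
#' rotation of image + ROI about the image centre, and jitter of the ROI
#' centre and radius): 5 variants, rotations within +/-15 degrees, centre
#' jitter +/-10 px, radius jitter +/-10 %.
#'
#' @param n_variants number of perturbed variants per case (>= 2).
#' @param rotation_range max absolute rotation in degrees.
#' @param roi_jitter_px max absolute ROI centre jitter per axis, px (at
#'   native scale; scaled by `scale`).
#' @param roi_radius_jitter_frac max relative radius jitter.
#' @param scale linear scale factor matching the image scale (default 1).
#' @param seed integer seed.
#' @return `augmentation_spec` list.
#' @export
augmentation_spec <- function(n_variants = 5, rotation_range = 15,
                              roi_jitter_px = 10, roi_radius_jitter_frac = 0.10,
                              scale = 1, seed = 1L) {
  stopifnot(n_variants >= 2, rotation_range >= 0, roi_jitter_px >= 0,
            roi_radius_jitter_frac >= 0)
  structure(list(n_variants = as.integer(n_variants),
                 rotation_range = rotation_range,
                 roi_jitter_px = roi_jitter_px * scale,
                 roi_radius_jitter_frac = roi_radius_jitter_frac,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Generate perturbed (image, ROI) variants of one case
#'
#' Each variant rotates the image and the ROI centre together about the
#' image centre by a seeded uniform angle, then jitters the ROI centre and
#' radius. Deterministic per `(spec$seed, case_seed_offset)`.
#'
#' @param image image matrix.
#' @param roi a [roi_from_center()] ROI.
#' @param spec an [augmentation_spec()].
#' @param case_seed_offset integer distinguishing cases under one spec seed.
#' @return list of `list(image, roi)` variants (length `spec$n_variants`).
#' @export
augment_case <- function(image, roi, spec, case_seed_offset = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, case_seed_offset))
  ext <- image_extent(image)
  lapply(seq_len(spec$n_variants), function(v) {
    ang <- stats::runif(1, -spec$rotation_range, spec$rotation_range)
    jit <- stats::runif(2, -spec$roi_jitter_px, spec$roi_jitter_px)
    rjit <- stats::runif(1, -spec$roi_radius_jitter_frac,
                         spec$roi_radius_jitter_frac)
    img_v <- rotate_image(image, ang)
    ctr_v <- rotate_point(c(roi$center_x, roi$center_y), ang, ext) + jit
    rad_v <- roi$radius * (1 + rjit)
    ctr_v <- pmin(pmax(ctr_v, rad_v), ext - 1 - rad_v)
    if (any(ctr_v < rad_v - 1e-9)) {
      stop("ROI jitter pushes the ROI out of the image bounds")
    }
    list(image = img_v, roi = roi_from_center(ctr_v, rad_v, ext))
  })
}

#' One-way random-effects, single-rater intraclass correlation ICC(1,1)
#'
#' `(MS_between - MS_within) / (MS_between + (k - 1) MS_within)` from the
#' one-way ANOVA decomposition of a cases x repeats matrix. When the total
#' variance is zero the ICC is undefined and `NA` is returned.
#'
#' @param m numeric matrix, rows = cases, columns = repeated measurements.
#' @return ICC value in \[-1, 1\], or `NA` if undefined.
#' @export
icc_1_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC(1,1) needs >= 2 cases and >= 2 repeats")
  if (anyNA(m)) stop("ICC(1,1) input must be complete")
  grand <- mean(m)
  rmeans <- rowMeans(m)
  ssb <- k * sum((rmeans - grand)^2)
  ssw <- sum((m - rmeans)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Stability-based feature selection across augmentation variants
#'
#' Computes ICC(1,1) per feature over a list of feature tables (one per
#' variant, identical case sets/order) and retains features with
#' `ICC > threshold`. Undefined ICCs (zero variance) are reported as `NA`
#' and dropped.
#'
#' @param tables list of feature data.frames (case_id + feature columns; a
#'   `label` column is ignored), one per augmentation variant.
#' @param threshold retention threshold (default 0.80, strict inequality).
#' @return data.frame `feature`, `icc`, `retained` (the stability report).
#' @export
select_stable <- function(tables, threshold = 0.80) {
  if (length(tables) < 2) stop("need >= 2 variants per case")
  ids <- lapply(tables, function(t) t$case_id)
  if (length(unique(lapply(ids, as.character))) != 1) {
    stop("mismatched case sets across variants")
  }
  feats <- setdiff(colnames(tables[[1]]), c("case_id", "label"))
  icc <- vapply(feats, function(f) {
    m <- vapply(tables, function(t) t[[f]], numeric(nrow(tables[[1]])))
    if (anyNA(m) || any(!is.finite(m))) return(NA_real_)
    icc_1_1(m)
  }, numeric(1))
  # strict inequality; perfectly repeatable features (exact ICC 1, zero
  # within-case variance) survive any threshold up to 1
  data.frame(feature = feats, icc = icc,
             retained = !is.na(icc) & (icc > threshold | icc >= 1),
             row.names = NULL)
}

# Seeded percentile-bootstrap CI of the median.
median_ci <- function(x, n_boot = 2000, conf = 0.95, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  meds <- vapply(seq_len(n_boot),
                 function(i) stats::median(sample(x, replace = TRUE)),
                 numeric(1))
  stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
}

#' Univariate predictor ranking (Wilcoxon rank-sum + Bonferroni)
#'
#' Per feature: two-sided rank-sum p (exact for <= 25 cases per class
#' without ties, normal approximation with tie correction otherwise -- the
#' `stats::wilcox.test` defaults), Bonferroni-corrected over the number of
#' features tested, class medians with seeded bootstrap 95% CIs, and an
#' optional classifier selection frequency. Constant features get p = 1 by
#' convention. Ranking: corrected p ascending, then frequency descending.
#'
#' @param features data.frame of feature columns (plus optional
#'   `case_id`/`label` columns, ignored for testing).
#' @param labels class labels ("AMD" / "Negative" or any two levels).
#' @param alpha significance levels reported against (default 0.05, 0.005).
#' @param frequencies optional named numeric vector of per-feature selection
#'   frequencies in the classifiers (see [selection_frequencies()]; defaults
#'   to 0). Used as the secondary ranking key; corrected p-values below
#'   machine epsilon count as tied on the primary key.
#' @param ci_seed seed for the bootstrap CIs.
#' @return data.frame ranking: feature, class medians and CIs, p values,
#'   significance flags, frequency, rank.
#' @export
rank_predictors <- function(features, labels, alpha = c(0.05, 0.005),
                            frequencies = NULL, ci_seed = 1L) {
  feats <- setdiff(colnames(features), c("case_id", "label"))
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("need exactly two non-empty classes")
  pos <- if ("AMD" %in% cls) "AMD" else cls[1]
  neg <- setdiff(cls, pos)
  m <- length(feats)
  rows <- lapply(seq_along(feats), function(fi) {
    f <- feats[fi]
    xa <- features[[f]][labels == pos]
    xb <- features[[f]][labels == neg]
    p <- if (length(unique(c(xa, xb))) < 2) 1 else
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    cia <- median_ci(xa, seed = derive_seed(ci_seed, 2 * fi))
    cib <- median_ci(xb, seed = derive_seed(ci_seed, 2 * fi + 1))
    data.frame(feature = f,
               median_pos = stats::median(xa), ci_lo_pos = cia[1], ci_hi_pos = cia[2],
               median_neg = stats::median(xb), ci_lo_neg = cib[1], ci_hi_neg = cib[2],
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant_0.05 <- out$p_corrected < alpha[1]
  out$significant_0.005 <- out$p_corrected < alpha[2]
  freq <- rep(0, m)
  if (!is.null(frequencies)) {
    freq <- unname(frequencies[out$feature])
    freq[is.na(freq)] <- 0
  }
  out$frequency <- freq
  # Corrected p-values below machine epsilon carry no statistical
  # information (the familiar "< 2.2e-16" reporting floor for the normal
  # approximation); they are treated as ties for ordering so the secondary
  # key -- selection frequency in the classifiers -- can discriminate.
  ord <- order(pmax(out$p_corrected, .Machine$double.eps), -out$frequency)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "positive_class") <- pos
  attr(out, "n_tests") <- m
  out
}
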