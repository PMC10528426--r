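# Radiomic feature extraction: preprocessing (grayscale, 2:1 mean-pool
# down-sampling), fixed-bin-number discretisation and the two intensity
# families, plus assembly of the full catalogue-ordered feature vector.

#' Fixed-bin-number intensity discretisation
#'
#' `level = min(n_bins, 1 + floor(n_bins * (x - min) / (max - min)))` over
#' in-mask intensities; a constant ROI (max == min) maps every pixel to
#' level 1.
#'
#' @param image numeric matrix image.
#' @param mask logical matrix (same dim) selecting ROI pixels.
#' @param n_bins number of bins (default 64).
#' @return list: `levels` (integer matrix, NA outside mask), `n_bins`,
#'   `range` (min/max intensities used).
#' @export
discretise <- function(image, mask, n_bins = 64) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask)) stop("empty mask")
  x <- image[mask]
  lo <- min(x); hi <- max(x)
  lv <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi > lo) {
    lv[mask] <- pmin(n_bins, 1L + as.integer(floor(n_bins * (x - lo) / (hi - lo))))
  } else {
    lv[mask] <- 1L
  }
  list(levels = lv, n_bins = as.integer(n_bins), range = c(min = lo, max = hi))
}

intensity_stat_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum",
  "percentile_10", "percentile_90", "maximum", "interquartile_range",
  "range", "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation",
  "quartile_coefficient_of_dispersion", "energy", "root_mean_square")

#' Intensity-based statistics on raw in-mask intensities
#'
#' Moments use the population (1/N) convention; skewness is 0 and excess
#' kurtosis -3 for zero-variance input; percentiles use the default (type 7)
#' quantile rule throughout the package.
#'
#' @param x numeric vector of in-mask intensities.
#' @return named numeric vector (18 features).
#' @export
intensity_features <- function(x) {
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rob <- x[x >= qs[1] & x <= qs[5]]
  c(mean = mu,
    variance = m2,
    skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else -3,
    median = qs[3],
    minimum = min(x),
    percentile_10 = qs[1],
    percentile_90 = qs[5],
    maximum = max(x),
    interquartile_range = qs[4] - qs[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation = mean(abs(rob - mean(rob))),
    median_absolute_deviation = mean(abs(x - qs[3])),
    coefficient_of_variation = if (mu != 0) sqrt(m2) / mu else NaN,
    quartile_coefficient_of_dispersion =
      if (qs[4] + qs[2] != 0) (qs[4] - qs[2]) / (qs[4] + qs[2]) else NaN,
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2)))
}

intensity_hist_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum",
  "percentile_10", "percentile_90", "maximum", "mode",
  "interquartile_range", "range", "mean_absolute_deviation",
  "robust_mean_absolute_deviation", "median_absolute_deviation",
  "coefficient_of_variation", "quartile_coefficient_of_dispersion",
  "entropy", "uniformity", "maximum_gradient", "maximum_gradient_level",
  "minimum_gradient", "minimum_gradient_level")

#' Intensity-histogram features on discretised levels
#'
#' Statistics of the level distribution plus entropy (base 2), uniformity,
#' and histogram-gradient features; the mode takes the lowest level on ties.
#'
#' @param levels integer vector of in-mask discretised levels (1..n_bins).
#' @param n_bins number of bins the levels were discretised to.
#' @return named numeric vector (23 features).
#' @export
histogram_features <- function(levels, n_bins) {
  if (length(levels) == 0) stop("empty mask")
  cnt <- tabulate(levels, n_bins)
  p <- cnt / sum(cnt)
  base <- intensity_features(levels)
  # histogram gradient over occupied level axis 1..n_bins
  grad <- c(cnt[2] - cnt[1],
            if (n_bins > 2) (cnt[3:n_bins] - cnt[1:(n_bins - 2)]) / 2,
            cnt[n_bins] - cnt[n_bins - 1])
  c(base[c("mean", "variance", "skewness", "kurtosis", "median", "minimum",
           "percentile_10", "percentile_90", "maximum")],
    mode = which.max(cnt),
    base[c("interquartile_range", "range", "mean_absolute_deviation",
           "robust_mean_absolute_deviation", "median_absolute_deviation",
           "coefficient_of_variation", "quartile_coefficient_of_dispersion")],
    entropy = -sum(xlog2(p)),
    uniformity = sum(p^2),
    maximum_gradient = max(grad),
    maximum_gradient_level = which.max(grad),
    minimum_gradient = min(grad),
    minimum_gradient_level = which.min(grad))
}

# ----------------------------------------------------------- catalogue ----

family_display <- c(
  stat = "Intensity-Based Statistics",
  hist = "Intensity Histogram",
  glcm = "Grey-Level Co-Occurrence Matrix",
  glrlm = "Grey-Level Run Length Matrix",
  glszm = "Grey-Level Size Zone Matrix",
  gldzm = "Grey-Level Distance Zone Matrix",
  ngtdm = "Neighbourhood Grey Tone Difference Matrix",
  ngldm = "Neighbouring Grey Level Dependence Matrix")

titleize <- function(s) {
  s <- gsub("_", " ", s)
  gsub("\\b([a-z])", "\\U\\1", s, perl = TRUE)
}

glcm_feature_names <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
  "contrast", "dissimilarity", "inverse_difference",
  "inverse_difference_normalised", "inverse_difference_moment",
  "inverse_difference_moment_normalised", "inverse_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "information_correlation_1",
  "information_correlation_2")

ngtdm_feature_names <- c("coarseness", "contrast", "busyness", "complexity",
                         "strength")

#' The default 270-entry radiomic feature catalogue
#'
#' Composition (a versioned package choice; a YAML copy ships under
#' `inst/extdata/feature_catalogue_v1.yaml`): intensity statistics (18) and
#' intensity histogram (23) once; GLCM under both aggregation schemes at
#' pixel distances 1 and 2 (100); GLRLM under both aggregation schemes (32);
#' GLSZM with 8- and 4-connected zones (32); GLDZM (16); NGTDM at
#' neighbourhood radii 1--3 (15); NGLDM at alpha 0 and 1 (34).
#'
#' @return data.frame with columns `id` (unique machine name), `family`
#'   (display family), `feature`, `variant` (aggregation/parameter tag) and
#'   `name` (full display nomenclature).
#' @export
default_catalogue <- function() {
  rows <- list()
  add <- function(fam, ids, tag = "", label = "") {
    prefix <- if (nzchar(tag)) paste0(fam, ".", tag, ".") else paste0(fam, ".")
    rows[[length(rows) + 1]] <<- data.frame(
      id = paste0(prefix, ids),
      family = family_display[[fam]],
      feature = titleize(ids),
      variant = label,
      name = paste0(family_display[[fam]], " ", titleize(ids),
                    if (nzchar(label)) paste0(" [", label, "]") else ""))
  }
  add("stat", intensity_stat_names)
  add("hist", intensity_hist_names)
  for (dd in 1:2) for (ag in c("avg", "mrg")) {
    add("glcm", glcm_feature_names, paste0("d", dd, ".", ag),
        paste0("distance ", dd, ", ", if (ag == "avg") "averaged" else "merged"))
  }
  for (ag in c("avg", "mrg")) {
    add("glrlm", glrlm_names, ag,
        if (ag == "avg") "averaged" else "merged")
  }
  for (cn in c(8, 4)) {
    add("glszm", glszm_names, paste0("c", cn), paste0(cn, "-connected"))
  }
  add("gldzm", gldzm_names)
  for (dd in 1:3) {
    add("ngtdm", ngtdm_feature_names, paste0("d", dd), paste0("distance ", dd))
  }
  for (al in 0:1) {
    add("ngldm", ngldm_names, paste0("a", al), paste0("alpha ", al))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a feature catalogue from its YAML form
#' @param path YAML file with a list of blocks `(family, tag, label,
#'   features)` as written by [write_catalogue()].
#' @return catalogue data.frame (see [default_catalogue()]).
#' @export
read_catalogue <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(y$blocks, function(b) {
    prefix <- if (nzchar(b$tag %||% "")) paste0(b$prefix, ".", b$tag, ".") else
      paste0(b$prefix, ".")
    data.frame(id = paste0(prefix, unlist(b$features)),
               family = b$family, feature = titleize(unlist(b$features)),
               variant = b$label %||% "",
               name = paste0(b$family, " ", titleize(unlist(b$features)),
                             if (nzchar(b$label %||% "")) paste0(" [", b$label, "]") else ""))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a catalogue data.frame to YAML
#' @param catalogue catalogue data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  key <- paste(catalogue$family, catalogue$variant, sep = "\r")
  blocks <- lapply(unique(key), function(k) {
    sub <- catalogue[key == k, ]
    id1 <- strsplit(sub$id[1], ".", fixed = TRUE)[[1]]
    list(prefix = id1[1], family = sub$family[1],
         tag = if (length(id1) > 2) paste(id1[-c(1, length(id1))], collapse = ".") else "",
         label = sub$variant[1],
         features = vapply(strsplit(sub$id, ".", fixed = TRUE),
                           function(p) p[length(p)], character(1)))
  })
  yaml::write_yaml(list(version = "v1", blocks = blocks), path)
  invisible(path)
}

# ------------------------------------------------------------- extract ----

# Compute one catalogue block worth of features from a discretised ROI.
compute_block <- function(prefix_tag, disc, values) {
  lv <- disc$levels; nb <- disc$n_bins
  parts <- strsplit(prefix_tag, ".", fixed = TRUE)[[1]]
  fam <- parts[1]
  switch(fam,
    stat = intensity_features(values),
    hist = histogram_features(lv[!is.na(lv)], nb),
    glcm = {
      dd <- as.integer(sub("d", "", parts[2]))
      glcm_family(lv, nb, distance = dd, agg = parts[3])
    },
    glrlm = glrlm_features(lv, nb, agg = parts[2]),
    glszm = glszm_features(lv, nb, connectivity = as.integer(sub("c", "", parts[2]))),
    gldzm = gldzm_features(lv, nb),
    ngtdm = ngtdm_features(lv, nb, dist = as.integer(sub("d", "", parts[2]))),
    ngldm = ngldm_features(lv, nb, alpha = as.integer(sub("a", "", parts[2]))),
    stop("unknown feature family: ", fam))
}

#' Extract the radiomic feature vector from a circular ROI
#'
#' Pipeline: grayscale conversion, optional 2:1 mean-pool down-sampling
#' (with the ROI scaled accordingly), fixed-bin-number discretisation, then
#' every matrix/intensity family the catalogue requests. Deterministic.
#'
#' @param image image matrix (or RGB array).
#' @param roi a [roi_from_center()] ROI on the full-resolution image.
#' @param catalogue catalogue data.frame (default [default_catalogue()]).
#' @param n_bins discretisation bins (default 64).
#' @param downsample apply the 2:1 down-sampling step (default TRUE).
#' @return named numeric vector in catalogue order (`catalogue$id` names).
#' @export
extract_features <- function(image, roi, catalogue = default_catalogue(),
                             n_bins = 64, downsample = TRUE) {
  img <- to_grayscale(image)
  if (downsample) {
    img <- downsample_2to1(img)
    roi <- scale_roi(roi, 0.5, image_extent(img))
  }
  stopifnot(identical(unname(dim(roi$mask)), unname(dim(img))))
  disc <- discretise(img, roi$mask, n_bins)
  values <- img[roi$mask]
  # restrict the matrix families to the mask bounding box (identical
  # results, far less dead computation on the NA frame)
  rr <- range(which(rowSums(roi$mask) > 0))
  cc <- range(which(colSums(roi$mask) > 0))
  disc$levels <- disc$levels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  block_of <- sub("\\.[a-z_0-9]+$", "", catalogue$id)
  out <- numeric(0)
  for (bk in unique(block_of)) {
    f <- tryCatch(compute_block(bk, disc, values),
                  error = function(e) stop("feature family block '", bk,
                                           "' failed: ", conditionMessage(e)))
    ids <- catalogue$id[block_of == bk]
    names(f) <- ids  # block functions emit features in catalogue order
    out <- c(out, f)
  }
  out[catalogue$id]
}

#' Extract a feature table for many cases
#'
#' @param records list of `list(image, roi, case_id, label)` entries (label
#'   optional).
#' @param catalogue,n_bins,downsample passed to [extract_features()].
#' @return data.frame: `case_id`, `label` (if supplied), then one column per
#'   catalogue feature.
#' @export
extract_feature_table <- function(records, catalogue = default_catalogue(),
                                  n_bins = 64, downsample = TRUE) {
  vecs <- lapply(records, function(r) {
    extract_features(r$image, r$roi, catalogue, n_bins, downsample)
  })
  tab <- as.data.frame(do.call(rbind, vecs))
  ids <- vapply(seq_along(records), function(i) {
    records[[i]]$case_id %||% sprintf("case_%03d", i)
  }, character(1))
  labs <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  cbind(data.frame(case_id = ids, label = labs), tab)
}
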