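# Macula localisation. The production system this mirrors used a trained
# object detector; here the detector is a pluggable contract (image -> list
# of bounding boxes with confidences) with a matched-filter default, plus the
# fixed crop prior, highest-confidence selection and mean-position fallback.

#' Crop window prior for the macular region
#'
#' At the native 3900 x 3072 resolution the retained pixel ranges are
#' 901--2700 on x and 801--2600 on y (1-based inclusive, giving a square
#' 1800 x 1800 field). For other resolutions the same window is applied
#' fractionally: 0-based start `round((lo - 1) / W_native * W)` and extent
#' `round((hi - lo + 1) / W_native * W)`.
#'
#' @param x_range,y_range 1-based inclusive pixel ranges at native resolution.
#' @param native_extent `c(width, height)` the ranges refer to.
#' @return object of class `crop_window`.
#' @export
crop_window <- function(x_range = c(901, 2700), y_range = c(801, 2600),
                        native_extent = c(3900, 3072)) {
  stopifnot(x_range[1] >= 1, y_range[1] >= 1,
            x_range[2] <= native_extent[1], y_range[2] <= native_extent[2])
  structure(list(x_range = x_range, y_range = y_range,
                 native_extent = native_extent),
            class = "crop_window")
}

# 0-based start and extent of the window on an image of the given extent.
window_geometry <- function(window, extent) {
  fx0 <- (window$x_range[1] - 1) / window$native_extent[1]
  fy0 <- (window$y_range[1] - 1) / window$native_extent[2]
  fw <- diff(window$x_range + c(-1, 0)) / window$native_extent[1]
  fh <- diff(window$y_range + c(-1, 0)) / window$native_extent[2]
  x0 <- round(fx0 * extent[1]); y0 <- round(fy0 * extent[2])
  w <- round(fw * extent[1]); h <- round(fh * extent[2])
  if (x0 + w > extent[1] || y0 + h > extent[2]) {
    stop("crop window lies outside the image (extent ",
         extent[1], " x ", extent[2], ")")
  }
  list(x0 = x0, y0 = y0, width = w, height = h)
}

#' Crop an image to the macular field
#'
#' Pixel values are untouched; the 0-based origin of the crop within the
#' source image is attached as attribute `"origin"` so detections can be
#' mapped back to full-image coordinates.
#'
#' @param image numeric matrix image.
#' @param window a [crop_window()].
#' @return cropped image with attribute `origin = c(x0, y0)`.
#' @export
crop_field <- function(image, window = crop_window()) {
  g <- window_geometry(window, image_extent(image))
  out <- image[(g$y0 + 1):(g$y0 + g$height), (g$x0 + 1):(g$x0 + g$width),
               drop = FALSE]
  attr(out, "origin") <- c(x = g$x0, y = g$y0)
  out
}

#' Crop-window margins as percentages and in sigma units
#'
#' Expresses each window bound as a rounded percentage of the native image
#' size, and the distance from the bound to the mean position of the nearest
#' ROI border (centre -/+ radius) in units of the matching centre SD,
#' rounded to integer.
#'
#' @param window a [crop_window()].
#' @param roi_center_mean,roi_center_std mean and SD (x, y) of ROI centres.
#' @param radius ROI radius in px.
#' @return list with `percent` (x_lo, x_hi, y_lo, y_hi) and `sigma` margins.
#' @export
crop_margins_report <- function(window, roi_center_mean = c(1971, 1588),
                                roi_center_std = c(46, 52), radius = 250) {
  if (any(roi_center_std <= 0)) stop("ROI centre SD components must be > 0")
  ne <- window$native_extent
  pct <- round(100 * c(window$x_range / ne[1], window$y_range / ne[2]))
  sig <- round(c(
    (roi_center_mean[1] - radius - window$x_range[1]) / roi_center_std[1],
    (window$x_range[2] - (roi_center_mean[1] + radius)) / roi_center_std[1],
    (roi_center_mean[2] - radius - window$y_range[1]) / roi_center_std[2],
    (window$y_range[2] - (roi_center_mean[2] + radius)) / roi_center_std[2]))
  names(pct) <- names(sig) <- c("x_lo", "x_hi", "y_lo", "y_hi")
  list(percent = pct, sigma = sig)
}

#' Bounding box
#' @param x,y 0-based top-left corner. @param width,height box size in px.
#' @param confidence detector score in \[0, 1\].
#' @return a `bounding_box` list.
#' @export
bounding_box <- function(x, y, width, height, confidence) {
  stopifnot(width > 0, height > 0, confidence >= 0, confidence <= 1)
  structure(list(x = x, y = y, width = width, height = height,
                 confidence = confidence), class = "bounding_box")
}

#' Select the accepted detection of highest confidence
#'
#' Returns the centre (corner + half size) of the box with maximal
#' confidence among those reaching `accept_threshold`, or `NULL` when none
#' does. Ties break by input order.
#'
#' @param boxes list of [bounding_box()] objects.
#' @param accept_threshold minimum confidence for a box to count.
#' @return `c(x, y)` centre or `NULL`.
#' @export
select_detection <- function(boxes, accept_threshold = 0.5) {
  if (length(boxes) == 0) return(NULL)
  conf <- vapply(boxes, function(b) b$confidence, numeric(1))
  ok <- which(conf >= accept_threshold)
  if (length(ok) == 0) return(NULL)
  best <- ok[which.max(conf[ok])]
  b <- boxes[[best]]
  c(x = b$x + b$width / 2, y = b$y + b$height / 2)
}

#' Mean ROI centre used as detection fallback
#'
#' @param training_rois non-empty list of ROIs (anything with `center_x`,
#'   `center_y` fields, e.g. [roi_from_center()] output).
#' @return `c(x, y)` arithmetic mean of centres, rounded to nearest pixel.
#' @export
fallback_center <- function(training_rois) {
  if (length(training_rois) == 0) stop("empty training ROI list")
  xs <- vapply(training_rois, function(r) r$center_x, numeric(1))
  ys <- vapply(training_rois, function(r) r$center_y, numeric(1))
  c(x = round(mean(xs)), y = round(mean(ys)))
}

#' Matched-filter macula detector
#'
#' Default detector honouring the box+confidence contract: normalised
#' cross-correlation of the image against a Gaussian-feathered dark-disc
#' template of the macular radius, computed with FFT filtering. Local
#' correlation peaks (greedy non-maximum suppression at one radius
#' separation) become bounding boxes whose confidence is the correlation
#' clamped to \[0, 1\]. A trained detector can be plugged into
#' [detect_macula()] unchanged.
#'
#' @param radius ROI (macula) radius in px on the image the detector will
#'   see; reported boxes have side `2 * radius`.
#' @param profile_scale ratio of the dark-blob template radius to `radius`
#'   (the macular darkening extends beyond the analysis ROI; default 1.5).
#' @param feather fraction of the template radius over which the dark core
#'   ramps back to background.
#' @param max_boxes number of correlation peaks to report.
#' @return function: image matrix -> list of [bounding_box()].
#' @export
matched_filter_detector <- function(radius, profile_scale = 1.5,
                                    feather = 0.25, max_boxes = 3) {
  r <- radius
  rt <- profile_scale * radius
  side <- 2 * ceiling(1.05 * rt) + 1
  cc <- (side - 1) / 2
  d <- sqrt(outer(((0:(side - 1)) - cc)^2, ((0:(side - 1)) - cc)^2, `+`))
  core <- (1 - feather) * rt
  tmpl <- ifelse(d <= core, -1,
                 ifelse(d >= rt, 0, -0.5 * (1 + cos(pi * (d - core) / (rt - core)))))
  t0 <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(t0^2))
  n <- length(t0)
  ones <- matrix(1, side, side)

  function(image) {
    stopifnot(is.matrix(image))
    num <- EBImage::filter2(image, t0, boundary = "replicate")
    s1 <- EBImage::filter2(image, ones, boundary = "replicate")
    s2 <- EBImage::filter2(image^2, ones, boundary = "replicate")
    denom <- sqrt(pmax(s2 - s1^2 / n, 1e-9))
    ncc <- num / (tnorm * denom)
    # exclude a half-template border band from peak search
    m <- ceiling(cc / 2)
    h <- nrow(ncc); w <- ncol(ncc)
    valid <- matrix(FALSE, h, w)
    valid[(m + 1):(h - m), (m + 1):(w - m)] <- TRUE
    boxes <- list()
    for (k in seq_len(max_boxes)) {
      idx <- which(valid)
      if (length(idx) == 0) break
      best <- idx[which.max(ncc[idx])]
      by <- (best - 1) %% h; bx <- (best - 1) %/% h
      conf <- min(1, max(0, ncc[best]))
      boxes[[k]] <- bounding_box(bx - r, by - r, 2 * r, 2 * r, conf)
      sup_x <- pmax(1, bx + 1 - r):pmin(w, bx + 1 + r)
      sup_y <- pmax(1, by + 1 - r):pmin(h, by + 1 + r)
      valid[sup_y, sup_x] <- FALSE
    }
    boxes
  }
}

#' Locate the macula and emit the fixed-radius circular ROI
#'
#' Composes the crop prior, the pluggable detector, highest-confidence
#' selection and the circular-ROI construction; when no detection reaches
#' `accept_threshold` the ROI is centred at `fallback` and the outcome is
#' tagged `source = "fallback"`.
#'
#' @param image full fundus image (matrix).
#' @param detector function image -> list of [bounding_box()] (runs on the
#'   cropped field); default: [matched_filter_detector()] at `radius` scaled
#'   for the crop.
#' @param fallback `c(x, y)` full-image fallback centre (see
#'   [fallback_center()]).
#' @param radius ROI radius in px.
#' @param window crop prior, a [crop_window()].
#' @param accept_threshold detection acceptance threshold (correlation units
#'   for the default detector; the production cut-off is not standardised, so
#'   it stays configurable).
#' @return `detector_outcome` list: `roi` ([roi_from_center()]), `source`
#'   (`"model"` or `"fallback"`), `raw_boxes`.
#' @export
detect_macula <- function(image, detector = NULL, fallback, radius,
                          window = crop_window(), accept_threshold = 0.5) {
  field <- crop_field(image, window)
  if (is.null(detector)) detector <- matched_filter_detector(radius)
  boxes <- tryCatch(detector(field),
                    error = function(e) stop("detector failed: ",
                                             conditionMessage(e)))
  ctr <- select_detection(boxes, accept_threshold)
  origin <- attr(field, "origin")
  if (is.null(ctr)) {
    ctr_full <- c(x = fallback[[1]], y = fallback[[2]])
    source <- "fallback"
  } else {
    ctr_full <- c(x = ctr[[1]] + origin[[1]], y = ctr[[2]] + origin[[2]])
    source <- "model"
  }
  structure(list(roi = roi_from_center(ctr_full, radius, image_extent(image)),
                 source = source, raw_boxes = boxes),
            class = "detector_outcome")
}

#' Preprocess annotated pairs for detector training
#'
#' Mirrors the annotation preprocessing used for detector training: halve
#' the ROI radius, then resample the (already cropped, square) image to
#' `target` x `target`, scaling centre and radius by `target / side`.
#'
#' @param pairs list of `list(image, roi)` with square images; `roi` needs
#'   `center_x`, `center_y`, `radius`.
#' @param target output side in px (default 300).
#' @return list of `list(image, center, radius)` resampled pairs.
#' @export
preprocess_annotations <- function(pairs, target = 300) {
  lapply(pairs, function(p) {
    side <- nrow(p$image)
    if (ncol(p$image) != side) {
      stop("non-square input (", ncol(p$image), " x ", side,
           "): crop must be applied before resampling")
    }
    s <- target / side
    img <- if (side == target) p$image else
      as.matrix(EBImage::resize(p$image, w = target, h = target))
    list(image = img,
         center = c(x = p$roi$center_x * s, y = p$roi$center_y * s),
         radius = (p$roi$radius / 2) * s)
  })
}
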