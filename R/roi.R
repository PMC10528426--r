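# Circular regions of interest (the unit the whole pipeline consumes): a
# centre, a fixed radius (250 px at native resolution, ~2 mm on the retina)
# and the rasterised pixel mask, whose cardinality is the |A| / |B| entering
# the Dice similarity coefficient.

#' Circular region of interest
#'
#' A pixel belongs to the mask iff the Euclidean distance from its centre to
#' `center` is `<= radius`; the mask is clipped to the image extent.
#'
#' @param center numeric length-2, 0-based (x, y) centre (may be fractional).
#' @param radius circle radius in pixels (> 0).
#' @param extent `c(width, height)` of the image the ROI lives on.
#' @return object of class `circular_roi`: list with `center_x`, `center_y`,
#'   `radius`, `extent` and logical `mask` (height x width).
#' @export
roi_from_center <- function(center, radius, extent) {
  stopifnot(length(center) == 2, radius > 0, length(extent) == 2)
  w <- as.integer(extent[[1]]); h <- as.integer(extent[[2]])
  cx <- center[[1]]; cy <- center[[2]]
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    stop("ROI center (", cx, ", ", cy, ") lies outside the image extent ",
         w, " x ", h)
  }
  dx2 <- (0:(w - 1) - cx)^2
  dy2 <- (0:(h - 1) - cy)^2
  mask <- outer(dy2, dx2, `+`) <= radius^2
  structure(
    list(center_x = cx, center_y = cy, radius = radius,
         extent = c(width = w, height = h), mask = mask),
    class = "circular_roi"
  )
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi> center (%.1f, %.1f), radius %.1f, |mask| = %d\n",
              x$center_x, x$center_y, x$radius, roi_cardinality(x)))
  invisible(x)
}

#' Mask cardinality (pixel count) of a circular ROI
#' @param roi a `circular_roi`.
#' @return integer pixel count.
#' @export
roi_cardinality <- function(roi) sum(roi$mask)

#' Scale a circular ROI by a linear factor
#'
#' Used when the underlying image is resampled (e.g. the 2:1 down-sampling
#' before feature extraction): centre and radius scale linearly and the mask
#' is re-rasterised on the new extent.
#'
#' @param roi a `circular_roi`.
#' @param factor linear scale factor.
#' @param extent new image extent `c(width, height)`.
#' @return scaled `circular_roi`.
#' @export
scale_roi <- function(roi, factor, extent) {
  roi_from_center(c(roi$center_x * factor, roi$center_y * factor),
                  roi$radius * factor, extent)
}

#' Read / write ROI JSON files
#'
#' The on-disk format is `{"center": [x, y], "radius": r}` per ROI, with a
#' named object per case when several ROIs share a file.
#'
#' @param rois named list of `circular_roi` objects.
#' @param path JSON path.
#' @return `path` invisibly (`write_rois`); named list of bare
#'   `list(center, radius)` records (`read_rois` -- masks are re-rasterised
#'   lazily since the extent lives with the image, not the file).
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) {
    list(center = c(r$center_x, r$center_y), radius = r$radius)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(r) list(center = as.numeric(r$center),
                             radius = as.numeric(r$radius)))
}
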