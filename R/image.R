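#' @keywords internal
"_PACKAGE"

# Image convention used throughout the package:
#  * an image is a plain numeric matrix with rows = y (top to bottom) and
#    cols = x (left to right), intensities on the 8-bit scale [0, 255];
#  * pixel coordinates are 0-based, (x right, y down), so pixel (x, y) is
#    stored at img[y + 1, x + 1];
#  * the centre of pixel (x, y) is the point (x, y) -- circle membership and
#    all geometry are measured between pixel centres.

#' Dimensions of an image
#'
#' @param img numeric matrix image.
#' @return named numeric vector `c(width, height)` in pixels.
#' @export
image_extent <- function(img) {
  stopifnot(is.matrix(img))
  c(width = ncol(img), height = nrow(img))
}

#' Convert an image to grayscale
#'
#' Accepts a single-channel matrix (returned unchanged) or a 3-channel RGB
#' array (height x width x 3), which is collapsed with the Rec. 601 luma
#' weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img matrix or 3d array on the \[0, 255\] scale.
#' @return numeric matrix (grayscale image).
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc == 1) return(img[, , 1])
    if (nc == 3) {
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    }
    stop("unsupported channel count: ", nc)
  }
  stop("expected a matrix or a height x width x channels array")
}

#' 2:1 down-sampling by 2x2 mean pooling
#'
#' Each output pixel is the mean of the corresponding 2x2 input block; for
#' odd side lengths the trailing edge blocks average over the available
#' (1- or 2-pixel wide) remainder, so output sides are `ceiling(input / 2)`.
#'
#' @param img numeric matrix image.
#' @return pooled numeric matrix.
#' @export
downsample_2to1 <- function(img) {
  stopifnot(is.matrix(img), nrow(img) >= 1, ncol(img) >= 1)
  h <- nrow(img); w <- ncol(img)
  ri <- (seq_len(h) + 1L) %/% 2L  # block index per row
  ci <- (seq_len(w) + 1L) %/% 2L
  sums <- rowsum(img, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri), tabulate(ci))
  unname(sums / cnt)
}

#' Read an image file (PNG) as a grayscale matrix on \[0, 255\]
#' @param path PNG file path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  x <- png::readPNG(path)
  to_grayscale(x * 255)
}

#' Write a grayscale matrix (\[0, 255\]) to a PNG file
#' @param img numeric matrix image.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

# Bilinear sampling of `img` at continuous 0-based coordinates (xs, ys).
# Out-of-bounds samples take `background`.
bilinear_sample <- function(img, xs, ys, background = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  get <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- rep(background, length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Rotate an image about its centre
#'
#' Bilinear resampling on the same pixel grid; the rotation centre is the
#' geometric image centre ((w-1)/2, (h-1)/2) in pixel-centre coordinates and
#' positive angles rotate counter-clockwise in the (x right, y down) frame.
#' Samples falling outside the source take `background`.
#'
#' @param img numeric matrix image.
#' @param angle_deg rotation angle in degrees.
#' @param background fill value for out-of-bounds samples.
#' @return rotated image, same dimensions.
#' @export
rotate_image <- function(img, angle_deg, background = 0) {
  if (angle_deg %% 360 == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  xs <- rep(0:(w - 1), each = h) - cx
  ys <- rep(0:(h - 1), times = w) - cy
  # inverse map: source = R(-theta) %*% dest
  sx <- co * xs + si * ys + cx
  sy <- -si * xs + co * ys + cy
  matrix(bilinear_sample(img, sx, sy, background), nrow = h, ncol = w)
}

#' Rotate a point about the image centre
#'
#' Applies the same forward map as [rotate_image()] to a point, so that a
#' structure at `pt` in the original image lands at the returned location in
#' the rotated image.
#'
#' @param pt numeric length-2, 0-based (x, y).
#' @param angle_deg rotation angle in degrees (as in [rotate_image()]).
#' @param extent `c(width, height)` of the image.
#' @return rotated (x, y).
#' @export
rotate_point <- function(pt, angle_deg, extent) {
  cx <- (extent[[1]] - 1) / 2; cy <- (extent[[2]] - 1) / 2
  th <- angle_deg * pi / 180
  dx <- pt[[1]] - cx; dy <- pt[[2]] - cy
  c(x = cos(th) * dx - sin(th) * dy + cx,
    y = sin(th) * dx + cos(th) * dy + cy)
}
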