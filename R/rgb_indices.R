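#' Read an RGB image as an 8-bit array
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array with values in \code{[0, 255]} (channel
#'   order r, g, b; any alpha channel is dropped).
#' @export
read_rgb_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  round(px * 255)
}

#' Write an 8-bit RGB array as PNG
#'
#' @param image H x W x 3 array with values in \code{[0, 255]}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

validate_image <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_field("image", "must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop_field("image", "must be at least 1 x 1")
  if (any(image < 0) || any(image > 255))
    stop_field("image", "channel values must lie in [0, 255]")
  invisible(image)
}

#' Segment plant pixels against a uniform background
#'
#' Simple color-keyed segmentation standing in for the imaging platform's
#' proprietary pipeline: a pixel belongs to the plant when the largest
#' absolute channel difference from the background color exceeds
#' \code{tolerance}.
#'
#' @param image H x W x 3 array, values in \code{[0, 255]}.
#' @param background_color Length-3 rgb vector of the background.
#' @param tolerance Channel distance (\eqn{\ge} 0) up to which a pixel still
#'   counts as background. Default 0.
#' @return Logical H x W matrix, \code{TRUE} for plant pixels.
#' @export
segment_plant_pixels <- function(image, background_color, tolerance = 0) {
  validate_image(image)
  if (tolerance < 0) stop_field("tolerance", "must be >= 0")
  d <- pmax(abs(image[, , 1] - background_color[1]),
            abs(image[, , 2] - background_color[2]),
            abs(image[, , 3] - background_color[3]))
  d > tolerance
}

#' RGB to HSI (hue, saturation, intensity) conversion
#'
#' Uses the classical arccos formulation. With r, g, b scaled to
#' \code{[0, 1]}: intensity \eqn{I = (r+g+b)/3}; saturation
#' \eqn{S = 1 - \min(r,g,b)/I} for \eqn{I > 0}, else 0; hue
#' \deqn{H = \arccos\left(\frac{((r-g)+(r-b))/2}
#'   {\sqrt{(r-g)^2 + (r-b)(g-b)}}\right)}
#' in degrees, replaced by \eqn{360 - H} when \eqn{b > g}. Hue is undefined
#' (returned as \code{NA}) for achromatic pixels (\eqn{S = 0} or a zero
#' denominator).
#'
#' @param image H x W x 3 array (or N x 3 matrix of colors), values in
#'   \code{[0, 255]}.
#' @return List of matrices (or vectors, for matrix input) \code{h} (degrees
#'   in \code{[0, 360)}, \code{NA} where undefined), \code{s} in
#'   \code{[0, 1]}, \code{i} in \code{[0, 1]}.
#' @examples
#' rgb_to_hsi(matrix(c(0, 255, 0), 1))$h   # pure green: 120
#' @export
rgb_to_hsi <- function(image) {
  if (is.matrix(image) && ncol(image) == 3L) {
    r <- image[, 1] / 255; g <- image[, 2] / 255; b <- image[, 3] / 255
  } else {
    validate_image(image)
    r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  }
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  h <- ifelse(s == 0 | den == 0, NA_real_,
              rad2deg(acos(clamp(num / ifelse(den == 0, 1, den), -1, 1))))
  h <- ifelse(!is.na(h) & b > g, 360 - h, h)
  list(h = h, s = s, i = i)
}

#' Greener fraction (GGF) of the plant pixels of an image
#'
#' The fraction of plant pixels whose HSI hue lies strictly between 80 and
#' 180 degrees — the green band of the color circle. Pixels with undefined
#' (achromatic) hue count in the denominator only, so they dilute the
#' fraction. Used to track greenness and drought-induced senescence.
#'
#' @param image H x W x 3 array, values in \code{[0, 255]}.
#' @param mask Logical H x W plant mask (from
#'   \code{\link{segment_plant_pixels}}) with at least one \code{TRUE}
#'   pixel.
#' @param window Hue window (degrees, exclusive bounds). Default
#'   \code{c(80, 180)}.
#' @return GGF in \code{[0, 1]}.
#' @export
ggf <- function(image, mask, window = c(80, 180)) {
  validate_image(image)
  if (!is.logical(mask) || !all(dim(mask) == dim(image)[1:2]))
    stop_field("mask", "must be a logical H x W matrix matching the image")
  n_plant <- sum(mask)
  if (n_plant == 0L)
    stop("undefined GGF: the plant mask is empty", call. = FALSE)
  cols <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  h <- rgb_to_hsi(cols)$h
  sum(!is.na(h) & h > window[1] & h < window[2]) / n_plant
}

#' Per-view plant pixel counts
#'
#' @param n_sv0,n_sv45,n_sv90 Plant pixel counts of the three side views
#'   (0, 45 and 90 degrees).
#' @param n_tv Plant pixel count of the top view.
#' @return A named list of class \code{plant_view_counts}.
#' @export
plant_view_counts <- function(n_sv0, n_sv45, n_sv90, n_tv) {
  v <- c(n_sv0 = n_sv0, n_sv45 = n_sv45, n_sv90 = n_sv90, n_tv = n_tv)
  if (any(v < 0)) stop_field("counts", "must be non-negative")
  structure(as.list(v), class = "plant_view_counts")
}

#' Projected shoot area (PSA) from four-view pixel counts
#'
#' Weighted silhouette-pixel sum over one top view and three side views 45
#' degrees apart:
#' \deqn{PSA = N_{0^\circ SV} + N_{45^\circ SV} + N_{90^\circ SV}
#'   + 0.3 \times N_{TV}}
#' in pixels. PSA is the standard image-based proxy for shoot size in
#' multi-view phenotyping platforms.
#'
#' @param counts A \code{\link{plant_view_counts}} object, a named
#'   list/vector with elements \code{n_sv0}, \code{n_sv45}, \code{n_sv90},
#'   \code{n_tv}, or a plain numeric vector of length 4 in that order.
#' @return PSA in pixels (numeric scalar).
#' @examples
#' psa(plant_view_counts(100, 200, 300, 100))   # 630
#' @export
psa <- function(counts) {
  if (is.list(counts) || !is.null(names(counts))) {
    need <- c("n_sv0", "n_sv45", "n_sv90", "n_tv")
    if (!all(need %in% names(counts)))
      stop_field("counts", "needs n_sv0, n_sv45, n_sv90, n_tv")
    v <- as.numeric(unlist(counts[need]))
  } else {
    if (length(counts) != 4L)
      stop_field("counts", "needs 4 values (sv0, sv45, sv90, tv)")
    v <- as.numeric(counts)
  }
  if (any(v < 0)) stop_field("counts", "must be non-negative")
  v[1] + v[2] + v[3] + 0.3 * v[4]
}
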