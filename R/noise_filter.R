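#' Remove non-plant (noise) points by color
#'
#' Structure-from-motion reconstructions of potted plants carry dark
#' background points and bluish sky/pot reflections. A point is treated as
#' noise when its 8-bit color satisfies \code{r + g + b <= 70} (too dark to
#' be leaf tissue) or \code{g <= b} (blue-dominant, i.e. the green/blue ratio
#' is at most 1). Either condition alone removes the point. The ratio test is
#' evaluated as the integer comparison \code{g <= b}, which avoids division
#' and is well defined at \code{b = 0}.
#'
#' @param cloud A \code{colored_point_cloud}.
#' @return A list with elements \code{kept} and \code{removed}, both
#'   \code{colored_point_cloud}s, partitioning the input and preserving the
#'   original point order within each part. The removed points' original
#'   indices are attached as attribute \code{"removed_idx"} on the list.
#' @examples
#' cl <- point_cloud(matrix(0, 3, 3),
#'                   rbind(c(20L, 20L, 20L),    # dark: sum 60 <= 70
#'                         c(100L, 50L, 60L),   # bluish: g <= b
#'                         c(60L, 120L, 80L)))  # plant: kept
#' filter_noise_points(cl)$kept
#' @export
filter_noise_points <- function(cloud) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  co <- cloud$colors
  if (nrow(co) == 0L) {
    out <- list(kept = cloud, removed = cloud)
    attr(out, "removed_idx") <- integer(0)
    return(out)
  }
  noise <- (co[, 1] + co[, 2] + co[, 3] <= 70L) | (co[, 2] <= co[, 3])
  out <- list(kept = subset_cloud(cloud, !noise),
              removed = subset_cloud(cloud, noise))
  attr(out, "removed_idx") <- which(noise)
  out
}

#' Is a color a noise color?
#'
#' Vectorised predicate used by \code{\link{filter_noise_points}}; exposed so
#' callers can apply the same criterion to color tables directly.
#'
#' @param colors N x 3 integer matrix of r, g, b values in \code{[0, 255]}.
#' @return Logical vector of length N; \code{TRUE} where the point would be
#'   removed.
#' @export
is_noise_color <- function(colors) {
  colors <- as.matrix(colors)
  (colors[, 1] + colors[, 2] + colors[, 3] <= 70) | (colors[, 2] <= colors[, 3])
}
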