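#' Orthographic silhouette rendering of a point cloud into four views
#'
#' Projects the points orthographically into the four standard phenotyping
#' views: one top view (TV, looking down the z axis) and three side views
#' (SV at azimuths 0, 45 and 90 degrees, horizontal view directions 45
#' degrees apart). Each point covers exactly the pixel its projection falls
#' in; the exact number of distinct covered pixels per view is returned as
#' ground truth for the projected-shoot-area computation. Orthographic
#' projection keeps that pixel-count truth exact; no perspective model is
#' claimed.
#'
#' @param positions N x 3 matrix of point coordinates.
#' @param colors N x 3 integer matrix of point colors; a covered pixel takes
#'   the color of the first point (in input order) landing in it.
#' @param image_size Side length of the square images in pixels
#'   (\eqn{\ge 64}). Default 192.
#' @param background_color Length-3 rgb background, must differ from every
#'   point color. Default white.
#' @param scale World units per pixel; \code{NULL} (default) auto-fits the
#'   cloud into the frame with a 5\% margin using one common scale for all
#'   four views.
#' @param centers Optional 4 x 2 matrix of per-view projection centres
#'   (world units); \code{NULL} centres each view on the cloud.
#' @return List with \code{images} (named list \code{tv}, \code{sv0},
#'   \code{sv45}, \code{sv90} of H x W x 3 arrays in \code{[0, 255]}),
#'   \code{counts} (a \code{\link{plant_view_counts}}), \code{scale} and
#'   \code{centers}.
#' @export
render_views <- function(positions, colors, image_size = 192L,
                         background_color = c(255, 255, 255),
                         scale = NULL, centers = NULL) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop_field("image_size", "must be at least 64")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n > 0L) {
    colors <- as.matrix(colors)
    if (any(colors[, 1] == background_color[1] &
            colors[, 2] == background_color[2] &
            colors[, 3] == background_color[3]))
      stop_field("background_color",
                 "must be distinct from all point colors")
  }

  # per-view 2D projections (u = image x, v = image up)
  proj <- view_projections(positions)
  view_names <- names(proj)

  if (is.null(centers)) {
    centers <- t(vapply(proj, function(uv) {
      if (nrow(uv) == 0L) c(0, 0)
      else c(mean(range(uv[, 1])), mean(range(uv[, 2])))
    }, numeric(2)))
  }
  if (is.null(scale)) {
    ext <- max(0, vapply(proj, function(uv) {
      if (nrow(uv) == 0L) 0
      else max(diff(range(uv[, 1])), diff(range(uv[, 2])))
    }, numeric(1)))
    scale <- if (ext == 0) 1 else ext / (0.9 * image_size)
  }
  if (scale <= 0) stop_field("scale", "must be positive")

  images <- list()
  counts <- integer(length(proj))
  names(counts) <- view_names
  half <- image_size / 2
  for (v in seq_along(proj)) {
    uv <- proj[[v]]
    img <- array(0, dim = c(image_size, image_size, 3L))
    img[, , 1] <- background_color[1]
    img[, , 2] <- background_color[2]
    img[, , 3] <- background_color[3]
    if (nrow(uv) > 0L) {
      px <- floor((uv[, 1] - centers[v, 1]) / scale + half) + 1L
      py <- floor((uv[, 2] - centers[v, 2]) / scale + half) + 1L
      row <- image_size + 1L - py
      if (any(px < 1L | px > image_size | row < 1L | row > image_size))
        stop("plant projects outside the ", view_names[v],
             " frame; increase image_size or reduce the plant extent/scale",
             call. = FALSE)
      lin <- (px - 1L) * image_size + row
      first <- !duplicated(lin)
      counts[v] <- sum(first)
      idx <- which(first)
      for (ch in 1:3)
        img[cbind(row[idx], px[idx], ch)] <- colors[idx, ch]
    }
    images[[view_names[v]]] <- img
  }
  list(images = images,
       counts = plant_view_counts(counts[["sv0"]], counts[["sv45"]],
                                  counts[["sv90"]], counts[["tv"]]),
       scale = scale, centers = centers)
}

view_projections <- function(positions) {
  if (nrow(positions) == 0L) {
    e <- matrix(numeric(0), 0L, 2L)
    return(list(tv = e, sv0 = e, sv45 = e, sv90 = e))
  }
  sv <- function(alpha_deg) {
    a <- deg2rad(alpha_deg)
    cbind(positions %*% c(-sin(a), cos(a), 0), positions[, 3])
  }
  list(tv = positions[, 1:2, drop = FALSE],
       sv0 = sv(0), sv45 = sv(45), sv90 = sv(90))
}

#' Generate the four phenotyping view images of a synthetic plant
#'
#' Builds the plant of \code{spec} (clutter excluded — the imaging pathway
#' sees the plant against a clean background, unlike the reconstruction
#' pathway) and renders its orthographic silhouettes, returning the exact
#' per-view plant-pixel counts as truth.
#'
#' @param spec A \code{\link{plant_spec}}.
#' @param image_size Square image side in pixels (\eqn{\ge 64}). Default 192.
#' @param background_color Length-3 rgb background. Default white.
#' @param scale World units per pixel, \code{NULL} to auto-fit.
#' @return As \code{\link{render_views}}, plus element \code{plant} (the
#'   generated cloud and truth).
#' @export
generate_multiview_images <- function(spec, image_size = 192L,
                                      background_color = c(255, 255, 255),
                                      scale = NULL) {
  gen <- generate_plant_cloud(spec)
  keep <- !(gen$truth$labels %in% c("clutter_dark", "clutter_blue"))
  out <- render_views(gen$cloud$positions[keep, , drop = FALSE],
                      gen$cloud$colors[keep, , drop = FALSE],
                      image_size = image_size,
                      background_color = background_color, scale = scale)
  out$plant <- gen
  out
}
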