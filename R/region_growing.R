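#' Region-growing parameters
#'
#' Parameters of the normal-based region growing used to split a cleaned
#' plant cloud into smooth surface patches (leaf blades) and line-like
#' strands (petioles, stem).
#'
#' @param k_neighbors Neighbourhood size for local PCA normal/tangent
#'   estimation. Default 12.
#' @param angle_threshold_deg Maximum angular deviation (degrees, in
#'   \code{(0, 90)}) between the local directions of adjacent points within
#'   one region. Default 20.
#' @param distance_threshold Connection radius (length units) of the
#'   neighbour graph the regions grow over. Default 6.
#' @param min_region_size Regions smaller than this are discarded
#'   (their points stay unassigned). Default 15.
#' @param shape_ratio Local PCA eigenvalue ratio \eqn{\lambda_2/\lambda_1}
#'   below which a point's neighbourhood counts as line-like rather than
#'   surface-like. Default 0.25.
#' @return A list of class \code{region_growing_params}.
#' @export
region_growing_params <- function(k_neighbors = 12L,
                                  angle_threshold_deg = 20,
                                  distance_threshold = 6,
                                  min_region_size = 15L,
                                  shape_ratio = 0.25) {
  if (k_neighbors < 1) stop_field("k_neighbors", "must be positive")
  if (angle_threshold_deg <= 0 || angle_threshold_deg >= 90)
    stop_field("angle_threshold_deg", "must lie in (0, 90)")
  if (distance_threshold <= 0) stop_field("distance_threshold", "must be positive")
  if (min_region_size < 1) stop_field("min_region_size", "must be positive")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 angle_threshold_deg = angle_threshold_deg,
                 distance_threshold = distance_threshold,
                 min_region_size = as.integer(min_region_size),
                 shape_ratio = shape_ratio),
            class = "region_growing_params")
}

# k-nearest-neighbour indices and radius neighbourhoods in one chunked pass
# over the (implicit) squared-distance matrix. Returns list(knn = N x k
# integer matrix, radius = list of ascending integer vectors excluding self).
neighbor_structure <- function(pos, k, radius, chunk = 512L) {
  n <- nrow(pos)
  sq <- rowSums(pos^2)
  knn <- matrix(0L, n, k)
  rad <- vector("list", n)
  r2 <- radius^2 * (1 + 1e-12)
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(i0 + chunk - 1L, n)
    idx <- i0:i1
    D <- outer(sq[idx], sq, "+") - 2 * pos[idx, , drop = FALSE] %*% t(pos)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d <- D[r, ]
      d[i] <- Inf
      o <- order(d)
      knn[i, ] <- o[seq_len(k)]
      rad[[i]] <- which(d <= r2)
    }
    i0 <- i1 + 1L
  }
  list(knn = knn, radius = rad)
}

# Local PCA at every point over its k nearest neighbours (self included).
# Gives the surface normal (smallest-eigenvalue direction), the tangent
# (largest), the curvature proxy lambda3/sum, and a shape class:
# "surface" when lambda2/lambda1 >= shape_ratio, else "line" (no reliable
# normal; elongated neighbourhood).
local_pca <- function(pos, knn, shape_ratio = 0.25) {
  n <- nrow(pos)
  normals <- matrix(0, n, 3L)
  tangents <- matrix(0, n, 3L)
  curvature <- numeric(n)
  surface <- logical(n)
  for (i in seq_len(n)) {
    nb <- pos[c(i, knn[i, ]), , drop = FALSE]
    X <- sweep(nb, 2L, colMeans(nb))
    e <- eigen(crossprod(X), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    tot <- sum(lam)
    curvature[i] <- if (tot > 0) lam[3] / tot else 0
    normals[i, ] <- e$vectors[, 3L]
    tangents[i, ] <- e$vectors[, 1L]
    surface[i] <- lam[1] > 0 && lam[2] >= shape_ratio * lam[1]
  }
  list(normals = normals, tangents = tangents, curvature = curvature,
       surface = surface)
}

#' Region growing over a cleaned plant point cloud
#'
#' Splits the cloud into smooth connected regions. Growth starts from the
#' unvisited point of lowest curvature (ties broken by point index) and
#' expands across the \code{distance_threshold} neighbour graph. A
#' neighbour joins the region when its local shape class matches the current
#' front point's (surface-like vs line-like) and their local directions
#' agree within \code{angle_threshold_deg}: surface points compare normals,
#' line-like points (petioles, stem — whose normals are undefined) compare
#' tangents. Directions are compared without sign. Regions smaller than
#' \code{min_region_size} are dropped. Points left over after growth —
#' typically boundary and corner points whose small-sample PCA is unstable —
#' are absorbed by the nearest region within the connection radius; points
#' farther than that from every region stay unassigned.
#'
#' @param cloud A \code{colored_point_cloud}, already noise-filtered.
#' @param params A \code{\link{region_growing_params}} object.
#' @return A list with \code{regions} (list of ascending point-index
#'   vectors, ordered by the seed sequence), \code{unassigned} (indices in
#'   no region) and \code{pca} (the per-point local PCA, reused by
#'   \code{\link{segment_leaf_petiole}}). Deterministic for a given input.
#' @export
region_growing <- function(cloud, params = region_growing_params()) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  pos <- cloud$positions
  n <- nrow(pos)
  if (params$k_neighbors >= n)
    stop("k_neighbors (", params$k_neighbors,
         ") must be smaller than the number of points (", n, ")",
         call. = FALSE)
  nbs <- neighbor_structure(pos, params$k_neighbors,
                            params$distance_threshold)
  pca <- local_pca(pos, nbs$knn, params$shape_ratio)
  cosmin <- cos(deg2rad(params$angle_threshold_deg))

  visited <- logical(n)
  seed_order <- order(pca$curvature, seq_len(n))
  regions <- list()
  for (s in seed_order) {
    if (visited[s]) next
    visited[s] <- TRUE
    members <- integer(0)
    queue <- s
    head <- 1L
    while (head <= length(queue)) {
      i <- queue[head]; head <- head + 1L
      members <- c(members, i)
      di <- if (pca$surface[i]) pca$normals[i, ] else pca$tangents[i, ]
      for (j in nbs$radius[[i]]) {
        if (visited[j]) next
        if (pca$surface[j] != pca$surface[i]) next
        dj <- if (pca$surface[j]) pca$normals[j, ] else pca$tangents[j, ]
        if (abs(sum(di * dj)) >= cosmin) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    if (length(members) >= params$min_region_size)
      regions[[length(regions) + 1L]] <- sort(members)
  }
  # absorption: points left out by the direction test (unstable local PCA at
  # region boundaries and corners) join the region of their nearest assigned
  # point within the connection radius; repeated until stable
  region_of <- integer(n)
  for (r in seq_along(regions)) region_of[regions[[r]]] <- r
  if (length(regions) > 0L) {
    repeat {
      un <- which(region_of == 0L)
      if (length(un) == 0L) break
      snapshot <- region_of
      changed <- FALSE
      for (i in un) {
        nb <- nbs$radius[[i]]
        nb <- nb[snapshot[nb] > 0L]
        if (length(nb) == 0L) next
        d2 <- colSums((t(pos[nb, , drop = FALSE]) - pos[i, ])^2)
        region_of[i] <- snapshot[nb[which.min(d2)]]
        changed <- TRUE
      }
      if (!changed) break
    }
    regions <- lapply(seq_along(regions), function(r) which(region_of == r))
  }
  list(regions = regions,
       unassigned = which(region_of == 0L),
       pca = pca)
}

#' Fill small interior holes of a region by voxel completion
#'
#' Voxelises the region's bounding box at \code{voxel_size}. Empty voxels
#' forming a connected component (6-connectivity) that does not reach the
#' bounding box boundary and has at most \code{max_hole_voxels} voxels are
#' hole candidates; each candidate voxel with at least 4 of its 6 face
#' neighbours occupied gains one synthetic point at the voxel centre,
#' colored like its nearest existing point. Points are only ever added.
#'
#' @param points N x 3 matrix of the region's positions.
#' @param colors Optional N x 3 integer matrix of point colors.
#' @param voxel_size Edge length of the voxel grid (> 0).
#' @param max_hole_voxels Largest empty component still considered a hole.
#' @return List with \code{points} (input plus any fill points),
#'   \code{colors} (matching, if colors were given) and \code{n_added}.
#' @export
fill_small_holes <- function(points, colors = NULL, voxel_size,
                             max_hole_voxels = 8L) {
  points <- as.matrix(points)
  if (voxel_size <= 0) stop_field("voxel_size", "must be positive")
  n <- nrow(points)
  out <- list(points = points, colors = colors, n_added = 0L)
  if (n == 0L) return(out)
  lo <- apply(points, 2L, min)
  ijk <- floor(sweep(points, 2L, lo) / voxel_size) + 1L
  dims <- pmax(apply(ijk, 2L, max), 1L)
  if (prod(dims) > 4e6)
    stop("voxel grid too large (", paste(dims, collapse = "x"),
         "); increase voxel_size", call. = FALSE)
  occ <- array(FALSE, dim = dims)
  occ[ijk] <- TRUE

  lin <- function(i, j, k) i + dims[1] * ((j - 1L) + dims[2] * (k - 1L))
  empty_lin <- which(!occ)
  if (length(empty_lin) == 0L) return(out)
  comp <- integer(length(occ))      # 0 = unlabelled; only empty voxels get ids
  touches_boundary <- logical(0)
  comp_members <- list()
  nc <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in empty_lin) {
    if (comp[start] != 0L) next
    nc <- nc + 1L
    comp[start] <- nc
    members <- integer(0)
    queue <- start
    head <- 1L
    boundary <- FALSE
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      members <- c(members, v)
      a <- arrayInd(v, dims)
      # single-layer dimensions (flat slabs) cannot make a hole "exterior"
      if (any((a == 1L | a == dims) & dims > 1L)) boundary <- TRUE
      for (o in seq_len(6L)) {
        b <- a + offs[o, ]
        if (any(b < 1L) || any(b > dims)) next
        w <- lin(b[1], b[2], b[3])
        if (!occ[w] && comp[w] == 0L) {
          comp[w] <- nc
          queue <- c(queue, w)
        }
      }
    }
    comp_members[[nc]] <- members
    touches_boundary[nc] <- boundary
  }

  add <- integer(0)
  for (cidx in seq_len(nc)) {
    members <- comp_members[[cidx]]
    if (touches_boundary[cidx] || length(members) > max_hole_voxels) next
    for (v in members) {
      a <- arrayInd(v, dims)
      n_occ <- 0L
      for (o in seq_len(6L)) {
        b <- a + offs[o, ]
        if (any(b < 1L) || any(b > dims)) next
        if (occ[lin(b[1], b[2], b[3])]) n_occ <- n_occ + 1L
      }
      if (n_occ >= 4L) add <- c(add, v)
    }
  }
  if (length(add) == 0L) return(out)
  centers <- (arrayInd(add, dims) - 0.5) * voxel_size
  centers <- sweep(centers, 2L, lo, "+")
  out$points <- rbind(points, centers)
  out$n_added <- nrow(centers)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    nn <- apply(centers, 1L, function(p) {
      which.min(colSums((t(points) - p)^2))
    })
    out$colors <- rbind(colors, colors[nn, , drop = FALSE])
  }
  out
}
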