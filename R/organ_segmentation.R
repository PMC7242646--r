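#' Classify regions into leaf blades, petioles and stem
#'
#' Takes the regions found by \code{\link{region_growing}} and assigns plant
#' anatomy. Each region is classified by its principal-component spectrum
#' (eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3} of its position
#' covariance): \eqn{\lambda_2/\lambda_1 <} \code{linearity_threshold} marks
#' an elongated, line-like region (petiole or stem candidate);
#' otherwise \eqn{\lambda_3/\lambda_2 <} \code{planarity_threshold} marks a
#' flat, blade-like region. Among line-like regions, the one whose principal
#' axis is near-vertical and whose height extent spans most of the cloud is
#' the stem. Every remaining petiole candidate is paired with the blade
#' whose point set lies nearest its distal end (the end farther from the
#' stem); blades left without a petiole within \code{pairing_distance} are
#' flagged \code{petiole_missing} and are excluded from angle computation
#' downstream — mirroring the fact that only a subset of leaves is usually
#' recoverable from a real reconstruction. Supplying \code{seeds} (one point
#' index per leaf of interest) restricts the leaves to the blade regions
#' containing those points: the "semi-automatic" mode.
#'
#' @param cloud A noise-filtered \code{colored_point_cloud}.
#' @param growing Result of \code{\link{region_growing}} on \code{cloud}, or
#'   a plain list of point-index regions.
#' @param seeds Optional integer vector of point indices, each inside a
#'   distinct leaf blade.
#' @param linearity_threshold \eqn{\lambda_2/\lambda_1} below which a region
#'   is line-like. Default 0.15.
#' @param planarity_threshold \eqn{\lambda_3/\lambda_2} below which a
#'   non-linear region is blade-like. Default 0.2.
#' @param pairing_distance Maximum distance between a petiole's distal end
#'   and the nearest point of its blade. Default 12.
#' @param absorb_radius After classification, unassigned points (region-
#'   growing leftovers at organ boundaries) take the label of their nearest
#'   labelled point when within this distance; 0 disables. Default 6.
#' @param stem_angle_deg Maximal tilt from vertical (degrees) for a
#'   line-like region to count as a stem piece. Default 30.
#' @param stem_span_frac Minimal fraction of the cloud's height range the
#'   union of stem pieces must span for a stem to be declared. Default 0.5.
#' @return An object of class \code{organ_segmentation}: list with
#'   \code{labels} (character, one of \code{"stem"}, \code{"petiole_<k>"},
#'   \code{"blade_<k>"}, \code{"unassigned"} per point), \code{n_leaves},
#'   and \code{leaves}, a data frame with one row per blade
#'   (\code{leaf}, \code{has_petiole}, \code{junction_x/y/z} where paired).
#' @export
segment_leaf_petiole <- function(cloud, growing, seeds = NULL,
                                 linearity_threshold = 0.15,
                                 planarity_threshold = 0.2,
                                 pairing_distance = 12,
                                 absorb_radius = 6,
                                 stem_angle_deg = 30,
                                 stem_span_frac = 0.5) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  regions <- if (is.list(growing) && !is.null(growing$regions))
    growing$regions else growing
  pos <- cloud$positions
  n <- nrow(pos)
  labels <- rep("unassigned", n)

  if (length(regions) == 0L) {
    return(structure(list(labels = labels, n_leaves = 0L,
                          leaves = empty_leaf_table()),
                     class = "organ_segmentation"))
  }

  spectra <- lapply(regions, function(idx) {
    X <- pos[idx, , drop = FALSE]
    X <- sweep(X, 2L, colMeans(X))
    e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    list(lam = pmax(e$values, 0), axis = e$vectors[, 1L])
  })
  is_linear <- vapply(spectra, function(s) {
    s$lam[1] > 0 && s$lam[2] / s$lam[1] < linearity_threshold
  }, logical(1))
  is_planar <- !is_linear & vapply(spectra, function(s) {
    s$lam[2] > 0 && s$lam[3] / s$lam[2] < planarity_threshold
  }, logical(1))

  # stem: union of near-vertical line-like regions. Region growing breaks
  # the stem at every node (where petiole neighbourhoods disturb the local
  # tangents), so no single region spans the height range; the union of the
  # vertical pieces must.
  zr <- diff(range(pos[, 3]))
  stem_regions <- integer(0)
  lin_idx <- which(is_linear)
  if (length(lin_idx) > 0L && zr > 0) {
    vert <- vapply(lin_idx, function(r) {
      angle_line_deg(spectra[[r]]$axis, c(0, 0, 1)) <= stem_angle_deg
    }, logical(1))
    cand <- lin_idx[vert]
    if (length(cand) > 0L) {
      union_idx <- unlist(regions[cand], use.names = FALSE)
      if (diff(range(pos[union_idx, 3])) >= stem_span_frac * zr)
        stem_regions <- cand
    }
  }
  for (r in stem_regions) labels[regions[[r]]] <- "stem"

  blade_regions <- which(is_planar)
  if (!is.null(seeds)) {
    keep <- vapply(blade_regions, function(r) {
      any(seeds %in% regions[[r]])
    }, logical(1))
    blade_regions <- blade_regions[keep]
    # preserve the seed ordering of leaves
    seed_of <- vapply(blade_regions, function(r) {
      min(which(seeds %in% regions[[r]]))
    }, integer(1))
    blade_regions <- blade_regions[order(seed_of)]
  }
  petiole_regions <- setdiff(which(is_linear), stem_regions)

  n_leaves <- length(blade_regions)
  for (k in seq_len(n_leaves))
    labels[regions[[blade_regions[k]]]] <- paste0("blade_", k)

  # the two extreme points of each petiole candidate along its axis; the
  # distal end is whichever lies nearer the blade it pairs with
  pet_info <- lapply(petiole_regions, function(r) {
    idx <- regions[[r]]
    X <- pos[idx, , drop = FALSE]
    axis <- spectra[[r]]$axis
    t <- X %*% axis
    list(idx = idx,
         ends = X[c(which.min(t), which.max(t)), , drop = FALSE])
  })

  leaves <- empty_leaf_table(n_leaves)
  if (n_leaves > 0L) leaves$leaf <- seq_len(n_leaves)

  if (n_leaves > 0L && length(pet_info) > 0L) {
    # nearest blade approach distance per petiole end
    dmat <- matrix(Inf, length(pet_info), n_leaves)
    emat <- matrix(1L, length(pet_info), n_leaves)
    for (p in seq_along(pet_info)) {
      for (k in seq_len(n_leaves)) {
        bl <- pos[regions[[blade_regions[k]]], , drop = FALSE]
        d <- c(min_dist_to(pet_info[[p]]$ends[1, ], bl),
               min_dist_to(pet_info[[p]]$ends[2, ], bl))
        emat[p, k] <- which.min(d)
        dmat[p, k] <- min(d)
      }
    }
    # greedy globally-nearest pairing, deterministic
    repeat {
      if (!is.finite(min(dmat)) || min(dmat) > pairing_distance) break
      m <- which(dmat == min(dmat), arr.ind = TRUE)
      p <- m[1, 1]; k <- m[1, 2]
      distal <- pet_info[[p]]$ends[emat[p, k], ]
      labels[pet_info[[p]]$idx] <- paste0("petiole_", k)
      leaves$has_petiole[k] <- TRUE
      leaves$junction_x[k] <- distal[1]
      leaves$junction_y[k] <- distal[2]
      leaves$junction_z[k] <- distal[3]
      dmat[p, ] <- Inf
      dmat[, k] <- Inf
    }
  }

  if (absorb_radius > 0) {
    un <- which(labels == "unassigned")
    assigned <- which(labels != "unassigned")
    if (length(un) > 0L && length(assigned) > 0L) {
      tgt <- t(pos[assigned, , drop = FALSE])
      r2 <- absorb_radius^2
      for (i in un) {
        d2 <- colSums((tgt - pos[i, ])^2)
        j <- which.min(d2)
        if (d2[j] <= r2) labels[i] <- labels[assigned[j]]
      }
    }
  }

  structure(list(labels = labels, n_leaves = n_leaves, leaves = leaves),
            class = "organ_segmentation")
}

empty_leaf_table <- function(n = 0L) {
  data.frame(leaf = integer(n), has_petiole = logical(n),
             junction_x = rep(NA_real_, n), junction_y = rep(NA_real_, n),
             junction_z = rep(NA_real_, n))
}

# unsigned angle between a line direction and a reference vector, in [0, 90]
angle_line_deg <- function(d, ref) {
  a <- angle_between_deg(d, ref)
  min(a, 180 - a)
}

min_dist_to <- function(p, pts) {
  sqrt(min(colSums((t(pts) - p)^2)))
}

#' @export
print.organ_segmentation <- function(x, ...) {
  tab <- table(sub("_[0-9]+$", "", x$labels))
  cat(sprintf("Organ segmentation: %d leaves, %d paired with a petiole\n",
              x$n_leaves, sum(x$leaves$has_petiole)))
  cat("  points per label class:\n")
  for (nm in names(tab)) cat(sprintf("    %-10s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Export a segmentation as CSV and optionally a label-colored PLY
#'
#' @param segmentation An \code{organ_segmentation}.
#' @param cloud The segmented \code{colored_point_cloud}.
#' @param csv_path Output CSV path (\code{point_index,label}); \code{NULL}
#'   to skip.
#' @param ply_path Optional path of a PLY copy of the cloud recolored by
#'   label, for visual inspection.
#' @return Invisibly, the label table.
#' @export
write_segmentation <- function(segmentation, cloud, csv_path = NULL,
                               ply_path = NULL) {
  df <- data.frame(point_index = seq_along(segmentation$labels),
                   label = segmentation$labels)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(ply_path)) {
    base <- sub("_[0-9]+$", "", segmentation$labels)
    pal <- rbind(stem = c(139L, 90L, 43L), petiole = c(255L, 165L, 0L),
                 blade = c(34L, 139L, 34L), noise = c(40L, 40L, 40L),
                 unassigned = c(128L, 128L, 128L))
    cols <- pal[base, , drop = FALSE]
    write_cloud(point_cloud(cloud$positions, cols), ply_path, format = "ply")
  }
  invisible(df)
}
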