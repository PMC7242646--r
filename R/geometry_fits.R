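#' Total-least-squares plane fit for a leaf blade
#'
#' Fits the regression plane of a leaf blade by orthogonal (total)
#' least squares: the plane passes through the centroid and its normal is the
#' eigenvector of the smallest eigenvalue of the position covariance, so the
#' root-mean-square orthogonal distance of the points to the plane is
#' minimised. The normal sign is fixed by convention: non-negative z
#' component, with ties broken towards non-negative x (then y).
#'
#' @param points Numeric matrix with at least 3 rows (XYZ), not all collinear.
#' @return An object of class \code{blade_fit}: list with \code{centroid}
#'   (3-vector), \code{normal} (unit 3-vector), \code{rms_residual}
#'   (root-mean-square orthogonal distance) and \code{n}.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' fit_plane(sq)$normal   # (0, 0, 1)
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("degenerate input: plane fit needs at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  C <- crossprod(X) / nrow(points)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)           # guard tiny negatives from roundoff
  if (lam[2] <= lam[1] * 1e-12)
    stop("degenerate input: points are (nearly) collinear, plane undefined",
         call. = FALSE)
  nrm <- orient_sign(e$vectors[, 3L])
  structure(list(centroid = ctr, normal = nrm,
                 rms_residual = sqrt(lam[3]), n = nrow(points)),
            class = "blade_fit")
}

# Canonical sign: positive z, ties towards positive x, then y.
orient_sign <- function(v, tol = 1e-12) {
  s <- if (abs(v[3]) > tol) sign(v[3])
       else if (abs(v[1]) > tol) sign(v[1])
       else sign(v[2])
  if (s < 0) -v else v
}

#' Principal-axis line fit for a petiole
#'
#' Fits the petiole regression line through the centroid along the
#' eigenvector of the largest covariance eigenvalue. The residual is the
#' root-mean-square orthogonal distance to the line (square root of the sum
#' of the two smaller eigenvalues). The direction's sign ambiguity is
#' resolved with \code{direction_hint} when supplied (typically the
#' stem-to-blade, i.e. proximal-to-distal, direction); otherwise the sign
#' follows the canonical convention of \code{\link{fit_plane}}.
#'
#' @param points Numeric matrix with at least 2 rows, not all coincident.
#' @param direction_hint Optional 3-vector; the fitted direction is flipped
#'   if needed so its dot product with the hint is non-negative.
#' @return An object of class \code{petiole_fit}: list with \code{anchor}
#'   (centroid), \code{direction} (unit 3-vector), \code{rms_residual} and
#'   \code{n}.
#' @examples
#' pts <- t(sapply(0:3, function(t) t * c(1, 2, 2) / 3))
#' fit_line(pts)$direction   # (1, 2, 2) / 3
#' @export
fit_line <- function(points, direction_hint = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("degenerate input: line fit needs at least 2 points", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  C <- crossprod(X) / nrow(points)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1] <= 1e-24)
    stop("degenerate input: points are (nearly) coincident, line undefined",
         call. = FALSE)
  dir <- e$vectors[, 1L]
  if (!is.null(direction_hint)) {
    if (sum(dir * direction_hint) < 0) dir <- -dir
  } else {
    dir <- orient_sign(dir)
  }
  structure(list(anchor = ctr, direction = dir,
                 rms_residual = sqrt(lam[2] + lam[3]), n = nrow(points)),
            class = "petiole_fit")
}

#' @export
print.blade_fit <- function(x, ...) {
  cat(sprintf("Blade plane fit (n = %d)\n  normal  (%.4f, %.4f, %.4f)\n  rms residual %.4g\n",
              x$n, x$normal[1], x$normal[2], x$normal[3], x$rms_residual))
  invisible(x)
}

#' @export
print.petiole_fit <- function(x, ...) {
  cat(sprintf("Petiole line fit (n = %d)\n  direction (%.4f, %.4f, %.4f)\n  rms residual %.4g\n",
              x$n, x$direction[1], x$direction[2], x$direction[3],
              x$rms_residual))
  invisible(x)
}

#' 3D leaf angle from blade plane and petiole line
#'
#' The leaf angle is defined as the supplement of the deviation of the leaf
#' midrib from the petiole direction. The midrib is not fitted directly:
#' its direction is reconstructed in the blade plane as the unit projection
#' of the junction-to-blade-centroid vector onto the plane, which is exact
#' for a planar blade whose midrib runs through the blade centre. With
#' deviation \eqn{\theta = \arccos(d \cdot m)} between the
#' proximal-to-distal petiole direction \eqn{d} and the midrib proxy
#' \eqn{m}, the returned angle is \eqn{180 - \theta} degrees: 180° for a
#' blade continuing the petiole, small angles for strongly folded-back
#' blades, and values rising above 90° as leaves droop under drought.
#'
#' @param blade A \code{blade_fit}.
#' @param petiole A \code{petiole_fit} with proximal-to-distal orientation.
#' @param junction 3-vector: estimate of the petiole's distal endpoint
#'   (blade attachment point).
#' @return Leaf angle in degrees, in \code{[0, 180]}.
#' @export
leaf_angle_3d <- function(blade, petiole, junction) {
  stopifnot(inherits(blade, "blade_fit"), inherits(petiole, "petiole_fit"))
  v <- blade$centroid - as.numeric(junction)
  nv <- sqrt(sum(v^2))
  m <- v - sum(v * blade$normal) * blade$normal
  nm <- sqrt(sum(m^2))
  if (nv == 0 || nm < 1e-6 * nv)
    stop("undefined midrib: blade centroid lies (nearly) along the plane ",
         "normal from the junction", call. = FALSE)
  m <- m / nm
  theta <- rad2deg(acos(clamp(sum(petiole$direction * m), -1, 1)))
  180 - theta
}
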