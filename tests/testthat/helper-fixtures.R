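# Shared fixture builders and independent oracles.

# A small plant spec that keeps the test suite fast.
small_plant_spec <- function(n_leaves = 5L, position_noise_sd = 0,
                             n_clutter_dark = 0L, n_clutter_blue = 0L,
                             seed = 3L, ...) {
  plant_spec(n_leaves = n_leaves, position_noise_sd = position_noise_sd,
             n_clutter_dark = n_clutter_dark, n_clutter_blue = n_clutter_blue,
             seed = seed, ...)
}

# Random rigid motion (rotation + translation), seeded.
random_rigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 50))
}

apply_rigid <- function(points, rigid) {
  sweep(points %*% t(rigid$R), 2L, rigid$t, "+")
}

# Independent brute-force hue: angle of the chromaticity vector
# (2r - g - b, sqrt(3)(g - b)) on the color circle, in [0, 360).
oracle_hue <- function(r, g, b) {
  h <- atan2(sqrt(3) * (g - b), 2 * r - g - b) * 180 / pi
  h %% 360
}

# Fit leaf angles directly from truth labels (no automatic segmentation):
# the leaf_angle module exercised on perfectly segmented organs.
angles_from_truth <- function(gen) {
  n_leaf <- nrow(gen$truth$per_leaf)
  vapply(seq_len(n_leaf), function(k) {
    blade_pts <- gen$cloud$positions[
      truth_indices(gen$truth, paste0("blade_", k)), , drop = FALSE]
    pet_idx <- truth_indices(gen$truth, paste0("petiole_", k))
    pet_pts <- gen$cloud$positions[pet_idx, , drop = FALSE]
    blade <- fit_plane(blade_pts)
    petiole <- fit_line(pet_pts,
                        direction_hint = gen$truth$petiole_true_direction[k, ])
    t_max <- max(pet_pts %*% petiole$direction) -
      sum(petiole$anchor * petiole$direction)
    junction <- petiole$anchor + t_max * petiole$direction
    leaf_angle_3d(blade, petiole, junction)
  }, numeric(1))
}
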