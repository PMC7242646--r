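#' Specification of a synthetic grapevine-like plant
#'
#' Describes one potted plant for the synthetic point-cloud generator: a
#' vertical stem carrying leaves at given node heights, each leaf a straight
#' petiole leaving the stem horizontally (plus an optional insertion tilt)
#' and a planar disc blade whose midrib makes the configured leaf angle with
#' the petiole. Default angles span 75–110 degrees — the range observed in
#' grapevine going from well-watered to severely drought-stressed plants —
#' and default azimuths follow a 137.5-degree phyllotactic spiral so
#' neighbouring leaves do not overlap. Lengths are in arbitrary units
#' (millimetres by convention).
#'
#' @param n_leaves Number of leaves. Default 8.
#' @param stem_height Stem length (units). Default 300.
#' @param node_positions Heights of the leaf nodes along the stem; default
#'   evenly spaced over \code{[0.15, 0.95] * stem_height}.
#' @param petiole_length Petiole length. Default 40.
#' @param blade_radius Blade disc radius. Default 35.
#' @param leaf_angles_deg One target leaf angle per leaf, each in
#'   \code{(0, 180)}; default evenly spans 75–110.
#' @param azimuths_deg One azimuth per leaf (degrees); default phyllotactic
#'   spiral.
#' @param insertion_angle_deg Petiole tilt above horizontal at the stem.
#'   Default 0.
#' @param blade_curvature Out-of-plane bowing of the blade as a fraction of
#'   \code{blade_radius} at the rim (0 = perfectly planar). Default 0.
#' @param position_noise_sd Isotropic Gaussian jitter applied to plant
#'   points (units; emulates reconstruction noise). Default 0.7.
#' @param n_clutter_dark Number of dark clutter points
#'   (\code{r+g+b <= 70}). Default 150.
#' @param n_clutter_blue Number of blue-dominant clutter points
#'   (\code{g <= b}). Default 150.
#' @param points_per_stem,points_per_petiole,points_per_blade Sampling
#'   densities. Defaults 240, 80, 500.
#' @param seed RNG seed making the generated plant reproducible. Default 1.
#' @return A validated list of class \code{plant_spec}.
#' @export
plant_spec <- function(n_leaves = 8L,
                       stem_height = 300,
                       node_positions = NULL,
                       petiole_length = 40,
                       blade_radius = 35,
                       leaf_angles_deg = NULL,
                       azimuths_deg = NULL,
                       insertion_angle_deg = 0,
                       blade_curvature = 0,
                       position_noise_sd = 0.7,
                       n_clutter_dark = 150L,
                       n_clutter_blue = 150L,
                       points_per_stem = 240L,
                       points_per_petiole = 80L,
                       points_per_blade = 500L,
                       seed = 1L) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 0L)
    stop_field("n_leaves", "must be a non-negative integer")
  if (is.null(node_positions) && n_leaves > 0L)
    node_positions <- seq(0.15 * stem_height, 0.95 * stem_height,
                          length.out = n_leaves)
  if (is.null(node_positions)) node_positions <- numeric(0)
  if (is.null(leaf_angles_deg) && n_leaves > 0L)
    leaf_angles_deg <- if (n_leaves == 1L) 92.5
                       else seq(75, 110, length.out = n_leaves)
  if (is.null(leaf_angles_deg)) leaf_angles_deg <- numeric(0)
  if (is.null(azimuths_deg) && n_leaves > 0L)
    azimuths_deg <- ((seq_len(n_leaves) - 1L) * 137.5) %% 360
  if (is.null(azimuths_deg)) azimuths_deg <- numeric(0)

  spec <- structure(list(
    n_leaves = n_leaves, stem_height = stem_height,
    node_positions = as.numeric(node_positions),
    petiole_length = petiole_length, blade_radius = blade_radius,
    leaf_angles_deg = as.numeric(leaf_angles_deg),
    azimuths_deg = as.numeric(azimuths_deg),
    insertion_angle_deg = insertion_angle_deg,
    blade_curvature = blade_curvature,
    position_noise_sd = position_noise_sd,
    n_clutter_dark = as.integer(n_clutter_dark),
    n_clutter_blue = as.integer(n_clutter_blue),
    points_per_stem = as.integer(points_per_stem),
    points_per_petiole = as.integer(points_per_petiole),
    points_per_blade = as.integer(points_per_blade),
    seed = as.integer(seed)), class = "plant_spec")
  validate_plant_spec(spec)
}

validate_plant_spec <- function(spec) {
  n <- spec$n_leaves
  if (length(spec$leaf_angles_deg) != n)
    stop_field("leaf_angles_deg", "needs one angle per leaf")
  if (length(spec$azimuths_deg) != n)
    stop_field("azimuths_deg", "needs one azimuth per leaf")
  if (length(spec$node_positions) != n)
    stop_field("node_positions", "needs one height per leaf")
  if (n > 0L && (any(spec$leaf_angles_deg <= 0) ||
                 any(spec$leaf_angles_deg >= 180)))
    stop_field("leaf_angles_deg", "angles must lie strictly in (0, 180)")
  for (f in c("stem_height", "petiole_length", "blade_radius"))
    if (spec[[f]] <= 0) stop_field(f, "must be positive")
  if (spec$position_noise_sd < 0)
    stop_field("position_noise_sd", "must be >= 0")
  for (f in c("n_clutter_dark", "n_clutter_blue"))
    if (spec[[f]] < 0) stop_field(f, "must be >= 0")
  if (spec$points_per_stem < 0)
    stop_field("points_per_stem", "must be >= 0")
  for (f in c("points_per_petiole", "points_per_blade"))
    if (spec[[f]] < 1) stop_field(f, "must be positive")
  if (n > 0L && (any(spec$node_positions <= 0) ||
                 any(spec$node_positions > spec$stem_height)))
    stop_field("node_positions", "must lie in (0, stem_height]")
  spec
}

#' @export
print.plant_spec <- function(x, ...) {
  cat(sprintf(
    "Plant spec: %d leaves, stem %.0f, petiole %.0f, blade radius %.0f\n",
    x$n_leaves, x$stem_height, x$petiole_length, x$blade_radius))
  if (x$n_leaves > 0L)
    cat(sprintf("  leaf angles %.1f..%.1f deg, jitter sd %.2f, seed %d\n",
                min(x$leaf_angles_deg), max(x$leaf_angles_deg),
                x$position_noise_sd, x$seed))
  invisible(x)
}

# Geometry of one leaf: unit petiole direction, midrib direction and blade
# normal for a given azimuth, insertion tilt and leaf angle. The midrib
# deviates from the petiole by (180 - leaf_angle) degrees, rotated downward
# in the vertical plane through the petiole.
leaf_frame <- function(azimuth_deg, insertion_deg, leaf_angle_deg) {
  phi <- deg2rad(azimuth_deg)
  iota <- deg2rad(insertion_deg)
  u0 <- c(cos(phi), sin(phi), 0)            # horizontal outward
  a <- c(-sin(phi), cos(phi), 0)            # horizontal, perpendicular
  up <- cos(iota) * u0 + sin(iota) * c(0, 0, 1)
  w <- c(a[2] * up[3] - a[3] * up[2],       # a x up: downward-ish
         a[3] * up[1] - a[1] * up[3],
         a[1] * up[2] - a[2] * up[1])
  delta <- deg2rad(180 - leaf_angle_deg)
  um <- cos(delta) * up + sin(delta) * w
  nb <- c(um[2] * a[3] - um[3] * a[2],      # um x a: blade-plane normal
          um[3] * a[1] - um[1] * a[3],
          um[1] * a[2] - um[2] * a[1])
  list(petiole = up, midrib = unit_vector(um), inplane = a,
       normal = unit_vector(nb))
}

#' Generate a synthetic plant point cloud with ground truth
#'
#' Builds the cloud a structure-from-motion reconstruction of the plant
#' would yield: stem points along a vertical segment, petiole points along
#' straight segments leaving the stem at each node, blade points sampled
#' uniformly on planar discs whose midribs make the configured leaf angles
#' with their petioles (the blade disc is centred one radius along the
#' midrib from the petiole tip, so the petiole meets the disc rim and the
#' midrib runs through the disc centre). Plant points get green-dominant
#' colors (always \code{r+g+b > 70} and \code{g > b}), isotropic Gaussian
#' jitter of sd \code{position_noise_sd}, and the bounding volume is
#' peppered with dark (\code{r+g+b <= 70}) and blue-dominant
#' (\code{g <= b}) clutter points emulating reconstruction noise. The
#' companion truth object records per-point organ labels and each leaf's
#' exact generating vectors, angle and canopy region. The same spec (which
#' embeds its seed) always yields bit-identical output.
#'
#' @param spec A \code{\link{plant_spec}}.
#' @return List with elements \code{cloud} (a \code{colored_point_cloud})
#'   and \code{truth} (class \code{plant_truth}): \code{labels} (character
#'   per point: \code{"stem"}, \code{"petiole_<k>"}, \code{"blade_<k>"},
#'   \code{"clutter_dark"}, \code{"clutter_blue"}), \code{per_leaf} (data
#'   frame: \code{leaf}, \code{node}, \code{region},
#'   \code{true_angle_deg}), and unit-vector matrices
#'   \code{petiole_true_direction}, \code{midrib_true_direction},
#'   \code{blade_true_normal} (one row per leaf).
#' @export
generate_plant_cloud <- function(spec) {
  spec <- validate_plant_spec(spec)
  with_seed(spec$seed, {
    pos_list <- list()
    lab_list <- list()
    n_leaf <- spec$n_leaves

    z_stem <- sort(stats::runif(spec$points_per_stem, 0, spec$stem_height))
    pos_list$stem <- cbind(rep(0, spec$points_per_stem),
                           rep(0, spec$points_per_stem), z_stem)
    lab_list$stem <- rep("stem", spec$points_per_stem)

    petiole_dirs <- matrix(NA_real_, n_leaf, 3L)
    midrib_dirs <- matrix(NA_real_, n_leaf, 3L)
    blade_normals <- matrix(NA_real_, n_leaf, 3L)

    for (k in seq_len(n_leaf)) {
      fr <- leaf_frame(spec$azimuths_deg[k], spec$insertion_angle_deg,
                       spec$leaf_angles_deg[k])
      petiole_dirs[k, ] <- fr$petiole
      midrib_dirs[k, ] <- fr$midrib
      blade_normals[k, ] <- fr$normal
      base <- c(0, 0, spec$node_positions[k])
      tt <- stats::runif(spec$points_per_petiole, 0, spec$petiole_length)
      pet <- t(base + outer(fr$petiole, tt))
      junction <- base + spec$petiole_length * fr$petiole
      centre <- junction + spec$blade_radius * fr$midrib
      rr <- spec$blade_radius * sqrt(stats::runif(spec$points_per_blade))
      psi <- stats::runif(spec$points_per_blade, 0, 2 * pi)
      bow <- spec$blade_curvature * rr^2 / spec$blade_radius
      blade <- t(centre + outer(fr$midrib, rr * cos(psi)) +
                   outer(fr$inplane, rr * sin(psi)) +
                   outer(fr$normal, bow))
      pos_list[[paste0("petiole_", k)]] <- pet
      lab_list[[paste0("petiole_", k)]] <-
        rep(paste0("petiole_", k), nrow(pet))
      pos_list[[paste0("blade_", k)]] <- blade
      lab_list[[paste0("blade_", k)]] <- rep(paste0("blade_", k), nrow(blade))
    }

    plant_pos <- do.call(rbind, pos_list)
    n_plant <- nrow(plant_pos)
    if (spec$position_noise_sd > 0)
      plant_pos <- plant_pos +
        matrix(stats::rnorm(3 * n_plant, 0, spec$position_noise_sd),
               n_plant, 3L)
    plant_col <- cbind(
      sample(30:80, n_plant, replace = TRUE),
      sample(120:200, n_plant, replace = TRUE),
      sample(40:90, n_plant, replace = TRUE))

    if (n_plant > 0L) {
      lo <- apply(plant_pos, 2L, min) - 0.05 * diff(range(plant_pos))
      hi <- apply(plant_pos, 2L, max) + 0.05 * diff(range(plant_pos))
    } else {
      lo <- c(0, 0, 0); hi <- c(spec$stem_height, spec$stem_height,
                                spec$stem_height)
    }
    clutter <- function(m) {
      if (m == 0L) return(matrix(numeric(0), 0L, 3L))
      cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]),
            stats::runif(m, lo[3], hi[3]))
    }
    dark_pos <- clutter(spec$n_clutter_dark)
    dark_col <- dark_clutter_colors(spec$n_clutter_dark)
    blue_pos <- clutter(spec$n_clutter_blue)
    blue_col <- blue_clutter_colors(spec$n_clutter_blue)

    positions <- rbind(plant_pos, dark_pos, blue_pos)
    colors <- rbind(plant_col, dark_col, blue_col)
    labels <- c(unlist(lab_list, use.names = FALSE),
                rep("clutter_dark", spec$n_clutter_dark),
                rep("clutter_blue", spec$n_clutter_blue))

    per_leaf <- data.frame(
      leaf = seq_len(n_leaf),
      node = seq_len(n_leaf),
      region = node_region(seq_len(n_leaf)),
      true_angle_deg = spec$leaf_angles_deg)

    truth <- structure(list(
      labels = labels,
      per_leaf = per_leaf,
      petiole_true_direction = petiole_dirs,
      midrib_true_direction = midrib_dirs,
      blade_true_normal = blade_normals), class = "plant_truth")

    list(cloud = point_cloud(positions, colors), truth = truth)
  })
}

# channels summing to at most 70: dark background clutter
dark_clutter_colors <- function(m) {
  if (m == 0L) return(matrix(integer(0), 0L, 3L))
  r <- sample(0:70, m, replace = TRUE)
  g <- vapply(70L - r, function(u) sample(0:u, 1L), integer(1))
  b <- vapply(70L - r - g, function(u) sample(0:u, 1L), integer(1))
  cbind(r, g, b, deparse.level = 0)
}

# blue-dominant clutter: g <= b always, bright enough to not be "dark"
blue_clutter_colors <- function(m) {
  if (m == 0L) return(matrix(integer(0), 0L, 3L))
  b <- sample(100:255, m, replace = TRUE)
  g <- vapply(b, function(u) sample(0:u, 1L), integer(1))
  r <- sample(0:255, m, replace = TRUE)
  cbind(r, g, b, deparse.level = 0)
}

#' @export
print.plant_truth <- function(x, ...) {
  cat(sprintf("Plant truth: %d points, %d leaves\n",
              length(x$labels), nrow(x$per_leaf)))
  invisible(x)
}

#' Point indices of one organ in a truth labelling
#'
#' @param truth A \code{plant_truth}.
#' @param label Organ label, e.g. \code{"blade_3"} or \code{"stem"}.
#' @return Integer vector of point indices.
#' @export
truth_indices <- function(truth, label) which(truth$labels == label)
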