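#' Linear link between stem water potential and leaf angle
#'
#' Configurable stand-in for the observed linear relation between midday
#' stem water potential (MPa, negative) and leaf angle (degrees): angle
#' \eqn{= intercept + slope \cdot \Psi + \epsilon}. The defaults map the
#' measured \eqn{\Psi} range of \eqn{-0.4} (well-watered) to \eqn{-1.1} MPa
#' (severe drought) onto the observed 75–110 degree angle span; published
#' work reports the strength of this relation, not its coefficients, so the
#' defaults are illustrative conditions, not literature values.
#'
#' @param slope_deg_per_MPa Slope in degrees per MPa. Default -50.
#' @param intercept_deg Intercept in degrees (angle at \eqn{\Psi = 0}).
#'   Default 55.
#' @param noise_sd_deg Leaf-to-leaf Gaussian scatter in degrees
#'   (\eqn{\ge 0}). Default 2.
#' @return A list of class \code{link_model}.
#' @export
link_model <- function(slope_deg_per_MPa = -50, intercept_deg = 55,
                       noise_sd_deg = 2) {
  if (noise_sd_deg < 0) stop_field("noise_sd_deg", "must be >= 0")
  structure(list(slope_deg_per_MPa = slope_deg_per_MPa,
                 intercept_deg = intercept_deg,
                 noise_sd_deg = noise_sd_deg), class = "link_model")
}

#' Mean leaf angle implied by a link model at given water potentials
#'
#' @param link A \code{\link{link_model}}.
#' @param psi Stem water potential values (MPa, typically negative).
#' @return Angles in degrees (not clipped).
#' @export
link_angle <- function(link, psi) {
  link$intercept_deg + link$slope_deg_per_MPa * psi
}

#' Generate synthetic PSA-to-leaf-area calibration pairs
#'
#' Draws PSA uniformly on \code{psa_range} and sets
#' \code{la = slope * psa + intercept + N(0, noise_sd)} — the data-generating
#' process behind the linear leaf-area calibration.
#'
#' @param n Number of pairs (\eqn{\ge 3}, so a model remains fittable).
#' @param slope,intercept Generating coefficients.
#' @param psa_range Length-2 interval for PSA, non-degenerate.
#' @param noise_sd Gaussian noise sd on LA (\eqn{\ge 0}).
#' @param seed RNG seed.
#' @return Data frame with columns \code{psa} and \code{la}.
#' @export
generate_psa_la_pairs <- function(n, slope, intercept, psa_range,
                                  noise_sd, seed = 1L) {
  if (n < 3L) stop_field("n", "need at least 3 pairs (model unfittable)")
  if (length(psa_range) != 2L || diff(range(psa_range)) <= 0)
    stop_field("psa_range", "must be a non-degenerate interval")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  with_seed(seed, {
    psa <- stats::runif(n, min(psa_range), max(psa_range))
    la <- slope * psa + intercept + stats::rnorm(n, 0, noise_sd)
    data.frame(psa = psa, la = la)
  })
}

#' Generate a multi-plant drought time series of plant clouds
#'
#' Emulates a drought experiment: each plant follows its own stem-water-
#' potential trajectory over the measurement days, and each plant-day's
#' leaf angles are set through the linear \code{\link{link_model}} (plus
#' per-leaf noise), clipped to the open interval (0, 180) degrees. One
#' synthetic cloud per plant-day is produced via
#' \code{\link{generate_plant_cloud}}, along with a tidy covariate table.
#' A warning is raised when clipping engages on more than 10\% of leaves —
#' the sign of a misconfigured link.
#'
#' @param psi_trajectories Numeric matrix (plants x days) of stem water
#'   potentials in MPa, typically in \code{[-1.2, -0.3]}; row names become
#'   plant ids, column names the day labels.
#' @param link A \code{\link{link_model}}.
#' @param spec_template A \code{\link{plant_spec}} providing everything but
#'   the leaf angles and seed.
#' @param seed Base seed; each plant-day derives its own sub-seed.
#' @param days Optional day labels (defaults to trajectory column names or
#'   \code{1:n_days}).
#' @return List with \code{plants} (nested list: \code{[[plant]][[day]]},
#'   each a \code{generate_plant_cloud} result) and \code{covariates}
#'   (data frame: \code{plant}, \code{day}, \code{psi},
#'   \code{true_mean_angle_deg}).
#' @export
generate_drought_timeseries <- function(psi_trajectories, link,
                                        spec_template = plant_spec(),
                                        seed = 1L, days = NULL) {
  psi_trajectories <- as.matrix(psi_trajectories)
  if (!all(is.finite(psi_trajectories)))
    stop_field("psi_trajectories", "must be finite")
  n_plants <- nrow(psi_trajectories)
  n_days <- ncol(psi_trajectories)
  plant_ids <- rownames(psi_trajectories)
  if (is.null(plant_ids)) plant_ids <- paste0("plant_", seq_len(n_plants))
  if (is.null(days)) days <- colnames(psi_trajectories)
  if (is.null(days)) days <- seq_len(n_days)

  n_leaves <- spec_template$n_leaves
  clipped <- 0L
  total <- 0L
  plants <- stats::setNames(vector("list", n_plants), plant_ids)
  cov_rows <- list()
  for (p in seq_len(n_plants)) {
    plants[[p]] <- stats::setNames(vector("list", n_days),
                                   as.character(days))
    for (d in seq_len(n_days)) {
      psi <- psi_trajectories[p, d]
      sub_seed <- derive_seed(seed, (p - 1L) * n_days + d)
      angles <- with_seed(sub_seed,
        link_angle(link, psi) +
          stats::rnorm(n_leaves, 0, link$noise_sd_deg))
      clip_lo <- angles <= 0; clip_hi <- angles >= 180
      clipped <- clipped + sum(clip_lo | clip_hi)
      total <- total + n_leaves
      angles[clip_lo] <- 1e-3
      angles[clip_hi] <- 180 - 1e-3
      spec <- spec_template
      spec$leaf_angles_deg <- angles
      spec$seed <- sub_seed
      plants[[p]][[d]] <- generate_plant_cloud(spec)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        plant = plant_ids[p], day = days[d], psi = psi,
        true_mean_angle_deg = mean(angles))
    }
  }
  if (total > 0L && clipped / total > 0.1)
    warning(sprintf(
      "angle clipping engaged on %.0f%% of leaves; link model is likely misconfigured",
      100 * clipped / total), call. = FALSE)
  list(plants = plants, covariates = do.call(rbind, cov_rows))
}
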