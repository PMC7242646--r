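#' Build and validate an experiment configuration
#'
#' An experiment configuration drives \code{\link{run_experiment}}: a
#' simulated drought trial with several irrigation treatments, each a
#' stem-water-potential trajectory over the measurement days, plus the
#' parameters of every pipeline stage. Accepts a YAML file path or a nested
#' list with blocks \code{experiment}, \code{synthetic}, \code{pointcloud},
#' \code{indices}, \code{model} and \code{seed}; unknown keys anywhere are
#' rejected. Missing keys fall back to the package defaults, which emulate
#' the canonical design: treatments restoring 100\% (CTRL), 60\% and 30\%
#' of soil available water capacity, with \eqn{\Psi} drifting from -0.4 MPa
#' towards -1.1 MPa in the most stressed group.
#'
#' @param x Path to a YAML file, a list, or \code{NULL} for the defaults.
#' @return A validated list of class \code{experiment_config}.
#' @export
experiment_config <- function(x = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a list or a YAML path", call. = FALSE)

  defaults <- list(
    experiment = list(
      treatments = list(CTRL = c(-0.40, -0.40, -0.40, -0.40),
                        IRR60 = c(-0.40, -0.50, -0.62, -0.75),
                        IRR30 = c(-0.40, -0.62, -0.85, -1.10)),
      days = c(0, 3, 10, 14),
      n_plants = 3L),
    synthetic = list(
      n_leaves = 6L, stem_height = 300, petiole_length = 40,
      blade_radius = 35, insertion_angle_deg = 0, blade_curvature = 0,
      position_noise_sd = 0.7, n_clutter_dark = 150L, n_clutter_blue = 150L,
      points_per_stem = 240L, points_per_petiole = 80L,
      points_per_blade = 500L,
      link = list(slope_deg_per_MPa = -50, intercept_deg = 55,
                  noise_sd_deg = 2)),
    pointcloud = list(
      k_neighbors = 12L, angle_threshold_deg = 20, distance_threshold = 6,
      min_region_size = 15L, shape_ratio = 0.25,
      linearity_threshold = 0.15, planarity_threshold = 0.2,
      pairing_distance = 12,
      fill_holes = FALSE, voxel_size = 3, max_hole_voxels = 8L),
    indices = list(
      image_size = 192L, background_color = c(255L, 255L, 255L),
      tolerance = 0, scale = NULL, ggf_window = c(80, 180)),
    model = list(
      n_pairs = 500L, slope = 3.3027, intercept = -283.42,
      psa_range = c(400, 1000), noise_sd = 20, k = 10L),
    seed = 1L)

  cfg <- merge_config(defaults, x, path = "config")
  if (cfg$experiment$n_plants < 1L)
    stop_field("experiment.n_plants", "must be positive")
  nd <- length(cfg$experiment$days)
  for (tr in names(cfg$experiment$treatments)) {
    traj <- cfg$experiment$treatments[[tr]]
    if (length(traj) != nd)
      stop_field(paste0("experiment.treatments.", tr),
                 sprintf("needs one psi value per day (%d)", nd))
  }
  structure(cfg, class = "experiment_config")
}

# recursive defaults merge; rejects keys absent from the defaults skeleton
merge_config <- function(defaults, user, path) {
  if (length(user) == 0L) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  # treatments block carries user-chosen names; merge it verbatim
  if (length(unknown) > 0L)
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "treatments") {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[nm] <- user[nm]
    }
  }
  defaults
}

config_plant_spec <- function(cfg, leaf_angles, seed) {
  syn <- cfg$synthetic
  plant_spec(
    n_leaves = length(leaf_angles),
    stem_height = syn$stem_height,
    petiole_length = syn$petiole_length,
    blade_radius = syn$blade_radius,
    leaf_angles_deg = leaf_angles,
    insertion_angle_deg = syn$insertion_angle_deg,
    blade_curvature = syn$blade_curvature,
    position_noise_sd = syn$position_noise_sd,
    n_clutter_dark = syn$n_clutter_dark,
    n_clutter_blue = syn$n_clutter_blue,
    points_per_stem = syn$points_per_stem,
    points_per_petiole = syn$points_per_petiole,
    points_per_blade = syn$points_per_blade,
    seed = seed)
}

#' Run a simulated drought-phenotyping experiment end to end
#'
#' For every treatment, plant and day: generate the plant cloud at the leaf
#' angles implied by the water-potential trajectory through the linear
#' link; remove color-noise points; segment organs by region growing and
#' PCA classification; fit blade planes and petiole lines and compute 3D
#' leaf angles; render the four orthographic views; segment plant pixels,
#' compute the greener fraction (top view and pooled side views) and the
#' projected shoot area; and predict leaf area through the PSA calibration
#' fitted from the configured generating model. Finally regresses the
#' recovered per-plant-day mean angle on \eqn{\Psi}. Fully seeded and
#' reproducible; a failing plant-day is flagged in its result row rather
#' than aborting the run.
#'
#' @param config An \code{\link{experiment_config}}, or anything it
#'   accepts.
#' @param out_dir Optional directory; when given, writes
#'   \code{results.csv}, \code{la_model.json}, \code{angle_psi.json},
#'   \code{config.yaml} and \code{run.log} into it.
#' @param quiet Suppress per-plant-day progress messages. Default
#'   \code{TRUE}.
#' @return List of class \code{experiment_result}: \code{results} (one row
#'   per plant-day: \code{plant_id}, \code{day}, \code{treatment},
#'   \code{psi}, \code{true_mean_angle_deg}, \code{mean_angle_deg},
#'   \code{angle_se}, \code{yield}, \code{ggf_tv}, \code{ggf_sv},
#'   \code{psa}, \code{la_pred}, \code{status}), \code{angle_psi}
#'   (list: slope, intercept, r_squared, n of the angle-on-psi OLS),
#'   \code{la_model} and \code{config}.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = TRUE) {
  cfg <- if (inherits(config, "experiment_config")) config
         else experiment_config(config)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  mdl_cfg <- cfg$model
  pairs <- generate_psa_la_pairs(mdl_cfg$n_pairs, mdl_cfg$slope,
                                 mdl_cfg$intercept,
                                 mdl_cfg$psa_range, mdl_cfg$noise_sd,
                                 seed = derive_seed(cfg$seed, 999983L))
  la_mod <- fit_la_model(pairs, cv_k = mdl_cfg$k,
                         seed = derive_seed(cfg$seed, 999979L))
  say("calibration: LA' = %.4f x PSA %+.2f (R^2 %.3f, CV R^2 %.3f)",
      la_mod$slope, la_mod$intercept, la_mod$r_squared, la_mod$cv_r_squared)

  link <- do.call(link_model, cfg$synthetic$link)
  rg_params <- region_growing_params(
    k_neighbors = cfg$pointcloud$k_neighbors,
    angle_threshold_deg = cfg$pointcloud$angle_threshold_deg,
    distance_threshold = cfg$pointcloud$distance_threshold,
    min_region_size = cfg$pointcloud$min_region_size,
    shape_ratio = cfg$pointcloud$shape_ratio)

  # one common rendering scale across the whole run so PSA is comparable
  scale <- cfg$indices$scale
  if (is.null(scale)) {
    syn <- cfg$synthetic
    world <- 1.6 * max(syn$stem_height,
                       2 * (syn$petiole_length + 2 * syn$blade_radius))
    scale <- world / cfg$indices$image_size
  }
  bg <- cfg$indices$background_color

  rows <- list()
  treatments <- cfg$experiment$treatments
  days <- cfg$experiment$days
  unit <- 0L
  for (tr in names(treatments)) {
    for (p in seq_len(cfg$experiment$n_plants)) {
      plant_id <- sprintf("%s_p%d", tr, p)
      for (d in seq_along(days)) {
        unit <- unit + 1L
        psi <- treatments[[tr]][d]
        sub_seed <- derive_seed(cfg$seed, unit)
        row <- data.frame(plant_id = plant_id, day = days[d],
                          treatment = tr, psi = psi,
                          true_mean_angle_deg = NA_real_,
                          mean_angle_deg = NA_real_, angle_se = NA_real_,
                          yield = NA_real_, ggf_tv = NA_real_,
                          ggf_sv = NA_real_, psa = NA_real_,
                          la_pred = NA_real_, status = "ok",
                          stringsAsFactors = FALSE)
        res <- tryCatch({
          angles <- with_seed(sub_seed,
            link_angle(link, psi) +
              stats::rnorm(cfg$synthetic$n_leaves, 0, link$noise_sd_deg))
          angles <- clamp(angles, 1e-3, 180 - 1e-3)
          spec <- config_plant_spec(cfg, angles, sub_seed)
          gen <- generate_plant_cloud(spec)
          row$true_mean_angle_deg <- mean(angles)

          flt <- filter_noise_points(gen$cloud)
          grown <- region_growing(flt$kept, rg_params)
          seg <- segment_leaf_petiole(
            flt$kept, grown,
            linearity_threshold = cfg$pointcloud$linearity_threshold,
            planarity_threshold = cfg$pointcloud$planarity_threshold,
            pairing_distance = cfg$pointcloud$pairing_distance)
          ang <- plant_leaf_angles(flt$kept, seg, plant_id = plant_id)
          row$mean_angle_deg <- ang$mean_angle_deg
          row$angle_se <- ang$se_deg
          row$yield <- ang$yield

          keep <- !(gen$truth$labels %in% c("clutter_dark", "clutter_blue"))
          rv <- render_views(gen$cloud$positions[keep, , drop = FALSE],
                             gen$cloud$colors[keep, , drop = FALSE],
                             image_size = cfg$indices$image_size,
                             background_color = bg, scale = scale,
                             centers = NULL)
          masks <- lapply(rv$images, segment_plant_pixels,
                          background_color = bg,
                          tolerance = cfg$indices$tolerance)
          row$ggf_tv <- ggf(rv$images$tv, masks$tv,
                            window = cfg$indices$ggf_window)
          # pooled side-view pixels, not a mean of per-view fractions
          sv_green <- 0; sv_tot <- 0
          for (v in c("sv0", "sv45", "sv90")) {
            n_v <- sum(masks[[v]])
            sv_green <- sv_green +
              ggf(rv$images[[v]], masks[[v]],
                  window = cfg$indices$ggf_window) * n_v
            sv_tot <- sv_tot + n_v
          }
          row$ggf_sv <- sv_green / sv_tot
          row$psa <- psa(rv$counts)
          row$la_pred <- predict(la_mod, row$psa)
          row
        }, error = function(e) {
          say("plant-day failed (%s, day %s): %s", plant_id, days[d],
              conditionMessage(e))
          row$status <- paste0("failed: ", conditionMessage(e))
          row
        })
        rows[[unit]] <- res
        say("%s day %s: psi %.2f, angle %.1f (yield %.2f), PSA %.0f",
            plant_id, days[d], psi,
            if (is.na(res$mean_angle_deg)) NaN else res$mean_angle_deg,
            if (is.na(res$yield)) NaN else res$yield,
            if (is.na(res$psa)) NaN else res$psa)
      }
    }
  }
  results <- do.call(rbind, rows)

  ok <- results$status == "ok" & !is.na(results$mean_angle_deg)
  angle_psi <- list(slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, n = sum(ok))
  if (sum(ok) >= 3L) {
    fit <- stats::lm(mean_angle_deg ~ psi, data = results[ok, ])
    angle_psi$slope <- unname(stats::coef(fit)[2])
    angle_psi$intercept <- unname(stats::coef(fit)[1])
    angle_psi$r_squared <- summary(fit)$r.squared
  }
  say("angle ~ psi: slope %.3f deg/MPa, R^2 %.4f (n = %d)",
      angle_psi$slope, angle_psi$r_squared, angle_psi$n)

  out <- structure(list(results = results, angle_psi = angle_psi,
                        la_model = la_mod, config = cfg),
                   class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    write_la_model(la_mod, file.path(out_dir, "la_model.json"))
    jsonlite::write_json(angle_psi, file.path(out_dir, "angle_psi.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d plant-days (%d ok)\n",
              nrow(x$results), sum(x$results$status == "ok")))
  cat(sprintf("  angle ~ psi: slope %.2f deg/MPa, R^2 %.4f\n",
              x$angle_psi$slope, x$angle_psi$r_squared))
  print(x$la_model)
  invisible(x)
}
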