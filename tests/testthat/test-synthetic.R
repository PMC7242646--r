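test_that("plant spec invariants are validated with the field named", {
  expect_error(plant_spec(n_leaves = 3, leaf_angles_deg = c(90, 90)),
               "leaf_angles_deg")
  expect_error(plant_spec(n_leaves = 2, leaf_angles_deg = c(90, 190),
                          azimuths_deg = c(0, 120),
                          node_positions = c(50, 100)),
               "leaf_angles_deg")
  expect_error(plant_spec(stem_height = -1), "stem_height")
  expect_error(plant_spec(position_noise_sd = -0.1), "position_noise_sd")
  expect_error(plant_spec(n_clutter_dark = -1), "n_clutter_dark")
})

test_that("truth vectors satisfy the generating geometry", {
  gen <- generate_plant_cloud(plant_spec(seed = 4L))
  tr <- gen$truth
  n_leaf <- nrow(tr$per_leaf)
  expect_equal(n_leaf, 8L)
  for (k in seq_len(n_leaf)) {
    expect_equal(sum(tr$petiole_true_direction[k, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(tr$midrib_true_direction[k, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(tr$blade_true_normal[k, ]^2), 1, tolerance = 1e-9)
    dev <- acos(min(max(sum(tr$midrib_true_direction[k, ] *
                              tr$petiole_true_direction[k, ]), -1), 1)) *
      180 / pi
    expect_equal(dev, 180 - tr$per_leaf$true_angle_deg[k], tolerance = 1e-6)
    # midrib lies in the blade plane
    expect_equal(sum(tr$midrib_true_direction[k, ] *
                       tr$blade_true_normal[k, ]), 0, tolerance = 1e-9)
  }
})

test_that("every point carries exactly one label and counts add up", {
  spec <- plant_spec(n_leaves = 5L, seed = 2L)
  gen <- generate_plant_cloud(spec)
  expect_length(gen$truth$labels, n_points(gen$cloud))
  tab <- table(gen$truth$labels)
  expect_equal(sum(tab), n_points(gen$cloud))
  expect_equal(unname(tab[["stem"]]), spec$points_per_stem)
  expect_equal(unname(tab[["clutter_dark"]]), spec$n_clutter_dark)
  expect_equal(unname(tab[["clutter_blue"]]), spec$n_clutter_blue)
  expect_length(grep("^blade_", names(tab)), 5L)
  expect_equal(nrow(gen$truth$per_leaf), 5L)
  expect_true(all(gen$truth$per_leaf$region %in%
                    c("lower", "middle", "upper")))
})

test_that("clutter satisfies the color criterion and plant points do not", {
  gen <- generate_plant_cloud(plant_spec(seed = 7L))
  co <- gen$cloud$colors
  lab <- gen$truth$labels
  dark <- lab == "clutter_dark"
  blue <- lab == "clutter_blue"
  plant <- !(dark | blue)
  expect_true(all(rowSums(co[dark, , drop = FALSE]) <= 70))
  expect_true(all(co[blue, 2] <= co[blue, 3]))
  expect_true(all(rowSums(co[plant, , drop = FALSE]) > 70))
  expect_true(all(co[plant, 2] > co[plant, 3]))
  # hence the noise filter recovers exactly the plant
  flt <- filter_noise_points(gen$cloud)
  expect_identical(attr(flt, "removed_idx"), which(dark | blue))
})

test_that("the generator is bit-identical under a fixed seed", {
  spec <- plant_spec(seed = 123L)
  a <- generate_plant_cloud(spec)
  b <- generate_plant_cloud(spec)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$truth, b$truth)
  c <- generate_plant_cloud(plant_spec(seed = 124L))
  expect_false(identical(a$cloud$positions, c$cloud$positions))
})

test_that("noise-free organs give back the true angles within 0.5 degrees", {
  spec <- small_plant_spec()   # jitter 0, no clutter
  gen <- generate_plant_cloud(spec)
  est <- angles_from_truth(gen)
  expect_lt(max(abs(est - gen$truth$per_leaf$true_angle_deg)), 0.5)
})

test_that("canopy regions follow the node index rule", {
  expect_equal(node_region(c(1, 5, 6, 11, 12, 20)),
               c("lower", "lower", "middle", "middle", "upper", "upper"))
  spec <- plant_spec(n_leaves = 13L, seed = 1L)
  gen <- generate_plant_cloud(spec)
  expect_equal(gen$truth$per_leaf$region,
               node_region(seq_len(13)))
})

test_that("PSA-LA pair generator honours its contract", {
  exact <- generate_psa_la_pairs(50, 2, 5, c(100, 900), 0, seed = 9)
  expect_equal(exact$la, 2 * exact$psa + 5, tolerance = 1e-9)
  expect_true(all(exact$psa >= 100 & exact$psa <= 900))

  expect_error(generate_psa_la_pairs(2, 1, 0, c(0, 1), 0), "n")
  expect_error(generate_psa_la_pairs(10, 1, 0, c(5, 5), 0), "psa_range")

  a <- generate_psa_la_pairs(100, 2, 5, c(0, 10), 1, seed = 33)
  b <- generate_psa_la_pairs(100, 2, 5, c(0, 10), 1, seed = 33)
  expect_identical(a, b)

  # OLS refit lands within 2 closed-form standard errors of the truth
  big <- generate_psa_la_pairs(1e4, 2, 5, c(0, 10), 1, seed = 17)
  fit <- fit_la_model(big, cv_k = NULL)
  se_slope <- 1 / sqrt(sum((big$psa - mean(big$psa))^2))
  expect_lt(abs(fit$slope - 2), 2 * se_slope)
})

test_that("link arithmetic and drought series behave as configured", {
  lk <- link_model(slope_deg_per_MPa = -35, intercept_deg = 40,
                   noise_sd_deg = 0)
  expect_equal(link_angle(lk, -1), 75)
  expect_equal(link_angle(lk, -2), 110)

  # constant psi, zero link noise: identical true mean angle everywhere
  traj <- matrix(-0.6, nrow = 2, ncol = 3)
  ts <- generate_drought_timeseries(traj, lk, small_plant_spec(n_leaves = 2L),
                                    seed = 5)
  expect_equal(nrow(ts$covariates), 6L)
  expect_true(all(ts$covariates$true_mean_angle_deg ==
                    ts$covariates$true_mean_angle_deg[1]))

  # a misconfigured link that clips most angles warns
  bad <- link_model(slope_deg_per_MPa = 0, intercept_deg = 200,
                    noise_sd_deg = 0)
  expect_warning(
    generate_drought_timeseries(traj, bad, small_plant_spec(n_leaves = 2L),
                                seed = 5),
    "clipping")
})

test_that("regression across a drought series recovers the link slope", {
  lk <- link_model(noise_sd_deg = 0)   # defaults: -50 deg/MPa, 55
  traj <- rbind(seq(-0.4, -1.1, length.out = 4),
                seq(-0.4, -0.8, length.out = 4))
  ts <- generate_drought_timeseries(traj, lk, small_plant_spec(n_leaves = 3L),
                                    seed = 8)
  # recover each plant-day's mean angle from the generated clouds via truth
  est <- vapply(unlist(ts$plants, recursive = FALSE), function(gen) {
    mean(angles_from_truth(gen))
  }, numeric(1))
  fit <- stats::lm(est ~ psi, data = cbind(ts$covariates, est = est))
  expect_equal(unname(coef(fit)[2]), lk$slope_deg_per_MPa, tolerance = 0.005)
})
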