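test_that("exact planes are recovered with zero residual", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  fit <- fit_plane(sq)
  expect_equal(fit$normal, c(0, 0, 1))
  expect_equal(fit$rms_residual, 0)
  expect_equal(fit$centroid, c(0.5, 0.5, 0))

  # x + y + z = 1
  pl <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, 0.5, 0),
              c(0.25, 0.25, 0.5))
  fit2 <- fit_plane(pl)
  expect_equal(fit2$normal, rep(1, 3) / sqrt(3), tolerance = 1e-12)
  # residual is the sqrt of an eigenvalue at machine precision
  expect_lt(fit2$rms_residual, 1e-7)
})

test_that("noisy plane normals come back within 2 degrees", {
  set.seed(5)
  for (rep in 1:5) {
    nrm <- phenovine:::unit_vector(rnorm(3))
    # orthonormal in-plane basis
    a <- phenovine:::unit_vector(pracma::cross(nrm, c(1, 0.3, -0.2)))
    b <- pracma::cross(nrm, a)
    extent <- 10
    uv <- matrix(runif(400, -extent, extent), 200, 2)
    pts <- uv[, 1] %o% a + uv[, 2] %o% b +
      matrix(rnorm(600, 0, 0.01 * extent), 200, 3)
    fit <- fit_plane(pts)
    ang <- acos(min(abs(sum(fit$normal * nrm)), 1)) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("degenerate plane inputs are rejected", {
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  line <- cbind(0:9, 0, 0)
  expect_error(fit_plane(line), "collinear")
})

test_that("closed-form plane beats every normal on a 1-degree grid", {
  set.seed(8)
  pts <- cbind(runif(30, -5, 5), runif(30, -5, 5), rnorm(30, 0, 0.5))
  rigid <- random_rigid(99)
  pts <- apply_rigid(pts, rigid)
  fit <- fit_plane(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  rms_for <- function(nrm) sqrt(mean((X %*% nrm)^2))
  th <- seq(0, 180, by = 1) * pi / 180
  ph <- seq(0, 359, by = 1) * pi / 180
  grid <- cbind(rep(sin(th), each = length(ph)) * cos(ph),
                rep(sin(th), each = length(ph)) * sin(ph),
                rep(cos(th), each = length(ph)))
  grid_rms <- sqrt(colMeans((X %*% t(grid))^2))
  expect_lte(fit$rms_residual, min(grid_rms))
})

test_that("exact lines are recovered; orientation follows the hint", {
  pts <- t(vapply(0:3, function(t) t * c(1, 2, 2) / 3, numeric(3)))
  fit <- fit_line(pts)
  expect_equal(abs(sum(fit$direction * c(1, 2, 2) / 3)), 1, tolerance = 1e-12)
  expect_lt(fit$rms_residual, 1e-7)

  hinted <- fit_line(pts, direction_hint = c(-1, -2, -2))
  expect_lt(sum(hinted$direction * c(1, 2, 2)), 0)

  two <- rbind(c(0, 0, 0), c(1, 1, 0))
  f2 <- fit_line(two)
  expect_equal(abs(sum(f2$direction * c(1, 1, 0) / sqrt(2))), 1,
               tolerance = 1e-12)

  expect_error(fit_line(rbind(c(1, 1, 1), c(1, 1, 1))), "coincident")
  expect_error(fit_line(matrix(0, 1, 3)), "at least 2")
})

test_that("leaf angle matches the analytic cases", {
  blade_flat <- function(centroid) {
    structure(list(centroid = centroid, normal = c(0, 0, 1),
                   rms_residual = 0, n = 10L), class = "blade_fit")
  }
  pet <- function(d) structure(list(anchor = c(0, 0, 0),
                                    direction = d / sqrt(sum(d^2)),
                                    rms_residual = 0, n = 10L),
                               class = "petiole_fit")
  j <- c(0, 0, 0)
  # blade continues the petiole: deviation 0 -> angle 180
  expect_equal(leaf_angle_3d(blade_flat(c(1, 0, 0)), pet(c(1, 0, 0)), j), 180)
  # full fold-back: deviation 180 -> angle 0
  expect_equal(leaf_angle_3d(blade_flat(c(-1, 0, 0)), pet(c(1, 0, 0)), j), 0)
  # petiole at 45 degrees above a flat blade: deviation 45 -> angle 135
  expect_equal(leaf_angle_3d(blade_flat(c(1, 0, 0)), pet(c(1, 0, 1)), j), 135)
  # centroid along the normal: midrib projection undefined
  expect_error(leaf_angle_3d(blade_flat(c(0, 0, 1)), pet(c(1, 0, 0)), j),
               "undefined midrib")
})

test_that("fits are equivariant and the angle is rigid- and scale-invariant", {
  set.seed(21)
  gen <- generate_plant_cloud(small_plant_spec(n_leaves = 3L, seed = 10L))
  blade_idx <- truth_indices(gen$truth, "blade_2")
  pet_idx <- truth_indices(gen$truth, "petiole_2")
  blade_pts <- gen$cloud$positions[blade_idx, ]
  pet_pts <- gen$cloud$positions[pet_idx, ]
  hint <- gen$truth$petiole_true_direction[2, ]
  base_blade <- fit_plane(blade_pts)
  base_pet <- fit_line(pet_pts, direction_hint = hint)
  t_max <- max(pet_pts %*% base_pet$direction) -
    sum(base_pet$anchor * base_pet$direction)
  junction <- base_pet$anchor + t_max * base_pet$direction
  base_angle <- leaf_angle_3d(base_blade, base_pet, junction)

  for (s in 1:4) {
    rigid <- random_rigid(s)
    rb <- fit_plane(apply_rigid(blade_pts, rigid))
    rp <- fit_line(apply_rigid(pet_pts, rigid),
                   direction_hint = as.numeric(rigid$R %*% hint))
    expect_equal(rb$centroid,
                 as.numeric(apply_rigid(matrix(base_blade$centroid, 1), rigid)),
                 tolerance = 1e-9)
    expect_equal(abs(sum(rb$normal * (rigid$R %*% base_blade$normal))), 1,
                 tolerance = 1e-9)
    expect_equal(rb$rms_residual, base_blade$rms_residual, tolerance = 1e-6)
    rj <- as.numeric(apply_rigid(matrix(junction, 1), rigid))
    expect_equal(leaf_angle_3d(rb, rp, rj), base_angle, tolerance = 1e-6)
  }

  # scaling all coordinates leaves the angle unchanged
  for (c_scale in c(0.01, 1, 250)) {
    sb <- fit_plane(blade_pts * c_scale)
    sp <- fit_line(pet_pts * c_scale, direction_hint = hint)
    expect_equal(leaf_angle_3d(sb, sp, junction * c_scale), base_angle,
                 tolerance = 1e-8)
  }
})
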