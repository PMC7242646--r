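test_that("PCA spectrum separates line-like from blade-like regions", {
  set.seed(2)
  line_pts <- cbind(seq(0, 40, length.out = 80), 0, 5)
  disc <- local({
    r <- 15 * sqrt(runif(400)); a <- runif(400, 0, 2 * pi)
    cbind(60 + r * cos(a), r * sin(a), 5)
  })
  cl <- point_cloud(rbind(line_pts, disc),
                    cbind(rep(50L, 480), rep(160L, 480), rep(60L, 480)))
  regions <- list(seq_len(80), 81:480)
  seg <- segment_leaf_petiole(cl, regions, absorb_radius = 0)
  # the line is petiole-like (lambda2/lambda1 ~ 0), the disc blade-like
  expect_equal(seg$n_leaves, 1L)
  expect_true(all(seg$labels[81:480] == "blade_1"))
  expect_true(seg$leaves$has_petiole[1])
  expect_true(all(seg$labels[seq_len(80)] == "petiole_1"))
})

test_that("a noise-free separated plant recovers >= 95% true organ labels", {
  gen <- generate_plant_cloud(small_plant_spec())
  seg <- segment_leaf_petiole(gen$cloud, region_growing(gen$cloud))
  expect_equal(seg$n_leaves, 5L)
  # align estimated leaf ids with truth ids via blade majority vote
  remap <- vapply(seq_len(seg$n_leaves), function(k) {
    idx <- which(seg$labels == paste0("blade_", k))
    names(sort(table(gen$truth$labels[idx]), decreasing = TRUE))[1]
  }, character(1))
  relab <- seg$labels
  for (k in seq_len(seg$n_leaves)) {
    tid <- sub("blade_", "", remap[k])
    relab[seg$labels == paste0("blade_", k)] <- paste0("blade_", tid)
    relab[seg$labels == paste0("petiole_", k)] <- paste0("petiole_", tid)
  }
  expect_gte(mean(relab == gen$truth$labels), 0.95)
})

test_that("segmentation labels are invariant to a rigid motion", {
  gen <- generate_plant_cloud(small_plant_spec(n_leaves = 3L,
                                               position_noise_sd = 0.5,
                                               seed = 6L))
  seg <- segment_leaf_petiole(gen$cloud, region_growing(gen$cloud))
  rigid <- random_rigid(31)
  # rotation about z keeps the stem vertical (stem detection uses gravity)
  ang <- runif(1, 0, 2 * pi)
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- point_cloud(sweep(gen$cloud$positions %*% t(Rz), 2,
                             c(20, -40, 15), "+"),
                       gen$cloud$colors)
  seg2 <- segment_leaf_petiole(moved, region_growing(moved))
  expect_identical(seg2$labels, seg$labels)
})

test_that("deleting petioles lowers yield but keeps the other leaves", {
  gen <- generate_plant_cloud(small_plant_spec())
  drop <- c(truth_indices(gen$truth, "petiole_2"),
            truth_indices(gen$truth, "petiole_4"))
  keep <- setdiff(seq_len(n_points(gen$cloud)), drop)
  cl <- subset_cloud(gen$cloud, keep)
  seg <- segment_leaf_petiole(cl, region_growing(cl))
  ang <- plant_leaf_angles(cl, seg)
  expect_equal(nrow(ang$records), 3L)
  expect_equal(ang$yield, 3 / seg$n_leaves)
})

test_that("seed indices restrict and order the leaves (semi-automatic mode)", {
  gen <- generate_plant_cloud(small_plant_spec())
  rg <- region_growing(gen$cloud)
  seeds <- c(truth_indices(gen$truth, "blade_4")[1],
             truth_indices(gen$truth, "blade_1")[1])
  seg <- segment_leaf_petiole(gen$cloud, rg, seeds = seeds)
  expect_equal(seg$n_leaves, 2L)
  # leaf 1 of the result is the blade containing the first seed (truth leaf 4)
  idx1 <- which(seg$labels == "blade_1")
  maj <- names(sort(table(gen$truth$labels[idx1]), decreasing = TRUE))[1]
  expect_equal(maj, "blade_4")
})

test_that("a plant with zero paired leaves reports yield 0, not an error", {
  gen <- generate_plant_cloud(small_plant_spec(n_leaves = 2L, seed = 12L))
  drop <- c(truth_indices(gen$truth, "petiole_1"),
            truth_indices(gen$truth, "petiole_2"))
  cl <- subset_cloud(gen$cloud, setdiff(seq_len(n_points(gen$cloud)), drop))
  seg <- segment_leaf_petiole(cl, region_growing(cl))
  ang <- plant_leaf_angles(cl, seg)
  expect_equal(nrow(ang$records), 0L)
  expect_equal(ang$yield, 0)
})
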