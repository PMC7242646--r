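px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

test_that("HSI closed forms hold for primary and achromatic colors", {
  red <- rgb_to_hsi(px(255, 0, 0))
  expect_equal(as.numeric(red$h), 0)
  expect_equal(as.numeric(red$s), 1)
  expect_equal(as.numeric(red$i), 1 / 3)

  green <- rgb_to_hsi(px(0, 255, 0))
  expect_equal(as.numeric(green$h), 120)

  blue <- rgb_to_hsi(px(0, 0, 255))
  expect_equal(as.numeric(blue$h), 240)

  gray <- rgb_to_hsi(px(100, 100, 100))
  expect_true(is.na(as.numeric(gray$h)))
  expect_equal(as.numeric(gray$s), 0)

  black <- rgb_to_hsi(px(0, 0, 0))
  expect_true(is.na(as.numeric(black$h)))
  expect_equal(as.numeric(black$i), 0)
})

test_that("hue agrees with the chromaticity-angle oracle within 0.5 degree", {
  set.seed(14)
  n <- 10000L
  cols <- matrix(sample(0:255, 3 * n, replace = TRUE), n, 3)
  h <- rgb_to_hsi(cols)$h
  chromatic <- which(!is.na(h))
  expect_gt(length(chromatic), 9000L)
  ho <- oracle_hue(cols[chromatic, 1], cols[chromatic, 2],
                   cols[chromatic, 3])
  diff <- abs(h[chromatic] - ho)
  diff <- pmin(diff, 360 - diff)
  expect_lt(max(diff), 0.5)
})

test_that("GGF counts strictly inside the hue window over plant pixels", {
  img_of <- function(colors) {
    n <- nrow(colors)
    array(c(colors[, 1], colors[, 2], colors[, 3]), dim = c(n, 1, 3))
  }
  mask <- function(n) matrix(TRUE, n, 1)

  all_green <- img_of(matrix(rep(c(0, 255, 0), each = 100), 100))
  expect_equal(ggf(all_green, mask(100)), 1.0)

  half <- img_of(rbind(matrix(rep(c(0, 255, 0), each = 50), 50),
                       matrix(rep(c(255, 0, 0), each = 50), 50)))
  expect_equal(ggf(half, mask(100)), 0.5)

  # the window bounds are strict: a pixel whose hue lands exactly on the
  # lower edge is excluded from the numerator
  col <- c(120, 200, 40)
  h_c <- as.numeric(rgb_to_hsi(matrix(col, 1, 3))$h)
  img1 <- img_of(matrix(rep(col, each = 10), 10))
  expect_equal(ggf(img1, mask(10), window = c(h_c, 180)), 0)
  expect_equal(ggf(img1, mask(10), window = c(h_c - 1e-9, 180)), 1)

  # achromatic pixels dilute the denominator only
  mixed <- img_of(rbind(matrix(rep(c(0, 255, 0), each = 50), 50),
                        matrix(rep(c(128, 128, 128), each = 50), 50)))
  expect_equal(ggf(mixed, mask(100)), 0.5)

  expect_error(ggf(all_green, matrix(FALSE, 100, 1)), "empty")
})

test_that("recoloring an in-window pixel out of the window never raises GGF", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 40L
    cols <- matrix(sample(0:255, 3 * n, replace = TRUE), n, 3)
    img <- array(c(cols[, 1], cols[, 2], cols[, 3]), dim = c(n, 1, 3))
    m <- matrix(TRUE, n, 1)
    g0 <- ggf(img, m)
    h <- rgb_to_hsi(cols)$h
    inw <- which(!is.na(h) & h > 80 & h < 180)
    if (length(inw) == 0) next
    img2 <- img
    img2[inw[1], 1, ] <- c(255, 0, 0)   # recolor to red (out of window)
    expect_lte(ggf(img2, m), g0)
  }
})

test_that("PSA weights the top view by 0.3 and is SV-permutation invariant", {
  expect_equal(psa(plant_view_counts(100, 200, 300, 100)), 630.0)
  expect_equal(psa(plant_view_counts(0, 0, 0, 0)), 0.0)
  expect_equal(psa(plant_view_counts(0, 0, 0, 10)), 3.0)
  expect_equal(psa(plant_view_counts(300, 100, 200, 100)), 630.0)
  expect_equal(psa(c(n_sv45 = 2, n_tv = 10, n_sv0 = 1, n_sv90 = 3)), 9)
  # linear in each count
  base <- psa(plant_view_counts(10, 20, 30, 40))
  expect_equal(psa(plant_view_counts(10 + 7, 20, 30, 40)), base + 7)
  expect_equal(psa(plant_view_counts(10, 20, 30, 40 + 10)), base + 3)
  expect_error(psa(c(1, 2, 3)), "4 values")
  expect_error(psa(plant_view_counts(-1, 0, 0, 0)), "non-negative")
})

test_that("background segmentation honours the tolerance", {
  img <- array(200, dim = c(4, 4, 3))
  expect_equal(sum(segment_plant_pixels(img, c(200, 200, 200))), 0)
  img[2, 3, ] <- c(200, 201, 200)
  expect_equal(sum(segment_plant_pixels(img, c(200, 200, 200), 0)), 1)
  expect_equal(sum(segment_plant_pixels(img, c(200, 200, 200), 1)), 0)
})

test_that("PNG round trip preserves 8-bit images", {
  set.seed(5)
  img <- array(sample(0:255, 12 * 10 * 3, replace = TRUE), dim = c(12, 10, 3))
  f <- withr::local_tempfile(fileext = ".png")
  write_rgb_image(img, f)
  expect_equal(read_rgb_image(f), img)
})
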