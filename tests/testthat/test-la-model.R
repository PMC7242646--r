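test_that("an exact linear relation is fitted exactly", {
  pairs <- data.frame(psa = c(1, 2, 3, 4, 5), la = 2 * c(1, 2, 3, 4, 5) + 1)
  fit <- fit_la_model(pairs, cv_k = NULL)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), c(1, 2))
  expect_equal(residuals(fit), rep(0, 5))
  expect_equal(predict(fit, c(0, 10)), c(1, 21))
})

test_that("constant response gives slope 0 and R-squared 0", {
  pairs <- data.frame(psa = 1:10, la = rep(7, 10))
  fit <- fit_la_model(pairs, cv_k = NULL)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_la_model(data.frame(psa = c(1, 2), la = c(1, 2))),
               "at least 3")
  expect_error(fit_la_model(data.frame(psa = rep(1, 5), la = 1:5)),
               "all equal")
  expect_error(kfold_cv(data.frame(psa = 1:5, la = 1:5), k = 10), "at least")
})

test_that("10-fold CV on 20 rows partitions into disjoint folds of 2", {
  pairs <- generate_psa_la_pairs(20, 2, 1, c(0, 100), 5, seed = 4)
  cv <- kfold_cv(pairs, k = 10, seed = 2)
  folds <- attr(cv, "folds")
  expect_length(folds, 10L)
  expect_true(all(vapply(folds, length, integer(1)) == 2L))
  expect_setequal(unlist(folds), 1:20)
})

test_that("noiseless linear data cross-validates to R-squared 1", {
  pairs <- generate_psa_la_pairs(30, 3.5, -12, c(10, 90), 0, seed = 6)
  expect_equal(as.numeric(kfold_cv(pairs, k = 10, seed = 1)), 1,
               tolerance = 1e-9)
})

test_that("CV is reproducible under a fixed seed and bounded above by 1", {
  pairs <- generate_psa_la_pairs(57, 2, 3, c(0, 50), 4, seed = 8)
  a <- kfold_cv(pairs, k = 10, seed = 5)
  b <- kfold_cv(pairs, k = 10, seed = 5)
  expect_identical(a, b)
  expect_lte(as.numeric(a), 1)
  sizes <- vapply(attr(a, "folds"), length, integer(1))
  expect_true(all(sizes %in% c(5L, 6L)))   # floor/ceil of 57/10
  expect_setequal(unlist(attr(a, "folds")), 1:57)
})

test_that("refitting on its own predictions returns the same model", {
  pairs <- generate_psa_la_pairs(80, 3.3027, -283.42, c(400, 1000), 20,
                                 seed = 12)
  fit <- fit_la_model(pairs, cv_k = NULL)
  refit <- fit_la_model(data.frame(psa = pairs$psa,
                                   la = predict(fit, pairs$psa)),
                        cv_k = NULL)
  expect_equal(refit$slope, fit$slope, tolerance = 1e-12)
  expect_equal(refit$intercept, fit$intercept, tolerance = 1e-9)
  expect_equal(refit$r_squared, 1)
})

test_that("slope recovery is unbiased over repeated draws", {
  slopes <- vapply(1:200, function(s) {
    pairs <- generate_psa_la_pairs(200, 3.3027, -283.42, c(400, 1000), 20,
                                   seed = 1000 + s)
    fit_la_model(pairs, cv_k = NULL)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 3.3027) / 3.3027, 0.005)
})

test_that("prediction from the published coefficients is plain arithmetic", {
  # noiseless pairs generated from the published line refit to it exactly,
  # so prediction reproduces slope * PSA + intercept
  pairs <- generate_psa_la_pairs(10, 3.3027, -283.42, c(400, 1000), 0,
                                 seed = 3)
  fit <- fit_la_model(pairs, cv_k = NULL)
  expect_equal(predict(fit, 1000), 3019.28, tolerance = 1e-6)
  expect_equal(predict(fit, 0), -283.42, tolerance = 1e-6)
})

test_that("models persist to JSON and back", {
  pairs <- generate_psa_la_pairs(40, 2, 5, c(0, 100), 3, seed = 2)
  fit <- fit_la_model(pairs, cv_k = 5, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_la_model(fit, f)
  back <- read_la_model(f)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$cv_r_squared, fit$cv_r_squared)
  expect_equal(predict(back, 50), predict(fit, 50))
})
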