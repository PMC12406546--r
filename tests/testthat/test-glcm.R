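test_that("quantize bins linearly and is invariant to positive affine maps", {
  expect_equal(unique(as.vector(quantize(matrix(3.5, 4, 4), 8)$levels)), 1L)

  q <- quantize(matrix(c(0, 85, 170, 255), 2, 2), 4)
  expect_setequal(as.vector(q$levels), 1:4)

  set.seed(2)
  img <- matrix(runif(100, 0, 10), 10, 10)
  q1 <- quantize(img, 16)
  q2 <- quantize(3.7 * img + 12, 16)
  expect_identical(q1$levels, q2$levels)

  expect_error(quantize(img, 1), "n_levels")
  expect_error(quantize(img, 8, range_mode = "fixed", range = c(5, 5)),
               "hi > lo")
})

test_that("fixed-range quantization clamps and uses the given bounds", {
  img <- matrix(c(-5, 0, 50, 100, 150, 200), 2, 3)
  q <- quantize(img, 4, range_mode = "fixed", range = c(0, 100))
  expect_equal(as.vector(q$levels), c(1L, 1L, 3L, 4L, 4L, 4L))
})

test_that("the 4-pixel row image reproduces the hand-enumerated GLCM", {
  row <- matrix(c(0, 0, 85, 85), 1, 4)  # levels 1 1 2 2
  g <- compute_glcm(quantize(row, 2), directions = list(c(0, 1)))
  expect_equal(g$p, matrix(c(1/3, 1/6, 1/6, 1/3), 2, 2))
  expect_equal(g$n_pairs, 3L)
  expect_equal(sum(g$p), 1)
})

test_that("the checkerboard reproduces its hand-derived GLCM and features", {
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  g <- compute_glcm(quantize(cb, 2), directions = list(c(0, 1)))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  f <- texture_features(g)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["angular_second_moment"]), 0.5)
  expect_equal(unname(f["inverse_difference_moment"]), 0.5)
  expect_equal(unname(f["correlation"]), -1)
  expect_equal(unname(f["entropy"]), 1)  # bits
  expect_equal(unname(f["maximum_probability"]), 0.5)
  expect_equal(unname(f["autocorrelation"]), 2)
  expect_equal(unname(f["sum_average"]), 3)
  expect_equal(unname(f["sum_variance"]), 0)
  expect_equal(unname(f["cluster_shade"]), 0)
  expect_equal(unname(f["cluster_prominence"]), 0)
  expect_equal(unname(f["INN"]), 2/3)
  expect_equal(unname(f["IDN"]), 0.8)

  m <- glcm_marginals(g)
  expect_equal(unname(m$p_sum["3"]), 1)
  expect_equal(unname(m$p_diff["1"]), 1)
  expect_equal(m$mu_x, 1.5)
  expect_equal(m$p_x, m$p_y)  # symmetry
})

test_that("a constant image yields the analytic degenerate feature vector", {
  g <- compute_glcm(quantize(matrix(7, 6, 6), 16))
  f <- texture_features(g)
  expected <- c(angular_second_moment = 1, contrast = 0, correlation = 1,
                sum_of_squares_variance = 0, inverse_difference_moment = 1,
                sum_average = 2, sum_variance = 0, sum_entropy = 0,
                entropy = 0, difference_variance = 0,
                difference_entropy = 0, IMCI = 0, IMCII = 0,
                autocorrelation = 1, maximum_probability = 1,
                cluster_prominence = 0, cluster_shade = 0, INN = 1,
                IDN = 1, dissimilarity = 0)
  expect_equal(unclass(f)[names(expected)], expected,
               ignore_attr = TRUE)
})

test_that("single-cell marginals are degenerate in the documented way", {
  g <- as_glcm(matrix(c(1, 0, 0, 0), 2, 2))
  m <- glcm_marginals(g)
  expect_equal(m$mu_x, 1)
  expect_equal(m$sigma_x, 0)
  expect_equal(m$HX, 0)
  expect_equal(m$HXY, 0)
  expect_equal(m$HXY2, 0)
})

test_that("fully masked images give a flagged degenerate GLCM", {
  img <- matrix(NA_real_, 4, 4)
  g <- compute_glcm(quantize(img, 8))
  expect_equal(g$n_pairs, 0L)
  f <- texture_features(g)
  expect_true(all(is.na(f)))
  expect_true(attr(f, "degenerate"))
  expect_error(glcm_marginals(g), "degenerate")
})

test_that("masking restricts pair counting to valid endpoints", {
  img <- matrix(c(0, 0, NA, 85, 85, NA), 1, 6)
  g <- compute_glcm(quantize(img, 2), directions = list(c(0, 1)))
  # valid ordered pairs: (1,1) and (2,2) only; the NA breaks the chain
  expect_equal(g$n_pairs, 2L)
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("implementation matches the literal-loop oracle on random GLCMs", {
  set.seed(9)
  for (ng in c(4, 16, 64)) {
    for (r in 1:15) {
      p <- random_glcm_matrix(ng)
      impl <- unclass(texture_features(as_glcm(p)))
      orac <- oracle_texture_features(p)
      expect_equal(impl[names(orac)], orac, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("feature bounds hold on random GLCMs", {
  set.seed(10)
  for (r in 1:40) {
    ng <- sample(c(3, 8, 17), 1)
    f <- texture_features(as_glcm(random_glcm_matrix(ng)))
    expect_gte(f[["angular_second_moment"]], 0)
    expect_lte(f[["angular_second_moment"]], 1)
    expect_gte(f[["maximum_probability"]], 0)
    expect_lte(f[["maximum_probability"]], 1)
    expect_gte(f[["correlation"]], -1 - 1e-12)
    expect_lte(f[["correlation"]], 1 + 1e-12)
    expect_gte(f[["IMCII"]], 0)
    expect_lte(f[["IMCII"]], 1)
    for (k in c("inverse_difference_moment", "INN", "IDN")) {
      expect_gt(f[[k]], 0)
      expect_lte(f[[k]], 1)
    }
    expect_true(all(is.finite(unclass(f))))
  }
})

test_that("features are invariant to transposing a symmetric GLCM", {
  set.seed(12)
  p <- random_glcm_matrix(8)
  expect_equal(unclass(texture_features(as_glcm(p))),
               unclass(texture_features(as_glcm(t(p)))))
})

test_that("minmax quantization makes features affine-invariant on images", {
  set.seed(13)
  img <- matrix(runif(400, 10, 60), 20, 20)
  f1 <- texture_features(compute_glcm(quantize(img, 16)))
  f2 <- texture_features(compute_glcm(quantize(0.25 * img + 7, 16)))
  expect_equal(unclass(f1), unclass(f2))
})

test_that("correlation features rise and contrast falls with speckle smoothness", {
  sweep <- c(0.5, 1, 2, 4, 8)
  res <- sapply(sweep, function(cl) {
    rowMeans(sapply(1:20, function(s) {
      fld <- speckle_field(96, 96, contrast = 0.3, corr_len = cl,
                           seed = 1000 + s)
      f <- texture_features(compute_glcm(quantize(fld, 32)))
      c(f[["correlation"]], f[["inverse_difference_moment"]],
        f[["contrast"]])
    }))
  })
  expect_true(all(diff(res[1, ]) > 0))  # GLCM correlation increases
  expect_true(all(diff(res[2, ]) > 0))  # IDM increases
  expect_true(all(diff(res[3, ]) < 0))  # contrast decreases
})
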