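test_that("quantization is equal-width flooring into [0, Ng-1]", {
  expect_equal(as.vector(quantize(matrix(255L), 8)), 7L)
  expect_equal(as.vector(quantize(matrix(0L), 4)), 0L)
  expect_equal(as.vector(quantize(matrix(0L), 64)), 0L)
  expect_equal(as.vector(quantize(matrix(128L), 8)), 4L)
  expect_equal(as.vector(quantize(matrix(127L), 8)), 3L)
  expect_error(quantize(matrix(1L), 5), class = "soylodge_levels_error")
})

test_that("the toy image's symmetric horizontal GLCM matches hand enumeration", {
  g <- compute_glcm(toy_image(), levels = 4, d = 1, angle = 0)
  expect_equal(g$n_pairs, 24)
  counts <- g$P * 24
  expect_equal(counts[1, 1], 4)   # p(0,0) = 4/24
  expect_equal(counts[3, 3], 6)   # p(2,2) = 6/24
  expect_equal(counts[1, 2], 2)   # p(0,1) = 2/24
  expect_equal(counts[2, 1], 2)   # symmetric
  expect_equal(sum(g$P), 1)
  expect_true(isSymmetric(g$P))
})

test_that("toy-image Haralick values equal exact rationals", {
  f <- haralick_features(compute_glcm(toy_image(), levels = 4, d = 1, angle = 0))
  expect_equal(f$angular_second_moment, 84 / 576)
  expect_equal(f$contrast, 14 / 24)
})

test_that("GLCM invariants hold: normalization, symmetry, mask and errors", {
  q <- random_quantized(1)
  for (ang in c(0, 45, 90, 135)) {
    g <- compute_glcm(q, levels = 8, angle = ang)
    expect_lt(abs(sum(g$P) - 1), 1e-12)
    expect_true(isSymmetric(g$P))
    expect_true(all(g$P >= 0))
  }
  # constant image: all mass in one cell
  gc_ <- compute_glcm(matrix(3L, 8, 8), levels = 4)
  expect_equal(gc_$P[4, 4], 1)
  # mask that separates the two columns of every horizontal pair
  m <- matrix(FALSE, 4, 4); m[, 2] <- TRUE
  expect_error(compute_glcm(toy_image(), levels = 4, mask = m, angle = 0),
               class = "soylodge_degenerate_glcm")
})

test_that("masked GLCMs only count pairs fully inside the mask", {
  q <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L), 2, 3)   # rows: 0,1,0 / 1,0,1
  mask <- matrix(TRUE, 2, 3); mask[2, 3] <- FALSE
  g <- compute_glcm(q, levels = 2, mask = mask, angle = 0, symmetric = FALSE,
                    normalize = FALSE)
  # surviving ordered pairs: (0,1), (1,0) from row 1 and (1,0) from row 2
  expect_equal(g$P[1, 2], 1)
  expect_equal(g$P[2, 1], 2)
  expect_equal(sum(g$P), 3)
})

test_that("averaging GLCMs is the element-wise mean and keeps normalization", {
  q <- random_quantized(2)
  g0 <- compute_glcm(q, levels = 8, angle = 0)
  g90 <- compute_glcm(q, levels = 8, angle = 90)
  avg <- average_glcms(list(g0, g90))
  expect_equal(avg$P, (g0$P + g90$P) / 2)
  expect_lt(abs(sum(avg$P) - 1), 1e-12)
  expect_equal(average_glcms(list(g0))$P, g0$P)
  expect_equal(average_glcms(list(g0, g0))$P, g0$P)
  g4 <- compute_glcm(quantize(matrix(sample(0:255, 64, TRUE), 8), 4), levels = 4)
  expect_error(average_glcms(list(g0, g4)), class = "soylodge_levels_error")
})

test_that("features agree with an independent reference implementation", {
  # values computed with scikit-image graycomatrix/graycoprops (symmetric,
  # normed, distance 1) on this fixed 8x8 level-8 image
  im <- matrix(as.integer(c(
    3, 1, 4, 1, 5, 0, 2, 6,
    5, 3, 5, 0, 4, 7, 1, 3,
    2, 3, 0, 6, 2, 6, 4, 3,
    3, 2, 7, 0, 5, 0, 2, 4,
    1, 7, 1, 6, 3, 2, 0, 5,
    0, 2, 4, 4, 3, 7, 5, 1,
    6, 0, 3, 1, 7, 2, 5, 3,
    2, 6, 1, 4, 0, 5, 3, 7
  )), 8, 8, byrow = TRUE)
  f0 <- haralick_features(compute_glcm(im, levels = 8, d = 1, angle = 0))
  expect_equal(f0$contrast, 14.5, tolerance = 1e-10)
  expect_equal(f0$angular_second_moment, 0.02726403061224491, tolerance = 1e-10)
  expect_equal(f0$correlation, -0.4593068035943519, tolerance = 1e-9)
  expect_equal(f0$inverse_difference_moment, 0.15098237215884278, tolerance = 1e-10)
  favg <- haralick_features(average_glcms(list(
    compute_glcm(im, levels = 8, d = 1, angle = 0),
    compute_glcm(im, levels = 8, d = 1, angle = 90)
  )))
  expect_equal(favg$contrast, 13.92857142857143, tolerance = 1e-10)
  expect_equal(favg$angular_second_moment, 0.023238201530612252, tolerance = 1e-10)
  expect_equal(favg$correlation, -0.4215973442686976, tolerance = 1e-9)
  expect_equal(favg$inverse_difference_moment, 0.19705594087947034, tolerance = 1e-10)
})

test_that("features match a naive double-loop oracle on random matrices", {
  for (s in 1:5) {
    q <- random_quantized(s, levels = 6)
    g <- compute_glcm(q, levels = 6, angle = sample(c(0, 45, 90, 135), 1))
    f <- haralick_features(g)
    o <- naive_haralick(g$P)
    for (nm in names(o)) {
      expect_equal(f[[nm]], o[[nm]], tolerance = 1e-10,
                   label = sprintf("%s (seed %d)", nm, s))
    }
  }
})

test_that("constant-image degeneracies take their closed-form values", {
  f <- haralick_features(compute_glcm(matrix(5L, 8, 8), levels = 8))
  expect_equal(f$angular_second_moment, 1)
  expect_equal(f$contrast, 0)
  expect_equal(f$entropy, 0)
  expect_equal(f$inverse_difference_moment, 1)
  expect_equal(f$correlation, 0)
  expect_true(attr(f, "degenerate"))
})

test_that("feature ranges respect their analytic bounds", {
  for (s in 1:5) {
    g <- compute_glcm(random_quantized(10 + s), levels = 8)
    f <- haralick_features(g)
    expect_gt(f$angular_second_moment, 0)
    expect_lte(f$angular_second_moment, 1)
    expect_gte(f$contrast, 0)
    expect_gte(f$correlation, -1); expect_lte(f$correlation, 1)
    expect_gte(f$entropy, 0)
    expect_gte(f$sum_entropy, 0)
    expect_gte(f$difference_entropy, 0)
    expect_gte(f$info_measure_II, 0); expect_lte(f$info_measure_II, 1)
    expect_gte(f$max_correlation_coefficient, 0)
    expect_lte(f$max_correlation_coefficient, 1)
  }
})

test_that("contrast is zero iff all mass is diagonal; ASM=1 iff one cell", {
  # diagonal-mass image: constant columns produce only equal vertical pairs
  q <- matrix(rep(c(0L, 1L, 2L, 3L), each = 4), 4, 4)
  g <- compute_glcm(q, levels = 4, angle = 90)
  f <- haralick_features(g)
  expect_equal(f$contrast, 0)
  expect_lt(f$angular_second_moment, 1)  # several diagonal cells occupied
})

test_that("the averaged feature vector is invariant to image transposition", {
  q <- random_quantized(7)
  f1 <- extract_plot_features(matrix(as.integer(q * 31), nrow(q)), levels = 8)
  f2 <- extract_plot_features(matrix(as.integer(t(q) * 31), ncol(q)), levels = 8)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-12)
})

test_that("whole-field extraction yields a complete feature table", {
  fld <- generate_field(field_config(n_plots = 12,
                                     class_counts = c(NL = 6, ML = 3, HL = 2, SL = 1),
                                     seed = 6))
  ft <- suppressMessages(extract_field_features(fld))
  expect_equal(nrow(ft) + length(attr(ft, "skipped")), 12)
  expect_true(all(texture_feature_names() %in% names(ft)))
  expect_false(anyNA(ft[, texture_feature_names()]))
  expect_true(all(ft$provenance == "original"))
  # severity ordering shows up in the extracted contrast
  mc <- tapply(ft$contrast, as.character(ft$class), mean)
  if (all(c("NL", "SL") %in% names(mc))) expect_gt(mc["SL"], mc["NL"])
})
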