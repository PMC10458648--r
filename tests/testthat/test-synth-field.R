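test_that("scores map to their severity class and invalid scores error", {
  expect_equal(as.character(score_to_class(c(1.0, 1.5))), c("NL", "NL"))
  expect_equal(as.character(score_to_class(c(2.0, 2.5))), c("ML", "ML"))
  expect_equal(as.character(score_to_class(c(3.0, 3.5))), c("HL", "HL"))
  expect_equal(as.character(score_to_class(c(4.0, 4.5, 5.0))), rep("SL", 3))
  expect_error(score_to_class(0.7), class = "soylodge_invalid_score")
  expect_error(score_to_class(5.5), class = "soylodge_invalid_score")
  expect_error(score_to_class(2.3), class = "soylodge_invalid_score")
})

test_that("score sets are disjoint and jointly cover the 1-5 half-step scale", {
  sets <- lodging_score_sets()
  all_scores <- sort(unlist(sets, use.names = FALSE))
  expect_equal(all_scores, seq(1, 5, by = 0.5))
  expect_equal(anyDuplicated(all_scores), 0L)
})

test_that("generated fields honour class counts, bboxes and determinism", {
  counts <- c(NL = 20, ML = 5, HL = 3, SL = 2)
  cfg <- field_config(n_plots = 30, class_counts = counts, seed = 1)
  fld <- generate_field(cfg)
  expect_equal(nrow(fld$plots), 30)
  expect_equal(as.vector(table(fld$plots$class)), unname(counts[lodging_classes()]))
  # bboxes inside the image, and class consistent with score
  expect_true(all(fld$plots$row0 >= 0 & fld$plots$col0 >= 0))
  expect_true(all(fld$plots$row1 <= nrow(fld$image)))
  expect_true(all(fld$plots$col1 <= ncol(fld$image)))
  expect_equal(as.character(score_to_class(fld$plots$score)),
               as.character(fld$plots$class))
  # bit-identical regeneration
  fld2 <- generate_field(cfg)
  expect_identical(fld$image, fld2$image)
  expect_identical(fld$plots$score, fld2$plots$score)
  # and a different seed changes the image
  fld3 <- generate_field(field_config(n_plots = 30, class_counts = counts, seed = 2))
  expect_false(identical(fld$image, fld3$image))
})

test_that("default scaling reproduces the reference imbalance", {
  expect_equal(scaled_class_counts(1266),
               c(NL = 964L, ML = 206L, HL = 85L, SL = 11L))
  small <- scaled_class_counts(130)
  expect_equal(sum(small), 130L)
  expect_true(all(small >= 4))
  expect_true(small["NL"] > small["ML"] & small["ML"] > small["HL"] &
                small["HL"] >= small["SL"])
})

test_that("a grid too small for the plots raises a layout error", {
  expect_error(
    generate_field(field_config(n_plots = 30, grid = c(2, 2), seed = 1)),
    class = "soylodge_layout_error"
  )
})

test_that("plot textures get rougher and sparser with lodging severity", {
  seeds <- 1:20
  stats <- lapply(c("NL", "SL"), function(cl) {
    t(sapply(seeds, function(s) {
      p <- generate_plot_texture(cl, c(64, 48), seed = s)
      f <- extract_plot_features(p$patch, p$canopy)
      c(contrast = f$contrast, asm = f$angular_second_moment,
        canopy = mean(p$canopy))
    }))
  })
  names(stats) <- c("NL", "SL")
  # paired over seeds: SL strictly rougher, less uniform, more exposed soil
  expect_gt(mean(stats$SL[, "contrast"]), mean(stats$NL[, "contrast"]))
  expect_lt(mean(stats$SL[, "asm"]), mean(stats$NL[, "asm"]))
  expect_lt(mean(stats$SL[, "canopy"]), mean(stats$NL[, "canopy"]))
  # full ordering of expected contrast across all four classes
  mean_contrast <- sapply(lodging_classes(), function(cl) {
    mean(sapply(seeds, function(s) {
      p <- generate_plot_texture(cl, c(64, 48), seed = s)
      extract_plot_features(p$patch, p$canopy)$contrast
    }))
  })
  expect_true(all(diff(mean_contrast) > 0))
})

test_that("zero heterogeneity parameters give a constant patch", {
  p <- generate_plot_texture("NL", c(16, 16), seed = 1,
                             params = list(grain_sd = 0, streak_amp = 0,
                                           soil_frac = 0, base_amp = 0))
  expect_equal(length(unique(as.vector(p$patch))), 1L)
  expect_true(all(p$canopy))
})

test_that("generate_plot_texture validates its inputs", {
  expect_error(generate_plot_texture("XX", c(32, 32), seed = 1))
  expect_error(generate_plot_texture("NL", c(8, 32), seed = 1))
})

test_that("Gaussian feature tables have the requested size and structure", {
  p <- feature_table_params(12, separation = 1.5)
  tab <- generate_feature_table(c(NL = 964, ML = 206, HL = 85, SL = 11),
                                p$means, p$covs, seed = 1)
  expect_equal(nrow(tab), 1266)
  expect_equal(as.vector(table(tab$class)), c(964, 206, 85, 11))
  expect_equal(length(soylodge:::feature_columns(tab)), 12)
  expect_false(anyNA(tab))
  expect_true(all(tab$provenance == "original"))
  # determinism
  tab2 <- generate_feature_table(c(NL = 964, ML = 206, HL = 85, SL = 11),
                                 p$means, p$covs, seed = 1)
  expect_identical(tab, tab2)
  # degenerate: identical means, zero covariance -> identical rows per class
  z <- lapply(lodging_classes(), function(cl) rep(1, 3))
  names(z) <- lodging_classes()
  zc <- lapply(lodging_classes(), function(cl) matrix(0, 3, 3))
  names(zc) <- lodging_classes()
  tz <- generate_feature_table(c(NL = 5, ML = 4, HL = 4, SL = 4), z, zc, seed = 2)
  feats <- as.matrix(tz[, soylodge:::feature_columns(tz)])
  expect_true(all(feats == 1))
  # dimension mismatch errors
  bad <- z; bad$NL <- rep(1, 2)
  expect_error(generate_feature_table(c(NL = 5, ML = 4, HL = 4, SL = 4),
                                      bad, zc, seed = 2),
               class = "soylodge_dim_error")
})

test_that("field images and records round-trip through PNG and CSV", {
  fld <- generate_field(field_config(n_plots = 8, class_counts =
                                       c(NL = 2, ML = 2, HL = 2, SL = 2),
                                     seed = 4))
  img_path <- withr::local_tempfile(fileext = ".png")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, img_path, csv_path)
  back <- png::readPNG(img_path)
  expect_equal(matrix(as.integer(round(back * 255)), nrow(back)), fld$image)
  recs <- read.csv(csv_path)
  expect_equal(names(recs),
               c("plot_id", "row0", "col0", "row1", "col1", "score", "class"))
  expect_equal(nrow(recs), 8)
})

test_that("rgb mode produces a 3-band field whose luminance tracks the scene", {
  fld <- generate_field(field_config(n_plots = 4,
                                     class_counts = c(NL = 1, ML = 1, HL = 1, SL = 1),
                                     rgb = TRUE, seed = 9))
  expect_equal(length(dim(fld$image)), 3L)
  g <- to_grayscale(fld$image)
  # canopy patches are greener/brighter than soil background
  p <- fld$plots[1, ]
  patch_mean <- mean(crop_roi(g, c(p$row0, p$col0, p$row1, p$col1)))
  corner_mean <- mean(g[1:10, 1:10])
  expect_gt(patch_mean, corner_mean)
})
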