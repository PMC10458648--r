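#' Per-class canopy texture parameters
#'
#' The generator's texture model is additive: a flat canopy level, fine
#' Gaussian grain, a low-frequency brightness undulation, an oriented sinusoid
#' ("streaks" of flattened stems) and thresholded smooth-noise blobs of exposed
#' soil. Severity is encoded by making the grain, streaks and soil gaps
#' stronger from NL to SL, so that GLCM contrast increases and angular second
#' moment decreases with class order, and the canopy (foreground) fraction
#' shrinks as plants go down.
#'
#' @return A named list (one element per class) of parameter lists with
#'   entries `grain_sd` (sd of pixel-level Gaussian grain, grey levels),
#'   `streak_amp` (amplitude of the oriented sinusoid, grey levels),
#'   `soil_frac` (fraction of the patch opened up to bare soil, 0..1) and
#'   `base_amp` (amplitude of the low-frequency undulation, grey levels).
#' @examples
#' default_texture_params()$SL
#' @export
default_texture_params <- function() {
  list(
    NL = list(grain_sd = 6,  streak_amp = 0,  soil_frac = 0.00, base_amp = 4),
    ML = list(grain_sd = 10, streak_amp = 12, soil_frac = 0.05, base_amp = 6),
    HL = list(grain_sd = 14, streak_amp = 24, soil_frac = 0.15, base_amp = 8),
    SL = list(grain_sd = 18, streak_amp = 40, soil_frac = 0.30, base_amp = 10)
  )
}

#' Class counts for a field of a given size
#'
#' Scales the reference imbalance 964:206:85:11 (NL:ML:HL:SL over 1266 plots)
#' to `n_plots`, with a floor of `min_count` plots per class so that stratified
#' splitting and neighbour-based resampling stay defined at small sizes. At
#' `n_plots = 1266` the reference counts are returned exactly.
#'
#' @param n_plots Total number of plots.
#' @param min_count Minimum plots per class (default 4).
#' @return Named integer vector over `NL, ML, HL, SL` summing to `n_plots`.
#' @examples
#' scaled_class_counts(1266)
#' scaled_class_counts(130)
#' @export
scaled_class_counts <- function(n_plots, min_count = 4L) {
  ref <- c(NL = 964, ML = 206, HL = 85, SL = 11)
  counts <- round(ref / sum(ref) * n_plots)
  counts <- pmax(counts, min_count)
  counts["NL"] <- counts["NL"] + (n_plots - sum(counts))
  if (any(counts < 0) || sum(counts) != n_plots) {
    abort("`n_plots` too small to hold four classes at the configured floor.")
  }
  stats::setNames(as.integer(counts), names(ref))
}

#' Configuration for the synthetic plot field
#'
#' Bundles every knob of the synthetic orthomosaic generator: how many plots,
#' their class composition, the pixel geometry of the plot grid, soil/canopy
#' intensity levels and the per-class texture parameters.
#'
#' @param n_plots Number of plots (default 130, a small field with the
#'   reference imbalance).
#' @param class_counts Named counts over `NL, ML, HL, SL`; default
#'   [scaled_class_counts()] of `n_plots`.
#' @param plot_shape `c(rows, cols)` of one plot patch in pixels.
#' @param gap Gap between adjacent plots, pixels.
#' @param margin Field border, pixels.
#' @param grid Optional `c(rows, cols)` plot-grid dimensions; computed from
#'   `n_plots` when `NULL`.
#' @param canopy_level,soil_level Mean 8-bit intensity of canopy and soil.
#' @param soil_sd Grain sd of the soil background.
#' @param texture_params Per-class texture parameters, see
#'   [default_texture_params()].
#' @param rgb If `TRUE` the field is rendered as a 3-band array with
#'   green-tinted canopy and brown-tinted soil; default single-band.
#' @param seed Integer RNG seed; identical configs and seeds give bit-identical
#'   fields.
#' @return A list of class `field_config`.
#' @examples
#' cfg <- field_config(n_plots = 30, seed = 1)
#' @export
field_config <- function(n_plots = 130,
                         class_counts = NULL,
                         plot_shape = c(64L, 48L),
                         gap = 12L,
                         margin = 16L,
                         grid = NULL,
                         canopy_level = 170,
                         soil_level = 70,
                         soil_sd = 8,
                         texture_params = default_texture_params(),
                         rgb = FALSE,
                         seed = 1L) {
  if (is.null(class_counts)) class_counts <- scaled_class_counts(n_plots)
  class_counts <- class_counts[lodging_classes()]
  if (anyNA(class_counts) || any(class_counts < 0)) {
    abort("`class_counts` must be named non-negative counts over NL, ML, HL, SL.")
  }
  if (sum(class_counts) != n_plots) {
    abort("`class_counts` must sum to `n_plots`.")
  }
  structure(
    list(
      n_plots = as.integer(n_plots),
      class_counts = stats::setNames(as.integer(class_counts), lodging_classes()),
      plot_shape = as.integer(plot_shape),
      gap = as.integer(gap),
      margin = as.integer(margin),
      grid = if (!is.null(grid)) as.integer(grid),
      canopy_level = canopy_level,
      soil_level = soil_level,
      soil_sd = soil_sd,
      texture_params = texture_params,
      rgb = isTRUE(rgb),
      seed = as.integer(seed)
    ),
    class = "field_config"
  )
}

#' Generate one plot's canopy texture patch
#'
#' Draws an 8-bit texture patch for a single plot of the given lodging class,
#' together with the ground-truth canopy mask (FALSE where bare soil shows
#' through). See [default_texture_params()] for the texture model.
#'
#' @param class One of `"NL", "ML", "HL", "SL"`.
#' @param shape `c(rows, cols)`, at least 16 each.
#' @param seed Integer seed; determines the patch completely.
#' @param params Texture parameter list for this class (grain_sd, streak_amp,
#'   soil_frac, base_amp); default the class entry of
#'   [default_texture_params()].
#' @param canopy_level,soil_level Mean intensities.
#' @return List with `patch` (integer matrix, 0..255) and `canopy` (logical
#'   matrix, TRUE on canopy).
#' @examples
#' p <- generate_plot_texture("SL", c(32, 32), seed = 7)
#' mean(p$canopy)
#' @export
generate_plot_texture <- function(class, shape, seed,
                                  params = NULL,
                                  canopy_level = 170,
                                  soil_level = 70) {
  class <- match.arg(class, lodging_classes())
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 16)) {
    abort("`shape` must be c(rows, cols) with both >= 16.")
  }
  if (is.null(params)) params <- default_texture_params()[[class]]
  h <- shape[1]; w <- shape[2]
  with_seed(seed, {
    base <- matrix(canopy_level, h, w)
    if (params$base_amp > 0) {
      # blurred unit noise has sd ~ 1/(2 sigma sqrt(pi)); rescale so the
      # undulation's sd is ~base_amp grey levels
      base <- base + params$base_amp * 2 * 6 * sqrt(pi) *
        gauss_blur(matrix(rnorm(h * w), h, w), sigma = 6)
    }
    if (params$streak_amp > 0) {
      theta <- runif(1, 0, pi)
      lambda <- runif(1, 7, 13)
      phase <- runif(1, 0, 2 * pi)
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      base <- base + params$streak_amp *
        sin(2 * pi * (rr * cos(theta) + cc * sin(theta)) / lambda + phase)
    }
    if (params$grain_sd > 0) {
      base <- base + rnorm(h * w, sd = params$grain_sd)
    }
    canopy <- matrix(TRUE, h, w)
    if (params$soil_frac > 0) {
      blob <- gauss_blur(matrix(rnorm(h * w), h, w), sigma = 3)
      cut <- quantile(blob, 1 - params$soil_frac)
      canopy <- blob < cut
      soil <- matrix(soil_level, h, w) + rnorm(h * w, sd = max(params$grain_sd / 2, 1))
      base[!canopy] <- soil[!canopy]
    }
    list(patch = matrix(as.integer(round(clamp(base, 0, 255))), h, w),
         canopy = canopy)
  })
}

#' Generate a synthetic plot-field image with plot records
#'
#' Lays `n_plots` rectangular canopy patches on a soil-textured background in a
#' regular grid (emulating an orthomosaic of four-row breeding plots), one
#' patch per plot, with textures drawn by [generate_plot_texture()] for each
#' plot's lodging class. Scores are sampled uniformly from the class's
#' admissible score set. The output is fully determined by the configuration
#' (including its seed).
#'
#' @param config A [field_config()].
#' @return A list of class `lodging_field` with elements `image` (integer
#'   matrix 0..255, or rows x cols x 3 array in rgb mode), `plots` (a tibble:
#'   `plot_id, row0, col0, row1, col1, score, class` and a list-column
#'   `canopy_truth` of ground-truth masks; bounding boxes are 0-based,
#'   half-open) and `config`.
#' @examples
#' fld <- generate_field(field_config(n_plots = 30, seed = 1))
#' nrow(fld$plots)
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  n <- config$n_plots
  ph <- config$plot_shape[1]; pw <- config$plot_shape[2]
  if (is.null(config$grid)) {
    gc_ <- ceiling(sqrt(n)); gr <- ceiling(n / gc_)
  } else {
    gr <- config$grid[1]; gc_ <- config$grid[2]
  }
  if (gr * gc_ < n) {
    abort(sprintf("Grid %d x %d cannot hold %d plots.", gr, gc_, n),
          class = "soylodge_layout_error")
  }
  H <- 2L * config$margin + gr * ph + (gr - 1L) * config$gap
  W <- 2L * config$margin + gc_ * pw + (gc_ - 1L) * config$gap

  labels <- rep(lodging_classes(), times = config$class_counts)
  sets <- lodging_score_sets()

  with_seed(config$seed, {
    img <- matrix(config$soil_level, H, W) +
      6 * 2 * 10 * sqrt(pi) * gauss_blur(matrix(rnorm(H * W), H, W), sigma = 10) +
      rnorm(H * W, sd = config$soil_sd)
    labels <- sample(labels)
    scores <- vapply(labels, function(cl) {
      s <- sets[[cl]]
      s[sample.int(length(s), 1)]
    }, numeric(1))
  })

  recs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g_row <- (i - 1L) %/% gc_
    g_col <- (i - 1L) %% gc_
    r0 <- config$margin + g_row * (ph + config$gap)
    c0 <- config$margin + g_col * (pw + config$gap)
    tex <- generate_plot_texture(
      labels[i], c(ph, pw), seed = derive_seed(config$seed, i),
      params = config$texture_params[[labels[i]]],
      canopy_level = config$canopy_level, soil_level = config$soil_level
    )
    img[(r0 + 1):(r0 + ph), (c0 + 1):(c0 + pw)] <- tex$patch
    truths[[i]] <- tex$canopy
    recs[[i]] <- tibble(
      plot_id = sprintf("P%04d", i),
      row0 = r0, col0 = c0, row1 = r0 + ph, col1 = c0 + pw,
      score = scores[i], class = labels[i]
    )
  }
  plots <- bind_rows(recs)
  plots$class <- as_lodging_factor(plots$class)
  plots$canopy_truth <- truths
  img <- matrix(as.integer(round(clamp(img, 0, 255))), H, W)
  if (config$rgb) img <- tint_field(img, config)
  structure(list(image = img, plots = plots, config = config),
            class = "lodging_field")
}

# 3-band rendering: canopy-bright pixels tinted green, soil tinted brown
tint_field <- function(gray, config) {
  mid <- (config$canopy_level + config$soil_level) / 2
  g <- gray / 255
  veg <- gray >= mid
  out <- array(0, dim = c(nrow(gray), ncol(gray), 3L))
  out[, , 1] <- ifelse(veg, 0.45 * g, 0.80 * g) * 255
  out[, , 2] <- ifelse(veg, 0.95 * g, 0.65 * g) * 255
  out[, , 3] <- ifelse(veg, 0.40 * g, 0.45 * g) * 255
  array(as.integer(round(clamp(out, 0, 255))), dim = dim(out))
}

#' Write a field image and its plot records to disk
#'
#' @param field A `lodging_field` from [generate_field()].
#' @param image_path PNG path for the image.
#' @param records_path CSV path for the plot records
#'   (`plot_id,row0,col0,row1,col1,score,class`).
#' @return Invisibly, the two paths.
#' @export
write_field <- function(field, image_path, records_path) {
  stopifnot(inherits(field, "lodging_field"))
  img <- field$image / 255
  png::writePNG(img, image_path)
  recs <- field$plots[, c("plot_id", "row0", "col0", "row1", "col1", "score", "class")]
  write.csv(recs, records_path, row.names = FALSE)
  invisible(c(image = image_path, records = records_path))
}

#' Names of the 14 GLCM texture features
#' @return Character vector of the 14 feature names in canonical order.
#' @export
texture_feature_names <- function() {
  c("angular_second_moment", "contrast", "correlation", "variance",
    "inverse_difference_moment", "sum_average", "sum_variance", "sum_entropy",
    "entropy", "difference_variance", "difference_entropy",
    "info_measure_I", "info_measure_II", "max_correlation_coefficient")
}

#' Class-conditional Gaussian parameters for tabular simulations
#'
#' Builds per-class mean vectors on orthogonal indicator directions (class c
#' gets every (c-1 mod 4)-th dimension raised by `separation`) with identity
#' covariances, a deterministic geometry whose between-class distance grows
#' with `separation`. `separation` around 1.5 gives the moderate overlap the
#' imbalance treatments are designed for; 6 or more makes classes essentially
#' separable.
#'
#' @param n_features Number of features (default 12).
#' @param separation Mean offset per active dimension, in sd units.
#' @return List with `means` (named list of vectors) and `covs` (named list of
#'   covariance matrices).
#' @export
feature_table_params <- function(n_features = 12, separation = 1.5) {
  cls <- lodging_classes()
  means <- lapply(seq_along(cls), function(c) {
    mu <- numeric(n_features)
    mu[(seq_len(n_features) - 1) %% 4 == (c - 1)] <- separation
    mu
  })
  names(means) <- cls
  covs <- lapply(cls, function(c) diag(n_features))
  names(covs) <- cls
  list(means = means, covs = covs)
}

#' Generate a class-conditional Gaussian feature table
#'
#' Tabular stand-in for a per-plot texture feature table: rows are drawn from
#' a Gaussian per class. Used to exercise selection, resampling and the
#' classifiers under controlled geometry.
#'
#' @param class_counts Named counts over `NL, ML, HL, SL`.
#' @param class_means Named list of per-class mean vectors (equal lengths).
#' @param class_covs Named list of per-class covariance matrices.
#' @param seed Integer seed.
#' @param feature_names Optional feature names; defaults to the texture names
#'   (or `f01..` beyond 14).
#' @return A tibble with `plot_id`, the feature columns, `class` (ordered
#'   factor) and `provenance` (all `"original"`).
#' @examples
#' p <- feature_table_params(4, separation = 3)
#' tab <- generate_feature_table(c(NL = 20, ML = 10, HL = 5, SL = 5),
#'                               p$means, p$covs, seed = 1)
#' @export
generate_feature_table <- function(class_counts, class_means, class_covs, seed,
                                   feature_names = NULL) {
  cls <- lodging_classes()
  class_counts <- class_counts[cls]
  m <- length(class_means[[1]])
  if (!all(vapply(class_means, length, integer(1)) == m) ||
      !all(vapply(class_covs, function(S) all(dim(S) == m), logical(1)))) {
    abort("Mean/covariance dimensions disagree.", class = "soylodge_dim_error")
  }
  if (is.null(feature_names)) {
    feature_names <- if (m <= 14) texture_feature_names()[seq_len(m)]
                     else sprintf("f%02d", seq_len(m))
  }
  with_seed(seed, {
    rows <- lapply(cls, function(cl) {
      n_c <- class_counts[[cl]]
      if (n_c == 0) return(NULL)
      X <- MASS::mvrnorm(n_c, mu = class_means[[cl]], Sigma = class_covs[[cl]])
      X <- matrix(X, nrow = n_c)
      colnames(X) <- feature_names
      df <- as_tibble(as.data.frame(X))
      df$class <- cl
      df
    })
    out <- bind_rows(rows)
    out$class <- as_lodging_factor(out$class)
    out$provenance <- "original"
    out <- bind_cols(tibble(plot_id = sprintf("P%04d", seq_len(nrow(out)))), out)
    out
  })
}
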