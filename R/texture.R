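#' Quantize an 8-bit grayscale image to Ng levels
#'
#' Equal-width binning: level = floor(value * Ng / 256), an integer in
#' `[0, Ng - 1]`.
#'
#' @param image Integer matrix with values 0..255.
#' @param levels Number of grey levels, one of 4, 8, 16, 32, 64.
#' @return Integer matrix of levels.
#' @examples
#' quantize(matrix(c(0L, 128L, 255L), 1), 8)
#' @export
quantize <- function(image, levels = 16) {
  if (!levels %in% c(4, 8, 16, 32, 64)) {
    abort("`levels` must be one of 4, 8, 16, 32, 64.", class = "soylodge_levels_error")
  }
  matrix(as.integer(floor(image * levels / 256)), nrow(image), ncol(image))
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    abort("`angle` must be one of 0, 45, 90, 135 degrees.")
  )
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts ordered level pairs at pixel offset (distance `d`, angle `angle`)
#' where both pixels fall inside `mask`; in symmetric mode the transposed
#' count is added, and with `normalize = TRUE` the matrix is scaled to sum to
#' one.
#'
#' @param quantized Integer matrix of levels in `[0, levels - 1]` (see
#'   [quantize()]).
#' @param levels Number of grey levels.
#' @param mask Optional logical matrix; `NULL` means all pixels valid.
#' @param d Offset distance in pixels (>= 1).
#' @param angle Offset angle in degrees: 0, 45, 90 or 135.
#' @param symmetric Add the transposed counts (default TRUE).
#' @param normalize Scale to a probability matrix (default TRUE).
#' @return An object of class `glcm`: list with `P` (levels x levels matrix),
#'   `levels`, `d`, `angle`, `symmetric`, `normalized`, `n_pairs` (ordered
#'   pair count before normalisation).
#' @examples
#' img <- matrix(c(0L,0L,0L,2L, 0L,0L,2L,2L, 1L,1L,2L,3L, 1L,1L,2L,3L), 4)
#' compute_glcm(img, levels = 4)$P
#' @export
compute_glcm <- function(quantized, levels, mask = NULL, d = 1, angle = 0,
                         symmetric = TRUE, normalize = TRUE) {
  stopifnot(d >= 1)
  off <- glcm_offset(angle, as.integer(d))
  h <- nrow(quantized); w <- ncol(quantized)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  r_from <- max(1L, 1L - off[1]):min(h, h - off[1])
  c_from <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (length(r_from) == 0 || length(c_from) == 0) {
    abort("Offset larger than image.", class = "soylodge_degenerate_glcm")
  }
  a <- quantized[r_from, c_from, drop = FALSE]
  b <- quantized[r_from + off[1], c_from + off[2], drop = FALSE]
  ok <- mask[r_from, c_from, drop = FALSE] &
        mask[r_from + off[1], c_from + off[2], drop = FALSE]
  i <- a[ok]; j <- b[ok]
  counts <- matrix(tabulate(i * levels + j + 1L, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs < 2) {
    abort("Fewer than two valid pixel pairs: degenerate GLCM.",
          class = "soylodge_degenerate_glcm")
  }
  P <- if (normalize) counts / n_pairs else counts
  structure(
    list(P = P, levels = as.integer(levels), d = as.integer(d),
         angle = angle, symmetric = symmetric, normalized = normalize,
         n_pairs = n_pairs),
    class = "glcm"
  )
}

#' Average co-occurrence matrices across directions
#'
#' Element-wise mean of the probability matrices; the usual way to obtain a
#' rotation-tolerant texture description from the four offset angles.
#'
#' @param glcms List of `glcm` objects with equal `levels`.
#' @return A `glcm` object with the averaged matrix.
#' @export
average_glcms <- function(glcms) {
  stopifnot(length(glcms) >= 1)
  lv <- vapply(glcms, function(g) g$levels, integer(1))
  if (length(unique(lv)) != 1) {
    abort("All GLCMs must share the same number of levels.",
          class = "soylodge_levels_error")
  }
  P <- Reduce(`+`, lapply(glcms, function(g) g$P)) / length(glcms)
  structure(
    list(P = P, levels = lv[1], d = glcms[[1]]$d,
         angle = vapply(glcms, function(g) g$angle, numeric(1)),
         symmetric = all(vapply(glcms, function(g) g$symmetric, logical(1))),
         normalized = glcms[[1]]$normalized,
         n_pairs = sum(vapply(glcms, function(g) g$n_pairs, numeric(1)))),
    class = "glcm"
  )
}

# entropy with the 0 log 0 := 0 convention, log base 2
entropy0 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 14 Haralick texture features of a GLCM
#'
#' Computes, from a normalized co-occurrence matrix: angular second moment,
#' contrast, correlation, variance, inverse difference moment, sum average,
#' sum variance, sum entropy, entropy, difference variance, difference
#' entropy, the two information measures of correlation, and the maximal
#' correlation coefficient. Conventions: logarithms are base 2 with
#' 0 log 0 := 0; grey levels are indexed 1..Ng so the sum distribution runs
#' over 2..2Ng; "variance" is the second moment about the grand mean level
#' mu = sum_ij i p(i,j); sum variance is centred on the sum-entropy value (the
#' classical chained definition); difference variance is the statistical
#' variance of the difference distribution; the maximal correlation
#' coefficient is the square root of the second-largest eigenvalue of
#' Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k)), restricted to levels with
#' positive marginal mass.
#'
#' For a constant image (all mass in one cell) the correlation is undefined
#' (zero marginal sd); it is reported as 0 and the result carries a
#' `degenerate` attribute instead of erroring.
#'
#' @param glcm A `glcm` object (normalized).
#' @return A one-row tibble with the 14 features, attribute `degenerate`
#'   (logical).
#' @examples
#' img <- matrix(c(0L,0L,0L,2L, 0L,0L,2L,2L, 1L,1L,2L,3L, 1L,1L,2L,3L), 4)
#' haralick_features(compute_glcm(img, levels = 4))
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  P <- glcm$P
  Ng <- glcm$levels
  if (abs(sum(P) - 1) > 1e-8) {
    abort("GLCM must be normalized before computing features.")
  }
  i <- matrix(seq_len(Ng), Ng, Ng)          # row index
  j <- t(i)                                  # column index
  px <- rowSums(P)
  py <- colSums(P)

  # sum / difference distributions
  s <- i + j                                 # 2 .. 2Ng
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[s == k]), numeric(1))
  dff <- abs(i - j)                          # 0 .. Ng-1
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[dff == k]), numeric(1))

  mux <- sum(seq_len(Ng) * px)
  muy <- sum(seq_len(Ng) * py)
  sdx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))

  asm <- sum(P^2)
  contrast <- sum(k_diff^2 * p_diff)
  degenerate <- (sdx * sdy) < 1e-12
  correlation <- if (degenerate) 0 else (sum(i * j * P) - mux * muy) / (sdx * sdy)
  mu <- sum(i * P)                           # grand mean level
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(k_sum * p_sum)
  sum_entropy <- entropy0(p_sum)
  sum_variance <- sum((k_sum - sum_entropy)^2 * p_sum)
  ent <- entropy0(P)
  mu_diff <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - mu_diff)^2 * p_diff)
  difference_entropy <- entropy0(p_diff)

  HX <- entropy0(px)
  HY <- entropy0(py)
  pxy_outer <- outer(px, py)
  pos <- P > 0 & pxy_outer > 0
  HXY1 <- -sum(P[pos] * log2(pxy_outer[pos]))
  pos2 <- pxy_outer > 0
  HXY2 <- -sum(pxy_outer[pos2] * log2(pxy_outer[pos2]))
  denom <- max(HX, HY)
  info_I <- if (denom < 1e-12) 0 else (ent - HXY1) / denom
  info_II <- sqrt(max(0, 1 - exp(-2 * (HXY2 - ent))))

  mcc <- local({
    nz <- which(px > 0 & py > 0)
    if (length(nz) < 2) return(0)
    Pn <- P[nz, nz, drop = FALSE]
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
    A <- Pn / px[nz]                 # rows scaled by 1/px(i)
    B <- t(t(Pn) / py[nz])           # columns scaled by 1/py(k)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2) return(0)
    sqrt(clamp(ev[2], 0, 1))
  })

  out <- tibble(
    angular_second_moment = asm,
    contrast = contrast,
    correlation = correlation,
    variance = variance,
    inverse_difference_moment = idm,
    sum_average = sum_average,
    sum_variance = sum_variance,
    sum_entropy = sum_entropy,
    entropy = ent,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    info_measure_I = info_I,
    info_measure_II = info_II,
    max_correlation_coefficient = mcc
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Extract the 14 texture features of one plot
#'
#' Quantizes the ROI, builds one co-occurrence matrix per angle over the
#' canopy mask, averages them and computes [haralick_features()].
#'
#' @param roi Grayscale matrix (0..255).
#' @param mask Logical canopy mask, same shape; `NULL` uses all pixels.
#' @param levels Grey levels for quantization (default 16).
#' @param d Offset distance (default 1).
#' @param angles Offset angles in degrees (default `c(0, 45, 90, 135)`).
#' @return One-row tibble of 14 features (see [texture_feature_names()]).
#' @export
extract_plot_features <- function(roi, mask = NULL, levels = 16, d = 1,
                                  angles = c(0, 45, 90, 135)) {
  q <- quantize(roi, levels)
  glcms <- lapply(angles, function(a) {
    compute_glcm(q, levels = levels, mask = mask, d = d, angle = a)
  })
  haralick_features(average_glcms(glcms))
}

#' Segment every plot of a field and extract its texture features
#'
#' The per-plot half of the full analysis: each plot's ROI is cropped from the
#' field image with a soil margin around the recorded bounding box, the canopy
#' is separated from soil by [segment_canopy()], and the 14 GLCM features are
#' computed over the canopy pixels. Plots whose mask comes back empty (or
#' whose co-occurrence matrix is degenerate) are skipped with a message and
#' recorded in the `skipped` attribute.
#'
#' @param field A `lodging_field` from [generate_field()], or a plain matrix
#'   image combined with a `plots` record tibble via the `plots` argument.
#' @param plots Plot records tibble when `field` is a matrix.
#' @param roi_margin Pixels of background margin added around each bounding
#'   box (default 6, half the default inter-plot gap).
#' @param segment Apply Chan-Vese segmentation (default TRUE); when FALSE the
#'   whole ROI is used.
#' @param levels,d,angles GLCM parameters, see [extract_plot_features()].
#' @param segment_args List of extra arguments for [segment_canopy()].
#' @return A feature-table tibble: `plot_id`, 14 feature columns,
#'   `foreground_fraction`, `n_components`, `score`, `class`, `provenance`
#'   (all `"original"`). Attribute `skipped`: character vector of skipped
#'   plot ids.
#' @export
extract_field_features <- function(field, plots = NULL, roi_margin = 6,
                                   segment = TRUE, levels = 16, d = 1,
                                   angles = c(0, 45, 90, 135),
                                   segment_args = list()) {
  if (inherits(field, "lodging_field")) {
    image <- field$image
    plots <- field$plots
  } else {
    image <- field
    if (is.null(plots)) abort("`plots` records required with a raw image.")
  }
  if (length(dim(image)) == 3) image <- to_grayscale(image)
  H <- nrow(image); W <- ncol(image)
  rows <- vector("list", nrow(plots))
  skipped <- character(0)
  for (idx in seq_len(nrow(plots))) {
    p <- plots[idx, ]
    bbox <- c(max(0, p$row0 - roi_margin), max(0, p$col0 - roi_margin),
              min(H, p$row1 + roi_margin), min(W, p$col1 + roi_margin))
    roi <- crop_roi(image, bbox)
    res <- tryCatch({
      mask <- NULL
      fg <- 1; ncomp <- 1L
      if (segment) {
        cm <- withCallingHandlers(
          do.call(segment_canopy, c(list(roi), segment_args)),
          soylodge_degenerate_mask = function(w) invokeRestart("muffleWarning")
        )
        if (cm$degenerate) stop("empty mask")
        mask <- cm$mask
        fg <- cm$foreground_fraction
        ncomp <- cm$n_components
      }
      feats <- extract_plot_features(roi, mask, levels = levels, d = d,
                                     angles = angles)
      bind_cols(tibble(plot_id = p$plot_id), feats,
                tibble(foreground_fraction = fg, n_components = ncomp,
                       score = p$score, class = p$class))
    }, error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, p$plot_id)
      message(sprintf("Skipping plot %s: empty mask or degenerate GLCM.", p$plot_id))
    } else {
      rows[[idx]] <- res
    }
  }
  out <- bind_rows(rows)
  out$provenance <- "original"
  attr(out, "skipped") <- skipped
  out
}
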