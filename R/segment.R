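#' Crop a plot region of interest from a field image
#'
#' @param image Matrix (grayscale) or rows x cols x 3 array.
#' @param bbox `c(row0, col0, row1, col1)`, 0-based half-open pixel
#'   coordinates.
#' @return The exact sub-image, dimensions `(row1 - row0) x (col1 - col0)`.
#' @examples
#' crop_roi(matrix(1:100, 10), c(0, 0, 4, 4))
#' @export
crop_roi <- function(image, bbox) {
  bbox <- as.integer(bbox)
  d <- dim(image)
  if (length(bbox) != 4) abort("`bbox` must be c(row0, col0, row1, col1).")
  r0 <- bbox[1]; c0 <- bbox[2]; r1 <- bbox[3]; c1 <- bbox[4]
  if (r1 <= r0 || c1 <= c0) {
    abort("Empty bounding box.", class = "soylodge_bbox_error")
  }
  if (r0 < 0 || c0 < 0 || r1 > d[1] || c1 > d[2]) {
    abort("Bounding box exceeds the image.", class = "soylodge_bbox_error")
  }
  if (length(d) == 3) {
    image[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  } else {
    image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  }
}

#' Convert a 3-band image to 8-bit grayscale
#'
#' Uses the standard luminance weights 0.2989 R + 0.5870 G + 0.1140 B, rounded
#' half-up to an integer grey level.
#'
#' @param image rows x cols x 3 array of 8-bit values.
#' @return Integer matrix, 0..255.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    abort("`image` must be a rows x cols x 3 array.", class = "soylodge_band_error")
  }
  g <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  matrix(as.integer(round_half_up(g)), d[1], d[2])
}

#' Label 8-connected foreground components
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (!any(mask)) return(labels)
  # 8-neighbour offsets in linear (column-major) indexing need row bounds care
  current <- 0L
  todo <- which(mask)
  visited <- matrix(FALSE, h, w)
  for (start in todo) {
    if (visited[start]) next
    current <- current + 1L
    frontier <- start
    visited[start] <- TRUE
    labels[start] <- current
    while (length(frontier) > 0) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * h + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & !visited[nbr]]
      visited[nbr] <- TRUE
      labels[nbr] <- current
      frontier <- nbr
    }
  }
  labels
}

#' Remove small foreground components from a binary mask
#'
#' Deletes every 8-connected foreground component whose pixel area is below
#' `min_area`; all other components are untouched. Idempotent for a fixed
#' threshold.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in pixels (default 25).
#' @return Logical matrix.
#' @export
remove_small_regions <- function(mask, min_area = 25) {
  labels <- label_components(mask)
  if (max(labels) == 0) return(mask & FALSE)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Segment canopy foreground with a Chan-Vese active contour
#'
#' Region-based (piecewise-constant) Chan-Vese segmentation: starting from a
#' centred rectangular mask, the two region means and the partition are
#' updated alternately until the contour is stationary or the iteration
#' budget is spent. The partition update is a diffuse-and-threshold
#' (threshold-dynamics) step, which realises the energy's length penalty by
#' smoothing the region indicator with a Gaussian of width `mu` before
#' thresholding; `mu = 0` gives the pure piecewise-constant optimum given the
#' means. On a noise-free two-level image the result is the exact two-phase
#' partition. By convention the foreground is the brighter region (canopy
#' over soil); set `bright_foreground = FALSE` to flip. Small foreground
#' specks are removed afterwards with [remove_small_regions()].
#'
#' @param roi Grayscale matrix, at least 16 x 16.
#' @param mu Length-penalty strength: the sd (pixels) of the indicator
#'   diffusion (default 1; larger values smooth the contour more).
#' @param mu_weight Weight of the diffused-boundary term against the squared
#'   data terms, in normalized intensity units (default 0.05).
#' @param iterations Iteration budget (default 200; convergence is typically
#'   reached within ten sweeps).
#' @param init_fraction Side fraction of the centred rectangular initial mask
#'   (default 0.6).
#' @param min_area Minimum surviving component area (default 25).
#' @param bright_foreground Keep the brighter phase as foreground.
#' @return A list of class `canopy_mask`: `mask` (logical matrix),
#'   `foreground_fraction`, `n_components` and `degenerate` (TRUE when the
#'   contour collapsed and the mask is empty, signalled as a warning rather
#'   than an error).
#' @examples
#' img <- matrix(60, 32, 32); img[8:24, 8:24] <- 180
#' m <- segment_canopy(img)
#' m$foreground_fraction
#' @export
segment_canopy <- function(roi, mu = 1, mu_weight = 0.05, iterations = 200,
                           init_fraction = 0.6, min_area = 25,
                           bright_foreground = TRUE) {
  if (nrow(roi) < 16 || ncol(roi) < 16) {
    abort("ROI must be at least 16 x 16.", class = "soylodge_roi_error")
  }
  I <- roi / 255
  h <- nrow(I); w <- ncol(I)
  rh <- max(2L, round(h * init_fraction / 2))
  rw <- max(2L, round(w * init_fraction / 2))
  mask <- matrix(FALSE, h, w)
  mask[max(1, round(h / 2) - rh):min(h, round(h / 2) + rh),
       max(1, round(w / 2) - rw):min(w, round(w / 2) + rw)] <- TRUE

  for (it in seq_len(iterations)) {
    a1 <- sum(mask); a2 <- sum(!mask)
    if (a1 == 0 || a2 == 0) break
    c1 <- mean(I[mask])
    c2 <- mean(I[!mask])
    u <- if (mu > 0) gauss_blur(mask * 1, sigma = mu) else mask * 1
    score <- (I - c1)^2 - (I - c2)^2 - mu_weight * (2 * u - 1)
    new_mask <- score < 0
    if (identical(new_mask, mask)) { mask <- new_mask; break }
    mask <- new_mask
  }
  inside_mean <- if (any(mask)) mean(I[mask]) else -Inf
  outside_mean <- if (any(!mask)) mean(I[!mask]) else Inf
  if (bright_foreground && inside_mean < outside_mean) mask <- !mask
  if (!bright_foreground && inside_mean > outside_mean) mask <- !mask
  if (!any(mask) || all(mask) ||
      abs(inside_mean - outside_mean) < 1e-6) {
    warn("Chan-Vese segmentation degenerate: returning empty foreground.",
         class = "soylodge_degenerate_mask")
    mask <- matrix(FALSE, h, w)
  }
  mask <- remove_small_regions(mask, min_area)
  if (!any(mask)) {
    structure(list(mask = mask, foreground_fraction = 0,
                   n_components = 0L, degenerate = TRUE),
              class = "canopy_mask")
  } else {
    structure(list(mask = mask,
                   foreground_fraction = mean(mask),
                   n_components = max(label_components(mask)),
                   degenerate = FALSE),
              class = "canopy_mask")
  }
}
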