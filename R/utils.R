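#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# deterministic per-item child seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# separable Gaussian blur with edge replication; sigma in pixels
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  out <- apply(mat, 2, pad_conv)
  t(apply(t(out), 2, pad_conv))
}

#' Round half away from zero (half-up for positives), like printed tables do
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# feature columns of a lodging feature table: numeric columns that are not
# bookkeeping (plot_id / score / class / provenance)
feature_columns <- function(data) {
  reserved <- c("plot_id", "score", "class", "provenance", ".row_id")
  keep <- setdiff(names(data), reserved)
  keep[vapply(data[keep], is.numeric, logical(1))]
}

check_features_numeric <- function(X) {
  if (anyNA(X)) abort("Feature matrix contains missing values.", class = "soylodge_na_features")
  invisible(X)
}
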