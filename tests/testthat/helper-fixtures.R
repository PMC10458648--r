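# Shared fixtures, all built in code.

# The classic 4x4 two-bit toy image whose horizontal co-occurrences can be
# enumerated by hand (12 ordered left-right pairs, 24 after symmetrising).
toy_image <- function() {
  matrix(as.integer(c(
    0, 0, 1, 1,
    0, 0, 1, 1,
    0, 2, 2, 2,
    2, 2, 3, 3
  )), 4, 4, byrow = TRUE)
}

# Independent naive oracle for Haralick features: explicit loops over the
# matrix, no shared code with the package implementation.
naive_haralick <- function(P) {
  Ng <- nrow(P)
  asm <- 0; ent <- 0; idm <- 0; mu <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    asm <- asm + P[i, j]^2
    if (P[i, j] > 0) ent <- ent - P[i, j] * log2(P[i, j])
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    mu <- mu + i * P[i, j]
  }
  variance <- 0
  for (i in 1:Ng) for (j in 1:Ng) variance <- variance + (i - mu)^2 * P[i, j]
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
  sdx <- sqrt(sum(((1:Ng) - mux)^2 * px))
  sdy <- sqrt(sum(((1:Ng) - muy)^2 * py))
  corr_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) corr_num <- corr_num + i * j * P[i, j]
  correlation <- (corr_num - mux * muy) / (sdx * sdy)
  contrast <- 0
  for (k in 0:(Ng - 1)) {
    pk <- 0
    for (i in 1:Ng) for (j in 1:Ng) if (abs(i - j) == k) pk <- pk + P[i, j]
    contrast <- contrast + k^2 * pk
  }
  p_sum <- numeric(2 * Ng - 1)
  for (i in 1:Ng) for (j in 1:Ng) p_sum[i + j - 1] <- p_sum[i + j - 1] + P[i, j]
  sum_average <- sum((2:(2 * Ng)) * p_sum)
  sum_entropy <- -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0]))
  sum_variance <- sum(((2:(2 * Ng)) - sum_entropy)^2 * p_sum)
  p_diff <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + P[i, j]
  }
  dmu <- sum((0:(Ng - 1)) * p_diff)
  difference_variance <- sum(((0:(Ng - 1)) - dmu)^2 * p_diff)
  difference_entropy <- -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0]))
  list(angular_second_moment = asm, contrast = contrast,
       correlation = correlation, variance = variance,
       inverse_difference_moment = idm, sum_average = sum_average,
       sum_variance = sum_variance, sum_entropy = sum_entropy,
       entropy = ent, difference_variance = difference_variance,
       difference_entropy = difference_entropy)
}

# a small random quantized image, deterministic
random_quantized <- function(seed, h = 12, w = 12, levels = 8) {
  set.seed(seed)
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}

# Gaussian feature table with the reference imbalance at a given scale
imbalanced_table <- function(n_scale = 1, separation = 1.5, seed = 42,
                             m = 12) {
  p <- feature_table_params(m, separation = separation)
  counts <- round(c(NL = 964, ML = 206, HL = 85, SL = 11) * n_scale)
  counts <- pmax(counts, 4)
  generate_feature_table(counts, p$means, p$covs, seed = seed)
}

# printed per-class metrics of the four reference confusion matrices
printed_table2 <- function() {
  list(
    xgboost = list(p = c(0.93, 0.87, 0.94, 0.99), r = c(0.64, 0.96, 0.94, 0.99),
                   f = c(0.76, 0.91, 0.94, 0.99), oa = 0.94, kappa = 0.91),
    rf      = list(p = c(0.89, 0.87, 0.94, 0.98), r = c(0.60, 0.93, 0.96, 0.99),
                   f = c(0.71, 0.90, 0.95, 0.98), oa = 0.93, kappa = NA),
    knn     = list(p = c(0.92, 0.82, 0.92, 0.97), r = c(0.55, 0.87, 0.94, 1.00),
                   f = c(0.69, 0.84, 0.93, 0.99), oa = 0.91, kappa = 0.87),
    ann     = list(p = c(0.53, 0.99, 0.99, 1.00), r = c(0.92, 0.91, 0.98, 0.99),
                   f = c(0.67, 0.95, 0.98, 0.99), oa = 0.96, kappa = NA)
  )
}

round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
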