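#' Imbalance-treatment plan
#'
#' @param method One of `"smote_tomek"`, `"smote_enn"`, `"borderline_smote"`,
#'   `"smote_nc"`, `"adasyn"`.
#' @param k_smote Neighbour count for synthetic interpolation (default 5).
#' @param k_edit Neighbour count for ENN editing (default 3).
#' @param seed Integer seed.
#' @param nominal Character vector of nominal feature columns (SMOTE-NC only).
#' @return A list of class `resample_plan`.
#' @export
resample_plan <- function(method = c("smote_tomek", "smote_enn",
                                     "borderline_smote", "smote_nc", "adasyn"),
                          k_smote = 5, k_edit = 3, seed = 1L,
                          nominal = character(0)) {
  method <- match.arg(method)
  if (k_smote < 1 || k_edit < 1) abort("Neighbour counts must be >= 1.")
  structure(list(method = method, k_smote = k_smote, k_edit = k_edit,
                 seed = as.integer(seed), nominal = nominal),
            class = "resample_plan")
}

#' The five supported imbalance treatments
#' @return Character vector of method names accepted by [resample_plan()].
#' @export
resample_methods <- function() {
  c("smote_tomek", "smote_enn", "borderline_smote", "smote_nc", "adasyn")
}

# pairwise Euclidean distances between rows of A and rows of B
row_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# indices (into rows of B) of the k nearest neighbours of each row of A;
# self-exclusion by passing exclude_self = TRUE when A and B are identical.
# Ties are broken by lowest index (stable order).
knn_index <- function(A, B, k, exclude_self = FALSE) {
  D <- row_dist(A, B)
  if (exclude_self) diag(D) <- Inf
  res <- apply(D, 1, function(d) order(d)[seq_len(k)])
  # apply() drops to a vector when k = 1
  t(matrix(res, nrow = k))
}

#' Generate synthetic minority samples (SMOTE)
#'
#' Each synthetic row is `x + lambda * (y - x)` where `x` is a minority-class
#' row, `y` one of its `k` nearest minority neighbours (Euclidean) and
#' `lambda ~ U[0, 1]`: points uniformly on segments between adjacent minority
#' samples. `k` is capped at the class size minus one.
#'
#' @param data Feature-table tibble with a `class` column.
#' @param minority_class Class label to oversample.
#' @param n_new Number of synthetic rows (0 returns `data` unchanged).
#' @param k Neighbour count (default 5).
#' @param seed Integer seed.
#' @return `data` with `n_new` appended rows, their `provenance` set to
#'   `"synthetic"`.
#' @export
smote <- function(data, minority_class, n_new, k = 5, seed = 1L) {
  if (n_new == 0) return(data)
  feats <- feature_columns(data)
  idx <- which(data$class == minority_class)
  if (length(idx) < 2) {
    abort(sprintf("Class %s has fewer than 2 samples; cannot interpolate.",
                  minority_class),
          class = "soylodge_singleton_class")
  }
  X <- as.matrix(data[idx, feats])
  check_features_numeric(X)
  k <- min(k, nrow(X) - 1)
  nn <- knn_index(X, X, k, exclude_self = TRUE)
  with_seed(seed, {
    base <- sample.int(nrow(X), n_new, replace = TRUE)
    pick <- vapply(base, function(b) nn[b, sample.int(k, 1)], integer(1))
    lambda <- runif(n_new)
    synth <- X[base, , drop = FALSE] +
      lambda * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
    new_rows <- as_tibble(as.data.frame(synth))
    names(new_rows) <- feats
    new_rows$class <- factor(minority_class, levels = levels(data$class),
                             ordered = is.ordered(data$class))
    new_rows$provenance <- "synthetic"
    if ("plot_id" %in% names(data)) {
      new_rows$plot_id <- sprintf("S_%s_%04d", minority_class, seq_len(n_new))
    }
    bind_rows(data, new_rows)
  })
}

#' Find Tomek links
#'
#' A Tomek link is a pair of opposite-class points that are each other's
#' nearest neighbour. Distance ties are broken toward the lowest row index, so
#' duplicated points yield a single reported link.
#'
#' @param data Feature-table tibble with a `class` column (>= 2 classes).
#' @return Tibble with columns `a`, `b` (row indices, `a < b`) and the two
#'   class labels.
#' @export
tomek_links <- function(data) {
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats])
  check_features_numeric(X)
  y <- as.character(data$class)
  if (length(unique(y)) < 2) return(tibble(a = integer(0), b = integer(0)))
  D <- row_dist(X, X)
  diag(D) <- Inf
  nn1 <- apply(D, 1, which.min)   # lowest index on ties
  links <- list()
  for (a in seq_len(nrow(X))) {
    b <- nn1[a]
    if (b > a && nn1[b] == a && y[a] != y[b]) {
      links[[length(links) + 1]] <- tibble(a = a, b = b,
                                           class_a = y[a], class_b = y[b])
    }
  }
  if (length(links) == 0) {
    tibble(a = integer(0), b = integer(0),
           class_a = character(0), class_b = character(0))
  } else {
    bind_rows(links)
  }
}

#' Edited nearest-neighbour marking
#'
#' Marks every sample whose class disagrees with the majority vote of its `k`
#' nearest neighbours (itself excluded). Vote ties keep the sample: only a
#' clear disagreement marks it.
#'
#' @param data Feature-table tibble with a `class` column, `nrow > k`.
#' @param k Neighbour count (default 3).
#' @return Integer vector of row indices marked for removal.
#' @export
enn_edit <- function(data, k = 3) {
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats])
  check_features_numeric(X)
  y <- as.character(data$class)
  stopifnot(nrow(X) > k)
  nn <- knn_index(X, X, k, exclude_self = TRUE)
  marked <- vapply(seq_len(nrow(X)), function(r) {
    votes <- table(y[nn[r, ]])
    top <- names(votes)[votes == max(votes)]
    # tie (several top classes) keeps the sample
    length(top) == 1 && top != y[r]
  }, logical(1))
  which(marked)
}

# SMOTE every non-majority class up to the majority count; shared by the
# composite treatments. `danger_only` restricts seeds to borderline points,
# `adaptive` allocates per-point budgets ADASYN-style.
oversample_equalize <- function(data, k, seed, danger_only = FALSE,
                                adaptive = FALSE) {
  counts <- table(data$class)
  target <- max(counts)
  out <- data
  step <- 0L
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need <= 0 || counts[[cl]] == 0) next   # cannot synthesize absent classes
    step <- step + 1L
    sub_seed <- derive_seed(seed, step)
    if (!danger_only && !adaptive) {
      out <- smote(out, cl, need, k = k, seed = sub_seed)
    } else if (danger_only) {
      out <- borderline_smote_class(out, cl, need, k = k, seed = sub_seed)
    } else {
      out <- adasyn_class(out, cl, need, k = k, seed = sub_seed)
    }
  }
  out
}

# Borderline-SMOTE (variant 1) for one minority class: synthetic seeds are the
# "danger" points -- at least half, but not all, of their k neighbours (over
# all classes) belong to other classes. Falls back to plain SMOTE when no
# danger points exist.
borderline_smote_class <- function(data, minority_class, n_new, k = 5, seed = 1L) {
  if (n_new == 0) return(data)
  feats <- feature_columns(data)
  X_all <- as.matrix(data[, feats])
  idx_min <- which(data$class == minority_class)
  if (length(idx_min) < 2) {
    abort(sprintf("Class %s has fewer than 2 samples.", minority_class),
          class = "soylodge_singleton_class")
  }
  kk <- min(k, nrow(X_all) - 1)
  nn_all <- knn_index(X_all[idx_min, , drop = FALSE], X_all, kk)
  # drop self-matches (a minority point is its own 0-distance neighbour)
  other <- vapply(seq_along(idx_min), function(r) {
    nbr <- setdiff(nn_all[r, ], idx_min[r])[seq_len(kk - 1)]
    sum(data$class[nbr] != minority_class, na.rm = TRUE) / (kk - 1)
  }, numeric(1))
  danger <- idx_min[other >= 0.5 & other < 1]
  if (length(danger) < 2) danger <- idx_min
  X_min <- X_all[idx_min, , drop = FALSE]
  X_dan <- X_all[danger, , drop = FALSE]
  k_in <- min(k, nrow(X_min) - 1)
  nn_min <- knn_index(X_dan, X_min, k_in + 1)
  with_seed(seed, {
    base <- sample.int(nrow(X_dan), n_new, replace = TRUE)
    synth <- matrix(0, n_new, ncol(X_min))
    for (s in seq_len(n_new)) {
      b <- base[s]
      nbrs <- nn_min[b, ]
      nbrs <- nbrs[idx_min[nbrs] != danger[b]][seq_len(k_in)]
      y_i <- nbrs[sample.int(k_in, 1)]
      lam <- runif(1)
      synth[s, ] <- X_dan[b, ] + lam * (X_min[y_i, ] - X_dan[b, ])
    }
    append_synthetic(data, synth, feats, minority_class)
  })
}

# ADASYN for one minority class: per-point budgets proportional to the share
# of other-class points among its k neighbours; interpolation toward minority
# neighbours. Falls back to uniform budgets when no point has other-class
# neighbours.
adasyn_class <- function(data, minority_class, n_new, k = 5, seed = 1L) {
  if (n_new == 0) return(data)
  feats <- feature_columns(data)
  X_all <- as.matrix(data[, feats])
  idx_min <- which(data$class == minority_class)
  if (length(idx_min) < 2) {
    abort(sprintf("Class %s has fewer than 2 samples.", minority_class),
          class = "soylodge_singleton_class")
  }
  kk <- min(k, nrow(X_all) - 1)
  nn_all <- knn_index(X_all[idx_min, , drop = FALSE], X_all, kk + 1)
  r <- vapply(seq_along(idx_min), function(ri) {
    nbr <- setdiff(nn_all[ri, ], idx_min[ri])[seq_len(kk)]
    mean(data$class[nbr] != minority_class)
  }, numeric(1))
  w <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  # classical adaptive allocation: per-point rounding, so the total only
  # approximately matches the requested budget
  budget <- as.integer(round(w * n_new))
  n_new <- sum(budget)
  if (n_new == 0) return(data)
  X_min <- X_all[idx_min, , drop = FALSE]
  k_in <- min(k, nrow(X_min) - 1)
  nn_min <- knn_index(X_min, X_min, k_in, exclude_self = TRUE)
  with_seed(seed, {
    synth <- matrix(0, n_new, ncol(X_min))
    s <- 0L
    for (ri in seq_along(idx_min)) {
      if (budget[ri] == 0) next
      for (b in seq_len(budget[ri])) {
        s <- s + 1L
        y_i <- nn_min[ri, sample.int(k_in, 1)]
        lam <- runif(1)
        synth[s, ] <- X_min[ri, ] + lam * (X_min[y_i, ] - X_min[ri, ])
      }
    }
    append_synthetic(data, synth, feats, minority_class)
  })
}

append_synthetic <- function(data, synth, feats, minority_class) {
  new_rows <- as_tibble(as.data.frame(synth))
  names(new_rows) <- feats
  new_rows$class <- factor(minority_class, levels = levels(data$class),
                           ordered = is.ordered(data$class))
  new_rows$provenance <- "synthetic"
  if ("plot_id" %in% names(data)) {
    new_rows$plot_id <- sprintf("S_%s_%04d", minority_class, seq_len(nrow(synth)))
  }
  bind_rows(data, new_rows)
}

#' Apply an imbalance treatment to a feature table
#'
#' The five composite treatments:
#' \describe{
#'   \item{smote_tomek}{SMOTE every class up to the majority count, then drop
#'     the majority-class members of all Tomek links.}
#'   \item{smote_enn}{SMOTE to equal counts, then remove (from every class)
#'     each sample misclassified by the majority vote of its `k_edit`
#'     neighbours. Output counts are generally unequal and the original
#'     majority often ends up smallest.}
#'   \item{borderline_smote}{SMOTE restricted to "danger" minority seeds near
#'     the class boundary, to equal counts.}
#'   \item{smote_nc}{SMOTE-NC: the nominal columns in `plan$nominal` enter the
#'     distance as a constant penalty (the median of the continuous columns'
#'     standard deviations) per disagreeing nominal value, and synthetic rows
#'     take the modal nominal value among the neighbours. With no nominal
#'     columns this is exactly plain SMOTE equalization.}
#'   \item{adasyn}{Adaptive budgets: each minority point receives synthetic
#'     samples in proportion to how many of its neighbours belong to other
#'     classes; totals approximately (not exactly) equalize the classes.}
#' }
#' Resampling belongs on the training partition only; the `provenance` column
#' distinguishes real from synthetic rows downstream.
#'
#' @param data Feature-table tibble with a `class` column.
#' @param plan A [resample_plan()].
#' @return Resampled tibble with a `provenance` column.
#' @export
apply_resample <- function(data, plan) {
  stopifnot(inherits(plan, "resample_plan"))
  if (!"provenance" %in% names(data)) data$provenance <- "original"
  out <- switch(plan$method,
    smote_tomek = {
      over <- oversample_equalize(data, plan$k_smote, plan$seed)
      links <- tomek_links(over)
      counts <- table(over$class)
      majority <- names(counts)[which.max(counts)]
      drop <- unique(c(links$a[links$class_a == majority],
                       links$b[links$class_b == majority]))
      if (length(drop) > 0) over[-drop, ] else over
    },
    smote_enn = {
      over <- oversample_equalize(data, plan$k_smote, plan$seed)
      drop <- enn_edit(over, k = plan$k_edit)
      if (length(drop) > 0) over[-drop, ] else over
    },
    borderline_smote = oversample_equalize(data, plan$k_smote, plan$seed,
                                           danger_only = TRUE),
    smote_nc = smote_nc_equalize(data, plan),
    adasyn = oversample_equalize(data, plan$k_smote, plan$seed,
                                 adaptive = TRUE),
    abort(sprintf("Unknown resampling method '%s'.", plan$method))
  )
  out
}

# SMOTE-NC equalization. With zero nominal columns this calls the exact plain
# SMOTE path (same RNG stream), as the method reduces to SMOTE.
smote_nc_equalize <- function(data, plan) {
  if (length(plan$nominal) == 0) {
    return(oversample_equalize(data, plan$k_smote, plan$seed))
  }
  counts <- table(data$class)
  target <- max(counts)
  cont <- setdiff(feature_columns(data), plan$nominal)
  penalty <- stats::median(vapply(data[cont], sd, numeric(1)))
  out <- data
  step <- 0L
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need <= 0 || counts[[cl]] == 0) next
    step <- step + 1L
    out <- smote_nc_class(out, cl, need, k = plan$k_smote,
                          seed = derive_seed(plan$seed, step),
                          nominal = plan$nominal, penalty = penalty,
                          cont = cont)
  }
  out
}

smote_nc_class <- function(data, minority_class, n_new, k, seed,
                           nominal, penalty, cont) {
  idx <- which(data$class == minority_class)
  if (length(idx) < 2) {
    abort(sprintf("Class %s has fewer than 2 samples.", minority_class),
          class = "soylodge_singleton_class")
  }
  Xc <- as.matrix(data[idx, cont])
  Xn <- as.matrix(data[idx, nominal, drop = FALSE])
  k <- min(k, length(idx) - 1)
  # distance: Euclidean on continuous + penalty^2 per disagreeing nominal
  D2 <- row_dist(Xc, Xc)^2
  for (jn in seq_along(nominal)) {
    D2 <- D2 + penalty^2 * outer(Xn[, jn], Xn[, jn], "!=")
  }
  D <- sqrt(D2); diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  with_seed(seed, {
    base <- sample.int(length(idx), n_new, replace = TRUE)
    pick <- vapply(base, function(b) nn[b, sample.int(k, 1)], integer(1))
    lambda <- runif(n_new)
    synth_c <- Xc[base, , drop = FALSE] +
      lambda * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    # nominal columns: mode among the base point's neighbours
    synth_n <- matrix(0, n_new, length(nominal))
    for (s in seq_len(n_new)) {
      for (jn in seq_along(nominal)) {
        vals <- Xn[nn[base[s], ], jn]
        tab <- table(vals)
        synth_n[s, jn] <- as.numeric(names(tab)[which.max(tab)])
      }
    }
    synth <- cbind(synth_c, synth_n)
    colnames(synth) <- c(cont, nominal)
    synth <- synth[, feature_columns(data), drop = FALSE]
    append_synthetic(data, synth, feature_columns(data), minority_class)
  })
}
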