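#' Stratified train/test split
#'
#' Splits a feature table into training and testing partitions, stratified by
#' `class`: per class, `round(prop * n_c)` rows go to training, so the realised
#' proportions are within one sample per class of the target. Deterministic
#' under `seed`.
#'
#' @param data Feature-table tibble with a `class` column.
#' @param prop Training fraction (default 0.8).
#' @param stratified Stratify by class (default TRUE).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles (disjoint, exhaustive); both
#'   carry a `.row_id` column indexing rows of `data`.
#' @export
split_train_test <- function(data, prop = 0.8, stratified = TRUE, seed = 1L) {
  stopifnot(prop > 0, prop < 1)
  data$.row_id <- seq_len(nrow(data))
  with_seed(seed, {
    if (stratified) {
      counts <- table(data$class)
      if (any(counts < 2)) {
        abort("Every class needs at least 2 samples for a stratified split.",
              class = "soylodge_split_error")
      }
      train_idx <- unlist(lapply(names(counts), function(cl) {
        rows <- which(data$class == cl)
        n_tr <- round(prop * length(rows))
        n_tr <- min(max(n_tr, 1), length(rows) - 1)
        sample(rows, n_tr)
      }))
    } else {
      train_idx <- sample(nrow(data), round(prop * nrow(data)))
    }
    list(train = data[sort(train_idx), ],
         test = data[setdiff(seq_len(nrow(data)), train_idx), ])
  })
}

#' The four supported classifier families
#' @return Character vector of model type names accepted by [fit_lodging()].
#' @export
model_types <- function() c("xgboost", "random_forest", "knn", "ann")

default_hyperparams <- function(model_type) {
  switch(model_type,
    xgboost = list(nrounds = 100, eta = 0.3, max_depth = 6, subsample = 1,
                   colsample_bytree = 1, min_child_weight = 1),
    random_forest = list(ntree = 500, mtry = NULL, nodesize = 1,
                         maxnodes = NULL, sampsize_frac = 1, replace = TRUE),
    knn = list(n_neighbors = 3),
    ann = list(size = 8, maxit = 300, decay = 1e-4),
    abort(sprintf("Unknown model type '%s'.", model_type))
  )
}

#' Fit a lodging classifier
#'
#' One contract over the four model families: extreme gradient boosting
#' (xgboost backend), random forest (randomForest backend), brute-force
#' k-nearest neighbours (implemented here: Euclidean distances, majority vote,
#' distance ties broken toward the lowest training index) and a
#' single-hidden-layer neural network with softmax output (nnet backend).
#' Features are standardized with training-set mean/sd for the distance and
#' gradient models (knn, ann); tree models consume raw features.
#'
#' @param data Training tibble with a `class` column; all feature columns
#'   numeric, no missing values.
#' @param model_type One of `"xgboost"`, `"random_forest"`, `"knn"`, `"ann"`.
#' @param hyperparams Named list; missing entries filled with defaults (see
#'   [tune_lodging()]).
#' @param seed Integer seed (fits are deterministic given it).
#' @return An object of class `lodging_model` supporting
#'   `predict(type = "class")` and `predict(type = "prob")`.
#' @export
fit_lodging <- function(data, model_type = model_types(), hyperparams = NULL,
                        seed = 1L) {
  model_type <- match.arg(model_type)
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats])
  check_features_numeric(X)
  y <- as_lodging_factor(data$class)
  classes <- levels(y)
  hp <- utils::modifyList(default_hyperparams(model_type), hyperparams %||% list())

  center <- scale_ <- NULL
  if (model_type %in% c("knn", "ann")) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ < 1e-12] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }

  if (length(unique(as.character(y))) < 2) {
    # degenerate training set: every prediction is the one observed class
    return(structure(
      list(model_type = model_type, hyperparams = hp,
           fit = list(constant = as.character(y[1])),
           classes = classes, features = feats,
           center = center, scale = scale_, seed = as.integer(seed)),
      class = "lodging_model"
    ))
  }

  fit <- with_seed(seed, switch(model_type,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      eta = hp$eta, max_depth = hp$max_depth,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      min_child_weight = hp$min_child_weight,
                      nthread = 1, seed = as.integer(seed)),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    },
    random_forest = {
      args <- list(x = X, y = droplevels(factor(as.character(y), levels = classes)),
                   ntree = hp$ntree, nodesize = hp$nodesize,
                   replace = hp$replace)
      if (!is.null(hp$mtry)) args$mtry <- min(hp$mtry, ncol(X))
      if (!is.null(hp$maxnodes)) args$maxnodes <- hp$maxnodes
      if (!is.null(hp$sampsize_frac) && hp$sampsize_frac < 1) {
        args$sampsize <- max(2, floor(hp$sampsize_frac * nrow(X)))
      }
      do.call(randomForest::randomForest, args)
    },
    knn = list(X = X, y = y, k = hp$n_neighbors),
    ann = nnet::nnet(x = X,
                     y = stats::model.matrix(~ y - 1),
                     size = hp$size, maxit = hp$maxit, decay = hp$decay,
                     softmax = TRUE, trace = FALSE,
                     MaxNWts = 10000)
  ))

  structure(
    list(model_type = model_type, hyperparams = hp, fit = fit,
         classes = classes, features = feats,
         center = center, scale = scale_, seed = as.integer(seed)),
    class = "lodging_model"
  )
}

# reorder a probability matrix to the full class set, zero-filling classes
# absent from training
expand_prob <- function(p, classes) {
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  keep <- intersect(colnames(p), classes)
  out[, keep] <- p[, keep, drop = FALSE]
  out
}

# brute-force KNN vote probabilities; ties in distance resolved by lowest
# training index (stable order); the predicted label is the argmax of the
# vote fractions, first class on exact vote ties
knn_predict_prob <- function(fit, X, classes) {
  P <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
  D <- row_dist(X, fit$X)
  k <- min(fit$k, ncol(D))
  for (r in seq_len(nrow(X))) {
    nbr <- order(D[r, ])[seq_len(k)]
    votes <- table(factor(as.character(fit$y[nbr]), levels = classes))
    P[r, ] <- as.numeric(votes) / k
  }
  P
}

#' Predict classes or class probabilities
#'
#' @param object A `lodging_model`.
#' @param new_data Tibble or data frame with the training feature columns.
#' @param type `"class"` (default) for labels, `"prob"` for an
#'   n x 4 probability matrix whose columns follow `object$classes`; labels
#'   are always the argmax of the probabilities (first class wins exact ties).
#' @param ... Unused.
#' @return Factor of labels, or a probability matrix with rows summing to 1.
#' @export
predict.lodging_model <- function(object, new_data, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(new_data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing feature column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "soylodge_dim_error")
  }
  X <- as.matrix(new_data[, object$features])
  check_features_numeric(X)
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  if (!is.null(object$fit$constant)) {
    P <- matrix(0, nrow(X), length(object$classes),
                dimnames = list(NULL, object$classes))
    P[, object$fit$constant] <- 1
    if (type == "prob") return(P)
    return(factor(rep(object$fit$constant, nrow(X)),
                  levels = object$classes, ordered = TRUE))
  }
  P <- switch(object$model_type,
    xgboost = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(p)) {
        p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
      }
      dimnames(p) <- list(NULL, object$classes)
      p / rowSums(p)   # exact renormalization of float32 softmax output
    },
    random_forest = {
      p <- predict(object$fit, X, type = "prob")
      expand_prob(p, object$classes)
    },
    knn = knn_predict_prob(object$fit, X, object$classes),
    ann = {
      p <- predict(object$fit, X)
      colnames(p) <- sub("^y", "", colnames(p))
      p <- expand_prob(p, object$classes)
      p / rowSums(p)
    }
  )
  if (type == "prob") return(P)
  idx <- max.col(P, ties.method = "first")
  factor(object$classes[idx], levels = object$classes, ordered = TRUE)
}

#' @export
print.lodging_model <- function(x, ...) {
  cat(sprintf("<lodging_model: %s>\n", x$model_type))
  cat("classes:", paste(x$classes, collapse = " < "), "\n")
  cat("features:", length(x$features), "\n")
  hp <- x$hyperparams[!vapply(x$hyperparams, is.null, logical(1))]
  cat("hyperparams:",
      paste(sprintf("%s=%s", names(hp), unlist(hp)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.lodging_model <- function(x, ...) {
  hp <- x$hyperparams[!vapply(x$hyperparams, is.null, logical(1))]
  tibble(parameter = names(hp),
         value = vapply(hp, function(v) as.character(v), character(1)))
}

#' @export
glance.lodging_model <- function(x, ...) {
  tibble(model_type = x$model_type,
         n_features = length(x$features),
         n_classes = length(x$classes),
         seed = x$seed)
}

# stratified fold assignment: returns integer fold id per row
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(as.character(y))) {
      rows <- which(as.character(y) == cl)
      rows <- sample(rows)
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
    fold
  })
}

# mean k-fold CV accuracy of a model spec on `data`
cv_accuracy <- function(data, model_type, hyperparams, folds = 5, seed = 1L) {
  fold <- stratified_folds(data$class, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- data[fold != f, ]
    te <- data[fold == f, ]
    if (nrow(te) == 0 || length(unique(tr$class)) < 2) return(NA_real_)
    m <- fit_lodging(tr, model_type, hyperparams, seed = derive_seed(seed, f))
    mean(predict(m, te) == te$class)
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

# ---- Tree-structured Parzen estimator over a box of hyperparameters -------

tpe_space_xgboost <- function() {
  list(
    nrounds          = list(type = "int",    lo = 50,   hi = 300),
    eta              = list(type = "log",    lo = 0.01, hi = 0.5),
    max_depth        = list(type = "int",    lo = 2,    hi = 10),
    subsample        = list(type = "unif",   lo = 0.5,  hi = 1),
    colsample_bytree = list(type = "unif",   lo = 0.5,  hi = 1),
    min_child_weight = list(type = "int",    lo = 1,    hi = 10)
  )
}

sample_space <- function(space) {
  lapply(space, function(sp) {
    switch(sp$type,
      int = sample(seq(sp$lo, sp$hi), 1),
      unif = runif(1, sp$lo, sp$hi),
      log = exp(runif(1, log(sp$lo), log(sp$hi)))
    )
  })
}

# 1-d Parzen density of value v over observations obs within [lo, hi]
parzen_density <- function(v, obs, sp) {
  tr <- function(x) if (sp$type == "log") log(x) else x
  o <- tr(unlist(obs)); x <- tr(v)
  bw <- max((tr(sp$hi) - tr(sp$lo)) / 10, diff(range(o)) / max(length(o), 2), 1e-6)
  mean(dnorm(x, mean = o, sd = bw))
}

# Sequential model-based search: after `n_init` random draws, candidates are
# sampled from a Parzen mixture over the best observations and ranked by the
# good/bad density ratio.
tpe_search <- function(space, objective, budget, seed, n_init = 5,
                       gamma = 0.25, n_candidates = 20) {
  history <- list()
  scores <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(budget)) {
      if (t <= n_init || length(scores) < 4) {
        cand <- sample_space(space)
      } else {
        ord <- order(scores, decreasing = TRUE)
        n_good <- max(2, ceiling(gamma * length(scores)))
        good <- history[ord[seq_len(n_good)]]
        bad <- history[ord[-seq_len(n_good)]]
        cands <- replicate(n_candidates, {
          g <- good[[sample.int(length(good), 1)]]
          lapply(names(space), function(nm) {
            sp <- space[[nm]]
            tr <- function(x) if (sp$type == "log") log(x) else x
            un <- function(x) if (sp$type == "log") exp(x) else x
            bw <- (tr(sp$hi) - tr(sp$lo)) / 10
            v <- un(rnorm(1, tr(g[[nm]]), bw))
            v <- clamp(v, sp$lo, sp$hi)
            if (sp$type == "int") v <- as.integer(round(v))
            v
          }) |> stats::setNames(names(space))
        }, simplify = FALSE)
        ratio <- vapply(cands, function(cd) {
          lg <- sum(vapply(names(space), function(nm) {
            log(parzen_density(cd[[nm]], lapply(good, `[[`, nm), space[[nm]]) + 1e-12)
          }, numeric(1)))
          lb <- sum(vapply(names(space), function(nm) {
            log(parzen_density(cd[[nm]], lapply(bad, `[[`, nm), space[[nm]]) + 1e-12)
          }, numeric(1)))
          lg - lb
        }, numeric(1))
        cand <- cands[[which.max(ratio)]]
      }
      sc <- objective(cand)
      history[[t]] <- cand
      scores[t] <- sc
    }
  })
  best <- which.max(scores)
  list(best = history[[best]], score = scores[best],
       history = history, scores = scores)
}

#' Tune hyperparameters for a lodging classifier
#'
#' Tuning protocol per family: xgboost uses a tree-structured Parzen estimator
#' (TPE) over number of rounds, learning rate, depth, subsampling, column
#' subsampling and minimum child weight, maximizing mean 5-fold CV accuracy;
#' random forest uses a grid search over six parameters (trees, depth via
#' maxnodes, mtry, nodesize, sample fraction, bootstrap replacement) with
#' 5-fold CV; knn is fixed at 3 neighbours (no search); ann searches hidden
#' layer width and iteration cap.
#'
#' @param data Training tibble with a `class` column.
#' @param model_type One of the four family names.
#' @param budget Evaluation budget for the TPE search (default 15); must be
#'   >= 1.
#' @param folds CV folds used for scoring (default 5).
#' @param seed Integer seed.
#' @return Named list of hyperparameters (with attribute `cv_accuracy`, the
#'   best mean CV accuracy seen; NULL for knn, which is fixed by protocol).
#' @export
tune_lodging <- function(data, model_type = model_types(), budget = 15,
                         folds = 5, seed = 1L) {
  model_type <- match.arg(model_type)
  if (budget < 1) abort("`budget` must be >= 1.")
  if (model_type == "knn") {
    return(list(n_neighbors = 3))
  }
  score_fn <- function(hp) cv_accuracy(data, model_type, hp, folds, seed)
  if (model_type == "xgboost") {
    res <- tpe_search(tpe_space_xgboost(), score_fn, budget, seed)
    out <- res$best
    attr(out, "cv_accuracy") <- res$score
    return(out)
  }
  grid <- if (model_type == "random_forest") {
    expand.grid(ntree = c(200, 500), mtry = c(2, 4),
                nodesize = c(1, 5), maxnodes = c(NA, 32),
                sampsize_frac = c(0.8, 1), replace = c(TRUE, FALSE))
  } else {
    expand.grid(size = c(4, 8, 16), maxit = c(100, 300),
                decay = c(1e-4))
  }
  grid <- grid[seq_len(min(nrow(grid), max(budget, 1))), , drop = FALSE]
  scores <- vapply(seq_len(nrow(grid)), function(gi) {
    hp <- as.list(grid[gi, , drop = FALSE])
    hp <- lapply(hp, function(v) if (is.factor(v)) as.character(v) else v)
    if (!is.null(hp$maxnodes) && is.na(hp$maxnodes)) hp$maxnodes <- NULL
    score_fn(hp)
  }, numeric(1))
  best <- as.list(grid[which.max(scores), , drop = FALSE])
  best <- lapply(best, function(v) if (is.factor(v)) as.character(v) else v)
  if (!is.null(best$maxnodes) && is.na(best$maxnodes)) best$maxnodes <- NULL
  attr(best, "cv_accuracy") <- max(scores)
  best
}
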