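#' Recursive feature elimination with random-forest importance
#'
#' Starting from all features, repeatedly: score the current feature set by
#' stratified k-fold cross-validated random-forest accuracy, then drop the
#' feature with the lowest random-forest importance (mean decrease in Gini,
#' from a fit on all rows), until one feature remains. The selected subset is
#' the smallest one attaining the maximum of the score curve (ties broken
#' toward fewer features). Fold assignment is fixed once per call, so scores
#' at different subset sizes are comparable. Deterministic under `seed`.
#'
#' @param data Feature-table tibble with a `class` column and >= 2 numeric
#'   feature columns.
#' @param cv_folds Cross-validation folds (default 10).
#' @param ntree Trees per random forest (default 500).
#' @param seed Integer seed.
#' @return An object of class `rfe_result`: `elimination_order` (features
#'   worst-first), `score_curve` (tibble `n_features`, `cv_accuracy`,
#'   `features` list-column), `chosen_features`, `best_score`.
#' @examples
#' p <- feature_table_params(4, separation = 4)
#' tab <- generate_feature_table(c(NL = 30, ML = 20, HL = 15, SL = 15),
#'                               p$means, p$covs, seed = 1)
#' sel <- rf_rfe(tab, cv_folds = 5, ntree = 100, seed = 1)
#' sel$chosen_features
#' @export
rf_rfe <- function(data, cv_folds = 10, ntree = 500, seed = 1L) {
  feats <- feature_columns(data)
  if (length(feats) < 1) abort("No feature columns found.")
  y <- as_lodging_factor(data$class)
  if (length(unique(as.character(y))) < 2) {
    abort("Constant labels: feature selection is undefined.",
          class = "soylodge_constant_labels")
  }
  if (nrow(data) < cv_folds) abort("Need at least `cv_folds` rows.")
  fold <- stratified_folds(y, cv_folds, seed)
  yf <- droplevels(factor(as.character(y), levels = lodging_classes()))

  current <- feats
  elimination <- character(0)
  curve <- list()
  step <- 0L
  while (length(current) >= 1) {
    step <- step + 1L
    X <- as.matrix(data[, current, drop = FALSE])
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      if (!any(!tr)) return(NA_real_)
      m <- with_seed(derive_seed(seed, step * 100 + f),
        randomForest::randomForest(X[tr, , drop = FALSE], yf[tr], ntree = ntree))
      mean(as.character(predict(m, X[!tr, , drop = FALSE])) ==
             as.character(yf[!tr]))
    }, numeric(1))
    curve[[step]] <- tibble(n_features = length(current),
                            cv_accuracy = mean(acc, na.rm = TRUE),
                            features = list(current))
    if (length(current) == 1) break
    full <- with_seed(derive_seed(seed, step),
      randomForest::randomForest(X, yf, ntree = ntree, importance = FALSE))
    imp <- randomForest::importance(full)[, "MeanDecreaseGini"]
    worst <- names(imp)[which.min(imp)]
    elimination <- c(elimination, worst)
    current <- setdiff(current, worst)
  }
  score_curve <- bind_rows(curve)
  best_score <- max(score_curve$cv_accuracy)
  cands <- score_curve[score_curve$cv_accuracy >= best_score - 1e-12, ]
  chosen <- cands$features[[which.min(cands$n_features)]]
  structure(
    list(elimination_order = elimination,
         score_curve = score_curve[, c("n_features", "cv_accuracy", "features")],
         chosen_features = chosen,
         best_score = best_score,
         cv_folds = cv_folds, ntree = ntree, seed = as.integer(seed)),
    class = "rfe_result"
  )
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result: %d of %d features, best CV accuracy %.3f>\n",
              length(x$chosen_features),
              max(x$score_curve$n_features), x$best_score))
  cat("chosen:", paste(x$chosen_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.rfe_result <- function(x, ...) {
  x$score_curve[, c("n_features", "cv_accuracy")]
}

#' @export
glance.rfe_result <- function(x, ...) {
  tibble(n_selected = length(x$chosen_features),
         best_score = x$best_score,
         cv_folds = x$cv_folds, ntree = x$ntree, seed = x$seed)
}

#' @describeIn rf_rfe Plot the cross-validation score against subset size.
#' @param object,x An `rfe_result`.
#' @param ... Unused.
#' @export
autoplot.rfe_result <- function(object, ...) {
  df <- object$score_curve
  best <- df[df$cv_accuracy == object$best_score, ]
  ggplot(df, aes(x = .data$n_features, y = .data$cv_accuracy)) +
    geom_line(colour = "goldenrod") +
    geom_point() +
    geom_point(data = best, colour = "red", size = 3) +
    labs(x = "Number of features kept", y = "Mean CV accuracy",
         title = "Recursive feature elimination") +
    theme_minimal()
}

# JSON round-trip for selection results
#' Serialize a selection result to JSON
#' @param x An `rfe_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rfe_json <- function(x, path) {
  jsonlite::write_json(
    list(elimination_order = x$elimination_order,
         score_curve = x$score_curve[, c("n_features", "cv_accuracy")],
         chosen_features = x$chosen_features,
         best_score = x$best_score,
         cv_folds = x$cv_folds, ntree = x$ntree, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
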