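#' Confusion matrix over the four lodging classes
#'
#' Rows are actual classes, columns predicted, both in the order
#' `NL, ML, HL, SL`.
#'
#' @param truth,estimate Vectors of class labels (character or factor on the
#'   lodging scale), equal length, non-empty.
#' @return Integer 4 x 4 matrix of class `lodging_confusion`.
#' @examples
#' confusion_matrix(c("NL", "SL", "SL"), c("NL", "SL", "HL"))
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must be equal-length, non-empty.")
  }
  t_f <- as_lodging_factor(truth)
  e_f <- as_lodging_factor(estimate)
  C <- table(actual = t_f, predicted = e_f)
  C <- matrix(as.integer(C), 4, 4,
              dimnames = list(actual = lodging_classes(),
                              predicted = lodging_classes()))
  structure(C, class = c("lodging_confusion", "matrix"))
}

as_confusion <- function(C) {
  C <- as.matrix(C)
  if (!all(dim(C) == 4)) abort("Confusion matrix must be 4 x 4.")
  if (any(C < 0) || sum(C) == 0) abort("Counts must be >= 0 with a positive total.")
  storage.mode(C) <- "integer"
  dimnames(C) <- list(actual = lodging_classes(), predicted = lodging_classes())
  structure(C, class = c("lodging_confusion", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of correctly classified samples, trace(C) / N.
#' @param C Confusion matrix (rows actual, columns predicted).
#' @return Numeric scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(C) {
  C <- unclass(as_confusion(C))
  sum(diag(C)) / sum(C)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)`, with `Po` the overall
#' accuracy and `Pe = sum_c row_c * col_c / N^2` the agreement expected from
#' the marginals.
#' @param C Confusion matrix.
#' @return Numeric scalar.
#' @export
kappa_statistic <- function(C) {
  C <- unclass(as_confusion(C))
  N <- sum(C)
  po <- sum(diag(C)) / N
  pe <- sum(rowSums(C) * colSums(C)) / N^2
  if (pe >= 1 - 1e-12) {
    abort("Kappa undefined: expected agreement is 1 (all mass in one cell).",
          class = "soylodge_undefined_kappa")
  }
  (po - pe) / (1 - pe)
}

#' Misclassification rate
#'
#' Defined as 1 minus the overall accuracy.
#' @param C Confusion matrix.
#' @return Numeric scalar in `[0, 1]`.
#' @export
misclassification_rate <- function(C) 1 - overall_accuracy(C)

#' Per-class precision, recall and F1 (one-vs-rest)
#'
#' For each class c: TP = C\[c, c\], FP = column sum - TP, FN = row sum - TP,
#' TN = the rest. Precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = harmonic mean of the two. Zero denominators yield 0 with
#' `undefined = TRUE`.
#'
#' @param C Confusion matrix.
#' @return Tibble with one row per class: `class, tp, fp, fn, tn, precision,
#'   recall, f1, undefined`.
#' @export
per_class_prf <- function(C) {
  C <- unclass(as_confusion(C))
  N <- sum(C)
  out <- lapply(seq_len(4), function(c) {
    tp <- C[c, c]
    fp <- sum(C[, c]) - tp
    fn <- sum(C[c, ]) - tp
    tn <- N - tp - fp - fn
    undef <- (tp + fp) == 0 || (tp + fn) == 0
    prec <- if ((tp + fp) == 0) 0 else tp / (tp + fp)
    rec <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(class = lodging_classes()[c], tp = tp, fp = fp, fn = fn, tn = tn,
           precision = prec, recall = rec, f1 = f1,
           undefined = undef || (prec + rec == 0))
  })
  bind_rows(out)
}

# binary ROC: thresholds grouped on tied scores, trapezoidal AUC
binary_roc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  P <- sum(labels); Nn <- length(labels) - P
  if (P == 0 || Nn == 0) {
    abort("ROC undefined: only one class present.",
          class = "soylodge_undefined_curve")
  }
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / Nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = tibble(fpr = fpr, tpr = tpr), auc = auc)
}

# binary PR: step-wise average precision (sum over recall increments)
binary_pr <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  P <- sum(labels)
  if (P == 0 || P == length(labels)) {
    abort("PR curve undefined: only one class present.",
          class = "soylodge_undefined_curve")
  }
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fpv <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fpv <- fpv[last]
  rec <- tp / P
  prec <- tp / (tp + fpv)
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = tibble(recall = c(0, rec), precision = c(1, prec)), ap = ap)
}

#' One-vs-rest ROC and precision-recall curves
#'
#' For each class, the class-membership indicator is scored by that class's
#' predicted probability; the ROC area uses trapezoidal integration over
#' tie-grouped thresholds and the average precision uses the step-wise
#' precision-recall sum.
#'
#' @param truth Vector of actual class labels.
#' @param prob n x 4 probability matrix, columns named (or ordered) as
#'   `NL, ML, HL, SL`.
#' @return A list of class `lodging_curves`: `summary` (tibble `class, auc,
#'   average_precision`), `roc` and `pr` (tibbles of curve points per class).
#'   Classes absent from `truth` raise an undefined-curve error.
#' @export
roc_pr_curves <- function(truth, prob) {
  t_f <- as_lodging_factor(truth)
  prob <- as.matrix(prob)
  if (is.null(colnames(prob))) colnames(prob) <- lodging_classes()
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    warn("Probability rows do not sum to 1.")
  }
  roc_pts <- list(); pr_pts <- list(); summ <- list()
  for (cl in lodging_classes()) {
    lab <- as.integer(t_f == cl)
    roc <- binary_roc(lab, prob[, cl])
    pr <- binary_pr(lab, prob[, cl])
    roc_pts[[cl]] <- mutate(roc$curve, class = cl)
    pr_pts[[cl]] <- mutate(pr$curve, class = cl)
    summ[[cl]] <- tibble(class = cl, auc = roc$auc, average_precision = pr$ap)
  }
  structure(list(summary = bind_rows(summ),
                 roc = bind_rows(roc_pts),
                 pr = bind_rows(pr_pts)),
            class = "lodging_curves")
}

#' Full evaluation report for a set of predictions
#'
#' Combines the confusion matrix, per-class precision/recall/F1, overall
#' accuracy, Cohen's kappa, the misclassification rate (1 - OA) and, when a
#' probability matrix is supplied, one-vs-rest ROC-AUC and average precision
#' per class.
#'
#' @param truth Actual class labels.
#' @param estimate Predicted class labels (default: argmax of `prob`).
#' @param prob Optional n x 4 probability matrix.
#' @return An object of class `lodging_evaluation`.
#' @export
evaluate_predictions <- function(truth, estimate = NULL, prob = NULL) {
  if (is.null(estimate)) {
    if (is.null(prob)) abort("Provide `estimate` or `prob`.")
    pm <- as.matrix(prob)
    if (is.null(colnames(pm))) colnames(pm) <- lodging_classes()
    estimate <- colnames(pm)[max.col(pm, ties.method = "first")]
  }
  C <- confusion_matrix(truth, estimate)
  evaluate_confusion(C, truth = truth, prob = prob)
}

#' Evaluation report from a confusion matrix
#'
#' @param C 4 x 4 confusion matrix (rows actual, columns predicted).
#' @param truth,prob Optional originals for ROC/PR computation.
#' @return An object of class `lodging_evaluation`: `confusion`, `per_class`
#'   (precision/recall/F1 tibble), `oa`, `po`, `pe`, `kappa`,
#'   `misclassification_rate`, and `curves` (NULL without probabilities).
#' @export
evaluate_confusion <- function(C, truth = NULL, prob = NULL) {
  C <- as_confusion(C)
  Cm <- unclass(C)
  N <- sum(Cm)
  po <- sum(diag(Cm)) / N
  pe <- sum(rowSums(Cm) * colSums(Cm)) / N^2
  curves <- if (!is.null(prob) && !is.null(truth)) roc_pr_curves(truth, prob)
  structure(
    list(confusion = C,
         per_class = per_class_prf(C),
         n = N,
         oa = po, po = po, pe = pe,
         kappa = kappa_statistic(C),
         misclassification_rate = 1 - po,
         curves = curves),
    class = "lodging_evaluation"
  )
}

#' @export
print.lodging_evaluation <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows actual, columns predicted):\n")
  print(unclass(x$confusion))
  pc <- x$per_class
  pc$precision <- round_half_up(pc$precision, digits)
  pc$recall <- round_half_up(pc$recall, digits)
  pc$f1 <- round_half_up(pc$f1, digits)
  print(pc[, c("class", "precision", "recall", "f1")])
  cat(sprintf("OA = %.2f, kappa = %.2f, misclassification = %.2f\n",
              round_half_up(x$oa, digits), round_half_up(x$kappa, digits),
              round_half_up(x$misclassification_rate, digits)))
  if (!is.null(x$curves)) {
    print(x$curves$summary)
  }
  invisible(x)
}

#' @export
tidy.lodging_evaluation <- function(x, ...) {
  out <- x$per_class[, c("class", "precision", "recall", "f1")]
  if (!is.null(x$curves)) {
    out <- left_join(out, x$curves$summary, by = "class")
  }
  out
}

#' @export
glance.lodging_evaluation <- function(x, ...) {
  tibble(n = x$n, oa = x$oa, kappa = x$kappa,
         misclassification_rate = x$misclassification_rate)
}

#' Write an evaluation report to JSON
#' @param x A `lodging_evaluation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_json <- function(x, path) {
  payload <- list(
    confusion = unclass(x$confusion),
    per_class = x$per_class,
    n = x$n, oa = x$oa, po = x$po, pe = x$pe, kappa = x$kappa,
    misclassification_rate = x$misclassification_rate
  )
  if (!is.null(x$curves)) payload$curves_summary <- x$curves$summary
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @describeIn evaluate_confusion Heatmap of the confusion matrix.
#' @param object,x A `lodging_evaluation`.
#' @param ... Unused.
#' @export
autoplot.lodging_evaluation <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object$confusion)))
  names(df) <- c("actual", "predicted", "count")
  ggplot(df, aes(x = .data$predicted, y = .data$actual, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "darkgreen") +
    coord_equal() +
    labs(title = sprintf("OA = %.2f, kappa = %.2f", object$oa, object$kappa)) +
    theme_minimal()
}

#' Plot one-vs-rest ROC or precision-recall curves
#' @param object A `lodging_curves` result from [roc_pr_curves()].
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @export
autoplot.lodging_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
      geom_step() +
      geom_abline(linetype = "dashed", colour = "grey") +
      labs(x = "False positive rate", y = "True positive rate",
           title = "One-vs-rest ROC") +
      theme_minimal()
  } else {
    ggplot(object$pr, aes(x = .data$recall, y = .data$precision,
                          colour = .data$class)) +
      geom_step(direction = "hv") +
      labs(x = "Recall", y = "Precision", title = "One-vs-rest precision-recall") +
      theme_minimal()
  }
}
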