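#' The four-class lodging scale
#'
#' Breeders rate lodging visually on a 1 to 5 scale in 0.5 increments: 1 means
#' all plants erect, 5 means all plants flat on the ground. For classification
#' the eleven scores are grouped into four ordered severity classes:
#' no lodging (NL, scores 1.0 and 1.5), moderate lodging (ML, 2.0 and 2.5),
#' high lodging (HL, 3.0 and 3.5) and severe lodging (SL, 4.0, 4.5 and 5.0).
#'
#' @return `lodging_classes()` returns the ordered class labels
#'   `c("NL", "ML", "HL", "SL")`. `lodging_score_sets()` returns a named list
#'   mapping each class to its admissible scores.
#' @examples
#' lodging_classes()
#' lodging_score_sets()$SL
#' @export
lodging_classes <- function() c("NL", "ML", "HL", "SL")

#' @rdname lodging_classes
#' @export
lodging_score_sets <- function() {
  list(
    NL = c(1.0, 1.5),
    ML = c(2.0, 2.5),
    HL = c(3.0, 3.5),
    SL = c(4.0, 4.5, 5.0)
  )
}

#' Map visual lodging scores to severity classes
#'
#' @param score Numeric vector of visual lodging scores. Each score must lie on
#'   the breeder's scale: a multiple of 0.5 between 1.0 and 5.0.
#' @return A factor with levels `NL < ML < HL < SL`, same length as `score`.
#' @examples
#' score_to_class(c(1.5, 2.0, 5.0))
#' @export
score_to_class <- function(score) {
  if (!is.numeric(score) || length(score) == 0) {
    abort("`score` must be a non-empty numeric vector.", class = "soylodge_invalid_score")
  }
  sets <- lodging_score_sets()
  all_scores <- unlist(sets, use.names = FALSE)
  bad <- !vapply(score, function(s) any(abs(s - all_scores) < 1e-9), logical(1))
  if (any(bad)) {
    abort(
      sprintf(
        "Invalid lodging score(s): %s. Scores must be multiples of 0.5 in [1, 5].",
        paste(score[bad], collapse = ", ")
      ),
      class = "soylodge_invalid_score"
    )
  }
  cls <- vapply(score, function(s) {
    names(sets)[vapply(sets, function(set) any(abs(s - set) < 1e-9), logical(1))]
  }, character(1))
  factor(cls, levels = lodging_classes(), ordered = TRUE)
}

as_lodging_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% lodging_classes())) {
    abort(
      sprintf(
        "Unknown class label(s): %s",
        paste(unique(x[!x %in% lodging_classes()]), collapse = ", ")
      ),
      class = "soylodge_unknown_label"
    )
  }
  factor(x, levels = lodging_classes(), ordered = TRUE)
}
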