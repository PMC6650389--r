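# Stratified k-fold cross-validation for the two classifiers, and the
# combined two-stage labelling (PLS-DA lysed/intact, then SIMCA morphology).

#' Stratified fold assignment
#'
#' @param y Class labels.
#' @param folds Number of folds.
#' @param seed Integer seed making the assignment reproducible.
#' @return Integer vector of fold ids in `1..folds`, stratified by class so
#'   every fold contains every class (requires >= folds cells per class).
#' @export
stratified_folds <- function(y, folds = 7, seed = 1) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < folds))
    stop("class(es) ", paste(names(counts)[counts < folds], collapse = ", "),
         " have fewer cells than folds = ", folds)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in names(counts)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

.class_metrics <- function(truth, pred, classes) {
  out <- lapply(classes, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    fp <- sum(truth != cls & pred == cls)
    tn <- sum(truth != cls & pred != cls)
    data.frame(class = cls,
               sensitivity = tp / max(tp + fn, 1),
               specificity = tn / max(tn + fp, 1),
               accuracy = (tp + tn) / length(truth))
  })
  do.call(rbind, out)
}

#' Seven-fold cross-validated classification metrics
#'
#' @param X Feature matrix.
#' @param y Class labels (two classes for `"plsda"`; the four morphology
#'   classes for `"simca"`).
#' @param classifier `"plsda"` or `"simca"`.
#' @param folds Number of stratified folds (default 7).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [fit_plsda()] / [fit_simca()] (`n_components`,
#'   `k_by_class`, `alpha`).
#' @return `tibble` with per-class sensitivity, specificity and accuracy;
#'   the fold assignment is attached as attribute `"folds"`. Every sample is
#'   tested exactly once.
#' @export
crossvalidate <- function(X, y, classifier = c("plsda", "simca"), folds = 7,
                          seed = 1, ...) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- as.character(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    test <- fold == f
    if (classifier == "plsda") {
      m <- fit_plsda(X[!test, , drop = FALSE], y[!test], ...)
      pred[test] <- predict_plsda(m, X[test, , drop = FALSE])$labels
    } else {
      Xb <- split.data.frame(X[!test, , drop = FALSE], y[!test])
      m <- fit_simca(Xb, ...)
      pred[test] <- as.character(predict_simca(m, X[test, , drop = FALSE]))
    }
  }
  res <- .class_metrics(y, pred, sort(unique(y)))
  out <- tibble::as_tibble(res)
  attr(out, "folds") <- fold
  attr(out, "predictions") <- pred
  out
}

#' Two-stage labelling of cells: lysed vs intact, then morphology
#'
#' Applies the PLS-DA model to split lysed from intact cells, then the SIMCA
#' model to assign each intact cell one of the four morphology classes or
#' `"deformed"`. Every cell receives exactly one final label.
#'
#' @param plsda A `plsda_model` whose positive class is `"lysed"`.
#' @param simca A `simca_model`.
#' @param X Feature matrix.
#' @return Character vector of labels in
#'   lysed/normal/round/elongated/small/deformed.
#' @export
classify_cells <- function(plsda, simca, X) {
  X <- as.matrix(X)
  stage1 <- predict_plsda(plsda, X)$labels
  labels <- stage1
  intact <- stage1 != "lysed"
  if (any(intact))
    labels[intact] <-
      as.character(predict_simca(simca, X[intact, , drop = FALSE]))
  labels
}
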