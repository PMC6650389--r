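# PLS-DA: partial least squares discriminant analysis for the binary
# lysed-vs-intact decision. Single-response NIPALS formulation with
# deflation; y coded {0, 1}; features autoscaled on training statistics.

#' Fit a PLS-DA model
#'
#' Features are autoscaled (centered, unit variance) internally; the class
#' response is coded 0/1 and centered. Components are extracted by the
#' NIPALS algorithm for a single response: each weight vector is
#' proportional to the covariance of the deflated features with the
#' response, giving a deterministic fit.
#'
#' @param X Numeric matrix (cells x features).
#' @param y Binary labels: logical, 0/1 numeric, or a two-level
#'   factor/character vector. The second sorted level is the positive
#'   class.
#' @param n_components Number of latent components (default 3, the
#'   screening default).
#' @param threshold Decision threshold on the predicted response
#'   (default 0.5); predictions at or above it get the positive class.
#' @return A `plsda_model`: training means/scales, weights `W`, loadings
#'   `P`, response loadings `q`, regression vector `coef`, training scores,
#'   class names.
#' @export
fit_plsda <- function(X, y, n_components = 3, threshold = 0.5) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lev <- sort(unique(y))
    if (length(lev) != 2) stop("y must have exactly two classes")
    yb <- as.numeric(y == lev[2])
  } else {
    yb <- as.numeric(y)
    if (!all(yb %in% c(0, 1))) stop("numeric y must be coded 0/1")
    lev <- c("0", "1")
  }
  if (length(unique(yb)) < 2) stop("both classes must be present in y")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  keep <- sdev > .Machine$double.eps
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep],
              "/")
  ybar <- mean(yb)
  yc <- yb - ybar
  p <- ncol(Xs)
  if (n_components > min(p, nrow(Xs) - 1))
    stop("n_components exceeds the rank limit of the training matrix")
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Tm <- matrix(0, nrow(Xs), n_components)
  Xa <- Xs; ya <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stop("response covariance vanished at component ", a)
    w <- w / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pv)
    ya <- ya - t * qa
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- t
  }
  R <- W %*% solve(crossprod(P, W))   # so that scores = Xs %*% R
  coef <- drop(R %*% q)
  structure(list(
    n_components = n_components, mean = mu, scale = sdev, keep = keep,
    W = W, P = P, q = q, R = R, coef = coef, y_mean = ybar,
    scores = Tm, levels = lev, threshold = threshold,
    feature_names = colnames(X)), class = "plsda_model")
}

#' Predict class membership with a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param X Feature matrix with the training feature columns.
#' @return List: `labels` (character), `response` (continuous predicted
#'   response in 0/1 coding), `scores` (component scores for plotting).
#' @export
predict_plsda <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("feature count mismatch: model expects ", length(model$mean))
  if (!is.null(colnames(X)) && !is.null(model$feature_names) &&
      !identical(colnames(X), model$feature_names))
    stop("feature columns do not match the training order")
  Xs <- sweep(sweep(X[, model$keep, drop = FALSE], 2,
                    model$mean[model$keep]), 2,
              model$scale[model$keep], "/")
  scores <- Xs %*% model$R
  response <- drop(Xs %*% model$coef) + model$y_mean
  labels <- ifelse(response >= model$threshold,
                   model$levels[2], model$levels[1])
  list(labels = labels, response = response, scores = scores)
}

#' Serialize a PLS-DA model to JSON
#'
#' @param model A `plsda_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_plsda <- function(model, path) {
  obj <- lapply(unclass(model), function(x) if (is.matrix(x)) unclass(x) else x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
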