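# SIMCA: one PCA class model per morphology (elongated, normal, round,
# small); cells not accepted by any class model are labelled "deformed".
#
# The class-membership statistic is a reduced combined distance
#   d = T2/k + SPE/spe0
# (Mahalanobis distance in the retained score space over its component
# count, plus the orthogonal residual scaled by the mean training
# residual). The acceptance limit per class is the empirical (1 - alpha)
# quantile of d over that class's training cells.

#' Default SIMCA component counts per morphology class
#'
#' The screening defaults: elongated 1, normal 1, round 3, small 2
#' components (chosen in the source screens by seven-fold cross-validation).
#' @return Named integer vector.
#' @export
default_simca_components <- function() {
  c(elongated = 1L, normal = 1L, round = 3L, small = 2L)
}

.fit_class_pca <- function(X, k) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  sv <- svd(Xs, nu = 0, nv = k)
  lambda <- sv$d^2 / (n - 1)
  P <- sv$v
  Tm <- Xs %*% P
  t2 <- rowSums(sweep(Tm^2, 2, lambda[seq_len(k)], "/"))
  resid <- Xs - Tm %*% t(P)
  spe <- rowSums(resid^2)
  spe0 <- mean(spe)
  d <- t2 / k + if (spe0 > .Machine$double.eps) spe / spe0 else 0
  list(mean = mu, scale = sdev, loadings = P,
       lambda = lambda[seq_len(k)], resid_lambda = lambda[-seq_len(k)],
       k = k, spe0 = spe0, n = n, train_distance = d)
}

#' Fit a SIMCA model (one PCA per class)
#'
#' Each class is modelled by a PCA of its own autoscaled training cells with
#' a class-specific number of components; the class acceptance limit is the
#' empirical `1 - alpha` quantile of the combined membership distance over
#' the class's training cells, so about `100 * (1 - alpha)` percent of
#' in-class data is accepted.
#'
#' @param X_by_class Named list of feature matrices, one per class.
#' @param k_by_class Named integer vector of component counts (default
#'   [default_simca_components()] where names match, else 2).
#' @param alpha Rejection rate on in-class training data (default 0.05,
#'   i.e. 95 percent class-confidence regions).
#' @return A `simca_model`: per-class PCA models with limits.
#' @export
fit_simca <- function(X_by_class, k_by_class = default_simca_components(),
                      alpha = 0.05) {
  stopifnot(is.list(X_by_class), length(names(X_by_class)) > 0)
  classes <- names(X_by_class)
  models <- list()
  for (cls in classes) {
    X <- as.matrix(X_by_class[[cls]])
    k <- if (cls %in% names(k_by_class)) as.integer(k_by_class[[cls]]) else 2L
    if (nrow(X) <= k)
      stop("class '", cls, "' has ", nrow(X),
           " cells, not enough for ", k, " components")
    m <- .fit_class_pca(X, k)
    m$limit <- unname(quantile(m$train_distance, 1 - alpha, type = 7))
    models[[cls]] <- m
  }
  structure(list(classes = classes, models = models, alpha = alpha,
                 feature_names = colnames(as.matrix(X_by_class[[1]]))),
            class = "simca_model")
}

.simca_distance <- function(m, X) {
  Xs <- sweep(sweep(X, 2, m$mean), 2, m$scale, "/")
  Tm <- Xs %*% m$loadings
  t2 <- rowSums(sweep(Tm^2, 2, m$lambda, "/"))
  resid <- Xs - Tm %*% t(m$loadings)
  spe <- rowSums(resid^2)
  t2 / m$k + if (m$spe0 > .Machine$double.eps) spe / m$spe0 else 0
}

#' Classify cells with a SIMCA model
#'
#' Each cell's combined membership distance is computed against every class
#' model; classes whose distance is within their acceptance limit accept the
#' cell. Cells accepted by no class are labelled `"deformed"`; cells
#' accepted by several classes go to the class with the smallest reduced
#' distance (distance / limit), and the number of such ambiguous cells is
#' attached as attribute `"n_ambiguous"`.
#'
#' @param model A `simca_model`.
#' @param X Feature matrix of intact cells.
#' @return Character vector of labels with attributes `"distance"` (matrix
#'   of combined distances) and `"n_ambiguous"`.
#' @export
predict_simca <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (ncol(X) != length(model$models[[1]]$mean))
    stop("feature count mismatch")
  if (!is.null(colnames(X)) && !is.null(model$feature_names) &&
      !identical(colnames(X), model$feature_names))
    stop("feature columns do not match the training order")
  D <- vapply(model$classes,
              function(cls) .simca_distance(model$models[[cls]], X),
              numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X),
              dimnames = list(NULL, model$classes))
  limits <- vapply(model$classes, function(cls) model$models[[cls]]$limit, 0)
  Rd <- sweep(D, 2, limits, "/")
  accepted <- Rd <= 1
  n_acc <- rowSums(accepted)
  labels <- rep("deformed", nrow(X))
  any_acc <- n_acc > 0
  if (any(any_acc)) {
    best <- apply(Rd[any_acc, , drop = FALSE], 1, which.min)
    labels[any_acc] <- model$classes[best]
  }
  structure(labels, distance = D, n_ambiguous = sum(n_acc > 1))
}

#' Serialize a SIMCA model to JSON
#' @param model A `simca_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_simca <- function(model, path) {
  obj <- list(classes = model$classes, alpha = model$alpha,
              feature_names = model$feature_names,
              models = lapply(model$models, function(m)
                lapply(m, function(x) if (is.matrix(x)) unclass(x) else x)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
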