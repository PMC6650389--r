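# Wild-type PCA reference model and outlier statistics.
#
# The reference model is a PCA of the autoscaled wild-type phenotypic
# profiles. Each screened profile is scored by Hotelling's T2 (Mahalanobis
# distance of its projection within the retained score space) and SPE (the
# squared orthogonal residual from the model hyperplane). Strains beyond the
# 99th percentile of the wild-type sample distribution of either statistic
# are flagged.

#' Fit the wild-type PCA reference model
#'
#' Profiles are autoscaled on the training set; PCA is computed from the
#' full eigendecomposition so that both retained and residual eigenvalues
#' are available for the theoretical SPE limit. The number of retained
#' components defaults to the Kaiser rule for autoscaled data — retain the
#' components whose eigenvalue exceeds the mean eigenvalue — which keeps
#' the systematic (correlated) wild-type variability in the score space and
#' leaves counting noise to the residual. A cumulative-variance rule is
#' available via `k_rule = "variance"`; with the flat noise spectra of
#' proportion data it retains most components and makes resubstitution SPE
#' limits anti-conservative, so it is not the default. The choice of k is
#' reported in the output and on every screen manifest.
#'
#' @param wt_profiles Matrix (replicates x 18) of batch-corrected wild-type
#'   profiles; at least 30 rows.
#' @param k Number of retained components; `NULL` (default) applies
#'   `k_rule`.
#' @param k_rule `"kaiser"` (default) or `"variance"`.
#' @param var_explained Cumulative-variance threshold for
#'   `k_rule = "variance"` (default 0.90).
#' @param min_n Minimum number of replicates (default 30; relaxed
#'   internally for leave-one-out refits).
#' @return A `reference_model`: mean, scale, loadings (all p columns),
#'   eigenvalues, k, n, and the theta moments of the residual eigenvalues.
#' @export
fit_reference <- function(wt_profiles, k = NULL,
                          k_rule = c("kaiser", "variance"),
                          var_explained = 0.90, min_n = 30) {
  k_rule <- match.arg(k_rule)
  X <- as.matrix(wt_profiles)
  if (nrow(X) < min_n)
    stop("need at least ", min_n, " wild-type profiles, got ", nrow(X))
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev < .Machine$double.eps))
    stop("degenerate (zero-variance) profile variable: ",
         paste(colnames(X)[sdev < .Machine$double.eps], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  eg <- eigen(cov(Xs), symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  if (is.null(k)) {
    k <- if (k_rule == "kaiser") max(sum(lambda > mean(lambda)), 1L)
    else which(cumsum(lambda) / sum(lambda) >= var_explained)[1]
  }
  p <- ncol(X)
  if (k >= p) stop("k must be smaller than the profile dimension")
  resid_lambda <- lambda[(k + 1):p]
  theta <- vapply(1:3, function(i) sum(resid_lambda^i), 0)
  structure(list(mean = mu, scale = sdev, loadings = eg$vectors,
                 lambda = lambda, k = as.integer(k), n = nrow(X), p = p,
                 theta = theta, k_rule = k_rule,
                 var_explained = var_explained,
                 profile_names = colnames(X)), class = "reference_model")
}

#' Hotelling's T2 and SPE of profiles against a reference model
#'
#' T2 = sum over retained components of t_j^2 / lambda_j; SPE is the
#' squared norm of the difference between the autoscaled profile and its
#' rank-k reconstruction.
#'
#' @param model A `reference_model`.
#' @param profiles Matrix (or single vector) of 18-dimensional profiles on
#'   the same (batch-corrected) scale as the training profiles.
#' @return `tibble` with columns `t2` and `spe` (one row per profile).
#' @export
score_profiles <- function(model, profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  X <- as.matrix(profiles)
  if (ncol(X) != model$p)
    stop("profile length ", ncol(X), " does not match the model (",
         model$p, ")")
  Xs <- sweep(sweep(X, 2, model$mean), 2, model$scale, "/")
  k <- model$k
  Pk <- model$loadings[, seq_len(k), drop = FALSE]
  Tk <- Xs %*% Pk
  t2 <- rowSums(sweep(Tk^2, 2, model$lambda[seq_len(k)], "/"))
  resid <- Xs - Tk %*% t(Pk)
  spe <- rowSums(resid^2)
  tibble::tibble(t2 = unname(t2), spe = unname(spe))
}

#' Leave-one-out wild-type scores
#'
#' T2 and SPE for each wild-type replicate computed from a reference model
#' refitted without that replicate (at the fixed component count k). These
#' scores are exchangeable with the scores of new (mutant) profiles drawn
#' from the wild-type distribution, so percentile limits taken from them
#' are calibrated for out-of-sample flagging; plain resubstitution scores
#' understate both statistics and make the limits anti-conservative.
#'
#' @param wt_profiles Matrix of batch-corrected wild-type profiles.
#' @param k Retained component count (typically from the full-model
#'   [fit_reference()] fit).
#' @return `tibble` with columns `t2` and `spe`, one row per replicate.
#' @export
loo_scores <- function(wt_profiles, k) {
  X <- as.matrix(wt_profiles)
  n <- nrow(X)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    ref <- fit_reference(X[-i, , drop = FALSE], k = k, min_n = n - 1)
    s <- score_profiles(ref, X[i, , drop = FALSE])
    out[i, ] <- c(s$t2, s$spe)
  }
  tibble::tibble(t2 = out[, 1], spe = out[, 2])
}

#' Empirical control limits from wild-type scores
#'
#' Order-statistic percentiles of the wild-type sample distribution of each
#' statistic, with linear interpolation at rank `(n + 1) p` (quantile
#' type 6). For exchangeable scores this rank convention makes the
#' probability that a new wild-type-like profile exceeds the limit equal to
#' `1 - p` exactly, which is what a control limit is for; the more common
#' type-7 rank underestimates the tail at these sample sizes.
#'
#' @param wt_scores `tibble` from [loo_scores()] (calibrated, recommended)
#'   or [score_profiles()] on the training wild-type profiles
#'   (resubstitution).
#' @param percentiles Percentiles to report (default 95 and 99).
#' @return A `ms_limits` list: `t2` and `spe`, each a named vector of
#'   percentile values.
#' @export
empirical_limits <- function(wt_scores, percentiles = c(95, 99)) {
  n <- nrow(wt_scores)
  if (n < 100 / (100 - max(percentiles)))
    warning("only ", n, " wild-type scores for the ",
            max(percentiles), "th percentile")
  q <- function(x) setNames(quantile(x, percentiles / 100, type = 6,
                                     names = FALSE),
                            paste0("p", percentiles))
  structure(list(t2 = q(wt_scores$t2), spe = q(wt_scores$spe),
                 percentiles = percentiles, kind = "empirical"),
            class = "ms_limits")
}

#' Theoretical control limits (F / weighted-chi-squared approximations)
#'
#' T2 limit: `k (n^2 - 1) / (n (n - k))` times the F quantile with
#' `(k, n - k)` degrees of freedom. SPE limit: the weighted chi-squared
#' approximation `g * chisq_h` with `g = theta2 / theta1` and
#' `h = theta1^2 / theta2` computed from the residual eigenvalues. Provided
#' for diagnostics; the operative decision rule uses [empirical_limits()].
#'
#' @param model A `reference_model`.
#' @param alpha Tail probability (default 0.01).
#' @return A `ms_limits` list with single values `t2` and `spe`.
#' @export
theoretical_limits <- function(model, alpha = 0.01) {
  k <- model$k; n <- model$n
  t2_lim <- k * (n^2 - 1) / (n * (n - k)) * qf(1 - alpha, k, n - k)
  th <- model$theta
  if (th[1] < .Machine$double.eps) {
    warning("perfect fit: residual eigenvalues are zero, SPE limit is 0")
    spe_lim <- 0
  } else {
    g <- th[2] / th[1]
    h <- th[1]^2 / th[2]
    spe_lim <- g * qchisq(1 - alpha, h)
  }
  structure(list(t2 = c(limit = t2_lim), spe = c(limit = spe_lim),
                 alpha = alpha, kind = "theoretical"), class = "ms_limits")
}

#' Flag strains beyond the control limits
#'
#' A strain is flagged when at least one statistic lies strictly beyond its
#' limit (the default rule: the 99th percentile of the wild-type sample
#' distribution, either statistic).
#'
#' @param scores `tibble` from [score_profiles()] with one row per strain.
#' @param limits A `ms_limits` from [empirical_limits()].
#' @param strain_id Optional ids (default row index).
#' @param percentile Which percentile of `limits` to apply (default 99).
#' @return `tibble`: strain_id, t2, spe, flag in
#'   none/spe_only/t2_only/both; counts per category attached as attribute
#'   `"counts"`.
#' @export
flag_outliers <- function(scores, limits, strain_id = NULL,
                          percentile = 99) {
  key <- paste0("p", percentile)
  t2_lim <- if (key %in% names(limits$t2)) limits$t2[[key]] else
    limits$t2[[1]]
  spe_lim <- if (key %in% names(limits$spe)) limits$spe[[key]] else
    limits$spe[[1]]
  hi_t2 <- scores$t2 > t2_lim
  hi_spe <- scores$spe > spe_lim
  flag <- ifelse(hi_t2 & hi_spe, "both",
                 ifelse(hi_t2, "t2_only",
                        ifelse(hi_spe, "spe_only", "none")))
  if (is.null(strain_id)) strain_id <- as.character(seq_len(nrow(scores)))
  out <- tibble::tibble(strain_id = strain_id, t2 = scores$t2,
                        spe = scores$spe, flag = flag)
  attr(out, "counts") <- c(table(factor(flag, levels = c(
    "none", "spe_only", "t2_only", "both"))))
  attr(out, "limits") <- c(t2 = t2_lim, spe = spe_lim)
  out
}
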