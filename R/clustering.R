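# Clustering of flagged strains' profiles (k-means, k selected by mean
# silhouette width), a 2-D PCA embedding for plots, and Fisher's exact
# functional-category enrichment per cluster.

#' Seeded best-of-restarts k-means
#'
#' @param X Numeric matrix (strains x variables).
#' @param k Number of clusters (>= 2).
#' @param n_restarts Random restarts; the solution with smallest
#'   within-cluster sum of squares is kept (default 50).
#' @param seed Integer seed; the run is reproducible.
#' @return List: `assignment` (integer vector in 1..k), `centers`,
#'   `inertia` (total within-cluster sum of squares).
#' @export
cluster_kmeans <- function(X, k, n_restarts = 50, seed = 1) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k = ", k, " exceeds the number of points")
  if (k < 1 || n_restarts < 1) stop("k and n_restarts must be positive")
  if (k == nrow(X)) {
    return(list(assignment = seq_len(nrow(X)), centers = X, inertia = 0))
  }
  km <- withr::with_seed(seed,
    kmeans(X, centers = k, nstart = n_restarts, iter.max = 100))
  list(assignment = unname(km$cluster), centers = km$centers,
       inertia = km$tot.withinss)
}

#' Select the number of clusters by silhouette analysis
#'
#' Runs seeded k-means for every k in `k_range` and keeps the k with the
#' largest mean silhouette width (Euclidean distances). If no k achieves a
#' positive mean silhouette, the data are reported as unclustered.
#'
#' @param X Numeric matrix.
#' @param k_range Candidate k values (default 2:8), within `[2, n - 1]`.
#' @param n_restarts,seed Passed to [cluster_kmeans()].
#' @param standardize Autoscale columns before clustering (default TRUE).
#'   k-means and silhouette widths are scale-sensitive, and flagged outlier
#'   profiles span wildly different ranges per variable (a strain can sit
#'   tens of wild-type standard deviations out in one variable and one in
#'   another); autoscaling within the clustered set balances the variables'
#'   influence. Zero-variance columns are left centered.
#' @return A `cluster_result` list: `k` (NA if no structure), `assignment`,
#'   `silhouette` (per-point widths), `mean_silhouette` (named vector over
#'   the scanned k), `structure` (logical), `embedding` (2-D PCA
#'   coordinates from [pca_embed()]).
#' @export
select_k_by_silhouette <- function(X, k_range = 2:8, n_restarts = 50,
                                   seed = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) {
    sdv <- apply(X, 2, sd)
    X <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sdv, .Machine$double.eps),
               "/")
  }
  k_range <- k_range[k_range >= 2 & k_range <= nrow(X) - 1]
  if (!length(k_range)) stop("k_range empty after bounding to [2, n-1]")
  d <- dist(X)
  fits <- list(); msil <- setNames(numeric(length(k_range)),
                                   paste0("k", k_range))
  for (i in seq_along(k_range)) {
    fit <- cluster_kmeans(X, k_range[i], n_restarts, seed)
    sil <- cluster::silhouette(fit$assignment, d)
    fits[[i]] <- list(fit = fit, sil = sil)
    msil[i] <- mean(sil[, "sil_width"])
  }
  best <- which.max(msil)
  structure_found <- msil[best] > 0
  res <- list(
    k = if (structure_found) k_range[best] else NA_integer_,
    assignment = if (structure_found) fits[[best]]$fit$assignment else NULL,
    silhouette = if (structure_found)
      fits[[best]]$sil[, "sil_width"] else NULL,
    mean_silhouette = msil,
    structure = structure_found,
    embedding = if (nrow(X) >= 3) pca_embed(X) else NULL)
  class(res) <- "cluster_result"
  res
}

#' Two-dimensional PCA embedding of profiles
#'
#' First two principal-component scores of the autoscaled profiles, with a
#' fixed sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param profiles Matrix (>= 3 rows).
#' @param center,scale. Passed to [stats::prcomp()] (defaults TRUE; scaling
#'   is skipped for constant columns).
#' @return n x 2 matrix of coordinates.
#' @export
pca_embed <- function(profiles, center = TRUE, scale. = TRUE) {
  X <- as.matrix(profiles)
  if (nrow(X) < 3) stop("need at least 3 profiles")
  sdev <- apply(X, 2, sd)
  if (any(sdev < .Machine$double.eps)) scale. <- FALSE
  pc <- prcomp(X, center = center, scale. = scale., rank. = 2)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  emb <- pc$x[, 1:2, drop = FALSE]
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  colnames(emb) <- c("PC1", "PC2")
  emb
}

#' Fisher's exact enrichment of functional categories per cluster
#'
#' For every (cluster, category) pair, tests the 2x2 table of in-cluster vs
#' out-of-cluster strains carrying vs not carrying the category label with a
#' two-tailed Fisher's exact test (two-tailed convention: the sum of
#' probabilities of all tables with the same margins that are no more
#' probable than the observed one). The background is the clustered
#' (flagged) strain set. Strains may carry several category labels.
#'
#' @param clusters Named integer vector: strain id -> cluster.
#' @param categories data.frame with columns `strain_id` and `category`
#'   (one row per strain-category membership).
#' @param p_adjust Multiple-testing correction method for
#'   [stats::p.adjust()] (default `"none"`, matching a raw p < 0.05 rule).
#' @param alpha Significance level (default 0.05).
#' @return `tibble`: cluster, category, counts of the 2x2 table, odds_ratio
#'   (conditional MLE), p_value, p_adjusted, significant.
#' @export
fisher_enrichment <- function(clusters, categories, p_adjust = "none",
                              alpha = 0.05) {
  stopifnot(!is.null(names(clusters)),
            all(c("strain_id", "category") %in% names(categories)))
  categories <- categories[categories$strain_id %in% names(clusters), ]
  cats <- sort(unique(categories$category))
  rows <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- names(clusters)[clusters == cl]
    out_cl <- setdiff(names(clusters), in_cl)
    for (cat in cats) {
      with_cat <- unique(categories$strain_id[categories$category == cat])
      a <- sum(in_cl %in% with_cat)
      b <- length(in_cl) - a
      c_ <- sum(out_cl %in% with_cat)
      d <- length(out_cl) - c_
      if (a + c_ == 0) next  # category absent: skipped
      ft <- .fisher_test_2x2(a, b, c_, d)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, category = cat, in_with = a, in_without = b,
        out_with = c_, out_without = d,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_adjusted < alpha
  out
}

# Two-tailed Fisher's exact test of one 2x2 table; the single p-value
# route used for every enrichment table entry.
.fisher_test_2x2 <- function(a, b, c, d) {
  ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                    alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments and reference
#' labels (1 = identical partitions up to renaming).
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
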