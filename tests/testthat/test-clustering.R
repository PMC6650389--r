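blobs <- function(k = 3, n_per = 30, sep = 8, p = 5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(0, k, p)
    centers[cbind(1:k, 1:k)] <- sep        # unit-simplex-like layout
    X <- do.call(rbind, lapply(1:k, function(i)
      sweep(matrix(rnorm(n_per * p), n_per), 2, centers[i, ], "+")))
    list(X = X, labels = rep(1:k, each = n_per))
  })
}

test_that("k-means degenerate and planted cases behave", {
  # two points, k = 2: each its own cluster, zero inertia
  X2 <- rbind(c(0, 0), c(5, 5))
  km <- cluster_kmeans(X2, 2, n_restarts = 5, seed = 1)
  expect_equal(sort(km$assignment), c(1, 2))
  expect_equal(km$inertia, 0)
  # three separated blobs recovered up to label permutation
  b <- blobs()
  km3 <- cluster_kmeans(b$X, 3, seed = 2)
  expect_equal(adjusted_rand_index(km3$assignment, b$labels), 1)
  # duplicate rows get identical assignments
  Xd <- rbind(b$X, b$X[1:5, ])
  kmd <- cluster_kmeans(Xd, 3, seed = 3)
  expect_equal(kmd$assignment[nrow(b$X) + 1:5], kmd$assignment[1:5])
  # fixed seed: identical output
  expect_identical(cluster_kmeans(b$X, 3, seed = 4),
                   cluster_kmeans(b$X, 3, seed = 4))
  expect_error(cluster_kmeans(b$X, nrow(b$X) + 1, seed = 1), "exceeds")
})

test_that("silhouette analysis selects the planted number of clusters", {
  b <- blobs(k = 3, seed = 5)
  res <- select_k_by_silhouette(b$X, k_range = 2:8, seed = 5)
  expect_equal(res$k, 3L)
  expect_true(res$structure)
  expect_equal(adjusted_rand_index(res$assignment, b$labels), 1)
  expect_true(all(res$silhouette >= -1 & res$silhouette <= 1))
  expect_length(res$mean_silhouette, 7)
  # two tight, distant singleton-like clusters: mean silhouette near 1
  tight <- rbind(matrix(rnorm(40, 0, 1e-3), 20),
                 matrix(rnorm(40, 100, 1e-3), 20))
  res_t <- select_k_by_silhouette(tight, k_range = 2:4, seed = 1)
  expect_equal(res_t$k, 2L)
  expect_gt(max(res_t$mean_silhouette), 0.99)
})

test_that("an isotropic blob reports no cluster structure", {
  withr::with_seed(6, X <- matrix(rnorm(600), 100, 6))
  res <- select_k_by_silhouette(X, k_range = 2:6, seed = 6)
  # silhouettes are weak; either no structure or a very low maximum
  expect_lt(max(res$mean_silhouette), 0.25)
})

test_that("silhouette-selected k recovers planted k across seeded
          replicates", {
  hits <- 0
  for (s in 1:20) {
    b <- blobs(k = 3, n_per = 20, sep = 8, seed = 100 + s)
    res <- select_k_by_silhouette(b$X, k_range = 2:6, n_restarts = 10,
                                  seed = s)
    if (identical(res$k, 3L)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the PCA embedding is a contractive projection with fixed
          signs", {
  # collinear data: second coordinate vanishes
  withr::with_seed(7, {
    t <- rnorm(50)
    X <- cbind(t, 2 * t, -t) + matrix(rnorm(150, 0, 1e-9), 50)
  })
  emb <- pca_embed(X, scale. = FALSE)
  expect_lt(max(abs(emb[, 2])), 1e-6)
  # pairwise distances never grow under projection
  withr::with_seed(8, Y <- matrix(rnorm(30 * 6), 30))
  e <- pca_embed(Y, scale. = FALSE)
  d_full <- as.matrix(dist(scale(Y, scale = FALSE)))
  d_emb <- as.matrix(dist(e))
  expect_true(all(d_emb <= d_full + 1e-8))
  # sign convention: the largest-magnitude loading is positive
  expect_error(pca_embed(Y[1:2, ]), "at least 3")
})

test_that("Fisher enrichment matches the enumeration oracle", {
  # the 2x2 table [[5,1],[10,84]] via constructed memberships
  clusters <- setNames(rep(c(1, 2), c(6, 94)), paste0("s", 1:100))
  categories <- data.frame(
    strain_id = c(paste0("s", 1:5), paste0("s", 7:16)),
    category = "L")
  tab <- fisher_enrichment(clusters, categories)
  row <- tab[tab$cluster == 1 & tab$category == "L", ]
  expect_equal(c(row$in_with, row$in_without, row$out_with,
                 row$out_without), c(5, 1, 10, 84))
  expect_lt(abs(row$p_value - fisher_oracle(5, 1, 10, 84)), 1e-12)
  expect_true(row$significant)
  # a category present in every strain is never enriched
  cat_all <- data.frame(strain_id = paste0("s", 1:100), category = "X")
  tab2 <- fisher_enrichment(clusters, cat_all)
  expect_true(all(tab2$p_value[tab2$category == "X"] == 1))
  # extreme split equals the analytic hypergeometric tail
  cl3 <- setNames(rep(c(1, 2), c(4, 6)), paste0("t", 1:10))
  cat3 <- data.frame(strain_id = paste0("t", 1:4), category = "Z")
  tab3 <- fisher_enrichment(cl3, cat3)
  p_exact <- dhyper(4, 4, 6, 4)  # only the observed table is as extreme
  expect_lt(abs(tab3$p_value[tab3$cluster == 1] -
                  fisher_oracle(4, 0, 0, 6)), 1e-12)
  # randomized margins against the oracle
  withr::with_seed(9, {
    for (i in 1:50) {
      n <- sample(5:30, 1)
      cl <- setNames(sample(1:2, n, replace = TRUE), paste0("r", 1:n))
      if (length(unique(cl)) < 2) next
      members <- sample(names(cl), sample(1:n, 1))
      tab_i <- fisher_enrichment(cl, data.frame(strain_id = members,
                                                category = "C"))
      for (j in seq_len(nrow(tab_i))) {
        o <- fisher_oracle(tab_i$in_with[j], tab_i$in_without[j],
                           tab_i$out_with[j], tab_i$out_without[j])
        expect_lt(abs(tab_i$p_value[j] - o), 1e-12)
      }
    }
  })
  # optional multiple-testing correction
  tabc <- fisher_enrichment(clusters, categories, p_adjust = "bonferroni")
  expect_gte(tabc$p_adjusted[1], tabc$p_value[1])
})
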