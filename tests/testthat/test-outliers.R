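planar_profiles <- function(n = 100, p = 18, k = 2, noise = 1e-3,
                            seed = 1) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(p * k), p)
    matrix(rnorm(n * k), n) %*% t(L) * 3 +
      matrix(rnorm(n * p, 0, noise), n)
  })
}

test_that("the reference model recovers planted dimensionality", {
  X <- planar_profiles(200)
  ref <- fit_reference(X)
  expect_equal(ref$k, 2L)
  # 276 replicates (the reference screen size) are accepted
  X276 <- planar_profiles(276, noise = 0.2, seed = 2)
  expect_silent(ref276 <- fit_reference(X276))
  expect_equal(ref276$n, 276L)
  expect_error(fit_reference(X[1:10, ]), "at least 30")
  # eigenvalues non-negative, non-increasing
  expect_true(all(ref$lambda >= 0))
  expect_true(all(diff(ref$lambda) <= 1e-12))
})

test_that("scores are invariant to loading sign flips", {
  X <- planar_profiles(100, noise = 0.3, seed = 3)
  ref <- fit_reference(X, k = 3)
  flipped <- ref
  flipped$loadings <- -flipped$loadings
  s1 <- score_profiles(ref, X)
  s2 <- score_profiles(flipped, X)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("T2 and SPE match a brute-force reconstruction oracle", {
  withr::with_seed(4, {
    X <- matrix(rnorm(10 * 18), 10)
    Xtr <- matrix(rnorm(60 * 18), 60) %*%
      diag(sqrt(seq(3, 0.2, length.out = 18)))
  })
  ref <- fit_reference(Xtr, k = 4)
  sc <- score_profiles(ref, X)
  # oracle: explicit autoscale, eigendecomposition, reconstruction
  mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  eg <- eigen(cov(sweep(sweep(Xtr, 2, mu), 2, sdv, "/")), symmetric = TRUE)
  P <- eg$vectors[, 1:4]
  for (i in 1:10) {
    t_i <- drop(t(P) %*% Xs[i, ])
    t2_o <- sum(t_i^2 / eg$values[1:4])
    xhat <- drop(P %*% t_i)
    spe_o <- sum((Xs[i, ] - xhat)^2)
    expect_lt(abs(sc$t2[i] - t2_o), 1e-10)
    expect_lt(abs(sc$spe[i] - spe_o), 1e-10)
  }
  # profile at the training mean scores zero on both statistics
  s0 <- score_profiles(ref, matrix(mu, 1))
  expect_equal(s0$t2, 0, tolerance = 1e-20)
  expect_equal(s0$spe, 0, tolerance = 1e-20)
  # a point on the model plane far from the origin: SPE ~ 0, T2 large
  far <- mu + 50 * sdv * drop(eg$vectors[, 1])
  sfar <- score_profiles(ref, matrix(far, 1))
  expect_lt(sfar$spe, 1e-10)
  expect_gt(sfar$t2, 100)
  expect_error(score_profiles(ref, matrix(0, 1, 5)), "does not match")
})

test_that("SPE never increases when more components are retained", {
  Xtr <- planar_profiles(120, k = 6, noise = 0.5, seed = 5)
  X <- planar_profiles(20, k = 6, noise = 0.5, seed = 6)
  spe_by_k <- vapply(1:10, function(k)
    score_profiles(fit_reference(Xtr, k = k), X)$spe, numeric(20))
  expect_true(all(diff(t(spe_by_k)) <= 1e-10))
})

test_that("empirical limits are order-statistic percentiles", {
  withr::with_seed(7, s <- tibble::tibble(t2 = rexp(100), spe = rexp(100)))
  lim <- empirical_limits(s)
  # 99th percentile lies between the two largest order statistics
  o <- sort(s$t2)
  expect_gte(lim$t2[["p99"]], o[99])
  expect_lte(lim$t2[["p99"]], o[100])
  expect_gte(lim$t2[["p99"]], lim$t2[["p95"]])
  # all-equal scores: the limit equals that value
  expect_warning(
    lim2 <- empirical_limits(tibble::tibble(t2 = rep(2, 50),
                                            spe = rep(3, 50))),
    "wild-type scores")
  expect_equal(unname(lim2$t2[["p99"]]), 2)
  expect_equal(unname(lim2$spe[["p95"]]), 3)
  expect_warning(empirical_limits(tibble::tibble(t2 = 1:5, spe = 1:5)),
                 "wild-type scores")
})

test_that("leave-one-out scores exceed resubstitution scores on average", {
  X <- planar_profiles(80, k = 3, noise = 0.6, seed = 8)
  ref <- fit_reference(X, k = 3)
  resub <- score_profiles(ref, X)
  loo <- loo_scores(X, k = 3)
  expect_gt(mean(loo$spe), mean(resub$spe))
  expect_gt(mean(loo$t2), mean(resub$t2))
})

test_that("theoretical limits agree with their distributional
          approximations", {
  lam <- c(5, 3, 1.5, 0.8, 0.5, 0.3, 0.2, 0.1)
  withr::with_seed(9, {
    Xtr <- matrix(rnorm(5000 * 8), 5000) %*% diag(sqrt(lam))
    Xnew <- matrix(rnorm(50000 * 8), 50000) %*% diag(sqrt(lam))
  })
  ref <- fit_reference(Xtr, k = 2)
  sc <- score_profiles(ref, Xnew)
  tl <- theoretical_limits(ref, alpha = 0.01)
  # SPE 99th percentile within 10% of the weighted-chi-squared limit
  expect_lt(abs(quantile(sc$spe, 0.99) / tl$spe[["limit"]] - 1), 0.10)
  # T2 at k = 1, large n approaches the chi-squared quantile
  ref1 <- fit_reference(Xtr, k = 1)
  tl1 <- theoretical_limits(ref1, alpha = 0.01)
  expect_lt(abs(tl1$t2[["limit"]] / qchisq(0.99, 1) - 1), 0.01)
  # alpha = 0.5: limits match distribution medians
  tl5 <- theoretical_limits(ref, alpha = 0.5)
  expect_lt(abs(tl5$t2[["limit"]] / median(sc$t2) - 1), 0.10)
  expect_lt(abs(tl5$spe[["limit"]] / median(sc$spe) - 1), 0.10)
})

test_that("flagging uses a strict beyond-the-limit rule with categories", {
  lim <- structure(list(t2 = c(p95 = 2, p99 = 4), spe = c(p95 = 1, p99 = 3),
                        percentiles = c(95, 99), kind = "empirical"),
                   class = "ms_limits")
  sc <- tibble::tibble(t2 = c(4, 4.1, 5, 1), spe = c(3, 2, 4, 3.5))
  h <- flag_outliers(sc, lim)
  # exactly at the limit is not flagged
  expect_equal(h$flag, c("none", "t2_only", "both", "spe_only"))
  expect_equal(unname(attr(h, "counts")),
               c(1L, 1L, 1L, 1L))
})
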