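# Analytic contour fixtures and shared helpers.

# Closed polygon of a circle (n unclosed vertices).
circle_contour <- function(r = 1, center = c(0, 0), n = 64) {
  t <- 2 * pi * (0:(n - 1)) / n
  cbind(center[1] + r * cos(t), center[2] + r * sin(t))
}

# Radial boundary distance of a spherocylinder (length L, width W,
# centered at origin, long axis x) along direction theta.
.rod_radius <- function(theta, L, W) {
  a <- L / 2 - W / 2
  c <- cos(theta); s <- sin(theta)
  r_edge <- ifelse(abs(s) > 1e-12, (W / 2) / abs(s), -Inf)
  r_edge[abs(r_edge * c) > a] <- -Inf
  D <- (W / 2)^2 - (a * s)^2
  r_cap <- ifelse(D >= 0, a * abs(c) + sqrt(pmax(D, 0)), -Inf)
  pmax(r_edge, r_cap)
}

# Spherocylinder (rod) outline of length L, width W centered at origin.
rod_contour <- function(L = 40, W = 10, n = 200) {
  t <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  r <- .rod_radius(t, L, W)
  cbind(r * cos(t), r * sin(t))
}

# Rod with a mid-cell circular bulge of the given diameter.
bulged_rod_contour <- function(L = 40, W = 10, bulge = 18, n = 400) {
  t <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  r <- pmax(.rod_radius(t, L, W), bulge / 2)
  cbind(r * cos(t), r * sin(t))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

# Digital disc mask in an nx x ny frame.
disc_mask <- function(r = 10, center = c(32, 32), dim = c(64, 64)) {
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (x - center[1])^2 + (y - center[2])^2 <= r^2
}

# Greedy one-to-one centroid matching of segmentation output to ground
# truth; returns c(tp, n_gt, n_pred).
match_to_truth <- function(records, frame, tol = 5) {
  gt <- frame$cells[!frame$cells$clipped & !frame$cells$overlap, ]
  got <- records_table(records)
  tp <- 0
  used <- rep(FALSE, nrow(got))
  for (i in seq_len(nrow(gt))) {
    if (!nrow(got)) break
    d <- sqrt((got$centroid_x + 1 - gt$x[i])^2 +
                (got$centroid_y + 1 - gt$y[i])^2)
    j <- which.min(d)
    if (!used[j] && d[j] < tol) { tp <- tp + 1; used[j] <- TRUE }
  }
  c(tp = tp, n_gt = nrow(gt), n_pred = nrow(got))
}

# Exhaustive two-tailed Fisher oracle: sum of hypergeometric probabilities
# of all tables with the observed margins no more probable than the
# observed table.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  aa <- lo:hi
  pr <- dhyper(aa, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Small labelled training set rendered once per session and reused by the
# classification tests (rendering dominates runtime).
trained_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_classifiers(n_per_class = 40, seed = 42)
    cache
  }
})
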