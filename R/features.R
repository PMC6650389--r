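# Per-cell descriptor vector: 54 features in four blocks.
#
#   shape (22)            geometry of the mask/contour
#   fourier (10)          contour harmonic magnitudes, invariant to
#                         translation, rotation, scale and starting point
#   intensity (12)        statistics of pixel values inside the mask
#   microenvironment (10) cell-vs-surrounding-annulus contrasts
#
# The inventory and order are frozen; downstream models index by name.

.SHAPE_NAMES <- paste0("shape_", c(
  "area", "perimeter", "length", "width", "aspect_ratio", "circularity",
  "solidity", "eccentricity", "extent", "equiv_diameter", "convexity",
  "rectangularity", "radius_mean", "radius_sd", "radius_cv", "radius_max",
  "radius_min", "curvature_mean", "curvature_sd", "curvature_max",
  "bending_energy", "elongation"))
.FOURIER_NAMES <- paste0("four_h", sprintf("%02d", 1:10))
.INTENSITY_NAMES <- paste0("int_", c(
  "mean", "sd", "cv", "min", "max", "q10", "q25", "median", "q75", "q90",
  "iqr", "mad"))
.MICROENV_NAMES <- paste0("env_", c(
  "annulus_mean", "annulus_sd", "annulus_q10", "annulus_q90",
  "contrast_diff", "contrast_ratio", "contrast_norm", "contrast_michelson",
  "halo_strength", "local_snr"))

#' Names of the 54 per-cell descriptors, in frozen order
#' @return Character vector of length 54.
#' @export
feature_names <- function() {
  c(.SHAPE_NAMES, .FOURIER_NAMES, .INTENSITY_NAMES, .MICROENV_NAMES)
}

.close_polygon <- function(pts) {
  if (!all(pts[1, ] == pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  pts
}

#' Resample a closed contour to a fixed number of points by arc length
#'
#' @param contour n x 2 matrix of (x, y) vertices of a simple closed
#'   polygon (unclosed, i.e. last != first).
#' @param n Number of output points.
#' @return n x 2 matrix, uniformly spaced along the polygon's perimeter,
#'   starting at the first input vertex.
#' @export
resample_contour <- function(contour, n = 128) {
  pts <- .close_polygon(as.matrix(contour))
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  out <- matrix(0, n, 2)
  j <- 1
  for (i in seq_len(n)) {
    while (s[j + 1] < target[i]) j <- j + 1
    f <- if (seg[j] > 0) (target[i] - s[j]) / seg[j] else 0
    out[i, ] <- pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
  }
  out
}

#' Shape descriptor block (22 values)
#'
#' Length and width come from the minimum-area enclosing rectangle of the
#' contour (robust under rotation); circularity is 4*pi*A/P^2; curvature
#' summaries are computed on the arc-length-resampled contour.
#'
#' @param cell A `cell_record` (or a list with `contour` and `area`).
#' @return Named numeric vector of length 22.
#' @export
shape_features <- function(cell) {
  ct <- as.matrix(cell$contour)
  if (nrow(ct) <= 3) stop("degenerate contour (<= 3 points)")
  area_px <- if (!is.null(cell$area)) cell$area else
    abs(.polygon_area_signed(ct))
  a_poly <- abs(.polygon_area_signed(ct))
  closed <- .close_polygon(ct)
  per <- sum(sqrt(rowSums(diff(closed)^2)))
  lw <- .min_area_rect(ct)
  len <- lw[["length"]]; wid <- max(lw[["width"]], .Machine$double.eps)
  hull <- ct[rev(grDevices::chull(ct)), , drop = FALSE]
  hull_a <- abs(.polygon_area_signed(hull))
  hull_p <- sum(sqrt(rowSums(diff(.close_polygon(hull))^2)))
  cen <- colMeans(ct)
  rad <- sqrt(rowSums(sweep(ct, 2, cen)^2))
  # second moments of the contour vertices for eccentricity
  cc <- sweep(ct, 2, cen)
  mom <- crossprod(cc) / nrow(cc)
  ev <- sort(eigen(mom, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] > 0) sqrt(pmax(1 - ev[2] / ev[1], 0)) else 0
  bbox <- apply(ct, 2, range)
  bbox_a <- max(prod(bbox[2, ] - bbox[1, ]), .Machine$double.eps)
  k <- .contour_curvature(ct)
  setNames(c(
    area_px, per, len, wid, len / wid,
    4 * pi * a_poly / max(per^2, .Machine$double.eps),
    a_poly / max(hull_a, .Machine$double.eps),
    ecc, a_poly / bbox_a, 2 * sqrt(area_px / pi),
    hull_p / max(per, .Machine$double.eps),
    a_poly / max(len * wid, .Machine$double.eps),
    mean(rad), sd(rad), sd(rad) / max(mean(rad), .Machine$double.eps),
    max(rad), min(rad),
    mean(abs(k)), sd(k), max(abs(k)), mean(k^2),
    1 - wid / max(len, .Machine$double.eps)), .SHAPE_NAMES)
}

# Signed curvature at each point of a resampled closed contour (finite
# differences with light smoothing).
.contour_curvature <- function(ct, n = 128) {
  p <- resample_contour(ct, n)
  sm <- function(v) (v + v[c(2:n, 1)] + v[c(n, 1:(n - 1))]) / 3
  x <- sm(p[, 1]); y <- sm(p[, 2])
  d1x <- (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / 2
  d1y <- (y[c(2:n, 1)] - y[c(n, 1:(n - 1))]) / 2
  d2x <- x[c(2:n, 1)] - 2 * x + x[c(n, 1:(n - 1))]
  d2y <- y[c(2:n, 1)] - 2 * y + y[c(n, 1:(n - 1))]
  denom <- (d1x^2 + d1y^2)^1.5
  k <- (d1x * d2y - d1y * d2x) / pmax(denom, .Machine$double.eps)
  k
}

#' Fourier contour descriptors (10 values)
#'
#' Complex harmonic magnitudes of the arc-length-resampled contour,
#' normalized by the first positive harmonic: invariant to translation (the
#' DC term is dropped), scale (the normalization), rotation and contour
#' starting point (only magnitudes are kept). Contours are re-oriented
#' counter-clockwise so the first positive harmonic dominates.
#'
#' @param contour n x 2 (x, y) matrix of a simple closed polygon.
#' @param n_harmonics Number of descriptors (default 10: magnitudes of
#'   harmonics -5..-1 and +2..+6).
#' @param n_points Resampling density; must exceed `2 * n_harmonics + 2`.
#' @return Named numeric vector of length `n_harmonics`.
#' @export
fourier_descriptors <- function(contour, n_harmonics = 10, n_points = 128) {
  if (2 * n_harmonics + 2 > n_points)
    stop("n_harmonics too large for the resampling density")
  p <- resample_contour(contour, n_points)
  z <- complex(real = p[, 1], imaginary = p[, 2])
  cf <- fft(z) / length(z)
  pos <- function(k) cf[k + 1]              # frequency +k
  neg <- function(k) cf[length(cf) - k + 1] # frequency -k
  if (Mod(neg(1)) > Mod(pos(1))) {          # clockwise contour: reverse
    z <- rev(z)
    cf <- fft(z) / length(z)
  }
  ref <- Mod(pos(1))
  if (ref <= .Machine$double.eps) stop("degenerate contour")
  n_neg <- ceiling(n_harmonics / 2)
  n_pos <- n_harmonics - n_neg
  vals <- c(vapply(seq_len(n_neg), function(k) Mod(neg(k)) / ref, 0),
            vapply(seq_len(n_pos) + 1, function(k) Mod(pos(k)) / ref, 0))
  setNames(vals[seq_len(n_harmonics)],
           paste0("four_h", sprintf("%02d", seq_len(n_harmonics))))
}

#' Intensity descriptor block (12 values)
#'
#' Summary statistics of the pixel values inside the cell mask.
#'
#' @param cell A `cell_record`.
#' @param image The frame the cell was segmented from.
#' @return Named numeric vector of length 12.
#' @export
intensity_features <- function(cell, image) {
  image <- .as_matrix_image(image)
  if (!length(cell$pixels)) stop("empty mask")
  v <- image[cell$pixels]
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  m <- mean(v); s <- sd(v)
  if (is.na(s)) s <- 0
  setNames(c(m, s, s / max(abs(m), .Machine$double.eps), min(v), max(v),
             q[1], q[2], q[3], q[4], q[5], q[4] - q[2],
             mad(v)), .INTENSITY_NAMES)
}

.annulus_pixels <- function(cell, width, exclude = NULL) {
  nx <- cell$dim[1]; ny <- cell$dim[2]
  m <- cell_mask(cell)
  dil <- EBImage::dilate(EBImage::Image(m),
                         EBImage::makeBrush(2 * width + 1, shape = "disc"))
  ann <- which(EBImage::imageData(dil) > 0)
  ann <- setdiff(ann, cell$pixels)
  if (!is.null(exclude)) ann <- setdiff(ann, exclude)
  ann
}

#' Microenvironment descriptor block (10 values)
#'
#' Contrasts between the cell interior and an immediately surrounding
#' annulus (morphological dilation of the mask minus the mask), excluding
#' pixels that belong to neighboring cells. `contrast_norm` (difference over
#' pooled sd) and `local_snr` are invariant to affine intensity maps; the
#' remaining features are covariant as documented.
#'
#' @param cell A `cell_record`.
#' @param image The frame matrix.
#' @param annulus_width Dilation radius in px (default 3).
#' @param neighbor_pixels Optional integer vector of linear pixel indices of
#'   other cells to exclude from the annulus.
#' @return Named numeric vector of length 10. If the annulus is empty all
#'   values are 0 and attribute `"empty_annulus"` is set.
#' @export
microenvironment_features <- function(cell, image, annulus_width = 3,
                                      neighbor_pixels = NULL) {
  image <- .as_matrix_image(image)
  ann <- .annulus_pixels(cell, annulus_width, exclude = neighbor_pixels)
  if (!length(ann))
    return(structure(setNames(rep(0, 10), .MICROENV_NAMES),
                     empty_annulus = TRUE))
  va <- image[ann]; vc <- image[cell$pixels]
  ma <- mean(va); sa <- sd(va); if (is.na(sa)) sa <- 0
  mc <- mean(vc); sc <- sd(vc); if (is.na(sc)) sc <- 0
  qa <- quantile(va, c(0.1, 0.5, 0.9), names = FALSE)
  diff <- ma - mc
  pooled <- sqrt((sa^2 + sc^2) / 2)
  setNames(c(ma, sa, qa[1], qa[3], diff,
             mc / max(ma, .Machine$double.eps),
             diff / max(pooled, .Machine$double.eps),
             diff / max(ma + mc, .Machine$double.eps),
             qa[3] - qa[2],
             diff / max(sa, .Machine$double.eps)), .MICROENV_NAMES)
}

#' Full 54-descriptor feature vector for one cell
#'
#' Concatenates the shape (22), Fourier (10), intensity (12) and
#' microenvironment (10) blocks in the frozen order of [feature_names()].
#'
#' @param cell A `cell_record`.
#' @param image The frame matrix the cell came from.
#' @param annulus_width,neighbor_pixels Passed to
#'   [microenvironment_features()].
#' @return Named numeric vector of length 54.
#' @export
extract_features <- function(cell, image, annulus_width = 3,
                             neighbor_pixels = NULL) {
  v <- c(shape_features(cell),
         fourier_descriptors(cell$contour),
         intensity_features(cell, image),
         microenvironment_features(cell, image, annulus_width,
                                   neighbor_pixels))
  stopifnot(length(v) == 54)
  v
}

#' Feature table for all cells of a frame
#'
#' @param records `cell_record` list from [segment_frame()].
#' @param image Frame matrix.
#' @param meta Optional one-row data.frame of provenance columns (plate,
#'   well, time-point, frame) prepended to every row.
#' @return data.frame: meta columns, label_id, then the 54 feature columns.
#' @export
feature_table <- function(records, image, meta = NULL) {
  if (!length(records)) {
    out <- as.data.frame(matrix(numeric(0), 0, 55))
    names(out) <- c("label_id", feature_names())
    return(out)
  }
  all_pix <- unlist(lapply(records, `[[`, "pixels"))
  rows <- lapply(records, function(r) {
    nb <- setdiff(all_pix, r$pixels)
    c(label_id = r$label_id, extract_features(r, image,
                                              neighbor_pixels = nb))
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(meta)) out <- cbind(meta, out, row.names = NULL)
  out
}
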