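# Single-cell segmentation: contrast enhancement (CLAHE + top-hat),
# permissive binarization, and shape-criteria pruning. Touching cells are
# not split (cells imaged in liquid stay separated); merged blobs are
# removed by the aspect/area criteria instead.

#' Segmentation configuration
#'
#' @param clahe_clip CLAHE clip limit (contrast amplification cap).
#' @param clahe_tile CLAHE tile size in px (frame is divided into
#'   roughly frame/tile contextual regions per axis).
#' @param tophat_radius Radius (px) of the disc structuring element for
#'   top-hat background removal; must exceed the largest cell half-width.
#' @param threshold_nsd Binarization offset: number of robust standard
#'   deviations (MAD) above the background mode of the enhanced image. Kept
#'   deliberately permissive so low-contrast lysed ghosts survive; spurious
#'   regions are removed by pruning.
#' @param min_area,max_area Component area bounds in px^2.
#' @param min_solidity Minimum area/convex-hull-area ratio.
#' @param max_aspect Maximum length/width ratio (removes merged blobs).
#' @param border_policy `"discard"` (default) or `"keep"` for components
#'   touching the frame edge.
#' @return A `seg_config` list.
#' @export
seg_config <- function(clahe_clip = 2, clahe_tile = 64, tophat_radius = 15,
                       threshold_nsd = 4, min_area = 40, max_area = 4000,
                       min_solidity = 0.6, max_aspect = 12,
                       border_policy = c("discard", "keep")) {
  border_policy <- match.arg(border_policy)
  stopifnot(min_area < max_area, min_solidity > 0, min_solidity <= 1,
            tophat_radius > 0, max_aspect >= 1)
  structure(list(clahe_clip = clahe_clip, clahe_tile = clahe_tile,
                 tophat_radius = tophat_radius, threshold_nsd = threshold_nsd,
                 min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity, max_aspect = max_aspect,
                 border_policy = border_policy), class = "seg_config")
}

.as_matrix_image <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix (single grayscale channel)")
  image
}

#' Enhance local contrast of a phase-contrast frame
#'
#' Adaptive histogram equalization (CLAHE) followed by top-hat filtering on
#' the inverted image, so cells (dark on bright background) become bright
#' peaks on a flat near-zero background and slow shading is removed.
#' Deterministic.
#'
#' @param image Numeric matrix in 0..1.
#' @param config A [seg_config()].
#' @return Enhanced numeric matrix, same shape, cells bright.
#' @export
enhance <- function(image, config = seg_config()) {
  image <- .as_matrix_image(image)
  if (diff(range(image)) < .Machine$double.eps) {
    return(image * 0)  # constant image: nothing to enhance
  }
  norm <- EBImage::normalize(EBImage::Image(image))
  # CLAHE is only warranted when illumination is uneven; on an already
  # flat background (e.g. an image that has been enhanced before) it would
  # just amplify noise. Shading is detected as spread of coarse-tile
  # medians.
  tile_med <- function(m, g = 4) {
    ix <- ceiling(seq_len(nrow(m)) / (nrow(m) / g))
    iy <- ceiling(seq_len(ncol(m)) / (ncol(m) / g))
    tapply(m, list(ix[row(m)], iy[col(m)]), median)
  }
  eq <- norm
  if (diff(range(tile_med(EBImage::imageData(norm)))) > 0.05) {
    nx <- max(2, round(dim(image)[1] / config$clahe_tile))
    ny <- max(2, round(dim(image)[2] / config$clahe_tile))
    eq <- EBImage::normalize(EBImage::clahe(norm, nx = nx, ny = ny,
                                            limit = config$clahe_clip))
  }
  # polarity: cells must end up bright; phase-contrast frames arrive dark
  # cells on bright background (median high) and are inverted, an already
  # enhanced image (bright sparse cells, median low) is left alone
  if (median(eq) > 0.5) eq <- 1 - eq
  kern <- EBImage::makeBrush(2 * config$tophat_radius + 1, shape = "disc")
  th <- EBImage::whiteTopHat(eq, kern)
  EBImage::imageData(th)
}

#' Binarize an enhanced frame
#'
#' Threshold a fixed number of robust standard deviations (MAD) above the
#' background mode (median) of the enhanced image. Permissive by design:
#' both high-contrast intact cells and low-contrast lysed ghosts must end up
#' in the foreground; false structure is left to pruning. If the enhanced
#' image arrives with dark objects on a bright background (median above
#' mid-range), polarity is flipped first.
#'
#' @param image Enhanced image from [enhance()].
#' @param config A [seg_config()].
#' @return Logical matrix mask.
#' @export
binarize <- function(image, config = seg_config()) {
  image <- .as_matrix_image(image)
  if (median(image) > mean(range(image))) image <- max(image) - image
  bg <- median(image)
  s <- mad(image)
  if (s < .Machine$double.eps) s <- sd(image)
  mask <- image > bg + config$threshold_nsd * s
  # consolidate fragmented low-contrast objects (lysed ghosts) and fill
  # enclosed holes before component analysis
  m <- EBImage::closing(EBImage::Image(mask),
                        EBImage::makeBrush(5, shape = "disc"))
  mask <- EBImage::imageData(EBImage::fillHull(m)) > 0
  frac <- mean(mask)
  if (frac == 0 || frac == 1)
    warning("binarization produced an all-", if (frac == 1) "foreground"
            else "background", " mask")
  mask
}

# Contour (x, y, 0-based, counter-clockwise) of one labelled component.
# The traced pixel boundary is lightly smoothed (circular moving average)
# to a sub-pixel polygon, removing the staircase bias in perimeter and
# curvature estimates.
.component_contour <- function(labels, id, smooth_window = 5) {
  oc <- EBImage::ocontour(EBImage::Image(labels == id))[[1]]
  ct <- as.matrix(oc)  # EBImage returns 0-based (x, y)
  n <- nrow(ct)
  if (n > 2 * smooth_window) {
    w <- smooth_window
    half <- (w - 1) / 2
    idx <- function(shift) ((seq_len(n) - 1 + shift) %% n) + 1
    acc <- matrix(0, n, 2)
    for (s in -half:half) acc <- acc + ct[idx(s), ]
    ct <- acc / w
  }
  colnames(ct) <- c("x", "y")
  if (nrow(ct) >= 3 && .polygon_area_signed(ct) < 0) ct <- ct[nrow(ct):1, ]
  # the trace runs through boundary-pixel centers: push it half a pixel
  # outward along the local normal so the polygon encloses the mask area
  n <- nrow(ct)
  if (n >= 3) {
    tx <- ct[c(2:n, 1), 1] - ct[c(n, 1:(n - 1)), 1]
    ty <- ct[c(2:n, 1), 2] - ct[c(n, 1:(n - 1)), 2]
    len <- pmax(sqrt(tx^2 + ty^2), .Machine$double.eps)
    ct <- ct + 0.5 * cbind(ty, -tx) / len
  }
  ct
}

.polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Prune labelled components by minimal cell-shape criteria
#'
#' Removes components outside the area bounds, below the solidity floor,
#' above the aspect ceiling (merged blobs), or touching the frame border
#' (under the default discard policy), then traces the survivors' contours.
#' Ordering is deterministic (centroid row-major: y, then x).
#'
#' @param mask Logical matrix from [binarize()].
#' @param config A [seg_config()].
#' @param frame_ref Optional identifier recorded on every record.
#' @return List of `cell_record` objects: label_id, pixels (linear indices),
#'   dim, contour (0-based x,y, counter-clockwise), centroid, area. The
#'   number of components removed per criterion is attached as attribute
#'   `"pruned"`.
#' @export
prune <- function(mask, config = seg_config(), frame_ref = NULL) {
  stopifnot(is.matrix(mask))
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  n <- max(labels)
  if (n == 0) return(structure(list(), pruned = c()))
  nx <- nrow(mask); ny <- ncol(mask)
  records <- list()
  pruned <- c(area = 0L, solidity = 0L, aspect = 0L, border = 0L)
  for (id in seq_len(n)) {
    pix <- which(labels == id)
    area <- length(pix)
    if (area < config$min_area || area > config$max_area) {
      pruned["area"] <- pruned["area"] + 1L; next
    }
    px <- ((pix - 1) %% nx) + 1
    py <- ((pix - 1) %/% nx) + 1
    if (config$border_policy == "discard" &&
        (any(px == 1 | px == nx | py == 1 | py == ny))) {
      pruned["border"] <- pruned["border"] + 1L; next
    }
    ct <- .component_contour(labels, id)
    if (nrow(ct) < 4) { pruned["area"] <- pruned["area"] + 1L; next }
    lw <- .min_area_rect(ct)
    if (lw[1] / max(lw[2], 1) > config$max_aspect) {
      pruned["aspect"] <- pruned["aspect"] + 1L; next
    }
    hull <- ct[rev(grDevices::chull(ct)), , drop = FALSE]
    sol <- abs(.polygon_area_signed(ct)) /
      max(abs(.polygon_area_signed(hull)), 1)
    if (sol < config$min_solidity) {
      pruned["solidity"] <- pruned["solidity"] + 1L; next
    }
    records[[length(records) + 1]] <- structure(list(
      label_id = id, pixels = pix, dim = c(nx, ny), contour = ct,
      centroid = c(x = mean(px) - 1, y = mean(py) - 1),
      area = area, frame_ref = frame_ref), class = "cell_record")
  }
  if (length(records)) {
    ord <- order(vapply(records, function(r) r$centroid["y"], 0),
                 vapply(records, function(r) r$centroid["x"], 0))
    records <- records[ord]
    for (i in seq_along(records)) records[[i]]$label_id <- i
  }
  structure(records, pruned = pruned)
}

# Minimum-area enclosing rectangle (length, width) via rotating calipers
# over the convex hull.
.min_area_rect <- function(pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  m <- nrow(hull)
  if (m < 2) return(c(length = 0, width = 0))
  if (m == 2) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(c(length = d, width = 0))
  }
  best <- c(Inf, Inf, Inf)  # area, length, width
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2)); if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    du <- diff(range(pu)); dv <- diff(range(pv))
    if (du * dv < best[1]) best <- c(du * dv, max(du, dv), min(du, dv))
  }
  c(length = best[2], width = best[3])
}

#' Reconstruct a cell's logical mask
#'
#' @param cell A `cell_record`.
#' @return Logical matrix of the full frame size.
#' @export
cell_mask <- function(cell) {
  m <- matrix(FALSE, cell$dim[1], cell$dim[2])
  m[cell$pixels] <- TRUE
  m
}

#' Segment one frame end to end
#'
#' [enhance()], then [binarize()], then [prune()]; deterministic.
#'
#' @param image Numeric matrix in 0..1 (or an `ms_frame`, whose `$image` is
#'   used).
#' @param config A [seg_config()].
#' @param frame_ref Optional frame identifier.
#' @return List of `cell_record`s as from [prune()].
#' @export
segment_frame <- function(image, config = seg_config(), frame_ref = NULL) {
  if (inherits(image, "ms_frame")) image <- image$image
  prune(binarize(enhance(image, config), config), config, frame_ref)
}

#' Tabulate cell records for CSV export
#'
#' @param records List of `cell_record`s.
#' @return data.frame with label_id, centroid_x, centroid_y, area.
#' @export
records_table <- function(records) {
  if (!length(records))
    return(data.frame(label_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), area = integer()))
  data.frame(
    label_id = vapply(records, `[[`, 0L, "label_id"),
    centroid_x = vapply(records, function(r) unname(r$centroid["x"]), 0),
    centroid_y = vapply(records, function(r) unname(r$centroid["y"]), 0),
    area = vapply(records, `[[`, 0L, "area"))
}
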