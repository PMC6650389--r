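# Synthetic phase-contrast screen generator with ground truth.
#
# Cells are drawn as spherocylinders (rods), ellipses (round cells) or rods
# with a mid-cell Gaussian bulge (deformed); lysed cells are rendered as
# low-contrast, irregular "ghost" outlines. Appearance is the phase-contrast
# convention of dark cell bodies on a bright background with a bright halo
# rim; no optical model is attempted.

#' Default per-class geometry and contrast distributions
#'
#' Lengths and widths are in pixels (roughly 0.16 um/px at 40x so a normal
#' rod of ~24 px is ~3.8 um); contrast is the relative intensity drop of the
#' cell body against local background. The paper-scale taxonomy is six
#' classes: normal, small, elongated, round, deformed (intact) and lysed.
#' Class size distributions are package defaults (exemplars only exist in
#' the source screens), declared here and documented in the vignette.
#'
#' @return Nested list of per-class sampling parameters.
#' @export
default_cell_params <- function() {
  list(
    normal    = list(length = c(24, 2.5), width = c(9, 0.7)),
    small     = list(length = c(14, 1.5), width = c(8, 0.6)),
    elongated = list(length = c(48, 6.0), width = c(9, 0.7)),
    round     = list(diameter = c(14, 1.5), max_aspect = 1.25),
    deformed  = list(length = c(24, 2.5), width = c(9, 0.7),
                     bulge_factor = c(1.6, 2.2)),
    lysed     = list(length = c(26, 3.0), width = c(11, 1.0)),
    contrast  = list(intact = c(0.45, 0.04), lysed = c(0.10, 0.015))
  )
}

#' Default frame rendering / noise parameters
#'
#' @return List with background level, shading amplitude, additive Gaussian
#'   noise sd, halo width (px) and halo gain, all on a 0..1 intensity scale
#'   quantized to 16 bits on output.
#' @export
default_noise_params <- function() {
  list(background = 0.55, shading = 0.04, noise_sd = 0.010,
       halo_width = 2, halo_gain = 0.35, bit_depth = 16)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- x <= lower
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= lower
  }
  x
}

#' Sample the geometry of one synthetic cell
#'
#' @param morph_class One of `"normal"`, `"small"`, `"elongated"`,
#'   `"round"`, `"deformed"`, `"lysed"`.
#' @param params Per-class distributions, see [default_cell_params()].
#' @param centroid Numeric length-2 (x, y) pixel position.
#' @param orientation Angle in radians; default drawn uniformly.
#' @return A `cell_geometry` list: morph_class, centroid, orientation,
#'   length, width, bulge_diameter (0 unless deformed), contrast.
#' @export
sample_cell <- function(morph_class, params = default_cell_params(),
                        centroid = c(0, 0), orientation = NULL) {
  if (!morph_class %in% MS_STATES)
    stop("unknown morphology class: '", morph_class, "' (expected one of ",
         paste(MS_STATES, collapse = ", "), ")")
  p <- params[[morph_class]]
  if (is.null(orientation)) orientation <- runif(1, 0, pi)
  if (morph_class == "round") {
    d <- rnorm_trunc(1, p$diameter[1], p$diameter[2], 2)
    a <- runif(1, 1, p$max_aspect)
    len <- d * sqrt(a); wid <- d / sqrt(a)
  } else {
    len <- rnorm_trunc(1, p$length[1], p$length[2], 3)
    wid <- rnorm_trunc(1, p$width[1], p$width[2], 2)
    if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
  }
  bulge <- 0
  if (morph_class == "deformed")
    bulge <- wid * runif(1, p$bulge_factor[1], p$bulge_factor[2])
  ctr <- params$contrast[[if (morph_class == "lysed") "lysed" else "intact"]]
  structure(list(
    morph_class = morph_class,
    centroid = as.numeric(centroid),
    orientation = orientation,
    length = len, width = wid,
    bulge_diameter = bulge,
    contrast = rnorm_trunc(1, ctr[1], ctr[2], 0.01)
  ), class = "cell_geometry")
}

# Squared distance from grid points to the segment defining a
# spherocylinder's backbone.
.seg_dist2 <- function(px, py, cx, cy, theta, half) {
  dx <- cos(theta); dy <- sin(theta)
  t <- (px - cx) * dx + (py - cy) * dy
  t <- pmin(pmax(t, -half), half)
  (px - (cx + t * dx))^2 + (py - (cy + t * dy))^2
}

# Paint one cell into intensity and label canvases; returns updated canvases
# and whether this cell overlapped an existing one.
.paint_cell <- function(img, labels, cell, id, noise, bg_plane) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- cell$centroid[1]; cy <- cell$centroid[2]
  reach <- cell$length / 2 + max(cell$bulge_diameter / 2, cell$width / 2) +
    noise$halo_width + 2
  x0 <- max(1, floor(cx - reach)); x1 <- min(nx, ceiling(cx + reach))
  y0 <- max(1, floor(cy - reach)); y1 <- min(ny, ceiling(cy + reach))
  if (x0 > x1 || y0 > y1)
    return(list(img = img, labels = labels, overlap = FALSE, painted = 0L))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))

  r <- cell$width / 2
  if (cell$morph_class == "round") {
    # ellipse: normalized radial distance
    dx <- gx - cx; dy <- gy - cy
    u <- dx * cos(cell$orientation) + dy * sin(cell$orientation)
    v <- -dx * sin(cell$orientation) + dy * cos(cell$orientation)
    nd <- sqrt((u / (cell$length / 2))^2 + (v / r)^2)
    d <- (nd - 1) * r          # approximate signed distance, px
    inside <- nd <= 1
  } else {
    half <- max(cell$length / 2 - r, 0)
    d2 <- .seg_dist2(gx, gy, cx, cy, cell$orientation, half)
    dd <- sqrt(d2)
    if (cell$morph_class == "lysed") {
      # irregular ghost outline: radial modulation of the rim
      ang <- atan2(gy - cy, gx - cx)
      ph <- (id * c(1.7, 2.9)) %% (2 * pi)
      rmod <- r * (1 + 0.18 * sin(2 * ang + ph[1]) + 0.12 * sin(5 * ang + ph[2]))
      d <- dd - rmod
    } else {
      d <- dd - r
    }
    inside <- d <= 0
    if (cell$bulge_diameter > 0) {
      db <- sqrt((gx - cx)^2 + (gy - cy)^2) - cell$bulge_diameter / 2
      inside <- inside | db <= 0
      d <- pmin(d, db)
    }
  }
  halo <- !inside & d <= noise$halo_width
  idx <- cbind(gx, gy)
  bgv <- bg_plane[idx]
  body_int <- bgv * (1 - cell$contrast)
  overlap <- any(labels[idx][inside] > 0L)
  img[idx[inside, , drop = FALSE]] <- body_int[inside]
  if (cell$morph_class != "lysed" && any(halo))
    img[idx[halo, , drop = FALSE]] <-
      bgv[halo] * (1 + noise$halo_gain * cell$contrast)
  labels[idx[inside, , drop = FALSE]] <- id
  list(img = img, labels = labels, overlap = overlap, painted = sum(inside))
}

#' Render a phase-contrast-like frame from cell geometries
#'
#' Produces dark cells on a bright, gently shaded background with a bright
#' halo rim around intact cells, additive Gaussian noise, and intensities
#' quantized to the declared bit depth. The painted per-cell label image is
#' returned as ground truth.
#'
#' @param cells List of `cell_geometry` objects (may be empty).
#' @param image_shape Integer length-2, frame size in pixels (x, y).
#' @param noise_params See [default_noise_params()].
#' @return A `ms_frame` list: `image` (numeric matrix in 0..1, first index
#'   x), `labels` (integer label matrix, 0 = background), `cells`
#'   (data.frame of geometries with `clipped` and `overlap` flags).
#' @export
render_frame <- function(cells, image_shape = c(512, 512),
                         noise_params = default_noise_params()) {
  nx <- image_shape[1]; ny <- image_shape[2]
  gxn <- (seq_len(nx) - 1) / max(nx - 1, 1)
  gyn <- (seq_len(ny) - 1) / max(ny - 1, 1)
  bg_plane <- noise_params$background +
    noise_params$shading * (outer(gxn, gyn, function(a, b) a + b) - 1)
  img <- bg_plane
  labels <- matrix(0L, nx, ny)
  meta <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    res <- .paint_cell(img, labels, cl, i, noise_params, bg_plane)
    img <- res$img; labels <- res$labels
    clipped <- cl$centroid[1] - cl$length / 2 < 1 ||
      cl$centroid[1] + cl$length / 2 > nx ||
      cl$centroid[2] - cl$length / 2 < 1 ||
      cl$centroid[2] + cl$length / 2 > ny
    if (res$overlap)
      warning("cell ", i, " overlaps a previously painted cell")
    meta[[i]] <- data.frame(
      cell_id = i, morph_class = cl$morph_class,
      x = cl$centroid[1], y = cl$centroid[2],
      orientation = cl$orientation, length = cl$length, width = cl$width,
      bulge_diameter = cl$bulge_diameter, contrast = cl$contrast,
      clipped = clipped, overlap = res$overlap, painted_px = res$painted)
  }
  img <- img + matrix(rnorm(nx * ny, 0, noise_params$noise_sd), nx, ny)
  levels <- 2^noise_params$bit_depth - 1
  img <- round(pmin(pmax(img, 0), 1) * levels) / levels
  structure(list(image = img, labels = labels,
                 cells = if (length(meta)) do.call(rbind, meta) else
                   data.frame()),
            class = "ms_frame")
}

#' Place cells at random non-overlapping positions and render a frame
#'
#' @param class_counts Named integer vector over cell states, e.g.
#'   `c(normal = 5, lysed = 3)`.
#' @param image_shape,noise_params,params See [render_frame()],
#'   [default_cell_params()].
#' @param min_gap Minimum centroid spacing (px) enforced by rejection
#'   sampling.
#' @return `ms_frame` as in [render_frame()].
#' @export
simulate_frame <- function(class_counts, image_shape = c(512, 512),
                           noise_params = default_noise_params(),
                           params = default_cell_params(), min_gap = 60) {
  classes <- rep(names(class_counts), times = class_counts)
  margin <- 40
  pos <- matrix(numeric(0), 0, 2)
  cells <- list()
  for (cls in classes) {
    for (try in 1:200) {
      xy <- c(runif(1, margin, image_shape[1] - margin),
              runif(1, margin, image_shape[2] - margin))
      if (nrow(pos) == 0 ||
          min(sqrt(rowSums(sweep(pos, 2, xy)^2))) >= min_gap) break
    }
    pos <- rbind(pos, xy)
    cells[[length(cells) + 1]] <- sample_cell(cls, params, centroid = xy)
  }
  render_frame(cells, image_shape, noise_params)
}

#' Number of images to acquire for a well
#'
#' Wells with a sparse pilot image are imaged more: 9 frames when the pilot
#' frame holds fewer than 15 cells, 4 frames otherwise.
#'
#' @param pilot_cell_count Non-negative integer cell count in the pilot
#'   image.
#' @return 9 or 4.
#' @export
acquisition_policy <- function(pilot_cell_count) {
  if (length(pilot_cell_count) != 1 || is.na(pilot_cell_count) ||
      pilot_cell_count < 0 || pilot_cell_count != round(pilot_cell_count))
    stop("pilot_cell_count must be a single non-negative integer")
  if (pilot_cell_count < 15) 9L else 4L
}

#' Wild-type morphological trajectory under beta-lactam action
#'
#' Per-cell state proportions at the three imaging time-points for a strain
#' lysing on the wild-type schedule: rods progressively deform, round up and
#' lyse; by the last time-point most of the population is lysed. Rows are
#' time-points, columns the six mutually exclusive cell states
#' (lysed, normal, round, elongated, small, deformed); rows sum to 1.
#'
#' @return 3 x 6 numeric matrix.
#' @export
wt_trajectory <- function() {
  tr <- rbind(
    c(lysed = 0.15, normal = 0.50, round = 0.08, elongated = 0.07,
      small = 0.05, deformed = 0.15),
    c(lysed = 0.55, normal = 0.15, round = 0.08, elongated = 0.04,
      small = 0.03, deformed = 0.15),
    c(lysed = 0.85, normal = 0.03, round = 0.04, elongated = 0.01,
      small = 0.01, deformed = 0.06))
  rownames(tr) <- paste0("t", 1:3)
  tr
}

#' Deviant-strain trajectory archetypes
#'
#' Three archetypes of atypical antibiotic response: `slow_lysis` (the
#' population stays intact far longer than wild type, breaking the
#' time-lysis correlation), `stable_bulge` (bulged/deformed and round cells
#' accumulate and resist lysis) and `filamentous` (elongation dominates
#' before delayed lysis).
#'
#' @param archetype One of `"slow_lysis"`, `"stable_bulge"`,
#'   `"filamentous"`.
#' @return 3 x 6 trajectory matrix as in [wt_trajectory()].
#' @export
archetype_trajectory <- function(archetype = c("slow_lysis", "stable_bulge",
                                               "filamentous")) {
  archetype <- match.arg(archetype)
  tr <- switch(archetype,
    slow_lysis = rbind(
      c(0.05, 0.62, 0.06, 0.07, 0.05, 0.15),
      c(0.15, 0.52, 0.07, 0.06, 0.04, 0.16),
      c(0.40, 0.35, 0.06, 0.04, 0.02, 0.13)),
    stable_bulge = rbind(
      c(0.08, 0.30, 0.12, 0.04, 0.03, 0.43),
      c(0.25, 0.12, 0.20, 0.02, 0.02, 0.39),
      c(0.50, 0.04, 0.18, 0.01, 0.01, 0.26)),
    filamentous = rbind(
      c(0.10, 0.25, 0.04, 0.45, 0.02, 0.14),
      c(0.40, 0.10, 0.05, 0.30, 0.01, 0.14),
      c(0.75, 0.03, 0.03, 0.12, 0.01, 0.06)))
  dimnames(tr) <- list(paste0("t", 1:3), MS_STATES)
  tr
}

.derive_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647L)

# Loadings of the two latent biological factors on the log class fractions
# (rows: time-points, columns: cell states). The first factor jitters lysis
# timing (a positive draw delays lysis coherently across time-points), the
# second the bulging/deformation propensity. Together they give wild-type
# replicate profiles the low-dimensional correlated variability a PCA
# reference is meant to capture.
.FACTOR_LYSIS <- rbind(
  c(lysed = -0.25, normal = 0.15, round = 0.10, elongated = 0.10,
    small = 0.10, deformed = 0.10),
  c(lysed = -0.45, normal = 0.25, round = 0.15, elongated = 0.15,
    small = 0.15, deformed = 0.15),
  c(lysed = -0.30, normal = 0.15, round = 0.10, elongated = 0.10,
    small = 0.10, deformed = 0.10))
.FACTOR_DEFORM <- rbind(
  c(lysed = 0.00, normal = -0.15, round = 0.20, elongated = -0.05,
    small = -0.05, deformed = 0.30),
  c(lysed = 0.00, normal = -0.10, round = 0.25, elongated = -0.05,
    small = -0.05, deformed = 0.30),
  c(lysed = 0.00, normal = -0.05, round = 0.20, elongated = -0.05,
    small = -0.05, deformed = 0.25))

#' Simulate a full multi-plate screen with known ground truth
#'
#' Generates per-well, per-time-point cell-state counts (and optionally
#' rendered frames) for `n_strains` mutant wells plus `n_wt_replicates`
#' wild-type control wells distributed round-robin over `plates` plates.
#' Plate-level batch effects are injected as additive shifts on log class
#' fractions; well-level biological noise likewise. Deviant strains listed
#' in `effect_spec` follow archetype trajectories.
#'
#' @param n_strains Number of mutant strains (one well each).
#' @param n_wt_replicates Number of wild-type control wells (reference
#'   screens use 276 over three plates).
#' @param plates Number of plates.
#' @param timepoints Number of imaging time-points; values other than 3 are
#'   allowed but flagged since profiles then differ from 18 dimensions.
#' @param effect_spec Named character vector mapping strain ids (e.g.
#'   `"strain0007"`) to archetype names; empty means a null screen.
#' @param effect_severity Length-2 range; each deviant strain draws a fixed
#'   severity from this range and its trajectory is the log-space
#'   interpolation between the wild-type and archetype trajectories
#'   (deletion strains differ in how strongly they deviate; severity 1 is
#'   the full archetype).
#' @param cells_per_well Mean cell count per well at each time-point
#'   (recycled to `timepoints`).
#' @param bio_noise_sd Well-level independent log-fraction noise sd (on top
#'   of the latent-factor variability).
#' @param factor_sd Standard deviations of the two per-well latent
#'   biological factors (lysis timing, deformation propensity) whose fixed
#'   loadings give replicate profiles their correlated variability.
#' @param batch_sd Plate-level log-fraction shift sd.
#' @param seed Integer seed; all randomness derives from it.
#' @param level `"counts"` (default) emits per-well state counts only;
#'   `"frames"` additionally renders frames per the acquisition policy.
#' @param image_shape,noise_params,params Frame rendering controls (only
#'   used for `level = "frames"`).
#' @return A `ms_screen` list: `wells` (data.frame with strain_id, plate_id,
#'   is_wt, archetype, timepoint and one count column per cell state),
#'   `frames` (NULL or nested list), `truth` (trajectories and effect spec),
#'   `seed`.
#' @export
simulate_screen <- function(n_strains, n_wt_replicates = 276, plates = 3,
                            timepoints = 3, effect_spec = character(),
                            effect_severity = c(0.7, 1),
                            cells_per_well = c(173, 155, 164),
                            bio_noise_sd = 0.05, factor_sd = c(1, 1),
                            batch_sd = 0.30,
                            seed = 1, level = c("counts", "frames"),
                            image_shape = c(512, 512),
                            noise_params = default_noise_params(),
                            params = default_cell_params()) {
  level <- match.arg(level)
  if (timepoints != 3)
    warning("timepoints != 3: phenotypic profiles will not be 18-dimensional")
  cells_per_well <- rep_len(cells_per_well, timepoints)
  strain_ids <- sprintf("strain%04d", seq_len(n_strains))
  wt_ids <- sprintf("WT%03d", seq_len(n_wt_replicates))
  if (length(effect_spec) && !all(names(effect_spec) %in% strain_ids))
    stop("effect_spec names must be strain ids")

  wt_tr <- wt_trajectory()
  traj_for <- function(id, severity) {
    if (!id %in% names(effect_spec)) return(wt_tr)
    at <- archetype_trajectory(effect_spec[[id]])
    lp <- (1 - severity) * log(pmax(wt_tr, 1e-6)) +
      severity * log(pmax(at, 1e-6))
    tr <- exp(lp)
    sweep(tr, 1, rowSums(tr), "/")
  }
  all_ids <- c(wt_ids, strain_ids)
  plate_of <- rep_len(sprintf("plate%02d", seq_len(plates)), length(all_ids))

  withr::with_seed(.derive_seed(seed, 0L), {
    # plate x timepoint x state log-fraction offsets
    batch <- array(rnorm(plates * timepoints * 6, 0, batch_sd),
                   dim = c(plates, timepoints, 6))
  })

  rows <- vector("list", length(all_ids) * timepoints)
  frames <- if (level == "frames") list() else NULL
  for (i in seq_along(all_ids)) {
    id <- all_ids[i]
    pl <- match(plate_of[i], sprintf("plate%02d", seq_len(plates)))
    withr::with_seed(.derive_seed(seed, i), {
      sev <- runif(1, effect_severity[1], effect_severity[2])
      tr <- traj_for(id, sev)
      u <- rnorm(2, 0, factor_sd)
      for (tp in seq_len(timepoints)) {
        base <- tr[min(tp, nrow(tr)), ]
        fl <- .FACTOR_LYSIS[min(tp, 3), ]
        fd <- .FACTOR_DEFORM[min(tp, 3), ]
        lp <- log(pmax(base, 1e-6)) + batch[pl, tp, ] +
          u[1] * fl + u[2] * fd + rnorm(6, 0, bio_noise_sd)
        p <- exp(lp); p <- p / sum(p)
        n <- max(rpois(1, cells_per_well[tp]), 1L)
        counts <- as.vector(rmultinom(1, n, p))
        names(counts) <- MS_STATES
        rows[[(i - 1) * timepoints + tp]] <- data.frame(
          strain_id = id, plate_id = plate_of[i],
          is_wt = id %in% wt_ids,
          archetype = if (id %in% names(effect_spec)) effect_spec[[id]]
                      else "none",
          timepoint = tp, n_cells = n, t(counts))
        if (level == "frames") {
          n_img <- acquisition_policy(n)
          per_frame <- diff(round(seq(0, n, length.out = n_img + 1)))
          cells_left <- rep(MS_STATES, times = counts)
          cells_left <- sample(cells_left)
          off <- 0
          fr <- list()
          for (f in seq_len(n_img)) {
            take <- cells_left[seq_len(per_frame[f]) + off]
            off <- off + per_frame[f]
            cc <- table(factor(take, levels = MS_STATES))
            fr[[f]] <- simulate_frame(cc[cc > 0], image_shape,
                                      noise_params, params)
          }
          frames[[paste(id, tp, sep = "_")]] <- fr
        }
      }
    })
  }
  structure(list(
    wells = do.call(rbind, rows), frames = frames,
    truth = list(wt_trajectory = wt_tr, effect_spec = effect_spec,
                 batch = batch),
    seed = seed), class = "ms_screen")
}

#' Write screen frames and ground truth to disk
#'
#' Frames are written as 16-bit grayscale TIFF under
#' `out_dir/plate/well/t<k>/frame<j>.tif`, ground truth as CSV and a JSON
#' run manifest.
#'
#' @param screen A `ms_screen` from [simulate_screen()] with frames.
#' @param out_dir Output directory (created).
#' @return Invisibly, the manifest list.
#' @export
write_screen <- function(screen, out_dir) {
  stopifnot(inherits(screen, "ms_screen"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(screen$wells, file.path(out_dir, "ground_truth_counts.csv"),
            row.names = FALSE)
  n_frames <- 0
  if (!is.null(screen$frames)) {
    for (key in names(screen$frames)) {
      parts <- strsplit(key, "_")[[1]]
      well <- parts[1]; tp <- parts[2]
      wells <- screen$wells
      plate <- wells$plate_id[wells$strain_id == well][1]
      d <- file.path(out_dir, plate, well, paste0("t", tp))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (f in seq_along(screen$frames[[key]])) {
        fr <- screen$frames[[key]][[f]]
        EBImage::writeImage(EBImage::Image(fr$image),
                            file.path(d, sprintf("frame%02d.tif", f)),
                            type = "tiff", bits.per.sample = 16L)
        write.csv(fr$cells,
                  file.path(d, sprintf("frame%02d_truth.csv", f)),
                  row.names = FALSE)
        n_frames <- n_frames + 1
      }
    }
  }
  manifest <- list(seed = screen$seed, n_wells = nrow(screen$wells),
                   n_frames = n_frames,
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
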