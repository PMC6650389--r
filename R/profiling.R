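# Per-well aggregation of cell labels into morphology-category proportions,
# assembly of the 18-dimensional phenotypic profile (6 categories x 3
# time-points), per-plate batch correction, and well-level QC.
#
# All proportions use the whole population (intact + lysed) as denominator,
# so normal + round + elongated + small + deformed = intact for every well.

#' Summarize one well/time-point from per-cell labels
#'
#' @param labels Character vector of final cell labels (lysed, normal,
#'   round, elongated, small, deformed).
#' @param strain_id,plate_id,timepoint Provenance.
#' @param frame_counts Optional integer vector of per-frame cell counts
#'   (used by [qc_wells()]).
#' @return One-row data.frame: provenance, `n_cells`, `max_frame_count`, and
#'   the six category proportions (over all cells, lysed included). Zero
#'   cells yield NA proportions and `qc_pass = FALSE`.
#' @export
summarize_well <- function(labels, strain_id = NA_character_,
                           plate_id = NA_character_, timepoint = 1L,
                           frame_counts = NULL) {
  bad <- setdiff(labels, MS_STATES)
  if (length(bad))
    stop("unknown label(s): ", paste(unique(bad), collapse = ", "))
  n <- length(labels)
  if (n == 0) {
    props <- setNames(rep(NA_real_, 6), MS_CATEGORIES)
  } else {
    counts <- table(factor(labels, levels = MS_STATES))
    morphs <- counts[MS_MORPHS] / n
    deformed <- counts[["deformed"]] / n
    intact <- 1 - counts[["lysed"]] / n
    props <- c(intact = intact, morphs[c("normal", "round", "elongated",
                                         "small")], deformed = deformed)
    names(props) <- MS_CATEGORIES
  }
  mf <- if (is.null(frame_counts)) n else max(frame_counts)
  cbind(data.frame(strain_id = strain_id, plate_id = plate_id,
                   timepoint = as.integer(timepoint), n_cells = n,
                   max_frame_count = mf),
        as.data.frame(as.list(props)))
}

#' Assemble an 18-dimensional phenotypic profile
#'
#' @param summaries data.frame of three [summarize_well()] rows for the same
#'   strain/well at three distinct time-points (any input order; sorted by
#'   time internally).
#' @return Named numeric vector of length 18: categories in the order
#'   intact, normal, round, elongated, small, deformed within each
#'   time-point, time-points ascending (`intact_t1` ... `deformed_t3`).
#' @export
build_profile <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) != 3)
    stop("expected 3 time-points, got ", nrow(summaries))
  if (length(unique(summaries$timepoint)) != 3)
    stop("time-points must be distinct")
  if (length(unique(summaries$strain_id)) != 1)
    stop("summaries mix strains")
  if (anyNA(summaries[, MS_CATEGORIES]))
    stop("missing (NA) proportions: wells with zero cells cannot form a ",
         "profile")
  s <- summaries[order(summaries$timepoint), ]
  vals <- as.numeric(t(as.matrix(s[, MS_CATEGORIES])))
  names(vals) <- paste0(rep(MS_CATEGORIES, times = 3), "_t",
                        rep(1:3, each = 6))
  vals
}

#' Profile column names in frozen order
#' @return Character vector of length 18.
#' @export
profile_names <- function() {
  paste0(rep(MS_CATEGORIES, times = 3), "_t", rep(1:3, each = 6))
}

#' Per-plate batch correction of phenotypic profiles
#'
#' Within each plate, every profile variable is centered and scaled to unit
#' standard deviation using all wells on that plate. Variables with zero
#' variance on a plate are centered only (scale 1) with a warning.
#'
#' @param profiles Numeric matrix (wells x 18) of profiles.
#' @param plate Plate id per row.
#' @return Corrected matrix of the same shape; per-plate means/sds attached
#'   as attribute `"plate_stats"`.
#' @export
batch_correct <- function(profiles, plate) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(plate))
  out <- profiles
  stats <- list()
  for (pl in unique(plate)) {
    idx <- plate == pl
    if (sum(idx) < 2)
      stop("plate '", pl, "' has fewer than 2 wells")
    mu <- colMeans(profiles[idx, , drop = FALSE])
    sdv <- apply(profiles[idx, , drop = FALSE], 2, sd)
    zero <- sdv < .Machine$double.eps
    if (any(zero)) {
      warning("plate '", pl, "': zero-variance variable(s) ",
              paste(colnames(profiles)[zero], collapse = ", "),
              " centered but not scaled")
      sdv[zero] <- 1
    }
    out[idx, ] <- sweep(sweep(profiles[idx, , drop = FALSE], 2, mu), 2,
                        sdv, "/")
    stats[[pl]] <- list(mean = mu, sd = sdv)
  }
  attr(out, "plate_stats") <- stats
  out
}

#' Well-level quality control
#'
#' A well fails iff its total cell count over all frames and time-points is
#' below 50 or any single frame holds more than 150 cells; failing wells are
#' listed for repetition.
#'
#' @param counts data.frame with columns `well` (or `strain_id`) and
#'   `frame_count`, one row per frame.
#' @param min_total Minimum total cells per well (default 50, inclusive).
#' @param max_per_frame Maximum cells per frame (default 150, inclusive).
#' @return `tibble`: well, total_cells, max_frame_count, pass, reason.
#' @export
qc_wells <- function(counts, min_total = 50, max_per_frame = 150) {
  well_col <- if ("well" %in% names(counts)) "well" else "strain_id"
  stopifnot(well_col %in% names(counts), "frame_count" %in% names(counts))
  wells <- unique(counts[[well_col]])
  rows <- lapply(wells, function(w) {
    fc <- counts$frame_count[counts[[well_col]] == w]
    total <- sum(fc); mx <- max(fc)
    low <- total < min_total; high <- mx > max_per_frame
    reason <- if (low && high) "too few cells; overcrowded frame"
      else if (low) "too few cells"
      else if (high) "overcrowded frame"
      else ""
    data.frame(well = w, total_cells = total, max_frame_count = mx,
               pass = !(low || high), reason = reason)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Build profiles for every strain of a simulated screen
#'
#' Converts the per-well state counts of a [simulate_screen()] result into
#' well summaries and 18-dimensional profiles.
#'
#' @param screen A `ms_screen`.
#' @return List: `profiles` (matrix strains x 18), `plate` (plate id per
#'   row), `is_wt`, `archetype`, `strain_id`.
#' @export
screen_profiles <- function(screen) {
  stopifnot(inherits(screen, "ms_screen"))
  w <- screen$wells
  ids <- unique(w$strain_id)
  if (length(unique(w$timepoint)) != 3)
    stop("expected 3 time-points, got ", length(unique(w$timepoint)))
  counts <- as.matrix(w[, MS_STATES])
  n <- rowSums(counts)
  if (any(n == 0)) stop("well(s) with zero cells cannot form profiles")
  props <- cbind(intact = 1 - counts[, "lysed"] / n,
                 counts[, c("normal", "round", "elongated", "small",
                            "deformed")] / n)
  profs <- matrix(NA_real_, length(ids), 18,
                  dimnames = list(ids, profile_names()))
  row_of <- match(w$strain_id, ids)
  for (tp in 1:3) {
    sel <- w$timepoint == tp
    profs[row_of[sel], (tp - 1) * 6 + 1:6] <- props[sel, ]
  }
  if (anyNA(profs)) stop("missing strain/time-point combinations")
  meta <- w[!duplicated(w$strain_id),
            c("strain_id", "plate_id", "is_wt", "archetype")]
  list(profiles = profs, plate = meta$plate_id, is_wt = meta$is_wt,
       archetype = meta$archetype, strain_id = meta$strain_id)
}
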