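# End-to-end orchestration: simulate -> (segment -> features -> classify)
# -> profile -> batch-correct -> screen -> cluster, with config validation
# and a JSON run manifest. Intermediate artifacts are flat CSV/JSON.

#' Default run configuration
#'
#' @param seed Integer seed for every stochastic stage.
#' @param out Output directory or `NULL` for in-memory results only.
#' @return Nested `run_config` list; see [validate_config()] for the schema.
#' @export
default_config <- function(seed = 1, out = NULL) {
  structure(list(
    seed = seed,
    out = out,
    screen = list(n_strains = 12, n_wt_replicates = 36, plates = 3,
                  timepoints = 3, effect_spec = character(),
                  cells_per_well = c(173, 155, 164),
                  bio_noise_sd = 0.05, batch_sd = 0.30,
                  level = "counts", image_shape = c(512, 512)),
    segmentation = unclass(seg_config()),
    features = list(annulus_width = 3),
    classification = list(n_components = 3,
                          k_by_class = default_simca_components(),
                          alpha = 0.05, train_per_class = 60),
    outliers = list(k_rule = "kaiser", var_explained = 0.90,
                    percentile = 99, limit_scores = "loo"),
    clustering = list(k_range = 2:8, n_restarts = 50, min_flagged = 6)
  ), class = "run_config")
}

.CONFIG_KEYS <- list(
  top = c("seed", "out", "screen", "segmentation", "features",
          "classification", "outliers", "clustering"),
  screen = c("n_strains", "n_wt_replicates", "plates", "timepoints",
             "effect_spec", "cells_per_well", "bio_noise_sd", "batch_sd",
             "level", "image_shape"),
  segmentation = c("clahe_clip", "clahe_tile", "tophat_radius",
                   "threshold_nsd", "min_area", "max_area", "min_solidity",
                   "max_aspect", "border_policy"),
  features = "annulus_width",
  classification = c("n_components", "k_by_class", "alpha",
                     "train_per_class"),
  outliers = c("k_rule", "var_explained", "percentile", "limit_scores"),
  clustering = c("k_range", "n_restarts", "min_flagged"))

#' Validate a run configuration
#'
#' Schema check (unknown keys rejected) plus cross-field checks. Errors are
#' aggregated into one human-readable report.
#'
#' @param config A `run_config` list.
#' @return Invisibly TRUE; stops with the aggregated report on failure.
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  unknown <- setdiff(names(config), .CONFIG_KEYS$top)
  chk(!length(unknown),
      paste("unknown top-level key(s):", paste(unknown, collapse = ", ")))
  for (sec in c("screen", "segmentation", "features", "classification",
                "outliers", "clustering")) {
    if (!is.list(config[[sec]])) { chk(FALSE, paste(sec, "must be a list"))
      next }
    u <- setdiff(names(config[[sec]]), .CONFIG_KEYS[[sec]])
    chk(!length(u), paste0("unknown key(s) in ", sec, ": ",
                           paste(u, collapse = ", ")))
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be a
      single number")
  sc <- config$screen
  if (is.list(sc)) {
    chk(isTRUE(sc$n_strains >= 1), "screen$n_strains must be >= 1")
    chk(isTRUE(sc$plates >= 1), "screen$plates must be >= 1")
    es <- sc$effect_spec
    chk(length(es) == 0 || !is.null(names(es)),
        "screen$effect_spec must be a named vector (strain -> archetype)")
  }
  sg <- config$segmentation
  if (is.list(sg)) {
    chk(isTRUE(sg$tophat_radius > 0), "segmentation$tophat_radius must be
        positive")
    chk(isTRUE(sg$min_area < sg$max_area),
        "segmentation$min_area must be below max_area")
    chk(isTRUE(sg$min_solidity > 0 && sg$min_solidity <= 1),
        "segmentation$min_solidity must be in (0, 1]")
  }
  cl <- config$classification
  if (is.list(cl)) {
    chk(all(cl$k_by_class >= 1), "classification$k_by_class must be
        positive")
    chk(isTRUE(cl$n_components >= 1), "classification$n_components must be
        >= 1")
  }
  if (length(errs))
    stop("invalid configuration:\n  - ",
         paste(gsub("\\s+", " ", errs), collapse = "\n  - "))
  invisible(TRUE)
}

#' Train PLS-DA and SIMCA models on a labelled synthetic cell set
#'
#' Renders single-class frames per cell state, segments them, extracts
#' features, and fits the two classifiers: PLS-DA on lysed vs intact (all
#' five intact classes pooled) and SIMCA on the four target morphology
#' classes (deformed cells are deliberately excluded so they fall outside
#' every class region at prediction time).
#'
#' @param n_per_class Training cells per state (default 60).
#' @param seed Integer seed.
#' @param config Segmentation config.
#' @param n_components,k_by_class,alpha Classifier parameters.
#' @return List: `plsda`, `simca`, `features` (training table with a
#'   `true_class` column).
#' @export
train_classifiers <- function(n_per_class = 60, seed = 1,
                              config = seg_config(), n_components = 3,
                              k_by_class = default_simca_components(),
                              alpha = 0.05) {
  tabs <- list()
  withr::with_seed(seed, {
    for (cls in MS_STATES) {
      got <- 0; guard <- 0
      while (got < n_per_class && guard < 100) {
        guard <- guard + 1
        fr <- simulate_frame(setNames(8, cls))
        recs <- segment_frame(fr, config)
        if (!length(recs)) next
        ft <- feature_table(recs, fr$image)
        ft$true_class <- cls
        take <- min(nrow(ft), n_per_class - got)
        tabs[[length(tabs) + 1]] <- ft[seq_len(take), ]
        got <- got + take
      }
    }
  })
  train <- do.call(rbind, tabs)
  X <- as.matrix(train[, feature_names()])
  y_bin <- ifelse(train$true_class == "lysed", "lysed", "intact")
  plsda <- fit_plsda(X, y_bin, n_components = n_components)
  morph <- train$true_class %in% MS_MORPHS
  Xb <- split.data.frame(X[morph, , drop = FALSE], train$true_class[morph])
  simca <- fit_simca(Xb, k_by_class = k_by_class, alpha = alpha)
  list(plsda = plsda, simca = simca, features = train)
}

#' Run a full screen end to end
#'
#' Simulates a screen from the config, builds (or classifies, for
#' frame-level runs) per-cell labels, assembles and batch-corrects the
#' phenotypic profiles, fits the wild-type reference, flags atypical
#' strains at the configured percentile, clusters the flagged profiles, and
#' (when `config$out` is set) writes all stage outputs plus a JSON
#' manifest.
#'
#' @param config A `run_config`, see [default_config()].
#' @return A `screen_result` list: `profiles`, `corrected`, `reference`,
#'   `scores`, `limits`, `hits`, `clusters`, `qc`, `config`.
#' @export
run_screen <- function(config = default_config()) {
  validate_config(config)
  sc <- config$screen
  screen <- simulate_screen(
    n_strains = sc$n_strains, n_wt_replicates = sc$n_wt_replicates,
    plates = sc$plates, timepoints = sc$timepoints,
    effect_spec = sc$effect_spec, cells_per_well = sc$cells_per_well,
    bio_noise_sd = sc$bio_noise_sd, batch_sd = sc$batch_sd,
    seed = config$seed, level = sc$level, image_shape = sc$image_shape)
  if (sc$timepoints != 3)
    stop("profile stage requires exactly 3 time-points, got ",
         sc$timepoints)

  if (sc$level == "frames") {
    seg_cfg <- do.call(seg_config, config$segmentation)
    models <- train_classifiers(
      n_per_class = config$classification$train_per_class,
      seed = config$seed + 1, config = seg_cfg,
      n_components = config$classification$n_components,
      k_by_class = config$classification$k_by_class,
      alpha = config$classification$alpha)
    prof <- .profiles_from_frames(screen, seg_cfg, models)
  } else {
    prof <- screen_profiles(screen)
  }

  qc <- qc_wells(data.frame(strain_id = screen$wells$strain_id,
                            frame_count = screen$wells$n_cells))
  corrected <- batch_correct(prof$profiles, prof$plate)
  ref <- fit_reference(corrected[prof$is_wt, , drop = FALSE],
                       k_rule = config$outliers$k_rule,
                       var_explained = config$outliers$var_explained)
  wt_scores <- if (identical(config$outliers$limit_scores,
                             "resubstitution"))
    score_profiles(ref, corrected[prof$is_wt, , drop = FALSE])
  else loo_scores(corrected[prof$is_wt, , drop = FALSE], ref$k)
  limits <- empirical_limits(wt_scores)
  mut <- !prof$is_wt
  scores <- score_profiles(ref, corrected[mut, , drop = FALSE])
  hits <- flag_outliers(scores, limits,
                        strain_id = prof$strain_id[mut],
                        percentile = config$outliers$percentile)
  flagged <- hits$strain_id[hits$flag != "none"]
  clusters <- NULL
  if (length(flagged) >= config$clustering$min_flagged) {
    Xf <- corrected[match(flagged, prof$strain_id), , drop = FALSE]
    rownames(Xf) <- flagged
    clusters <- select_k_by_silhouette(Xf,
                                       k_range = config$clustering$k_range,
                                       n_restarts =
                                         config$clustering$n_restarts,
                                       seed = config$seed)
  }
  result <- structure(list(
    profiles = prof, corrected = corrected, reference = ref,
    wt_scores = wt_scores, scores = scores, limits = limits, hits = hits,
    clusters = clusters, qc = qc, config = config,
    truth = screen$truth), class = "screen_result")
  if (!is.null(config$out)) .write_screen_result(result, config$out)
  result
}

.profiles_from_frames <- function(screen, seg_cfg, models) {
  w <- screen$wells
  ids <- unique(w$strain_id)
  profs <- matrix(NA_real_, length(ids), 18,
                  dimnames = list(ids, profile_names()))
  meta <- w[!duplicated(w$strain_id),
            c("strain_id", "plate_id", "is_wt", "archetype")]
  for (i in seq_along(ids)) {
    sums <- list()
    for (tp in sort(unique(w$timepoint))) {
      frames <- screen$frames[[paste(ids[i], tp, sep = "_")]]
      labels <- character()
      for (fr in frames) {
        recs <- segment_frame(fr, seg_cfg)
        if (!length(recs)) next
        ft <- feature_table(recs, fr$image)
        labels <- c(labels, classify_cells(models$plsda, models$simca,
                                           as.matrix(ft[, feature_names()])))
      }
      sums[[tp]] <- summarize_well(labels, ids[i],
                                   meta$plate_id[meta$strain_id == ids[i]],
                                   tp)
    }
    profs[i, ] <- build_profile(do.call(rbind, sums))
  }
  list(profiles = profs, plate = meta$plate_id, is_wt = meta$is_wt,
       archetype = meta$archetype, strain_id = meta$strain_id)
}

.write_screen_result <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prof_df <- data.frame(strain_id = result$profiles$strain_id,
                        plate_id = result$profiles$plate,
                        is_wt = result$profiles$is_wt,
                        result$profiles$profiles, row.names = NULL)
  write.csv(prof_df, file.path(out, "profiles.csv"), row.names = FALSE)
  corr_df <- prof_df
  corr_df[, profile_names()] <- result$corrected
  write.csv(corr_df, file.path(out, "profiles_corrected.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$hits), file.path(out, "hits.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$qc), file.path(out, "qc.csv"),
            row.names = FALSE)
  if (!is.null(result$clusters) && result$clusters$structure) {
    cl <- result$clusters
    write.csv(data.frame(strain_id = rownames(cl$embedding),
                         cluster = cl$assignment,
                         silhouette = cl$silhouette,
                         PC1 = cl$embedding[, 1], PC2 = cl$embedding[, 2]),
              file.path(out, "clusters.csv"), row.names = FALSE)
  }
  manifest <- list(
    seed = result$config$seed,
    k_reference = result$reference$k,
    limits = attr(result$hits, "limits"),
    flag_counts = as.list(attr(result$hits, "counts")),
    selected_k = if (!is.null(result$clusters)) result$clusters$k else NA,
    parameters = result$config[c("segmentation", "features",
                                 "classification", "outliers",
                                 "clustering")])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
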