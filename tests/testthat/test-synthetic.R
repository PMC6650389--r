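test_that("sampled geometries respect their class definitions", {
  set.seed(1)
  rnd <- sample_cell("round")
  expect_lte(rnd$length / rnd$width, 1.3)
  def <- sample_cell("deformed")
  expect_gt(def$bulge_diameter, def$width)
  expect_error(sample_cell("banana"), "unknown morphology class")
  # class size ordering under defaults, Monte Carlo over the sampling
  # distributions
  set.seed(2)
  len <- function(cls) mean(vapply(1:1000,
                                   function(i) sample_cell(cls)$length, 0))
  m_small <- len("small"); m_normal <- len("normal"); m_elong <- len("elongated")
  expect_gt(m_elong, m_normal)
  expect_gt(m_normal, m_small)
  # lysed ghosts are low-contrast relative to intact cells
  set.seed(3)
  c_lys <- mean(vapply(1:200, function(i) sample_cell("lysed")$contrast, 0))
  c_int <- mean(vapply(1:200, function(i) sample_cell("normal")$contrast, 0))
  expect_lt(c_lys, c_int)
  # length >= width always
  set.seed(4)
  for (cls in c("normal", "small", "elongated", "round", "deformed",
                "lysed")) {
    g <- sample_cell(cls)
    expect_gte(g$length, g$width)
    expect_gt(g$width, 0)
  }
})

test_that("rendered frames carry per-cell ground truth", {
  # empty frame: background + noise only
  set.seed(1)
  fr <- render_frame(list(), image_shape = c(256, 256))
  np <- default_noise_params()
  expect_equal(dim(fr$image), c(256, 256))
  expect_true(all(fr$labels == 0))
  expect_lt(abs(mean(fr$image) - np$background), 0.02)
  expect_lt(sd(fr$image), np$noise_sd + np$shading)
  # one rod: one connected component
  set.seed(2)
  cell <- sample_cell("normal", centroid = c(128, 128))
  fr1 <- render_frame(list(cell), image_shape = c(256, 256))
  lab <- EBImage::bwlabel(EBImage::Image(fr1$labels > 0))
  expect_equal(max(lab), 1)
  # ten non-overlapping rods: ten ground-truth components
  set.seed(3)
  fr10 <- simulate_frame(c(normal = 10))
  lab10 <- EBImage::bwlabel(EBImage::Image(fr10$labels > 0))
  expect_equal(max(lab10), 10)
  expect_equal(nrow(fr10$cells), 10)
  # intensities quantized within the declared bit depth
  expect_true(all(fr10$image >= 0 & fr10$image <= 1))
  expect_true(all(abs(fr10$image * 65535 -
                        round(fr10$image * 65535)) < 1e-9))
})

test_that("fixed seed reproduces frames and screens bit for bit", {
  f <- function() {
    set.seed(7)
    simulate_frame(c(normal = 3, lysed = 2))
  }
  a <- f(); b <- f()
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  s1 <- simulate_screen(n_strains = 5, n_wt_replicates = 4, plates = 2,
                        seed = 3)
  s2 <- simulate_screen(n_strains = 5, n_wt_replicates = 4, plates = 2,
                        seed = 3)
  expect_identical(s1$wells, s2$wells)
})

test_that("acquisition policy takes 9 sparse-well images, else 4", {
  expect_equal(acquisition_policy(14), 9L)
  expect_equal(acquisition_policy(15), 4L)
  expect_equal(acquisition_policy(0), 9L)
  expect_equal(acquisition_policy(1000), 4L)
  expect_error(acquisition_policy(-1), "non-negative")
})

test_that("wild-type trajectory lyses over time; proportions are coherent", {
  tr <- wt_trajectory()
  expect_equal(unname(rowSums(tr)), rep(1, 3))
  intact <- 1 - tr[, "lysed"]
  expect_true(all(diff(intact) < 0))
  for (a in c("slow_lysis", "stable_bulge", "filamentous")) {
    ta <- archetype_trajectory(a)
    expect_equal(unname(rowSums(ta)), rep(1, 3), tolerance = 1e-12)
  }
  # slow lysis stays more intact than wild type at every time-point
  expect_true(all(archetype_trajectory("slow_lysis")[, "lysed"] <
                    tr[, "lysed"]))
})

test_that("simulated wells converge to their trajectory proportions", {
  scr <- simulate_screen(n_strains = 1, n_wt_replicates = 1, plates = 1,
                         cells_per_well = 20000, bio_noise_sd = 0,
                         factor_sd = c(0, 0), batch_sd = 0, seed = 1)
  w <- scr$wells[scr$wells$is_wt, ]
  tr <- wt_trajectory()
  for (tp in 1:3) {
    counts <- as.numeric(w[w$timepoint == tp,
                           c("lysed", "normal", "round", "elongated",
                             "small", "deformed")])
    expect_equal(counts / sum(counts), unname(tr[tp, ]), tolerance = 0.02)
  }
  # intact fraction decreases across the three time-points
  intact <- 1 - w$lysed / w$n_cells
  expect_true(all(diff(intact[order(w$timepoint)]) < 0))
})

test_that("plate batch offsets shift raw fractions and correction removes
          them", {
  scr <- simulate_screen(n_strains = 0, n_wt_replicates = 240, plates = 3,
                         batch_sd = 0.5, seed = 8)
  prof <- screen_profiles(scr)
  raw_means <- aggregate(prof$profiles, by = list(plate = prof$plate),
                         mean)[, -1]
  # per-plate means of raw fractions differ
  spread_raw <- max(apply(raw_means, 2, function(x) diff(range(x))))
  expect_gt(spread_raw, 0.02)
  corr <- batch_correct(prof$profiles, prof$plate)
  cor_means <- aggregate(corr, by = list(plate = prof$plate), mean)[, -1]
  expect_lt(max(abs(as.matrix(cor_means))), 1e-12)
})

test_that("non-standard time-point counts are allowed but flagged", {
  expect_warning(simulate_screen(n_strains = 1, n_wt_replicates = 1,
                                 plates = 1, timepoints = 2, seed = 1),
                 "18-dimensional")
})

test_that("screens round-trip to disk as TIFF + CSV + manifest", {
  out <- withr::local_tempdir()
  scr <- simulate_screen(n_strains = 1, n_wt_replicates = 1, plates = 1,
                         cells_per_well = 12, seed = 4, level = "frames")
  man <- write_screen(scr, out)
  expect_true(file.exists(file.path(out, "ground_truth_counts.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  tifs <- list.files(out, pattern = "\\.tif$", recursive = TRUE,
                     full.names = TRUE)
  expect_gt(length(tifs), 0)
  img <- EBImage::readImage(tifs[1])
  key <- names(scr$frames)[1]
  orig <- scr$frames[[key]][[1]]$image
  expect_equal(dim(EBImage::imageData(img)), dim(orig))
  expect_lt(max(abs(EBImage::imageData(img) - orig)), 2 / 65535)
})
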