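test_that("concentric-disk features match the analytic values", {
  H <- 64
  cell <- disk_mask(H, H, 32, 32, 10)
  nuc <- disk_mask(H, H, 32, 32, 5)
  cl <- matrix(0L, H, H); cl[cell] <- 1L
  nl <- matrix(0L, H, H); nl[nuc] <- 1L
  arr <- array(0.01, dim = c(H, H, 4))
  arr[, , 1][nuc] <- 0.8
  arr[, , 2][cell] <- 100
  fe <- extract_features(manual_segmentation(cl, nl, um_per_px = 1),
                         manual_frame(arr, um_per_px = 1))
  expect_equal(fe$cell_eccentricity, 0, tolerance = 0.05)
  expect_equal(fe$nuclear_to_cell_area_ratio, 0.25, tolerance = 0.03)
  expect_equal(fe$mean_outline_to_nucleus_center_distance_um, 10,
               tolerance = 0.3)
  expect_equal(fe$cell_area_um2, pi * 100, tolerance = pi * 100 * 0.02)
  expect_equal(fe$ck_median_intensity, 100)
  expect_equal(fe$dapi_median_intensity, 0.8)
  expect_equal(fe$cell_circularity, 1, tolerance = 0.03)
})

test_that("rasterized ellipse eccentricity matches sqrt(1-(b/a)^2)", {
  H <- 96
  m <- disk_mask(H, H, 48, 48, 20, 10, theta = 0.4)
  cl <- matrix(0L, H, H); cl[m] <- 1L
  arr <- array(0.01, dim = c(H, H, 4))
  fe <- extract_features(manual_segmentation(cl, matrix(0L, H, H)),
                         manual_frame(arr)) # DAPI-negative: nucleus empty
  expect_equal(fe$cell_eccentricity, sqrt(1 - (10 / 20)^2), tolerance = 0.02)
  expect_true(fe$nucleus_missing)
  expect_equal(fe$nucleus_area_um2, 0)
  expect_equal(fe$cell_circularity, 0.5, tolerance = 0.03) # minor/major
})

test_that("features are invariant to translation and 90-degree rotation", {
  H <- 96
  build <- function(cy, cx, rot = FALSE) {
    cell <- disk_mask(H, H, cy, cx, 14, 8, theta = 0.3)
    nuc <- disk_mask(H, H, cy, cx, 9, 5, theta = 0.3)
    cl <- matrix(0L, H, H); cl[cell] <- 1L
    nl <- matrix(0L, H, H); nl[nuc] <- 1L
    arr <- array(0.01, dim = c(H, H, 4))
    arr[, , 1][nuc] <- 0.7; arr[, , 2][cell] <- 0.5
    if (rot) {
      rot90 <- function(m) t(m)[, nrow(m):1]
      cl <- rot90(cl); nl <- rot90(nl)
      arr2 <- array(0.01, dim = c(H, H, 4))
      for (ci in 1:4) arr2[, , ci] <- rot90(arr[, , ci])
      arr <- arr2
    }
    extract_features(manual_segmentation(cl, nl), manual_frame(arr))
  }
  ref <- build(40, 40)
  shifted <- build(55, 30)
  rotated <- build(40, 40, rot = TRUE)
  cols <- c("cell_area_um2", "nucleus_area_um2", "cell_eccentricity",
            "nuclear_to_cell_area_ratio",
            "mean_outline_to_nucleus_center_distance_um",
            "ck_median_intensity")
  for (cn in cols) {
    expect_equal(shifted[[cn]], ref[[cn]],
                 tolerance = 0.02 * max(abs(ref[[cn]]), 1e-6))
    expect_equal(rotated[[cn]], ref[[cn]],
                 tolerance = 0.02 * max(abs(ref[[cn]]), 1e-6))
  }
})

test_that("intensity rescale scales CK median linearly, leaves shape alone", {
  spec <- benchmark_slide_spec(frames = 1, seed = 13)
  rf <- render_frame(spec, 1)
  sg <- segment_frame(rf$frame)
  f1 <- extract_features(sg, rf$frame)
  fr2 <- rf$frame
  fr2$pixels <- fr2$pixels * 2
  fr2$background_level <- fr2$background_level * 2
  fr2$noise_sd <- fr2$noise_sd * 2
  f2 <- extract_features(sg, fr2)
  expect_equal(f2$ck_median_intensity, 2 * f1$ck_median_intensity,
               tolerance = 1e-8)
  expect_equal(f2$cell_eccentricity, f1$cell_eccentricity)
  expect_equal(f2$cell_area_um2, f1$cell_area_um2)
})

test_that("channel at background level is called negative", {
  H <- 64
  cell <- disk_mask(H, H, 32, 32, 10)
  nuc <- disk_mask(H, H, 32, 32, 8)
  cl <- matrix(0L, H, H); cl[cell] <- 1L
  nl <- matrix(0L, H, H); nl[nuc] <- 1L
  arr <- array(0.1, dim = c(H, H, 4))
  arr[, , 1][nuc] <- 0.7
  fr <- manual_frame(arr, um_per_px = 0.5, background_level = rep(0.1, 4),
                     noise_sd = rep(0.01, 4))
  calls <- call_channels(manual_segmentation(cl, nl, 0.5), fr)
  expect_false(calls$ck_positive)
  expect_identical(calls$ck_texture, "none")
})

test_that("texture round trips reach 90% accuracy per class", {
  lib <- phenotype_library("Landscape")
  run_class <- function(pop, rate, ch, frames, seed0, frame_px = 448,
                        dapi = TRUE, min_area = 40) {
    out <- character(0)
    for (s in seq_len(frames)) {
      sp <- one_pop_spec(pop, rate, frame_px = frame_px, seed = seed0 + s)
      rf <- render_frame(sp, 1)
      sg <- segment_frame(rf$frame)
      if (!nrow(sg$events)) next
      fe <- extract_features(sg, rf$frame)
      cls <- call_channels(sg, rf$frame, fe)
      # score the population's own events: right DAPI state, unclipped size
      keep <- fe$dapi_positive == dapi & fe$cell_area_um2 > min_area &
        cls[[paste0(ch, "_positive")]]
      out <- c(out, cls[[paste0(ch, "_texture")]][keep])
    }
    out
  }
  # diffuse: oncosome-like CK fill
  dif <- run_class(lib$onc_ck, 8, "ck", 12, 100, frame_px = 320,
                   dapi = FALSE, min_area = 12)
  expect_gt(length(dif), 60)
  expect_gte(mean(dif == "diffuse"), 0.9)
  # filamentous: epithelial-CTC-like CK fibres
  fil <- run_class(lib$epi_ctc, 6, "ck", 25, 200)
  expect_gt(length(fil), 100)
  expect_gte(mean(fil == "filamentous"), 0.9)
  # punctate: megakaryocyte-like CD45/CD31 speckle
  pun <- run_class(lib$mega, 3, "ch4", 30, 300)
  expect_gt(length(pun), 60)
  expect_gte(mean(pun == "punctate"), 0.9)
})
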