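test_that("frame rendering is bit-identical for identical specs", {
  spec <- benchmark_slide_spec(frames = 2, seed = 7)
  a <- render_frame(spec, 1)
  b <- render_frame(spec, 1)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  c2 <- render_frame(spec, 2)
  expect_false(identical(a$frame$pixels, c2$frame$pixels))
})

test_that("WBC-only slide yields the requested Poisson density", {
  pop <- phenotype_library("Landscape")$WBC
  counts <- vapply(1:50, function(s) {
    nrow(render_frame(one_pop_spec(pop, 100, frame_px = 512, seed = s),
                      1)$truth)
  }, 0)
  se <- sqrt(100 / 50)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("all-zero rates give a blank frame and empty truth", {
  pop <- phenotype_library("Landscape")$WBC
  rf <- render_frame(one_pop_spec(pop, 0, frame_px = 128, seed = 3), 1)
  expect_equal(nrow(rf$truth), 0)
  # only background + noise left
  expect_lt(max(abs(rf$frame$pixels[, , 1] - 0.1)), 0.08)
  expect_equal(sum(rf$truth_cell_labels), 0)
})

test_that("rendered oncosomes are DAPI-dark and circular in truth masks", {
  pop <- phenotype_library("Landscape")$onc_ck
  pop$attach_prob <- 0 # isolated, so truth masks are unoccluded
  hits <- 0; n <- 0
  for (s in 1:6) {
    rf <- render_frame(one_pop_spec(pop, 4, frame_px = 256, seed = s), 1)
    if (!nrow(rf$truth)) next
    sh <- rarebiopsy:::label_shape(rf$truth_cell_labels,
                                   max(rf$truth_cell_labels))
    for (k in rf$truth$event_id) {
      if (sh$area[k] < 20) next
      n <- n + 1
      pix <- which(rf$truth_cell_labels == k)
      dapi_med <- median(rf$frame$pixels[, , 1][pix])
      if (dapi_med < 0.1 + 5 * 0.01 && sh$roundness[k] >= 0.9) hits <- hits + 1
    }
  }
  expect_gt(n, 10)
  expect_equal(hits, n)
})

test_that("per-frame ground-truth counts are Poisson", {
  pop <- phenotype_library("Landscape")$dapi_only
  spec <- one_pop_spec(pop, 5, frame_px = 128, frames = 250, seed = 11)
  counts <- vapply(1:250, function(f) nrow(render_frame(spec, f)$truth), 0)
  brk <- c(-0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(brk, lambda = 5))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort generation matches the study design", {
  co <- generate_cohort(cohort_spec(seed = 5))
  ml <- co$samples[co$samples$arm == "mCRC" & co$samples$protocol == "Landscape", ]
  expect_equal(nrow(ml), 18) # 10 patients, 2 missing draw 2
  expect_equal(sum(co$samples$arm == "ND"), 50)
  expect_equal(sum(!is.na(co$survival$pfs_months)), 9)
  expect_true(all(co$survival$pfs_months > 0, na.rm = TRUE))
  expect_true(all(co$truth$true_events_per_ml > 0))
  # deterministic regeneration
  co2 <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(co$truth, co2$truth)
  expect_identical(co$survival, co2$survival)
})

test_that("perfect monotone PFS link gives Spearman rho of 1", {
  co <- generate_cohort(cohort_spec(seed = 3, pfs_strength = 1,
                                    n_missing_pfs = 0, n_nd_donors = 0))
  a <- merge(co$truth[co$truth$draw == 1 & co$truth$protocol == "Landscape" &
                        co$truth$classification == "Onc CK|CD45/CD31", ],
             co$survival, by = "patient_id")
  expect_equal(cor(a$true_events_per_ml, a$pfs_months, method = "spearman"), 1)
})

test_that("zero link strength gives uniform correlation p-values", {
  ps <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(seed = s, pfs_strength = 0,
                                      n_missing_pfs = 0, n_nd_donors = 0))
    a <- merge(co$truth[co$truth$draw == 1 & co$truth$protocol == "Landscape" &
                          co$truth$classification == "Onc CK|CD45/CD31", ],
               co$survival, by = "patient_id")
    analyte_pfs_correlation(a$true_events_per_ml, a$pfs_months)$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("impossible censoring fraction is rejected", {
  expect_error(cohort_spec(censoring_fraction = 1), "censoring")
})

test_that("frame TIFF round trip preserves pixels and metadata", {
  spec <- benchmark_slide_spec(frames = 1, seed = 2)
  rf <- render_frame(spec, 1)
  path <- file.path(tempdir(), "frame_roundtrip.tif")
  write_frame_tiff(rf$frame, path)
  back <- read_frame_tiff(path)
  expect_equal(back$pixels, rf$frame$pixels, tolerance = 1e-5)
  expect_identical(back$channel_roles, rf$frame$channel_roles)
  expect_equal(back$um_per_px, rf$frame$um_per_px)
  unlink(c(path, paste0(path, ".yml")))
})
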