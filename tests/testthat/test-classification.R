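test_that("channel-type nomenclature follows the fixed channel order", {
  # (DAPI+, CK+, Vim-, CD45/CD31-) -> "CK"; (DAPI+, CK+, Vim+) -> "CK|Vim";
  # (DAPI-, CK+, Vim+, circular) -> "Onc CK|Vim"; all-negative DAPI- -> artifact
  lab <- assign_channel_type(
    ck_positive = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    ch3_positive = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    ch4_positive = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    dapi_positive = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    is_oncosome = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    protocol = "Landscape")
  expect_identical(lab, c("CK", "CK|Vim", "Onc CK|Vim", "artifact",
                          "Vim|CD45/CD31"))
  expect_identical(
    assign_channel_type(TRUE, TRUE, TRUE, TRUE, FALSE, "CDX2"),
    "CK|CDX2|CD45")
  expect_identical(
    assign_channel_type(FALSE, FALSE, FALSE, TRUE, FALSE, "Landscape"),
    "DAPI only")
})

test_that("labels partition rare events into the taxonomy or artifact", {
  spec <- benchmark_slide_spec(frames = 2, seed = 51)
  rf <- render_frame(spec, 1)
  pf <- process_frame(rf$frame, "Landscape", "s")
  allowed <- c(classification_levels("Landscape"), "artifact", "common-like")
  expect_true(all(pf$records$channel_type %in% allowed))
  expect_equal(length(classification_levels("Landscape")), 12)
  expect_equal(length(classification_levels("CDX2")), 12)
  expect_equal(sum(grepl("^Onc ", classification_levels("CDX2"))), 4)
})

test_that("oncosome rule: circular DAPI-negative CK blobs only", {
  fe <- data.frame(dapi_positive = c(TRUE, FALSE, FALSE, FALSE),
                   cell_circularity = c(0.95, 0.95, 0.40, 0.95),
                   cell_equiv_diameter_um = c(8, 8, 8, 20))
  calls <- data.frame(ck_positive = c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(call_oncosome(fe, calls),
                   c(FALSE, TRUE, FALSE, FALSE))
  # CK-negative DAPI-negative blob is never an oncosome
  calls$ck_positive <- FALSE
  expect_false(any(call_oncosome(fe, calls)))
})

test_that("elongated CK debris is rejected by the circularity rule", {
  pop <- phenotype_library("Landscape")$ck_debris
  onc_calls <- 0; n <- 0
  for (s in 1:10) {
    sp <- one_pop_spec(pop, 4, frame_px = 320, seed = 60 + s)
    rf <- render_frame(sp, 1)
    pf <- process_frame(rf$frame, "Landscape", "s")
    neg <- pf$features$event_id[!pf$features$dapi_positive]
    n <- n + length(neg)
    onc_calls <- onc_calls +
      sum(pf$records$is_oncosome[pf$records$event_id %in% neg])
  }
  expect_gt(n, 20)
  expect_lte(onc_calls / n, 0.05)
})

test_that("CTC subtypes require the right markers and a clear nucleus", {
  spec <- benchmark_slide_spec(frames = 6, seed = 71)
  ev <- evaluate_detection(spec)
  tr <- ev$truth
  recs <- ev$records
  # records matched to true epithelial CTCs carry the Epi.CTC subtype
  for (f in unique(recs$frame)) {
    tf <- tr[tr$frame == f, ]
    sel <- recs$frame == f & !is.na(recs$matched_truth)
    lab <- tf$label[recs$matched_truth[sel]]
    sub <- recs$subtype[sel]
    expect_true(all(sub[lab == "CK"] == "Epi.CTC"))
    expect_true(all(sub[lab == "CK|Vim"] == "Mes.CTC"))
    expect_true(all(sub[recs$is_oncosome[sel]] == "none"))
  }
})

test_that("megakaryocyte candidates are flagged by size and punctate signal", {
  pops <- phenotype_library("Landscape")[c("WBC", "mega")]
  pops$WBC$count_per_frame <- 40
  pops$mega$count_per_frame <- 2
  spec <- sample_spec("m", frames = 12, frame_px = 512,
                      populations = pops, seed = 81)
  ev <- evaluate_detection(spec)
  recs <- ev$records
  hits <- 0; n <- 0
  for (f in unique(recs$frame)) {
    tf <- ev$truth[ev$truth$frame == f, ]
    sel <- recs$frame == f & !is.na(recs$matched_truth)
    lab <- tf$label[recs$matched_truth[sel]]
    n <- n + sum(lab == "CD45/CD31")
    hits <- hits + sum(recs$mega_candidate[sel][lab == "CD45/CD31"])
  }
  expect_gt(n, 15)
  expect_gte(hits / n, 0.9)
})

test_that("endothelial-like flag is independent of variable CK state", {
  pops <- phenotype_library("Landscape")[c("WBC", "cec")]
  pops$WBC$count_per_frame <- 40
  pops$cec$count_per_frame <- 2
  pops$cec$cluster_propensity <- 0
  spec <- sample_spec("c", frames = 14, frame_px = 512,
                      populations = pops, seed = 91)
  ev <- evaluate_detection(spec)
  recs <- ev$records
  by_ck <- list(`TRUE` = c(0, 0), `FALSE` = c(0, 0))
  for (f in unique(recs$frame)) {
    tf <- ev$truth[ev$truth$frame == f, ]
    sel <- which(recs$frame == f & !is.na(recs$matched_truth))
    for (i in sel) {
      t1 <- tf[recs$matched_truth[i], ]
      if (t1$label != "Vim|CD45/CD31") next
      key <- as.character(t1$ck_positive)
      by_ck[[key]] <- by_ck[[key]] + c(recs$cec_candidate[i], 1)
    }
  }
  expect_gt(by_ck[["TRUE"]][2], 5)
  expect_gt(by_ck[["FALSE"]][2], 5)
  expect_gte(by_ck[["TRUE"]][1] / by_ck[["TRUE"]][2], 0.8)
  expect_gte(by_ck[["FALSE"]][1] / by_ck[["FALSE"]][2], 0.8)
})

test_that("ordinary WBC features raise no subtype flags", {
  lib <- phenotype_library("Landscape")
  set.seed(5)
  fe <- simulate_phenotype_features(lib$WBC, 20)
  fe$event_id <- seq_len(nrow(fe))
  fe$cell_circularity <- sqrt(1 - fe$cell_eccentricity^2)
  fe$cell_equiv_diameter_um <- 2 * sqrt(fe$cell_area_um2 / pi)
  fe$nucleus_solidity <- 0.95
  calls <- data.frame(event_id = fe$event_id,
                      ck_positive = FALSE, ck_texture = "none",
                      ck_median = 0.1,
                      ch3_positive = FALSE, ch3_texture = "none",
                      ch3_median = 0.1,
                      ch4_positive = TRUE, ch4_texture = "diffuse",
                      ch4_median = 0.45)
  recs <- classify_events(fe, calls, "Landscape", "s")
  expect_false(any(recs$mega_candidate))
  expect_false(any(recs$cec_candidate))
  expect_true(all(recs$subtype == "none"))
  # and they are relabelled common-like, excluded from enumeration
  expect_true(all(recs$channel_type == "common-like"))
})
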