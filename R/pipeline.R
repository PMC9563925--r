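#' Process one frame through detection and classification
#'
#' segment -> features -> channel calls -> rare-event detection ->
#' classification, returning per-frame tables.
#'
#' @param frame An `if_frame`.
#' @param protocol Staining protocol.
#' @param sample_id Sample identifier for the records.
#' @param seg,call,detect Parameter objects.
#' @return List: `records` (rare events only), `features` (all events),
#'   `calls`, `detection`, `n_nuclei` (DAPI-positive events found).
#' @export
process_frame <- function(frame, protocol = frame$protocol,
                          sample_id = NA_character_,
                          seg = seg_params(), call = call_params(),
                          detect = detect_params()) {
  sg <- segment_frame(frame, seg)
  feats <- extract_features(sg, frame)
  feats$frame_id <- frame$frame_id
  feats$um_per_px <- frame$um_per_px
  cls <- call_channels(sg, frame, feats, call)
  det <- suppressWarnings(detect_rare(feats, detect))
  rare_ids <- det$event_id[det$is_rare]
  fr <- feats[feats$event_id %in% rare_ids, , drop = FALSE]
  cr <- cls[cls$event_id %in% rare_ids, , drop = FALSE]
  recs <- classify_events(fr, cr, protocol, sample_id, all_features = feats)
  list(records = recs, features = feats, calls = cls, detection = det,
       n_nuclei = sum(feats$dapi_positive))
}

#' Process a full synthetic slide end-to-end
#'
#' Renders every frame of a [sample_spec()], runs [process_frame()] on each,
#' and enumerates the classified rare events using the detected DAPI-nuclei
#' count for the blood-volume conversion.
#'
#' @param spec A [sample_spec()].
#' @param sample_id Identifier; defaults to `patient_id_draw`.
#' @param rate_multiplier If rare classes were spiked at an inflated rate,
#'   events/mL are divided by it.
#' @param keep_truth Keep per-frame ground truth (for benchmarking).
#' @param seg,call,detect Parameter objects.
#' @return List: `enumeration` (per-class table), `records`, `n_nuclei`,
#'   `truth` (if kept).
#' @export
process_sample <- function(spec, sample_id = NULL, rate_multiplier = 1,
                           keep_truth = FALSE, seg = seg_params(),
                           call = call_params(), detect = detect_params()) {
  sample_id <- sample_id %||% paste0(spec$patient_id, "_d", spec$draw)
  recs <- list(); truths <- list(); n_nuclei <- 0
  for (f in seq_len(spec$frames)) {
    rf <- render_frame(spec, f)
    pf <- process_frame(rf$frame, spec$protocol, sample_id, seg, call, detect)
    recs[[f]] <- pf$records
    n_nuclei <- n_nuclei + pf$n_nuclei
    if (keep_truth) truths[[f]] <- rf$truth
  }
  records <- do.call(rbind, recs)
  enum <- enumeration_table(records, sample_id, spec$protocol,
                            dapi_nuclei_count = max(n_nuclei, 1),
                            wbc_concentration_per_ml =
                              spec$wbc_concentration_per_ml)
  if (rate_multiplier != 1) {
    enum$events_per_ml <- enum$events_per_ml / rate_multiplier
    enum$positive <- enum$events_per_ml >= 5
  }
  list(enumeration = enum, records = records, n_nuclei = n_nuclei,
       truth = if (keep_truth) do.call(rbind, truths) else NULL)
}

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default, as a nested list
#' that can be written to / read from YAML.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Config list.
#' @export
default_config <- function(seed = 1L, out_dir = "rarebiopsy_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    protocols = c("Landscape", "CDX2"),
    cohort = list(n_mcrc_patients = 10, n_nd_donors = 50,
                  pfs_analyte = "Onc CK|CD45/CD31", pfs_strength = 0.8),
    image = list(enabled = TRUE, n_patients = 2, frames = 4, frame_px = 384,
                 wbc_per_frame = 60, rate_multiplier = 40),
    segmentation = unclass(seg_params()),
    channel_calls = unclass(call_params()),
    detection = unclass(detect_params())[c("var_target", "common_fraction",
                                           "k_max", "scope")],
    multi_assay = list(k_range = c(2, 16)),
    survival = list(alpha = 0.05, p_method = "t")
  )
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, optionally runs the imaging pipeline
#' end-to-end on a subset of slides (demo scale), produces cohort
#' enumerations, summaries, cohort contrasts, cross-assay correlations and the
#' survival screen, and writes everything (CSV + JSON manifest) under
#' `config$out_dir`. Fully determined by the config (including its seed).
#'
#' @param config A config list ([default_config()]) or path to a YAML file.
#' @return Invisibly, a list with the main tables and the output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$protocols)) {
    stop("config validation: 'protocols' missing", call. = FALSE)
  }
  stopifnot(all(config$protocols %in% c("Landscape", "CDX2")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  paths <- character(0)

  cs <- cohort_spec(
    n_mcrc_patients = config$cohort$n_mcrc_patients %||% 10,
    n_nd_donors = config$cohort$n_nd_donors %||% 50,
    pfs_analyte = config$cohort$pfs_analyte %||% "Onc CK|CD45/CD31",
    pfs_strength = config$cohort$pfs_strength %||% 0.8,
    seed = config$seed
  )
  cohort <- generate_cohort(cs)
  enum <- simulate_enumeration(cohort, seed = derive_seed(config$seed, 1))
  paths["enumeration"] <- wr(enum, "cohort_enumeration.csv")
  paths["survival"] <- wr(cohort$survival, "survival.csv")

  summaries <- list()
  for (p in config$protocols) {
    e <- enum[enum$protocol == p & enum$arm == "mCRC", ]
    if (nrow(e)) {
      summaries[[p]] <- summarize_cohort(e, p)
      paths[paste0("summary_", p)] <-
        wr(summaries[[p]], paste0("cohort_summary_", gsub("/", "-", p), ".csv"))
    }
  }

  contrast <- NULL
  if ("Landscape" %in% config$protocols) {
    contrast <- compare_cohorts(
      enum[enum$protocol == "Landscape" & enum$arm == "mCRC", ],
      enum[enum$protocol == "Landscape" & enum$arm == "ND", ])
    paths["contrast"] <- wr(contrast, "cohort_contrast.csv")
  }

  xassay <- NULL
  if (all(c("Landscape", "CDX2") %in% config$protocols)) {
    el <- enum[enum$protocol == "Landscape" & enum$arm == "mCRC", ]
    ec <- enum[enum$protocol == "CDX2" & enum$arm == "mCRC", ]
    el$sample_id <- paste0(el$patient_id, "_d", el$draw)
    ec$sample_id <- paste0(ec$patient_id, "_d", ec$draw)
    xassay <- cross_assay_correlations(el, ec)
    paths["xassay_rho"] <- wr(as.data.frame(xassay$rho), "cross_assay_rho.csv")
    paths["xassay_p"] <- wr(as.data.frame(xassay$p), "cross_assay_p.csv")
  }

  surv_screen <- NULL
  if (!is.null(cohort$survival)) {
    e1 <- enum[enum$protocol == "Landscape" & enum$arm == "mCRC" &
                 enum$draw == 1, ]
    surv_screen <- screen_pfs_analytes(e1, cohort$survival,
                                       alpha = config$survival$alpha %||% 0.05,
                                       method = config$survival$p_method %||% "t")
    paths["pfs_screen"] <- wr(surv_screen, "pfs_screen_draw1_landscape.csv")
  }

  image_out <- NULL
  if (isTRUE(config$image$enabled)) {
    im <- config$image
    ids <- cohort$samples$sample_id[cohort$samples$arm == "mCRC" &
                                      cohort$samples$draw == 1]
    ids <- ids[seq_len(min(2 * (im$n_patients %||% 2), length(ids)))]
    image_out <- list()
    for (sid in ids) {
      sp <- as_sample_spec(cohort, sid, frames = im$frames %||% 4,
                           frame_px = im$frame_px %||% 384,
                           wbc_per_frame = im$wbc_per_frame %||% 60,
                           rate_multiplier = im$rate_multiplier %||% 40)
      res <- process_sample(sp, sample_id = sid,
                            rate_multiplier = im$rate_multiplier %||% 40)
      image_out[[sid]] <- res
    }
    img_enum <- do.call(rbind, lapply(image_out, `[[`, "enumeration"))
    img_recs <- do.call(rbind, lapply(image_out, `[[`, "records"))
    paths["image_enumeration"] <- wr(img_enum, "image_enumeration.csv")
    paths["image_records"] <- wr(img_recs, "image_records.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rarebiopsy")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = as.list(paths)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, enumeration = enum, summaries = summaries,
                 contrast = contrast, cross_assay = xassay,
                 pfs_screen = surv_screen, image = image_out, paths = paths))
}
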