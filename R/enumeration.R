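#' Blood volume analysed on a slide
#'
#' The exact blood volume a slide represents is the number of DAPI-positive
#' nuclei plated on it divided by the sample's leukocyte concentration measured
#' at processing.
#'
#' @param dapi_nuclei_count Number of DAPI-positive nuclei on the slide.
#' @param wbc_concentration_per_ml Leukocyte concentration (cells/mL).
#' @return Volume in mL.
#' @export
blood_volume <- function(dapi_nuclei_count, wbc_concentration_per_ml) {
  if (any(dapi_nuclei_count <= 0) || any(wbc_concentration_per_ml <= 0)) {
    stop("blood_volume() needs positive nuclei count and WBC concentration",
         call. = FALSE)
  }
  dapi_nuclei_count / wbc_concentration_per_ml
}

#' Convert a raw count to events/mL
#'
#' @param raw_count Event count (vectorized).
#' @param volume_ml Blood volume analysed, mL.
#' @return Events per mL.
#' @export
to_events_per_ml <- function(raw_count, volume_ml) {
  if (any(volume_ml <= 0)) stop("volume must be positive", call. = FALSE)
  raw_count / volume_ml
}

#' Per-sample enumeration table
#'
#' Counts classified rare events per channel-type classification (all 12
#' classes are present, zero-filled), converts to events/mL via the analysed
#' blood volume, and computes per-sample positivity (>= `positivity_threshold`
#' events/mL) and frequency as percent of the sample's total rare events.
#'
#' @param records Rare-event records ([classify_events()]); "artifact" rows are
#'   excluded.
#' @param sample_id Sample identifier.
#' @param protocol Staining protocol.
#' @param dapi_nuclei_count,wbc_concentration_per_ml Volume inputs
#'   (ground-truth nuclei count in simulation, detected nuclei in image mode).
#' @param positivity_threshold Events/mL threshold for sample positivity.
#' @return data.frame, one row per classification, with attributes
#'   `blood_volume_ml`, `dapi_nuclei_count`, `wbc_concentration_per_ml`.
#' @export
enumeration_table <- function(records, sample_id, protocol,
                              dapi_nuclei_count, wbc_concentration_per_ml,
                              positivity_threshold = 5) {
  lev <- classification_levels(protocol)
  vol <- blood_volume(dapi_nuclei_count, wbc_concentration_per_ml)
  cts <- table(factor(records$channel_type[records$channel_type != "artifact"],
                      levels = lev))
  raw <- as.integer(cts)
  epm <- to_events_per_ml(raw, vol)
  total <- sum(epm)
  out <- data.frame(
    sample_id = sample_id,
    protocol = protocol,
    classification = lev,
    raw_count = raw,
    events_per_ml = epm,
    positive = epm >= positivity_threshold,
    frequency_pct = if (total > 0) 100 * epm / total else 0,
    stringsAsFactors = FALSE
  )
  attr(out, "blood_volume_ml") <- vol
  attr(out, "dapi_nuclei_count") <- dapi_nuclei_count
  attr(out, "wbc_concentration_per_ml") <- wbc_concentration_per_ml
  out
}

#' Cohort summary in the published table shape
#'
#' Per classification: sample positivity (k of n at the >= 5 events/mL
#' threshold), mean, standard error (sd/sqrt(n samples)), percent of total
#' rare events (100 x class mean / sum of all class means within the
#' protocol), median and range. Samples with zero events in a class contribute
#' zeros.
#'
#' @param enum Stacked enumeration rows for one protocol: needs `sample_id`,
#'   `classification`, `events_per_ml` (and optionally `positive`).
#' @param protocol Staining protocol (classification order).
#' @param positivity_threshold Events/mL threshold.
#' @return data.frame with columns `classification`, `positive_samples`,
#'   `n_samples`, `mean_events_per_ml`, `se_events_per_ml`, `pct_of_total`,
#'   `median_events_per_ml`, `min_events_per_ml`, `max_events_per_ml`.
#' @export
summarize_cohort <- function(enum, protocol = c("Landscape", "CDX2"),
                             positivity_threshold = 5) {
  protocol <- match.arg(protocol)
  stopifnot(nrow(enum) >= 1,
            all(c("sample_id", "classification", "events_per_ml") %in%
                  names(enum)))
  lev <- classification_levels(protocol)
  samples <- unique(enum$sample_id)
  n <- length(samples)
  # zero-fill missing (sample, classification) pairs
  full <- expand.grid(sample_id = samples, classification = lev,
                      stringsAsFactors = FALSE)
  full <- merge(full, enum[, c("sample_id", "classification", "events_per_ml")],
                by = c("sample_id", "classification"), all.x = TRUE)
  full$events_per_ml[is.na(full$events_per_ml)] <- 0
  sp <- split(full$events_per_ml, factor(full$classification, levels = lev))
  means <- vapply(sp, mean, 0)
  out <- data.frame(
    classification = lev,
    positive_samples = vapply(sp, function(v)
      sum(v >= positivity_threshold), 0L),
    n_samples = n,
    mean_events_per_ml = means,
    se_events_per_ml = vapply(sp, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0, 0),
    pct_of_total = 100 * means / sum(means),
    median_events_per_ml = vapply(sp, stats::median, 0),
    min_events_per_ml = vapply(sp, min, 0),
    max_events_per_ml = vapply(sp, max, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Composition shares of a cohort summary
#'
#' Aggregate shares of the rare-event profile: the oncosome share and rare-cell
#' (nucleated) share of all rare events, the CK-positive share within rare
#' cells, and per-class percent of total, all computed from the per-class mean
#' enumerations.
#'
#' @param summary Output of [summarize_cohort()].
#' @return Named list of percentages.
#' @export
composition_shares <- function(summary) {
  onc <- grepl("^Onc ", summary$classification)
  means <- summary$mean_events_per_ml
  total <- sum(means)
  cells <- !onc
  ckpos_cell <- cells & grepl("(^|\\|)CK(\\||$)", summary$classification)
  list(
    oncosome_pct_of_total = 100 * sum(means[onc]) / total,
    rare_cell_pct_of_total = 100 * sum(means[cells]) / total,
    ck_positive_pct_of_rare_cells = 100 * sum(means[ckpos_cell]) /
      sum(means[cells]),
    pct_of_total = stats::setNames(summary$pct_of_total,
                                   summary$classification)
  )
}
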