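#' Expected classification label of a ground-truth event
#'
#' Builds the channel-type label a perfect pipeline would assign from the
#' ground-truth positivity vector (the instance-level truth, so variably
#' expressed markers are honoured).
#'
#' @param truth Ground-truth data.frame from [render_frame()].
#' @param protocol Staining protocol.
#' @return Character vector.
#' @export
truth_channel_type <- function(truth, protocol = "Landscape") {
  onc <- !truth$dapi_positive & truth$ck_positive & truth$label != "debris"
  assign_channel_type(truth$ck_positive, truth$ch3_positive,
                      truth$ch4_positive, truth$dapi_positive, onc, protocol)
}

#' End-to-end detection and classification benchmark
#'
#' Renders every frame of a slide spec, runs the full pipeline
#' (segment, features, calls, rare-event detection, classification), matches
#' detected rare events to the ground truth by centroid proximity and scores
#' per-class recall and overall rare-event precision.
#'
#' @param spec A [sample_spec()] containing a WBC background plus spiked rare
#'   populations.
#' @param match_dist_px Maximum centroid distance for a truth match.
#' @param seg,call,detect Parameter objects.
#' @return List: `per_class` (data.frame: class, n_truth, n_recalled, recall),
#'   `precision` (detected rare events matching any rare truth event),
#'   `rare_recall` (any-label rare recall), `records`, `truth`.
#' @export
evaluate_detection <- function(spec, match_dist_px = 8,
                               seg = seg_params(), call = call_params(),
                               detect = detect_params()) {
  truth_all <- list(); det_all <- list()
  for (f in seq_len(spec$frames)) {
    rf <- render_frame(spec, f)
    pf <- process_frame(rf$frame, spec$protocol, "bench", seg, call, detect)
    tr <- rf$truth
    tr$expected <- truth_channel_type(tr, spec$protocol)
    tr$matched_label <- NA_character_
    recs <- pf$records
    if (nrow(recs)) {
      fx <- pf$features[match(recs$event_id, pf$features$event_id), ]
      recs$centroid_row <- fx$centroid_row
      recs$centroid_col <- fx$centroid_col
      recs$matched_truth <- NA_integer_
      enum_ok <- recs$channel_type %in%
        c(classification_levels(spec$protocol))
      # match enumerable records first so a coincident artifact fragment
      # cannot shadow the real detection of the same truth event
      for (i in order(!enum_ok)) {
        d <- sqrt((tr$centroid_row - recs$centroid_row[i])^2 +
                    (tr$centroid_col - recs$centroid_col[i])^2)
        j <- which.min(d)
        if (length(j) && d[j] <= match_dist_px) {
          recs$matched_truth[i] <- j
          # keep the best (first) detection per truth event
          if (is.na(tr$matched_label[j])) {
            tr$matched_label[j] <- recs$channel_type[i]
          }
        }
      }
      recs$frame <- f
      det_all[[f]] <- recs
    }
    tr$frame <- f
    truth_all[[f]] <- tr
  }
  truth <- do.call(rbind, truth_all)
  records <- do.call(rbind, det_all)
  rare_truth <- truth[truth$label != "WBC", , drop = FALSE]
  classes <- sort(unique(rare_truth$expected))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- rare_truth$expected == cl
    data.frame(class = cl, n_truth = sum(sel),
               n_recalled = sum(rare_truth$matched_label[sel] == cl,
                                na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_class$recall <- per_class$n_recalled / per_class$n_truth
  # precision over enumerable records: detections labelled artifact or
  # common-like never enter an enumeration table
  precision <- if (!is.null(records) && nrow(records)) {
    enum_ok <- records$channel_type %in% classification_levels(spec$protocol)
    rl <- records[enum_ok, , drop = FALSE]
    tl <- rep(NA_character_, nrow(rl))
    for (f in unique(rl$frame)) {
      tf <- truth[truth$frame == f, ]
      sel <- rl$frame == f & !is.na(rl$matched_truth)
      tl[sel] <- tf$label[rl$matched_truth[sel]]
    }
    mean(!is.na(tl) & tl != "WBC")
  } else NA_real_
  rare_recall <- mean(!is.na(rare_truth$matched_label))
  list(per_class = per_class, precision = precision,
       rare_recall = rare_recall, records = records, truth = truth)
}

#' Segmentation accuracy against ground truth
#'
#' Renders frames and matches segmented events to ground-truth events by
#' centroid proximity; reports recall and precision of event detection.
#'
#' @param spec A [sample_spec()].
#' @param frames How many frames to evaluate.
#' @param match_dist_px Matching tolerance.
#' @param seg [seg_params()].
#' @return List: `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
evaluate_segmentation <- function(spec, frames = spec$frames,
                                  match_dist_px = 6, seg = seg_params()) {
  n_truth <- 0; n_det <- 0; n_matched_truth <- 0; n_matched_det <- 0
  for (f in seq_len(frames)) {
    rf <- render_frame(spec, f)
    sg <- segment_frame(rf$frame, seg)
    tr <- rf$truth
    ev <- sg$events
    n_truth <- n_truth + nrow(tr)
    n_det <- n_det + nrow(ev)
    if (nrow(tr) && nrow(ev)) {
      d <- outer(tr$centroid_row, ev$centroid_row, "-")^2 +
        outer(tr$centroid_col, ev$centroid_col, "-")^2
      d <- sqrt(d)
      n_matched_truth <- n_matched_truth +
        sum(apply(d, 1, min) <= match_dist_px)
      n_matched_det <- n_matched_det +
        sum(apply(d, 2, min) <= match_dist_px)
    }
  }
  list(recall = n_matched_truth / max(n_truth, 1),
       precision = n_matched_det / max(n_det, 1),
       n_truth = n_truth, n_detected = n_det)
}
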