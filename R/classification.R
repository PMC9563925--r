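#' Channel-type label from positivity calls
#'
#' Labels concatenate the positive non-DAPI channels in fixed channel order
#' (CK, then the protocol's third and fourth markers), "DAPI only" when a
#' nucleated event is negative in all three. DAPI-negative events are labelled
#' as oncosomes ("Onc " prefix) when `is_oncosome`, otherwise "artifact"
#' (non-cellular debris, excluded from enumeration).
#'
#' @param ck_positive,ch3_positive,ch4_positive Logical vectors.
#' @param dapi_positive Logical vector.
#' @param is_oncosome Logical vector (see [call_oncosome()]).
#' @param protocol `"Landscape"` or `"CDX2"`.
#' @return Character vector of labels.
#' @export
assign_channel_type <- function(ck_positive, ch3_positive, ch4_positive,
                                dapi_positive, is_oncosome,
                                protocol = c("Landscape", "CDX2")) {
  protocol <- match.arg(protocol)
  ch <- channel_roles(protocol)[2:4]
  n <- length(ck_positive)
  lab <- character(n)
  for (i in seq_len(n)) {
    pos <- c(ck_positive[i], ch3_positive[i], ch4_positive[i])
    base <- paste(ch[pos], collapse = "|")
    if (dapi_positive[i]) {
      lab[i] <- if (base == "") "DAPI only" else base
    } else if (is_oncosome[i]) {
      lab[i] <- paste("Onc", base)
    } else {
      lab[i] <- "artifact"
    }
  }
  lab
}

#' Oncosome call for DAPI-negative events
#'
#' An oncosome is a circular, DAPI-negative event with positive CK expression:
#' CK-positive AND circularity at or above `circularity_min` AND equivalent
#' diameter at most `max_diameter_um` (vesicles range up to roughly the size of
#' a neighbouring WBC, ~10 um).
#'
#' @param features Feature rows (needs `dapi_positive`, `cell_circularity`,
#'   `cell_equiv_diameter_um`).
#' @param calls Matching [call_channels()] rows (needs `ck_positive`).
#' @param circularity_min,max_diameter_um Rule thresholds.
#' @return Logical vector (always `FALSE` for DAPI-positive events).
#' @export
call_oncosome <- function(features, calls, circularity_min = 0.85,
                          max_diameter_um = 12) {
  !features$dapi_positive &
    calls$ck_positive &
    !is.na(features$cell_circularity) &
    features$cell_circularity >= circularity_min &
    features$cell_equiv_diameter_um <= max_diameter_um
}

#' Morphological subtype flags
#'
#' `mega_candidate`: punctate fourth-channel (CD45/CD31 or CD45) signal on a
#' cell at least `mega_area_factor` times the WBC median area, any CK/third
#' channel state -- the megakaryocyte-candidate phenotype. `cec_candidate`
#' (Landscape only): filamentous Vim together with punctate CD45/CD31,
#' CK-agnostic -- the endothelial-like phenotype. `clustered`: another rare
#' event centroid within `cluster_radius_factor` cell diameters.
#' `attached_oncosome`: a DAPI-negative event whose centroid lies within 1.2x
#' the summed equivalent radii of a nucleated event.
#'
#' @param records Classification records under construction (needs
#'   `event_id`, `channel_type`, `is_oncosome`).
#' @param features Features for the same events.
#' @param calls Channel calls for the same events.
#' @param all_features Features for every segmented event in the same frames
#'   (used for WBC median area and oncosome adjacency); defaults to `features`.
#' @param protocol Staining protocol.
#' @param wbc_median_area_um2 Median WBC area; estimated from the DAPI-positive
#'   non-rare background when `NULL` via `all_features`.
#' @param mega_area_factor,cluster_radius_factor Rule constants.
#' @return `records` with logical columns `mega_candidate`, `cec_candidate`,
#'   `clustered`, `attached_oncosome` added.
#' @export
flag_morph_subtypes <- function(records, features, calls,
                                all_features = features,
                                protocol = c("Landscape", "CDX2"),
                                wbc_median_area_um2 = NULL,
                                mega_area_factor = 2,
                                cluster_radius_factor = 1.5) {
  protocol <- match.arg(protocol)
  if (is.null(wbc_median_area_um2)) {
    bgpop <- all_features$cell_area_um2[all_features$dapi_positive]
    wbc_median_area_um2 <- if (length(bgpop)) stats::median(bgpop) else 78.5
  }
  pun4 <- calls$ch4_positive & calls$ch4_texture == "punctate"
  records$mega_candidate <- pun4 &
    features$cell_area_um2 >= mega_area_factor * wbc_median_area_um2
  records$cec_candidate <- if (protocol == "Landscape") {
    calls$ch3_positive & calls$ch3_texture == "filamentous" & pun4
  } else rep(FALSE, nrow(records))

  # clustered: pairwise centroid distances among rare events, per frame
  records$clustered <- FALSE
  if (nrow(records) > 1 &&
      all(c("centroid_row", "centroid_col") %in% names(features))) {
    fid <- if ("frame_id" %in% names(features)) as.character(features$frame_id)
      else rep("all", nrow(features))
    for (f in unique(fid)) {
      ii <- which(fid == f)
      if (length(ii) < 2) next
      d <- as.matrix(stats::dist(features[ii, c("centroid_row", "centroid_col")]))
      diag(d) <- Inf
      diam_px <- features$cell_equiv_diameter_um[ii] /
        (features$um_per_px[1] %||% 0.5)
      near <- apply(d, 1, min) <= cluster_radius_factor * diam_px
      records$clustered[ii] <- near
    }
  }

  records$attached_oncosome <- FALSE
  neg <- which(records$is_oncosome)
  if (length(neg) &&
      all(c("centroid_row", "centroid_col") %in% names(all_features))) {
    nucl <- all_features[all_features$dapi_positive, , drop = FALSE]
    if (nrow(nucl)) {
      upp <- all_features$um_per_px[1] %||% 0.5
      for (i in neg) {
        fi <- features[i, ]
        same <- if ("frame_id" %in% names(nucl) && "frame_id" %in% names(fi)) {
          nucl[as.character(nucl$frame_id) == as.character(fi$frame_id), ,
               drop = FALSE]
        } else nucl
        if (!nrow(same)) next
        d <- sqrt((same$centroid_row - fi$centroid_row)^2 +
                  (same$centroid_col - fi$centroid_col)^2)
        rsum <- (same$cell_equiv_diameter_um + fi$cell_equiv_diameter_um) / 2 / upp
        records$attached_oncosome[i] <- any(d <= 1.2 * rsum)
      }
    }
  }
  records
}

#' Classify rare events
#'
#' Builds the rare-event record for each detected rare event: channel-type
#' label, oncosome call, named CTC subtype and morphological flags.
#'
#' Subtypes: `Epi.CTC` = CK-positive, third- and fourth-channel negative with
#' a clearly defined nucleus (operationalized as nucleus area >=
#' `min_nucleus_area_um2` and nucleus solidity >= `min_nucleus_solidity`);
#' `Mes.CTC` = CK- and Vim-positive, CD45/CD31-negative with a clear nucleus
#' (Landscape); `CDX2.CTC` = CK- and CDX2-positive, CD45-negative (CDX2
#' protocol).
#'
#' @param features Features of the rare events.
#' @param calls Channel calls of the rare events.
#' @param protocol Staining protocol.
#' @param sample_id Sample identifier attached to every record.
#' @param all_features Features of all segmented events (adjacency/WBC size
#'   context); defaults to `features`.
#' @param min_nucleus_area_um2,min_nucleus_solidity "Clear nucleus" rule.
#' @param ... Passed to [flag_morph_subtypes()] and [call_oncosome()].
#' @return data.frame of rare-event records.
#' @export
classify_events <- function(features, calls,
                            protocol = c("Landscape", "CDX2"),
                            sample_id = NA_character_,
                            all_features = features,
                            min_nucleus_area_um2 = 20,
                            min_nucleus_solidity = 0.9,
                            ...) {
  protocol <- match.arg(protocol)
  stopifnot(nrow(features) == nrow(calls),
            all(features$event_id == calls$event_id))
  if (!nrow(features)) {
    return(data.frame(event_id = integer(0), sample_id = character(0),
                      channel_type = character(0), is_oncosome = logical(0),
                      subtype = character(0)))
  }
  onc <- call_oncosome(features, calls, ...)
  ct <- assign_channel_type(calls$ck_positive, calls$ch3_positive,
                            calls$ch4_positive, features$dapi_positive,
                            onc, protocol)
  clear_nuc <- features$dapi_positive &
    features$nucleus_area_um2 >= min_nucleus_area_um2 &
    features$nucleus_solidity >= min_nucleus_solidity
  subtype <- rep("none", nrow(features))
  if (protocol == "Landscape") {
    subtype[ct == "CK" & clear_nuc] <- "Epi.CTC"
    subtype[ct == "CK|Vim" & clear_nuc] <- "Mes.CTC"
  } else {
    subtype[ct == "CK|CDX2" & clear_nuc] <- "CDX2.CTC"
  }
  records <- data.frame(
    event_id = features$event_id,
    sample_id = sample_id,
    frame_id = if ("frame_id" %in% names(features)) features$frame_id else NA,
    channel_type = ct,
    is_oncosome = onc,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
  records <- flag_morph_subtypes(records, features, calls,
                                 all_features = all_features,
                                 protocol = protocol)
  # ordinary leukocytes stripped as statistical outliers (crowding, mask
  # clipping) still look like WBCs: only the leukocyte channel positive, with
  # the diffuse texture and ordinary size. They are relabelled common-like
  # (excluded from enumeration), the automated surrogate of analyst review.
  bgpop <- all_features$cell_area_um2[all_features$dapi_positive]
  wbc_med <- if (length(bgpop)) stats::median(bgpop) else 78.5
  ch4lab <- channel_roles(protocol)[4]
  # the 3x bound also absorbs under-split doublets of crowded leukocytes;
  # only the punctate fourth-channel texture marks a genuinely distinct cell
  common_like <- records$channel_type == ch4lab &
    calls$ch4_texture != "punctate" &
    features$cell_area_um2 < 3 * wbc_med
  records$channel_type[common_like] <- "common-like"
  records
}
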