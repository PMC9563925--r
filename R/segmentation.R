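#' Segmentation parameters
#'
#' @param dapi_floor_k The DAPI threshold is per-frame Otsu with a floor at
#'   `background + dapi_floor_k * noise SD` (scanning normalizes background
#'   across slides, so the floor is stated in noise units).
#' @param marker_k Marker channels are considered signal above
#'   `background + marker_k * noise SD`.
#' @param min_nucleus_area_um2 Nuclear components smaller than this are noise.
#' @param dapi_neg_area_um2 Area bounds (um^2) for DAPI-negative candidates;
#'   the default upper bound admits vesicles up to ~12 um equivalent diameter.
#' @param max_expand_um Maximum cytoplasm expansion beyond the nuclear mask.
#' @param split_tolerance Watershed tolerance (in distance-map units) when
#'   splitting touching nuclei.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(dapi_floor_k = 3,
                       marker_k = 3,
                       min_nucleus_area_um2 = 3,
                       dapi_neg_area_um2 = c(2, 120),
                       max_expand_um = 2,
                       split_tolerance = 1) {
  structure(list(dapi_floor_k = dapi_floor_k, marker_k = marker_k,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 dapi_neg_area_um2 = dapi_neg_area_um2,
                 max_expand_um = max_expand_um,
                 split_tolerance = split_tolerance),
            class = "seg_params")
}

# Background location/scale per channel: the frame metadata when present,
# otherwise a robust estimate (median / MAD) over the whole channel, which is
# dominated by background at rare-event densities.
channel_background <- function(frame, ci) {
  v <- frame$pixels[, , ci]
  bg <- if (!is.null(frame$background_level)) frame$background_level[ci] else
    stats::median(v)
  ns <- if (!is.null(frame$noise_sd)) frame$noise_sd[ci] else stats::mad(v)
  c(bg = bg, noise = max(ns, 1e-6))
}

#' Split a connected mask into per-nucleus masks
#'
#' Watershed split of a binary mask seeded on local maxima of the smoothed
#' DAPI signal (falling back to the distance map when DAPI is flat). The union
#' of the output masks equals the input mask exactly.
#'
#' @param mask Logical or 0/1 matrix, a single connected component (or any
#'   binary mask; each component is split independently).
#' @param dapi DAPI channel matrix, same shape.
#' @param tolerance Watershed tolerance; larger merges more.
#' @return Integer label matrix, same shape as `mask`.
#' @export
split_touching <- function(mask, dapi, tolerance = 1) {
  m <- mask > 0
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(EBImage::Image(m * 1))
  elev <- as.matrix(dm)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(dapi), sigma = 2))
  # combine shape (distance map) and intensity so adjacent nuclei with a
  # shared boundary still present two maxima
  rng <- range(sm[m])
  if (diff(rng) > 1e-8) {
    elev <- elev + (sm - rng[1]) / diff(rng) * max(elev) * 0.5
  }
  elev[!m] <- 0
  ws <- EBImage::watershed(EBImage::Image(elev), tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(as.matrix(ws)), nrow(m), ncol(m))
  lab[!m] <- 0L
  # watershed borders: assign any unlabeled mask pixels to the nearest label
  orphan <- which(m & lab == 0L)
  if (length(orphan)) {
    lab <- fill_orphans(lab, m, orphan)
  }
  lab
}

# Assign mask pixels that a watershed left unlabeled to an adjacent label by
# iterative 4-neighbour dilation (conserves the pixel set).
fill_orphans <- function(lab, m, orphan) {
  H <- nrow(lab)
  for (iter in 1:50) {
    if (!length(orphan)) break
    nb <- cbind(orphan - 1L, orphan + 1L, orphan - H, orphan + H)
    nb[nb < 1L | nb > length(lab)] <- NA
    vals <- matrix(lab[nb], ncol = 4)
    pick <- apply(vals, 1, function(v) {
      v <- v[!is.na(v) & v > 0L]
      if (length(v)) v[1] else 0L
    })
    lab[orphan[pick > 0L]] <- pick[pick > 0L]
    orphan <- orphan[pick == 0L]
  }
  lab
}

#' Segment all candidate events in a frame
#'
#' DAPI-positive events: per-frame Otsu threshold (floored at background +
#' `dapi_floor_k` noise SD), hole filling, watershed split of touching nuclei,
#' then bounded cytoplasm expansion over the union of the marker channels.
#' DAPI-negative candidates: connected marker-signal components that overlap no
#' nuclear or cytoplasm mask, with area inside `dapi_neg_area_um2`.
#'
#' @param frame An `if_frame`.
#' @param params A [seg_params()].
#' @return A list of class `segmentation`: `events` (data.frame with
#'   `event_id`, centroid, `dapi_positive`, areas), `nuc_labels` and
#'   `cell_labels` (integer matrices; values are event ids), plus the pixel
#'   geometry needed downstream.
#' @export
segment_frame <- function(frame, params = seg_params()) {
  if (!inherits(frame, "if_frame") || dim(frame$pixels)[3] != 4) {
    stop("segment_frame() needs a 4-channel if_frame", call. = FALSE)
  }
  H <- dim(frame$pixels)[1]; W <- dim(frame$pixels)[2]
  px_area_um2 <- frame$um_per_px^2

  dapi <- frame$pixels[, , 1]
  bgd <- channel_background(frame, 1)
  dmax <- max(dapi, 1e-6)
  th_otsu <- EBImage::otsu(EBImage::Image(pmin(dapi / dmax, 1))) * dmax
  th <- max(th_otsu, bgd["bg"] + params$dapi_floor_k * bgd["noise"])
  nmask <- dapi > th
  if (any(nmask)) {
    nmask <- as.matrix(EBImage::fillHull(EBImage::Image(nmask * 1))) > 0
    nmask <- as.matrix(EBImage::opening(EBImage::Image(nmask * 1),
                                        EBImage::makeBrush(3, "diamond"))) > 0
  }

  min_npx <- params$min_nucleus_area_um2 / px_area_um2
  nuc_labels <- matrix(0L, H, W)
  if (any(nmask)) {
    nuc_labels <- split_touching(nmask, dapi, tolerance = params$split_tolerance)
    sizes <- tabulate(nuc_labels)
    drop <- which(sizes < min_npx)
    if (length(drop)) nuc_labels[nuc_labels %in% drop] <- 0L
    # compact ids
    ids <- sort(unique(nuc_labels[nuc_labels > 0L]))
    if (length(ids)) nuc_labels[] <- match(nuc_labels, ids, nomatch = 0L)
  }
  n_nuc <- max(nuc_labels, 0L)

  # marker signal union
  signal <- matrix(FALSE, H, W)
  marker_sum <- matrix(0, H, W)
  for (ci in 2:4) {
    bgc <- channel_background(frame, ci)
    chm <- frame$pixels[, , ci] > (bgc["bg"] + params$marker_k * bgc["noise"])
    signal <- signal | chm
    marker_sum <- marker_sum + pmax(frame$pixels[, , ci] - bgc["bg"], 0)
  }
  if (any(signal)) {
    signal <- as.matrix(EBImage::opening(EBImage::Image(signal * 1),
                                         EBImage::makeBrush(3, "diamond"))) > 0
  }

  # cytoplasm: expand each nucleus over nearby marker signal, bounded by a
  # dilation of the nuclear mask; large nuclei (giant cells) get a
  # proportionally wider band so their cytoplasm is not truncated
  cell_labels <- nuc_labels
  if (n_nuc > 0) {
    expand_px <- ceiling(params$max_expand_um / frame$um_per_px)
    allowed <- as.matrix(EBImage::dilate(
      EBImage::Image((nuc_labels > 0L) * 1),
      EBImage::makeBrush(2L * expand_px + 1L, "disc")
    )) > 0
    sizes_nuc <- tabulate(nuc_labels, n_nuc)
    big <- which(sizes_nuc * px_area_um2 >= 150)
    if (length(big)) {
      big_px <- 2L * ceiling(2 * params$max_expand_um / frame$um_per_px) + 1L
      big_mask <- matrix((nuc_labels %in% big) * 1, nrow(nuc_labels))
      allowed <- allowed | (as.matrix(EBImage::dilate(
        EBImage::Image(big_mask),
        EBImage::makeBrush(big_px, "disc")
      )) > 0)
    }
    pmask <- (signal & allowed) | nuc_labels > 0L
    prop <- EBImage::propagate(EBImage::Image(marker_sum),
                               EBImage::Image(nuc_labels),
                               mask = EBImage::Image(pmask * 1))
    cell_labels <- matrix(as.integer(as.matrix(prop)), H, W)
    cell_labels[nuc_labels > 0L] <- nuc_labels[nuc_labels > 0L]
  }

  # DAPI-negative candidates: marker components untouched by any cell mask
  neg <- signal & cell_labels == 0L & nuc_labels == 0L
  neg_ids <- integer(0)
  if (any(neg)) {
    neg_lab <- matrix(as.integer(as.matrix(
      EBImage::bwlabel(EBImage::Image(neg * 1)))), H, W)
    sizes <- tabulate(neg_lab)
    lo <- params$dapi_neg_area_um2[1] / px_area_um2
    hi <- params$dapi_neg_area_um2[2] / px_area_um2
    # components touching a cell mask are kept: attached vesicles are real
    # events; cytoplasm spillover fragments fail the downstream circularity
    # rule and are excluded from enumeration as artifacts
    keep <- which(sizes >= lo & sizes <= hi)
    if (length(keep)) {
      new_ids <- n_nuc + seq_along(keep)
      remap <- integer(max(neg_lab))
      remap[keep] <- new_ids
      sel <- neg_lab > 0L & neg_lab %in% keep
      cell_labels[sel] <- remap[neg_lab[sel]]
      neg_ids <- new_ids
    }
  }

  all_ids <- seq_len(n_nuc + length(neg_ids))
  if (length(all_ids)) {
    cs <- label_centroids(cell_labels, max(all_ids))
    ns <- label_centroids(nuc_labels, n_nuc)
    events <- data.frame(
      event_id = all_ids,
      frame_id = frame$frame_id %||% NA_character_,
      centroid_row = cs$row, centroid_col = cs$col,
      dapi_positive = all_ids <= n_nuc,
      nucleus_area_px = c(ns$area, rep(0L, length(neg_ids))),
      cell_area_px = cs$area,
      stringsAsFactors = FALSE
    )
    events <- events[events$cell_area_px > 0, , drop = FALSE]
  } else {
    events <- data.frame(event_id = integer(), frame_id = character(),
                         centroid_row = numeric(), centroid_col = numeric(),
                         dapi_positive = logical(), nucleus_area_px = integer(),
                         cell_area_px = integer(), stringsAsFactors = FALSE)
  }
  structure(list(events = events, nuc_labels = nuc_labels,
                 cell_labels = cell_labels, um_per_px = frame$um_per_px,
                 frame_id = frame$frame_id),
            class = "segmentation")
}

# Areas and centroids for labels 1..n of a label matrix.
label_centroids <- function(lab, n) {
  if (n == 0) return(list(area = integer(0), row = numeric(0), col = numeric(0)))
  idx <- which(lab > 0L)
  l <- lab[idx]
  H <- nrow(lab)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(l, nbins = n)
  sr <- rowsum_safe(rows, l, n)
  sc <- rowsum_safe(cols, l, n)
  list(area = area, row = sr / pmax(area, 1), col = sc / pmax(area, 1))
}

rowsum_safe <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(as.numeric(x), g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}
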