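#' Channel-call and texture-rule parameters
#'
#' @param positivity_k A channel is positive when the median intensity inside
#'   the cell mask exceeds the frame background median plus `positivity_k`
#'   noise SD (MAD-based when metadata is absent).
#' @param cv_diffuse In-mask intensity coefficient of variation below which a
#'   positive signal is called diffuse.
#' @param bright_factor Bright-structure threshold as a multiple of the in-mask
#'   median.
#' @param min_spots Minimum local-maximum count for a punctate fallback call
#'   when the tensor statistics are unavailable (tiny masks).
#' @param filament_score Threshold on the ridge score
#'   `coherence - entropy_weight * orientation_entropy`; at or above it a
#'   heterogeneous signal is called filamentous, below it punctate.
#' @param entropy_weight Weight of the gradient-orientation entropy in the
#'   ridge score.
#' @return List of class `call_params`. Texture thresholds were fixed once
#'   against the slide simulator and are not data-adaptive.
#' @export
call_params <- function(positivity_k = 5,
                        cv_diffuse = 0.20,
                        bright_factor = 1.5,
                        min_spots = 3,
                        filament_score = -0.84,
                        entropy_weight = 0.75) {
  structure(list(positivity_k = positivity_k, cv_diffuse = cv_diffuse,
                 bright_factor = bright_factor, min_spots = min_spots,
                 filament_score = filament_score,
                 entropy_weight = entropy_weight),
            class = "call_params")
}

# Mean structure-tensor coherence over the given pixels: per-pixel gradient
# outer products are window-averaged (Gaussian), and coherence is the
# normalized eigenvalue gap (lambda1 - lambda2)/(lambda1 + lambda2): ~1 along
# a ridge (one dominant gradient direction), low inside isotropic blobs.
tensor_coherence <- function(sm, sel) {
  H <- nrow(sm); W <- ncol(sm)
  if (H < 5 || W < 5) return(NA_real_)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gy[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
  gx[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
  smooth <- function(m) {
    # gblur's kernel spans 2*ceil(3*sigma)+1 = 11 px
    if (min(H, W) >= 11) {
      as.matrix(EBImage::gblur(EBImage::Image(m), sigma = 1.5))
    } else m
  }
  jxx <- smooth(gx * gx); jyy <- smooth(gy * gy); jxy <- smooth(gx * gy)
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy + 1e-12)
  if (!any(sel)) return(NA_real_)
  mean(coh[sel])
}

# Moments-based shape summaries for labels 1..n: eccentricity via the
# eigenvalues of the second central moment matrix.
label_shape <- function(lab, n) {
  out <- data.frame(area = rep(0, n), row = rep(NA_real_, n),
                    col = rep(NA_real_, n), ecc = rep(0, n),
                    major_px = rep(0, n), minor_px = rep(0, n),
                    roundness = rep(1, n))
  if (n == 0) return(out)
  idx <- which(lab > 0L)
  if (!length(idx)) return(out)
  l <- lab[idx]
  H <- nrow(lab)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(l, nbins = n)
  sr <- rowsum_safe(r, l, n); sc <- rowsum_safe(c, l, n)
  mr <- sr / pmax(area, 1); mc <- sc / pmax(area, 1)
  dr <- r - mr[l]; dc <- c - mc[l]
  mu20 <- rowsum_safe(dr * dr, l, n) / pmax(area, 1)
  mu02 <- rowsum_safe(dc * dc, l, n) / pmax(area, 1)
  mu11 <- rowsum_safe(dr * dc, l, n) / pmax(area, 1)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 > 1e-12, sqrt(pmax(1 - l2 / l1, 0)), 0)
  out$area <- area; out$row <- mr; out$col <- mc
  out$ecc <- pmin(ecc, 0.999999)
  # full axis lengths of the equivalent ellipse (variance a^2/16 along an axis
  # of full length a); roundness = minor/major = sqrt(1 - ecc^2)
  out$major_px <- 4 * sqrt(pmax(l1, 0))
  out$minor_px <- 4 * sqrt(pmax(l2, 0))
  out$roundness <- ifelse(l1 > 1e-12, sqrt(pmax(l2, 0) / l1), 1)
  out
}

# Boundary pixels of each label (4-connectivity; image border counts).
label_boundaries <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) return(list(idx = integer(0), label = integer(0)))
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  v <- lab[idx]
  nb_diff <- (r == 1L) | (r == H) | (c == 1L) | (c == W)
  inner <- !nb_diff
  if (any(inner)) {
    ii <- idx[inner]
    nb_diff[inner] <- lab[ii - 1L] != v[inner] | lab[ii + 1L] != v[inner] |
      lab[ii - H] != v[inner] | lab[ii + H] != v[inner]
  }
  list(idx = idx[nb_diff], label = v[nb_diff],
       row = r[nb_diff], col = c[nb_diff])
}

# Convex-hull area per label from boundary points (shoelace formula).
label_solidity <- function(lab, n, area) {
  bd <- label_boundaries(lab)
  sol <- rep(NA_real_, n)
  if (!length(bd$idx)) return(sol)
  sp <- split(seq_along(bd$label), bd$label)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    pr <- bd$row[sp[[nm]]]; pc <- bd$col[sp[[nm]]]
    if (length(pr) < 3) { sol[i] <- 1; next }
    h <- grDevices::chull(pc, pr)
    x <- pc[h]; y <- pr[h]
    ha <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    # hull of pixel centres underestimates the pixelated area; pad by the
    # half-pixel boundary band
    ha <- ha + length(h) * 0.5
    sol[i] <- min(area[i] / max(ha, 1), 1)
  }
  sol
}

# Per-label median/mean/max/sd of an intensity channel.
label_intensity <- function(ch, lab, n) {
  idx <- which(lab > 0L)
  out <- data.frame(median = rep(NA_real_, n), mean = rep(NA_real_, n),
                    max = rep(NA_real_, n), sd = rep(NA_real_, n))
  if (!length(idx)) return(out)
  v <- ch[idx]; l <- lab[idx]
  sp <- split(v, l)
  ids <- as.integer(names(sp))
  out$median[ids] <- vapply(sp, stats::median, 0)
  out$mean[ids] <- vapply(sp, mean, 0)
  out$max[ids] <- vapply(sp, max, 0)
  out$sd[ids] <- vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else 0, 0)
  out
}

#' Extract morphometric and intensity features for segmented events
#'
#' Produces one row per event with the eight shared multi-assay features --
#' DAPI and CK median intensity, cell and nucleus eccentricity and area,
#' nuclear-to-cell area ratio, and the mean distance of the cell outline to
#' the nucleus centre -- plus a documented superset of shape and per-channel
#' intensity features. All lengths are in micrometres via the frame's pixel
#' size. DAPI-negative events carry zero nucleus features and
#' `nucleus_missing = TRUE`; their outline distance is taken to the cell
#' centroid.
#'
#' @param seg A `segmentation` (see [segment_frame()]).
#' @param frame The `if_frame` it came from.
#' @return data.frame keyed by `event_id`.
#' @export
extract_features <- function(seg, frame) {
  stopifnot(inherits(seg, "segmentation"))
  ev <- seg$events
  n <- if (nrow(ev)) max(ev$event_id) else 0L
  if (n == 0L) return(empty_features())
  upp <- seg$um_per_px
  cellS <- label_shape(seg$cell_labels, n)
  nucS <- label_shape(seg$nuc_labels, n)
  if (any(cellS$area[ev$event_id] <= 0)) {
    stop("event with empty cell mask", call. = FALSE)
  }

  shp <- EBImage::computeFeatures.shape(seg$cell_labels)
  perim <- rep(NA_real_, n)
  rad_sd <- rep(NA_real_, n)
  if (!is.null(shp) && nrow(shp)) {
    perim[seq_len(nrow(shp))] <- shp[, "s.perimeter"]
    rad_sd[seq_len(nrow(shp))] <- shp[, "s.radius.sd"]
  }
  sol_cell <- label_solidity(seg$cell_labels, n, cellS$area)
  sol_nuc <- label_solidity(seg$nuc_labels, n, nucS$area)

  ints <- lapply(1:4, function(ci) label_intensity(frame$pixels[, , ci],
                                                   seg$cell_labels, n))
  dapi_nuc <- label_intensity(frame$pixels[, , 1], seg$nuc_labels, n)
  bg <- vapply(1:4, function(ci) channel_background(frame, ci)["bg"], 0)

  # mean outline-to-nucleus-centre distance
  bd <- label_boundaries(seg$cell_labels)
  ref_r <- ifelse(is.na(nucS$row), cellS$row, nucS$row)
  ref_c <- ifelse(is.na(nucS$col), cellS$col, nucS$col)
  dist_mean <- rep(NA_real_, n)
  if (length(bd$idx)) {
    d <- sqrt((bd$row - ref_r[bd$label])^2 + (bd$col - ref_c[bd$label])^2)
    sums <- rowsum_safe(d, bd$label, n)
    cnts <- tabulate(bd$label, nbins = n)
    dist_mean <- sums / pmax(cnts, 1)
  }

  has_nuc <- nucS$area > 0
  out <- data.frame(
    event_id = seq_len(n),
    dapi_positive = has_nuc,
    nucleus_missing = !has_nuc,
    # the 8 shared multi-assay features
    dapi_median_intensity = ifelse(has_nuc, dapi_nuc$median, ints[[1]]$median),
    ck_median_intensity = ints[[2]]$median,
    cell_eccentricity = cellS$ecc,
    nucleus_eccentricity = ifelse(has_nuc, nucS$ecc, 0),
    cell_area_um2 = cellS$area * upp^2,
    nucleus_area_um2 = nucS$area * upp^2,
    nuclear_to_cell_area_ratio = ifelse(has_nuc,
                                        pmin(nucS$area / cellS$area, 1), 0),
    mean_outline_to_nucleus_center_distance_um = dist_mean * upp,
    # superset
    cell_perimeter_um = perim * upp,
    # moments-based roundness (minor/major axis ratio); 1 for a circle,
    # robust to pixelated boundaries, used by the oncosome circularity rule
    cell_circularity = cellS$roundness,
    cell_major_axis_um = cellS$major_px * upp,
    cell_minor_axis_um = cellS$minor_px * upp,
    cell_equiv_diameter_um = 2 * sqrt(cellS$area / pi) * upp,
    nucleus_equiv_diameter_um = 2 * sqrt(nucS$area / pi) * upp,
    cell_solidity = sol_cell,
    nucleus_solidity = ifelse(has_nuc, sol_nuc, 0),
    cell_radius_sd_um = rad_sd * upp,
    centroid_row = cellS$row,
    centroid_col = cellS$col,
    stringsAsFactors = FALSE
  )
  ch_names <- c("dapi", "ck", "ch3", "ch4")
  for (ci in 1:4) {
    nm <- ch_names[ci]
    out[[paste0(nm, "_mean_intensity")]] <- ints[[ci]]$mean
    out[[paste0(nm, "_max_intensity")]] <- ints[[ci]]$max
    out[[paste0(nm, "_intensity_cv")]] <-
      ints[[ci]]$sd / pmax(ints[[ci]]$mean, 1e-9)
    out[[paste0(nm, "_median_bgsub")]] <-
      pmax((if (ci == 2) ints[[2]]$median else
        if (ci == 1) out$dapi_median_intensity else ints[[ci]]$median) - bg[ci], 0)
    if (ci > 2) out[[paste0(nm, "_median_intensity")]] <- ints[[ci]]$median
  }
  out <- out[out$event_id %in% ev$event_id, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(is.finite(as.matrix(
    out[, c("cell_eccentricity", "cell_area_um2",
            "nuclear_to_cell_area_ratio")]))))
  out
}

empty_features <- function() {
  data.frame(event_id = integer(0), dapi_positive = logical(0),
             nucleus_missing = logical(0))
}

#' Classify the texture of a positive signal
#'
#' Decision rule over the pixels of one channel inside one mask: low intensity
#' coefficient of variation is diffuse. Otherwise the rule separates ridges
#' from spots with two gradient statistics -- the mean structure-tensor
#' coherence over bright pixels (high along line segments at any crossing
#' angle) and the entropy of the gradient-orientation histogram (low when a
#' few fibre directions dominate, maximal for isotropic spots): signals whose
#' ridge score `coherence - entropy_weight * entropy` reaches `filament_score`
#' are filamentous, the rest punctate. Masks too small for tensor statistics
#' fall back to counting local maxima above `bright_factor` x the in-mask
#' median.
#'
#' @param pixels Numeric matrix (a crop of one channel).
#' @param mask Logical matrix, same shape; the event mask within the crop.
#' @param params [call_params()].
#' @return List: `texture` plus the diagnostic statistics
#'   (`cv`, `n_spots`, `coherence`, `orientation_entropy`).
#' @export
classify_texture <- function(pixels, mask, params = call_params()) {
  v <- pixels[mask]
  if (!length(v)) return(list(texture = "none", cv = NA, n_spots = 0,
                              coherence = NA, orientation_entropy = NA))
  cv <- stats::sd(v) / max(mean(v), 1e-9)
  if (!is.finite(cv) || cv < params$cv_diffuse) {
    return(list(texture = "diffuse", cv = cv, n_spots = 0, coherence = NA,
                orientation_entropy = NA))
  }
  sm <- if (min(dim(pixels)) >= 9) {
    as.matrix(EBImage::gblur(EBImage::Image(pixels), sigma = 1))
  } else pixels
  med <- stats::median(v)
  thr <- med * params$bright_factor
  H <- nrow(sm); W <- ncol(sm)
  # strict local maxima above threshold, interior pixels only
  n_spots <- 0L
  if (H > 2 && W > 2) {
    ctr <- sm[2:(H - 1), 2:(W - 1)]
    ismax <- ctr > thr & mask[2:(H - 1), 2:(W - 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ismax <- ismax & ctr > sm[2:(H - 1) + dr, 2:(W - 1) + dc]
    }
    n_spots <- sum(ismax)
  }
  bright <- sm > thr & mask
  coherence <- if (sum(bright) >= 5) tensor_coherence(sm, bright) else NA_real_
  entropy <- orientation_entropy(sm, mask)
  texture <- if (!is.na(coherence) && !is.na(entropy)) {
    if (coherence - params$entropy_weight * entropy >= params$filament_score)
      "filamentous" else "punctate"
  } else if (n_spots >= params$min_spots) {
    "punctate"
  } else {
    "diffuse"
  }
  list(texture = texture, cv = cv, n_spots = n_spots, coherence = coherence,
       orientation_entropy = entropy)
}

# Entropy (nats, 8 bins over [0, pi)) of the gradient-orientation histogram
# over the strongest-gradient quartile of in-mask pixels.
orientation_entropy <- function(sm, mask) {
  H <- nrow(sm); W <- ncol(sm)
  if (H < 5 || W < 5) return(NA_real_)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gy[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
  gx[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
  g <- sqrt(gx^2 + gy^2)
  sel <- mask & g > stats::quantile(g[mask], 0.75)
  if (sum(sel) < 8) return(NA_real_)
  ang <- atan2(gy[sel], gx[sel]) %% pi
  p <- tabulate(pmin(8L, floor(ang / pi * 8) + 1L), 8L)
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Per-channel positivity and texture calls
#'
#' A channel is positive when the event's median intensity inside its cell
#' mask exceeds the frame background plus `positivity_k` noise SD. Texture is
#' assigned only for positive channels ("none" otherwise).
#'
#' @param seg A `segmentation`.
#' @param frame The `if_frame`.
#' @param features Output of [extract_features()] (computed if `NULL`).
#' @param params [call_params()].
#' @return data.frame keyed by `event_id` with `<ch>_positive`, `<ch>_texture`
#'   and `<ch>_median` for channels `ck`, `ch3`, `ch4`.
#' @export
call_channels <- function(seg, frame, features = NULL,
                          params = call_params()) {
  if (is.null(features)) features <- extract_features(seg, frame)
  n <- nrow(features)
  out <- data.frame(event_id = features$event_id)
  if (n == 0) {
    for (nm in c("ck", "ch3", "ch4")) {
      out[[paste0(nm, "_positive")]] <- logical(0)
      out[[paste0(nm, "_texture")]] <- character(0)
      out[[paste0(nm, "_median")]] <- numeric(0)
    }
    return(out)
  }
  H <- nrow(seg$cell_labels)
  idx_all <- which(seg$cell_labels > 0L)
  lab_all <- seg$cell_labels[idx_all]
  sp <- split(idx_all, lab_all)
  for (ci in 2:4) {
    nm <- c(NA, "ck", "ch3", "ch4")[ci]
    bgc <- channel_background(frame, ci)
    thr <- bgc["bg"] + params$positivity_k * bgc["noise"]
    med <- if (ci == 2) features$ck_median_intensity else
      features[[paste0(nm, "_median_intensity")]]
    pos <- !is.na(med) & med > thr
    tex <- rep("none", n)
    ch <- frame$pixels[, , ci]
    for (i in which(pos)) {
      id <- as.character(features$event_id[i])
      pix <- sp[[id]]
      if (is.null(pix)) { pos[i] <- FALSE; next }
      r <- ((pix - 1L) %% H) + 1L
      c <- ((pix - 1L) %/% H) + 1L
      r0 <- max(1L, min(r) - 2L); r1 <- min(nrow(ch), max(r) + 2L)
      c0 <- max(1L, min(c) - 2L); c1 <- min(ncol(ch), max(c) + 2L)
      crop <- ch[r0:r1, c0:c1, drop = FALSE]
      mk <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      mk[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
      tex[i] <- classify_texture(crop, mk, params)$texture
    }
    out[[paste0(nm, "_positive")]] <- pos
    out[[paste0(nm, "_texture")]] <- tex
    out[[paste0(nm, "_median")]] <- med
  }
  out
}
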