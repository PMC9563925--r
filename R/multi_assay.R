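#' The eight shared multi-assay features
#'
#' Both staining protocols share DAPI and CK, so cells from the two assays can
#' be compared on: the median intensity of those two channels, the eccentricity
#' and area of both the cell and the nucleus, the nuclear-to-cell area ratio,
#' and the mean distance of the cell outline to the nucleus centre.
#'
#' @return Character vector of 8 feature names.
#' @export
shared_feature_names <- function() {
  c("dapi_median_intensity", "ck_median_intensity",
    "cell_eccentricity", "nucleus_eccentricity",
    "cell_area_um2", "nucleus_area_um2",
    "nuclear_to_cell_area_ratio",
    "mean_outline_to_nucleus_center_distance_um")
}

#' Harmonize rare cells from the two protocols
#'
#' Pools rare cells (oncosomes are excluded) from the Landscape and CDX2
#' protocols on the eight shared features and z-scores each feature over the
#' pooled retained set. Cells failing mask QC are dropped with a reason:
#' nuclear-to-cell area ratio outside (0, 1], any non-finite feature, or cell
#' solidity below `min_solidity` (highly aberrant masking).
#'
#' @param landscape,cdx2 Feature data.frames from the respective protocols;
#'   need the [shared_feature_names()] columns plus `dapi_positive` (and
#'   `is_oncosome` if oncosomes were not already removed).
#' @param min_solidity QC floor on cell solidity when present.
#' @return List: `cells` (data.frame: `protocol`, `event_id`, z-scored shared
#'   features), `z_matrix` (numeric matrix of the same), `qc` (dropped rows
#'   with `qc_reason`), `center`, `scale`.
#' @export
harmonize <- function(landscape, cdx2, min_solidity = 0.3) {
  if (is.null(landscape) || !nrow(landscape)) {
    stop("protocol absent: Landscape", call. = FALSE)
  }
  if (is.null(cdx2) || !nrow(cdx2)) stop("protocol absent: CDX2", call. = FALSE)
  prep <- function(df, protocol) {
    if ("is_oncosome" %in% names(df)) df <- df[!df$is_oncosome, , drop = FALSE]
    if ("dapi_positive" %in% names(df)) {
      df <- df[df$dapi_positive, , drop = FALSE]
    }
    df$protocol <- protocol
    df
  }
  pool <- rbind(
    prep(landscape, "Landscape")[, c("protocol", "event_id",
                                     intersect(names(landscape),
                                               c(shared_feature_names(),
                                                 "cell_solidity")))],
    prep(cdx2, "CDX2")[, c("protocol", "event_id",
                           intersect(names(cdx2),
                                     c(shared_feature_names(),
                                       "cell_solidity")))]
  )
  f <- shared_feature_names()
  stopifnot(all(f %in% names(pool)))
  x <- as.matrix(pool[, f])
  reason <- rep(NA_character_, nrow(pool))
  bad_ratio <- pool$nuclear_to_cell_area_ratio <= 0 |
    pool$nuclear_to_cell_area_ratio > 1
  reason[bad_ratio] <- "nuclear_to_cell_area_ratio outside (0,1]"
  nonfin <- rowSums(!is.finite(x)) > 0
  reason[is.na(reason) & nonfin] <- "non-finite feature"
  if ("cell_solidity" %in% names(pool)) {
    bad_sol <- !is.na(pool$cell_solidity) & pool$cell_solidity < min_solidity
    reason[is.na(reason) & bad_sol] <- "aberrant mask (low solidity)"
  }
  keep <- is.na(reason)
  qc <- pool[!keep, , drop = FALSE]
  qc$qc_reason <- reason[!keep]
  pool <- pool[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  cells <- cbind(pool[, c("protocol", "event_id")], as.data.frame(z))
  rownames(cells) <- NULL
  list(cells = cells, z_matrix = z, qc = qc, center = ctr, scale = scl)
}

#' Joint Ward clustering with silhouette-selected cluster number
#'
#' Agglomerative clustering (Euclidean metric, Ward linkage) of the harmonized
#' cells for every k in `k_range`; the solution returned maximizes the mean
#' silhouette width (ties broken toward smaller k). k values exceeding n - 1
#' are skipped.
#'
#' @param cells A [harmonize()] result, or a numeric matrix of z-scored
#'   features.
#' @param k_range Integer `c(min, max)` of cluster numbers to evaluate.
#' @param protocol Optional per-cell protocol labels (taken from the
#'   harmonized cells when available) for the occupancy table.
#' @return List of class `cluster_solution`: `k`, `assignments`,
#'   `silhouette_by_k` (named vector), `occupancy` (cluster x protocol table,
#'   when protocols are known).
#' @export
cluster_multi_assay <- function(cells, k_range = c(2, 16), protocol = NULL) {
  if (is.list(cells) && !is.null(cells$z_matrix)) {
    protocol <- protocol %||% cells$cells$protocol
    x <- cells$z_matrix
  } else {
    x <- as.matrix(cells)
  }
  n <- nrow(x)
  ks <- seq(max(2L, k_range[1]), k_range[2])
  ks <- ks[ks <= n - 1]
  if (!length(ks)) stop("not enough cells for any k in range", call. = FALSE)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
  cuts <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    ct <- stats::cutree(hc, k = ks[i])
    cuts[[i]] <- ct
    sil[i] <- mean(cluster::silhouette(ct, d)[, "sil_width"])
  }
  best <- which(sil >= max(sil) - 1e-12)[1] # ties toward smaller k
  assignments <- cuts[[best]]
  occupancy <- if (!is.null(protocol)) {
    table(cluster = assignments, protocol = protocol)
  } else NULL
  structure(list(k = ks[best], assignments = assignments,
                 silhouette_by_k = sil, occupancy = occupancy),
            class = "cluster_solution")
}

#' Cross-assay Spearman correlations of enumerations
#'
#' For every (Landscape classification, CDX2 classification) pair, the Spearman
#' rank correlation of events/mL over sample-matched slides, with two-tailed
#' p-values and a significance mask at `alpha`. Constant series give NA.
#'
#' @param enum_landscape,enum_cdx2 Stacked enumeration rows (`sample_id`,
#'   `classification`, `events_per_ml`) for each protocol.
#' @param alpha Two-tailed significance level.
#' @return List: `rho`, `p` (matrices Landscape x CDX2), `significant`
#'   (logical), `n` matched samples.
#' @export
cross_assay_correlations <- function(enum_landscape, enum_cdx2, alpha = 0.05) {
  wl <- enum_wide(enum_landscape, "Landscape")
  wc <- enum_wide(enum_cdx2, "CDX2")
  common <- intersect(rownames(wl), rownames(wc))
  if (length(common) < 4) stop("need >= 4 matched samples", call. = FALSE)
  wl <- wl[common, , drop = FALSE]
  wc <- wc[common, , drop = FALSE]
  rho <- matrix(NA_real_, ncol(wl), ncol(wc),
                dimnames = list(colnames(wl), colnames(wc)))
  p <- rho
  for (i in seq_len(ncol(wl))) {
    for (j in seq_len(ncol(wc))) {
      x <- wl[, i]; y <- wc[, j]
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             alternative = "two.sided"))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = p, significant = !is.na(p) & p <= alpha,
       n = length(common))
}

enum_wide <- function(enum, protocol) {
  lev <- classification_levels(protocol)
  samples <- unique(enum$sample_id)
  w <- matrix(0, length(samples), length(lev),
              dimnames = list(as.character(samples), lev))
  for (r in seq_len(nrow(enum))) {
    cl <- enum$classification[r]
    if (cl %in% lev) {
      w[as.character(enum$sample_id[r]), cl] <- enum$events_per_ml[r]
    }
  }
  w
}
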