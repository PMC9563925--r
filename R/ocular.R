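#' Columns used for rare-event detection
#'
#' The curated morphometric/intensity feature set the detector clusters on:
#' the eight shared features plus shape (circularity, solidity, perimeter,
#' equivalent diameters) and per-channel median/max/CV intensities.
#' Identifiers, centroids and constant metadata are excluded.
#' @param features Output of [extract_features()].
#' @return Character vector of column names.
#' @export
detection_feature_columns <- function(features) {
  wanted <- c(
    shared_feature_names(),
    "cell_circularity", "cell_solidity", "nucleus_solidity",
    "cell_perimeter_um", "cell_equiv_diameter_um",
    "nucleus_equiv_diameter_um", "cell_radius_sd_um",
    "dapi_mean_intensity", "dapi_max_intensity", "dapi_intensity_cv",
    "ck_mean_intensity", "ck_max_intensity", "ck_intensity_cv",
    "ch3_median_intensity", "ch3_mean_intensity", "ch3_max_intensity",
    "ch3_intensity_cv",
    "ch4_median_intensity", "ch4_mean_intensity", "ch4_max_intensity",
    "ch4_intensity_cv"
  )
  intersect(wanted, names(features))
}

#' Detection parameters
#'
#' @param var_target Fraction of variance the retained principal components
#'   must explain.
#' @param common_fraction Clusters holding more than this fraction of the
#'   events in scope are labelled common; the dendrogram is stripped top-down
#'   until only such clusters remain.
#' @param k_max Upper bound on stripped rare clusters (safety cap).
#' @param scope `"frame"` (cluster each frame separately; the default,
#'   matching per-frame scanning) or `"slide"`.
#' @export
detect_params <- function(var_target = 0.95, common_fraction = 0.20,
                          k_max = 10, scope = c("frame", "slide")) {
  structure(list(var_target = var_target, common_fraction = common_fraction,
                 k_max = k_max, scope = match.arg(scope)),
            class = "detect_params")
}

#' Reduce standardized features to principal components
#'
#' Z-scores each column (constant columns are dropped with a warning), takes
#' the principal components, retains the smallest number explaining at least
#' `var_target` of the variance, and fixes the sign of each component so its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (events x features).
#' @param var_target Variance fraction to retain.
#' @param scale. Standardize columns before the decomposition (default); turn
#'   off for inputs already on a common scale.
#' @return List: `scores` (events x retained components), `rotation`, `sdev`,
#'   `kept_columns`.
#' @export
reduce_dimensions <- function(x, var_target = 0.95, scale. = TRUE) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  const <- !is.finite(sds) | sds < 1e-12
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped")
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (ncol(x) == 0) {
    return(list(scores = matrix(0, nrow(x), 1), rotation = NULL,
                sdev = 0, kept_columns = character(0)))
  }
  z <- if (scale.) scale(x) else scale(x, scale = FALSE)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(varfrac >= var_target)[1]
  if (is.na(m)) m <- length(pc$sdev)
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(m)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(scores = z %*% rot, rotation = rot, sdev = pc$sdev[seq_len(m)],
       kept_columns = colnames(x))
}

# Top-down outlier stripping on a Ward dendrogram: recursively 2-cut the
# current core; a side holding at most common_fraction of all events in scope
# is peeled off as a rare cluster, and the recursion stops when a split is
# balanced (both sides above the fraction) -- that core is the common
# population. Returns cluster ids (0 = common core, 1.. = stripped rare
# clusters).
strip_outliers <- function(scores, common_fraction, max_iter = 50L) {
  n <- nrow(scores)
  assign <- rep(0L, n)
  core <- seq_len(n)
  next_id <- 1L
  for (iter in seq_len(max_iter)) {
    if (length(core) < 4) break
    hc <- stats::hclust(stats::dist(scores[core, , drop = FALSE]),
                        method = "ward.D2")
    ct <- stats::cutree(hc, k = 2)
    sizes <- tabulate(ct, 2)
    small <- which.min(sizes)
    if (sizes[small] > common_fraction * n) break # balanced: core is common
    assign[core[ct == small]] <- next_id
    next_id <- next_id + 1L
    core <- core[ct != small]
  }
  assign
}

#' Separate rare events from common cells
#'
#' The unbiased rare-event detection step: DAPI-positive events are z-scored,
#' reduced by PCA, and Ward-clustered (Euclidean metric) on the retained
#' components; the dendrogram is cut by top-down outlier stripping so that
#' every final cluster holding more than `common_fraction` of the events in
#' scope is labelled common -- the dominant leukocyte background -- while all
#' stripped smaller clusters are rare.
#' DAPI-negative events bypass clustering and are rare by definition. Scopes
#' with fewer than 5 DAPI-positive events flag everything rare with a warning.
#'
#' @param features Feature data.frame from [extract_features()] (may span
#'   several frames; add a `frame_id` column for per-frame scope).
#' @param params [detect_params()].
#' @return data.frame: `event_id`, `frame_id`, `is_rare`, `cluster_id`,
#'   `rarity_score` (1 - own cluster share).
#' @export
detect_rare <- function(features, params = detect_params()) {
  if (!nrow(features)) {
    return(data.frame(event_id = integer(0), frame_id = character(0),
                      is_rare = logical(0), cluster_id = integer(0),
                      rarity_score = numeric(0)))
  }
  fid <- if ("frame_id" %in% names(features) && params$scope == "frame") {
    as.character(features$frame_id)
  } else rep("all", nrow(features))
  features <- features[order(fid, features$event_id), , drop = FALSE]
  fid <- sort(fid)
  out <- lapply(unique(fid), function(f) {
    fe <- features[fid == f, , drop = FALSE]
    detect_rare_scope(fe, params, f)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

detect_rare_scope <- function(fe, params, scope_id) {
  pos <- fe$dapi_positive
  res <- data.frame(
    event_id = fe$event_id,
    frame_id = if ("frame_id" %in% names(fe)) fe$frame_id else scope_id,
    is_rare = !pos, # DAPI-negative bypass
    cluster_id = NA_integer_,
    rarity_score = ifelse(pos, NA_real_, 1),
    stringsAsFactors = FALSE
  )
  np <- sum(pos)
  if (np == 0) return(res)
  if (np < 5) {
    warning("fewer than 5 DAPI-positive events in scope '", scope_id,
            "': all flagged rare (low confidence)")
    res$is_rare[pos] <- TRUE
    res$rarity_score[pos] <- 1
    return(res)
  }
  cols <- detection_feature_columns(fe)
  x <- as.matrix(fe[pos, cols, drop = FALSE])
  x[!is.finite(x)] <- 0
  red <- reduce_dimensions(x, params$var_target)
  cl <- strip_outliers(red$scores, params$common_fraction)
  sizes <- tabulate(cl + 1L, max(cl) + 1L)
  share <- sizes[cl + 1L] / np
  res$cluster_id[pos] <- cl
  res$is_rare[pos] <- cl > 0L
  res$rarity_score[pos] <- 1 - share
  res
}
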