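#' Define a synthetic slide (one stained sample)
#'
#' A sample spec fully determines a synthetic slide: the staining protocol,
#' imaging geometry, per-channel background and noise, the populations plated
#' on it, and the seed. Regeneration from an identical spec is bit-identical.
#'
#' The defaults are a desk-scale stand-in for a production slide: a slide is
#' scanned as 2304 frames holding ~3 million nucleated cells; here 64 frames of
#' 512x512 px at 0.5 um/px are used by default, preserving object scale
#' (a 10 um WBC is 20 px across) while keeping simulation tractable.
#'
#' @param patient_id,draw,protocol Sample identity; `draw` is 1 or 2.
#' @param wbc_concentration_per_ml Leukocyte concentration measured at
#'   processing (cells/mL); used to convert counts to events/mL.
#' @param frames Number of frames on the slide.
#' @param frame_px Frame side length in pixels (square frames).
#' @param um_per_px Physical pixel size.
#' @param populations List of [population_spec()] objects.
#' @param background_level,noise_sd Per-channel (length 4) background offset
#'   and Gaussian noise SD, in the same normalized intensity units as the
#'   rendered signal.
#' @param seed Integer seed; every frame derives its own stream from it.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(patient_id,
                        draw = 1L,
                        protocol = c("Landscape", "CDX2"),
                        wbc_concentration_per_ml = 5.66e6,
                        frames = 64L,
                        frame_px = 512L,
                        um_per_px = 0.5,
                        populations = phenotype_library(protocol),
                        background_level = rep(0.10, 4),
                        noise_sd = rep(0.01, 4),
                        seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(draw %in% c(1L, 2L), wbc_concentration_per_ml > 0, frames >= 1,
            frame_px >= 64, um_per_px > 0,
            length(background_level) == 4, all(background_level >= 0),
            length(noise_sd) == 4, all(noise_sd >= 0))
  structure(
    list(
      patient_id = patient_id, draw = as.integer(draw), protocol = protocol,
      wbc_concentration_per_ml = wbc_concentration_per_ml,
      frames = as.integer(frames), frame_px = as.integer(frame_px),
      um_per_px = um_per_px, populations = populations,
      background_level = background_level, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sample_spec"
  )
}

new_frame <- function(pixels, protocol, um_per_px, frame_id,
                      background_level, noise_sd) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 4, um_per_px > 0)
  structure(
    list(pixels = pixels, channel_roles = channel_roles(protocol),
         protocol = protocol, um_per_px = um_per_px, frame_id = frame_id,
         background_level = background_level, noise_sd = noise_sd),
    class = "if_frame"
  )
}

# Ellipse pixel mask inside an H x W frame. Returns integer pixel indices
# (column-major, 1-based) and their (row, col) coordinates.
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  ext <- max(a, b)
  r0 <- max(1L, floor(cy - ext)); r1 <- min(H, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(W, ceiling(cx + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  rho2 <- u * u + v * v
  keep <- rho2 <= 1
  if (!any(keep)) return(NULL)
  rr <- rep(rows, times = length(cols))[keep]
  cc <- rep(cols, each = length(rows))[keep]
  list(idx = rr + (cc - 1L) * H, row = rr, col = cc, rho2 = rho2[keep])
}

# Texture renderers: given the mask geometry, return the signal added to each
# mask pixel. Filamentous = 3-8 anti-aliased line segments through the
# cytoplasm; punctate = Gaussian spots (sigma 2-3 px); diffuse = flat fill.
render_texture <- function(texture, scale, px, cy, cx, radius_px) {
  n <- length(px$idx)
  if (texture == "diffuse") return(rep(scale, n))
  if (texture == "punctate") {
    val <- rep(0.25 * scale, n)
    nspots <- max(5L, min(30L, as.integer(round(n / 60))))
    centers <- sample.int(n, nspots, replace = TRUE)
    sig <- stats::runif(nspots, 2, 3)
    for (s in seq_len(nspots)) {
      d2 <- (px$row - px$row[centers[s]])^2 + (px$col - px$col[centers[s]])^2
      val <- val + 1.3 * scale * exp(-d2 / (2 * sig[s]^2))
    }
    return(val)
  }
  if (texture == "filamentous") {
    val <- rep(0.20 * scale, n)
    # constant filament density: 3-8 segments scaled with cytoplasm area so
    # small cells keep resolvable individual fibres
    nlines <- max(3L, min(8L, as.integer(round(n / 250))))
    for (l in seq_len(nlines)) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(2, -0.4, 0.4) * radius_px
      y0 <- cy + off[1]; x0 <- cx + off[2]
      d <- abs((px$col - x0) * sin(th) - (px$row - y0) * cos(th))
      t <- stats::runif(1, 1.2, 1.8)
      val <- val + 1.2 * scale * pmax(0, 1 - (d / t)^2)
    }
    return(val)
  }
  rep(0, n)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Render one synthetic frame with ground truth
#'
#' Draws a Poisson number of instances of every population, places them by
#' rejection sampling (WBC crowding allows up to 30% mask overlap; a
#' DAPI-negative instance is "adjacent" when placed against a nucleated cell),
#' renders the nuclear stain and the per-channel signal textures, and adds
#' per-channel background and Gaussian noise.
#'
#' @param spec A [sample_spec()].
#' @param frame_index Frame number in `1:spec$frames`.
#' @return A list with elements:
#'   \describe{
#'     \item{frame}{an `if_frame` (4-channel pixel array + metadata)}
#'     \item{truth}{data.frame of ground-truth events (one row per rendered
#'       instance): centroid, true label, per-channel positivity, attachment
#'       state for DAPI-negative events}
#'     \item{truth_cell_labels, truth_nuc_labels}{integer label matrices
#'       mapping pixels to ground-truth event ids}
#'   }
#' @export
render_frame <- function(spec, frame_index = 1L) {
  stopifnot(inherits(spec, "sample_spec"),
            frame_index >= 1, frame_index <= spec$frames)
  with_seed(derive_seed(spec$seed, frame_index), {
    H <- spec$frame_px; W <- spec$frame_px
    arr <- array(0, dim = c(H, W, 4))
    cell_lab <- matrix(0L, H, W)
    nuc_lab <- matrix(0L, H, W)
    truth <- list()
    k <- 0L
    placed <- list() # per population: matrix of (cy, cx, r)
    nucleated <- NULL # (cy, cx, r) of all dapi-positive instances

    pops <- spec$populations
    ord <- order(!vapply(pops, function(p) p$dapi_positive, logical(1)))
    pops <- pops[ord]

    for (pop in pops) {
      n_inst <- stats::rpois(1, pop$count_per_frame)
      if (n_inst == 0) next
      max_overlap <- if (pop$label == "WBC") 0.30 else 0.10
      for (i in seq_len(n_inst)) {
        d_um <- rtrunc_norm(1, pop$cell_diameter_um[1], pop$cell_diameter_um[2],
                            pop$cell_diameter_um[3], pop$cell_diameter_um[4])
        r_px <- d_um / 2 / spec$um_per_px
        ecc <- min(0.98, max(0, stats::rnorm(1, pop$eccentricity[1],
                                             pop$eccentricity[2])))
        aspect <- (1 - ecc^2)^0.25
        a <- r_px / aspect; b <- r_px * aspect
        theta <- stats::runif(1, 0, pi)

        attached <- FALSE
        ok <- FALSE
        for (attempt in 1:200) {
          anchor <- NULL
          if (!pop$dapi_positive && !is.null(nucleated) &&
              stats::runif(1) < pop$attach_prob) {
            anchor <- nucleated[sample.int(nrow(nucleated), 1), ]
            attached_try <- TRUE
          } else if (pop$cluster_propensity > 0 &&
                     !is.null(placed[[pop$label]]) &&
                     stats::runif(1) < pop$cluster_propensity) {
            pp <- placed[[pop$label]]
            anchor <- pp[sample.int(nrow(pp), 1), ]
            attached_try <- FALSE
          } else {
            attached_try <- FALSE
          }
          if (!is.null(anchor)) {
            # "in contact": tangent to just-separated
            dist <- (anchor[3] + r_px) * stats::runif(1, 1.03, 1.15)
            ang <- stats::runif(1, 0, 2 * pi)
            cy <- anchor[1] + dist * sin(ang)
            cx <- anchor[2] + dist * cos(ang)
          } else {
            cy <- stats::runif(1, r_px + 1, H - r_px)
            cx <- stats::runif(1, r_px + 1, W - r_px)
          }
          if (cy < 2 || cy > H - 1 || cx < 2 || cx > W - 1) next
          px <- ellipse_pixels(cy, cx, a, b, theta, H, W)
          if (is.null(px)) next
          ovl <- mean(cell_lab[px$idx] > 0L)
          if (ovl <= max_overlap) {
            ok <- TRUE
            attached <- attached_try && !is.null(anchor)
            break
          }
        }
        if (!ok) {
          stop("overlap saturation: cannot place population '", pop$label,
               "' at the requested density", call. = FALSE)
        }

        k <- k + 1L
        cell_lab[px$idx] <- k

        # channel expression for this instance (variable markers resolve here)
        expressed <- c(ck = FALSE, ch3 = FALSE, ch4 = FALSE)
        for (nm in names(pop$channel_profile)) {
          p <- pop$channel_profile[[nm]]
          if (isTRUE(p$expressed) && stats::runif(1) < p$express_prob) {
            expressed[nm] <- TRUE
            ci <- match(nm, c("ck", "ch3", "ch4")) + 1L
            arr[, , ci][px$idx] <- arr[, , ci][px$idx] +
              render_texture(p$texture, p$intensity_scale, px, cy, cx, r_px)
          }
        }

        if (pop$dapi_positive) {
          npx <- ellipse_pixels(cy, cx, a * sqrt(pop$nucleus_fraction),
                                b * sqrt(pop$nucleus_fraction), theta, H, W)
          if (!is.null(npx)) {
            # gentle radial profile keeps a single interior maximum per
            # nucleus, which seeds the watershed split of touching cells
            arr[, , 1][npx$idx] <- arr[, , 1][npx$idx] +
              pop$dapi_intensity * (1 - 0.35 * npx$rho2)
            nuc_lab[npx$idx] <- k
          }
          nucleated <- rbind(nucleated, c(cy, cx, r_px))
        }
        placed[[pop$label]] <- rbind(placed[[pop$label]], c(cy, cx, r_px))

        truth[[k]] <- data.frame(
          frame = frame_index, event_id = k, label = pop$label,
          centroid_row = cy, centroid_col = cx,
          diameter_um = d_um, eccentricity = ecc,
          dapi_positive = pop$dapi_positive,
          ck_positive = unname(expressed["ck"]),
          ch3_positive = unname(expressed["ch3"]),
          ch4_positive = unname(expressed["ch4"]),
          attachment = if (pop$dapi_positive) NA_character_ else
            if (attached) "adjacent" else "isolated",
          stringsAsFactors = FALSE
        )
      }
    }

    for (ci in 1:4) {
      arr[, , ci] <- pmax(0, arr[, , ci] + spec$background_level[ci] +
                            stats::rnorm(H * W, 0, spec$noise_sd[ci]))
    }
    truth_df <- if (k > 0) do.call(rbind, truth) else
      data.frame(frame = integer(), event_id = integer(), label = character(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 diameter_um = numeric(), eccentricity = numeric(),
                 dapi_positive = logical(), ck_positive = logical(),
                 ch3_positive = logical(), ch4_positive = logical(),
                 attachment = character(), stringsAsFactors = FALSE)
    list(
      frame = new_frame(arr, spec$protocol, spec$um_per_px,
                        frame_id = paste0(spec$patient_id, "_d", spec$draw, "_f",
                                          frame_index),
                        spec$background_level, spec$noise_sd),
      truth = truth_df,
      truth_cell_labels = cell_lab,
      truth_nuc_labels = nuc_lab
    )
  })
}

#' Write / read a frame as a multi-page TIFF with a metadata sidecar
#'
#' One 32-bit float page per channel plus a YAML sidecar (`<file>.yml`) holding
#' channel roles, pixel size and frame id.
#'
#' @param x An `if_frame`.
#' @param path Output TIFF path.
#' @return `write_frame_tiff` returns `path` invisibly; `read_frame_tiff`
#'   returns an `if_frame`.
#' @export
write_frame_tiff <- function(x, path) {
  stopifnot(inherits(x, "if_frame"))
  # TIFF stores [0,1]; keep the normalization factor in the sidecar
  scale <- max(x$pixels, 1)
  pages <- lapply(1:4, function(ci) x$pixels[, , ci] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(channel_roles = x$channel_roles, protocol = x$protocol,
         um_per_px = x$um_per_px, frame_id = x$frame_id,
         intensity_scale = scale,
         background_level = x$background_level, noise_sd = x$noise_sd),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 4)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  scale <- meta$intensity_scale %||% 1
  arr <- array(0, dim = c(dim(pages[[1]]), 4))
  for (ci in 1:4) arr[, , ci] <- pages[[ci]] * scale
  new_frame(arr, meta$protocol, meta$um_per_px, meta$frame_id,
            unlist(meta$background_level), unlist(meta$noise_sd))
}
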