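# Shared fixtures, all generated in code.

# A frame with hand-placed geometry: build an if_frame directly from a pixel
# array (bypassing the renderer) so analytic oracles apply.
manual_frame <- function(arr, protocol = "Landscape", um_per_px = 1,
                         background_level = rep(0, 4),
                         noise_sd = rep(1e-6, 4)) {
  rarebiopsy:::new_frame(arr, protocol, um_per_px, "manual",
                         background_level, noise_sd)
}

# A synthetic segmentation built straight from label matrices.
manual_segmentation <- function(cell_labels, nuc_labels, um_per_px = 1) {
  n <- max(cell_labels)
  cs <- rarebiopsy:::label_centroids(cell_labels, n)
  ns <- rarebiopsy:::label_centroids(nuc_labels, n)
  events <- data.frame(
    event_id = seq_len(n), frame_id = "manual",
    centroid_row = cs$row, centroid_col = cs$col,
    dapi_positive = ns$area > 0,
    nucleus_area_px = ns$area, cell_area_px = cs$area,
    stringsAsFactors = FALSE
  )
  structure(list(events = events, nuc_labels = nuc_labels,
                 cell_labels = cell_labels, um_per_px = um_per_px,
                 frame_id = "manual"),
            class = "segmentation")
}

# Disk / ellipse rasterizer independent of the package's renderer.
disk_mask <- function(H, W, cy, cx, a, b = a, theta = 0) {
  m <- matrix(FALSE, H, W)
  for (r in 1:H) for (cc in 1:W) {
    dx <- cc - cx; dy <- r - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    if (u^2 + v^2 <= 1) m[r, cc] <- TRUE
  }
  m
}

# Single-population slide spec for texture / shape round trips.
one_pop_spec <- function(pop, rate, frame_px = 320, frames = 1, seed = 1,
                         protocol = "Landscape") {
  pop$count_per_frame <- rate
  sample_spec("fix", frames = frames, frame_px = frame_px,
              populations = list(pop), seed = seed, protocol = protocol)
}

# Benchmark slide used by the end-to-end acceptance checks: dense WBC
# monolayer plus every default rare phenotype spiked at a workable rate.
benchmark_slide_spec <- function(frames = 20, seed = 101) {
  pops <- phenotype_library("Landscape")
  pops$WBC$count_per_frame <- 60
  for (nm in c("epi_ctc", "dapi_only", "third_only", "mega", "mes_ctc",
               "cec", "onc_ck", "onc_ck_third", "onc_ck_fourth",
               "onc_ck_third_fourth")) {
    pops[[nm]]$count_per_frame <- 0.7
  }
  pops$ck_debris$count_per_frame <- 0.5
  sample_spec("bench", frames = frames, frame_px = 512,
              populations = pops, seed = seed)
}

# Feature-space cells for a population, fixed seed.
phen_features <- function(pop, n, seed) {
  set.seed(seed)
  simulate_phenotype_features(pop, n)
}
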