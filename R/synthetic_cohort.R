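#' Published cohort enumeration summary
#'
#' The per-classification cohort summary (sample positivity at >= 5 events/mL,
#' mean, SE, percent of total, median, range) for both staining protocols, as
#' shipped in `inst/extdata/published_enumeration_summary.csv`. Used as the
#' default effect sizes of the synthetic patient arm and as input for
#' composition arithmetic.
#'
#' @return data.frame.
#' @export
published_enumeration_summary <- function() {
  path <- system.file("extdata", "published_enumeration_summary.csv",
                      package = "rarebiopsy", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Default normal-donor per-class mean enumerations (Landscape)
#'
#' Chosen so the ND aggregates match the published ND cohort: rare-cell mean
#' ~43.2 /mL, CK-positive cell mean ~19-20 /mL, total ~50 /mL, oncosomes
#' scarce.
#' @return Named numeric vector (events/mL) over the 12 Landscape classes.
#' @export
nd_class_means <- function() {
  c("DAPI only" = 9.0, "CK" = 0.8, "Vim" = 4.5, "CD45/CD31" = 2.6,
    "CK|Vim" = 2.3, "CK|CD45/CD31" = 1.6, "Vim|CD45/CD31" = 7.0,
    "CK|Vim|CD45/CD31" = 15.4,
    "Onc CK" = 1.5, "Onc CK|Vim" = 0.8, "Onc CK|CD45/CD31" = 1.2,
    "Onc CK|Vim|CD45/CD31" = 3.25)
}

# Per-class concentration distribution for the patient arm, matched to the
# published median and mean of each classification: lognormal with
# meanlog = log(median), sdlog = sqrt(2 log(mean/median)). Classes whose
# printed median is ~0 fall back to a zero-heavy gamma with shape matched to
# the median/mean ratio.
class_dispersion <- function(protocol) {
  pub <- published_enumeration_summary()
  pub <- pub[pub$protocol == protocol, ]
  ratio <- pmin(pmax(pub$median_events_per_ml / pub$mean_events_per_ml,
                     0.005), 0.98)
  out <- lapply(seq_len(nrow(pub)), function(i) {
    if (pub$median_events_per_ml[i] > 0.05 * pub$mean_events_per_ml[i]) {
      list(type = "lognormal",
           sdlog = sqrt(2 * log(1 / ratio[i])))
    } else {
      list(type = "gamma", shape = gamma_shape_from_median_mean(ratio[i]))
    }
  })
  stats::setNames(out, pub$classification)
}

# draw one concentration per class given per-class means and dispersion
draw_concentrations <- function(means, disp) {
  vapply(seq_along(means), function(i) {
    d <- disp[[names(means)[i]]] %||% list(type = "lognormal", sdlog = 0.9)
    if (d$type == "lognormal") {
      stats::rlnorm(1, log(means[i]) - d$sdlog^2 / 2, d$sdlog)
    } else {
      stats::rgamma(1, shape = d$shape, rate = d$shape / means[i])
    }
  }, 0)
}

#' Define a synthetic cohort
#'
#' Study-shaped defaults: 10 patients with two draws each (two patients missing
#' draw 2, giving 18 samples), each draw stained with both protocols; 50 normal
#' donors with one Landscape-stained sample each. Patient per-class mean
#' enumerations default to the published cohort summary; normal-donor means to
#' [nd_class_means()]. Per-sample concentrations are lognormal with per-class
#' dispersion matched to the published median/mean ratios (a zero-heavy gamma
#' where the published median is ~0), multiplied by a per-draw lognormal
#' tumor-burden latent shared by CK-positive and oncosome classes (this latent
#' is what links the two assays and survival).
#'
#' @param n_mcrc_patients,n_nd_donors Cohort sizes.
#' @param n_missing_draw2 Patients missing their second draw.
#' @param n_missing_pfs Patients without a PFS value.
#' @param mcrc_means_landscape,mcrc_means_cdx2,nd_means Named per-class mean
#'   events/mL.
#' @param pfs_analyte,pfs_direction,pfs_strength,censoring_fraction The PFS
#'   model: the draw-1 Landscape analyte monotonically linked (Gaussian copula,
#'   `pfs_strength` in [0, 1]) to lognormal PFS (mean ~7 months); direction
#'   +1 = higher analyte, longer PFS.
#' @param burden_sd SD (log scale) of the shared tumor-burden latent.
#' @param wbc_concentration_mean Typical leukocyte concentration (cells/mL);
#'   used as the median of the per-sample lognormal.
#' @param cells_per_slide Nucleated cells plated per slide.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mcrc_patients = 10, n_nd_donors = 50,
                        n_missing_draw2 = 2, n_missing_pfs = 1,
                        mcrc_means_landscape = NULL, mcrc_means_cdx2 = NULL,
                        nd_means = nd_class_means(),
                        pfs_analyte = "Onc CK|CD45/CD31",
                        pfs_direction = 1, pfs_strength = 0.8,
                        censoring_fraction = 0,
                        burden_sd = 0.5,
                        wbc_concentration_mean = 5.66e6,
                        cells_per_slide = 3e6,
                        seed = 1L) {
  if (censoring_fraction >= 1) stop("censoring fraction must be < 1",
                                    call. = FALSE)
  pub <- published_enumeration_summary()
  get_means <- function(p) {
    m <- pub[pub$protocol == p, ]
    stats::setNames(m$mean_events_per_ml, m$classification)
  }
  structure(list(
    n_mcrc_patients = n_mcrc_patients, n_nd_donors = n_nd_donors,
    n_missing_draw2 = n_missing_draw2, n_missing_pfs = n_missing_pfs,
    mcrc_means_landscape = mcrc_means_landscape %||% get_means("Landscape"),
    mcrc_means_cdx2 = mcrc_means_cdx2 %||% get_means("CDX2"),
    nd_means = nd_means,
    pfs_analyte = pfs_analyte, pfs_direction = pfs_direction,
    pfs_strength = pfs_strength, censoring_fraction = censoring_fraction,
    burden_sd = burden_sd,
    wbc_concentration_mean = wbc_concentration_mean,
    cells_per_slide = cells_per_slide, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# classes that scale with the shared tumor-burden latent
burden_classes <- function(classes) {
  grepl("^Onc ", classes) | grepl("(^|\\|)CK(\\||$)", classes)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-sample true concentrations, leukocyte concentrations and survival
#' times from a [cohort_spec()]. Deterministic given the spec (including its
#' seed).
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`:
#'   \describe{
#'     \item{samples}{data.frame: `sample_id`, `patient_id`, `draw`, `arm`,
#'       `protocol`, `wbc_concentration_per_ml`, `expected_volume_ml`}
#'     \item{truth}{data.frame of true per-class concentrations
#'       (`sample_id`, `classification`, `true_events_per_ml`)}
#'     \item{survival}{data.frame: `patient_id`, `pfs_months`, `event_flag`}
#'     \item{spec}{the input spec}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    samples <- list(); truth <- list()
    disp_l <- class_dispersion("Landscape")
    disp_c <- class_dispersion("CDX2")
    # normal donors: mildly skewed, matching the published ND aggregate
    # median/mean ratio (~0.8 -> lognormal sdlog ~0.67)
    disp_nd <- stats::setNames(
      rep(list(list(type = "lognormal", sdlog = 0.67)),
          length(spec$nd_means)), names(spec$nd_means))

    add_sample <- function(sid, pid, draw, arm, protocol, means, disp,
                           burden) {
      # median-matched lognormal: the published typical concentration is the
      # cohort median, so analysed volumes centre on ~0.53 mL
      wbc <- stats::rlnorm(1, log(spec$wbc_concentration_mean), 0.2)
      vol <- spec$cells_per_slide / wbc
      cls <- names(means)
      conc <- draw_concentrations(means, disp)
      conc[burden_classes(cls)] <- conc[burden_classes(cls)] * burden
      samples[[sid]] <<- data.frame(
        sample_id = sid, patient_id = pid, draw = draw, arm = arm,
        protocol = protocol, wbc_concentration_per_ml = wbc,
        expected_volume_ml = vol, stringsAsFactors = FALSE)
      truth[[sid]] <<- data.frame(
        sample_id = sid, patient_id = pid, draw = draw, arm = arm,
        protocol = protocol, classification = cls,
        true_events_per_ml = conc, stringsAsFactors = FALSE)
    }

    miss2 <- if (spec$n_missing_draw2 > 0) {
      sample.int(spec$n_mcrc_patients, spec$n_missing_draw2)
    } else integer(0)
    for (p in seq_len(spec$n_mcrc_patients)) {
      pid <- sprintf("P%02d", p)
      draws <- if (p %in% miss2) 1L else c(1L, 2L)
      for (d in draws) {
        burden <- stats::rlnorm(1, -spec$burden_sd^2 / 2, spec$burden_sd)
        add_sample(sprintf("%s_d%d_L", pid, d), pid, d, "mCRC", "Landscape",
                   spec$mcrc_means_landscape, disp_l, burden)
        add_sample(sprintf("%s_d%d_C", pid, d), pid, d, "mCRC", "CDX2",
                   spec$mcrc_means_cdx2, disp_c, burden)
      }
    }
    for (q in seq_len(spec$n_nd_donors)) {
      pid <- sprintf("ND%02d", q)
      add_sample(sprintf("%s_d1_L", pid), pid, 1L, "ND", "Landscape",
                 spec$nd_means, disp_nd, 1)
    }
    truth <- do.call(rbind, truth)
    samples <- do.call(rbind, samples)
    rownames(truth) <- rownames(samples) <- NULL

    # survival: PFS linked to the draw-1 Landscape concentration of the
    # configured analyte through a Gaussian copula
    pids <- sprintf("P%02d", seq_len(spec$n_mcrc_patients))
    a <- vapply(pids, function(pid) {
      v <- truth$true_events_per_ml[truth$patient_id == pid &
                                      truth$draw == 1 &
                                      truth$protocol == "Landscape" &
                                      truth$classification == spec$pfs_analyte]
      if (length(v)) v[1] else NA_real_
    }, 0)
    n <- length(pids)
    z_a <- stats::qnorm(rank(a, ties.method = "first") / (n + 1)) *
      spec$pfs_direction
    s <- spec$pfs_strength
    z <- s * z_a + if (s < 1) sqrt(1 - s^2) * stats::rnorm(n) else 0
    sdlog <- 0.5
    pfs <- stats::qlnorm(stats::pnorm(z), log(6.98) - sdlog^2 / 2, sdlog)
    event <- rep(1L, n)
    if (spec$censoring_fraction > 0) {
      cens <- stats::runif(n) < spec$censoring_fraction
      event[cens] <- 0L
    }
    if (spec$n_missing_pfs > 0) {
      pfs[sample.int(n, min(spec$n_missing_pfs, n))] <- NA_real_
    }
    survival <- data.frame(patient_id = pids, pfs_months = pfs,
                           event_flag = event, stringsAsFactors = FALSE)
    structure(list(samples = samples, truth = truth, survival = survival,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' Count-level enumeration of a synthetic cohort
#'
#' Bypasses imaging: for each sample, draws the realized nucleated-cell count
#' and per-class Poisson event counts implied by the true concentrations, then
#' converts back to events/mL through [blood_volume()] -- the ground-truth
#' route used to validate the enumeration arithmetic and to drive the
#' cohort-level statistics at full slide scale.
#'
#' @param cohort A `synthetic_cohort`.
#' @param seed Integer seed.
#' @return Stacked enumeration data.frame (one row per sample x
#'   classification) with `patient_id`, `draw`, `arm`, `protocol`,
#'   `raw_count`, `events_per_ml`, `positive`, `frequency_pct`,
#'   `blood_volume_ml`.
#' @export
simulate_enumeration <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  with_seed(seed, {
    out <- vector("list", nrow(cohort$samples))
    for (i in seq_len(nrow(cohort$samples))) {
      s <- cohort$samples[i, ]
      tr <- cohort$truth[cohort$truth$sample_id == s$sample_id, ]
      nuclei <- stats::rpois(1, cohort$spec$cells_per_slide)
      vol <- blood_volume(nuclei, s$wbc_concentration_per_ml)
      counts <- stats::rpois(nrow(tr), tr$true_events_per_ml * vol)
      epm <- to_events_per_ml(counts, vol)
      total <- sum(epm)
      out[[i]] <- data.frame(
        sample_id = s$sample_id, patient_id = s$patient_id, draw = s$draw,
        arm = s$arm, protocol = s$protocol,
        classification = tr$classification,
        raw_count = counts, events_per_ml = epm,
        positive = epm >= 5,
        frequency_pct = if (total > 0) 100 * epm / total else 0,
        blood_volume_ml = vol, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Materialize a cohort sample as a renderable slide spec
#'
#' Maps a sample's true concentrations onto per-frame Poisson rates at the
#' requested (desk) scale, so the image pipeline can be run end-to-end on it.
#' The per-frame rate of a class is `concentration x frame blood volume`,
#' where the frame volume follows from the WBC rate and the sample's leukocyte
#' concentration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sample_id Which sample.
#' @param frames,frame_px,wbc_per_frame Desk-scale geometry.
#' @param rate_multiplier Optional factor inflating rare-class rates (spiking
#'   more events per frame for detection benchmarks); enumeration must then
#'   divide by it.
#' @return A [sample_spec()].
#' @export
as_sample_spec <- function(cohort, sample_id, frames = 8L, frame_px = 512L,
                           wbc_per_frame = 100, rate_multiplier = 1) {
  s <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  stopifnot(nrow(s) == 1)
  tr <- cohort$truth[cohort$truth$sample_id == sample_id, ]
  frame_vol_ml <- wbc_per_frame / s$wbc_concentration_per_ml
  lib <- phenotype_library(s$protocol)
  pops <- list(WBC = lib$WBC)
  pops$WBC$count_per_frame <- wbc_per_frame
  for (i in seq_len(nrow(tr))) {
    cl <- tr$classification[i]
    pop <- population_for_class(cl, s$protocol)
    pop$count_per_frame <- tr$true_events_per_ml[i] * frame_vol_ml *
      rate_multiplier
    pops[[cl]] <- pop
  }
  sample_spec(s$patient_id, s$draw, s$protocol,
              wbc_concentration_per_ml = s$wbc_concentration_per_ml,
              frames = frames, frame_px = frame_px, populations = pops,
              seed = derive_seed(cohort$spec$seed,
                                 match(sample_id, cohort$samples$sample_id)))
}

#' Population spec for a channel-type classification
#'
#' Looks the label up in the [phenotype_library()]; classifications without a
#' bespoke phenotype get a generic spec whose expressed channels are parsed
#' from the label (diffuse texture, mid intensity).
#'
#' @param label A classification label (possibly "Onc "-prefixed).
#' @param protocol Staining protocol.
#' @return A [population_spec()].
#' @export
population_for_class <- function(label, protocol = "Landscape") {
  lib <- phenotype_library(protocol)
  hit <- vapply(lib, function(p) identical(p$label, label), logical(1))
  if (any(hit)) return(lib[[which(hit)[1]]])
  ch <- channel_roles(protocol)[2:4]
  onc <- grepl("^Onc ", label)
  base <- sub("^Onc ", "", label)
  parts <- if (base == "DAPI only") character(0) else
    strsplit(base, "|", fixed = TRUE)[[1]]
  prof <- list()
  nm <- c("ck", "ch3", "ch4")
  for (i in 1:3) {
    if (ch[i] %in% parts) {
      prof[[nm[i]]] <- list(expressed = TRUE, texture = "diffuse",
                            intensity_scale = if (onc) 0.45 else 0.40)
    }
  }
  if (onc) {
    population_spec(label, 0, c(6, 1.5, 3, 10), 0, c(0.10, 0.05), prof,
                    dapi_positive = FALSE, attach_prob = 0.49)
  } else {
    population_spec(label, 0, c(13, 1.3, 9, 18), 0.55, c(0.40, 0.10), prof)
  }
}

#' Sample shared morphometric features for a phenotype
#'
#' Draws the eight shared multi-assay features directly from a population
#' spec's geometry (sizes, nuclear fraction, eccentricity, channel profile)
#' with multiplicative measurement noise, emulating what [extract_features()]
#' measures on rendered instances. Used for feature-space benchmarks where
#' rendering every cell is unnecessary.
#'
#' @param pop A [population_spec()].
#' @param n Number of cells.
#' @param background CK-channel background level.
#' @param jitter Multiplicative log-SD of measurement noise.
#' @return data.frame with [shared_feature_names()] columns and `label`.
#' @export
simulate_phenotype_features <- function(pop, n, background = 0.1,
                                        jitter = 0.05) {
  d <- rtrunc_norm(n, pop$cell_diameter_um[1], pop$cell_diameter_um[2],
                   pop$cell_diameter_um[3], pop$cell_diameter_um[4])
  ecc <- pmin(0.98, pmax(0, stats::rnorm(n, pop$eccentricity[1],
                                         pop$eccentricity[2])))
  cell_area <- pi * (d / 2)^2 * exp(stats::rnorm(n, 0, jitter))
  nf <- pmin(0.95, pmax(0.05, pop$nucleus_fraction *
                          exp(stats::rnorm(n, 0, 0.08))))
  has_nuc <- pop$dapi_positive
  nucleus_area <- if (has_nuc) nf * cell_area else rep(0, n)
  ratio <- if (has_nuc) nucleus_area / cell_area else rep(0, n)
  nuc_ecc <- if (has_nuc) {
    pmin(0.98, pmax(0, ecc * 0.8 + stats::rnorm(n, 0, 0.05)))
  } else rep(0, n)
  q <- sqrt(sqrt(1 - ecc^2)) # aspect^(1/2) scaling of the two semi-axes
  r_eq <- sqrt(cell_area / pi)
  outline <- r_eq * (1 / q + q) / 2 * exp(stats::rnorm(n, 0, jitter))
  dapi_med <- if (has_nuc) {
    background + 0.82 * pop$dapi_intensity * exp(stats::rnorm(n, 0, jitter))
  } else {
    background * exp(stats::rnorm(n, 0, jitter))
  }
  ckp <- pop$channel_profile$ck
  on <- if (isTRUE(ckp$expressed)) stats::runif(n) < ckp$express_prob else
    rep(FALSE, n)
  ck_signal <- switch(ckp$texture %||% "none",
                      diffuse = ckp$intensity_scale,
                      filamentous = 0.35 * ckp$intensity_scale,
                      punctate = 0.30 * ckp$intensity_scale, 0)
  ck_med <- background + ifelse(on, ck_signal, 0) *
    exp(stats::rnorm(n, 0, jitter))
  out <- data.frame(
    dapi_median_intensity = dapi_med,
    ck_median_intensity = ck_med,
    cell_eccentricity = ecc,
    nucleus_eccentricity = nuc_ecc,
    cell_area_um2 = cell_area,
    nucleus_area_um2 = nucleus_area,
    nuclear_to_cell_area_ratio = ratio,
    mean_outline_to_nucleus_center_distance_um = outline,
    stringsAsFactors = FALSE
  )
  out$label <- rep(pop$label, n)
  out$dapi_positive <- rep(has_nuc, n)
  out
}
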