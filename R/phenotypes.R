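#' Channel roles for a staining protocol
#'
#' Both protocols image four fluorescence channels. Channel 1 is always the
#' nuclear stain (DAPI) and channel 2 the pan-cytokeratin stain (CK). The
#' "Landscape" protocol adds vimentin (Vim) and a combined CD45/CD31 exclusion
#' channel; the "CDX2" protocol adds the intestinal transcription factor CDX2
#' and CD45.
#'
#' @param protocol `"Landscape"` or `"CDX2"`.
#' @return Character vector of length 4 naming the channels in order.
#' @export
channel_roles <- function(protocol = c("Landscape", "CDX2")) {
  protocol <- match.arg(protocol)
  if (protocol == "Landscape") {
    c("DAPI", "CK", "Vim", "CD45/CD31")
  } else {
    c("DAPI", "CK", "CDX2", "CD45")
  }
}

#' Channel-type classification taxonomy
#'
#' The 12 per-protocol channel-type classifications: 8 nucleated (DAPI-positive)
#' cell classes formed from the three non-DAPI markers, and the 4 corresponding
#' DAPI-negative oncosome classes ("Onc " prefix), which are by definition
#' CK-positive.
#'
#' @param protocol `"Landscape"` or `"CDX2"`.
#' @return Character vector of the 12 classification labels, cell classes
#'   first, in marker order.
#' @export
classification_levels <- function(protocol = c("Landscape", "CDX2")) {
  protocol <- match.arg(protocol)
  ch <- channel_roles(protocol)[2:4]
  cells <- c(
    "DAPI only",
    ch[1], ch[2], ch[3],
    paste(ch[1], ch[2], sep = "|"),
    paste(ch[1], ch[3], sep = "|"),
    paste(ch[2], ch[3], sep = "|"),
    paste(ch[1], ch[2], ch[3], sep = "|")
  )
  onc <- paste("Onc", c(
    ch[1],
    paste(ch[1], ch[2], sep = "|"),
    paste(ch[1], ch[3], sep = "|"),
    paste(ch[1], ch[2], ch[3], sep = "|")
  ))
  c(cells, onc)
}

#' Define a synthetic cell or oncosome population
#'
#' A population spec describes one phenotype rendered by the slide simulator:
#' its per-frame Poisson rate, size distribution, nuclear fraction, per-channel
#' expression (with signal texture and intensity), and placement behaviour.
#'
#' @param label Phenotype name. Ground-truth labels use the channel-type
#'   classification taxonomy plus `"WBC"` and optional debris classes.
#' @param count_per_frame Poisson mean number of instances per frame.
#' @param cell_diameter_um Numeric `c(mean, sd, min, max)` of cell equivalent
#'   diameter in micrometres.
#' @param nucleus_fraction Fraction of cell area occupied by the nucleus
#'   (0 for DAPI-negative populations).
#' @param eccentricity Numeric `c(mean, sd)` of elliptical eccentricity of the
#'   cell outline.
#' @param channel_profile Named list for channels 2:4 (`ck`, `ch3`, `ch4`),
#'   each `list(expressed =, texture =, intensity_scale =, express_prob =)`.
#'   `texture` is one of `"filamentous"`, `"diffuse"`, `"punctate"`;
#'   `express_prob` allows variably expressed markers (default 1 when
#'   expressed).
#' @param cluster_propensity Probability an instance is placed adjacent to a
#'   previously placed instance of the same population.
#' @param dapi_positive Logical; `FALSE` only for oncosome/debris populations.
#' @param attach_prob For DAPI-negative populations, probability of placement
#'   adjacent to a nucleated cell (the attached-vs-isolated dichotomy).
#' @param dapi_intensity Peak DAPI signal for the nucleus fill.
#' @return A `population_spec` list.
#' @export
population_spec <- function(label,
                            count_per_frame,
                            cell_diameter_um,
                            nucleus_fraction,
                            eccentricity = c(0.3, 0.1),
                            channel_profile = list(),
                            cluster_propensity = 0,
                            dapi_positive = TRUE,
                            attach_prob = 0,
                            dapi_intensity = 0.6) {
  stopifnot(
    count_per_frame >= 0,
    length(cell_diameter_um) == 4, all(cell_diameter_um[c(1, 3, 4)] > 0),
    nucleus_fraction >= 0, nucleus_fraction <= 1,
    cluster_propensity >= 0, cluster_propensity <= 1
  )
  prof <- list(ck = NULL, ch3 = NULL, ch4 = NULL)
  for (nm in names(channel_profile)) {
    p <- channel_profile[[nm]]
    p$express_prob <- p$express_prob %||% 1
    if (isTRUE(p$expressed)) {
      stopifnot(p$intensity_scale > 0,
                p$texture %in% c("filamentous", "diffuse", "punctate"))
    } else {
      p$intensity_scale <- 0
    }
    prof[[nm]] <- p
  }
  for (nm in names(prof)) {
    if (is.null(prof[[nm]])) {
      prof[[nm]] <- list(expressed = FALSE, texture = "none",
                         intensity_scale = 0, express_prob = 0)
    }
  }
  if (!dapi_positive) {
    stopifnot(nucleus_fraction == 0)
    if (grepl("^Onc ", label)) {
      stopifnot(isTRUE(prof$ck$expressed), cell_diameter_um[4] <= 12)
    }
  }
  structure(
    list(
      label = label,
      count_per_frame = count_per_frame,
      cell_diameter_um = cell_diameter_um,
      nucleus_fraction = nucleus_fraction,
      eccentricity = eccentricity,
      channel_profile = prof,
      cluster_propensity = cluster_propensity,
      dapi_positive = dapi_positive,
      attach_prob = attach_prob,
      dapi_intensity = dapi_intensity
    ),
    class = "population_spec"
  )
}

#' Built-in phenotype library
#'
#' Default population specs for the phenotypes the pipeline is designed to
#' recover: the dense WBC monolayer, epithelial and mesenchymal CTCs, a
#' CDX2-positive CTC, marker-sparse rare cells (DAPI-only, Vim-only),
#' megakaryocyte candidates (very large, punctate CD45/CD31), endothelial-like
#' cells (filamentous Vim with punctate CD45/CD31 and variable CK), the four
#' oncosome classes, and an elongated CK debris class used as a negative
#' control for the oncosome circularity rule.
#'
#' Sizes are stated relative to the ~10 um WBC; oncosomes range up to WBC size.
#' Rates are per frame and are normally overridden by the cohort generator.
#'
#' @param protocol `"Landscape"` or `"CDX2"`.
#' @return Named list of [population_spec()] objects.
#' @export
phenotype_library <- function(protocol = c("Landscape", "CDX2")) {
  protocol <- match.arg(protocol)
  ch3 <- if (protocol == "Landscape") "Vim" else "CDX2"
  ch4 <- if (protocol == "Landscape") "CD45/CD31" else "CD45"
  expr <- function(texture, scale, prob = 1) {
    list(expressed = TRUE, texture = texture, intensity_scale = scale,
         express_prob = prob)
  }
  lib <- list(
    WBC = population_spec(
      "WBC", 100, c(10, 1, 7, 13), 0.65, c(0.30, 0.12),
      list(ch4 = expr("diffuse", 0.35)), cluster_propensity = 0.10
    ),
    epi_ctc = population_spec(
      "CK", 0, c(16, 1.5, 12, 22), 0.50, c(0.30, 0.10),
      list(ck = expr("filamentous", 0.55)), cluster_propensity = 0.15
    ),
    dapi_only = population_spec(
      "DAPI only", 0, c(9, 0.8, 7, 12), 0.80, c(0.25, 0.10)
    ),
    third_only = population_spec(
      ch3, 0, c(12, 1.2, 9, 16), 0.55, c(0.45, 0.12),
      list(ch3 = expr("filamentous", 0.45))
    ),
    mega = population_spec(
      ch4, 0, c(30, 3, 22, 42), 0.55, c(0.60, 0.10),
      list(ch4 = expr("punctate", 0.50))
    ),
    onc_ck = population_spec(
      "Onc CK", 0, c(6, 1.5, 3, 10), 0, c(0.10, 0.05),
      list(ck = expr("diffuse", 0.50)), dapi_positive = FALSE,
      attach_prob = 0.49
    ),
    onc_ck_third = population_spec(
      paste0("Onc CK|", ch3), 0, c(6, 1.5, 3, 10), 0, c(0.10, 0.05),
      list(ck = expr("diffuse", 0.50), ch3 = expr("diffuse", 0.40)),
      dapi_positive = FALSE, attach_prob = 0.49
    ),
    onc_ck_fourth = population_spec(
      paste0("Onc CK|", ch4), 0, c(6, 1.5, 3, 10), 0, c(0.10, 0.05),
      list(ck = expr("diffuse", 0.50), ch4 = expr("diffuse", 0.40)),
      dapi_positive = FALSE, attach_prob = 0.49
    ),
    onc_ck_third_fourth = population_spec(
      paste0("Onc CK|", ch3, "|", ch4), 0, c(6, 1.5, 3, 10), 0, c(0.10, 0.05),
      list(ck = expr("diffuse", 0.50), ch3 = expr("diffuse", 0.40),
           ch4 = expr("diffuse", 0.40)),
      dapi_positive = FALSE, attach_prob = 0.49
    ),
    ck_debris = population_spec(
      "debris", 0, c(8, 1, 5, 11), 0, c(0.95, 0.02),
      list(ck = expr("diffuse", 0.45)), dapi_positive = FALSE
    )
  )
  if (protocol == "Landscape") {
    lib$mes_ctc <- population_spec(
      "CK|Vim", 0, c(14, 1.5, 10, 19), 0.50, c(0.65, 0.10),
      list(ck = expr("filamentous", 0.50), ch3 = expr("filamentous", 0.45))
    )
    lib$cec <- population_spec(
      "Vim|CD45/CD31", 0, c(20, 2, 15, 27), 0.45, c(0.85, 0.05),
      list(ch3 = expr("filamentous", 0.50),
           ch4 = expr("punctate", 0.40),
           ck = expr("diffuse", 0.35, prob = 0.46)),
      cluster_propensity = 0.36
    )
  } else {
    lib$cdx2_ctc <- population_spec(
      "CK|CDX2", 0, c(16, 1.5, 12, 22), 0.50, c(0.30, 0.10),
      list(ck = expr("filamentous", 0.55), ch3 = expr("diffuse", 0.45)),
      cluster_propensity = 0.20
    )
    lib$ck_cd45 <- population_spec(
      "CK|CD45", 0, c(12, 1.2, 9, 16), 0.55, c(0.40, 0.10),
      list(ck = expr("diffuse", 0.45), ch4 = expr("diffuse", 0.35))
    )
  }
  lib
}

#' Benchmark phenotypes for the multi-assay clustering analysis
#'
#' Eight populations that are morphometrically distinct in the eight shared
#' features, echoing the cell groups the joint clustering of the two assays is
#' expected to separate: the WBC-like background morphology, two large-nucleus
#' groups (round and eccentric), megakaryocyte-like giants, CK-only CTCs, an
#' elongated CK morphology, endothelial-like elongated cells with moderate CK,
#' and a large mega-like CK-positive group. Used as the ground-truth fixture
#' for silhouette-based cluster-number selection.
#'
#' @return Named list of [population_spec()] objects.
#' @export
multi_assay_benchmark_populations <- function() {
  mk <- function(label, d, ecc, nf, ck = 0) {
    prof <- if (ck > 0) {
      list(ck = list(expressed = TRUE, texture = "diffuse",
                     intensity_scale = ck))
    } else list()
    population_spec(label, 0, c(d, d * 0.07, d * 0.7, d * 1.4), nf,
                    c(ecc, 0.06), prof)
  }
  list(
    wbc_like = mk("wbc_like", 10, 0.30, 0.65),
    large_round_nuc = mk("large_round_nuc", 16, 0.10, 0.88),
    large_ecc_nuc = mk("large_ecc_nuc", 16, 0.70, 0.88),
    mega = mk("mega", 30, 0.60, 0.55),
    epi_ctc = mk("epi_ctc", 16, 0.25, 0.50, ck = 0.55),
    elongated_ck = mk("elongated_ck", 12, 0.92, 0.60, ck = 0.55),
    endothelial = mk("endothelial", 22, 0.80, 0.40, ck = 0.30),
    mega_like_ck = mk("mega_like_ck", 26, 0.30, 0.60, ck = 0.45)
  )
}
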