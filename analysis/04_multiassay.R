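#!/usr/bin/env Rscript
# Multi-assay analysis: cluster rare cells from both protocols jointly on the
# eight shared morphometric features (Ward linkage, silhouette-selected k)
# and correlate enumerations across the sample-matched assays.

suppressMessages(library(rarebiopsy))
dir.create("results", showWarnings = FALSE)

# joint clustering of the 8-phenotype benchmark population
bench <- multi_assay_benchmark_populations()
set.seed(3)
cells <- do.call(rbind, lapply(bench, simulate_phenotype_features, n = 60))
# alternate protocol labels as in a sample-matched two-stain design
cells$protocol <- rep(c("Landscape", "CDX2"), length.out = nrow(cells))
sol <- cluster_multi_assay(scale(as.matrix(cells[, shared_feature_names()])),
                           c(2, 16), protocol = cells$protocol)
cat("silhouette-selected k:", sol$k, "\n")
occ <- as.data.frame.matrix(sol$occupancy)
write.csv(occ, "results/multiassay_cluster_occupancy.csv")
pur <- table(sol$assignments, cells$label)
cat("cluster purity:",
    round(sum(apply(pur, 1, max)) / nrow(cells), 3), "\n")
write.csv(data.frame(k = as.integer(names(sol$silhouette_by_k)),
                     mean_silhouette = as.numeric(sol$silhouette_by_k)),
          "results/multiassay_silhouette_by_k.csv", row.names = FALSE)

# cross-assay enumeration correlations on the matched cohort
cohort <- generate_cohort(cohort_spec(seed = 1))
enum <- simulate_enumeration(cohort, seed = 2)
el <- enum[enum$protocol == "Landscape" & enum$arm == "mCRC", ]
ec <- enum[enum$protocol == "CDX2" & enum$arm == "mCRC", ]
el$sample_id <- paste0(el$patient_id, "_d", el$draw)
ec$sample_id <- paste0(ec$patient_id, "_d", ec$draw)
cx <- cross_assay_correlations(el, ec)
write.csv(as.data.frame(cx$rho), "results/cross_assay_rho.csv")
write.csv(as.data.frame(cx$p), "results/cross_assay_p.csv")
cat("matched samples:", cx$n, "| significant pairs:",
    sum(cx$significant, na.rm = TRUE), "of", sum(!is.na(cx$p)), "\n")
cat("Onc CK (Landscape) vs Onc CK (CDX2): rho =",
    round(cx$rho["Onc CK", "Onc CK"], 2), "\n")
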