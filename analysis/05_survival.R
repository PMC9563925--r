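#!/usr/bin/env Rscript
# Clinical statistics: screen draw-1 analytes against PFS, stratify the top
# analyte at its median for Kaplan-Meier curves, and compute draw-to-draw
# kinetics.

suppressMessages(library(rarebiopsy))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(seed = 1))
enum <- simulate_enumeration(cohort, seed = 2)
surv <- cohort$survival

e1 <- enum[enum$protocol == "Landscape" & enum$arm == "mCRC" &
             enum$draw == 1, ]
screen <- screen_pfs_analytes(e1, surv)
write.csv(screen, "results/pfs_screen_draw1.csv", row.names = FALSE)
cat("analytes screened:", nrow(screen), "| significant at p <= 0.05:",
    sum(screen$significant), "\n")
print(head(screen, 4), row.names = FALSE)

top <- screen$classification[1]
m <- merge(e1[e1$classification == top, ], surv, by = "patient_id")
m <- m[is.finite(m$pfs_months), ]
km <- km_stratify(m$events_per_ml, m$pfs_months, m$event_flag)
write.csv(km$curves, "results/km_curves_top_analyte.csv", row.names = FALSE)
cat(sprintf("top analyte '%s': median threshold %.2f events/mL\n",
            top, km$threshold))
cat(sprintf("median PFS: high group %.1f vs low group %.1f months\n",
            median(m$pfs_months[km$group == "high"]),
            median(m$pfs_months[km$group == "low"])))

eml <- enum[enum$arm == "mCRC" & enum$protocol == "Landscape" &
              enum$classification == top &
              enum$patient_id %in% surv$patient_id[!is.na(surv$pfs_months)], ]
kin <- kinetics(eml)
waterfall <- merge(data.frame(patient_id = names(kin$delta),
                              delta_events_per_ml = as.numeric(kin$delta)),
                   surv, by = "patient_id")
waterfall <- waterfall[order(-waterfall$pfs_months), ]
write.csv(waterfall, "results/kinetics_waterfall.csv", row.names = FALSE)
cat("kinetics evaluable in", length(kin$delta), "patients (",
    kin$n_excluded, "excluded for a missing draw )\n")
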