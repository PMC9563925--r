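#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 10 patients sampled at two draws
# (two missing draw 2 -> 18 patient samples), each stained with both the
# Landscape and CDX2-targeted protocols, plus 50 normal donors (Landscape
# only), with ground-truth analyte concentrations and survival times.

suppressMessages(library(rarebiopsy))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(seed = 1))

write.csv(cohort$samples, "results/cohort_samples.csv", row.names = FALSE)
write.csv(cohort$truth, "results/cohort_truth_concentrations.csv",
          row.names = FALSE)
write.csv(cohort$survival, "results/cohort_survival.csv", row.names = FALSE)

cat("samples:", nrow(cohort$samples),
    "| mCRC Landscape slides:",
    sum(cohort$samples$arm == "mCRC" &
          cohort$samples$protocol == "Landscape"),
    "| ND slides:", sum(cohort$samples$arm == "ND"), "\n")
cat("patients with PFS:", sum(!is.na(cohort$survival$pfs_months)),
    "| mean PFS:",
    round(mean(cohort$survival$pfs_months, na.rm = TRUE), 2), "months\n")

# one rendered example frame of the first patient slide, for inspection
sp <- as_sample_spec(cohort, cohort$samples$sample_id[1],
                     frames = 1, frame_px = 512, wbc_per_frame = 100,
                     rate_multiplier = 40)
rf <- render_frame(sp, 1)
write_frame_tiff(rf$frame, "results/example_frame.tif")
write.csv(rf$truth, "results/example_frame_truth.csv", row.names = FALSE)
cat("example frame:", nrow(rf$truth), "events rendered ->",
    "results/example_frame.tif\n")
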