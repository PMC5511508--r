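#!/usr/bin/env Rscript
# Stage 2 - echocardiographic derivations.
#
# Reads results/cohort.csv, applies the deterministic derivation layer
# (Boyd BSA, BSA-indexed masses and volumes, ejection fraction, stroke
# volume, mass/EDV, E/A, E/E', mass per head circumference, cube-formula
# LV mass) and writes results/derived.csv plus the group-by-stage summary
# table with two-group test flags.

suppressPackageStartupMessages(library(cardiogrowth))

cohort <- read_cohort_csv("results/cohort.csv")
derived <- derive_measures(cohort)
write.csv(derived, "results/derived.csv", row.names = FALSE, na = "")

tbl <- summarize_table2(derived)
write.csv(tbl, "results/summary_table2.csv", row.names = FALSE)

cat("Birth-assessment group contrasts (mean (SD), preterm vs term):\n")
show <- tbl[tbl$stage == "birth" &
              tbl$measure %in% c("lvmi", "lv_edvi", "ef", "tapse"), ]
print(as.data.frame(show), row.names = FALSE)
cat("\nAt birth the preterm group shows the calibrated deficit in indexed",
    "mass and\nvolume; the derivation layer reproduces the configured",
    "group means from the\nraw per-visit measures.\n")
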