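#!/usr/bin/env Rscript
# Stage 1 - simulate the study cohort.
#
# Generates the full synthetic cohort with the default calibration: 121
# preterm and 134 term infants with birth and 3-month echocardiography,
# a fetal scan history for a subset plus 137 fetal-only pregnancies, and
# four-chamber endocardial/epicardial contour pairs per postnatal visit.
# Writes results/cohort.csv and results/contours.csv.

suppressPackageStartupMessages(library(cardiogrowth))

seed <- 20260901L
dir.create("results", showWarnings = FALSE)

cfg <- default_calibration()
write_config(cfg, "results/generator_config.json")

report <- run_pipeline(cfg, "results", seed = seed, stages = "generate")

cat("Generated", report$counts$subjects, "subjects,",
    report$counts$visits, "visits,",
    report$counts$contour_pairs, "contour pairs.\n")
cat("The calibration targets a mean LVMI change of 57.8% (preterm) vs",
    "27.3% (term)\nand corr(GA, %dLVMI) = -0.49 on the combined cohort.\n")
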