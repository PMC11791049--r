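#!/usr/bin/env Rscript
# Stage 3 -- score subject-level measures and apply exclusions.
#
# Per subject and condition: mean fixation duration, fixation count,
# missing-data proportion, mean within-fixation RMS; plus the naturalistic
# AOI proportions (face looking on inactive actors, active-actor looking in
# mixed frames). Condition-level exclusion rules (missing data > 45.6%/47.6%,
# fewer than 5/3 fixations, proportions exactly 0 or 1) are then applied.

library(twingaze)

st <- readRDS("scratch/01_cohort.rds")
fixations <- readRDS("scratch/02_fixations.rds")

measures <- subject_measures(st$cohort$recordings, fixations, demo_schedules())
measures <- apply_exclusions(measures, st$cfg$exclusions)
write.csv(measures, "results/measures.csv", row.names = FALSE)
saveRDS(measures, "scratch/03_measures.rds")

message(sprintf("Scored %d subjects.", nrow(measures)))
message(sprintf("Excluded: naturalistic %d, abstract %d, degenerate face %d / active %d.",
                sum(!is.na(measures$excl_naturalistic)),
                sum(!is.na(measures$excl_abstract)),
                sum(measures$excl_prop_face %in% "degenerate"),
                sum(measures$excl_prop_active %in% "degenerate")))
message(sprintf("Mean fixation duration: naturalistic %.1f (SD %.1f), abstract %.1f (SD %.1f) ms.",
                mean(measures$mean_fd_naturalistic, na.rm = TRUE),
                sd(measures$mean_fd_naturalistic, na.rm = TRUE),
                mean(measures$mean_fd_abstract, na.rm = TRUE),
                sd(measures$mean_fd_abstract, na.rm = TRUE)))
message(sprintf("Proportion on face %.2f (SD %.2f); proportion on active %.2f (SD %.2f).",
                mean(measures$prop_face, na.rm = TRUE),
                sd(measures$prop_face, na.rm = TRUE),
                mean(measures$prop_active, na.rm = TRUE),
                sd(measures$prop_active, na.rm = TRUE)))
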