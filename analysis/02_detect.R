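#!/usr/bin/env Rscript
# Stage 2 -- classify fixations.
#
# Runs the adaptive velocity-threshold classifier on every recording and
# applies the duration (100-2358 ms) and precision (RMS <= 1.77 px) filters.

library(twingaze)

st <- readRDS("scratch/01_cohort.rds")
message(sprintf("Classifying %d recordings ...", length(st$cohort$recordings)))
fixations <- detect_fixations(st$cohort$recordings, st$cfg$filter)

saveRDS(fixations, "scratch/02_fixations.rds")

kept <- fixations[fixations$kept, ]
rej <- table(fixations$reject_reason[!fixations$kept])
summ <- data.frame(
  n_fixations = nrow(fixations), n_kept = nrow(kept),
  too_short = sum(fixations$reject_reason %in% "too_short"),
  too_long = sum(fixations$reject_reason %in% "too_long"),
  too_noisy = sum(fixations$reject_reason %in% "too_noisy"),
  mean_duration_naturalistic = mean(kept$duration_ms[kept$condition == "naturalistic"]),
  mean_duration_abstract = mean(kept$duration_ms[kept$condition == "abstract"]))
write.csv(summ, "results/fixation_summary.csv", row.names = FALSE)

message(sprintf("%d fixations, %d kept (rejected: %s).",
                summ$n_fixations, summ$n_kept,
                paste(names(rej), rej, sep = "=", collapse = ", ")))
message(sprintf("Pooled mean duration: naturalistic %.1f ms, abstract %.1f ms.",
                summ$mean_duration_naturalistic, summ$mean_duration_abstract))
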