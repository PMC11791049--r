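#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates ~285 same-sex twin pairs (146 MZ, 139 DZ, ~6% with one co-twin
# missing) whose latent fixation-duration traits follow a bivariate AE model
# (standardized A = 0.25 abstract / 0.30 naturalistic, genetic cross-
# covariance 0.17, unique-environment cross-covariance 0.16), plus a
# univariate AE face-looking trait (A = 0.19). Latent traits are mapped to
# subject-level mean fixation durations (552.53 +/- 115.77 ms naturalistic,
# 602.84 +/- 149.87 ms abstract) and realized as raw 120 Hz gaze streams
# over the six 21 s demonstration videos.

library(twingaze)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- pipeline_config(seed = 20260926)

fd_pairs <- simulate_twin_traits(cfg$fd_params, cfg$n_mz_pairs, cfg$n_dz_pairs,
                                 seed = cfg$seed,
                                 p_missing_twin = cfg$p_missing_twin)
face_pairs <- simulate_twin_traits(cfg$face_params, cfg$n_mz_pairs,
                                   cfg$n_dz_pairs, seed = cfg$seed + 1)
subjects <- from_pair_table(fd_pairs, c("y1", "y2"))
sc <- cfg$fd_scale
subject_means <- data.frame(
  subject_id = subjects$subject_id,
  mean_fd_abstract = pmin(pmax(sc$abstract["mean"] +
                                 sc$abstract["sd"] * subjects$y1, 150), 2200),
  mean_fd_naturalistic = pmin(pmax(sc$naturalistic["mean"] +
                                     sc$naturalistic["sd"] * subjects$y2, 150), 2200))
rownames(subject_means) <- NULL

schedules <- demo_schedules()
message(sprintf("Simulating gaze for %d subjects x %d videos ...",
                nrow(subject_means), length(schedules)))
cohort <- simulate_gaze_cohort(subject_means, schedules, cfg$gaze,
                               seed = cfg$seed + 2)

saveRDS(list(cfg = cfg, fd_pairs = fd_pairs, face_pairs = face_pairs,
             subjects = subjects, subject_means = subject_means,
             cohort = cohort),
        "scratch/01_cohort.rds")
write.csv(subject_means, "results/subject_means.csv", row.names = FALSE)

message(sprintf(paste0("Cohort: %d pairs (%d MZ / %d DZ), %d subjects with ",
                       "gaze, %d recordings."),
                nrow(fd_pairs), cfg$n_mz_pairs, cfg$n_dz_pairs,
                nrow(subject_means), length(cohort$recordings)))
message(sprintf("Latent grand means: naturalistic %.1f ms, abstract %.1f ms.",
                mean(subject_means$mean_fd_naturalistic),
                mean(subject_means$mean_fd_abstract)))
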