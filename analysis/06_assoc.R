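#!/usr/bin/env Rscript
# Stage 6 -- association analyses.
#
# Condition effect on fixation duration (within-subject contrast, clustered
# on individual, run separately per twin slot with quality covariates), the
# age x condition interaction, and associations of seven simulated polygenic
# scores with abstract-condition fixation duration (clustered on twin pair,
# age + sex + 10 ancestry PCs as covariates, Bonferroni alpha 0.05/4).

library(twingaze)

st <- readRDS("scratch/01_cohort.rds")
pp <- readRDS("scratch/04_prepped.rds")
m <- pp$m

long <- rbind(
  data.frame(subject_id = m$subject_id, pair_id = m$pair_id,
             twin = as.integer(sub(".*_", "", m$subject_id)),
             age_days = m$age_days, condition = "naturalistic",
             fd_raw = m$mean_fd_naturalistic, n_fix = m$n_fix_naturalistic,
             mean_rms = m$mean_rms_naturalistic,
             prop_missing = m$prop_missing_naturalistic),
  data.frame(subject_id = m$subject_id, pair_id = m$pair_id,
             twin = as.integer(sub(".*_", "", m$subject_id)),
             age_days = m$age_days, condition = "abstract",
             fd_raw = m$mean_fd_abstract, n_fix = m$n_fix_abstract,
             mean_rms = m$mean_rms_abstract,
             prop_missing = m$prop_missing_abstract))
long$fd <- standardize(long$fd_raw)

rows <- NULL
for (slot in 1:2) {
  g <- condition_effect(long, "fd", twin_slot = slot,
                        quality_covariates = c("n_fix", "mean_rms",
                                               "prop_missing"))
  b <- g$beta["conditionnaturalistic"]; p <- g$p["conditionnaturalistic"]
  message(sprintf("Condition effect (Twin %d): beta = %.2f, p = %.2g", slot, b, p))
  ga <- condition_effect(long, "fd", twin_slot = slot, with_age = TRUE)
  it <- grep(":age_days", ga$term, value = TRUE)
  message(sprintf("  age x condition (Twin %d): beta = %.3f, p = %.2f",
                  slot, ga$beta[it], ga$p[it]))
  rows <- rbind(rows,
                data.frame(twin = slot, term = "condition", beta = b,
                           se = g$se["conditionnaturalistic"], p = p),
                data.frame(twin = slot, term = "age_x_condition",
                           beta = ga$beta[it], se = ga$se[it], p = ga$p[it]))
}
write.csv(rows, "results/condition_effects.csv", row.names = FALSE)

pgs_effect <- st$cfg$pgs_effect
pgs_tab <- simulate_pgs_table(st$fd_pairs, effect = unname(pgs_effect),
                              score_names = names(pgs_effect),
                              trait = "y1",        # abstract-condition trait
                              seed = st$cfg$seed + 3)
res <- suppressWarnings(
  pgs_association(pgs_tab, names(pgs_effect),
                  alpha_divisor = st$cfg$alpha_divisor))
print(res)
message(sprintf(paste0("Schizophrenia score: beta = %.2f, p = %.3f ",
                       "(raw %s, Bonferroni alpha = %.4f: %s)"),
                res$beta[res$score == "schizophrenia"],
                res$p[res$score == "schizophrenia"],
                ifelse(res$sig_raw[res$score == "schizophrenia"],
                       "significant", "ns"),
                attr(res, "alpha_bonferroni"),
                ifelse(res$sig_bonferroni[res$score == "schizophrenia"],
                       "significant", "not significant")))
write.csv(res, "results/associations.csv", row.names = FALSE)
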