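#' Pipeline configuration
#'
#' Bundles every stage's settings with a single master seed. Defaults
#' reproduce the study conditions of the emulated cohort: ~285 same-sex twin
#' pairs (146 MZ, 139 DZ) with ~6% partially complete pairs, three
#' naturalistic plus three abstract 21 s videos, a bivariate AE generative
#' model for fixation duration with standardized genetic variances 0.25
#' (abstract) and 0.30 (naturalistic), genetic cross-covariance 0.17 and
#' unique-environment cross-covariance 0.16 (phenotypic correlation 0.33),
#' and a univariate AE model with A = 0.19 for face-looking proportion.
#' Subject-level mean fixation durations are the latent traits mapped to the
#' observed scale (552.53 +/- 115.77 ms naturalistic, 602.84 +/- 149.87 ms
#' abstract).
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts.
#' @param p_missing_twin Probability a pair misses one co-twin.
#' @param fd_params Bivariate [cholesky_params()] for fixation duration,
#'   trait order (abstract, naturalistic).
#' @param face_params Univariate [cholesky_params()] for face proportion.
#' @param fd_scale Data frame-free list: observed means/SDs per condition.
#' @param gaze A [gaze_gen_params()].
#' @param filter A [filter_config()].
#' @param exclusions An [exclusion_config()].
#' @param families Model families fit to the bivariate fixation-duration
#'   traits.
#' @param pgs_effect Named standardized effects of the simulated polygenic
#'   scores on abstract-condition fixation duration.
#' @param alpha_divisor Bonferroni divisor for the score associations.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(
    n_mz_pairs = 146, n_dz_pairs = 139, p_missing_twin = 0.06,
    fd_params = cholesky_params(
      a = safe_chol_lower(matrix(c(0.25, 0.17, 0.17, 0.30), 2)),
      e = safe_chol_lower(matrix(c(0.75, 0.16, 0.16, 0.70), 2))),
    face_params = cholesky_params(a = sqrt(0.19), e = sqrt(0.81)),
    fd_scale = list(naturalistic = c(mean = 552.53, sd = 115.77),
                    abstract = c(mean = 602.84, sd = 149.87)),
    gaze = gaze_gen_params(),
    filter = filter_config(),
    exclusions = exclusion_config(),
    families = c("ACE", "AE", "CE", "E"),
    pgs_effect = c(IQ = 0, EA = 0, autism = 0, ADHD = 0,
                   schizophrenia = -0.13, depression = 0, bipolar = 0),
    alpha_divisor = 4,
    seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run the full analysis pipeline
#'
#' simulate -> detect -> score -> prep -> fit -> assoc. Every stage's
#' record counts are logged; outputs (measures, pair table, fits,
#' associations) are returned and, when `out_dir` is set, written as CSV and
#' JSON stamped with the seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with `measures`, `pairs_fd`, `pairs_face`, `sat_free`,
#'   `sat_constrained`, `fits`, `comparison`, `condition_effects`,
#'   `pgs`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  logl <- list(seed = config$seed)
  set.seed(config$seed)

  ## -- simulate ----------------------------------------------------------
  say("simulate: %d MZ + %d DZ pairs", config$n_mz_pairs, config$n_dz_pairs)
  fd_pairs <- simulate_twin_traits(config$fd_params, config$n_mz_pairs,
                                   config$n_dz_pairs,
                                   seed = config$seed,
                                   p_missing_twin = config$p_missing_twin)
  face_pairs <- simulate_twin_traits(config$face_params, config$n_mz_pairs,
                                     config$n_dz_pairs,
                                     seed = config$seed + 1,
                                     p_missing_twin = 0)
  subjects <- from_pair_table(fd_pairs, c("y1", "y2"))
  sc <- config$fd_scale
  subject_means <- data.frame(
    subject_id = subjects$subject_id,
    mean_fd_abstract = clamp(sc$abstract["mean"] + sc$abstract["sd"] * subjects$y1,
                             150, 2200),
    mean_fd_naturalistic = clamp(sc$naturalistic["mean"] +
                                   sc$naturalistic["sd"] * subjects$y2,
                                 150, 2200))
  schedules <- demo_schedules()
  cohort <- simulate_gaze_cohort(subject_means, schedules, config$gaze,
                                 seed = config$seed + 2)
  logl$n_subjects <- nrow(subject_means)
  logl$n_recordings <- length(cohort$recordings)

  ## -- detect ------------------------------------------------------------
  say("detect: classifying fixations in %d recordings", logl$n_recordings)
  fixations <- detect_fixations(cohort$recordings, config$filter)
  logl$n_fixations_kept <- sum(fixations$kept)
  logl$n_rejected <- table(fixations$reject_reason[!fixations$kept])

  ## -- score -------------------------------------------------------------
  say("score: AOI measures for %d subjects", logl$n_subjects)
  measures <- subject_measures(cohort$recordings, fixations, schedules)
  measures <- apply_exclusions(measures, config$exclusions)
  logl$n_excluded_nat <- sum(!is.na(measures$excl_naturalistic))
  logl$n_excluded_abs <- sum(!is.na(measures$excl_abstract))

  ## -- prep --------------------------------------------------------------
  say("prep: quality screen + residualize + standardize")
  meta <- subjects[, c("subject_id", "pair_id", "zygosity", "sex", "age_days")]
  m <- merge(meta, measures, by = "subject_id")
  qual_nat <- c("n_fix_naturalistic", "mean_rms_naturalistic",
                "prop_missing_naturalistic")
  qual_abs <- c("n_fix_abstract", "mean_rms_abstract", "prop_missing_abstract")
  prep_nat <- prepare_measure(m, "mean_fd_naturalistic", qual_nat)
  prep_abs <- prepare_measure(m, "mean_fd_abstract", qual_abs)
  m$fd_nat_std <- prep_nat$values
  m$fd_abs_std <- prep_abs$values
  has_face <- !all(is.na(m$prop_face))
  if (has_face) {
    prep_face <- prepare_measure(m, "prop_face", qual_nat)
    m$face_std <- prep_face$values
  }
  pairs_fd <- to_pair_table(m, c("fd_abs_std", "fd_nat_std"))
  logl$n_pairs_analysed <- nrow(pairs_fd)

  ## -- fit ---------------------------------------------------------------
  say("fit: saturated + %s on fixation-duration traits",
      paste(config$families, collapse = "/"))
  traits <- c("fd_abs_std", "fd_nat_std")
  fdml <- fiml_data(pairs_fd, traits)
  sat_free <- fit_saturated(fdml)
  sat_con <- fit_saturated(fdml, constrained = TRUE)
  assumptions <- assumption_test(sat_free, sat_con)
  fits <- lapply(config$families, function(fam) fit_twin_model(fdml, fam))
  names(fits) <- config$families
  comparison <- select_model(fits, sat_free)
  face_fit <- NULL
  pairs_face <- NULL
  if (has_face) {
    pairs_face <- to_pair_table(m, "face_std")
    face_fit <- fit_twin_model(fiml_data(pairs_face, "face_std"), "AE")
  }

  ## -- assoc -------------------------------------------------------------
  say("assoc: condition effects + polygenic scores")
  # condition contrasts need one common scale across conditions, so the raw
  # means are stacked and standardized jointly (per-condition z-scores would
  # erase the level difference being tested)
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
  cond_eff <- lapply(1:2, function(slot) {
    tryCatch(condition_effect(long, "fd", twin_slot = slot,
                              quality_covariates = c("n_fix", "mean_rms",
                                                     "prop_missing")),
             error = function(e) NULL)
  })
  pgs_tab <- simulate_pgs_table(fd_pairs, effect = unname(config$pgs_effect),
                                score_names = names(config$pgs_effect),
                                trait = "y1", seed = config$seed + 3)
  pgs_res <- suppressWarnings(
    pgs_association(pgs_tab, names(config$pgs_effect),
                    alpha_divisor = config$alpha_divisor))

  out <- list(measures = m, pairs_fd = pairs_fd, pairs_face = pairs_face,
              sat_free = sat_free, sat_constrained = sat_con,
              assumptions = assumptions, fits = fits,
              comparison = comparison, face_fit = face_fit,
              condition_effects = cond_eff, pgs = pgs_res, log = logl)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(m, file.path(config$out_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs_fd, file.path(config$out_dir, "pairs_fd.csv"),
                     row.names = FALSE)
    utils::write.csv(pgs_res, file.path(config$out_dir, "associations.csv"),
                     row.names = FALSE)
    fits_json <- list(
      seed = config$seed,
      saturated = list(
        free = list(neg2ll = sat_free$neg2ll, n_params = sat_free$n_params,
                    correlations = sat_free$correlations),
        constrained = list(neg2ll = sat_con$neg2ll,
                           n_params = sat_con$n_params,
                           correlations = sat_con$correlations)),
      assumptions = assumptions,
      models = lapply(fits, function(f) list(
        family = f$family, neg2ll = f$neg2ll, aic = f$aic,
        standardized = as.data.frame(f$standardized))),
      selected = comparison$selected,
      face_AE = if (!is.null(face_fit)) list(
        neg2ll = face_fit$neg2ll,
        standardized = as.data.frame(face_fit$standardized)))
    jsonlite::write_json(fits_json, file.path(config$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
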