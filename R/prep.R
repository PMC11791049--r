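#' Screen data-quality covariates against a measure
#'
#' Regresses the measure on each quality covariate in turn with
#' cluster-robust (twin-pair) inference and reports the covariates whose
#' two-sided p-value falls below `alpha`. Constant covariates are skipped
#' with a warning.
#'
#' @param data Data frame with the measure, covariates and cluster id.
#' @param measure Column name of the measure.
#' @param covariates Character vector of quality covariate columns
#'   (typically number of fixations, mean RMS, proportion missing).
#' @param cluster Column name of the cluster id (default `"pair_id"`).
#' @param alpha Significance level (default 0.05, two-sided).
#' @return Character vector of significant covariates; the full screening
#'   table is attached as `attr(, "screen")`.
#' @export
quality_screen <- function(data, measure, covariates, cluster = "pair_id",
                           alpha = 0.05) {
  y <- data[[measure]]
  if (is.null(y) || all(is.na(y))) stop("quality_screen: empty measure column")
  rows <- NULL
  for (cv in covariates) {
    d <- data[stats::complete.cases(data[, c(measure, cv, cluster)]), ]
    if (length(unique(d[[cv]])) < 2) {
      warning(sprintf("quality_screen: covariate '%s' is constant; skipped", cv))
      next
    }
    fit <- gee_fit(stats::reformulate(cv, response = measure), d,
                   cluster = d[[cluster]])
    rows <- rbind(rows, data.frame(covariate = cv,
                                   beta = fit$beta[cv],
                                   p = fit$p[cv]))
  }
  sel <- if (is.null(rows)) character(0) else rows$covariate[rows$p < alpha]
  structure(sel, screen = rows)
}

#' Regress covariates out of a measure
#'
#' Ordinary least-squares residuals of the measure on the selected quality
#' covariates; age and sex are always included for twin-model inputs. The
#' residual keeps mean zero (intercept absorbed). Rows with missing measure
#' stay missing; rows with missing covariates become missing.
#'
#' @param data Data frame.
#' @param measure Column name of the measure.
#' @param covariates Character vector of covariates to remove (may be empty).
#' @param always_include Covariates forced into the design (default age and
#'   sex; set `character(0)` to disable).
#' @return Numeric vector of residuals aligned with `data` rows.
#' @export
residualize <- function(data, measure, covariates = character(0),
                        always_include = c("age_days", "sex")) {
  covs <- union(always_include, covariates)
  if (length(covs) == 0) {
    y <- data[[measure]]
    return(y - mean(y, na.rm = TRUE))
  }
  fml <- stats::reformulate(covs, response = measure)
  mf <- stats::model.frame(fml, data, na.action = stats::na.exclude)
  X <- stats::model.matrix(fml, mf)
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop(sprintf("residualize: rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(fml, data, na.action = stats::na.exclude)
  as.numeric(stats::residuals(fit))
}

#' Z-score a measure
#'
#' @param x Numeric vector with positive standard deviation (`NA`s ignored).
#' @return Vector with mean 0 and SD 1 over the non-missing entries.
#' @export
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("standardize: zero or undefined variance")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Build a wide twin-pair table from a subject table
#'
#' One row per pair with per-trait columns `<trait>_t1` / `<trait>_t2`. Twin
#' order within a pair is assigned deterministically by sorted subject id;
#' singleton pairs carry `NA` on the missing side. Pairs listing more than
#' two subjects or duplicate subject ids are data errors.
#'
#' @param subjects Data frame with `subject_id`, `pair_id`, `zygosity`,
#'   `sex`, `age_days` and the trait columns.
#' @param traits Character vector of trait column names.
#' @return A `pair_table` data frame.
#' @export
to_pair_table <- function(subjects, traits) {
  if (anyDuplicated(subjects$subject_id)) {
    stop("to_pair_table: duplicate subject id")
  }
  counts <- table(subjects$pair_id)
  if (any(counts > 2)) {
    stop(sprintf("to_pair_table: pair(s) with more than two subjects: %s",
                 paste(names(counts)[counts > 2], collapse = ", ")))
  }
  pair_ids <- sort(unique(subjects$pair_id))
  rows <- lapply(pair_ids, function(pid) {
    d <- subjects[subjects$pair_id == pid, ]
    d <- d[order(d$subject_id), ]
    row <- data.frame(pair_id = pid, zygosity = d$zygosity[1], sex = d$sex[1],
                      age_days = mean(d$age_days))
    for (tr in traits) {
      row[[paste0(tr, "_t1")]] <- d[[tr]][1]
      row[[paste0(tr, "_t2")]] <- if (nrow(d) == 2) d[[tr]][2] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pair_table", "data.frame"))
}

#' Flatten a pair table back to a subject table
#'
#' Inverse of [to_pair_table()] (lossless up to subject ids, which are
#' reconstructed as `<pair_id>_1` / `<pair_id>_2`); twins whose traits are
#' all missing are dropped.
#'
#' @param pairs A `pair_table`.
#' @param traits Character vector of trait stems.
#' @return Subject-level data frame.
#' @export
from_pair_table <- function(pairs, traits) {
  out <- NULL
  for (slot in 1:2) {
    d <- data.frame(subject_id = paste0(pairs$pair_id, "_", slot),
                    pair_id = pairs$pair_id, zygosity = pairs$zygosity,
                    sex = pairs$sex, age_days = pairs$age_days)
    for (tr in traits) d[[tr]] <- pairs[[paste0(tr, "_t", slot)]]
    keep <- rowSums(!is.na(d[, traits, drop = FALSE])) > 0
    out <- rbind(out, d[keep, ])
  }
  rownames(out) <- NULL
  out[order(out$subject_id), ]
}

#' Prepare analysis-ready twin traits
#'
#' Full preparation path for one measure: quality screen, residualization on
#' the significant quality covariates plus age and sex, standardization, and
#' pair-table assembly.
#'
#' @param subjects Subject table with measure, quality covariates, `pair_id`,
#'   `zygosity`, `sex`, `age_days`.
#' @param measure Measure column name.
#' @param quality_covariates Quality covariate columns to screen.
#' @return List with `values` (standardized residual per subject), `selected`
#'   (screened covariates) and `screen` table.
#' @export
prepare_measure <- function(subjects, measure,
                            quality_covariates = character(0)) {
  selected <- if (length(quality_covariates)) {
    quality_screen(subjects, measure, quality_covariates)
  } else character(0)
  res <- residualize(subjects, measure, covariates = as.character(selected))
  list(values = standardize(res), selected = as.character(selected),
       screen = attr(selected, "screen"))
}
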