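#' Cholesky path parameters for a twin generative model
#'
#' Houses the lower-triangular path matrices of an ACE/ADE(-style) Cholesky
#' decomposition for one or two traits. Variance components are implied as
#' `Sigma_A = a %*% t(a)` etc., so any path values give a valid (PSD)
#' component. C and D paths cannot both be nonzero: shared-environment and
#' dominance variance are not jointly identifiable from twin data alone.
#'
#' @param a,c,d,e Lower-triangular path matrices (`n x n`, n = 1 or 2), or
#'   scalars for the univariate case. `e` must have strictly positive
#'   diagonal. Defaults: zero `c`/`d`.
#' @param means Trait means (length n, default 0).
#' @param sds Trait scale factors applied on top of the path-implied variance
#'   (length n, default 1). With standardized paths (components summing to 1)
#'   these are the phenotypic SDs.
#' @return Object of class `"cholesky_params"`.
#' @export
#' @examples
#' # univariate AE model with heritability 0.30
#' cholesky_params(a = sqrt(0.30), e = sqrt(0.70))
cholesky_params <- function(a, e, c = NULL, d = NULL, means = NULL, sds = NULL) {
  as_lt <- function(m, n) {
    if (is.null(m)) m <- matrix(0, n, n)
    if (!is.matrix(m)) m <- matrix(m, 1, 1)
    stopifnot(nrow(m) == n, ncol(m) == n)
    if (any(m[upper.tri(m)] != 0)) stop("path matrices must be lower triangular")
    m
  }
  n <- if (is.matrix(a)) nrow(a) else 1L
  if (!n %in% 1:2) stop("cholesky_params: n_traits must be 1 or 2")
  a <- as_lt(a, n); e <- as_lt(e, n); c <- as_lt(c, n); d <- as_lt(d, n)
  if (!all(is.finite(a)) || !all(is.finite(e)) || !all(is.finite(c)) ||
      !all(is.finite(d))) stop("cholesky_params: non-finite path value")
  if (any(c != 0) && any(d != 0)) {
    stop("cholesky_params: C and D paths cannot both be nonzero")
  }
  if (any(diag(e) <= 0)) stop("cholesky_params: e diagonal must be > 0")
  if (is.null(means)) means <- rep(0, n)
  if (is.null(sds)) sds <- rep(1, n)
  stopifnot(length(means) == n, length(sds) == n, all(sds > 0))
  structure(list(n_traits = n, a = a, c = c, d = d, e = e,
                 means = means, sds = sds),
            class = "cholesky_params")
}

#' Variance components implied by Cholesky paths
#' @param params A [cholesky_params()].
#' @return List with matrices `A`, `C`, `D`, `E` and `total`.
#' @export
implied_components <- function(params) {
  s <- diag(params$sds, params$n_traits)
  comp <- lapply(params[c("a", "c", "d", "e")],
                 function(m) s %*% tcrossprod(m) %*% s)
  names(comp) <- c("A", "C", "D", "E")
  comp$total <- comp$A + comp$C + comp$D + comp$E
  comp
}

#' Expected twin-pair covariance matrix
#'
#' Builds the `2n x 2n` covariance of the stacked phenotype vector
#' (twin 1 traits, then twin 2 traits) implied by the Cholesky paths. The
#' within-twin block is `A + C + D + E`; the cross-twin block is
#' `kA * A + C + kD * D` with genetic sharing weights `(kA, kD) = (1, 1)` for
#' MZ pairs and `(0.5, 0.25)` for DZ pairs (MZ twins share all segregating
#' variants, DZ twins on average half; dominance sharing is one quarter).
#'
#' @param params A [cholesky_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Symmetric positive semi-definite matrix.
#' @export
implied_pair_covariance <- function(params, zygosity) {
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  comp <- implied_components(params)
  within <- comp$total
  kA <- if (zygosity == "MZ") 1 else 0.5
  kD <- if (zygosity == "MZ") 1 else 0.25
  cross <- kA * comp$A + comp$C + kD * comp$D
  rbind(cbind(within, cross), cbind(cross, within))
}

# Deterministic multivariate normal draws via the Cholesky factor.
rmvn_chol <- function(n, mean, sigma) {
  p <- length(mean)
  L <- chol(sigma, pivot = FALSE)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2, mean, "+")
}

#' Simulate twin-pair phenotypes from a Cholesky generative model
#'
#' Draws pair phenotype vectors from the multivariate normal distribution with
#' covariance [implied_pair_covariance()]. Optionally marks one co-twin of a
#' random subset of pairs as entirely missing, emulating partially complete
#' pairs.
#'
#' @param params A [cholesky_params()].
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param seed Integer seed; all randomness flows from it.
#' @param p_missing_twin Probability that a pair has one co-twin missing
#'   (default 0).
#' @return A `pair_table` data frame with one row per pair: `pair_id`,
#'   `zygosity`, `sex`, `age_days`, and per-trait columns `<trait>_t1`,
#'   `<trait>_t2`. Trait names are `y1`, `y2`.
#' @export
simulate_twin_traits <- function(params, n_mz, n_dz, seed = 1,
                                 p_missing_twin = 0) {
  stopifnot(n_mz >= 0, n_dz >= 0, p_missing_twin >= 0, p_missing_twin < 1)
  set.seed(seed)
  n <- params$n_traits
  mu <- rep(params$means, 2)
  one_zyg <- function(nn, zyg) {
    if (nn == 0) return(NULL)
    sigma <- implied_pair_covariance(params, zyg)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(ev)) {
      stop("simulate_twin_traits: implied covariance is not PSD")
    }
    y <- rmvn_chol(nn, mu, sigma)
    data.frame(zygosity = zyg, y, check.names = FALSE)
  }
  out <- rbind(one_zyg(n_mz, "MZ"), one_zyg(n_dz, "DZ"))
  if (is.null(out)) {
    out <- data.frame(zygosity = character(0))
    cols <- c(paste0("y", seq_len(n), "_t1"), paste0("y", seq_len(n), "_t2"))
    for (cl in cols) out[[cl]] <- numeric(0)
    return(structure(cbind(data.frame(pair_id = character(0), sex = character(0),
                                      age_days = numeric(0)), out),
                     class = c("pair_table", "data.frame")))
  }
  names(out)[-1] <- c(paste0("y", seq_len(n), "_t1"),
                      paste0("y", seq_len(n), "_t2"))
  n_pairs <- nrow(out)
  out$pair_id <- sprintf("P%05d", seq_len(n_pairs))
  out$sex <- sample(c("F", "M"), n_pairs, replace = TRUE)
  # ages centred on 5 months (~168 days), SD ~9 days as in infant twin cohorts
  out$age_days <- round(stats::rnorm(n_pairs, 168, 9))
  if (p_missing_twin > 0) {
    drop <- stats::runif(n_pairs) < p_missing_twin
    side <- sample(1:2, n_pairs, replace = TRUE)
    for (i in which(drop)) {
      cols <- paste0("y", seq_len(n), "_t", side[i])
      out[i, cols] <- NA_real_
    }
  }
  rownames(out) <- NULL
  cols <- c("pair_id", "zygosity", "sex", "age_days",
            setdiff(names(out), c("pair_id", "zygosity", "sex", "age_days")))
  structure(out[, cols], class = c("pair_table", "data.frame"))
}

#' Simulate a polygenic-score table for a twin cohort
#'
#' Scores are standard normal in the population, identical within MZ pairs and
#' correlated 0.5 within DZ pairs (the expected additive sharing). Phenotype
#' coupling is linear: `effect[j]` is the standardized regression coefficient
#' of the phenotype on score j. Ten standard-normal ancestry principal
#' components (independent of scores and phenotype) are appended as the usual
#' covariates.
#'
#' @param pairs A `pair_table` as from [simulate_twin_traits()].
#' @param effect Numeric vector of standardized effects, one per score.
#' @param score_names Names for the score columns (default `pgs1..pgsK`).
#' @param n_pcs Number of ancestry PCs to simulate (default 10).
#' @param trait Trait stem the effects act on (default `"y1"`).
#' @param seed Integer seed.
#' @return A data frame with one row per individual: `subject_id`, `pair_id`,
#'   `zygosity`, `sex`, `age_days`, `phenotype`, score columns and `PC1..PCk`.
#'   The phenotype equals the pair-table trait plus the score contributions.
#' @export
simulate_pgs_table <- function(pairs, effect, score_names = NULL, n_pcs = 10,
                               trait = "y1", seed = 1) {
  set.seed(seed)
  k <- length(effect)
  if (is.null(score_names)) score_names <- paste0("pgs", seq_len(k))
  stopifnot(length(score_names) == k)
  n_pairs <- nrow(pairs)
  # shared + unique score halves: MZ identical, DZ correlation 0.5
  long <- NULL
  for (slot in 1:2) {
    ph <- pairs[[paste0(trait, "_t", slot)]]
    keep <- !is.na(ph)
    long <- rbind(long, data.frame(
      subject_id = paste0(pairs$pair_id, "_", slot),
      pair_id = pairs$pair_id, zygosity = pairs$zygosity,
      sex = pairs$sex, age_days = pairs$age_days,
      twin = slot, phenotype_base = ph)[keep, ])
  }
  shared <- matrix(stats::rnorm(n_pairs * k), n_pairs, k,
                   dimnames = list(pairs$pair_id, score_names))
  unique1 <- matrix(stats::rnorm(n_pairs * k), n_pairs, k)
  unique2 <- matrix(stats::rnorm(n_pairs * k), n_pairs, k)
  mk_scores <- function(slot) {
    u <- if (slot == 1) unique1 else unique2
    mz <- shared
    dz <- sqrt(0.5) * shared + sqrt(0.5) * u
    out <- mz
    is_dz <- pairs$zygosity == "DZ"
    out[is_dz, ] <- dz[is_dz, ]
    out
  }
  scores <- rbind(mk_scores(1), mk_scores(2))
  rownames(scores) <- c(paste0(pairs$pair_id, "_1"), paste0(pairs$pair_id, "_2"))
  sc <- scores[long$subject_id, , drop = FALSE]
  long$phenotype <- long$phenotype_base + as.numeric(sc %*% effect)
  pcs <- matrix(stats::rnorm(nrow(long) * n_pcs), nrow(long), n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  out <- cbind(long[, c("subject_id", "pair_id", "zygosity", "sex",
                        "age_days", "phenotype")],
               as.data.frame(sc), as.data.frame(pcs))
  rownames(out) <- NULL
  out
}
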