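## Twin-model estimation by full-information maximum likelihood.
##
## Pair phenotype vectors are stacked as (twin1 traits, twin2 traits). Pairs
## with a missing co-twin (or missing single traits) contribute the
## likelihood of their observed subvector, which is what allows partially
## complete pairs. All deviance evaluations run on per-missingness-pattern
## sufficient statistics, so cohort size does not affect optimization cost.

#' Precompute FIML sufficient statistics for a pair table
#'
#' Groups pairs by zygosity and missingness pattern and stores, per group,
#' the count, sum and sum of squares/cross-products of the observed
#' subvectors. Every deviance evaluation then costs one Cholesky per group.
#'
#' @param pairs A `pair_table` data frame.
#' @param traits Character vector of trait stems (columns `<trait>_t1/_t2`).
#' @return Object of class `"fiml_data"`.
#' @export
fiml_data <- function(pairs, traits) {
  n <- length(traits)
  cols <- c(paste0(traits, "_t1"), paste0(traits, "_t2"))
  stopifnot(all(cols %in% names(pairs)))
  Y <- as.matrix(pairs[, cols])
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  zyg <- pairs$zygosity[keep]
  pat <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  groups <- list()
  for (z in c("MZ", "DZ")) {
    for (p in unique(pat[zyg == z])) {
      rows <- which(zyg == z & pat == p)
      o <- obs[rows[1], ]
      X <- Y[rows, o, drop = FALSE]
      groups[[length(groups) + 1]] <- list(
        zygosity = z, obs = o, n = nrow(X),
        sx = colSums(X), sxx = crossprod(X), pattern = p)
    }
  }
  structure(list(traits = traits, n_traits = n, dim = 2 * n,
                 groups = groups, n_pairs = nrow(Y),
                 n_by_zyg = table(factor(zyg, levels = c("MZ", "DZ")))),
            class = "fiml_data")
}

# Core deviance on sufficient statistics; +Inf when a covariance is not PD.
neg2ll_suff <- function(fd, mean_vec, sigma_mz, sigma_dz, hard_error = FALSE) {
  total <- 0
  for (g in fd$groups) {
    sigma <- if (g$zygosity == "MZ") sigma_mz else sigma_dz
    o <- g$obs
    S <- sigma[o, o, drop = FALSE]
    mu <- mean_vec[o]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10)) {
      if (hard_error) {
        stop(sprintf("singular observed covariance for %s pairs with pattern %s",
                     g$zygosity, g$pattern))
      }
      return(Inf)
    }
    logdet <- 2 * sum(log(diag(ch)))
    k <- sum(o)
    # sum of (x-mu)' S^-1 (x-mu) over the group via the scatter matrix
    Sc <- g$sxx - tcrossprod(g$sx, mu) - tcrossprod(mu, g$sx) +
      g$n * tcrossprod(mu)
    quad <- sum(chol2inv(ch) * Sc)
    total <- total + g$n * (k * log(2 * pi) + logdet) + quad
  }
  total
}

#' FIML deviance (-2 log-likelihood) of a mean/covariance structure
#'
#' Sums, over pairs, the multivariate-normal deviance of each pair's
#' observed phenotype subvector given the structure's mean vector and
#' zygosity-specific pair covariance. For complete data this equals the
#' standard dense multivariate-normal deviance.
#'
#' @param mean_vec Mean vector of the stacked pair phenotype (length
#'   `2 * n_traits`).
#' @param sigma_mz,sigma_dz Pair covariance matrices per zygosity.
#' @param pairs A `pair_table` or a prebuilt [fiml_data()].
#' @param traits Trait stems (required when `pairs` is a pair table).
#' @return Scalar deviance.
#' @export
fiml_neg2ll <- function(mean_vec, sigma_mz, sigma_dz, pairs, traits = NULL) {
  fd <- if (inherits(pairs, "fiml_data")) pairs else fiml_data(pairs, traits)
  neg2ll_suff(fd, mean_vec, sigma_mz, sigma_dz, hard_error = TRUE)
}

# Lower-triangular Cholesky-like factor of a possibly indefinite matrix,
# after clipping eigenvalues at a small floor.
safe_chol_lower <- function(M, floor = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  t(chol(e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)))
}

# Moment-based starting values: Falconer-style decomposition of the
# complete-pair cross-twin covariance blocks.
moment_inits <- function(fd) {
  n <- fd$n_traits
  idx1 <- seq_len(n); idx2 <- n + idx1
  stats_zyg <- function(z) {
    g_list <- Filter(function(g) g$zygosity == z && all(g$obs), fd$groups)
    if (length(g_list) == 0) return(NULL)
    g <- g_list[[1]]
    mu <- g$sx / g$n
    S <- g$sxx / g$n - tcrossprod(mu)
    list(mu = mu, S = S, n = g$n)
  }
  mz <- stats_zyg("MZ"); dz <- stats_zyg("DZ")
  if (is.null(mz) || is.null(dz)) {
    total <- diag(1, n)
    return(list(mean = rep(0, n), A = 0.3 * total, C = 0.1 * total,
                E = 0.6 * total, total = total))
  }
  total <- (mz$S[idx1, idx1] + mz$S[idx2, idx2] +
              dz$S[idx1, idx1] + dz$S[idx2, idx2]) / 4
  cross_mz <- (mz$S[idx1, idx2] + t(mz$S[idx1, idx2])) / 2
  cross_dz <- (dz$S[idx1, idx2] + t(dz$S[idx1, idx2])) / 2
  A <- 2 * (cross_mz - cross_dz)
  C <- 2 * cross_dz - cross_mz
  E <- total - cross_mz
  list(mean = (mz$mu[idx1] + mz$mu[idx2] + dz$mu[idx1] + dz$mu[idx2]) / 4,
       A = A, C = C, E = E, total = total)
}

lt_count <- function(n) n * (n + 1) / 2
vec_to_lt <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}
lt_to_vec <- function(m) m[lower.tri(m, diag = TRUE)]

family_components <- function(family) {
  switch(family,
         ACE = c("a", "c"), ADE = c("a", "d"), AE = "a", CE = "c", E = character(0),
         stop(sprintf("unknown model family '%s'", family)))
}

#' Fit a univariate or bivariate Cholesky twin model by FIML
#'
#' Estimates lower-triangular path coefficients for the requested variance
#' components (plus E, always present) by minimizing the FIML deviance of
#' the implied pair covariance structure. Optimization is quasi-Newton
#' (`nlminb`) from five deterministic starts: a moment-based (Falconer)
#' decomposition and fixed perturbations of it. Diagonal paths are
#' sign-normalized to be non-negative, removing reflection invariance.
#'
#' @param pairs A `pair_table` or [fiml_data()].
#' @param family One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param traits Trait stems; for bivariate fits the order fixes the
#'   Cholesky ordering (first trait first). For the fixation-duration
#'   analysis the convention is abstract first, naturalistic second, so the
#'   second trait's unique path isolates naturalistic-specific genetic
#'   variance.
#' @param ci `"none"`, or `"wald"` for delta-method intervals on the
#'   standardized components.
#' @return Object of class `"twin_fit"`: path matrices, implied components,
#'   standardized components per trait, deviance, AIC, parameter count,
#'   convergence and boundary flags.
#' @export
fit_twin_model <- function(pairs, family = "AE", traits = NULL, ci = "none") {
  fd <- if (inherits(pairs, "fiml_data")) pairs else fiml_data(pairs, traits)
  n <- fd$n_traits
  comps <- family_components(family)
  k_lt <- lt_count(n)
  init <- moment_inits(fd)

  build_params <- function(theta) {
    means <- theta[seq_len(n)]
    pos <- n
    paths <- list(a = NULL, c = NULL, d = NULL)
    for (cm in comps) {
      paths[[cm]] <- vec_to_lt(theta[pos + seq_len(k_lt)], n)
      pos <- pos + k_lt
    }
    e <- vec_to_lt(theta[pos + seq_len(k_lt)], n)
    diag(e) <- pmax(abs(diag(e)), 1e-8)
    cholesky_params(a = if (is.null(paths$a)) matrix(0, n, n) else paths$a,
                    e = e, c = paths$c, d = paths$d, means = means)
  }
  objective <- function(theta) {
    p <- tryCatch(build_params(theta), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    mu <- rep(p$means, 2)
    val <- neg2ll_suff(fd, mu, implied_pair_covariance(p, "MZ"),
                       implied_pair_covariance(p, "DZ"))
    if (!is.finite(val)) 1e12 else val
  }

  base_paths <- list(
    a = if ("a" %in% comps) safe_chol_lower(init$A) else NULL,
    c = if ("c" %in% comps) safe_chol_lower(init$C) else NULL,
    d = if ("d" %in% comps) safe_chol_lower(init$C) else NULL)
  e0 <- safe_chol_lower(init$E)
  equal_split <- safe_chol_lower(init$total / (length(comps) + 1))
  starts <- list()
  mk_theta <- function(scale_paths, use_equal = FALSE) {
    th <- init$mean
    for (cm in comps) {
      m <- if (use_equal) equal_split else base_paths[[cm]]
      th <- c(th, lt_to_vec(m * scale_paths))
    }
    e_m <- if (use_equal) equal_split else e0
    c(th, lt_to_vec(e_m))
  }
  starts[[1]] <- mk_theta(1)
  starts[[2]] <- mk_theta(0.5)
  starts[[3]] <- mk_theta(1.5)
  starts[[4]] <- mk_theta(1, use_equal = TRUE)
  starts[[5]] <- mk_theta(0.1)

  best <- NULL
  for (th0 in starts) {
    opt <- stats::nlminb(th0, objective,
                         control = list(iter.max = 500, eval.max = 2000,
                                        rel.tol = 1e-10))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (!is.finite(best$objective) || best$objective >= 1e12) {
    stop("fit_twin_model: optimization failed to find a finite deviance")
  }
  theta <- best$par
  params <- build_params(theta)
  # sign-normalize diagonals (likelihood is invariant to column reflections)
  for (cm in c(comps, "e")) {
    m <- params[[if (cm == "e") "e" else cm]]
    for (j in seq_len(n)) if (m[j, j] < 0) m[, j] <- -m[, j]
    params[[if (cm == "e") "e" else cm]] <- m
  }
  comp <- implied_components(params)
  std <- sapply(c("A", "C", "D"), function(k) {
    diag(comp[[k]]) / diag(comp$total)
  })
  std <- matrix(std, nrow = n)
  # E as the residual share, so components sum to one exactly
  std <- cbind(std, 1 - rowSums(std))
  dimnames(std) <- list(fd$traits, c("A", "C", "D", "E"))
  n_params <- length(theta)
  boundary <- any(std[, c(comps, "e") |> toupper()] < 1e-4)
  fit <- structure(list(
    family = family, traits = fd$traits, n_traits = n, params = params,
    components = comp, standardized = std, theta = theta,
    neg2ll = best$objective, n_params = n_params,
    aic = best$objective + 2 * n_params,
    n_pairs = fd$n_pairs, convergence = best$convergence,
    boundary = boundary, fiml = fd), class = "twin_fit")
  if (identical(ci, "wald")) fit$ci <- wald_ci_components(fit)
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s twin model (%d trait%s, %d pairs): -2LL = %.2f, AIC = %.2f\n",
              x$family, x$n_traits, if (x$n_traits > 1) "s" else "",
              x$n_pairs, x$neg2ll, x$aic))
  cat("Standardized components:\n")
  print(round(x$standardized, 3))
  if (isTRUE(x$boundary)) cat("note: estimate at a variance boundary\n")
  invisible(x)
}

# Delta-method (Wald) CIs for the standardized components, clipped to [0,1].
wald_ci_components <- function(fit, level = 0.95) {
  fd <- fit$fiml
  n <- fit$n_traits
  comps <- family_components(fit$family)
  obj <- function(theta) {
    p <- rebuild_params(fit, theta)
    mu <- rep(p$means, 2)
    val <- neg2ll_suff(fd, mu, implied_pair_covariance(p, "MZ"),
                       implied_pair_covariance(p, "DZ"))
    if (!is.finite(val)) 1e12 else val
  }
  H <- stats::optimHess(fit$theta, obj)
  cov_theta <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_theta)) return(NULL)
  std_fun <- function(theta) {
    p <- rebuild_params(fit, theta)
    comp <- implied_components(p)
    as.numeric(sapply(c("A", "C", "D", "E"),
                      function(k) diag(comp[[k]]) / diag(comp$total)))
  }
  g0 <- std_fun(fit$theta)
  eps <- 1e-5
  J <- sapply(seq_along(fit$theta), function(j) {
    tp <- fit$theta; tp[j] <- tp[j] + eps
    tm <- fit$theta; tm[j] <- tm[j] - eps
    (std_fun(tp) - std_fun(tm)) / (2 * eps)
  })
  se <- sqrt(pmax(diag(J %*% cov_theta %*% t(J)), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    trait = rep(fit$traits, 4),
    component = rep(c("A", "C", "D", "E"), each = n),
    estimate = g0,
    lower = pmax(g0 - zq * se, 0), upper = pmin(g0 + zq * se, 1),
    method = "wald")
  out[out$component %in% c(toupper(comps), "E"), ]
}

rebuild_params <- function(fit, theta) {
  n <- fit$n_traits
  comps <- family_components(fit$family)
  k_lt <- lt_count(n)
  means <- theta[seq_len(n)]
  pos <- n
  paths <- list(a = NULL, c = NULL, d = NULL)
  for (cm in comps) {
    paths[[cm]] <- vec_to_lt(theta[pos + seq_len(k_lt)], n)
    pos <- pos + k_lt
  }
  e <- vec_to_lt(theta[pos + seq_len(k_lt)], n)
  diag(e) <- pmax(abs(diag(e)), 1e-8)
  cholesky_params(a = if (is.null(paths$a)) matrix(0, n, n) else paths$a,
                  e = e, c = paths$c, d = paths$d, means = means)
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' Univariate fits only: the model is reparameterized as (mean, total
#' variance, standardized components), the target component is fixed on a
#' grid of candidate values, the remaining parameters are re-optimized, and
#' the bounds are where the profiled deviance rises by the chi-square
#' quantile (3.841 for 95%). Bounds are clipped to `[0, 1]`; when a bound is
#' pinned at the boundary the interval is one-sided (flagged).
#'
#' @param fit A univariate `"twin_fit"`.
#' @param component `"A"`, `"C"`, `"D"` or `"E"`.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `level`, `one_sided`.
#' @export
profile_ci <- function(fit, component = "A", level = 0.95) {
  if (fit$n_traits != 1) {
    stop("profile_ci: implemented for univariate fits; use Wald CIs for bivariate")
  }
  comps_l <- family_components(fit$family)
  comps <- toupper(comps_l)
  free <- c(comps, "E")
  if (!component %in% free) {
    stop(sprintf("component %s is not in family %s", component, fit$family))
  }
  fd <- fit$fiml
  others <- setdiff(free, component)[1]  # at most one other free component
  has_other <- length(setdiff(free, component)) > 0 && !is.na(others)

  dev_at <- function(h) {
    # nuisance: mean, log total variance, (optionally) the other component's
    # share of the remainder on a logit-like scale
    nuis_obj <- function(par) {
      mu <- par[1]; V <- exp(par[2])
      rest <- 1 - h
      other_val <- 0
      if (has_other && length(par) >= 3) {
        w <- 1 / (1 + exp(-par[3]))
        other_val <- w * rest
      }
      val_of <- function(k) {
        if (k == component) h else if (has_other && identical(others, k)) other_val else 0
      }
      A <- val_of("A"); C <- val_of("C"); D <- val_of("D")
      E <- 1 - A - C - D
      if (E <= 1e-8) return(1e12)
      p <- cholesky_params(a = matrix(sqrt(A * V), 1, 1),
                           c = matrix(sqrt(C * V), 1, 1),
                           d = matrix(sqrt(D * V), 1, 1),
                           e = matrix(sqrt(E * V), 1, 1), means = mu)
      val <- neg2ll_suff(fd, rep(mu, 2), implied_pair_covariance(p, "MZ"),
                         implied_pair_covariance(p, "DZ"))
      if (!is.finite(val)) 1e12 else val
    }
    V0 <- fit$components$total[1, 1]
    par0 <- c(fit$params$means[1], log(V0))
    if (has_other) {
      est_other <- fit$standardized[1, others]
      rest <- max(1 - h, 1e-6)
      w0 <- min(max(est_other / rest, 1e-4), 1 - 1e-4)
      par0 <- c(par0, log(w0 / (1 - w0)))
    }
    stats::nlminb(par0, nuis_obj, control = list(iter.max = 200))$objective
  }

  # the E component is constrained only through the others; profiling E means
  # fixing E = h and letting the non-E components share 1 - h
  if (component == "E") {
    if (length(comps) == 0) {
      stop("profile_ci: E is identically 1 under the E-only family")
    }
    dev_fun <- function(h) {
      h_nonE <- 1 - h
      if (length(comps_l) == 1) {
        profile_dev_single(fit, fd, comps_l[1], h_nonE)
      } else {
        profile_dev_pair(fit, fd, comps_l, h_nonE)
      }
    }
  } else {
    dev_fun <- dev_at
  }

  crit <- fit$neg2ll + stats::qchisq(level, df = 1)
  est <- fit$standardized[1, component]
  eps <- 1e-6
  f <- function(h) dev_fun(h) - crit
  lower <- if (est <= eps || f(eps) < 0) 0 else {
    stats::uniroot(f, c(eps, est), tol = 1e-4)$root
  }
  upper <- if (est >= 1 - eps || f(1 - eps) < 0) 1 else {
    stats::uniroot(f, c(est, 1 - eps), tol = 1e-4)$root
  }
  list(lower = lower, upper = upper, level = level,
       one_sided = (lower == 0 && est <= eps) || (upper == 1 && est >= 1 - eps))
}

# profiled deviance helpers used when profiling E
profile_dev_single <- function(fit, fd, comp_name, h_comp) {
  obj <- function(par) {
    mu <- par[1]; V <- exp(par[2])
    A <- if (comp_name == "a") h_comp else 0
    C <- if (comp_name == "c") h_comp else 0
    D <- if (comp_name == "d") h_comp else 0
    E <- 1 - A - C - D
    if (E <= 1e-8) return(1e12)
    p <- cholesky_params(a = matrix(sqrt(A * V), 1, 1),
                         c = matrix(sqrt(C * V), 1, 1),
                         d = matrix(sqrt(D * V), 1, 1),
                         e = matrix(sqrt(E * V), 1, 1), means = mu)
    val <- neg2ll_suff(fd, rep(mu, 2), implied_pair_covariance(p, "MZ"),
                       implied_pair_covariance(p, "DZ"))
    if (!is.finite(val)) 1e12 else val
  }
  V0 <- fit$components$total[1, 1]
  stats::nlminb(c(fit$params$means[1], log(V0)), obj,
                control = list(iter.max = 200))$objective
}

profile_dev_pair <- function(fit, fd, comp_names, h_total) {
  obj <- function(par) {
    mu <- par[1]; V <- exp(par[2]); w <- 1 / (1 + exp(-par[3]))
    shares <- stats::setNames(c(w * h_total, (1 - w) * h_total),
                              toupper(comp_names))
    A <- if ("A" %in% names(shares)) shares[["A"]] else 0
    C <- if ("C" %in% names(shares)) shares[["C"]] else 0
    D <- if ("D" %in% names(shares)) shares[["D"]] else 0
    E <- 1 - A - C - D
    if (E <= 1e-8) return(1e12)
    p <- cholesky_params(a = matrix(sqrt(A * V), 1, 1),
                         c = matrix(sqrt(C * V), 1, 1),
                         d = matrix(sqrt(D * V), 1, 1),
                         e = matrix(sqrt(E * V), 1, 1), means = mu)
    val <- neg2ll_suff(fd, rep(mu, 2), implied_pair_covariance(p, "MZ"),
                       implied_pair_covariance(p, "DZ"))
    if (!is.finite(val)) 1e12 else val
  }
  V0 <- fit$components$total[1, 1]
  stats::nlminb(c(fit$params$means[1], log(V0), 0), obj,
                control = list(iter.max = 200))$objective
}
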