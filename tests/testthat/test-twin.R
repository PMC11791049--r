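test_that("FIML deviance equals known values and the dense oracle", {
  # one complete univariate MZ pair at the mean with identity covariance
  pr <- data.frame(pair_id = "P1", zygosity = "MZ", sex = "F", age_days = 168,
                   y1_t1 = 0, y1_t2 = 0)
  class(pr) <- c("pair_table", "data.frame")
  val <- fiml_neg2ll(c(0, 0), diag(2), diag(2), pr, "y1")
  expect_equal(val, 2 * log(2 * pi), tolerance = 1e-12)

  # complete + partial cohort vs per-pair dense multivariate-normal oracle
  p <- bivariate_ae_params()
  pairs <- simulate_twin_traits(p, 100, 100, seed = 12, p_missing_twin = 0.15)
  mu <- rep(0, 4)
  smz <- implied_pair_covariance(p, "MZ")
  sdz <- implied_pair_covariance(p, "DZ")
  mine <- fiml_neg2ll(mu, smz, sdz, pairs, c("y1", "y2"))
  oracle <- dense_neg2ll_oracle(mu, smz, sdz, pairs, c("y1", "y2"))
  expect_equal(mine, oracle, tolerance = 1e-8 * abs(oracle))

  # a pair with one missing twin contributes its univariate marginal
  pr2 <- data.frame(pair_id = "P1", zygosity = "MZ", sex = "F", age_days = 168,
                    y1_t1 = 1.3, y1_t2 = NA)
  class(pr2) <- c("pair_table", "data.frame")
  v <- 0.8
  got <- fiml_neg2ll(c(0, 0), v * diag(2), v * diag(2), pr2, "y1")
  expect_equal(got, -2 * dnorm(1.3, 0, sqrt(v), log = TRUE), tolerance = 1e-12)

  # singular observed covariance errors with the pattern identified
  smz_bad <- matrix(1, 2, 2)
  expect_error(fiml_neg2ll(c(0, 0), smz_bad, smz_bad,
                           simulate_twin_traits(ae_params(0.3), 5, 5, seed = 1),
                           "y1"),
               "singular")
})

test_that("fitting exact implied moments recovers the generating paths", {
  p <- bivariate_ae_params()
  mk_group <- function(z) {
    sig <- implied_pair_covariance(p, z)
    n <- 1e6
    list(zygosity = z, obs = rep(TRUE, 4), n = n,
         sx = rep(0, 4), sxx = n * sig, pattern = "1111")
  }
  fd <- structure(list(traits = c("y1", "y2"), n_traits = 2L, dim = 4L,
                       groups = list(mk_group("MZ"), mk_group("DZ")),
                       n_pairs = 2e6,
                       n_by_zyg = table(factor(rep(c("MZ", "DZ"), 1e6),
                                               levels = c("MZ", "DZ")))),
                  class = "fiml_data")
  fit <- fit_twin_model(fd, "AE")
  expect_equal(unname(fit$standardized[, "A"]), c(0.25, 0.30), tolerance = 1e-3)
  expect_equal(fit$components$A[1, 2], 0.17, tolerance = 1e-3)
})

test_that("univariate AE recovery across generative heritabilities", {
  for (A in c(0, 0.19, 0.30)) {
    pairs <- simulate_twin_traits(ae_params(A), 20000, 20000,
                                  seed = 1000 + round(100 * A))
    fit <- fit_twin_model(pairs, "AE", "y1")
    expect_lt(abs(fit$standardized[1, "A"] - A), 0.03)
    expect_equal(sum(fit$standardized[1, ]), 1, tolerance = 1e-6)
  }
  # E-only data
  pairs <- simulate_twin_traits(cholesky_params(a = 0, e = 1), 5000, 5000,
                                seed = 77)
  fit <- fit_twin_model(pairs, "AE", "y1")
  expect_lt(fit$standardized[1, "A"], 0.03)
  expect_gt(fit$standardized[1, "E"], 0.97)
})

test_that("deviance decreases along nested families and components sum to one", {
  pairs <- simulate_twin_traits(ae_params(0.3), 400, 400, seed = 5,
                                p_missing_twin = 0.06)
  fd <- fiml_data(pairs, "y1")
  fits <- lapply(c("E", "AE", "CE", "ACE"), function(f) fit_twin_model(fd, f))
  names(fits) <- c("E", "AE", "CE", "ACE")
  expect_lte(fits$AE$neg2ll, fits$E$neg2ll + 1e-6)
  expect_lte(fits$CE$neg2ll, fits$E$neg2ll + 1e-6)
  expect_lte(fits$ACE$neg2ll, fits$AE$neg2ll + 1e-6)
  expect_lte(fits$ACE$neg2ll, fits$CE$neg2ll + 1e-6)
  for (f in fits) expect_equal(sum(f$standardized[1, ]), 1, tolerance = 1e-6)
  expect_true(all(f$standardized >= 0 & f$standardized <= 1))
})

test_that("bivariate Cholesky splits trait-2 genetic variance into shared and unique", {
  p <- bivariate_ae_params()
  pairs <- simulate_twin_traits(p, 8000, 8000, seed = 3)
  fit <- fit_twin_model(pairs, "AE", c("y1", "y2"))
  a <- fit$params$a
  # algebraic identity: a21^2 + a22^2 equals the implied genetic variance
  expect_equal(a[2, 1]^2 + a[2, 2]^2, fit$components$A[2, 2], tolerance = 1e-10)
  expect_gt(a[2, 1]^2, 0.01)  # shared genetic variance present
  expect_gt(a[2, 2]^2, 0.01)  # condition-unique genetic variance present
})

test_that("saturated free fit matches sample moments on complete data", {
  pairs <- simulate_twin_traits(bivariate_ae_params(), 500, 500, seed = 8)
  fd <- fiml_data(pairs, c("y1", "y2"))
  sat <- fit_saturated(fd)
  mz <- pairs[pairs$zygosity == "MZ", ]
  Y <- as.matrix(mz[, c("y1_t1", "y2_t1", "y1_t2", "y2_t2")])
  expect_equal(unname(sat$mean_mz), unname(colMeans(Y)), tolerance = 1e-10)
  expect_equal(unname(sat$sigma_mz),
               unname(stats::cov(Y) * (nrow(Y) - 1) / nrow(Y)),
               tolerance = 1e-10)
})

test_that("constrained saturated fit is symmetric under twin-order permutation", {
  pairs <- simulate_twin_traits(bivariate_ae_params(), 300, 300, seed = 21)
  fd <- fiml_data(pairs, c("y1", "y2"))
  con <- fit_saturated(fd, constrained = TRUE)
  swapped <- pairs
  swapped[, c("y1_t1", "y2_t1", "y1_t2", "y2_t2")] <-
    pairs[, c("y1_t2", "y2_t2", "y1_t1", "y2_t1")]
  con2 <- fit_saturated(fiml_data(swapped, c("y1", "y2")), constrained = TRUE)
  expect_equal(con$neg2ll, con2$neg2ll, tolerance = 1e-4)
  expect_equal(con$correlations$r_ph, con2$correlations$r_ph, tolerance = 1e-4)
})

test_that("assumption test behaves as a likelihood-ratio test", {
  pairs <- simulate_twin_traits(ae_params(0.3), 200, 200, seed = 2)
  fd <- fiml_data(pairs, "y1")
  free <- fit_saturated(fd)
  con <- fit_saturated(fd, constrained = TRUE)
  at <- assumption_test(free, con)
  expect_gte(at$chisq, 0)
  expect_equal(at$df, free$n_params - con$n_params)
  expect_error(assumption_test(con, free), "free and a constrained")

  # identical fits give chi-square zero, p = 1
  at0 <- assumption_test(structure(list(constrained = FALSE, traits = "y1",
                                        n_params = 10, neg2ll = 100),
                                   class = "saturated_fit"),
                         structure(list(constrained = TRUE, traits = "y1",
                                        n_params = 4, neg2ll = 100),
                                   class = "saturated_fit"))
  expect_equal(at0$chisq, 0)
  expect_equal(at0$p, 1)

  # injected twin-order mean difference is detected
  shifted <- pairs
  shifted$y1_t1 <- shifted$y1_t1 + 1.5
  fd2 <- fiml_data(shifted, "y1")
  at2 <- assumption_test(fit_saturated(fd2),
                         fit_saturated(fd2, constrained = TRUE))
  expect_lt(at2$p, 1e-6)
})

test_that("profile intervals cover the generative value and shrink with n", {
  fit_small <- fit_twin_model(simulate_twin_traits(ae_params(0.3), 300, 300,
                                                   seed = 40), "AE", "y1")
  fit_big <- fit_twin_model(simulate_twin_traits(ae_params(0.3), 5000, 5000,
                                                 seed = 41), "AE", "y1")
  ci_s <- profile_ci(fit_small, "A")
  ci_b <- profile_ci(fit_big, "A")
  expect_lt(ci_b$upper - ci_b$lower, ci_s$upper - ci_s$lower)
  expect_true(ci_b$lower <= 0.3 && 0.3 <= ci_b$upper)
  # A and E intervals mirror each other under AE
  ci_e <- profile_ci(fit_big, "E")
  expect_equal(ci_e$lower, 1 - ci_b$upper, tolerance = 1e-3)
  expect_equal(ci_e$upper, 1 - ci_b$lower, tolerance = 1e-3)

  # component estimated at zero pins the lower bound at zero
  fit0 <- fit_twin_model(simulate_twin_traits(cholesky_params(a = 0, e = 1),
                                              800, 800, seed = 42), "AE", "y1")
  ci0 <- profile_ci(fit0, "A")
  expect_equal(ci0$lower, 0)
})

test_that("model selection prefers the generating family and honors the ACE convention", {
  pairs <- simulate_twin_traits(ae_params(0.4), 5000, 5000, seed = 55)
  fd <- fiml_data(pairs, "y1")
  sat <- fit_saturated(fd)
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(f) fit_twin_model(fd, f))
  cmp <- select_model(fits, sat)
  expect_equal(cmp$selected, "AE")
  expect_equal(cmp$table$aic, cmp$table$neg2ll + 2 * cmp$table$n_params)

  # single fit is trivially selected
  cmp1 <- select_model(fits[2])
  expect_equal(cmp1$selected, "AE")

  # r_MZ > 2 r_DZ: ADE indicated, ACE-family model reported by convention
  mock_fit <- function(family, aic, n2 = 1000) {
    structure(list(family = family, neg2ll = n2, n_params = (aic - n2) / 2,
                   aic = aic), class = "twin_fit")
  }
  mock_sat <- structure(list(constrained = FALSE, traits = "y1", n_params = 10,
                             neg2ll = 995,
                             correlations = list(r_mz = 0.4, r_dz = 0.05)),
                        class = "saturated_fit")
  cmp2 <- select_model(list(mock_fit("ADE", 1006), mock_fit("ACE", 1008),
                            mock_fit("AE", 1007)), mock_sat)
  expect_equal(cmp2$selected, "AE")
  expect_true(any(grepl("non-additive", cmp2$notes)))
})
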