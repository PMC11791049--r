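test_that("implied pair covariance carries the MZ/DZ genetic sharing weights", {
  p <- ae_params(0.30)
  smz <- implied_pair_covariance(p, "MZ")
  sdz <- implied_pair_covariance(p, "DZ")
  expect_equal(smz[1, 2], 0.30, tolerance = 1e-12)
  expect_equal(sdz[1, 2], 0.15, tolerance = 1e-12)
  expect_equal(diag(smz), c(1, 1))

  # E-only model: cross-twin covariance zero for both zygosities
  pe <- cholesky_params(a = 0, e = 1)
  expect_equal(implied_pair_covariance(pe, "MZ")[1, 2], 0)
  expect_equal(implied_pair_covariance(pe, "DZ")[1, 2], 0)

  # bivariate: cross-twin cross-trait entry = genetic cross-covariance
  a <- matrix(c(0.5, 0.34, 0, 0.4), 2, 2, byrow = FALSE)
  pb <- cholesky_params(a = a, e = diag(c(0.6, 0.6)))
  expect_equal(a[1, 1] * a[2, 1], 0.17)
  smz <- implied_pair_covariance(pb, "MZ")
  sdz <- implied_pair_covariance(pb, "DZ")
  expect_equal(smz[1, 4], 0.17, tolerance = 1e-12)
  expect_equal(sdz[1, 4], 0.085, tolerance = 1e-12)
  # direct matrix-arithmetic oracle for the whole matrix
  A <- a %*% t(a); E <- diag(c(0.6, 0.6)) %*% diag(c(0.6, 0.6))
  oracle <- rbind(cbind(A + E, 0.5 * A), cbind(0.5 * A, A + E))
  expect_equal(sdz, oracle, tolerance = 1e-12)
})

test_that("invalid path configurations are rejected", {
  expect_error(cholesky_params(a = 0.5, e = 0.5, c = 0.2, d = 0.2), "both")
  expect_error(cholesky_params(a = 0.5, e = 0), "diagonal")
  expect_error(cholesky_params(a = NaN, e = 1), "non-finite")
  expect_error(cholesky_params(a = matrix(c(0.5, 0, 0.3, 0.5), 2), e = diag(2)),
               "triangular")
})

test_that("simulated twin traits reproduce the implied covariance", {
  p <- ae_params(0.30)
  # average the empirical covariance over independent cohorts of 50,000 per
  # zygosity: a single draw leaves ~5% tail probability above the bound from
  # sampling noise alone, while averaging keeps the check sensitive to bias
  emp <- list(MZ = matrix(0, 2, 2), DZ = matrix(0, 2, 2))
  reps <- 4
  for (r in seq_len(reps)) {
    pairs <- simulate_twin_traits(p, 50000, 50000, seed = 100 + r)
    for (z in c("MZ", "DZ")) {
      d <- pairs[pairs$zygosity == z, ]
      emp[[z]] <- emp[[z]] + stats::cov(cbind(d$y1_t1, d$y1_t2)) / reps
    }
  }
  for (z in c("MZ", "DZ")) {
    expect_lt(norm(emp[[z]] - implied_pair_covariance(p, z), "F"), 0.02)
  }
  pairs <- simulate_twin_traits(p, 50000, 50000, seed = 101)
  mz <- pairs[pairs$zygosity == "MZ", ]
  expect_lt(abs(cor(mz$y1_t1, mz$y1_t2) - 0.30), 0.01)

  # determinism and edge cases
  again <- simulate_twin_traits(p, 50, 50, seed = 7)
  expect_identical(simulate_twin_traits(p, 50, 50, seed = 7), again)
  expect_equal(nrow(simulate_twin_traits(p, 0, 0)), 0)

  # MZ correlation is at least the DZ correlation whenever A > 0
  for (A in c(0.1, 0.3, 0.6)) {
    pr <- simulate_twin_traits(ae_params(A), 5000, 5000, seed = round(100 * A))
    mzc <- cor(pr$y1_t1[pr$zygosity == "MZ"], pr$y1_t2[pr$zygosity == "MZ"])
    dzc <- cor(pr$y1_t1[pr$zygosity == "DZ"], pr$y1_t2[pr$zygosity == "DZ"])
    expect_gt(mzc, dzc - 0.03)
  }
})

test_that("partially complete pairs appear at the requested rate", {
  p <- ae_params(0.3)
  pairs <- simulate_twin_traits(p, 2000, 2000, seed = 5, p_missing_twin = 0.1)
  miss <- is.na(pairs$y1_t1) | is.na(pairs$y1_t2)
  expect_lt(abs(mean(miss) - 0.1), 0.02)
  expect_false(any(is.na(pairs$y1_t1) & is.na(pairs$y1_t2)))
})

test_that("gaze recordings have the nominal sampling structure", {
  sch <- demo_schedule("naturalistic", 1)
  gp <- gaze_gen_params(noise_rms_px = 0, missing_proportion_target = 0,
                        wander_fraction = 0, fd_bounds_ms = c(15000, 20999))
  rec <- simulate_gaze_recording(20000, sch, gp, seed = 3)
  expect_equal(nrow(rec), 2520)  # 21 s at 120 Hz
  truth <- attr(rec, "truth")
  expect_equal(nrow(truth), 1)
  pts <- unique(round(cbind(rec$x_px[rec$valid == 1], rec$y_px[rec$valid == 1]), 9))
  expect_equal(nrow(pts), 1)  # zero noise: every sample at one point

  # missingness target
  gp2 <- gaze_gen_params(missing_proportion_target = 0.10)
  rec2 <- simulate_gaze_recording(553, sch, gp2, seed = 4)
  expect_lt(abs(mean(rec2$valid == 0) - 0.10), 0.02)

  # determinism
  r1 <- simulate_gaze_recording(553, sch, gp2, seed = 11)
  r2 <- simulate_gaze_recording(553, sch, gp2, seed = 11)
  expect_identical(r1, r2)

  expect_error(gaze_gen_params(missing_proportion_target = 1), "missing")
})

test_that("successive-sample noise matches the RMS calibration", {
  sch <- demo_schedule("naturalistic", 1)
  gp <- gaze_gen_params(noise_rms_px = 0.66, missing_proportion_target = 0)
  rec <- simulate_gaze_recording(1500, sch, gp, seed = 8)
  # within long fixations, successive displacement RMS ~ noise_rms
  truth <- attr(rec, "truth")
  i <- which.max(truth$offset_ms - truth$onset_ms)
  idx <- which(rec$t_ms >= truth$onset_ms[i] + 20 & rec$t_ms < truth$offset_ms[i] - 20)
  d <- sqrt(diff(rec$x_px[idx])^2 + diff(rec$y_px[idx])^2)
  expect_equal(sqrt(mean(d^2)), 0.66, tolerance = 0.1)
})

test_that("polygenic scores share the twin genetic structure", {
  p <- ae_params(0.3)
  pairs <- simulate_twin_traits(p, 1500, 1500, seed = 2)
  tab <- simulate_pgs_table(pairs, effect = rep(0, 7), seed = 3)
  expect_true(all(paste0("PC", 1:10) %in% names(tab)))
  w <- reshape(tab[, c("pair_id", "subject_id", "pgs1", "zygosity")],
               idvar = "pair_id", timevar = "subject_id", direction = "wide")
  # MZ co-twins carry identical scores; DZ correlate ~0.5
  s1 <- tab$pgs1[order(tab$subject_id)]
  byp <- split(tab[, c("pgs1", "zygosity")], tab$pair_id)
  byp <- byp[vapply(byp, nrow, 0L) == 2]
  z <- vapply(byp, function(d) d$zygosity[1], "")
  x1 <- vapply(byp, function(d) d$pgs1[1], 0)
  x2 <- vapply(byp, function(d) d$pgs1[2], 0)
  expect_equal(x1[z == "MZ"], x2[z == "MZ"], tolerance = 1e-12)
  expect_equal(cor(x1[z == "DZ"], x2[z == "DZ"]), 0.5, tolerance = 0.08)
  # zero effect: no score-phenotype correlation
  expect_lt(abs(cor(tab$pgs1, tab$phenotype)), 0.05)
})
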