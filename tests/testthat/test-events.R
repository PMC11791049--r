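test_that("sample velocity is the smoothed centered difference in px/s", {
  # stationary
  d <- dwell_samples(200, 500, 400)
  v <- sample_velocity(make_recording(d$x, d$y))
  expect_true(all(v[!is.na(v)] == 0))

  # linear motion: 120 px per sample step at 120 Hz -> 14,400 px/s
  n <- 30
  rec <- make_recording(120 * (0:(n - 1)), rep(0, n))
  v <- sample_velocity(rec)
  expect_equal(unique(round(v[!is.na(v)], 6)), 14400)

  # single valid sample: no velocity defined
  rec1 <- make_recording(c(NA, 500, NA), c(NA, 400, NA), valid = c(0, 1, 0))
  expect_true(all(is.na(sample_velocity(rec1))))
})

test_that("adaptive threshold converges to mean + 6 SD of the noise component", {
  set.seed(42)
  speeds <- c(rnorm(5000, 20, 5), rep(1e4, 250))
  thr <- adaptive_threshold(speeds)
  expect_equal(thr, 20 + 6 * 5, tolerance = 0.1 * 50)
  # brute-force iteration oracle
  t_cur <- 250
  for (i in 1:50) {
    sub <- speeds[speeds < t_cur]
    t_new <- mean(sub) + 6 * sd(sub)
    if (abs(t_new - t_cur) < 1) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  expect_equal(thr, max(t_cur, 5 * median(speeds[speeds < t_cur]), 10),
               tolerance = 1e-8)

  # scale equivariance: doubling the noise scale roughly doubles the threshold
  thr2 <- adaptive_threshold(c(rnorm(5000, 40, 10), rep(1e4, 250)))
  expect_equal(thr2 / thr, 2, tolerance = 0.1)

  # zero-noise degenerate data: clamp applies
  expect_equal(adaptive_threshold(c(rep(0, 100), 1e4)), 10)
  expect_warning(thr0 <- adaptive_threshold(rep(1e4, 50)), "no sub-threshold")
  expect_equal(thr0, 250)
  expect_error(adaptive_threshold(rep(NA_real_, 5)), "no defined")
})

test_that("threshold never decreases when noise is added", {
  sch <- demo_schedule("naturalistic", 1)
  thrs <- sapply(c(0.2, 0.66, 1.5, 3), function(nr) {
    gp <- gaze_gen_params(noise_rms_px = nr, missing_proportion_target = 0)
    rec <- simulate_gaze_recording(553, sch, gp, seed = 99)
    adaptive_threshold(sample_velocity(rec))
  })
  expect_true(all(diff(thrs) > 0))
})

test_that("classifier finds single dwells, merges blink gaps, keeps separate dwells apart", {
  # one noiseless 500 ms dwell flanked by saccades
  pre <- dwell_samples(300, 200, 300)
  s1 <- ramp_samples(50, c(200, 300), c(600, 400))
  mid <- dwell_samples(500, 600, 400)
  s2 <- ramp_samples(50, c(600, 400), c(1000, 500))
  post <- dwell_samples(300, 1000, 500)
  rec <- make_recording(c(pre$x, s1$x, mid$x, s2$x, post$x),
                        c(pre$y, s1$y, mid$y, s2$y, post$y))
  fx <- classify_fixations(rec)
  expect_equal(nrow(fx), 3)
  mid_fx <- fx[which.min(abs(fx$cx - 600)), ]
  expect_equal(mid_fx$duration_ms, 500, tolerance = PERIOD_MS)

  # dwell split by a 40 ms blink at the same location -> merged back
  a <- dwell_samples(250, 600, 400)
  b <- dwell_samples(250, 600, 400)
  gapn <- round(40 / PERIOD_MS)
  rec2 <- make_recording(c(a$x, rep(NA, gapn), b$x),
                         c(a$y, rep(NA, gapn), b$y),
                         valid = c(rep(1, length(a$x)), rep(0, gapn),
                                   rep(1, length(b$x))))
  fx2 <- classify_fixations(rec2)
  expect_equal(nrow(fx2), 1)
  expect_equal(fx2$duration_ms, 540, tolerance = 2 * PERIOD_MS)

  # two dwells 300 px apart are never merged
  fx3 <- classify_fixations(two_dwell_recording(p2 = c(900, 400)))
  expect_equal(nrow(fx3), 2)
  expect_true(all(abs(sort(fx3$cx) - c(600, 900)) < 1))
})

test_that("classifier recovers generator boundaries on clean streams", {
  sch <- demo_schedule("naturalistic", 1)
  gp <- gaze_gen_params(noise_rms_px = 0, missing_proportion_target = 0)
  hits <- 0; total <- 0
  for (s in 1:5) {
    rec <- simulate_gaze_recording(553, sch, gp, seed = 200 + s)
    truth <- attr(rec, "truth")
    fx <- classify_fixations(rec)
    for (i in seq_len(nrow(truth))) {
      total <- total + 1
      # the generator's event boundaries are continuous while classified
      # boundaries sit on the sample grid, so matching allows one sample
      # period plus the sub-sample phase
      ok <- any(abs(fx$onset_ms - truth$onset_ms[i]) <= 1.5 * PERIOD_MS &
                  abs(fx$offset_ms - truth$offset_ms[i]) <= 1.5 * PERIOD_MS)
      hits <- hits + ok
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("duration and RMS filters partition fixations with the stated bounds", {
  fx <- data.frame(onset_ms = 0, offset_ms = 1,
                   duration_ms = c(90, 100, 553, 2358, 2400),
                   cx = 0, cy = 0, rms = 0.5, n_samples = 10)
  out <- apply_filters(fx)
  expect_equal(out$duration_ms[out$kept], c(100, 553))
  expect_equal(out$reject_reason[!out$kept], c("too_short", "too_long", "too_long"))
  # kept and rejected partition the input; filtering is idempotent
  expect_equal(sum(out$kept) + sum(!out$kept), nrow(fx))
  again <- apply_filters(out[out$kept, names(fx)])
  expect_true(all(again$kept))

  noisy <- data.frame(onset_ms = 0, offset_ms = 1, duration_ms = 500,
                      cx = 0, cy = 0, rms = 1.78, n_samples = 10)
  expect_equal(apply_filters(noisy)$reject_reason, "too_noisy")
  edge <- noisy; edge$rms <- 1.77
  expect_true(apply_filters(edge)$kept)

  empty <- apply_filters(fx[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("noisier streams are rejected as too_noisy at least as often", {
  sch <- demo_schedule("naturalistic", 1)
  count_noisy <- function(nr, seed) {
    gp <- gaze_gen_params(noise_rms_px = nr, missing_proportion_target = 0)
    rec <- simulate_gaze_recording(553, sch, gp, seed = seed)
    fx <- apply_filters(classify_fixations(rec))
    sum(fx$reject_reason %in% "too_noisy")
  }
  lo <- sum(sapply(1:4, function(s) count_noisy(0.66, s)))
  hi <- sum(sapply(1:4, function(s) count_noisy(2.5, s)))
  expect_gte(hi, lo)
  expect_gt(hi, 0)
})

test_that("condition summary pools kept fixations and counts missing samples", {
  d <- dwell_samples(2000, 600, 400)
  rec <- make_recording(d$x, d$y)
  fx <- data.frame(subject_id = "S1", video_id = "nat_1",
                   condition = "naturalistic",
                   onset_ms = c(0, 1000), offset_ms = c(400, 1600),
                   duration_ms = c(400, 600), cx = 600, cy = 400, rms = 0.2,
                   n_samples = 10, kept = TRUE, reject_reason = NA)
  cs <- condition_summary(list(rec), fx)
  expect_equal(cs$mean_fd, 500)
  expect_equal(cs$n_fix, 2)
  expect_equal(cs$prop_missing, 0)

  # all samples invalid: measure missing, prop_missing = 1
  rec2 <- make_recording(rep(NA_real_, 100), rep(NA_real_, 100),
                         valid = rep(0, 100), subject_id = "S2")
  expect_true(all(is.na(sample_velocity(rec2))))
  expect_equal(nrow(classify_fixations(rec2)), 0)
  cs2 <- condition_summary(list(rec2), detect_fixations(list(rec2)))
  expect_equal(cs2$prop_missing, 1)
  expect_true(is.na(cs2$mean_fd))
  expect_equal(cs2$n_fix, 0)
})
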