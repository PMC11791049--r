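test_that("fixation dwell is apportioned to frames by overlap", {
  sch <- fixed_activity_schedule()
  # centroid in actor 1's face box; spans frames 0..2 exactly
  fc <- c(525, 450 - 262 / 3)
  fx <- data.frame(onset_ms = 0, offset_ms = 120, cx = fc[1], cy = fc[2])
  al <- allocate_fixations(fx, sch)
  expect_equal(nrow(al), 3)
  expect_equal(al$frame, 0:2)
  expect_equal(al$dwell_ms, rep(40, 3))
  expect_true(all(al$in_face))
  expect_equal(al$actor_id, rep(1, 3))
  expect_true(all(al$actor_active == FALSE))

  # centroid outside all actor rects
  fx2 <- data.frame(onset_ms = 0, offset_ms = 120, cx = 310, cy = 180)
  al2 <- allocate_fixations(fx2, sch)
  expect_true(all(is.na(al2$actor_id)))

  # straddling actor 1's inactive -> active transition at frame 200
  fx3 <- data.frame(onset_ms = 200 * 40 - 60, offset_ms = 200 * 40 + 100,
                    cx = 525, cy = 350)
  al3 <- allocate_fixations(fx3, sch)
  expect_equal(sum(al3$dwell_ms[al3$actor_active == FALSE]), 60)
  expect_equal(sum(al3$dwell_ms[al3$actor_active == TRUE]), 100)
  expect_setequal(unique(al3$frame_state[al3$frame >= 200]), "mixed")
})

test_that("dwell is conserved and proportions are scale invariant", {
  sch <- fixed_activity_schedule()
  set.seed(14)
  fx <- data.frame(onset_ms = sort(runif(40, 0, 20000)))
  fx$offset_ms <- fx$onset_ms + runif(40, 100, 1200)
  fx$cx <- runif(40, 320, 1600); fx$cy <- runif(40, 180, 880)
  al <- allocate_fixations(fx, sch)
  total_in <- sum(pmin(fx$offset_ms, 21000) - pmax(fx$onset_ms, 0))
  expect_equal(sum(al$dwell_ms), total_in, tolerance = 1e-9)

  p1 <- proportion_on_face(al)
  al2 <- al; al2$dwell_ms <- al$dwell_ms * 3.7
  p2 <- proportion_on_face(al2)
  expect_equal(p1$prop, p2$prop)
  a1 <- proportion_on_active(al); a2 <- proportion_on_active(al2)
  expect_equal(a1$prop, a2$prop)
})

test_that("face proportion follows the inactive-actor dwell arithmetic", {
  mk <- function(dwell, actor, face, active, state) {
    data.frame(fixation = seq_along(dwell), frame = 0, dwell_ms = dwell,
               actor_id = actor, in_face = face, actor_active = active,
               frame_state = state)
  }
  # 300 ms face-inactive + 200 ms body-inactive + 500 ms active actor
  al <- mk(c(300, 200, 500), c(1, 1, 2), c(TRUE, FALSE, FALSE),
           c(FALSE, FALSE, TRUE), "mixed")
  expect_equal(proportion_on_face(al)$prop, 300 / 500)

  # no inactive-actor dwell -> missing
  al2 <- mk(400, 2, FALSE, TRUE, "mixed")
  expect_true(is.na(proportion_on_face(al2)$prop))

  # all inactive dwell in face -> 1.0
  al3 <- mk(c(250, 250), c(1, 3), TRUE, FALSE, "all_inactive")
  expect_equal(proportion_on_face(al3)$prop, 1)

  # active proportion: 710 on active actors of mixed frames / 1000 total mixed
  al4 <- mk(c(710, 190, 100), c(1, 2, NA), FALSE, c(TRUE, FALSE, NA), "mixed")
  expect_equal(proportion_on_active(al4)$prop, 0.71)

  # no mixed frames -> missing
  al5 <- mk(c(500, 500), c(1, 2), FALSE, FALSE, "all_inactive")
  expect_true(is.na(proportion_on_active(al5)$prop))
})

test_that("exclusion rules drop conditions and degenerate proportions", {
  m <- data.frame(
    subject_id = c("A", "B", "C", "D"),
    mean_fd_naturalistic = c(500, 510, 520, 530),
    n_fix_naturalistic = c(30, 4, 30, 30),
    prop_missing_naturalistic = c(0.50, 0.10, 0.10, 0.10),
    mean_rms_naturalistic = 0.6,
    mean_fd_abstract = c(600, 610, 620, 630),
    n_fix_abstract = c(20, 4, 20, 20),
    prop_missing_abstract = c(0.10, 0.10, 0.10, 0.10),
    mean_rms_abstract = 0.7,
    prop_face = c(0.5, 0.6, 0, 0.7),
    prop_active = c(0.7, 0.7, 0.7, 1))
  out <- apply_exclusions(m)
  # A: naturalistic missing 50% > 45.6% -> all naturalistic measures dropped
  expect_true(is.na(out$mean_fd_naturalistic[1]))
  expect_true(is.na(out$prop_face[1]))
  expect_equal(out$excl_naturalistic[1], "high_missing")
  expect_false(is.na(out$mean_fd_abstract[1]))
  # B: 4 fixations < 5 for naturalistic but >= 3 for abstract
  expect_true(is.na(out$mean_fd_naturalistic[2]))
  expect_false(is.na(out$mean_fd_abstract[2]))
  # C: prop_face exactly 0 dropped, everything else retained
  expect_true(is.na(out$prop_face[3]))
  expect_equal(out$excl_prop_face[3], "degenerate")
  expect_false(is.na(out$mean_fd_naturalistic[3]))
  expect_false(is.na(out$prop_active[3]))
  # D: prop_active exactly 1 dropped
  expect_true(is.na(out$prop_active[4]))
})

test_that("cohorts recover the generative face-looking probability", {
  set.seed(31)
  n <- 30
  subs <- data.frame(subject_id = sprintf("S%02d", 1:n),
                     mean_fd_naturalistic = rnorm(n, 552.53, 115.77),
                     mean_fd_abstract = rnorm(n, 602.84, 149.87))

  # on a transition-free (all-inactive) scene the face share of
  # inactive-actor dwell equals the generative probability exactly in
  # expectation
  quiet <- fixed_activity_schedule(matrix(FALSE, 525, 3))
  quiet$video_id <- "nat_q"
  sched_q <- list(nat_q = quiet)
  coh_q <- simulate_gaze_cohort(subs, sched_q,
                                gaze_gen_params(wander_fraction = 0),
                                seed = 18)
  mm_q <- subject_measures(coh_q$recordings,
                           detect_fixations(coh_q$recordings), sched_q)
  expect_lt(abs(mean(mm_q$prop_face, na.rm = TRUE) - 0.60), 0.04)

  # on dynamic scenes, fixations straddling activity transitions attenuate
  # both proportions; bounds account for that
  sched <- demo_schedules()[c("nat_1", "nat_2")]
  coh <- simulate_gaze_cohort(subs, sched, gaze_gen_params(), seed = 17)
  mm <- subject_measures(coh$recordings, detect_fixations(coh$recordings),
                         sched)
  expect_lt(abs(mean(mm$prop_face, na.rm = TRUE) - 0.60), 0.08)
  expect_lt(abs(mean(mm$prop_active, na.rm = TRUE) - 0.71), 0.08)
})
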