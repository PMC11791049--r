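#' Parameters of the synthetic gaze-stream generator
#'
#' Defaults emulate the acquisition and descriptive statistics of a 5-month
#' infant cohort viewing 21 s dynamic scenes on a 120 Hz eye-tracker:
#' fixation durations are lognormal (right-skewed) truncated to the
#' analysable range 100-2358 ms, saccades are 20-80 ms linear ramps,
#' per-sample positional noise is calibrated so the successive-sample RMS is
#' ~0.66 px, about 10% of samples are invalid, inactive-actor looks land on
#' the face 60% of the time, and 71% of looks during mixed frames target an
#' active actor.
#'
#' @param fd_shape Lognormal sigma of the fixation-duration law (default 0.5).
#' @param fd_bounds_ms Truncation bounds for generated durations; the
#'   lognormal location is solved per subject so the truncated mean equals the
#'   subject's latent mean, which makes downstream mean recovery unbiased by
#'   construction.
#' @param saccade_gap_ms Range of inter-fixation gaps (linear ramps).
#' @param noise_rms_px Target successive-sample RMS displacement (px); the
#'   per-axis noise SD is half of it.
#' @param missing_proportion_target Target fraction of invalid samples in
#'   `[0, 1)`; short dropout runs (2-8 samples) are inserted until reached.
#' @param p_face_given_inactive_look Probability an inactive-actor look
#'   targets the face box.
#' @param p_active_actor_look Probability a look starting in a mixed frame
#'   targets an active actor.
#' @param wander_fraction Expected fraction of video time spent in
#'   non-fixation wandering gaze (smooth meandering movement the classifier
#'   leaves out of fixations). Infants spend much of a trial in such
#'   unclassifiable gaze: it is what keeps fixation counts low and highly
#'   variable even when little data is missing, giving the count independent
#'   variance from the fixation-duration trait. 0 disables wandering.
#' @param wander_speed_px_s Speed range of wandering legs (px/s); kept above
#'   any realistic velocity threshold and below saccadic speeds.
#' @param sample_hz Sampling rate (default 120).
#' @return Object of class `"gaze_gen_params"`.
#' @export
gaze_gen_params <- function(fd_shape = 0.5,
                            fd_bounds_ms = c(100, 2358),
                            saccade_gap_ms = c(20, 80),
                            noise_rms_px = 0.66,
                            missing_proportion_target = 0.10,
                            p_face_given_inactive_look = 0.60,
                            p_active_actor_look = 0.71,
                            wander_fraction = 0.5,
                            wander_speed_px_s = c(400, 900),
                            sample_hz = 120) {
  stopifnot(fd_shape > 0, length(fd_bounds_ms) == 2,
            fd_bounds_ms[1] < fd_bounds_ms[2],
            noise_rms_px >= 0, sample_hz > 0,
            wander_fraction >= 0, wander_fraction < 1,
            length(wander_speed_px_s) == 2)
  probs <- c(missing_proportion_target, p_face_given_inactive_look,
             p_active_actor_look)
  if (any(probs < 0 | probs > 1) || missing_proportion_target >= 1) {
    stop("gaze_gen_params: probabilities must lie in [0,1] and the missing target below 1")
  }
  structure(as.list(environment()), class = "gaze_gen_params")
}

# Mean of a lognormal(mu, s) truncated to [a, b]. At extreme locations the
# normalizing mass underflows; the mean then approaches the nearer bound.
trunc_lnorm_mean <- function(mu, s, a, b) {
  za <- (log(a) - mu) / s; zb <- (log(b) - mu) / s
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  if (!is.finite(denom) || denom < 1e-12) {
    return(if (mu > (log(a) + log(b)) / 2) b * (1 - 1e-9) else a * (1 + 1e-9))
  }
  val <- exp(mu + s^2 / 2) *
    (stats::pnorm(zb - s) - stats::pnorm(za - s)) / denom
  if (!is.finite(val)) {
    return(if (mu > (log(a) + log(b)) / 2) b * (1 - 1e-9) else a * (1 + 1e-9))
  }
  val
}

# Solve the lognormal location so the truncated mean equals `target_mean`.
solve_lnorm_mu <- function(target_mean, s, a, b) {
  if (target_mean <= a || target_mean >= b) {
    stop("subject mean fixation duration must lie strictly inside the truncation bounds")
  }
  stats::uniroot(function(mu) trunc_lnorm_mean(mu, s, a, b) - target_mean,
                 lower = log(a) - 10 * s, upper = log(b) + 10 * s,
                 tol = 1e-8)$root
}

r_trunc_lnorm <- function(n, mu, s, a, b) {
  u <- stats::runif(n, stats::plnorm(a, mu, s), stats::plnorm(b, mu, s))
  stats::qlnorm(u, mu, s)
}

runif_in_rect <- function(r) {
  c(stats::runif(1, r$x0, r$x0 + r$width), stats::runif(1, r$y0, r$y0 + r$height))
}

# Uniform point in actor rect but outside its face rect (rejection sampling).
runif_in_body <- function(actor, face) {
  for (i in 1:200) {
    p <- runif_in_rect(actor)
    if (!rect_contains(face, p[1], p[2])) return(p)
  }
  p
}

# Choose a fixation target given the frame state at fixation onset.
choose_target <- function(schedule, t_ms, gp) {
  fr <- frame_index_at(schedule, min(t_ms, schedule$duration_ms - 1e-9))
  active <- schedule$activity[fr + 1, ]
  pick_inactive_style <- function(actor_id) {
    if (stats::runif(1) < gp$p_face_given_inactive_look) {
      list(p = runif_in_rect(schedule$face_rects[[actor_id]]),
           kind = "face")
    } else {
      list(p = runif_in_body(schedule$actor_rects[[actor_id]],
                             schedule$face_rects[[actor_id]]),
           kind = "body")
    }
  }
  n_active <- sum(active)
  if (n_active == 0) {
    a <- sample.int(3, 1)
    tg <- pick_inactive_style(a)
  } else if (n_active == 3) {
    a <- sample.int(3, 1)
    tg <- list(p = runif_in_rect(schedule$actor_rects[[a]]), kind = "body")
  } else if (stats::runif(1) < gp$p_active_actor_look) {
    a <- if (n_active == 1) which(active) else sample(which(active), 1)
    tg <- list(p = runif_in_rect(schedule$actor_rects[[a]]), kind = "body")
  } else {
    a <- if (n_active == 2) which(!active) else sample(which(!active), 1)
    tg <- pick_inactive_style(a)
  }
  list(p = tg$p, actor = a, kind = tg$kind)
}

#' Simulate one raw gaze recording
#'
#' Produces an alternating fixation/saccade sample stream over one video at
#' the configured sampling rate. Fixation durations follow the subject's
#' truncated-lognormal law; targets are drawn from the scene AOIs conditional
#' on the frame state at fixation onset; saccades are linear ramps; isotropic
#' Gaussian noise is added per sample; short invalid runs approximate the
#' missing-data target. The trailing part of the video that cannot hold one
#' more complete fixation is marked invalid (the infant looks away), so no
#' duration-censored fixation enters the stream.
#'
#' @param subject_mean_fd_ms Subject's latent mean fixation duration (ms),
#'   strictly inside the truncation bounds.
#' @param schedule A [scene_schedule()].
#' @param gp A [gaze_gen_params()].
#' @param subject_id Identifier.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so cohort-level seeding governs everything).
#' @return A `gaze_recording` data frame with columns `subject_id`,
#'   `video_id`, `condition`, `t_ms`, `x_px`, `y_px`, `valid`; the generating
#'   fixation events are attached as `attr(, "truth")` (onset/offset/target).
#' @export
simulate_gaze_recording <- function(subject_mean_fd_ms, schedule,
                                    gp = gaze_gen_params(),
                                    subject_id = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- gp$fd_bounds_ms[1]; b <- gp$fd_bounds_ms[2]
  mu <- solve_lnorm_mu(subject_mean_fd_ms, gp$fd_shape, a, b)
  dur <- schedule$duration_ms
  period <- 1000 / gp$sample_hz
  n_samples <- floor(dur / period)
  t_ms <- (seq_len(n_samples) - 1) * period

  # Event sequence: fixation / saccade alternation, optionally interleaved
  # with wandering-gaze segments (smooth meandering legs at sub-saccadic,
  # supra-threshold speed). The final fixation that would cross the end of
  # the video is dropped, so no duration-censored fixation enters the
  # stream; any remaining tail is wander or invalid.
  stim <- schedule$stimulus_rect
  clamp_pt <- function(p) {
    c(min(max(p[1], stim$x0 + 10), stim$x0 + stim$width - 10),
      min(max(p[2], stim$y0 + 10), stim$y0 + stim$height - 10))
  }
  wf <- gp$wander_fraction
  mean_gap <- mean(gp$saccade_gap_ms)
  ev <- list(); t_cur <- 0; cur_p <- NULL
  repeat {
    fd <- r_trunc_lnorm(1, mu, gp$fd_shape, a, b)
    pre <- list()
    t_next <- t_cur
    p_mv <- cur_p
    if (!is.null(cur_p)) {
      if (wf > 0) {
        dw <- stats::rexp(1, rate = (1 - wf) /
                            (wf * (subject_mean_fd_ms + mean_gap)))
        ctr <- rect_center(stim)
        while (dw > 1 && t_next < dur) {
          leg_dt <- min(stats::runif(1, 100, 400), dw)
          sp <- stats::runif(1, gp$wander_speed_px_s[1], gp$wander_speed_px_s[2])
          ang <- stats::runif(1, 0, 2 * pi)
          step <- sp * leg_dt / 1000
          p_new <- p_mv + step * c(cos(ang), sin(ang))
          if (!all(rect_contains(stim, p_new[1], p_new[2]))) {
            # head back toward the panel centre instead of stalling at an
            # edge (a clamped leg would look like a spurious fixation)
            dirv <- ctr - p_mv
            dirv <- dirv / max(sqrt(sum(dirv^2)), 1)
            p_new <- clamp_pt(p_mv + step * dirv)
          }
          pre[[length(pre) + 1]] <- list(type = "wander", on = t_next,
                                         off = t_next + leg_dt,
                                         p0 = p_mv, p1 = p_new)
          t_next <- t_next + leg_dt; p_mv <- p_new; dw <- dw - leg_dt
        }
      }
      gap <- stats::runif(1, gp$saccade_gap_ms[1], gp$saccade_gap_ms[2])
      pre[[length(pre) + 1]] <- list(type = "sac", on = t_next,
                                     off = t_next + gap, p0 = p_mv, p1 = NULL)
      t_next <- t_next + gap
    }
    if (t_next + fd > dur) {
      # keep trailing wander (clipped at the video end); drop the saccade
      pre <- Filter(function(e) e$type == "wander" && e$on < dur, pre)
      ev <- c(ev, pre)
      break
    }
    tg <- choose_target(schedule, t_next, gp)
    if (length(pre) > 0 && pre[[length(pre)]]$type == "sac") {
      pre[[length(pre)]]$p1 <- tg$p
    }
    ev <- c(ev, pre)
    ev[[length(ev) + 1]] <- list(type = "fix", on = t_next, off = t_next + fd,
                                 p = tg$p, actor = tg$actor, kind = tg$kind)
    t_cur <- t_next + fd
    cur_p <- tg$p
  }
  if (!any(vapply(ev, function(e) e$type == "fix", logical(1)))) {
    stop("video too short for a single fixation")
  }

  x <- rep(NA_real_, n_samples); y <- rep(NA_real_, n_samples)
  valid <- rep(FALSE, n_samples)
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    idx <- which(t_ms >= e$on & t_ms < e$off)
    if (length(idx) == 0) next
    if (e$type == "fix") {
      x[idx] <- e$p[1]; y[idx] <- e$p[2]
    } else {
      p1 <- if (!is.null(e$p1)) e$p1 else ev[[i + 1]]$p
      w <- (t_ms[idx] - e$on) / (e$off - e$on)
      x[idx] <- e$p0[1] + w * (p1[1] - e$p0[1])
      y[idx] <- e$p0[2] + w * (p1[2] - e$p0[2])
    }
    valid[idx] <- TRUE
  }
  if (gp$noise_rms_px > 0) {
    s <- gp$noise_rms_px / 2
    x <- x + stats::rnorm(n_samples, 0, s)
    y <- y + stats::rnorm(n_samples, 0, s)
  }
  # Invalid runs model blink-like tracker dropouts: short (2-8 samples) and
  # strictly interior to fixations, so the classifier's gap-merge rule can
  # repair the split and no fixation boundary is censored. The invalid tail
  # after the last complete fixation already counts toward the target.
  if (gp$missing_proportion_target > 0) {
    fix_idx <- which(vapply(ev, function(e) e$type == "fix", logical(1)))
    spans <- lapply(fix_idx, function(i) {
      idx <- which(t_ms >= ev[[i]]$on & t_ms < ev[[i]]$off)
      if (length(idx) >= 22) idx else NULL
    })
    spans <- Filter(Negate(is.null), spans)
    n_invalid <- sum(!valid)
    target_invalid <- gp$missing_proportion_target * n_samples
    misses <- 0
    while (n_invalid < target_invalid && misses < 400 && length(spans) > 0) {
      len <- sample(2:8, 1)
      sp <- spans[[sample.int(length(spans), 1)]]
      # keep 6 clean samples at each fixation edge: the outer ~2 have
      # saccade-contaminated centered/smoothed velocities and the classifier
      # needs an anchor run next to the gap
      lo <- sp[7]; hi <- sp[length(sp) - 5 - len]
      if (hi < lo) { misses <- misses + 1; next }
      st <- sample(lo:hi, 1)
      run <- st:(st + len - 1)
      # keep a 3-sample valid margin around existing dropouts so gaps stay
      # below the merge limit
      margin <- max(run[1] - 3, 1):min(run[length(run)] + 3, n_samples)
      if (any(!valid[margin])) { misses <- misses + 1; next }
      valid[run] <- FALSE
      n_invalid <- n_invalid + len
    }
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_

  fixes <- ev[vapply(ev, function(e) e$type == "fix", logical(1))]
  truth <- data.frame(
    onset_ms = vapply(fixes, function(e) e$on, 0),
    offset_ms = vapply(fixes, function(e) e$off, 0),
    x = vapply(fixes, function(e) e$p[1], 0),
    y = vapply(fixes, function(e) e$p[2], 0),
    actor = vapply(fixes, function(e) e$actor, 0),
    kind = vapply(fixes, function(e) e$kind, "")
  )
  rec <- data.frame(subject_id = subject_id, video_id = schedule$video_id,
                    condition = schedule$condition, t_ms = t_ms,
                    x_px = x, y_px = y, valid = as.integer(valid))
  attr(rec, "truth") <- truth
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

#' Simulate a full gaze cohort
#'
#' One recording per subject x video. Subject latent mean fixation durations
#' per condition are supplied as a data frame; subjects are assigned to the
#' two fixed presentation orders alternately (the order is recorded as
#' metadata; it does not affect scoring).
#'
#' @param subject_means Data frame with columns `subject_id`,
#'   `mean_fd_naturalistic`, `mean_fd_abstract`, and optionally
#'   `wander_fraction` (a per-subject engagement trait). When the column is
#'   absent and the generator's wander fraction is positive, per-subject
#'   fractions are drawn from a Beta distribution centred on it
#'   (concentration 3, capped at 0.9), giving fixation counts the large
#'   between-subject spread seen in infant cohorts.
#' @param schedules List of [scene_schedule()]s (default [demo_schedules()]).
#' @param gp A [gaze_gen_params()].
#' @param seed Integer seed for the whole cohort.
#' @return List with `recordings` (list of `gaze_recording`) and `meta`
#'   (subject_id, order_group, wander_fraction).
#' @export
simulate_gaze_cohort <- function(subject_means, schedules = demo_schedules(),
                                 gp = gaze_gen_params(), seed = 1) {
  set.seed(seed)
  n_subj <- nrow(subject_means)
  wfrac <- if ("wander_fraction" %in% names(subject_means)) {
    subject_means$wander_fraction
  } else if (gp$wander_fraction > 0) {
    m <- gp$wander_fraction
    pmin(stats::rbeta(n_subj, 3 * m, 3 * (1 - m)), 0.9)
  } else rep(0, n_subj)
  recs <- vector("list", n_subj * length(schedules))
  k <- 0
  for (i in seq_len(n_subj)) {
    sid <- subject_means$subject_id[i]
    gp_i <- gp
    gp_i$wander_fraction <- wfrac[i]
    for (sch in schedules) {
      m <- if (sch$condition == "naturalistic") {
        subject_means$mean_fd_naturalistic[i]
      } else subject_means$mean_fd_abstract[i]
      k <- k + 1
      recs[[k]] <- simulate_gaze_recording(m, sch, gp_i, subject_id = sid)
    }
  }
  meta <- data.frame(subject_id = subject_means$subject_id,
                     order_group = rep(c("A", "B"), length.out = n_subj),
                     wander_fraction = wfrac)
  list(recordings = recs, meta = meta)
}

#' Write gaze recordings to CSV
#' @param recordings List of `gaze_recording` data frames.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_gaze_csv <- function(recordings, path) {
  df <- do.call(rbind, lapply(recordings, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read gaze recordings from CSV
#' @param path CSV path with columns subject_id, video_id, condition, t_ms,
#'   x_px, y_px, valid.
#' @return List of `gaze_recording` data frames (one per subject x video).
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$subject_id, df$video_id, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t_ms), ]
    rownames(d) <- NULL
    class(d) <- c("gaze_recording", "data.frame")
    d
  })
}
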