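#' Fixation filter configuration
#'
#' Holds the classifier and exclusion-filter settings. Duration bounds follow
#' the half-open convention `[min_dur_ms, max_dur_ms)`: fixations shorter than
#' 100 ms or at/above 2358 ms are excluded; the within-fixation RMS bound is
#' inclusive at 1.77 px. The velocity threshold is adapted per recording from
#' an initial 250 px/s by iterating mean + k*SD of sub-threshold speeds, so
#' noisier data yield more conservative thresholds.
#'
#' @param min_dur_ms,max_dur_ms Duration bounds in ms (kept iff
#'   `min <= d < max`).
#' @param max_rms Within-fixation RMS bound in px (kept iff `rms <= max_rms`).
#' @param init_threshold_px_s Starting velocity threshold (px/s).
#' @param k SD multiplier of the adaptive rule (default 6).
#' @param tol_px_s Convergence tolerance of the iteration (px/s).
#' @param floor_px_s Absolute lower clamp for the threshold; guards the
#'   zero-noise degenerate case.
#' @param merge_gap_ms Maximum gap between runs that may be merged.
#' @param merge_dist_px Maximum centroid displacement for merging (default
#'   `0.7 * max_rms * sqrt(2)`).
#' @return Object of class `"filter_config"`.
#' @export
filter_config <- function(min_dur_ms = 100, max_dur_ms = 2358, max_rms = 1.77,
                          init_threshold_px_s = 250, k = 6, tol_px_s = 1,
                          floor_px_s = 10, merge_gap_ms = 75,
                          merge_dist_px = 0.7 * max_rms * sqrt(2)) {
  stopifnot(min_dur_ms < max_dur_ms, max_rms > 0, init_threshold_px_s > 0,
            k > 0, merge_gap_ms >= 0, merge_dist_px >= 0)
  structure(as.list(environment()), class = "filter_config")
}

#' Per-sample gaze speed
#'
#' Centered finite-difference speed (px/s) over runs of consecutive valid
#' samples, smoothed with a 3-sample centered moving average. Undefined
#' (`NA`) wherever a neighbouring sample is invalid or missing, so speeds
#' never bridge blink gaps.
#'
#' @param recording A `gaze_recording` data frame.
#' @return Numeric vector of speeds aligned with the samples (`NA` where
#'   undefined). Empty-valid recordings give all-`NA`.
#' @export
sample_velocity <- function(recording) {
  n <- nrow(recording)
  v <- rep(NA_real_, n)
  if (n < 3) return(v)
  ok <- recording$valid == 1 & is.finite(recording$x_px) & is.finite(recording$y_px)
  x <- recording$x_px; y <- recording$y_px; t <- recording$t_ms
  i <- 2:(n - 1)
  def <- ok[i - 1] & ok[i] & ok[i + 1]
  dx <- x[i + 1] - x[i - 1]; dy <- y[i + 1] - y[i - 1]
  dt <- (t[i + 1] - t[i - 1]) / 1000
  v[i][def] <- (sqrt(dx^2 + dy^2) / dt)[def]
  # 3-sample centered moving average over defined neighbours
  vs <- v
  fin <- is.finite(v)
  num <- ifelse(fin, v, 0)
  cnt <- as.numeric(fin)
  ssum <- num + c(0, num[-n]) + c(num[-1], 0)
  scnt <- cnt + c(0, cnt[-n]) + c(cnt[-1], 0)
  vs[fin] <- (ssum / pmax(scnt, 1))[fin]
  vs
}

#' Adaptive velocity threshold
#'
#' Iterative data-driven threshold: starting from `init_threshold_px_s`, the
#' next threshold is `mean + k*SD` of all speeds below the current one, until
#' the change drops below `tol_px_s` (or 50 iterations). The result is
#' clamped from below by five times the sub-threshold median speed and by an
#' absolute floor, so the threshold never collapses to zero on noise-free
#' data. Adding noise shifts the sub-threshold speed distribution upward and
#' therefore never decreases the threshold in expectation.
#'
#' @param speeds Numeric speeds (px/s), `NA`s allowed.
#' @param config A [filter_config()].
#' @return Threshold in px/s. Falls back to the initial threshold (with a
#'   warning) when no speed lies below it.
#' @export
adaptive_threshold <- function(speeds, config = filter_config()) {
  sp <- speeds[is.finite(speeds)]
  if (length(sp) == 0) stop("adaptive_threshold: no defined speeds")
  t_cur <- config$init_threshold_px_s
  if (!any(sp < t_cur)) {
    warning("adaptive_threshold: no sub-threshold speeds; using initial threshold")
    return(t_cur)
  }
  for (iter in 1:50) {
    sub <- sp[sp < t_cur]
    if (length(sub) < 2) break
    t_new <- mean(sub) + config$k * stats::sd(sub)
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < config$tol_px_s) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  noise_floor <- stats::median(sp[sp < t_cur])
  if (!is.finite(noise_floor)) noise_floor <- 0
  max(t_cur, 5 * noise_floor, config$floor_px_s)
}

#' Classify fixations in a raw gaze recording
#'
#' Adaptive I-VT classification: maximal runs of consecutive valid samples
#' with speed below the adaptive threshold become candidate fixations. Run
#' edges eroded by the centered-difference/smoothing support are reclaimed
#' when their one-sided step speed toward the run is sub-threshold (saccade
#' ramp samples are not, as their steps are large). Runs separated by invalid
#' or supra-threshold gaps shorter than `merge_gap_ms` whose centroids lie
#' within `merge_dist_px` are merged, repairing fixations split by short
#' dropouts. Onsets are at the first sample time; offsets at the last sample
#' time plus one sample period, so durations count whole sample windows.
#'
#' @param recording A `gaze_recording` data frame.
#' @param config A [filter_config()].
#' @return Data frame of fixations: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `cx`, `cy`, `rms`, `n_samples` (possibly zero rows), with the threshold
#'   used attached as `attr(, "threshold")`.
#' @export
classify_fixations <- function(recording, config = filter_config()) {
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx = numeric(0),
                      cy = numeric(0), rms = numeric(0),
                      n_samples = integer(0))
  n <- nrow(recording)
  if (n == 0) return(empty)
  ok <- recording$valid == 1 & is.finite(recording$x_px) & is.finite(recording$y_px)
  v <- sample_velocity(recording)
  if (!any(is.finite(v))) return(empty)
  thr <- adaptive_threshold(v, config)
  t <- recording$t_ms; x <- recording$x_px; y <- recording$y_px
  period <- stats::median(diff(t))

  cand <- ok & is.finite(v) & v < thr
  # reclaim eroded run edges using one-sided finite differences
  step_speed <- function(i, j) {
    sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2) / ((t[j] - t[i]) / 1000)
  }
  for (pass in 1:4) {
    changed <- FALSE
    idx <- which(ok & !cand)
    for (i in idx) {
      if (i < n && cand[i + 1] && step_speed(i, i + 1) < thr) {
        cand[i] <- TRUE; changed <- TRUE
      } else if (i > 1 && cand[i - 1] && step_speed(i - 1, i) < thr) {
        cand[i] <- TRUE; changed <- TRUE
      }
    }
    if (!changed) break
  }

  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1 >= 2, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  centroid <- function(s, e) {
    i <- s:e; i <- i[cand[i]]
    c(mean(x[i]), mean(y[i]))
  }
  # transitive merge of neighbouring runs
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    gap_ms <- t[runs$start[i]] - (t[merged$end[last]] + period)
    c1 <- centroid(merged$start[last], merged$end[last])
    c2 <- centroid(runs$start[i], runs$end[i])
    if (gap_ms < config$merge_gap_ms &&
        sqrt(sum((c1 - c2)^2)) < config$merge_dist_px) {
      merged$end[last] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }

  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    sel <- (s:e)[cand[s:e]]
    cx <- mean(x[sel]); cy <- mean(y[sel])
    # RMS over adjacent valid sample pairs (never across gaps)
    p1 <- sel[-length(sel)]; p2 <- sel[-1]
    adj <- (t[p2] - t[p1]) <= 1.5 * period
    rms <- if (any(adj)) {
      sqrt(mean((x[p2] - x[p1])[adj]^2 + (y[p2] - y[p1])[adj]^2))
    } else 0
    data.frame(onset_ms = t[s], offset_ms = t[e] + period,
               duration_ms = t[e] + period - t[s], cx = cx, cy = cy,
               rms = rms, n_samples = length(sel))
  }))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Apply the duration and precision filters
#'
#' Keeps fixations with `min_dur_ms <= duration < max_dur_ms` and
#' `rms <= max_rms`; rejections are tagged `too_short`, `too_long` or
#' `too_noisy` (duration checked first). Kept and rejected rows partition the
#' input and the operation is idempotent on the kept set.
#'
#' @param fixations Data frame from [classify_fixations()].
#' @param config A [filter_config()].
#' @return The input with logical `kept` and character `reject_reason`
#'   (`NA` for kept rows) columns appended.
#' @export
apply_filters <- function(fixations, config = filter_config()) {
  if (nrow(fixations) == 0) {
    fixations$kept <- logical(0)
    fixations$reject_reason <- character(0)
    return(fixations)
  }
  d <- fixations$duration_ms
  reason <- rep(NA_character_, nrow(fixations))
  reason[d < config$min_dur_ms] <- "too_short"
  reason[is.na(reason) & d >= config$max_dur_ms] <- "too_long"
  reason[is.na(reason) & fixations$rms > config$max_rms] <- "too_noisy"
  fixations$kept <- is.na(reason)
  fixations$reject_reason <- reason
  fixations
}

#' Detect and filter fixations for a set of recordings
#'
#' Convenience wrapper: classifies and filters each recording, stamping
#' subject/video/condition identifiers.
#'
#' @param recordings List of `gaze_recording` data frames.
#' @param config A [filter_config()].
#' @return One data frame of fixations across recordings.
#' @export
detect_fixations <- function(recordings, config = filter_config()) {
  out <- lapply(recordings, function(rec) {
    fx <- apply_filters(classify_fixations(rec, config), config)
    if (nrow(fx) == 0) return(NULL)
    cbind(data.frame(subject_id = rec$subject_id[1],
                     video_id = rec$video_id[1],
                     condition = rec$condition[1]), fx)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), video_id = character(0),
                      condition = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), duration_ms = numeric(0),
                      cx = numeric(0), cy = numeric(0), rms = numeric(0),
                      n_samples = integer(0), kept = logical(0),
                      reject_reason = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-subject, per-condition fixation summary and quality metrics
#'
#' Mean fixation duration over kept fixations pooled across a condition's
#' videos, together with the quality metrics used downstream: number of kept
#' fixations, proportion of invalid samples over the condition's videos
#' (robustness), and mean within-fixation RMS (precision). Subjects with no
#' kept fixations in a condition get `NA` for the mean and RMS.
#'
#' @param recordings List of `gaze_recording` data frames.
#' @param fixations Output of [detect_fixations()].
#' @return Data frame with one row per subject x condition: `subject_id`,
#'   `condition`, `mean_fd`, `n_fix`, `prop_missing`, `mean_rms`.
#' @export
condition_summary <- function(recordings, fixations) {
  samp <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(subject_id = r$subject_id[1], condition = r$condition[1],
               n_samples = nrow(r), n_invalid = sum(r$valid == 0))
  }))
  agg_s <- stats::aggregate(cbind(n_samples, n_invalid) ~ subject_id + condition,
                            samp, sum)
  agg_s$prop_missing <- agg_s$n_invalid / agg_s$n_samples
  kept <- fixations[fixations$kept, , drop = FALSE]
  if (nrow(kept) > 0) {
    agg_f <- stats::aggregate(cbind(mean_fd = duration_ms) ~ subject_id + condition,
                              kept, mean)
    agg_r <- stats::aggregate(cbind(mean_rms = rms) ~ subject_id + condition,
                              kept, mean)
    agg_n <- stats::aggregate(cbind(n_fix = duration_ms) ~ subject_id + condition,
                              kept, length)
    out <- Reduce(function(a, b) merge(a, b, all.x = TRUE),
                  list(agg_s[, c("subject_id", "condition", "prop_missing")],
                       agg_n, agg_f, agg_r))
  } else {
    out <- agg_s[, c("subject_id", "condition", "prop_missing")]
    out$n_fix <- NA_integer_; out$mean_fd <- NA_real_; out$mean_rms <- NA_real_
  }
  out$n_fix[is.na(out$n_fix)] <- 0L
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition), ]
}
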