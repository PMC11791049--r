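#' Subject-level exclusion thresholds
#'
#' Condition-level measures are dropped when the proportion of missing gaze
#' exceeds the 95th-percentile cut (45.6% naturalistic, 47.6% abstract) or
#' the number of kept fixations falls below the 5th-percentile cut (5
#' naturalistic, 3 abstract); AOI proportions are additionally dropped when
#' exactly 0 or 1. The percentile cuts are sample-derived in the original
#' workflow; here they are fixed defaults, with optional recomputation from
#' the cohort at hand via [apply_exclusions()].
#'
#' @param max_missing Named vector of missing-data bounds per condition.
#' @param min_nfix Named vector of minimum fixation counts per condition.
#' @param exclude_degenerate_proportions Drop proportions exactly 0 or 1.
#' @return Object of class `"exclusion_config"`.
#' @export
exclusion_config <- function(max_missing = c(naturalistic = 0.456, abstract = 0.476),
                             min_nfix = c(naturalistic = 5, abstract = 3),
                             exclude_degenerate_proportions = TRUE) {
  stopifnot(all(max_missing >= 0 & max_missing <= 1), all(min_nfix >= 0))
  structure(list(max_missing = max_missing, min_nfix = min_nfix,
                 exclude_degenerate_proportions = exclude_degenerate_proportions),
            class = "exclusion_config")
}

frame_states <- function(schedule) {
  n_active <- rowSums(schedule$activity)
  c("all_inactive", "mixed", "mixed", "all_active")[n_active + 1]
}

#' Apportion fixations to video frames and AOIs
#'
#' Each fixation's dwell is split across the frames it overlaps by overlap
#' length. AOI membership is evaluated at the fixation centroid (robust to
#' sample noise); the attributed actor's activity is read per frame, so a
#' fixation straddling an activity transition contributes dwell under both
#' states.
#'
#' @param fixations Data frame with `onset_ms`, `offset_ms`, `cx`, `cy` (rows
#'   overlapping the video timeline; dwell outside it is clipped).
#' @param schedule A [scene_schedule()].
#' @return Data frame with one row per fixation x overlapped frame:
#'   `fixation` (input row), `frame` (0-based), `dwell_ms`, `actor_id`
#'   (`NA` when the centroid is outside all actor AOIs), `in_face`,
#'   `actor_active` (`NA` without an actor), `frame_state`.
#' @export
allocate_fixations <- function(fixations, schedule) {
  fp <- schedule$frame_period_ms
  on <- pmax(fixations$onset_ms, 0)
  off <- pmin(fixations$offset_ms, schedule$duration_ms)
  keep <- which(off > on)
  empty <- data.frame(fixation = integer(0), frame = integer(0),
                      dwell_ms = numeric(0), actor_id = integer(0),
                      in_face = logical(0), actor_active = logical(0),
                      frame_state = character(0))
  if (length(keep) == 0) return(empty)
  on <- on[keep]; off <- off[keep]
  f0 <- pmin(floor(on / fp), schedule$n_frames - 1)
  f1 <- pmin(floor((off - 1e-9) / fp), schedule$n_frames - 1)
  counts <- f1 - f0 + 1
  fix_idx <- rep(keep, counts)
  frame <- unlist(mapply(seq, f0, f1, SIMPLIFY = FALSE), use.names = FALSE)
  dwell <- pmin(rep(off, counts), (frame + 1) * fp) -
    pmax(rep(on, counts), frame * fp)

  actor_of <- rep(NA_integer_, nrow(fixations))
  face_of <- rep(FALSE, nrow(fixations))
  for (a in 1:3) {
    inr <- rect_contains(schedule$actor_rects[[a]], fixations$cx, fixations$cy)
    actor_of[inr] <- a
    face_of[inr] <- rect_contains(schedule$face_rects[[a]],
                                  fixations$cx, fixations$cy)[inr]
  }
  actor <- actor_of[fix_idx]
  active <- rep(NA, length(frame))
  has_actor <- !is.na(actor)
  active[has_actor] <- schedule$activity[cbind(frame[has_actor] + 1,
                                               actor[has_actor])]
  st <- frame_states(schedule)
  data.frame(fixation = fix_idx, frame = frame, dwell_ms = dwell,
             actor_id = actor, in_face = face_of[fix_idx],
             actor_active = active, frame_state = st[frame + 1])
}

#' @rdname allocate_fixations
#' @param fix Single-row fixation data frame (or list with the same fields).
#' @export
allocate_fixation <- function(fix, schedule) {
  allocate_fixations(as.data.frame(as.list(fix)[c("onset_ms", "offset_ms", "cx", "cy")]),
                     schedule)
}

#' Proportion of inactive-actor dwell spent on faces
#'
#' Summed dwell on a face AOI while the attributed actor is inactive, over
#' all dwell on inactive-actor AOIs. `NA` when no inactive-actor dwell exists
#' (a missing measure, not an error).
#'
#' @param allocations Output of [allocate_fixations()].
#' @return List with `prop` (fraction or `NA`) and `denom_ms`.
#' @export
proportion_on_face <- function(allocations) {
  base <- !is.na(allocations$actor_id) & allocations$actor_active %in% FALSE
  den <- sum(allocations$dwell_ms[base])
  if (den <= 0) return(list(prop = NA_real_, denom_ms = 0))
  num <- sum(allocations$dwell_ms[base & allocations$in_face])
  list(prop = num / den, denom_ms = den)
}

#' Proportion of mixed-frame dwell spent on active actors
#'
#' Summed dwell on an active actor's AOI during frames with at least one
#' active and one inactive actor, over all dwell (any screen location) during
#' those mixed frames. `NA` when the video yields no mixed-frame dwell.
#'
#' @param allocations Output of [allocate_fixations()].
#' @return List with `prop` (fraction or `NA`) and `denom_ms`.
#' @export
proportion_on_active <- function(allocations) {
  mixed <- allocations$frame_state == "mixed"
  den <- sum(allocations$dwell_ms[mixed])
  if (den <= 0) return(list(prop = NA_real_, denom_ms = 0))
  num <- sum(allocations$dwell_ms[mixed & !is.na(allocations$actor_id) &
                                    allocations$actor_active %in% TRUE])
  list(prop = num / den, denom_ms = den)
}

#' Subject-level measures from fixations and scene schedules
#'
#' Combines the per-condition fixation summary with the spatial allocation
#' measures. The AOI proportions are computed from the naturalistic videos
#' only, matching the analysis design (face looking is scored on inactive
#' actors of the naturalistic scenes).
#'
#' @param recordings List of `gaze_recording` data frames.
#' @param fixations Output of [detect_fixations()].
#' @param schedules Named list of [scene_schedule()]s keyed by video id.
#' @return Wide data frame, one row per subject: per-condition `mean_fd_*`,
#'   `n_fix_*`, `prop_missing_*`, `mean_rms_*`, plus `prop_face`,
#'   `prop_active`.
#' @export
subject_measures <- function(recordings, fixations, schedules) {
  summ <- condition_summary(recordings, fixations)
  wide <- stats::reshape(summ, idvar = "subject_id", timevar = "condition",
                         direction = "wide", sep = "_")
  names(wide) <- sub("^(\\w+)\\.(\\w+)$", "\\1_\\2", names(wide))
  kept <- fixations[fixations$kept & fixations$condition == "naturalistic", ]
  subjects <- unique(wide$subject_id)
  pf <- pa <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  for (sid in subjects) {
    fsub <- kept[kept$subject_id == sid, ]
    if (nrow(fsub) == 0) next
    num_f <- den_f <- num_a <- den_a <- 0
    for (vid in unique(fsub$video_id)) {
      sch <- schedules[[vid]]
      alloc <- allocate_fixations(fsub[fsub$video_id == vid, ], sch)
      f <- proportion_on_face(alloc); a <- proportion_on_active(alloc)
      if (!is.na(f$prop)) { num_f <- num_f + f$prop * f$denom_ms; den_f <- den_f + f$denom_ms }
      mixed_num <- if (!is.na(a$prop)) a$prop * a$denom_ms else 0
      if (!is.na(a$prop)) { num_a <- num_a + mixed_num; den_a <- den_a + a$denom_ms }
    }
    if (den_f > 0) pf[sid] <- num_f / den_f
    if (den_a > 0) pa[sid] <- num_a / den_a
  }
  wide$prop_face <- pf[as.character(wide$subject_id)]
  wide$prop_active <- pa[as.character(wide$subject_id)]
  rownames(wide) <- NULL
  attr(wide, "reshapeWide") <- NULL
  wide
}

#' Apply subject-level exclusion rules
#'
#' Sets condition-level measures to `NA` when missing data exceed the bound
#' or fixation counts fall short, and drops AOI proportions that are exactly
#' 0 or 1. Reasons are recorded per condition (`high_missing`, `few_fix`) and
#' per proportion (`degenerate`). With `recompute = TRUE` the thresholds are
#' re-derived from the cohort (95th percentile of missingness, 5th of
#' fixation counts) instead of the fixed defaults.
#'
#' @param measures Output of [subject_measures()].
#' @param cfg An [exclusion_config()].
#' @param recompute Recompute percentile thresholds from this cohort.
#' @return `measures` with exclusions applied and `excl_*` reason columns.
#' @export
apply_exclusions <- function(measures, cfg = exclusion_config(),
                             recompute = FALSE) {
  out <- measures
  for (cond in c("naturalistic", "abstract")) {
    pm_col <- paste0("prop_missing_", cond)
    nf_col <- paste0("n_fix_", cond)
    if (!pm_col %in% names(out)) next
    max_missing <- cfg$max_missing[[cond]]
    min_nfix <- cfg$min_nfix[[cond]]
    if (recompute) {
      max_missing <- stats::quantile(out[[pm_col]], 0.95, na.rm = TRUE, names = FALSE)
      min_nfix <- stats::quantile(out[[nf_col]], 0.05, na.rm = TRUE, names = FALSE)
    }
    bad_miss <- !is.na(out[[pm_col]]) & out[[pm_col]] > max_missing
    bad_nfix <- !is.na(out[[nf_col]]) & out[[nf_col]] < min_nfix
    reason <- rep(NA_character_, nrow(out))
    reason[bad_nfix] <- "few_fix"
    reason[bad_miss] <- "high_missing"
    excl <- bad_miss | bad_nfix
    cond_cols <- paste0(c("mean_fd_", "mean_rms_"), cond)
    for (cl in intersect(cond_cols, names(out))) out[[cl]][excl] <- NA_real_
    if (cond == "naturalistic") {
      out$prop_face[excl] <- NA_real_
      out$prop_active[excl] <- NA_real_
    }
    out[[paste0("excl_", cond)]] <- reason
  }
  if (cfg$exclude_degenerate_proportions) {
    for (cl in c("prop_face", "prop_active")) {
      if (!cl %in% names(out)) next
      deg <- !is.na(out[[cl]]) & (out[[cl]] == 0 | out[[cl]] == 1)
      out[[cl]][deg] <- NA_real_
      out[[paste0("excl_", cl)]] <- ifelse(deg, "degenerate", NA_character_)
    }
  }
  out
}
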