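#' Axis-aligned pixel rectangle
#'
#' Rectangles use 0-based pixel coordinates with the origin at the top-left of
#' the screen and y increasing downward. Membership is half-open:
#' a point (x, y) lies in the rectangle iff `x0 <= x < x0 + width` and
#' `y0 <= y < y0 + height`.
#'
#' @param x0,y0 Top-left corner (px).
#' @param width,height Extent (px); both must be strictly positive.
#' @return An object of class `"rect"` (a named list).
#' @export
rect <- function(x0, y0, width, height) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(width), is.numeric(height))
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0) {
    stop("rect: width and height must be finite and > 0")
  }
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "rect")
}

#' Test whether points fall inside a rectangle
#'
#' Vectorized over `x` and `y`; uses the half-open convention
#' \[x0, x0 + width) x \[y0, y0 + height).
#'
#' @param r A [rect()].
#' @param x,y Point coordinates (px).
#' @return Logical vector.
#' @export
rect_contains <- function(r, x, y) {
  x >= r$x0 & x < r$x0 + r$width & y >= r$y0 & y < r$y0 + r$height
}

rect_center <- function(r) {
  c(x = r$x0 + r$width / 2, y = r$y0 + r$height / 2)
}

#' Face area-of-interest rectangle for an actor
#'
#' Builds the face AOI box used for face-looking scoring: 350 x 262 px,
#' horizontally centred on the face, with the box centre raised by one third
#' of the box height (~87 px) above the face centre so forehead and face stay
#' inside. The vertical offset is configurable; `v_offset_frac = 0` centres
#' the box on the face.
#'
#' @param face_center Numeric length-2 vector `c(x, y)`, the face centre in px.
#' @param stimulus_rect The stimulus [rect()]; the face centre must lie inside.
#' @param width,height Box size in px (defaults 350 x 262).
#' @param v_offset_frac Fraction of `height` by which the box centre sits above
#'   the face centre (default 1/3).
#' @return A [rect()].
#' @export
face_rect_for_actor <- function(face_center, stimulus_rect,
                                width = 350, height = 262,
                                v_offset_frac = 1 / 3) {
  stopifnot(length(face_center) == 2, is.numeric(face_center))
  if (!all(rect_contains(stimulus_rect, face_center[1], face_center[2]))) {
    stop("face_rect_for_actor: face_center lies outside the stimulus rectangle")
  }
  cy <- face_center[2] - v_offset_frac * height
  rect(x0 = face_center[1] - width / 2, y0 = cy - height / 2,
       width = width, height = height)
}

#' Scene schedule for one stimulus video
#'
#' Describes the geometry and per-frame activity of one 21 s video: the
#' stimulus rectangle on screen, three actor AOI rectangles with their face
#' sub-rectangles, and for every frame whether each actor is active (moving)
#' or inactive. Both the gaze simulator and the AOI scorer consume this
#' object; no pixel data are involved.
#'
#' @param condition `"naturalistic"` or `"abstract"`.
#' @param video_id Identifier string.
#' @param actor_rects List of 3 [rect()]s, pairwise disjoint.
#' @param face_rects List of 3 [rect()]s, one per actor.
#' @param activity Logical matrix `n_frames x 3`; `TRUE` = active.
#' @param frame_period_ms Frame period (default 40 ms, i.e. 25 fps).
#' @param duration_ms Video duration (default 21000 ms).
#' @param stimulus_rect Stimulus [rect()] (default the 1310 x 737 px panel
#'   centred in a 1920 x 1080 screen).
#' @return An object of class `"scene_schedule"`.
#' @export
scene_schedule <- function(condition, video_id, actor_rects, face_rects,
                           activity, frame_period_ms = 40,
                           duration_ms = 21000,
                           stimulus_rect = rect(305, 171, 1310, 737)) {
  condition <- match.arg(condition, c("naturalistic", "abstract"))
  stopifnot(length(actor_rects) == 3, length(face_rects) == 3,
            is.matrix(activity), ncol(activity) == 3, is.logical(activity))
  n_frames <- nrow(activity)
  if (n_frames * frame_period_ms < duration_ms) {
    stop("scene_schedule: activity frames do not cover the video duration")
  }
  for (i in 1:2) for (j in (i + 1):3) {
    a <- actor_rects[[i]]; b <- actor_rects[[j]]
    overlap <- a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
      a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height
    if (overlap) stop("scene_schedule: actor rectangles must be disjoint")
  }
  structure(list(condition = condition, video_id = video_id,
                 duration_ms = duration_ms, frame_period_ms = frame_period_ms,
                 stimulus_rect = stimulus_rect, actor_rects = actor_rects,
                 face_rects = face_rects, activity = activity,
                 n_frames = n_frames),
            class = "scene_schedule")
}

#' Frame index at a time point
#'
#' Maps a time within the video to its (0-based) frame index:
#' `floor(t_ms / frame_period_ms)`, clipped to the last frame.
#'
#' @param schedule A [scene_schedule()].
#' @param t_ms Time in ms; must satisfy `0 <= t_ms < duration_ms`. Vectorized.
#' @return Integer frame indices.
#' @export
frame_index_at <- function(schedule, t_ms) {
  if (any(t_ms < 0 | t_ms >= schedule$duration_ms)) {
    stop("frame_index_at: t_ms outside [0, duration_ms)")
  }
  pmin(floor(t_ms / schedule$frame_period_ms), schedule$n_frames - 1)
}

#' Global activity state of a frame
#'
#' A frame is `"all_inactive"` when no actor moves, `"all_active"` when all
#' three do, and `"mixed"` when at least one active and one inactive actor
#' are present.
#'
#' @param schedule A [scene_schedule()].
#' @param frame 0-based frame index (vectorized).
#' @return Character vector in `{"all_inactive", "mixed", "all_active"}`.
#' @export
global_frame_state <- function(schedule, frame) {
  if (any(frame < 0 | frame >= schedule$n_frames)) {
    stop("global_frame_state: frame index out of range")
  }
  n_active <- rowSums(schedule$activity[frame + 1, , drop = FALSE])
  c("all_inactive", "mixed", "mixed", "all_active")[n_active + 1]
}

#' Build a demonstration scene schedule
#'
#' Three side-by-side actors (400 x 600 px AOIs) inside the stimulus panel,
#' each with a 350 x 262 px face box. Activity alternates through segments of
#' all-inactive, one-active, two-active and all-active states so that every
#' global frame state occurs; the phase is rotated per video so the three
#' videos of a condition differ. Abstract videos share the geometry and
#' dynamics of their naturalistic counterparts (scrambling preserves both).
#'
#' @param condition `"naturalistic"` or `"abstract"`.
#' @param video_id Video number 1-3 (also sets the activity phase).
#' @param frame_period_ms Frame period in ms (default 40).
#' @return A [scene_schedule()].
#' @export
demo_schedule <- function(condition = "naturalistic", video_id = 1,
                          frame_period_ms = 40) {
  stim <- rect(305, 171, 1310, 737)
  actor_x0 <- c(325, 760, 1195)
  actor_rects <- lapply(actor_x0, function(x0) rect(x0, 200, 400, 600))
  face_rects <- lapply(actor_x0, function(x0) {
    face_rect_for_actor(c(x0 + 200, 450), stim)
  })
  n_frames <- ceiling(21000 / frame_period_ms)
  # 3 s segments cycling: none / one / two / all active, actor roles rotating
  seg_len <- ceiling(3000 / frame_period_ms)
  patterns <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                   c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                   c(FALSE, TRUE, TRUE), c(FALSE, FALSE, TRUE),
                   c(FALSE, TRUE, FALSE))
  activity <- matrix(FALSE, n_frames, 3)
  for (f in seq_len(n_frames)) {
    seg <- ((f - 1) %/% seg_len + (video_id - 1)) %% length(patterns) + 1
    activity[f, ] <- patterns[[seg]]
  }
  scene_schedule(condition, sprintf("%s_%d", substr(condition, 1, 3), video_id),
                 actor_rects, face_rects, activity,
                 frame_period_ms = frame_period_ms)
}

#' The six demonstration videos (3 naturalistic + 3 abstract)
#' @return Named list of [scene_schedule()]s keyed by video id.
#' @export
demo_schedules <- function() {
  out <- list()
  for (cond in c("naturalistic", "abstract")) {
    for (v in 1:3) {
      s <- demo_schedule(cond, v)
      out[[s$video_id]] <- s
    }
  }
  out
}

rect_to_list <- function(r) unclass(r)

#' Write / read a scene schedule as JSON
#'
#' Activity is stored run-length encoded per actor as
#' `[start_frame, end_frame, active]` triples (0-based, end exclusive).
#'
#' @param schedule A [scene_schedule()].
#' @param path File path.
#' @return `read_schedule_json` returns a [scene_schedule()];
#'   `write_schedule_json` returns `path` invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  rle_actor <- function(col) {
    r <- rle(schedule$activity[, col])
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    data.frame(start_frame = starts, end_frame = ends, active = r$values)
  }
  doc <- list(
    condition = schedule$condition, video_id = schedule$video_id,
    duration_ms = schedule$duration_ms,
    frame_period_ms = schedule$frame_period_ms,
    stimulus_rect = rect_to_list(schedule$stimulus_rect),
    actors = lapply(1:3, function(i) list(
      rect = rect_to_list(schedule$actor_rects[[i]]),
      face_rect = rect_to_list(schedule$face_rects[[i]]),
      activity = rle_actor(i)
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_rect <- function(l) rect(l$x0, l$y0, l$width, l$height)
  n_frames <- max(vapply(doc$actors[[1]]$activity,
                         function(r) r$end_frame, numeric(1)))
  activity <- matrix(FALSE, n_frames, 3)
  for (i in 1:3) {
    for (run in doc$actors[[i]]$activity) {
      if (isTRUE(run$active)) {
        activity[(run$start_frame + 1):run$end_frame, i] <- TRUE
      }
    }
  }
  scene_schedule(doc$condition, doc$video_id,
                 lapply(doc$actors, function(a) as_rect(a$rect)),
                 lapply(doc$actors, function(a) as_rect(a$face_rect)),
                 activity, frame_period_ms = doc$frame_period_ms,
                 duration_ms = doc$duration_ms,
                 stimulus_rect = as_rect(doc$stimulus_rect))
}
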