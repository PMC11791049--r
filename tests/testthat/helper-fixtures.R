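# Shared fixtures, built in code.

PERIOD_MS <- 1000 / 120

# A gaze recording from explicit sample positions (constant sampling rate).
make_recording <- function(x, y, valid = rep(1L, length(x)),
                           subject_id = "S1", video_id = "nat_1",
                           condition = "naturalistic") {
  n <- length(x)
  rec <- data.frame(subject_id = subject_id, video_id = video_id,
                    condition = condition,
                    t_ms = (seq_len(n) - 1) * PERIOD_MS,
                    x_px = x, y_px = y, valid = as.integer(valid))
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

# Stationary dwell samples at (x0, y0) for a given duration.
dwell_samples <- function(duration_ms, x0, y0) {
  n <- round(duration_ms / PERIOD_MS)
  list(x = rep(x0, n), y = rep(y0, n))
}

# Linear saccade ramp between two points over `duration_ms`.
ramp_samples <- function(duration_ms, from, to) {
  n <- max(round(duration_ms / PERIOD_MS), 1)
  w <- seq_len(n) / (n + 1)
  list(x = from[1] + w * (to[1] - from[1]),
       y = from[2] + w * (to[2] - from[2]))
}

# dwell / saccade / dwell recording used by several classifier tests
two_dwell_recording <- function(d1 = 500, d2 = 500, gap = 50,
                                p1 = c(600, 400), p2 = c(900, 400)) {
  a <- dwell_samples(d1, p1[1], p1[2])
  s <- ramp_samples(gap, p1, p2)
  b <- dwell_samples(d2, p2[1], p2[2])
  make_recording(c(a$x, s$x, b$x), c(a$y, s$y, b$y))
}

# Small schedule with controllable activity for AOI arithmetic tests:
# 3 actors, 40 ms frames, 21 s.
fixed_activity_schedule <- function(active_matrix = NULL) {
  n_frames <- 525
  if (is.null(active_matrix)) {
    active_matrix <- matrix(FALSE, n_frames, 3)
    active_matrix[201:350, 1] <- TRUE          # mixed frames
    active_matrix[351:400, ] <- TRUE           # all active
  }
  stim <- rect(305, 171, 1310, 737)
  actor_rects <- lapply(c(325, 760, 1195), function(x0) rect(x0, 200, 400, 600))
  face_rects <- lapply(c(325, 760, 1195), function(x0) {
    face_rect_for_actor(c(x0 + 200, 450), stim)
  })
  scene_schedule("naturalistic", "fx_1", actor_rects, face_rects,
                 active_matrix, frame_period_ms = 40)
}

# Independent dense multivariate-normal deviance oracle: per-pair, no
# sufficient-statistic grouping (used to cross-check the FIML implementation).
dense_neg2ll_oracle <- function(mean_vec, sigma_mz, sigma_dz, pairs, traits) {
  cols <- c(paste0(traits, "_t1"), paste0(traits, "_t2"))
  Y <- as.matrix(pairs[, cols])
  total <- 0
  for (i in seq_len(nrow(Y))) {
    o <- !is.na(Y[i, ])
    if (!any(o)) next
    sigma <- if (pairs$zygosity[i] == "MZ") sigma_mz else sigma_dz
    S <- sigma[o, o, drop = FALSE]
    r <- Y[i, o] - mean_vec[o]
    total <- total + sum(o) * log(2 * pi) +
      determinant(S, logarithm = TRUE)$modulus[1] +
      drop(t(r) %*% solve(S, r))
  }
  total
}

ae_params <- function(A, means = 0, sds = 1) {
  cholesky_params(a = sqrt(A), e = sqrt(1 - A), means = means, sds = sds)
}

bivariate_ae_params <- function(A11 = 0.25, A22 = 0.30, A12 = 0.17,
                                E12 = 0.16) {
  Amat <- matrix(c(A11, A12, A12, A22), 2)
  Emat <- matrix(c(1 - A11, E12, E12, 1 - A22), 2)
  cholesky_params(a = t(chol(Amat)), e = t(chol(Emat)))
}
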