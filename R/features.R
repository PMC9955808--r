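# Catch detection and per-stretch feature extraction.
#
# The catch is the jerk-like instant of maximum deceleration of the elbow
# during a fast passive stretch; where it falls within the range of motion
# is the key clinical cue for the MAS grade.

.FEATURE_NAMES <- c(
  # kinematic
  "rom", "catch_angle", "catch_angle_over_rom",
  "angle_max_semg", "angle_max_semg_over_rom",
  "angle_max_force", "angle_max_force_over_rom",
  "max_angular_velocity",
  # kinetic
  "force_catch_over_initial", "norm_force_increment_at_catch",
  "norm_avg_force", "norm_avg_force_after_catch",
  "slope_force_after_max", "slope_force_after_catch",
  # physiological (unique)
  "norm_semg_at_catch", "norm_avg_semg_after_catch",
  "norm_avg_slope_semg_after_catch")

#' Canonical names of the 17 stretch features
#'
#' Eight kinematic, six kinetic and three physiological features that are
#' unique; the force-at-catch to initial-force ratio additionally belongs to
#' the physiological group (see [feature_groups()]), giving the clinically
#' reported 8/6/4 grouping over 17 unique values.
#'
#' @return Character vector of length 17, in canonical column order.
#' @export
feature_names <- function() .FEATURE_NAMES

#' Feature grouping metadata
#'
#' Returns the kinematic / kinetic / physiological grouping. The
#' physiological group lists four features, of which
#' `force_catch_over_initial` is shared with the kinetic group (flagged in
#' the `shared` element); the vector of unique features has length 17.
#'
#' @return List with elements `kinematic` (8), `kinetic` (6),
#'   `physiological` (4) and `shared` (the duplicated feature name).
#' @export
feature_groups <- function() {
  list(kinematic = .FEATURE_NAMES[1:8],
       kinetic = .FEATURE_NAMES[9:14],
       physiological = c("force_catch_over_initial", .FEATURE_NAMES[15:17]),
       shared = "force_catch_over_initial")
}

#' Angular velocity of the elbow
#'
#' Central finite difference of the (already filtered) angle series, scaled
#' to deg/s; one-sided differences at the endpoints.
#'
#' @param angle Angle series (deg).
#' @param fs Sample rate (Hz).
#' @return Velocity series (deg/s), same length as `angle`.
#' @export
angular_velocity <- function(angle, fs = 1000) {
  n <- length(angle)
  if (n < 3L) stop("angle series too short for differentiation (need >= 3)")
  v <- numeric(n)
  v[2:(n - 1L)] <- (angle[3:n] - angle[1:(n - 2L)]) * fs / 2
  v[1L] <- (angle[2L] - angle[1L]) * fs
  v[n] <- (angle[n] - angle[n - 1L]) * fs
  v
}

#' Detect the catch within one stretch segment
#'
#' The catch is located as the sample of minimum angular acceleration
#' (maximum deceleration) within the interior of the segment; a guard band
#' of `guard_frac` of the segment length is excluded at both ends to avoid
#' endpoint differentiation artefacts. Ties break toward the earliest index.
#' An event is always returned: for non-spastic stretches (MAS 0) it is the
#' ordinary movement deceleration peak, whose force/sEMG context is still
#' informative for separating spastic from non-spastic arms.
#'
#' @param angle Segment angle series (deg).
#' @param fs Sample rate (Hz).
#' @param guard_frac Interior guard fraction at each end (default 0.05).
#' @param deriv_half_s Half-window (s) of the central differences used for
#'   the acceleration estimate. Differentiating twice at single-sample
#'   scale amplifies measurement noise by the squared sample rate; a 10 ms
#'   window keeps the catch's deceleration transient while suppressing
#'   sample-level noise.
#' @return List with `idx` (sample index within segment), `angle_at` (deg)
#'   and `time_at` (s from segment start).
#' @export
detect_catch <- function(angle, fs = 1000, guard_frac = 0.05,
                         deriv_half_s = 0.01) {
  n <- length(angle)
  if (n < ceiling(3 / guard_frac)) {
    stop("segment too short for catch detection (need >= ",
         ceiling(3 / guard_frac), " samples)")
  }
  k <- max(1L, min(as.integer(round(deriv_half_s * fs)), (n - 1L) %/% 4L))
  acc <- .central_diff(.central_diff(angle, fs, k), fs, k)
  g <- as.integer(floor(n * guard_frac))
  lo <- max(2L * k + 1L, g + 1L)
  hi <- min(n - 2L * k, n - g)
  idx <- lo + which.min(acc[lo:hi]) - 1L
  list(idx = idx, angle_at = angle[idx], time_at = (idx - 1L) / fs)
}

# central difference over a +-k sample window; edge values are carried from
# the nearest interior estimate
.central_diff <- function(x, fs, k) {
  n <- length(x)
  d <- numeric(n)
  i <- (k + 1L):(n - k)
  d[i] <- (x[i + k] - x[i - k]) * fs / (2 * k)
  d[seq_len(k)] <- d[k + 1L]
  d[(n - k + 1L):n] <- d[n - k]
  d
}

# ordinary least-squares slope of y against time (s)
.ols_slope <- function(y, fs) {
  m <- length(y)
  if (m < 2L) return(0)
  t <- (seq_len(m) - 1) / fs
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Extract the 17 stretch features from one segment
#'
#' Angles are measured as excursion from the segment-start (minimum) angle
#' so that ratio features lie in \[0, 1\] and are comparable across
#' patients. Normalised force/sEMG features are divided by the within-
#' segment maximum of the corresponding channel, making them invariant to
#' uniform channel gain. The initial force is the mean over the first
#' `f_init_frac` of the segment; "slope after" features are ordinary
#' least-squares slopes over the full post-event window.
#'
#' @param seg A `stretch_segment` (see [segment_session()]), or any list
#'   with `angle`, `force`, `semg_env` and `fs`.
#' @param fs Sample rate (Hz); defaults to `seg$fs` or 1000.
#' @param guard_frac Interior guard for [detect_catch()].
#' @param f_init_frac Fraction of the segment defining the initial-force
#'   window (default 0.05).
#' @param eps Floor applied to non-positive denominators (initial force
#'   after levelling, degenerate channel maxima), with a warning.
#' @return Named numeric vector of length 17 (see [feature_names()]).
#' @export
extract_features <- function(seg, fs = NULL, guard_frac = 0.05,
                             f_init_frac = 0.05, eps = 1e-6) {
  if (is.null(fs)) fs <- if (!is.null(seg$fs)) seg$fs else 1000
  ang <- seg$angle; frc <- seg$force; env <- seg$semg_env
  n <- length(ang)
  if (length(frc) != n || length(env) != n) {
    stop("segment channels must have equal length")
  }
  a0 <- min(ang)
  rom <- max(ang) - a0
  if (rom <= eps) {
    stop("degenerate segment: zero range of motion, ratio features undefined")
  }
  catch <- detect_catch(ang, fs = fs, guard_frac = guard_frac)
  ci <- catch$idx

  f_max <- max(frc)
  if (f_max <= 0) {
    warning("non-positive force maximum; flooring denominator at eps")
    f_max <- eps
  }
  e_max <- max(env)
  if (e_max <= 0) {
    warning("non-positive sEMG envelope maximum; flooring denominator at eps")
    e_max <- eps
  }
  n_init <- max(1L, round(f_init_frac * n))
  f_init <- mean(frc[seq_len(n_init)])
  if (f_init <= 0) {
    warning("non-positive initial force after levelling; flooring at eps")
    f_init <- eps
  }

  c(rom = rom,
    catch_angle = ang[ci] - a0,
    catch_angle_over_rom = (ang[ci] - a0) / rom,
    angle_max_semg = ang[which.max(env)] - a0,
    angle_max_semg_over_rom = (ang[which.max(env)] - a0) / rom,
    angle_max_force = ang[which.max(frc)] - a0,
    angle_max_force_over_rom = (ang[which.max(frc)] - a0) / rom,
    max_angular_velocity = max(angular_velocity(ang, fs)),
    force_catch_over_initial = frc[ci] / f_init,
    norm_force_increment_at_catch = (frc[ci] - f_init) / f_max,
    norm_avg_force = mean(frc) / f_max,
    norm_avg_force_after_catch = mean(frc[ci:n]) / f_max,
    slope_force_after_max = .ols_slope(frc[which.max(frc):n], fs),
    slope_force_after_catch = .ols_slope(frc[ci:n], fs),
    norm_semg_at_catch = env[ci] / e_max,
    norm_avg_semg_after_catch = mean(env[ci:n]) / e_max,
    norm_avg_slope_semg_after_catch = .ols_slope(env[ci:n], fs) / e_max)
}

#' Features for every stretch of one session
#'
#' Full per-session chain: [process_recording()], [segment_session()], then
#' [extract_features()] per stretch. Returns one row per stretch in the
#' canonical feature-table layout.
#'
#' @param rec A [stretch_recording()].
#' @param ... Passed to [segment_session()] (e.g. `expected_stretches`,
#'   `refine`).
#' @return data.frame with the meta columns `subject_id, trial_id,
#'   stretch_index, speed, mas_label` and the 17 features.
#' @export
session_features <- function(rec, ...) {
  proc <- process_recording(rec)
  segs <- segment_session(proc, ...)
  feats <- t(vapply(segs, extract_features, numeric(length(.FEATURE_NAMES))))
  out <- data.frame(
    subject_id = rec$subject_id, trial_id = rec$trial_id,
    stretch_index = seq_along(segs),
    speed = vapply(segs, `[[`, character(1), "speed"),
    mas_label = rec$mas_label,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Feature table for a cohort of recordings
#'
#' @param recordings List of [stretch_recording()] objects.
#' @param ... Passed to [session_features()].
#' @return Row-bound feature table across all sessions.
#' @export
cohort_features <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, session_features, ...))
}
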