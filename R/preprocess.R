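# Signal conditioning and stretch segmentation.
#
# Channel-specific cleaning chains (applied exactly once, in order):
#   angle:  resultant of the two goniometer planes -> median(5) -> mean(5)
#   force:  median(5) -> mean(5) -> fix-zero levelling (first 100 ms baseline)
#   sEMG:   zero-mean levelling -> full-wave rectification ->
#           4th-order 10 Hz low-pass Butterworth (zero phase) -> decimation
#           onto the 1000 Hz time base

# minimum sEMG length accepted by the zero-phase Butterworth stage
.SEMG_MIN_LEN <- 50L

#' Resultant elbow angle from twin-axis goniometer planes
#'
#' Combines the x- and y-plane goniometer readings into a single elbow angle
#' as the Euclidean resultant `sqrt(theta_x^2 + theta_y^2)`.
#'
#' @param angle_x,angle_y Plane angle series (deg), equal length.
#' @return Non-negative resultant angle series (deg).
#' @export
#' @examples
#' resultant_angle(3, 4)  # 5
resultant_angle <- function(angle_x, angle_y) {
  if (length(angle_x) != length(angle_y)) {
    stop("angle_x and angle_y must have equal length")
  }
  sqrt(angle_x^2 + angle_y^2)
}

.reflect_pad <- function(x, h) {
  n <- length(x)
  if (h == 0L) return(x)
  if (n < h + 1L) stop("series too short for window length ", 2L * h + 1L)
  c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
}

#' Sliding-window median filter
#'
#' Fifth-order by default, matching the angle/force cleaning chain. Edges are
#' handled by mirror reflection (without repeating the edge sample) so output
#' length equals input length.
#'
#' @param x Numeric series.
#' @param order Odd window length (samples).
#' @return Filtered series, same length as `x`.
#' @export
median_filter <- function(x, order = 5) {
  order <- as.integer(order)
  if (order < 1L || order %% 2L == 0L) stop("filter order must be odd and >= 1")
  if (order == 1L) return(as.numeric(x))
  h <- (order - 1L) %/% 2L
  padded <- .reflect_pad(as.numeric(x), h)
  out <- stats::runmed(padded, k = order, endrule = "keep")
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' Sliding-window mean filter
#'
#' @inheritParams median_filter
#' @return Filtered series, same length as `x`.
#' @export
mean_filter <- function(x, order = 5) {
  order <- as.integer(order)
  if (order < 1L || order %% 2L == 0L) stop("filter order must be odd and >= 1")
  if (order == 1L) return(as.numeric(x))
  h <- (order - 1L) %/% 2L
  padded <- .reflect_pad(as.numeric(x), h)
  out <- stats::filter(padded, rep(1 / order, order), sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' Fix-zero levelling of the force channel
#'
#' Removes the myometer's resting offset by subtracting the mean of the first
#' `baseline_s` seconds of the series (the recording is assumed to start with
#' the arm at rest, before the clinician engages).
#'
#' @param x Force series (N).
#' @param fs Sample rate (Hz).
#' @param baseline_s Baseline window duration (s); default 0.1.
#' @return Levelled series; the mean of its first baseline window is ~0.
#' @export
fix_zero_levelling <- function(x, fs = 1000, baseline_s = 0.1) {
  n0 <- max(1L, round(baseline_s * fs))
  if (length(x) < n0) {
    stop("series shorter than the ", baseline_s, " s baseline window")
  }
  x - mean(x[seq_len(n0)])
}

#' Condition the surface-EMG channel into an activity envelope
#'
#' Applies, in order: zero-mean levelling (subtract the series mean),
#' full-wave rectification (absolute value), and a 4th-order 10 Hz low-pass
#' Butterworth filter run forward-backward (zero phase, so the envelope peak
#' is not lag-shifted relative to the catch). Small negative excursions from
#' filter ringing are clipped to zero.
#'
#' @param semg Raw sEMG series (mV).
#' @param fs Sample rate (Hz); default 2000.
#' @param cutoff Low-pass cutoff (Hz); default 10.
#' @param order Butterworth order; default 4.
#' @return Non-negative envelope series, same length and rate as the input.
#' @export
semg_condition <- function(semg, fs = 2000, cutoff = 10, order = 4) {
  if (length(semg) < .SEMG_MIN_LEN) {
    stop("sEMG series too short for envelope filtering (need >= ",
         .SEMG_MIN_LEN, " samples)")
  }
  x <- abs(semg - mean(semg))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  env <- signal::filtfilt(bf, x)
  pmax(env, 0)
}

#' Align the sEMG envelope onto the low-rate time base
#'
#' Decimates the 2000 Hz envelope to 1000 Hz by keeping every second sample
#' (output sample `i` is envelope sample `2i - 1`, 1-based). The 10 Hz
#' low-pass applied beforehand acts as the anti-aliasing filter.
#'
#' @param semg_env Envelope at the high rate.
#' @param target_len Length of the low-rate channels.
#' @return Envelope series of length `target_len`.
#' @export
align_semg <- function(semg_env, target_len) {
  if (abs(length(semg_env) - 2L * target_len) > 2L) {
    stop("sEMG length ", length(semg_env),
         " does not match twice the low-rate length ", target_len)
  }
  idx <- pmin(2L * (seq_len(target_len) - 1L) + 1L, length(semg_env))
  semg_env[idx]
}

# Collapse exact-value runs; keep first/last index of each run so that
# plateau extrema can be snapped to the plateau edge facing the rise.
.local_extrema <- function(x) {
  r <- rle(x)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  v <- r$values
  m <- length(v)
  empty <- data.frame(idx_first = integer(), idx_last = integer(),
                      value = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  if (m < 3L) return(empty)
  d <- sign(diff(v))
  turn <- which(d[-1L] != d[-(m - 1L)]) + 1L
  if (!length(turn)) return(empty)
  data.frame(idx_first = first[turn], idx_last = last[turn],
             value = v[turn],
             type = ifelse(d[turn - 1L] > 0, "max", "min"),
             stringsAsFactors = FALSE)
}

# vectorised alternation repair: drop the weaker of consecutive same-type
# extrema until the min/max sequence alternates
.merge_same_type <- function(e) {
  repeat {
    m <- nrow(e)
    if (m < 2L) return(e)
    same <- which(e$type[-1L] == e$type[-m])
    if (!length(same)) return(e)
    drop <- logical(m)
    j <- 1L
    while (j < m) {
      if (!drop[j] && e$type[j + 1L] == e$type[j]) {
        keep_first <- if (e$type[j] == "max") e$value[j] >= e$value[j + 1L]
                      else e$value[j] <= e$value[j + 1L]
        drop[if (keep_first) j + 1L else j] <- TRUE
        if (!keep_first) j <- j + 1L else j <- j + 2L
      } else j <- j + 1L
    }
    e <- e[!drop, , drop = FALSE]
  }
}

.prune_extrema <- function(e, min_amp) {
  # iteratively remove the weakest adjacent extremum pair (amplitude below
  # min_amp), re-merging to keep alternation; vector representation for
  # speed (sessions yield thousands of raw noise extrema)
  idx_first <- e$idx_first; idx_last <- e$idx_last
  value <- e$value; type <- e$type
  repeat {
    m <- length(value)
    if (m < 2L) break
    amp <- abs(diff(value))
    weak <- amp < min_amp
    if (!any(weak)) break
    # removing an adjacent min/max pair keeps the sequence alternating
    j <- which(weak)[which.min(amp[weak])]
    keep <- setdiff(seq_len(m), c(j, j + 1L))
    idx_first <- idx_first[keep]; idx_last <- idx_last[keep]
    value <- value[keep]; type <- type[keep]
  }
  data.frame(idx_first = idx_first, idx_last = idx_last, value = value,
             type = type, stringsAsFactors = FALSE)
}

# noise-robust peak angular velocity: central difference over +-25 ms
.peak_velocity <- function(angle, fs, half_w = 0.025) {
  k <- max(1L, round(half_w * fs))
  n <- length(angle)
  if (n <= 2L * k) k <- max(1L, (n - 1L) %/% 2L)
  max(abs(angle[(1L + 2L * k):n] - angle[1L:(n - 2L * k)])) * fs / (2 * k)
}

# Session-level noise scale: median of the quietest quartile of block-wise
# standard deviations. Rest plateaus dominate the quiet blocks, so this is
# the post-filtering measurement noise; it is exactly zero for noise-free
# plateaus.
.noise_sigma <- function(angle, block = 100L) {
  n <- length(angle)
  if (n < 2L * block) return(0)
  nb <- n %/% block
  idx <- rep(seq_len(nb), each = block)
  sds <- vapply(split(angle[seq_len(nb * block)], idx), sd, numeric(1))
  stats::median(sort(sds)[seq_len(max(1L, nb %/% 4L))])
}

# Snap a coarse rise window to the samples where the angle leaves the
# bottom plateau / reaches the top plateau by more than 5x the session
# noise level. Exact for noise-free plateaus.
.snap_window <- function(angle, start, end, sigma) {
  seg <- angle[start:end]
  qs <- min(seg) + 5 * sigma + 1e-9
  qe <- max(seg) - 5 * sigma - 1e-9
  imax <- which.max(seg)
  cand_s <- which(seg <= qs & seq_along(seg) < imax)
  ns <- if (length(cand_s)) start + max(cand_s) - 1L else start
  cand_e <- which(seg >= qe & seq_along(seg) >= (ns - start + 1L))
  ne <- if (length(cand_e)) start + min(cand_e) - 1L else end
  if (ne <= ns) c(as.integer(start), as.integer(end))
  else c(as.integer(ns), as.integer(ne))
}

# Refine a boundary as the intersection of two local line fits: one on each
# side of the corner, excluding the corner neighbourhood itself. For a
# plateau-to-ramp corner under noise this localises far better than any
# threshold crossing, because both fits use distant leverage.
.line_intersect_refine <- function(b, angle, fs, gap_s = 0.1, span_s = 0.35) {
  n <- length(angle)
  gap <- round(gap_s * fs); span <- round(span_s * fs)
  l0 <- max(1L, b - gap - span); l1 <- max(1L, b - gap)
  r0 <- min(n, b + gap); r1 <- min(n, b + gap + span)
  if (l1 - l0 < 10L || r1 - r0 < 10L) return(as.integer(b))
  fit <- function(i0, i1) {
    t <- (i0:i1) / fs
    y <- angle[i0:i1]
    beta <- .ols_slope_at(t, y)
    c(intercept = mean(y) - beta * mean(t), slope = beta)
  }
  fl <- fit(l0, l1); fr <- fit(r0, r1)
  dslope <- fr["slope"] - fl["slope"]
  if (abs(dslope) < 1e-9) return(as.integer(b))
  t_star <- (fl["intercept"] - fr["intercept"]) / dslope
  b_star <- as.integer(round(t_star * fs))
  if (b_star < b - gap || b_star > b + gap) as.integer(b) else b_star
}

.ols_slope_at <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Detect stretch windows from the elbow-angle series
#'
#' Finds alternating local minima and maxima of the (already filtered)
#' angle with at least `min_prominence` degrees of amplitude and
#' `min_separation` seconds between neighbouring extrema, then pairs each
#' minimum with the following maximum: one window per rising (flexed to
#' extended) phase. Exact plateaus are snapped to the plateau edge facing
#' the rise, so noise-free boundaries land on the motion onset/offset.
#'
#' @param angle Filtered angle series (deg).
#' @param fs Sample rate (Hz).
#' @param min_prominence Minimum rise amplitude (deg) for a window.
#' @param min_separation Minimum rest time (s) between consecutive windows;
#'   of two windows closer than this, the smaller-amplitude one is dropped.
#' @param refine If `TRUE`, each boundary is re-localised by a two-segment
#'   linear change-point fit in its neighbourhood; recommended for noisy
#'   recordings where plateau noise jitters the threshold-crossing position.
#' @param smooth_s Width (s) of the extra mean smoothing used only in the
#'   coarse extremum-detection stage (noise extrema must stay well below the
#'   prominence threshold); boundary localisation always works on the
#'   full-resolution input. Set to 0 to disable.
#' @return data.frame with integer columns `start_idx`, `end_idx` (1-based,
#'   inclusive), ordered in time, non-overlapping. Zero rows if no stretch
#'   is found.
#' @export
detect_stretch_windows <- function(angle, fs = 1000, min_prominence = 10,
                                   min_separation = 0.5, refine = FALSE,
                                   smooth_s = 0.05) {
  n <- length(angle)
  empty <- data.frame(start_idx = integer(), end_idx = integer())
  if (n < 3L) return(empty)
  k <- round(smooth_s * fs)
  if (k %% 2L == 0L) k <- k + 1L
  coarse <- if (k >= 3L && n > 3L * k) mean_filter(angle, k) else angle
  pad <- (k - 1L) %/% 2L + 5L
  monotone <- function() {
    if (max(coarse) - min(coarse) >= min_prominence &&
        which.min(coarse) < which.max(coarse)) {
      return(data.frame(start_idx = which.min(coarse),
                        end_idx = which.max(coarse)))
    }
    empty
  }
  ex <- .local_extrema(coarse)
  if (nrow(ex) == 0L) return(monotone())
  e <- .merge_same_type(ex)
  e <- .prune_extrema(e, min_prominence)
  if (nrow(e) == 0L) return(monotone())
  # a rise touching a session edge has no interior extremum on that side:
  # synthesise the edge candidate from the flanking region
  if (e$type[1L] == "max") {
    region <- coarse[seq_len(e$idx_first[1L])]
    iw <- which(region == min(region))
    e <- rbind(data.frame(idx_first = min(iw), idx_last = max(iw),
                          value = min(region), type = "min",
                          stringsAsFactors = FALSE), e)
  }
  if (e$type[nrow(e)] == "min") {
    region <- coarse[e$idx_last[nrow(e)]:n]
    iw <- which(region == max(region)) + e$idx_last[nrow(e)] - 1L
    e <- rbind(e, data.frame(idx_first = min(iw), idx_last = max(iw),
                             value = max(region), type = "max",
                             stringsAsFactors = FALSE))
  }
  if (nrow(e) < 2L) return(empty)
  is_rise <- e$type[-nrow(e)] == "min" & e$type[-1L] == "max" &
    (e$value[-1L] - e$value[-nrow(e)]) >= min_prominence
  if (!any(is_rise)) return(empty)
  i <- which(is_rise)
  win <- data.frame(start_idx = e$idx_last[i], end_idx = e$idx_first[i + 1L])
  win <- win[win$end_idx > win$start_idx, , drop = FALSE]
  # snap each boundary to where the full-resolution angle departs from its
  # plateau beyond the session noise level (exact on noise-free plateaus;
  # removes coarse-smoothing shift and plateau-noise jitter). The search
  # region is padded by the coarse smoothing half-width.
  if (nrow(win)) {
    sigma <- .noise_sigma(angle)
    snapped <- t(vapply(seq_len(nrow(win)), function(j) {
      .snap_window(angle, max(1L, win$start_idx[j] - pad),
                   min(n, win$end_idx[j] + pad), sigma)
    }, integer(2)))
    win$start_idx <- snapped[, 1L]
    win$end_idx <- snapped[, 2L]
  }
  # enforce a minimum rest between consecutive windows: of two windows
  # closer than min_separation, keep the larger rise
  if (nrow(win) > 1L) {
    amp <- angle[win$end_idx] - angle[win$start_idx]
    keep <- rep(TRUE, nrow(win))
    last <- 1L
    for (j in 2L:nrow(win)) {
      if (win$start_idx[j] - win$end_idx[last] < min_separation * fs) {
        if (amp[j] > amp[last]) keep[last] <- FALSE else keep[j] <- FALSE
        if (keep[j]) last <- j
      } else last <- j
    }
    win <- win[keep, , drop = FALSE]
  }
  if (refine && nrow(win)) {
    win$start_idx <- vapply(win$start_idx, .line_intersect_refine,
                            integer(1), angle = angle, fs = fs)
    win$end_idx <- vapply(win$end_idx, .line_intersect_refine,
                          integer(1), angle = angle, fs = fs)
    win <- win[win$end_idx > win$start_idx, , drop = FALSE]
  }
  rownames(win) <- NULL
  win
}

#' Segment a processed session into its six stretches
#'
#' Applies [detect_stretch_windows()] and returns one `stretch_segment` per
#' expected stretch: the first half tagged `"slow"`, the second half
#' `"fast"`, matching the assessment protocol (three slow stretches followed
#' by three fast). Surplus low-amplitude windows (artefacts) are pruned by
#' rise-amplitude ranking; too few windows is an error. As a sanity check,
#' the peak angular velocity of every fast segment should exceed that of
#' every slow segment; a warning is issued otherwise.
#'
#' The prominence threshold adapts downwards to half the session's angular
#' range so that severely limited-ROM sessions (MAS 4, ROM < 10 deg) still
#' segment; set `adaptive_prominence = FALSE` for a hard threshold.
#'
#' @param proc A `processed_session` from [process_recording()].
#' @param expected_stretches Number of stretches in the protocol (6).
#' @param min_prominence,min_separation,refine Passed to
#'   [detect_stretch_windows()].
#' @param adaptive_prominence Lower the prominence floor for low-ROM sessions.
#' @return List of `stretch_segment` objects, each with fields `start_idx`,
#'   `end_idx`, `speed`, `time`, `angle`, `force`, `semg_env`, `rom`.
#' @export
segment_session <- function(proc, expected_stretches = 6, min_prominence = 10,
                            min_separation = 0.5, refine = FALSE,
                            adaptive_prominence = TRUE) {
  prom <- min_prominence
  if (adaptive_prominence) {
    prom <- min(prom, 0.35 * (max(proc$angle) - min(proc$angle)))
  }
  win <- detect_stretch_windows(proc$angle, fs = proc$fs,
                                min_prominence = prom,
                                min_separation = min_separation,
                                refine = refine)
  if (nrow(win) < expected_stretches) {
    stop("segmentation error: found ", nrow(win), " of ",
         expected_stretches, " stretch windows")
  }
  if (nrow(win) > expected_stretches) {
    amp <- proc$angle[win$end_idx] - proc$angle[win$start_idx]
    keep <- order(amp, decreasing = TRUE)[seq_len(expected_stretches)]
    win <- win[sort(keep), , drop = FALSE]
  }
  n_slow <- expected_stretches %/% 2L
  segs <- lapply(seq_len(nrow(win)), function(i) {
    idx <- win$start_idx[i]:win$end_idx[i]
    ang <- proc$angle[idx]
    structure(list(
      start_idx = win$start_idx[i], end_idx = win$end_idx[i],
      speed = if (i <= n_slow) "slow" else "fast",
      time = proc$time[idx], angle = ang, force = proc$force[idx],
      semg_env = proc$semg_env[idx], rom = max(ang) - min(ang),
      fs = proc$fs), class = "stretch_segment")
  })
  # robust peak velocity (50 ms central difference) so the sanity check is
  # not dominated by sample-level differentiation noise
  peak_v <- vapply(segs, function(s) .peak_velocity(s$angle, s$fs), numeric(1))
  slow_i <- seq_len(n_slow)
  if (min(peak_v[-slow_i]) <= max(peak_v[slow_i])) {
    warning("speed-tag sanity check: some fast stretch is no faster than ",
            "the slowest slow stretch; protocol order may not hold")
  }
  segs
}

#' Run the full conditioning chain on a raw recording
#'
#' Produces a `processed_session` with all channels cleaned and aligned on
#' the common low-rate time base: resultant filtered angle, filtered and
#' zero-levelled force, and the decimated sEMG envelope.
#'
#' @param rec A [stretch_recording()].
#' @param filter_order Median/mean window length (samples).
#' @param baseline_s Fix-zero levelling baseline duration (s).
#' @param semg_cutoff sEMG envelope low-pass cutoff (Hz).
#' @return Object of class `processed_session` with fields `time`, `angle`,
#'   `force`, `semg_env`, `fs`.
#' @export
process_recording <- function(rec, filter_order = 5, baseline_s = 0.1,
                              semg_cutoff = 10) {
  validate_recording(rec)
  ang <- resultant_angle(rec$angle_x, rec$angle_y)
  ang <- mean_filter(median_filter(ang, filter_order), filter_order)
  frc <- mean_filter(median_filter(rec$force, filter_order), filter_order)
  frc <- fix_zero_levelling(frc, fs = rec$fs_lo, baseline_s = baseline_s)
  env <- semg_condition(rec$semg, fs = rec$fs_hi, cutoff = semg_cutoff)
  env <- align_semg(env, length(ang))
  structure(list(time = rec$time_lo, angle = ang, force = frc,
                 semg_env = env, fs = rec$fs_lo),
            class = "processed_session")
}
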