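# Event-detection chain: point-of-gaze -> visual angle -> Savitzky-Golay
# kinematics -> blinks (zero pupil) -> adaptive velocity-threshold saccades
# -> fixations as the complement.

#' Detector configuration
#'
#' All constants of the event-detection chain. The saccade detector uses an
#' iterative data-driven peak threshold (Nystrom-Holmqvist style): starting
#' from `pt_init_dps`, the threshold is repeatedly set to
#' `mean + pt_k * SD` of the velocity samples strictly below the current
#' threshold until it moves by less than `pt_tol_dps`. Saccade onsets and
#' offsets are refined to the nearest local minimum of the raw (central
#' difference) velocity below the onset threshold (`mean + onset_k * SD` of
#' the sub-threshold samples); refining on the raw rather than the smoothed
#' velocity avoids the half-window onset bias that Savitzky-Golay smoothing
#' would otherwise introduce.
#'
#' @param sg_window Savitzky-Golay window, samples (odd).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param pt_init_dps initial peak threshold, deg/s.
#' @param pt_k,onset_k SD multipliers for the peak and onset thresholds.
#' @param pt_tol_dps convergence tolerance of the threshold iteration, deg/s.
#' @param pt_floor_dps lower bound on the peak threshold (guards the
#'   degenerate noiseless case), deg/s.
#' @param onset_floor_dps lower bound on the onset threshold, deg/s.
#' @param ramp_guard_s sub-threshold samples within this distance of an
#'   above-threshold sample are excluded from the threshold statistics.
#' @param min_saccade_s,min_fixation_s,min_blink_s minimum event durations, s.
#' @param blink_margin_samples padding around zero-pupil runs (partial
#'   occlusion guard); set 0 for exact-arithmetic tests.
#' @param pupil_cutoff_hz,pupil_filter_order zero-phase Butterworth low-pass
#'   applied to the interpolated pupil series.
#' @param event_sg_window shorter Savitzky-Golay window used only for
#'   per-event peak velocity/acceleration metrology: the 19-sample
#'   detection filter attenuates the peak of a 30-50 ms saccade velocity
#'   pulse by almost half, which would bias the main-sequence slope.
#' @param min_valid_samples minimum usable velocity samples for the
#'   threshold iteration.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(sg_window = 19L, sg_order = 2L,
                            pt_init_dps = 100, pt_k = 6, onset_k = 3,
                            pt_tol_dps = 1, pt_floor_dps = 10,
                            onset_floor_dps = 2, ramp_guard_s = 0.05,
                            min_saccade_s = 0.010, min_fixation_s = 0.040,
                            min_blink_s = 0.010, blink_margin_samples = 2L,
                            pupil_cutoff_hz = 4, pupil_filter_order = 3L,
                            event_sg_window = 7L,
                            min_valid_samples = 50L) {
  p <- as.list(environment())
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || v < 0, TRUE)]
  if (length(bad))
    abort(sprintf("detector parameter(s) must be numeric >= 0: %s",
                  paste(bad, collapse = ", ")), "config_error")
  structure(p, class = "detector_params")
}

# Angle (deg) subtended at the eye between two on-screen points, exact
# trigonometric form: atan2(|v1 x v2|, v1.v2) for the 3-D eye->point vectors.
gaze_angle_deg <- function(x1, y1, x2, y2, distance_cm) {
  d <- distance_cm
  dot <- x1 * x2 + y1 * y2 + d * d
  cx <- y1 * d - d * y2
  cy <- d * x2 - x1 * d
  cz <- x1 * y2 - y1 * x2
  atan2(sqrt(cx^2 + cy^2 + cz^2), dot) * 180 / pi
}

#' Convert point-of-gaze to an inter-sample visual-angle series
#'
#' Per-sample angular step = exact angle subtended at the eye between
#' consecutive gaze points (no small-angle shortcut); `theta_deg` is its
#' cumulative sum, the scalar gaze path in degrees.
#'
#' @param recording a [gaze_recording()].
#' @return object of class `angle_series` with fields `time_s`, `step_deg`
#'   (first element 0), `theta_deg`, `fs`, and the recording geometry.
#' @export
point_of_gaze_to_angles <- function(recording) {
  g <- recording$geometry
  if (!is.numeric(g$distance_cm) || g$distance_cm <= 0)
    abort("viewing distance must be positive", "config_error")
  n <- length(recording$time_s)
  x <- recording$gaze_x_cm; y <- recording$gaze_y_cm
  step <- c(0, gaze_angle_deg(x[-n], y[-n], x[-1], y[-1], g$distance_cm))
  fs <- 1 / median(diff(recording$time_s))
  structure(list(time_s = recording$time_s, step_deg = step,
                 theta_deg = cumsum(step), fs = fs, geometry = g),
            class = "angle_series")
}

#' Angular velocity and acceleration by Savitzky-Golay differentiation
#'
#' Smoothed first and second derivatives of the cumulative visual-angle
#' series, scaled by the sampling rate. Half-window edge samples are `NA`.
#' Also carries the raw one-sided step velocity (step assigned to its
#' right endpoint) used for onset/offset refinement.
#'
#' @param angles an [point_of_gaze_to_angles()] result.
#' @param window window length in samples (odd), default 19.
#' @param order polynomial order, default 2.
#' @param event_window shorter window for per-event peak metrology.
#' @return object of class `kinematics_series` with `velocity_dps`,
#'   `acceleration_dps2`, `raw_velocity_dps`, `time_s`, `fs`, `half_window`.
#' @export
angular_kinematics <- function(angles, window = 19L, order = 2L,
                               event_window = 7L) {
  n <- length(angles$theta_deg)
  if (n < window)
    abort(sprintf("series length %d < required window %d", n, window),
          "length_error")
  fs <- angles$fs
  th <- angles$theta_deg
  vel <- sg_apply(th, sg_coefficients(window, order, 1L)) * fs
  acc <- sg_apply(th, sg_coefficients(window, order, 2L)) * fs^2
  raw <- c(NA_real_, diff(th) * fs)   # one-sided step velocity
  ev_vel <- sg_apply(th, sg_coefficients(event_window, order, 1L)) * fs
  ev_acc <- sg_apply(th, sg_coefficients(event_window, order, 2L)) * fs^2
  structure(list(time_s = angles$time_s, velocity_dps = vel,
                 acceleration_dps2 = acc, raw_velocity_dps = raw,
                 event_velocity_dps = ev_vel,
                 event_acceleration_dps2 = ev_acc,
                 fs = fs, half_window = (window - 1L) %/% 2L),
            class = "kinematics_series")
}

# onset/offset convention: events are half-open [onset_s, offset_s) covering
# their sample range [onset_idx, offset_idx]; offset_s is the next sample's
# timestamp (or last time + 1/fs at the record end).
run_times <- function(runs, time_s, fs) {
  n <- length(time_s)
  onset <- time_s[runs$start]
  offset <- ifelse(runs$end < n, time_s[runs$end + 1L], time_s[n] + 1 / fs)
  data.frame(onset_s = onset, offset_s = offset,
             onset_idx = runs$start, offset_idx = runs$end,
             duration_s = offset - onset)
}

#' Detect blinks from zero-valued pupil samples
#'
#' Maximal runs of `pupil_mm == 0` are extended by `margin_samples` on both
#' sides (partial-occlusion guard), merged when they meet after extension,
#' and kept as blinks when at least `min_duration_s` long. Shorter runs are
#' returned via the `"invalid_runs"` attribute so they can be excluded from
#' fixations rather than silently absorbed.
#'
#' @param recording a [gaze_recording()].
#' @param min_duration_s minimum blink duration, s.
#' @param margin_samples extension on each side, samples.
#' @return data.frame of blink events (`kind`, `onset_s`, `offset_s`,
#'   `onset_idx`, `offset_idx`, `duration_s`, `partial`).
#' @export
detect_blinks <- function(recording, min_duration_s = 0.010,
                          margin_samples = 2L) {
  n <- length(recording$pupil_mm)
  fs <- 1 / median(diff(recording$time_s))
  zero <- recording$pupil_mm == 0
  if (!any(zero)) {
    ev <- empty_events()
    attr(ev, "invalid_runs") <- data.frame(start = integer(0),
                                           end = integer(0))
    return(ev)
  }
  runs <- logical_runs(zero)
  runs$start <- pmax(1L, runs$start - margin_samples)
  runs$end <- pmin(n, runs$end + margin_samples)
  runs <- merge_runs(runs)
  tm <- run_times(runs, recording$time_s, fs)
  keep <- tm$duration_s >= min_duration_s - 1e-12
  ev <- data.frame(kind = rep("blink", sum(keep)),
                   tm[keep, , drop = FALSE],
                   partial = runs$start[keep] == 1L | runs$end[keep] == n)
  rownames(ev) <- NULL
  attr(ev, "invalid_runs") <- runs[!keep, , drop = FALSE]
  ev
}

empty_events <- function() {
  data.frame(kind = character(0), onset_s = numeric(0), offset_s = numeric(0),
             onset_idx = integer(0), offset_idx = integer(0),
             duration_s = numeric(0), partial = logical(0))
}

events_mask <- function(events, n, extend = 0L) {
  m <- logical(n)
  if (NROW(events) == 0L) return(m)
  for (i in seq_len(nrow(events))) {
    a <- max(1L, events$onset_idx[i] - extend)
    b <- min(n, events$offset_idx[i] + extend)
    m[a:b] <- TRUE
  }
  m
}

#' Preprocess the pupil-diameter series
#'
#' Zero runs (blinks plus margins) are linearly interpolated from flanking
#' valid samples (record-edge blinks take the nearest valid value), then the
#' series is low-pass filtered with a zero-phase (forward-backward)
#' Butterworth filter.
#'
#' @param recording a [gaze_recording()].
#' @param blinks blink events from [detect_blinks()].
#' @param cutoff_hz low-pass corner frequency, Hz (default 4).
#' @param filter_order Butterworth order (default 3).
#' @return object of class `pupil_series`: `time_s`, `pupil_mm` (filtered,
#'   no zeros), `blink_mask`.
#' @export
preprocess_pupil <- function(recording, blinks, cutoff_hz = 4,
                             filter_order = 3L) {
  n <- length(recording$pupil_mm)
  fs <- 1 / median(diff(recording$time_s))
  mask <- events_mask(blinks, n) | recording$pupil_mm == 0
  inv <- attr(blinks, "invalid_runs")
  if (!is.null(inv) && nrow(inv))
    mask <- mask | events_mask(data.frame(onset_idx = inv$start,
                                          offset_idx = inv$end), n)
  if (all(mask)) abort("no pupil signal: every sample is a blink",
                       "signal_error")
  x <- interp_masked(recording$pupil_mm, mask)
  co <- butter_lowpass(filter_order, cutoff_hz, fs)
  y <- filtfilt_fb(co$b, co$a, x)
  structure(list(time_s = recording$time_s, pupil_mm = y, blink_mask = mask,
                 fs = fs), class = "pupil_series")
}

# Fixed-point iteration of the data-driven peak threshold
# PT <- mean + pt_k * SD over sub-threshold samples. Samples within
# `guard` samples of any above-threshold sample are excluded from the
# statistics so saccadic on/off ramps do not inflate the noise estimate
# (without this the iteration can escape to a high fixed point on
# low-noise data); `pt_floor` keeps the threshold usable when the noise
# estimate degenerates to ~0 on noiseless input.
adaptive_peak_threshold <- function(v, raw, pool, pt_init, pt_k, onset_k,
                                    pt_tol, pt_floor, onset_floor,
                                    guard = 18L, max_iter = 100L) {
  pt <- pt_init
  dilate <- function(mask) {
    if (guard < 1L) return(mask)
    f <- stats::filter(as.numeric(mask), rep(1, 2L * guard + 1L),
                       sides = 2)
    out <- !is.na(f) & f > 0
    out | mask
  }
  sub_mask <- pool
  for (i in seq_len(max_iter)) {
    above <- !is.na(v) & v >= pt
    sub_mask <- pool & !dilate(above)
    sub <- v[sub_mask]
    if (length(sub) < 2L) break
    new_pt <- max(mean(sub) + pt_k * sd(sub), pt_floor)
    if (abs(new_pt - pt) < pt_tol) {
      pt <- new_pt
      break
    }
    pt <- new_pt
  }
  # onset threshold on the raw-velocity scale of the same quiet samples
  rs <- raw[sub_mask & !is.na(raw)]
  ot <- if (length(rs) >= 2L) mean(rs) + onset_k * sd(rs) else onset_floor
  list(pt = pt, onset_threshold = max(ot, onset_floor))
}

# Walk from the peak in direction `dir` to the first raw-velocity sample
# at or below `thr` (threshold crossing); if none is found within `limit`
# steps, the index of the smallest velocity seen is returned. With the
# one-sided step velocity, the crossing sample itself is the saccade onset
# when walking backward, and the sample before it is the offset when
# walking forward.
walk_to_crossing <- function(v, from, dir, thr, limit) {
  i <- from
  n <- length(v)
  steps <- 0L
  best <- from
  while (steps < limit) {
    j <- i + dir
    if (j < 1L || j > n) break
    vi <- v[j]
    if (!is.na(vi)) {
      if (is.na(v[best]) || vi < v[best]) best <- j
      if (vi <= thr) return(j)
    }
    i <- j
    steps <- steps + 1L
  }
  best
}

#' Detect saccades with a data-driven adaptive velocity threshold
#'
#' Implements the iterative peak-threshold scheme described in
#' [detector_params()]: threshold iteration, candidate above-threshold runs,
#' onset/offset refinement to the nearest raw-velocity local minimum below
#' the onset threshold, and rejection of candidates that overlap blinks or
#' are shorter than `min_saccade_s`. Per-event amplitude (angle between
#' onset and offset gaze points), peak velocity, peak
#' acceleration/deceleration, and curvature (maximum perpendicular
#' deviation of the gaze path from the onset-offset chord, in degrees) are
#' computed when `recording` is supplied.
#'
#' @param kinematics an [angular_kinematics()] result.
#' @param blinks blink events.
#' @param params a [detector_params()].
#' @param recording the source [gaze_recording()] (for amplitude/curvature).
#' @param include_mask optional logical per-sample mask restricting the
#'   samples that inform the adaptive threshold (e.g. task cycles only).
#' @return data.frame of saccade events with kinematic columns.
#' @export
detect_saccades <- function(kinematics, blinks, params = detector_params(),
                            recording = NULL, include_mask = NULL) {
  v <- kinematics$velocity_dps
  n <- length(v)
  blink_ext <- events_mask(blinks, n, extend = kinematics$half_window)
  valid <- !is.na(v) & !blink_ext
  thr_pool <- valid
  if (!is.null(include_mask)) thr_pool <- thr_pool & include_mask
  if (sum(thr_pool) < params$min_valid_samples)
    abort(sprintf("only %d valid velocity samples (< %d required)",
                  sum(thr_pool), params$min_valid_samples), "signal_error")
  raw <- kinematics$raw_velocity_dps
  ad <- adaptive_peak_threshold(
    v, raw, thr_pool, params$pt_init_dps, params$pt_k, params$onset_k,
    params$pt_tol_dps, params$pt_floor_dps, params$onset_floor_dps,
    guard = max(1L, as.integer(round(params$ramp_guard_s *
                                       kinematics$fs))))
  vmask <- !is.na(v) & v >= ad$pt & !blink_ext
  if (!any(vmask)) {
    ev <- empty_events()
    attr(ev, "peak_threshold") <- ad$pt
    attr(ev, "onset_threshold") <- ad$onset_threshold
    return(ev)
  }
  runs <- logical_runs(vmask)
  limit <- max(1L, as.integer(round(0.15 * kinematics$fs)))  # 150 ms reach
  onset <- integer(nrow(runs)); offset <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    rng <- runs$start[i]:runs$end[i]
    peak <- rng[which.max(v[rng])]
    onset[i] <- walk_to_crossing(raw, peak, -1L, ad$onset_threshold,
                                 limit)
    off_j <- walk_to_crossing(raw, peak, +1L, ad$onset_threshold, limit)
    offset[i] <- max(off_j - 1L, peak)  # raw[j] quiet => last moving = j-1
  }
  cand <- merge_runs(data.frame(start = onset, end = offset))
  tm <- run_times(cand, kinematics$time_s, kinematics$fs)
  keep <- tm$duration_s >= params$min_saccade_s - 1e-12
  # discard candidates touching blink-contaminated samples
  if (any(keep)) {
    overlap <- vapply(which(keep), function(i)
      any(blink_ext[cand$start[i]:cand$end[i]]), TRUE)
    keep[which(keep)[overlap]] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  tm <- tm[keep, , drop = FALSE]
  ev <- data.frame(kind = rep("saccade", nrow(cand)), tm,
                   partial = cand$start == 1L | cand$end == n)
  ev$peak_vel_dps <- NA_real_; ev$peak_acc_dps2 <- NA_real_
  ev$peak_dec_dps2 <- NA_real_; ev$amplitude_deg <- NA_real_
  ev$curvature_deg <- NA_real_
  ve <- kinematics$event_velocity_dps %||% v
  a <- kinematics$event_acceleration_dps2 %||% kinematics$acceleration_dps2
  for (i in seq_len(nrow(ev))) {
    rng <- cand$start[i]:cand$end[i]
    ev$peak_vel_dps[i] <- max(ve[rng], v[rng], na.rm = TRUE)
    acc <- a[rng]
    if (any(!is.na(acc))) {
      ev$peak_acc_dps2[i] <- max(acc, na.rm = TRUE)
      ev$peak_dec_dps2[i] <- abs(min(acc, na.rm = TRUE))
    }
    if (!is.null(recording)) {
      i1 <- cand$start[i]; i2 <- cand$end[i]
      g <- recording$geometry
      ev$amplitude_deg[i] <- gaze_angle_deg(
        recording$gaze_x_cm[i1], recording$gaze_y_cm[i1],
        recording$gaze_x_cm[i2], recording$gaze_y_cm[i2], g$distance_cm)
      ev$curvature_deg[i] <- saccade_curvature_deg(
        recording$gaze_x_cm[rng], recording$gaze_y_cm[rng], g$distance_cm)
    }
  }
  rownames(ev) <- NULL
  attr(ev, "peak_threshold") <- ad$pt
  attr(ev, "onset_threshold") <- ad$onset_threshold
  ev
}

# Max perpendicular deviation (cm) of the gaze path from the onset-offset
# chord, converted to degrees of visual angle at the viewing distance.
saccade_curvature_deg <- function(x, y, distance_cm) {
  n <- length(x)
  if (n < 3L) return(0)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len < 1e-12) return(0)
  d_cm <- abs(dx * (y - y[1]) - dy * (x - x[1])) / len
  atan(max(d_cm) / distance_cm) * 180 / pi
}

#' Assemble the full event sequence
#'
#' Complement intervals of blinks and saccades become fixations; fixations
#' shorter than `min_fixation_s` are marked invalid. Every sample is
#' assigned exactly one class in blink / saccade / fixation / invalid
#' (the partition property). Fixation centers are mean gaze positions.
#'
#' @param recording a [gaze_recording()].
#' @param blinks,saccades event data.frames.
#' @param min_fixation_s minimum fixation duration, s.
#' @return object of class `event_sequence`: `events` (ordered data.frame),
#'   `sample_class` (factor), `time_s`, `fs`.
#' @export
segment_events <- function(recording, blinks, saccades,
                           min_fixation_s = 0.040) {
  n <- length(recording$time_s)
  fs <- 1 / median(diff(recording$time_s))
  bm <- events_mask(blinks, n)
  sm <- events_mask(saccades, n)
  if (any(bm & sm))
    abort("blink and saccade events overlap", "integrity_error")
  cls <- rep("fixation", n)
  cls[bm] <- "blink"; cls[sm] <- "saccade"
  inv <- attr(blinks, "invalid_runs")
  if (!is.null(inv) && nrow(inv))
    cls[events_mask(data.frame(onset_idx = inv$start, offset_idx = inv$end),
                    n)] <- "invalid"
  fix_runs <- logical_runs(cls == "fixation")
  fixations <- empty_events()
  if (nrow(fix_runs)) {
    tm <- run_times(fix_runs, recording$time_s, fs)
    ok <- tm$duration_s >= min_fixation_s - 1e-12
    for (i in which(!ok)) cls[fix_runs$start[i]:fix_runs$end[i]] <- "invalid"
    tm <- tm[ok, , drop = FALSE]
    fix_runs <- fix_runs[ok, , drop = FALSE]
    if (nrow(tm)) {
      fixations <- data.frame(kind = "fixation", tm,
                              partial = fix_runs$start == 1L |
                                fix_runs$end == n)
      fixations$center_x_cm <- vapply(seq_len(nrow(fix_runs)), function(i)
        mean(recording$gaze_x_cm[fix_runs$start[i]:fix_runs$end[i]]), 0)
      fixations$center_y_cm <- vapply(seq_len(nrow(fix_runs)), function(i)
        mean(recording$gaze_y_cm[fix_runs$start[i]:fix_runs$end[i]]), 0)
    }
  }
  events <- rbind_events(list(blinks, saccades, fixations))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events,
                 sample_class = factor(cls, levels = c("blink", "saccade",
                                                       "fixation",
                                                       "invalid")),
                 time_s = recording$time_s, fs = fs),
            class = "event_sequence")
}

rbind_events <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  lst <- lapply(lst, function(d) {
    for (cn in setdiff(cols, names(d)))
      d[[cn]] <- if (cn == "kind") character(nrow(d)) else
        rep(NA_real_, nrow(d))
    d[cols]
  })
  do.call(rbind, lst)
}

#' @export
print.event_sequence <- function(x, ...) {
  tab <- table(x$events$kind)
  cat("<event_sequence>",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      sprintf("| %d samples\n", length(x$sample_class)))
  invisible(x)
}
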