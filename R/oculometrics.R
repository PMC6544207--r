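# Segment-level oculometric features: blink, saccade, fixation/dispersion,
# pupil, and attention-dynamics families, plus the per-segment orchestrator
# that masks out KSS pauses and micro-breaks.

# Helper: mean of x, NA (missing) when empty.
mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

# complete (non-partial) events of a kind, ordered by onset
events_of <- function(events, kind, complete_only = TRUE) {
  e <- events[events$kind == kind, , drop = FALSE]
  if (complete_only && nrow(e)) e <- e[!e$partial, , drop = FALSE]
  e[order(e$onset_s), , drop = FALSE]
}

#' Blink-family oculometrics
#'
#' Computes BF (blink frequency, Hz), BD (mean blink duration, s), IBI
#' (mean inter-blink interval, gaps > `ibi_max_s` excluded), LBF/LBR (long
#' blinks > `long_blink_s`), DBF (double-blink frequency: preceding gap <
#' `dbf_max_s`), BGF/BGR (blinks accompanied by a gaze shift >
#' `gaze_shift_deg` between flanking fixation centers), TBS (mean
#' blink-offset to next-saccade-onset latency, < `tbs_max_s`), and PERCLOS
#' (100 x closed-eye samples / opened-eye samples). Inter-blink gaps are
#' measured from one blink's offset to the next blink's onset.
#'
#' @param events an [segment_events()] result.
#' @param duration_s included segment duration, s.
#' @param closed_samples,open_samples sample counts for PERCLOS.
#' @param geometry a [screen_geometry()] (for the BGF gaze-shift test).
#' @param long_blink_s,ibi_max_s,dbf_max_s,tbs_max_s,gaze_shift_deg
#'   thresholds (defaults 0.2 s, 20 s, 0.7 s, 0.7 s, 2 deg).
#' @return named list: BF, BD, IBI, LBF, LBR, DBF, BGF, BGR, TBS, PERCLOS.
#' @export
blink_metrics <- function(events, duration_s, closed_samples, open_samples,
                          geometry = screen_geometry(),
                          long_blink_s = 0.2, ibi_max_s = 20,
                          dbf_max_s = 0.7, tbs_max_s = 0.7,
                          gaze_shift_deg = 2) {
  stopifnot(duration_s > 0)
  ev <- events$events
  b <- events_of(ev, "blink")
  s <- events_of(ev, "saccade")
  f <- events_of(ev, "fixation")
  nb <- nrow(b)
  perclos <- if (open_samples > 0) 100 * closed_samples / open_samples
             else NA_real_
  out <- list(BF = nb / duration_s, BD = NA_real_, IBI = NA_real_,
              LBF = 0, LBR = NA_real_, DBF = 0, BGF = 0, BGR = NA_real_,
              TBS = NA_real_, PERCLOS = perclos)
  if (nb == 0L) return(out)
  out$BD <- mean(b$duration_s)
  long <- b$duration_s > long_blink_s
  out$LBF <- sum(long) / duration_s
  out$LBR <- sum(long) / nb
  if (nb >= 2L) {
    gaps <- b$onset_s[-1] - b$offset_s[-nb]
    out$IBI <- mean_or_na(gaps[gaps <= ibi_max_s])
    out$DBF <- sum(gaps < dbf_max_s) / duration_s
  }
  # gaze shift across a blink: angle between flanking fixation centers
  if (nrow(f) >= 1L) {
    shifts <- vapply(seq_len(nb), function(i) {
      before <- f[f$offset_s <= b$onset_s[i] + 1e-9, , drop = FALSE]
      after <- f[f$onset_s >= b$offset_s[i] - 1e-9, , drop = FALSE]
      if (!nrow(before) || !nrow(after)) return(NA_real_)
      p <- before[nrow(before), ]; q <- after[1L, ]
      gaze_angle_deg(p$center_x_cm, p$center_y_cm,
                     q$center_x_cm, q$center_y_cm, geometry$distance_cm)
    }, 0)
    n_shift <- sum(!is.na(shifts) & shifts > gaze_shift_deg)
    out$BGF <- n_shift / duration_s
    out$BGR <- n_shift / nb
  }
  if (nrow(s)) {
    lat <- vapply(seq_len(nb), function(i) {
      nxt <- s$onset_s[s$onset_s >= b$offset_s[i] - 1e-9]
      if (!length(nxt)) return(NA_real_)
      nxt[1] - b$offset_s[i]
    }, 0)
    lat <- lat[!is.na(lat) & lat < tbs_max_s]
    out$TBS <- mean_or_na(lat)
  }
  out
}

ols_slope <- function(x, y) {
  if (length(unique(x)) < 2L) return(NA_real_)
  unname(coef(lm(y ~ x))[2])
}

#' Saccade-family oculometrics
#'
#' SF (saccade frequency, Hz), event means SCD, SPV, SA, SCR, SPA, SPD,
#' ISI (mean inter-saccade interval over gaps < `isi_max_s`), and the
#' main-sequence slopes SVA (peak velocity on amplitude, 1/s) and SDA
#' (duration on amplitude, s/deg), fitted by least squares with an
#' intercept; slopes require >= 3 saccades.
#'
#' @param events an [segment_events()] result.
#' @param duration_s included segment duration, s.
#' @param isi_max_s inter-saccade interval cap (default 0.25 s).
#' @return named list: SF, SCD, SPV, SA, SCR, SPA, SPD, ISI, SVA, SDA.
#' @export
saccade_metrics <- function(events, duration_s, isi_max_s = 0.25) {
  stopifnot(duration_s > 0)
  s <- events_of(events$events, "saccade")
  ns <- nrow(s)
  out <- list(SF = ns / duration_s, SCD = NA_real_, SPV = NA_real_,
              SA = NA_real_, SCR = NA_real_, SPA = NA_real_, SPD = NA_real_,
              ISI = NA_real_, SVA = NA_real_, SDA = NA_real_)
  if (ns == 0L) return(out)
  out$SCD <- mean(s$duration_s)
  out$SPV <- mean(s$peak_vel_dps)
  out$SA <- mean(s$amplitude_deg)
  out$SCR <- mean_or_na(na.omit(s$curvature_deg))
  out$SPA <- mean_or_na(na.omit(s$peak_acc_dps2))
  out$SPD <- mean_or_na(na.omit(s$peak_dec_dps2))
  if (ns >= 2L) {
    gaps <- s$onset_s[-1] - s$offset_s[-ns]
    out$ISI <- mean_or_na(gaps[gaps < isi_max_s])
  }
  if (ns >= 3L) {
    out$SVA <- ols_slope(s$amplitude_deg, s$peak_vel_dps)
    out$SDA <- ols_slope(s$amplitude_deg, s$duration_s)
  }
  out
}

#' Fixation and gaze-dispersion oculometrics
#'
#' FF (fixation frequency, Hz), FD (mean duration, s), LFR (percentage of
#' fixations > `long_fixation_s`), and over successive fixation pairs whose
#' separating interval is at most `max_pair_gap_s` and contains a
#' connecting saccade: FF_disp (mean distance between the two centers, cm),
#' FF_dist (mean summed gaze path length over the connecting saccade, cm),
#' FF_disp_dist (mean per-pair disp/dist ratio). OD = mean distance of each
#' fixation center to the centroid of all centers, cm.
#'
#' @param events an [segment_events()] result.
#' @param recording the source [gaze_recording()] (for path lengths).
#' @param duration_s included segment duration, s.
#' @param max_pair_gap_s maximum inter-fixation gap (default 0.1 s).
#' @param long_fixation_s long-fixation threshold (default 0.9 s).
#' @return named list: FF, FD, LFR, FF_disp, FF_dist, FF_disp_dist, OD.
#' @export
fixation_metrics <- function(events, recording, duration_s,
                             max_pair_gap_s = 0.1, long_fixation_s = 0.9) {
  stopifnot(duration_s > 0)
  f <- events_of(events$events, "fixation")
  s <- events_of(events$events, "saccade")
  nf <- nrow(f)
  out <- list(FF = nf / duration_s, FD = NA_real_, LFR = NA_real_,
              FF_disp = NA_real_, FF_dist = NA_real_,
              FF_disp_dist = NA_real_, OD = NA_real_)
  if (nf == 0L) return(out)
  out$FD <- mean(f$duration_s)
  out$LFR <- 100 * mean(f$duration_s > long_fixation_s)
  cx <- mean(f$center_x_cm); cy <- mean(f$center_y_cm)
  out$OD <- mean(sqrt((f$center_x_cm - cx)^2 + (f$center_y_cm - cy)^2))
  if (nf >= 2L) {
    disp <- numeric(0); dist <- numeric(0)
    for (i in seq_len(nf - 1L)) {
      gap <- f$onset_s[i + 1L] - f$offset_s[i]
      if (gap > max_pair_gap_s) next
      conn <- s[s$onset_s >= f$offset_s[i] - 1e-9 &
                  s$offset_s <= f$onset_s[i + 1L] + 1e-9, , drop = FALSE]
      if (!nrow(conn)) next
      dsp <- sqrt((f$center_x_cm[i + 1L] - f$center_x_cm[i])^2 +
                    (f$center_y_cm[i + 1L] - f$center_y_cm[i])^2)
      rng <- conn$onset_idx[1]:conn$offset_idx[nrow(conn)]
      dx <- diff(recording$gaze_x_cm[rng]); dy <- diff(recording$gaze_y_cm[rng])
      dst <- sum(sqrt(dx^2 + dy^2))
      if (dst <= 1e-12) next
      disp <- c(disp, dsp); dist <- c(dist, dst)
    }
    if (length(disp) >= 2L) {
      out$FF_disp <- mean(disp)
      out$FF_dist <- mean(dist)
      out$FF_disp_dist <- mean(disp / dist)
    }
  }
  out
}

#' Pupil-family oculometrics
#'
#' PD (mean pupil diameter, mm), PDIR (interquartile range, linear
#' interpolation between order statistics, mm), PCV (coefficient of
#' variation), and PH: the mean resultant length of the per-sample
#' instantaneous-phase increments of the mean-removed low-passed pupil
#' signal (analytic-signal construction). PH is 1 for a perfectly regular
#' oscillation and decreases with phase jitter. Blink-mask samples are
#' excluded from PD/PDIR/PCV and from the PH increment pool.
#'
#' @param pupil a [preprocess_pupil()] result.
#' @param included_mask logical per-sample mask of included task samples
#'   (default: all).
#' @return named list: PD, PDIR, PCV, PH.
#' @export
pupil_metrics <- function(pupil, included_mask = NULL) {
  n <- length(pupil$pupil_mm)
  if (is.null(included_mask)) included_mask <- rep(TRUE, n)
  use <- included_mask & !pupil$blink_mask
  x <- pupil$pupil_mm[use]
  if (length(x) < 2L)
    abort("need >= 2 included non-blink pupil samples", "signal_error")
  out <- list(PD = mean(x),
              PDIR = unname(quantile(x, 0.75, type = 7) -
                              quantile(x, 0.25, type = 7)),
              PCV = if (mean(x) > 0) sd(x) / mean(x) else NA_real_,
              PH = NA_real_)
  if (sd(x) < 1e-12) {
    out$PCV <- 0
    return(out)   # degenerate constant signal: PH undefined
  }
  z <- analytic_signal(pupil$pupil_mm - mean(pupil$pupil_mm[included_mask]))
  phase <- Arg(z)
  dphi <- diff(phase)
  ok <- use[-1] & use[-n]
  dphi <- dphi[ok]
  if (length(dphi))
    out$PH <- Mod(mean(complex(modulus = 1, argument = dphi)))
  out
}

#' Ambient/focal attention coefficient (KPA)
#'
#' For each complete fixation followed by a saccade, the standardized
#' fixation duration minus the standardized amplitude of the following
#' saccade, averaged over pairs; z-scores are computed within the segment.
#' Positive values indicate focal viewing (long fixations, small
#' saccades), negative values ambient viewing.
#'
#' @param events an [segment_events()] result.
#' @return KPA (unitless), or `NA` with fewer than 3 pairs or zero
#'   variance in either pair member.
#' @export
attention_dynamics <- function(events) {
  f <- events_of(events$events, "fixation")
  s <- events_of(events$events, "saccade")
  if (!nrow(f) || !nrow(s)) return(NA_real_)
  dur <- numeric(0); amp <- numeric(0)
  for (i in seq_len(nrow(f))) {
    nxt <- which(s$onset_s >= f$offset_s[i] - 1e-9)
    if (!length(nxt)) next
    dur <- c(dur, f$duration_s[i])
    amp <- c(amp, s$amplitude_deg[nxt[1]])
  }
  if (length(dur) < 3L) return(NA_real_)
  if (sd(dur) < 1e-12 || sd(amp) < 1e-12 || anyNA(amp)) return(NA_real_)
  mean(scale(dur)[, 1] - scale(amp)[, 1])
}

# Half-open interval membership for sample timestamps.
in_intervals <- function(time_s, intervals) {
  m <- logical(length(time_s))
  for (i in seq_len(nrow(intervals)))
    m <- m | (time_s >= intervals$start_s[i] - 1e-9 &
                time_s < intervals$end_s[i] - 1e-9)
  m
}

segment_cycle_intervals <- function(recording, segment_index, meta) {
  cps <- meta$cycles_per_segment
  wanted <- paste0("cycle:", ((segment_index - 1L) * cps + 1L):
                     (segment_index * cps))
  ann <- recording$annotations
  iv <- ann[ann$label %in% wanted, , drop = FALSE]
  if (!nrow(iv))
    abort(sprintf("segment %d has no annotated cycles", segment_index),
          "annotation_error")
  iv
}

#' Compute the full oculometric feature set for one segment
#'
#' Runs the complete chain (visual angles, Savitzky-Golay kinematics, blink
#' detection, pupil preprocessing, adaptive-threshold saccade detection,
#' event segmentation, the five feature families) restricted to the union
#' of the segment's task-cycle intervals: samples inside KSS pauses and
#' micro-breaks never contribute to any feature. Events are counted only
#' when they lie entirely inside an included interval.
#'
#' @param recording a [gaze_recording()] with cycle annotations.
#' @param segment_index 1-based segment number.
#' @param meta a [session_meta()] (supplies `age`, `sex`,
#'   `cycles_per_segment`).
#' @param params a [detector_params()].
#' @return object of class `segment_features`: named list of the 32
#'   oculometric features plus `age` and `sex`.
#' @export
compute_segment_features <- function(recording, segment_index, meta,
                                     params = detector_params()) {
  iv <- segment_cycle_intervals(recording, segment_index, meta)
  included <- in_intervals(recording$time_s, iv)
  duration_s <- sum(iv$end_s - iv$start_s)
  blinks <- detect_blinks(recording, params$min_blink_s,
                          params$blink_margin_samples)
  feats <- tryCatch({
    pupil <- preprocess_pupil(recording, blinks, params$pupil_cutoff_hz,
                              params$pupil_filter_order)
    angles <- point_of_gaze_to_angles(recording)
    kin <- angular_kinematics(angles, params$sg_window, params$sg_order,
                              event_window = params$event_sg_window)
    saccades <- detect_saccades(kin, blinks, params, recording = recording,
                                include_mask = included)
    seq <- segment_events(recording, blinks, saccades,
                          params$min_fixation_s)
    seq_in <- restrict_events(seq, iv)
    closed <- sum(included & recording$pupil_mm == 0)
    open <- sum(included & recording$pupil_mm > 0)
    c(blink_metrics(seq_in, duration_s, closed, open,
                    geometry = recording$geometry),
      saccade_metrics(seq_in, duration_s),
      fixation_metrics(seq_in, recording, duration_s),
      pupil_metrics(pupil, included),
      list(KPA = attention_dynamics(seq_in)))
  }, signal_error = function(e) {
    warning(sprintf("segment %d: %s; features set to missing",
                    segment_index, conditionMessage(e)))
    setNames(as.list(rep(NA_real_, length(OCULOMETRIC_FEATURES))),
             OCULOMETRIC_FEATURES)
  })
  feats <- feats[OCULOMETRIC_FEATURES]
  feats$age <- meta$age
  feats$sex <- meta$sex
  structure(feats, class = "segment_features",
            segment_index = segment_index, duration_s = duration_s)
}

# Keep only events fully inside one of the included intervals.
restrict_events <- function(seq, intervals) {
  ev <- seq$events
  if (nrow(ev)) {
    inside <- vapply(seq_len(nrow(ev)), function(i)
      any(ev$onset_s[i] >= intervals$start_s - 1e-9 &
            ev$offset_s[i] <= intervals$end_s + 1e-9), TRUE)
    seq$events <- ev[inside, , drop = FALSE]
  }
  seq
}

#' Extract feature rows for every segment of a recording
#'
#' @param recording a [gaze_recording()].
#' @param meta a [session_meta()].
#' @param params a [detector_params()].
#' @return data.frame, one row per segment, columns `participant_id`,
#'   `segment_index`, the [OCULOMETRIC_FEATURES], `age`, `sex` (and `kss`
#'   when present in `meta`).
#' @export
extract_features <- function(recording, meta, params = detector_params()) {
  n_seg <- meta$cycle_count %/% meta$cycles_per_segment
  rows <- lapply(seq_len(n_seg), function(k) {
    sf <- compute_segment_features(recording, k, meta, params)
    as_feature_row(sf, meta$participant_id, k)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta$kss_by_segment))
    out$kss <- meta$kss_by_segment[seq_len(n_seg)]
  out
}

as_feature_row <- function(sf, participant_id, segment_index) {
  row <- data.frame(participant_id = participant_id,
                    segment_index = segment_index)
  for (f in OCULOMETRIC_FEATURES) row[[f]] <- sf[[f]] %||% NA_real_
  row$age <- sf$age
  row$sex <- sf$sex
  row
}
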