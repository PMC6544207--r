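# Build an event_sequence directly from an event table, for unit tests of
# the feature-family operations that do not need the detection chain.
make_event_sequence <- function(kind, onset_s, offset_s,
                                amplitude_deg = NA_real_,
                                peak_vel_dps = NA_real_,
                                duration_total_s = max(offset_s),
                                center_x_cm = NA_real_,
                                center_y_cm = 0,
                                fs = 360) {
  n <- length(kind)
  ev <- data.frame(kind = kind, onset_s = onset_s, offset_s = offset_s,
                   onset_idx = pmax(1L, as.integer(round(onset_s * fs)) +
                                      1L),
                   offset_idx = as.integer(round(offset_s * fs)),
                   duration_s = offset_s - onset_s,
                   partial = FALSE,
                   amplitude_deg = rep_len(amplitude_deg, n),
                   peak_vel_dps = rep_len(peak_vel_dps, n),
                   peak_acc_dps2 = NA_real_, peak_dec_dps2 = NA_real_,
                   curvature_deg = NA_real_,
                   center_x_cm = rep_len(center_x_cm, n),
                   center_y_cm = rep_len(center_y_cm, n))
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  structure(list(events = ev, sample_class = factor(character(0)),
                 time_s = numeric(0), fs = fs),
            class = "event_sequence")
}

# flat-pupil recording with optional zero (blink) runs, cycle-annotated
make_flat_recording <- function(duration_s = 2, fs = 360, pupil = 3.5,
                                zero_runs = NULL, x = 0, y = 0,
                                n_cycles = 1L) {
  n <- as.integer(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  p <- rep(pupil, n)
  if (!is.null(zero_runs))
    for (r in zero_runs) p[r[1]:r[2]] <- 0
  cyc <- duration_s / n_cycles
  ann <- data.frame(label = paste0("cycle:", seq_len(n_cycles)),
                    start_s = cyc * (seq_len(n_cycles) - 1),
                    end_s = cyc * seq_len(n_cycles))
  gaze_recording(t, rep_len(x, n), rep_len(y, n), p, annotations = ann)
}
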