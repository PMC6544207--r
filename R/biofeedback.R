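# Session state machine: cycle/segment bookkeeping, KSS pauses, manual and
# automatic micro-break triggering, and the offline session simulator.
# Nominal phase durations: task cycle ~10 s, KSS pause 5 s, micro-break
# 25 s; a 180-cycle session spans 30.75 min (no breaks) to 34.5 min (a
# break after each of the 9 segments).

#' Initialize a biofeedback session state
#'
#' @param meta a [session_meta()] (mode, cycle count, cycles per segment).
#' @param cycle_s,pause_s,break_s nominal phase durations, seconds.
#' @return object of class `session_state`.
#' @export
session_state <- function(meta, cycle_s = 10, pause_s = 5, break_s = 25) {
  structure(list(
    meta = meta, current_cycle = 0L, mode = meta$mode,
    pending_manual_request = FALSE, awaiting_trigger = NA_integer_,
    kss_log = integer(0),
    break_log = data.frame(segment_index = integer(0),
                           trigger = character(0)),
    timeline = data.frame(phase = character(0), start_s = numeric(0),
                          duration_s = numeric(0)),
    cycle_s = cycle_s, pause_s = pause_s, break_s = break_s,
    complete = FALSE, model_consults = 0L), class = "session_state")
}

timeline_end <- function(state) {
  tl <- state$timeline
  if (!nrow(tl)) 0 else tl$start_s[nrow(tl)] + tl$duration_s[nrow(tl)]
}

append_phase <- function(state, phase, duration_s) {
  state$timeline <- rbind(state$timeline,
                          data.frame(phase = phase,
                                     start_s = timeline_end(state),
                                     duration_s = duration_s))
  state
}

#' Advance the session by one task cycle
#'
#' Appends a cycle phase; when the completed cycle closes a segment
#' (a multiple of `cycles_per_segment`), a 5-s KSS pause follows, the
#' segment is marked closed (enabling [auto_trigger()]), and a pending
#' manual break request is honored immediately after that pause.
#' Advancing past the final cycle sets `complete` (a signal, not an
#' error).
#'
#' @param state a [session_state()].
#' @return the updated state.
#' @export
advance_cycle <- function(state) {
  if (state$current_cycle >= state$meta$cycle_count) {
    state$complete <- TRUE
    return(state)
  }
  state$current_cycle <- state$current_cycle + 1L
  state <- append_phase(state, "cycle", state$cycle_s)
  if (state$current_cycle %% state$meta$cycles_per_segment == 0L) {
    seg <- state$current_cycle %/% state$meta$cycles_per_segment
    state <- append_phase(state, "kss_pause", state$pause_s)
    state$awaiting_trigger <- seg
    if (state$mode == "manual" && state$pending_manual_request) {
      state <- append_phase(state, "micro_break", state$break_s)
      state$break_log <- rbind(state$break_log,
                               data.frame(segment_index = seg,
                                          trigger = "manual"))
      state$pending_manual_request <- FALSE
    }
  }
  if (state$current_cycle >= state$meta$cycle_count) state$complete <- TRUE
  state
}

#' Request a self-triggered micro-break
#'
#' Manual mode only: sets the pending flag; repeated requests within one
#' segment collapse to a single break, scheduled immediately after the
#' earliest upcoming KSS pause.
#'
#' @param state a [session_state()].
#' @return the updated state.
#' @export
request_manual_break <- function(state) {
  if (state$mode != "manual")
    abort("manual break requests are only valid in manual mode",
          "mode_error")
  state$pending_manual_request <- TRUE
  state
}

#' Trigger a micro-break from the fatigue model
#'
#' Automatic mode only, immediately after a segment closes: classifies the
#' segment's features with [predict_segment()]; a fatigued prediction
#' appends a 25-s micro-break right after the segment's KSS pause, an
#' alert prediction appends nothing. KSS ratings never enter this
#' decision.
#'
#' @param state a [session_state()] with a just-closed segment.
#' @param features the segment's `segment_features` (or named list).
#' @param model a [train_ensemble()] model.
#' @return the updated state.
#' @export
auto_trigger <- function(state, features, model) {
  if (state$mode != "automatic")
    abort("auto_trigger is only valid in automatic mode", "mode_error")
  if (is.null(model)) abort("automatic mode requires a model",
                            "config_error")
  if (is.na(state$awaiting_trigger))
    abort("no segment is awaiting a trigger decision", "state_error")
  seg <- state$awaiting_trigger
  pred <- predict_segment(model, features)
  state$model_consults <- state$model_consults + 1L
  if (pred$label == "fatigued") {
    state <- append_phase(state, "micro_break", state$break_s)
    state$break_log <- rbind(state$break_log,
                             data.frame(segment_index = seg,
                                        trigger = "automatic"))
  }
  state$awaiting_trigger <- NA_integer_
  attr(state, "last_prediction") <- pred
  state
}

#' Simulate a complete biofeedback session offline
#'
#' Drives the state machine over all cycles. At each segment close the
#' segment's oculometric features are computed — from the recording via
#' [compute_segment_features()] (pause/break samples never included), or
#' from a [sample_participant_profile()] via the generator fast path — and,
#' in automatic mode, fed to [auto_trigger()]. Manual mode consumes a
#' scripted request trace and never consults the model. Deterministic
#' given inputs and `seed`.
#'
#' @param source a [gaze_recording()], a `synthetic_profile`, or `NULL`
#'   (manual mode without feature extraction).
#' @param meta a [session_meta()].
#' @param model a [train_ensemble()] model (required in automatic mode).
#' @param requests_at_cycles integer cycles during which a manual request
#'   occurs (manual mode).
#' @param fatigue_trajectory latent fatigue per segment for a profile
#'   source (default: linear 0 to 1).
#' @param params a [detector_params()] for recording sources.
#' @param seed integer seed.
#' @return object of class `session_log`: final `state`, `per_segment`
#'   data.frame (kss, posterior, prediction, break trigger), `timeline`,
#'   `total_s`.
#' @export
run_session <- function(source, meta, model = NULL,
                        requests_at_cycles = integer(0),
                        fatigue_trajectory = NULL,
                        params = detector_params(), seed = 1L) {
  if (meta$mode == "automatic" && is.null(model))
    abort("automatic mode requires a trained model", "config_error")
  if (meta$mode == "automatic" && length(requests_at_cycles))
    abort("manual requests are rejected in automatic mode", "mode_error")
  n_seg <- meta$cycle_count %/% meta$cycles_per_segment
  if (inherits(source, "synthetic_profile") && is.null(fatigue_trajectory))
    fatigue_trajectory <- seq(0, 1, length.out = n_seg)
  state <- session_state(meta)
  per_segment <- data.frame(segment_index = seq_len(n_seg),
                            kss = NA_integer_, posterior = NA_real_,
                            prediction = NA_character_,
                            trigger = NA_character_)
  seg_features <- vector("list", n_seg)
  for (cyc in seq_len(meta$cycle_count)) {
    if (cyc %in% requests_at_cycles)
      state <- request_manual_break(state)
    state <- advance_cycle(state)
    if (!is.na(state$awaiting_trigger)) {
      seg <- state$awaiting_trigger
      feats <- segment_features_from_source(source, seg, meta, params,
                                            fatigue_trajectory, seed)
      seg_features[[seg]] <- feats
      if (!is.null(meta$kss_by_segment))
        per_segment$kss[seg] <- meta$kss_by_segment[seg]
      state$kss_log <- c(state$kss_log, per_segment$kss[seg])
      if (meta$mode == "automatic") {
        state <- auto_trigger(state, feats, model)
        pred <- attr(state, "last_prediction")
        per_segment$posterior[seg] <- pred$posterior
        per_segment$prediction[seg] <- as.character(pred$label)
      } else {
        state$awaiting_trigger <- NA_integer_
      }
    }
  }
  bl <- state$break_log
  per_segment$trigger[match(bl$segment_index,
                            per_segment$segment_index)] <- bl$trigger
  structure(list(state = state, per_segment = per_segment,
                 features = seg_features, timeline = state$timeline,
                 break_log = bl, total_s = timeline_end(state),
                 seed = seed), class = "session_log")
}

segment_features_from_source <- function(source, seg, meta, params,
                                         trajectory, seed) {
  if (is.null(source)) return(NULL)
  if (inherits(source, "gaze_recording")) {
    feats <- tryCatch(
      compute_segment_features(source, seg, meta, params),
      annotation_error = function(e)
        abort(sprintf("recording shorter than the session: segment %d %s",
                      seg, conditionMessage(e)), "truncation_error"))
    return(feats)
  }
  if (inherits(source, "synthetic_profile")) {
    set.seed(derive_seed(seed, 5000L + seg))
    tf <- truth_features(source, trajectory[seg])
    row <- noisy_feature_row(source, tf, 200)
    feats <- as.list(row)
    feats$age <- source$age
    feats$sex <- source$sex
    return(structure(feats, class = "segment_features"))
  }
  abort("unsupported session source", "validation_error")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %d cycles, %d breaks (%s), total %.1f s (%.2f min)\n",
    x$state$current_cycle, nrow(x$break_log), x$state$mode, x$total_s,
    x$total_s / 60))
  invisible(x)
}
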