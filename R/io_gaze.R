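# File formats and validated containers for gaze recordings, session
# metadata, and segment-level feature tables.

#' Table-ordered oculometric feature mnemonics
#'
#' The canonical column order of the 32 oculometric features in a feature
#' table, followed by `age`, `sex`, `kss`, `label` on disk.
#' @export
OCULOMETRIC_FEATURES <- c(
  "BF", "BD", "BGF", "IBI", "LBF", "LBR", "DBF", "BGR", "TBS", "PERCLOS",
  "PD", "PDIR", "PCV", "PH", "FF_disp_dist", "FD", "FF", "FF_disp",
  "FF_dist", "OD", "LFR", "SVA", "SCD", "SF", "SPV", "SDA", "SCR", "SA",
  "SPD", "SPA", "ISI", "KPA")

#' Screen and viewing geometry
#'
#' Physical geometry needed to convert on-screen gaze coordinates (cm,
#' origin at screen center, right/up positive) to visual angle. Defaults
#' describe a 19-inch 5:4 display viewed from 58 cm, subtending roughly
#' 27 x 22 degrees.
#'
#' @param distance_cm viewing distance from eye to screen plane, cm.
#' @param width_cm,height_cm physical screen size, cm.
#' @return object of class `screen_geometry`.
#' @export
screen_geometry <- function(distance_cm = 58, width_cm = 27.8,
                            height_cm = 22.5) {
  if (!is.numeric(distance_cm) || distance_cm <= 0)
    abort("viewing distance must be positive", "config_error")
  structure(list(distance_cm = distance_cm, width_cm = width_cm,
                 height_cm = height_cm), class = "screen_geometry")
}

#' Construct a validated gaze recording
#'
#' A time-stamped monocular gaze/pupil sample stream with half-open
#' `[start, end)` session interval annotations (task cycles, KSS pauses,
#' micro-breaks). Pupil diameter 0 encodes a closed eye or missing pupil
#' image.
#'
#' @param time_s numeric, strictly increasing timestamps in seconds
#'   (nominal 360 Hz).
#' @param gaze_x_cm,gaze_y_cm point-of-gaze screen coordinates in cm
#'   relative to screen center.
#' @param pupil_mm pupil diameter in mm, `>= 0`; 0 = closed/missing.
#' @param geometry a [screen_geometry()].
#' @param annotations `data.frame(label, start_s, end_s)` of half-open
#'   intervals; labels are `cycle:<k>`, `kss_pause`, `micro_break`.
#' @return object of class `gaze_recording`.
#' @export
gaze_recording <- function(time_s, gaze_x_cm, gaze_y_cm, pupil_mm,
                           geometry = screen_geometry(),
                           annotations = NULL) {
  n <- length(time_s)
  if (length(gaze_x_cm) != n || length(gaze_y_cm) != n ||
      length(pupil_mm) != n)
    abort("sample columns must have equal length", "format_error")
  d <- diff(time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1L
    abort(sprintf("timestamps not strictly increasing at row %d", i),
          "integrity_error")
  }
  if (any(pupil_mm < 0))
    abort("pupil_mm must be >= 0 (0 = closed eye)", "format_error")
  if (is.null(annotations))
    annotations <- data.frame(label = character(0), start_s = numeric(0),
                              end_s = numeric(0))
  stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
  if (any(annotations$end_s <= annotations$start_s))
    abort("annotation intervals must have end > start", "integrity_error")
  check_annotation_overlap(annotations)
  structure(list(time_s = as.numeric(time_s),
                 gaze_x_cm = as.numeric(gaze_x_cm),
                 gaze_y_cm = as.numeric(gaze_y_cm),
                 pupil_mm = as.numeric(pupil_mm),
                 geometry = geometry,
                 annotations = annotations),
            class = "gaze_recording")
}

# Within a label class ("cycle:*" treated as one class), intervals must not
# overlap under the half-open convention.
check_annotation_overlap <- function(ann) {
  cls <- ifelse(startsWith(ann$label, "cycle:"), "cycle", ann$label)
  for (k in unique(cls)) {
    a <- ann[cls == k, , drop = FALSE]
    a <- a[order(a$start_s), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start_s[-1] < a$end_s[-nrow(a)] - 1e-12))
      abort(sprintf("overlapping '%s' annotations", k), "integrity_error")
  }
  invisible(TRUE)
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples, %.1f s, %d annotations\n",
              length(x$time_s), diff(range(x$time_s)), nrow(x$annotations)))
  invisible(x)
}

#' Read a gaze recording from delimiter-separated files
#'
#' The sample file must contain columns `time_s, gaze_x_cm, gaze_y_cm,
#' pupil_mm`; an optional sidecar annotation file has `label, start_s,
#' end_s`. Lines starting with `#` are ignored.
#'
#' @param path sample file path.
#' @param geometry a [screen_geometry()].
#' @param annotations_path optional annotation file path; defaults to
#'   `<path>.annotations.csv` when that file exists.
#' @return a [gaze_recording()].
#' @export
read_gaze_recording <- function(path, geometry = screen_geometry(),
                                annotations_path = NULL) {
  if (!file.exists(path))
    abort(sprintf("gaze file not found: %s", path), "io_error")
  d <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  need <- c("time_s", "gaze_x_cm", "gaze_y_cm", "pupil_mm")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    abort(sprintf("gaze file missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), "format_error")
  ann <- NULL
  if (is.null(annotations_path)) {
    cand <- paste0(path, ".annotations.csv")
    if (file.exists(cand)) annotations_path <- cand
  }
  if (!is.null(annotations_path)) {
    ann <- data.table::fread(annotations_path, sep = ",", header = TRUE,
                             data.table = FALSE)
    ann_missing <- setdiff(c("label", "start_s", "end_s"), names(ann))
    if (length(ann_missing))
      abort(sprintf("annotation file missing column(s): %s",
                    paste(ann_missing, collapse = ", ")), "format_error")
  }
  gaze_recording(d$time_s, d$gaze_x_cm, d$gaze_y_cm, d$pupil_mm,
                 geometry = geometry, annotations = ann)
}

#' Write a gaze recording
#'
#' Writes the sample stream to `path` and (when present) annotations to
#' `<path>.annotations.csv`; [read_gaze_recording()] round-trips losslessly
#' to numeric precision.
#'
#' @param recording a [gaze_recording()].
#' @param path output sample file path.
#' @export
write_gaze_recording <- function(recording, path) {
  d <- data.frame(time_s = recording$time_s,
                  gaze_x_cm = recording$gaze_x_cm,
                  gaze_y_cm = recording$gaze_y_cm,
                  pupil_mm = recording$pupil_mm)
  data.table::fwrite(d, path)
  if (nrow(recording$annotations))
    data.table::fwrite(recording$annotations,
                       paste0(path, ".annotations.csv"))
  invisible(path)
}

#' Session metadata
#'
#' @param participant_id scalar identifier.
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param mode `"manual"` (self-triggered micro-breaks) or `"automatic"`
#'   (biofeedback-triggered).
#' @param kss_by_segment integer KSS ratings, 1 (extremely alert) to 10
#'   (extremely sleepy), one per segment; may be `NULL` before a session.
#' @param cycle_count total task cycles (default 180).
#' @param cycles_per_segment cycles per segment (default 20).
#' @return object of class `session_meta`.
#' @export
session_meta <- function(participant_id, age = NA_real_,
                         sex = c("F", "M"), mode = c("manual", "automatic"),
                         kss_by_segment = NULL, cycle_count = 180L,
                         cycles_per_segment = 20L) {
  sex <- match.arg(sex)
  mode <- match.arg(mode)
  if (cycle_count %% cycles_per_segment != 0L)
    abort("cycle_count must be divisible by cycles_per_segment",
          "config_error")
  if (!is.null(kss_by_segment)) check_kss(kss_by_segment)
  structure(list(participant_id = participant_id, age = age, sex = sex,
                 mode = mode, kss_by_segment = kss_by_segment,
                 cycle_count = as.integer(cycle_count),
                 cycles_per_segment = as.integer(cycles_per_segment)),
            class = "session_meta")
}

check_kss <- function(kss) {
  if (any(!is.na(kss) & (kss < 1 | kss > 10 | kss != round(kss))))
    abort("KSS ratings must be integers in [1, 10]", "validation_error")
  invisible(TRUE)
}

#' Construct a labeled segment-feature dataset
#'
#' One row per (participant, segment) with the 32 oculometric features,
#' `age`, `sex`, a KSS rating and the dichotomized `label`. Labels are
#' always recomputed as fatigued iff `kss >= threshold`.
#'
#' @param df data.frame with columns `participant_id`, `segment_index`,
#'   the [OCULOMETRIC_FEATURES], `age`, `sex`, `kss`.
#' @param threshold KSS dichotomization threshold (default 5).
#' @return `labeled_dataset`: a data.frame with a `label` factor column
#'   (`alert`/`fatigued`) and attribute `kss_threshold`.
#' @export
labeled_dataset <- function(df, threshold = 5L) {
  need <- c("participant_id", "segment_index", "age", "sex", "kss")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort(sprintf("dataset missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), "format_error")
  for (f in setdiff(OCULOMETRIC_FEATURES, names(df)))
    df[[f]] <- rep(NA_real_, nrow(df))
  if (nrow(df)) check_kss(df$kss)
  if (anyDuplicated(df[c("participant_id", "segment_index")]))
    abort("duplicate (participant, segment) rows", "integrity_error")
  df$label <- dichotomize_kss(df$kss, threshold)
  df <- df[c("participant_id", "segment_index", OCULOMETRIC_FEATURES,
             "age", "sex", "kss", "label")]
  structure(df, class = c("labeled_dataset", "data.frame"),
            kss_threshold = as.integer(threshold))
}

#' Load a segment-feature table
#'
#' Reads a feature table written by [write_features_table()]. Labels are
#' recomputed from `kss` at `threshold`; empty cells stay missing (never
#' coerced to zero); unknown feature columns are dropped with a warning.
#'
#' @param path file path.
#' @param threshold KSS dichotomization threshold.
#' @return a [labeled_dataset()].
#' @export
load_dataset <- function(path, threshold = 5L) {
  if (!file.exists(path))
    abort(sprintf("feature table not found: %s", path), "io_error")
  d <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                         na.strings = c("", "NA"))
  known <- c("participant_id", "segment_index", OCULOMETRIC_FEATURES,
             "age", "sex", "kss", "label")
  unknown <- setdiff(names(d), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(unknown, collapse = ", ")))
    d <- d[setdiff(names(d), unknown)]
  }
  d$label <- NULL
  if (nrow(d) == 0L) {
    d <- d[known[known %in% c(names(d))]]
  }
  labeled_dataset(d, threshold = threshold)
}

#' Write a segment-feature table
#'
#' Deterministic column order: `participant_id, segment_index`, the
#' [OCULOMETRIC_FEATURES], `age, sex, kss, label`. Missing cells are
#' written empty; round-trip with [load_dataset()] is lossless.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @export
write_features_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  ok <- tryCatch({
    data.table::fwrite(as.data.frame(dataset), path, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort(sprintf("cannot write feature table to %s: %s", path,
                  conditionMessage(ok)), "io_error")
  invisible(path)
}
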