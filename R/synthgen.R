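# Synthetic gaze/pupil generator with ground truth. Emulates the
# statistical shape of a previously collected oculometrics dataset: 38
# participants x 12 segments, ~45% fatigued base rate, and
# fatigue-dependent drift of blink frequency (+), PERCLOS (+), saccade
# frequency (-), main-sequence slope (-); the pupil-diameter interquartile
# range carries no monotone drift by default.

#' Population configuration for the synthetic generator
#'
#' Baseline ranges (uniform per participant) and fatigue-drift
#' coefficients (per unit latent fatigue on `[0, 1]`). Values are chosen
#' once as typical of screen-work oculomotor behavior; see the methods
#' vignette for the rationale.
#'
#' @param ... overrides of the default entries.
#' @return list of class `population_config`.
#' @export
population_config <- function(...) {
  cfg <- list(
    blink_rate_hz = c(0.10, 0.35),
    blink_dur_s = c(0.10, 0.20),
    fixation_dur_s = c(0.35, 0.60),
    fixation_dur_sd_s = c(0.05, 0.10),
    saccade_amp_deg = c(4, 8),
    sva = c(40, 55),
    sva_noise_dps = c(0, 0),
    pupil_mm = c(3.2, 4.8),
    pupil_osc_mm = c(0.15, 0.35),
    pupil_osc_hz = c(0.05, 0.15),
    pupil_noise_mm = c(0.005, 0.015),
    pos_jitter_cm = c(0.00, 0.03),
    age = c(22, 35),
    # drift per unit latent fatigue (signs: BF +, PERCLOS via BD +, SF via
    # fixation duration +, SVA -, PDIR none)
    drift = list(blink_rate_hz = 0.10, blink_dur_s = 0.08,
                 fixation_dur_s = 0.15, sva = -6, pdir_mm = 0),
    kss = list(base = 2.5, gain = 6, noise = 0.6),
    trajectory = list(f0 = c(0, 0.25), f1 = c(0.4, 1.0), sd = 0.05))
  over <- list(...)
  cfg <- modifyList(cfg, over)
  rng <- cfg[c("blink_rate_hz", "blink_dur_s", "fixation_dur_s",
               "fixation_dur_sd_s", "saccade_amp_deg", "sva",
               "sva_noise_dps", "pupil_mm", "pupil_osc_mm", "pupil_osc_hz",
               "pupil_noise_mm", "pos_jitter_cm", "age")]
  bad <- names(rng)[vapply(rng, function(r) r[2] < r[1], TRUE)]
  if (length(bad))
    abort(sprintf("inverted range(s): %s", paste(bad, collapse = ", ")),
          "validation_error")
  structure(cfg, class = "population_config")
}

derive_seed <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483587)

#' Sample a per-participant synthetic profile
#'
#' Draws participant baselines uniformly from the population ranges;
#' deterministic given `seed`.
#'
#' @param population a [population_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_profile`.
#' @export
sample_participant_profile <- function(population = population_config(),
                                       seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  draw <- function(r) runif(1, r[1], r[2])
  p <- list(
    blink_rate_hz = draw(population$blink_rate_hz),
    blink_dur_s = draw(population$blink_dur_s),
    fixation_dur_s = draw(population$fixation_dur_s),
    fixation_dur_sd_s = draw(population$fixation_dur_sd_s),
    saccade_amp_deg = draw(population$saccade_amp_deg),
    sva = draw(population$sva),
    sva_noise_dps = draw(population$sva_noise_dps),
    pupil_mm = draw(population$pupil_mm),
    pupil_osc_mm = draw(population$pupil_osc_mm),
    pupil_osc_hz = draw(population$pupil_osc_hz),
    pupil_noise_mm = draw(population$pupil_noise_mm),
    pos_jitter_cm = draw(population$pos_jitter_cm),
    age = round(draw(population$age)),
    sex = sample(c("F", "M"), 1),
    drift = population$drift,
    kss = population$kss,
    seed = seed)
  structure(p, class = "synthetic_profile")
}

# Generating (noise-free expected) feature values at latent fatigue f.
# FF exceeds SF by the blink rate because a mid-fixation blink splits one
# fixation into two.
truth_features <- function(profile, f) {
  d <- profile$drift
  bf <- profile$blink_rate_hz + d$blink_rate_hz * f
  bd <- profile$blink_dur_s + d$blink_dur_s * f
  fd <- profile$fixation_dur_s + d$fixation_dur_s * f
  sva <- profile$sva + d$sva * f
  sacc_dur <- 2 / sva
  sf <- (1 - bf * bd) / (fd + sacc_dur)
  list(BF = bf, BD = bd, FD = fd, SVA = sva, SCD = sacc_dur, SF = sf,
       FF = sf + bf,
       PERCLOS = 100 * bf * bd / (1 - bf * bd),
       PD = profile$pupil_mm,
       PDIR = sqrt(2) * profile$pupil_osc_mm + d$pdir_mm * f,
       SA = profile$saccade_amp_deg,
       SPV = sva * profile$saccade_amp_deg)
}

#' Render one synthetic gaze segment with ground truth
#'
#' Builds an alternating fixation/saccade renewal process. Saccade
#' velocity profiles are raised-cosine pulses with
#' `v_peak = SVA * amplitude + noise`; fixations are jittered around their
#' centers; blinks (zero pupil) are Poisson-placed inside fixations, kept
#' clear of fixation edges by `blink_guard_s`; the pupil is a baseline
#' plus a slow oscillation plus noise, zeroed during blinks. Latent
#' fatigue shifts the generating parameters through the profile's drift
#' coefficients.
#'
#' @param profile a [sample_participant_profile()].
#' @param fatigue_level latent fatigue scalar in `[0, 1]`.
#' @param duration_s segment duration (default 200 s = 20 cycles of 10 s).
#' @param fs sampling rate, Hz (default 360).
#' @param seed integer seed.
#' @param segment_index 1-based segment number (sets cycle annotation
#'   labels).
#' @param cycles_per_segment cycles annotated over the duration.
#' @param blink_guard_s minimum gap kept between a blink and the
#'   enclosing fixation's edges (hence adjacent saccades).
#' @param geometry a [screen_geometry()].
#' @return list with `recording` (a [gaze_recording()]) and `truth`
#'   (generating parameters, expected features, and the event table).
#' @export
synthesize_segment <- function(profile, fatigue_level = 0,
                               duration_s = 200, fs = 360, seed = 1L,
                               segment_index = 1L,
                               cycles_per_segment = 20L,
                               blink_guard_s = 0.12,
                               geometry = screen_geometry()) {
  if (duration_s <= 0) abort("duration must be positive", "validation_error")
  tf <- truth_features(profile, fatigue_level)
  if (fs * min(2 / tf$SVA, tf$BD) < 4)
    abort("sampling rate too low to render the shortest events",
          "config_error")
  set.seed(derive_seed(seed, segment_index))
  half_w <- geometry$width_cm / 2 - 1
  half_h <- geometry$height_cm / 2 - 1
  # --- continuous-time event schedule -------------------------------------
  ev_kind <- character(0); ev_on <- numeric(0); ev_off <- numeric(0)
  ev_amp <- numeric(0); ev_vpk <- numeric(0)
  seg <- list()  # rasterization plan: fixation/saccade/blink pieces
  cursor <- 0
  cx <- 0; cy <- 0
  fix_start <- 0
  repeat {
    # open fixation time (eye open, stable gaze)
    fd_i <- max(rlnorm(1, log(tf$FD), profile$fixation_dur_sd_s / tf$FD),
                2 * blink_guard_s + 0.05)
    # blinks inside this fixation
    lambda <- tf$BF * (fd_i + tf$SCD) / (1 - tf$BF * tf$BD)
    nb <- rpois(1, lambda)
    room <- fd_i - 2 * blink_guard_s
    bds <- numeric(0); bstarts <- numeric(0)
    if (nb > 0) {
      bds <- pmax(rlnorm(nb, log(tf$BD), 0.15), 0.05)
      # blink positions live on the open-time axis (blinks insert extra
      # time); keep >= 0.1 s open time between successive blinks
      avail <- room - 0.1 * (nb - 1)
      while (nb > 0 && avail < 0) {
        nb <- nb - 1L
        bds <- bds[seq_len(nb)]
        avail <- room - 0.1 * max(nb - 1, 0)
      }
      if (nb > 0) {
        gaps <- diff(c(0, sort(runif(nb)))) * avail
        off <- blink_guard_s
        for (i in seq_len(nb)) {
          off <- off + gaps[i]
          bstarts <- c(bstarts, off)
          off <- off + 0.1
        }
      }
    }
    fix_total <- fd_i + sum(bds)
    # emit fixation pieces split by blinks (times relative to cursor)
    open_prev <- 0
    for (i in seq_along(bstarts)) {
      b_on <- bstarts[i] + sum(bds[seq_len(i - 1L)])
      seg[[length(seg) + 1L]] <- list(kind = "fixation",
                                      on = cursor + open_prev,
                                      off = cursor + b_on, x = cx, y = cy)
      seg[[length(seg) + 1L]] <- list(kind = "blink",
                                      on = cursor + b_on,
                                      off = cursor + b_on + bds[i],
                                      x = cx, y = cy)
      ev_kind <- c(ev_kind, "blink")
      ev_on <- c(ev_on, cursor + b_on); ev_off <- c(ev_off, cursor + b_on +
                                                     bds[i])
      ev_amp <- c(ev_amp, NA); ev_vpk <- c(ev_vpk, NA)
      open_prev <- b_on + bds[i]
    }
    seg[[length(seg) + 1L]] <- list(kind = "fixation",
                                    on = cursor + open_prev,
                                    off = cursor + fix_total,
                                    x = cx, y = cy)
    cursor <- cursor + fix_total
    if (cursor >= duration_s) break
    # saccade to a new center
    amp <- min(max(rlnorm(1, log(tf$SA), 0.3), 1), 12)
    for (try in 1:50) {
      ang <- runif(1, 0, 2 * pi)
      r_cm <- geometry$distance_cm * tan(amp * pi / 180)
      nx <- cx + r_cm * cos(ang); ny <- cy + r_cm * sin(ang)
      if (abs(nx) <= half_w && abs(ny) <= half_h) break
    }
    true_amp <- gaze_angle_deg(cx, cy, nx, ny, geometry$distance_cm)
    vpk <- tf$SVA * true_amp + rnorm(1, 0, profile$sva_noise_dps)
    vpk <- max(vpk, 50)
    sd_s <- 2 * true_amp / vpk
    ev_kind <- c(ev_kind, "saccade")
    ev_on <- c(ev_on, cursor); ev_off <- c(ev_off, cursor + sd_s)
    ev_amp <- c(ev_amp, true_amp); ev_vpk <- c(ev_vpk, vpk)
    seg[[length(seg) + 1L]] <- list(kind = "saccade", on = cursor,
                                    off = cursor + sd_s,
                                    x = cx, y = cy, x2 = nx, y2 = ny)
    cursor <- cursor + sd_s
    cx <- nx; cy <- ny
    if (cursor >= duration_s) break
  }
  # --- rasterize -----------------------------------------------------------
  n <- as.integer(round(duration_s * fs))
  tgrid <- (seq_len(n) - 1L) / fs
  x <- numeric(n); y <- numeric(n); pupil <- numeric(n)
  blink_mask <- logical(n)
  for (piece in seg) {
    idx <- which(tgrid >= piece$on - 1e-9 & tgrid < piece$off - 1e-9)
    if (!length(idx)) next
    if (piece$kind == "saccade") {
      tau <- (tgrid[idx] - piece$on) / (piece$off - piece$on)
      frac <- tau - sin(2 * pi * tau) / (2 * pi)   # raised-cosine progress
      x[idx] <- piece$x + frac * (piece$x2 - piece$x)
      y[idx] <- piece$y + frac * (piece$y2 - piece$y)
    } else {
      x[idx] <- piece$x; y[idx] <- piece$y
      if (piece$kind == "blink") blink_mask[idx] <- TRUE
    }
  }
  if (profile$pos_jitter_cm > 0) {
    jit_idx <- !blink_mask
    x[jit_idx] <- x[jit_idx] + rnorm(sum(jit_idx), 0, profile$pos_jitter_cm)
    y[jit_idx] <- y[jit_idx] + rnorm(sum(jit_idx), 0, profile$pos_jitter_cm)
  }
  phi <- runif(1, 0, 2 * pi)
  pupil <- profile$pupil_mm +
    profile$pupil_osc_mm * sin(2 * pi * profile$pupil_osc_hz * tgrid + phi)
  if (profile$pupil_noise_mm > 0)
    pupil <- pupil + rnorm(n, 0, profile$pupil_noise_mm)
  pupil[blink_mask] <- 0
  cyc_len <- duration_s / cycles_per_segment
  k0 <- (segment_index - 1L) * cycles_per_segment
  ann <- data.frame(
    label = paste0("cycle:", k0 + seq_len(cycles_per_segment)),
    start_s = cyc_len * (seq_len(cycles_per_segment) - 1L),
    end_s = cyc_len * seq_len(cycles_per_segment))
  rec <- gaze_recording(tgrid, x, y, pupil, geometry = geometry,
                        annotations = ann)
  events <- data.frame(kind = ev_kind, onset_s = ev_on, offset_s = ev_off,
                       amplitude_deg = ev_amp, peak_vel_dps = ev_vpk)
  events <- events[events$offset_s <= duration_s + 1e-9, , drop = FALSE]
  list(recording = rec,
       truth = list(features = tf, events = events,
                    fatigue_level = fatigue_level,
                    n_blinks = sum(events$kind == "blink"),
                    n_saccades = sum(events$kind == "saccade")))
}

# latent fatigue trajectories: monotone in expectation with ordinal noise
latent_trajectory <- function(cfg, n_segments) {
  f0 <- runif(1, cfg$trajectory$f0[1], cfg$trajectory$f0[2])
  f1 <- runif(1, cfg$trajectory$f1[1], cfg$trajectory$f1[2])
  s <- seq_len(n_segments)
  ramp <- if (n_segments > 1) (s - 1) / (n_segments - 1) else rep(0, 1)
  pmin(pmax(f0 + (f1 - f0) * ramp + rnorm(n_segments, 0,
                                          cfg$trajectory$sd), 0), 1)
}

# discretized-logistic ordinal KSS noise around the latent map
kss_from_latent <- function(f, kss_cfg, offset) {
  lat <- kss_cfg$base + kss_cfg$gain * f + offset
  noise <- stats::rlogis(length(f), 0, kss_cfg$noise)
  pmin(pmax(round(lat + noise), 1), 10)
}

# Calibrate a global KSS offset so that E[P(KSS >= threshold)] matches the
# target fatigued fraction under the population config (Monte Carlo over a
# dedicated RNG stream; deterministic given seed).
calibrate_kss_offset <- function(population, n_segments, target,
                                 threshold = 5, seed = 1L, n_mc = 4000L) {
  set.seed(derive_seed(seed, 999983L))
  lat <- numeric(0)
  for (r in seq_len(ceiling(n_mc / n_segments))) {
    f <- latent_trajectory(population, n_segments)
    lat <- c(lat, population$kss$base + population$kss$gain * f +
               stats::rlogis(n_segments, 0, population$kss$noise))
  }
  # fatigued iff round(lat + offset) >= threshold  <=>  lat + offset >=
  # threshold - 0.5
  (threshold - 0.5) - quantile(lat, 1 - target, names = FALSE)
}

#' Generate a labeled synthetic dataset with ground truth
#'
#' Fast path: per-participant latent fatigue trajectories (monotone in
#' expectation), generating feature values from [truth_features()] plus
#' per-segment sampling noise matching a 200-s extraction window, and KSS
#' ratings from a calibrated monotone latent map with discretized-logistic
#' noise, tuned so the expected fatigued fraction matches
#' `fatigued_fraction`.
#'
#' @param n_participants,n_segments dataset shape (defaults 38 x 12).
#' @param fatigued_fraction target base rate of `KSS >= threshold`
#'   (default 0.45).
#' @param threshold KSS dichotomization threshold.
#' @param population a [population_config()].
#' @param duration_s nominal segment duration used for the sampling-noise
#'   scales.
#' @param seed integer seed; all randomness derives from it.
#' @return list: `dataset` (a [labeled_dataset()]) and `truth`
#'   (per-participant profiles, latent trajectories, generating features).
#' @export
generate_dataset <- function(n_participants = 38L, n_segments = 12L,
                             fatigued_fraction = 0.45, threshold = 5L,
                             population = population_config(),
                             duration_s = 200, seed = 1L) {
  if (n_participants < 2L)
    abort("need at least 2 participants", "validation_error")
  if (fatigued_fraction <= 0 || fatigued_fraction >= 1)
    abort("fatigued_fraction must lie in (0, 1)", "validation_error")
  offset <- calibrate_kss_offset(population, n_segments, fatigued_fraction,
                                 threshold, seed)
  rows <- list(); truth <- list()
  for (p in seq_len(n_participants)) {
    profile <- sample_participant_profile(population,
                                          seed = derive_seed(seed, p))
    set.seed(derive_seed(seed, 100000L + p))
    f <- latent_trajectory(population, n_segments)
    kss <- kss_from_latent(f, population$kss, offset)
    seg_rows <- lapply(seq_len(n_segments), function(s) {
      tf <- truth_features(profile, f[s])
      noisy_feature_row(profile, tf, duration_s)
    })
    df <- do.call(rbind, seg_rows)
    df <- cbind(data.frame(participant_id = sprintf("P%02d", p),
                           segment_index = seq_len(n_segments)), df)
    df$age <- profile$age
    df$sex <- profile$sex
    df$kss <- kss
    rows[[p]] <- df
    truth[[p]] <- list(profile = profile, fatigue = f, kss = kss)
  }
  dataset <- labeled_dataset(do.call(rbind, rows), threshold = threshold)
  list(dataset = dataset, truth = truth, kss_offset = offset)
}

# One synthetic feature row: generating values + sampling noise at the
# scale of a `duration_s` extraction window. Blink count couples BF and
# PERCLOS; features without a stated fatigue relation are drawn around
# plausible constants.
noisy_feature_row <- function(profile, tf, duration_s) {
  Tn <- duration_s
  nb <- rpois(1, tf$BF * Tn)
  ns <- max(rpois(1, tf$SF * Tn), 3L)
  bf <- nb / Tn
  bd <- if (nb > 0) tf$BD * exp(rnorm(1, 0, 0.15 / sqrt(nb))) else NA_real_
  closed <- nb * (bd %||% 0)
  perclos <- 100 * closed / (Tn - closed)
  sf <- ns / Tn
  fd <- tf$FD + rnorm(1, 0, profile$fixation_dur_sd_s / sqrt(ns))
  sva_se <- (profile$sva_noise_dps + 2) /
    (0.3 * profile$saccade_amp_deg * sqrt(ns))
  sva <- tf$SVA + rnorm(1, 0, sva_se)
  pd <- tf$PD + rnorm(1, 0, 0.01)
  pdir <- max(tf$PDIR + rnorm(1, 0, 0.02), 0)
  data.frame(
    BF = bf, BD = bd, BGF = 0.1 * bf, IBI = min(1 / max(bf, 1e-3), 20),
    LBF = bf * 0.2, LBR = 0.2, DBF = bf * 0.1, BGR = 0.1,
    TBS = runif(1, 0.2, 0.5),
    PERCLOS = perclos, PD = pd, PDIR = pdir,
    PCV = abs(rnorm(1, 0.05, 0.01)),
    PH = runif(1, 0.7, 0.99),
    FF_disp_dist = runif(1, 0.85, 1),
    FD = fd, FF = sf + bf,
    FF_disp = runif(1, 2, 5), FF_dist = runif(1, 2.2, 5.5),
    OD = runif(1, 2, 5), LFR = 100 * mean(rnorm(3, 0.05, 0.02)),
    SVA = sva, SCD = tf$SCD * exp(rnorm(1, 0, 0.05)), SF = sf,
    SPV = tf$SPV + rnorm(1, 0, 5),
    SDA = abs(rnorm(1, 0.002, 5e-4)), SCR = abs(rnorm(1, 0.3, 0.1)),
    SA = profile$saccade_amp_deg * exp(rnorm(1, 0, 0.3 / sqrt(ns))),
    SPD = tf$SPV * 20 + rnorm(1, 0, 50),
    SPA = tf$SPV * 20 + rnorm(1, 0, 50),
    ISI = runif(1, 0.05, 0.15), KPA = rnorm(1, 0, 0.3))
}
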