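# Shared fixtures, all generated in code.

# population with every measurement-noise scale at zero
noiseless_population <- function(...) {
  population_config(pos_jitter_cm = c(0, 0), pupil_noise_mm = c(0, 0),
                    sva_noise_dps = c(0, 0), ...)
}

# large-effect population: narrow baselines, strong fatigue drift, and
# sharp (low-noise) KSS labels -- an effect constructed to be large
large_effect_population <- function() {
  population_config(
    blink_rate_hz = c(0.18, 0.22), fixation_dur_s = c(0.42, 0.48),
    sva = c(46, 50), pupil_mm = c(3.9, 4.1),
    drift = list(blink_rate_hz = 0.35, blink_dur_s = 0.12,
                 fixation_dur_s = 0.55, sva = -20, pdir_mm = 0),
    kss = list(base = 2.5, gain = 6, noise = 0.2))
}

# perfectly separable dataset: one feature equals the class
make_separable_dataset <- function(n_participants = 4L, n_segments = 6L,
                                   seed = 1L) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    kss <- sample(c(2L, 7L), n_segments, replace = TRUE)
    data.frame(participant_id = sprintf("P%d", p),
               segment_index = seq_len(n_segments),
               age = 25 + p, sex = c("F", "M")[1 + p %% 2], kss = kss)
  }))
  lab <- as.numeric(rows$kss >= 5)
  rows$BF <- lab * 2 + 0.1 + rnorm(nrow(rows), 0, 0.05)
  rows$SF <- rnorm(nrow(rows), 2, 0.3)
  rows$PERCLOS <- rnorm(nrow(rows), 4, 1)
  rows$SVA <- rnorm(nrow(rows), 45, 3)
  rows$PDIR <- rnorm(nrow(rows), 0.4, 0.05)
  labeled_dataset(rows)
}

# features carry no label information
make_null_dataset <- function(n_participants = 6L, n_segments = 6L,
                              seed = 1L,
                              features = c("BF", "SF", "PERCLOS")) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    data.frame(participant_id = sprintf("P%d", p),
               segment_index = seq_len(n_segments),
               age = 25, sex = "F",
               kss = sample(c(2L, 7L), n_segments, replace = TRUE))
  }))
  for (f in features) rows[[f]] <- rnorm(nrow(rows))
  labeled_dataset(rows)
}

# 2 jointly informative (shared-nuisance construction) + 8 noise features
make_planted_dataset <- function(n_participants = 6L, n_segments = 8L,
                                 seed = 1L) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    data.frame(participant_id = sprintf("P%d", p),
               segment_index = seq_len(n_segments),
               age = 25, sex = "F",
               kss = ifelse(rbinom(n_segments, 1, 0.5) == 1, 7L, 2L))
  }))
  lab <- 2 * (rows$kss >= 5) - 1
  u <- rnorm(nrow(rows), 0, 0.9)
  for (f in OCULOMETRIC_FEATURES[1:10]) rows[[f]] <- rnorm(nrow(rows))
  rows$BF <- 0.8 * lab + u + rnorm(nrow(rows), 0, 0.35)
  rows$BD <- 0.8 * lab - u + rnorm(nrow(rows), 0, 0.35)
  labeled_dataset(rows)
}
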