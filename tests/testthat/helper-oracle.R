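# Independent per-millisecond brute-force scorer. Evaluates the AOI step
# function at every millisecond midpoint (t + 0.5 for t = 0..duration-1) and
# computes every looking measure by straight counting, with no shared code
# with the package's interval-based implementation.

oracle_aoi_grid <- function(trial) {
  s <- trial$samples
  mids <- seq_len(trial$trial_duration_ms) - 0.5
  idx <- findInterval(mids, s$t_ms)
  aoi <- rep("missing", length(mids))
  aoi[idx > 0] <- as.character(s$aoi[idx[idx > 0]])
  aoi
}

oracle_scores <- function(trial, cfg = task_config()) {
  aoi <- oracle_aoi_grid(trial)
  on <- aoi %in% c("left", "right")
  # first look: AOI at onset; else scan samples after the onset sample
  s <- trial$samples
  onset <- cfg$first_change_onset_ms
  i0 <- findInterval(onset, s$t_ms)
  at <- if (i0 >= 1) as.character(s$aoi[i0]) else "missing"
  fl_side <- if (at %in% c("left", "right")) at else {
    later <- which(seq_len(nrow(s)) > i0 &
                     s$t_ms <= cfg$firstlook_fallback_end_ms &
                     s$aoi %in% c("left", "right"))
    if (length(later)) as.character(s$aoi[later[1]]) else NA_character_
  }
  first_look <- if (is.na(fl_side)) "unclassified"
                else if (fl_side == trial$change_side) "change" else "no_change"
  # change preference over ms in [w1, w2)
  w <- seq(cfg$cp_window[1] + 1, cfg$cp_window[2])  # ms indices in window
  n_ch <- sum(aoi[w] == trial$change_side)
  n_nc <- sum(aoi[w] == setdiff(c("left", "right"), trial$change_side))
  away_frac <- 1 - mean(on)
  cp <- if (away_frac > cfg$away_exclusion_fraction || n_ch + n_nc == 0)
    NA_real_ else n_ch / (n_ch + n_nc)
  # shift rate: collapse per-ms on-screen sequence to runs
  sides <- aoi[on]
  sr <- if (!length(sides)) NA_real_ else {
    runs <- rle(sides)$values
    sum(runs[-1] != runs[-length(runs)]) / (length(sides) / 1000)
  }
  # LookingWindow1
  wl <- seq(cfg$lw1_window[1] + 1, cfg$lw1_window[2])
  w_aoi <- aoi[wl]
  w_on <- w_aoi[w_aoi %in% c("left", "right")]
  lw1 <- if (!length(w_on)) NA_real_ else mean(w_on == w_on[1])
  list(first_look = first_look, change_preference = cp, shift_rate = sr,
       looking_window1 = lw1, away_fraction = away_frac)
}

# Random trial with integer-ms sample times at a random cadence and random
# AOI run structure (occasionally degenerate: all away / all missing).
random_trial <- function(seed) {
  set.seed(seed)
  dt <- sample(c(2, 10, 20, 40), 1)
  t_ms <- seq(0, 10000 - dt, by = dt)
  n_runs <- sample(1:40, 1)
  probs <- c(left = 0.35, right = 0.35, away = 0.2, missing = 0.1)
  if (runif(1) < 0.05) probs <- c(left = 0, right = 0, away = 0.5, missing = 0.5)
  run_aoi <- sample(names(probs), n_runs, replace = TRUE, prob = probs + 1e-9)
  run_len <- rmultinom(1, length(t_ms), runif(n_runs) + 0.05)[, 1]
  aoi <- rep(run_aoi, run_len)[seq_along(t_ms)]
  aoi[is.na(aoi)] <- "missing"
  if (runif(1) < 0.3) {  # late start: no sample before some time
    k <- min(sample(1:200, 1), length(t_ms) - 1)
    t_ms <- t_ms[-seq_len(k)]
    aoi <- aoi[-seq_len(k)]
  }
  gaze_trial("px", sample(1:2, 1), 1,
             data.frame(t_ms = t_ms, aoi = aoi, stringsAsFactors = FALSE),
             load = 2, load_level = "medium",
             change_side = sample(c("left", "right"), 1),
             source_used = "eyetracker")
}

# small seeded battery of generator-produced trials (eyetracker only, so all
# sample times are integer ms and the per-ms oracle is exact)
generator_trials <- function(n_households, seed, years = 1, trial_count = 6,
                             rate = 100) {
  hh <- generate_households(n_households, seed = seed)
  tru <- make_truth(hh, seed = seed + 1)
  cfg <- gen_config(n_households = n_households, trial_count = trial_count,
                    blocks = 1, sample_rate_hz = rate, video_fraction = 0)
  generate_gaze_trials(hh, tru, cfg, seed = seed + 2, years = years)
}

mirror_trial <- function(trial) {
  sw <- c(left = "right", right = "left", away = "away", missing = "missing")
  s <- trial$samples
  s$aoi <- unname(sw[s$aoi])
  gaze_trial(trial$participant_id, trial$year, trial$trial_index, s,
             load = trial$load, load_level = trial$load_level,
             change_side = unname(sw[trial$change_side]),
             source_used = trial$source_used,
             trial_duration_ms = trial$trial_duration_ms)
}
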