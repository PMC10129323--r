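#' Synthetic-study generation configuration
#'
#' Defaults encode the study design being emulated: up to 6 in-home
#' monitoring rounds of 3 days at one reading every 10 s; 36 change-detection
#' trials per participant-year in six blocks of six (three loads x two change
#' sides per block); eye-tracking at 500 Hz with a fraction of trials
#' hand-coded from video at 30 fps; diurnal AQI peaks at morning and evening
#' meal-preparation times superimposed on a seasonal cycle peaking in winter.
#'
#' @param n_households Number of households (one enrolled infant each).
#' @param n_rounds Monitoring rounds per household (<= 6; default 4, the
#'   average number of completed visits).
#' @param round_days Days of continuous monitoring per round (3).
#' @param sample_interval_s Device cadence in seconds (10).
#' @param baseline_aqi Grand-mean AQI level (186).
#' @param seasonal_amplitude Amplitude of the annual cycle in AQI units (60).
#' @param diurnal_peak_hours Clock hours of meal-time peaks (c(7, 18)).
#' @param diurnal_amplitude Peak height in AQI units (40).
#' @param diurnal_sd_h Width (hours) of each meal-time peak (1.5).
#' @param noise_sd Marginal SD of the AR(1) device noise (20).
#' @param ar1_coefficient AR(1) coefficient of device noise at the device
#'   cadence (0.6).
#' @param trial_count,blocks Trials per participant-year and block count
#'   (36 in 6 blocks).
#' @param missingness_rate Per-sample probability that a gaze sample is
#'   recorded as missing (0.1).
#' @param sample_rate_hz Eye-tracker sampling rate (500).
#' @param video_fraction Fraction of trials hand-coded from video at 30 fps
#'   instead of eye-tracked (0.3).
#' @param start_date First monitoring round start (ISO date).
#' @param tz Fixed time zone for all timestamps (no DST handling).
#' @return list of class `gen_config`.
#' @export
gen_config <- function(n_households = 215, n_rounds = 4, round_days = 3,
                       sample_interval_s = 10, baseline_aqi = 186,
                       seasonal_amplitude = 60, diurnal_peak_hours = c(7, 18),
                       diurnal_amplitude = 40, diurnal_sd_h = 1.5,
                       noise_sd = 20, ar1_coefficient = 0.6,
                       trial_count = 36, blocks = 6,
                       missingness_rate = 0.1, sample_rate_hz = 500,
                       video_fraction = 0.3,
                       start_date = "2019-01-10", tz = "Asia/Kolkata") {
  stopifnot(n_households >= 1, n_rounds >= 1, n_rounds <= 6,
            round_days >= 1, sample_interval_s > 0,
            missingness_rate >= 0, missingness_rate <= 1,
            video_fraction >= 0, video_fraction <= 1,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            trial_count %% blocks == 0)
  structure(as.list(environment()), class = "gen_config")
}

# Cooking-fuel probabilities conditional on SES screening group. Qualitative
# structure: LPG concentrates in high-SES households, wood and cow dung in
# low-SES households.
fuel_probs_by_ses <- function() {
  p <- rbind(high = c(cow_dung = 0.12, wood = 0.56, lpg = 0.34),
             low  = c(cow_dung = 0.12, wood = 0.85, lpg = 0.04))
  sweep(p, 1, rowSums(p), "/")
}

income_probs_by_ses <- function() {
  p <- rbind(high = c(low = 0.21, medium = 0.27, high = 0.54),
             low  = c(low = 0.44, medium = 0.40, high = 0.17))
  sweep(p, 1, rowSums(p), "/")
}

electricity_prob_by_ses <- c(high = 0.88, low = 0.40)

#' Generate synthetic households
#'
#' Draws Kuppuswamy-like SES scores and assigns cooking fuel, electricity and
#' income tertile with probabilities conditional on the SES screening group,
#' so that LPG use concentrates in high-SES households and solid fuels (wood,
#' cow dung) in low-SES households. Each household enrols one infant in
#' either the 6-month or 9-month age cohort.
#'
#' @param n Number of households (>= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return data.frame with household_id, participant_id, ses_score,
#'   ses_group, cooking_fuel, electricity, income_tertile, cohort.
#' @export
generate_households <- function(n, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  ses <- pmin(29, pmax(3, rnorm(n, 15, 5)))
  grp <- ifelse(ses >= 15, "high", "low")
  fp <- fuel_probs_by_ses()
  ip <- income_probs_by_ses()
  fuel <- vapply(grp, function(g)
    sample(colnames(fp), 1, prob = fp[g, ]), character(1))
  income <- vapply(grp, function(g)
    sample(colnames(ip), 1, prob = ip[g, ]), character(1))
  elec <- runif(n) < electricity_prob_by_ses[grp]
  data.frame(household_id = sprintf("h%03d", seq_len(n)),
             participant_id = sprintf("p%03d", seq_len(n)),
             ses_score = ses,
             ses_group = grp,
             cooking_fuel = fuel,
             electricity = elec,
             income_tertile = income,
             cohort = sample(c("6mo", "9mo"), n, replace = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground-truth ledger for a synthetic dataset
#'
#' Fixes every latent quantity the downstream recovery tests need: the
#' realized per-household AQI offset (cooking-fuel effect + SES slope +
#' household noise), the exposure effects on shift rate and on change
#' preference by year (a year-1-specific working-memory effect and a null
#' year-2 effect), the SES effect on standardized assessment scores (with a
#' null exposure effect), and latent working-memory capacity per cohort and
#' year. Effect sizes default to small values of the order reported for
#' in-home air pollution and infant visual cognition.
#'
#' @param households data.frame from [generate_households()].
#' @param seed Integer seed for the household offset noise.
#' @param fuel_offsets Named AQI offsets by fuel; cow dung > wood > LPG.
#' @param offset_ses_slope AQI offset change per SES unit (negative: higher
#'   SES, cleaner air).
#' @param offset_noise_sd SD of the household-specific offset noise (AQI).
#' @param beta_aqi_shift Shift-rate change per AQI unit of household offset
#'   (shifts/s; negative).
#' @param beta_aqi_cp_y1,beta_aqi_cp_y2 Change-preference change per AQI
#'   unit in years 1 and 2 (year 2 defaults to 0, the null).
#' @param beta_ses_assessment Assessment-score points per SES unit.
#' @param capacity_by_age Latent capacity (items) per cohort and year.
#' @return list of class `synth_truth` including `household_offsets` (named,
#'   AQI units) and all generative parameters.
#' @export
make_truth <- function(households, seed = 1,
                       fuel_offsets = c(cow_dung = 35, wood = 10, lpg = -30),
                       offset_ses_slope = -1.15,
                       offset_noise_sd = 20,
                       beta_aqi_shift = -1e-3,
                       beta_aqi_cp_y1 = -1e-3,
                       beta_aqi_cp_y2 = 0,
                       beta_ses_assessment = 0.8,
                       capacity_by_age = list(`6mo` = c(1.5, 3.5),
                                              `9mo` = c(2.5, 4.0))) {
  set.seed(seed)
  off <- fuel_offsets[households$cooking_fuel] +
    offset_ses_slope * (households$ses_score - 15) +
    rnorm(nrow(households), 0, offset_noise_sd)
  names(off) <- households$household_id
  structure(list(household_offsets = off,
                 fuel_offsets = fuel_offsets,
                 offset_ses_slope = offset_ses_slope,
                 offset_noise_sd = offset_noise_sd,
                 beta_aqi_shift = beta_aqi_shift,
                 beta_aqi_cp_y1 = beta_aqi_cp_y1,
                 beta_aqi_cp_y2 = beta_aqi_cp_y2,
                 beta_ses_assessment = beta_ses_assessment,
                 capacity_by_age = capacity_by_age,
                 # cell-level score model used by simulate_score_table()
                 cp_intercept = 0.49, cp_load_eff = c(low = 0.03, medium = 0,
                                                      high = -0.03),
                 cp_age_eff = 0.027, cp_participant_sd = 0.08,
                 cp_resid_sd = 0.12,
                 shift_intercept = 0.63,
                 shift_load_eff = c(low = 0.04, medium = 0, high = -0.04),
                 shift_age_eff = 0.012, shift_participant_sd = 0.10,
                 shift_resid_sd = 0.15,
                 seed = seed),
            class = "synth_truth")
}

#' Write / read a ground-truth ledger
#' @param truth A `synth_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  for (f in c("household_offsets", "fuel_offsets", "cp_load_eff",
              "shift_load_eff"))
    x[[f]] <- as.list(x[[f]])  # keep names as JSON object keys
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$household_offsets <- unlist(x$household_offsets)
  x$capacity_by_age <- lapply(x$capacity_by_age, unlist)
  for (f in c("fuel_offsets", "cp_load_eff", "shift_load_eff"))
    x[[f]] <- unlist(x[[f]])
  structure(x, class = "synth_truth")
}

#' Generate in-home air-quality device logs
#'
#' One reading every `sample_interval_s` seconds for `round_days` continuous
#' days per monitoring round. Each series is a smooth seasonal term (annual
#' cosine peaking in winter) plus a diurnal term with Gaussian bumps at the
#' configured meal-preparation hours, a household offset from the truth
#' ledger, and AR(1) noise; readings are floored at 0. Round start dates are
#' spaced about 90 days apart with a household-specific stagger.
#'
#' @param households data.frame from [generate_households()].
#' @param cfg A [gen_config()].
#' @param truth A [make_truth()] ledger.
#' @param seed Integer seed.
#' @return data.frame with device_id, household_id, timestamp (ISO-8601,
#'   fixed zone), aqi, round_index.
#' @export
generate_aqi_logs <- function(households, cfg = gen_config(), truth, seed = 1) {
  if (nrow(households) < 1) stop("households must be nonempty")
  set.seed(seed)
  n_per_round <- as.integer(cfg$round_days * 86400 / cfg$sample_interval_s)
  start0 <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = cfg$tz)
  stagger <- sample(0:13, nrow(households), replace = TRUE)
  out <- vector("list", nrow(households) * cfg$n_rounds)
  k <- 0
  for (i in seq_len(nrow(households))) {
    hid <- households$household_id[i]
    dev <- sprintf("d%02d", (i - 1) %% 20 + 1)
    off <- truth$household_offsets[hid]
    for (r in seq_len(cfg$n_rounds)) {
      t0 <- start0 + ((r - 1) * 90 + stagger[i]) * 86400
      tt <- t0 + (seq_len(n_per_round) - 1) * cfg$sample_interval_s
      lt <- as.POSIXlt(tt)
      doy <- lt$yday + 1
      hr <- lt$hour + lt$min / 60 + lt$sec / 3600
      seas <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
      diur <- 0
      for (p in cfg$diurnal_peak_hours) {
        dh <- pmin(abs(hr - p), 24 - abs(hr - p))  # circular hour distance
        diur <- diur + cfg$diurnal_amplitude *
          exp(-0.5 * (dh / cfg$diurnal_sd_h)^2)
      }
      noise <- if (cfg$noise_sd > 0) {
        e <- rnorm(n_per_round, 0,
                   cfg$noise_sd * sqrt(1 - cfg$ar1_coefficient^2))
        as.numeric(stats::filter(e, cfg$ar1_coefficient, method = "recursive"))
      } else 0
      k <- k + 1
      out[[k]] <- data.frame(
        device_id = dev, household_id = hid,
        timestamp = format(tt, "%Y-%m-%dT%H:%M:%S%z"),
        aqi = pmax(0, cfg$baseline_aqi + seas + diur + off + noise),
        round_index = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# design for one participant-year: blocks x (3 loads x 2 sides)
trial_design <- function(year, cfg) {
  loads <- LOADS_BY_YEAR[[as.character(year)]]
  per_block <- expand.grid(load = loads, change_side = c("left", "right"),
                           stringsAsFactors = FALSE)
  n_blocks <- cfg$trial_count / nrow(per_block)
  d <- per_block[rep(seq_len(nrow(per_block)), n_blocks), ]
  d$block <- rep(seq_len(n_blocks), each = nrow(per_block))
  d$trial_index <- seq_len(nrow(d))
  d
}

# Simulate one trial's look process: a two-state (left/right) semi-Markov
# renewal process. Look durations are exponential with mean 1000/rate ms;
# when the load is within capacity ("detect"), dwells shorten on the
# no-change side, lengthen on the change side, and releases are biased
# toward the change side. Away gaps may intervene between looks.
simulate_trial_stream <- function(duration_ms, rate, detect, change_side,
                                  p_away = 0.3, away_mean_ms = 400) {
  other <- function(s) if (s == "left") "right" else "left"
  no_change <- other(change_side)
  side <- sample(c("left", "right"), 1)
  t <- 0; ev_aoi <- character(0); ev_dur <- numeric(0)
  # Dwell multipliers and release biases under detection; the baseline look
  # intensity is normalized per regime so that the realized switch rate per
  # looking second stays ~rate in both, keeping the capacity channel (which
  # shapes side occupancy, hence change preference) separate from the speed
  # channel (which sets the shift rate).
  a <- 1.8; b <- 0.6            # detect dwell multipliers: change / no-change
  p_stay_c <- 0.7; p_leave_nc <- 0.85
  pi_c <- p_leave_nc / (p_leave_nc + (1 - p_stay_c))  # stationary look share
  switch_frac <- pi_c * (1 - p_stay_c) + (1 - pi_c) * p_leave_nc
  dwell_mult <- pi_c * a + (1 - pi_c) * b
  base_mean <- if (detect) 1000 * switch_frac / (rate * dwell_mult)
               else 500 / rate
  while (t < duration_ms) {
    mult <- if (detect && side == change_side) a
            else if (detect && side == no_change) b else 1
    dur <- rexp(1, 1 / (base_mean * mult))
    ev_aoi <- c(ev_aoi, side); ev_dur <- c(ev_dur, dur); t <- t + dur
    if (t >= duration_ms) break
    if (runif(1) < p_away) {
      gap <- rexp(1, 1 / away_mean_ms)
      ev_aoi <- c(ev_aoi, "away"); ev_dur <- c(ev_dur, gap); t <- t + gap
    }
    p_to_change <- if (detect) (if (side == no_change) p_leave_nc else p_stay_c)
                   else 0.5
    side <- if (runif(1) < p_to_change) change_side else no_change
  }
  list(aoi = ev_aoi, dur = ev_dur)
}

#' Generate synthetic gaze trials
#'
#' For each participant-year, generates the full trial design (blocks
#' balanced over load and change side) and simulates each trial's AOI stream
#' from a two-state semi-Markov look process. A trial's load is "detected"
#' with probability increasing in (capacity - load), where capacity comes
#' from the truth ledger's cohort/year values shifted by the household's
#' exposure offset; detection biases dwells and releases toward the changing
#' display. The participant's switch intensity (and hence shift rate)
#' decreases linearly in the exposure offset via `beta_aqi_shift`. Streams
#' are sampled at the eye-tracker rate (or 30 fps for the video-coded trial
#' fraction) and samples are knocked out to "missing" at the configured
#' missingness rate.
#'
#' @param households data.frame from [generate_households()].
#' @param truth A [make_truth()] ledger.
#' @param cfg A [gen_config()].
#' @param seed Integer seed.
#' @param years Years to simulate (default both).
#' @param participants Optional subset of participant ids.
#' @return list of `gaze_trial` objects with metadata attached.
#' @export
generate_gaze_trials <- function(households, truth, cfg = gen_config(),
                                 seed = 1, years = c(1, 2),
                                 participants = NULL) {
  set.seed(seed)
  hh <- households
  if (!is.null(participants)) {
    if (!all(participants %in% hh$participant_id))
      stop("unknown participant id(s): ",
           paste(setdiff(participants, hh$participant_id), collapse = ", "))
    hh <- hh[hh$participant_id %in% participants, , drop = FALSE]
  }
  cp_per_item <- 0.05  # CP units per item of capacity, links cp betas to capacity
  out <- list()
  for (i in seq_len(nrow(hh))) {
    x <- truth$household_offsets[hh$household_id[i]]
    caps <- truth$capacity_by_age[[hh$cohort[i]]]
    rate_base <- truth$shift_intercept + truth$beta_aqi_shift * x +
      rnorm(1, 0, truth$shift_participant_sd)
    for (yr in years) {
      beta_cp <- if (yr == 1) truth$beta_aqi_cp_y1 else truth$beta_aqi_cp_y2
      cap_eff <- caps[yr] + (beta_cp / cp_per_item) * x
      design <- trial_design(yr, cfg)
      is_video <- runif(nrow(design)) < cfg$video_fraction
      for (j in seq_len(nrow(design))) {
        lvl <- LOAD_LEVELS[match(design$load[j],
                                 LOADS_BY_YEAR[[as.character(yr)]])]
        rate <- max(0.1, rate_base + truth$shift_load_eff[[lvl]] +
                      rnorm(1, 0, 0.05))
        detect <- runif(1) < plogis(1.5 * (cap_eff - design$load[j] + 0.5))
        ev <- simulate_trial_stream(10000, rate, detect, design$change_side[j])
        hz <- if (is_video[j]) 30 else cfg$sample_rate_hz
        t_ms <- seq(0, 10000 - 1000 / hz, by = 1000 / hz)
        bnd <- cumsum(c(0, ev$dur))
        aoi <- ev$aoi[pmin(findInterval(t_ms, bnd), length(ev$aoi))]
        aoi[runif(length(aoi)) < cfg$missingness_rate] <- "missing"
        out[[length(out) + 1]] <- gaze_trial(
          hh$participant_id[i], yr, design$trial_index[j],
          samples = data.frame(t_ms = t_ms, aoi = aoi,
                               stringsAsFactors = FALSE),
          load = design$load[j],
          load_level = LOAD_LEVELS[match(design$load[j],
                                         LOADS_BY_YEAR[[as.character(yr)]])],
          change_side = design$change_side[j],
          source_used = if (is_video[j]) "video" else "eyetracker")
      }
    }
  }
  out
}

#' Flatten gaze trials to the canonical CSV tables
#'
#' @param trials list of `gaze_trial`.
#' @return list with `samples` (long-form gaze CSV columns) and `trials`
#'   (metadata table).
#' @export
trials_to_tables <- function(trials) {
  samples <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id, year = tr$year,
               trial_index = tr$trial_index, t_ms = tr$samples$t_ms,
               aoi = tr$samples$aoi, source = tr$source_used,
               stringsAsFactors = FALSE)
  }))
  meta <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id, year = tr$year,
               trial_index = tr$trial_index, load = tr$load,
               change_side = tr$change_side, stringsAsFactors = FALSE)
  }))
  list(samples = samples, trials = meta)
}

#' Generate standardized assessment scores
#'
#' Year-1 scores emulate a cognitive composite T-score (population mean ~100)
#' and year-2 scores emulate questionnaire problem-solving / motor scores
#' (means ~30-37). Scores carry a positive SES effect
#' (`truth$beta_ses_assessment` points per SES unit), a small cohort effect,
#' Gaussian noise — and, by construction, a zero effect of household
#' exposure, the generator's null for the exposure-assessment analyses.
#'
#' @param households data.frame from [generate_households()].
#' @param truth A [make_truth()] ledger.
#' @param seed Integer seed.
#' @param noise_sd Named noise SDs for year-1 and year-2 measures.
#' @return data.frame with participant_id, household_id, year, measure,
#'   score.
#' @export
generate_assessments <- function(households, truth, seed = 1,
                                 noise_sd = c(mullen = 10, asq = 9)) {
  set.seed(seed)
  n <- nrow(households)
  ses_c <- households$ses_score - mean(households$ses_score)
  age_c <- ifelse(households$cohort == "9mo", 0.5, -0.5)
  b <- truth$beta_ses_assessment
  mk <- function(year, measure, intercept, age_eff, sd) {
    data.frame(participant_id = households$participant_id,
               household_id = households$household_id,
               year = year, measure = measure,
               score = intercept + b * ses_c + age_eff * age_c +
                 0 * truth$household_offsets[households$household_id] +
                 rnorm(n, 0, sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(mk(1, "mullen_composite", 101.3, -0.35, noise_sd[["mullen"]]),
        mk(2, "asq_problem_solving", 30.6, -5.5, noise_sd[["asq"]]),
        mk(2, "asq_fine_motor", 34.2, -5.7, noise_sd[["asq"]]),
        mk(2, "asq_gross_motor", 36.8, -8.2, noise_sd[["asq"]]))
}

#' Simulate analysis-cell score means directly (scaled generator)
#'
#' Bypasses the stream-level gaze simulation and draws the participant x
#' year x load-level cell means of the change-preference and shift-rate
#' scores directly from the truth ledger's linear model: fixed load, cohort
#' and exposure effects (the change-preference exposure effect being
#' year-specific), a participant random intercept, and cell-level residual
#' noise. This is the generator used for power / type-I-error simulations
#' where refitting mixed models hundreds of times on stream-level data would
#' be pointless.
#'
#' @param households data.frame from [generate_households()].
#' @param truth A [make_truth()] ledger.
#' @param seed Integer seed.
#' @param years Years to simulate.
#' @param beta_year_ses_std Optional standardized Year x SES interaction on
#'   both scores (units of the residual SD per (year-code x SES-z) unit);
#'   0 by default, set to ~0.3 in selection-power simulations.
#' @return data.frame with one row per participant x year x load level:
#'   cp (first-look no-change change preference), shift (shift rate),
#'   lw1 covariate, ses_score, cohort, and aqi (the true household offset,
#'   centered across the sample).
#' @export
simulate_score_table <- function(households, truth, seed = 1, years = c(1, 2),
                                 beta_year_ses_std = 0) {
  set.seed(seed)
  n <- nrow(households)
  x <- truth$household_offsets[households$household_id]
  x <- x - mean(x)
  ses_z <- (households$ses_score - mean(households$ses_score)) /
    max(sd(households$ses_score), 1e-9)
  age_c <- ifelse(households$cohort == "9mo", 0.5, -0.5)
  u_cp <- rnorm(n, 0, truth$cp_participant_sd)
  u_sh <- rnorm(n, 0, truth$shift_participant_sd)
  lw1 <- pmin(1, pmax(0, rnorm(n, 0.7, 0.12)))
  grid <- expand.grid(i = seq_len(n), year = years,
                      load_level = LOAD_LEVELS, stringsAsFactors = FALSE)
  i <- grid$i
  year_c <- ifelse(grid$year == 2, 0.5, -0.5)
  beta_cp_x <- ifelse(grid$year == 1, truth$beta_aqi_cp_y1, truth$beta_aqi_cp_y2)
  cp <- truth$cp_intercept + truth$cp_load_eff[grid$load_level] +
    truth$cp_age_eff * age_c[i] + beta_cp_x * x[i] + u_cp[i] +
    beta_year_ses_std * truth$cp_resid_sd * year_c * ses_z[i] +
    rnorm(nrow(grid), 0, truth$cp_resid_sd)
  shift <- truth$shift_intercept + truth$shift_load_eff[grid$load_level] +
    truth$shift_age_eff * age_c[i] + truth$beta_aqi_shift * x[i] + u_sh[i] +
    beta_year_ses_std * truth$shift_resid_sd * year_c * ses_z[i] +
    rnorm(nrow(grid), 0, truth$shift_resid_sd)
  data.frame(participant_id = households$participant_id[i],
             household_id = households$household_id[i],
             year = grid$year,
             cohort = households$cohort[i],
             ses_score = households$ses_score[i],
             load_level = grid$load_level,
             lw1 = lw1[i],
             aqi = as.numeric(x[i]),
             cp = pmin(1, pmax(0, cp)),
             shift = pmax(0, shift),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete synthetic study and write it to disk
#'
#' Runs every generator with seeds derived from one master seed and, when
#' `out_dir` is given, writes `households.csv`, `aqi_log.csv`,
#' `gaze_samples.csv`, `trials.csv`, `assessments.csv` and the ground-truth
#' ledger `truth.json`. Identical (config, seed) pairs produce identical
#' files.
#'
#' @param cfg A [gen_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional output directory (created if needed).
#' @param years Years of gaze data to simulate.
#' @return (invisibly) list with households, truth, aqi, trials, gaze
#'   tables, assessments.
#' @export
simulate_dataset <- function(cfg = gen_config(), seed = 1, out_dir = NULL,
                             years = c(1, 2)) {
  households <- generate_households(cfg$n_households, seed = seed)
  truth <- make_truth(households, seed = seed + 1)
  aqi <- generate_aqi_logs(households, cfg, truth, seed = seed + 2)
  trials <- generate_gaze_trials(households, truth, cfg, seed = seed + 3,
                                 years = years)
  tabs <- trials_to_tables(trials)
  assessments <- generate_assessments(households, truth, seed = seed + 4)
  res <- list(households = households, truth = truth, aqi = aqi,
              trials = trials, gaze_samples = tabs$samples,
              trial_meta = tabs$trials, assessments = assessments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(households, file.path(out_dir, "households.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(aqi, file.path(out_dir, "aqi_log.csv"),
              row.names = FALSE, quote = FALSE)
    write_gaze_csv(tabs$samples, file.path(out_dir, "gaze_samples.csv"))
    write.csv(tabs$trials, file.path(out_dir, "trials.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(assessments, file.path(out_dir, "assessments.csv"),
              row.names = FALSE, quote = FALSE)
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  invisible(res)
}
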