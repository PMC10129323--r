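test_that("household generation is seeded, validated, and SES-structured", {
  expect_error(generate_households(0), ">= 1")
  expect_identical(generate_households(3, seed = 7),
                   generate_households(3, seed = 7))
  hh <- generate_households(1000, seed = 1)
  p_lpg <- tapply(hh$cooking_fuel == "lpg", hh$ses_group, mean)
  expect_gt(p_lpg["high"], p_lpg["low"])
  # empirical fuel x SES table tracks the generator's own probability matrix
  hh2 <- generate_households(2000, seed = 2)
  probs <- gazecog:::fuel_probs_by_ses()
  for (g in c("high", "low")) {
    emp <- table(factor(hh2$cooking_fuel[hh2$ses_group == g],
                        levels = colnames(probs))) /
      sum(hh2$ses_group == g)
    expect_true(all(abs(emp - probs[g, ]) <= 0.05 + 1e-12))
  }
})

test_that("AQI log generation reflects fuel offsets, seasonality and meal peaks", {
  hh <- generate_households(80, seed = 3)
  tru <- make_truth(hh, seed = 4)
  cfg <- gen_config(n_households = 80, n_rounds = 1, sample_interval_s = 1800)
  logs <- generate_aqi_logs(hh, cfg, tru, seed = 5)
  expect_error(generate_aqi_logs(hh[0, ], cfg, tru), "nonempty")
  expect_true(all(logs$aqi >= 0))
  by_fuel <- tapply(logs$aqi, hh$cooking_fuel[match(logs$household_id,
                                                    hh$household_id)], mean)
  expect_gt(by_fuel["cow_dung"], by_fuel["lpg"])
  # degenerate config: flat terms and no noise give a constant series
  cfg0 <- gen_config(n_households = 1, n_rounds = 1, sample_interval_s = 3600,
                     seasonal_amplitude = 0, diurnal_amplitude = 0,
                     noise_sd = 0)
  tru0 <- make_truth(hh[1, , drop = FALSE], seed = 1,
                     fuel_offsets = c(cow_dung = 0, wood = 0, lpg = 0),
                     offset_ses_slope = 0, offset_noise_sd = 0)
  flat <- generate_aqi_logs(hh[1, , drop = FALSE], cfg0, tru0, seed = 1)
  expect_true(all(flat$aqi == cfg0$baseline_aqi))
  # hourly means peak at the configured meal hours
  cfg1 <- gen_config(n_households = 1, n_rounds = 6, round_days = 3,
                     sample_interval_s = 900, noise_sd = 0,
                     seasonal_amplitude = 0,
                     diurnal_peak_hours = c(7, 18))
  one <- generate_aqi_logs(hh[1, , drop = FALSE], cfg1, tru0, seed = 2)
  hm <- downsample_hourly(one)
  prof <- tapply(hm$aqi_mean, hm$hour, mean)
  top2 <- as.integer(names(sort(prof, decreasing = TRUE)))[1:2]
  expect_setequal(top2, c(7, 18))
})

test_that("marginal AQI mean converges to baseline plus mean offset", {
  hh <- generate_households(60, seed = 9)
  tru <- make_truth(hh, seed = 10)
  cfg <- gen_config(n_households = 60, n_rounds = 2, sample_interval_s = 600,
                    seasonal_amplitude = 0, diurnal_amplitude = 0)
  logs <- generate_aqi_logs(hh, cfg, tru, seed = 11)
  expected <- cfg$baseline_aqi + mean(tru$household_offsets)
  expect_lt(abs(mean(logs$aqi) - expected) / expected, 0.01)
})

test_that("gaze trial generation respects the design and the missingness switch", {
  hh <- generate_households(4, seed = 12)
  tru <- make_truth(hh, seed = 13)
  cfg <- gen_config(n_households = 4, trial_count = 36, blocks = 6,
                    sample_rate_hz = 50, missingness_rate = 0)
  expect_error(generate_gaze_trials(hh, tru, cfg, participants = "nope"),
               "unknown participant")
  trials <- generate_gaze_trials(hh, tru, cfg, seed = 14, years = 2,
                                 participants = hh$participant_id[1])
  expect_length(trials, 36)
  loads <- vapply(trials, function(tr) tr$load, 1L)
  sides <- vapply(trials, function(tr) tr$change_side, "")
  expect_equal(sort(unique(loads)), c(2L, 4L, 6L))
  expect_equal(as.integer(table(loads)), rep(12L, 3))  # loads balanced
  expect_equal(as.integer(table(sides)), rep(18L, 2))  # sides balanced
  expect_false(any(vapply(trials,
                          function(tr) any(tr$samples$aoi == "missing"),
                          TRUE)))
  # duration always 10 s; AOI labels closed
  expect_true(all(vapply(trials, function(tr)
    max(tr$samples$t_ms) < 10000 && all(tr$samples$aoi %in% AOI_LEVELS),
    TRUE)))
})

test_that("high-capacity no-change starters prefer the changing display", {
  hh <- generate_households(30, seed = 15)
  tru <- make_truth(hh, seed = 16,
                    fuel_offsets = c(cow_dung = 0, wood = 0, lpg = 0),
                    offset_ses_slope = 0, offset_noise_sd = 0,
                    capacity_by_age = list(`6mo` = c(9, 9), `9mo` = c(9, 9)))
  cfg <- gen_config(n_households = 30, trial_count = 36, blocks = 6,
                    sample_rate_hz = 50, missingness_rate = 0)
  trials <- generate_gaze_trials(hh, tru, cfg, seed = 17, years = 1)
  sc <- score_dataset(trials)$scores
  # detection drives infants off the static display quickly, so no-change
  # starters are the minority of classified trials
  nc <- sc[sc$first_look == "no_change" & !is.na(sc$change_preference), ]
  expect_gt(nrow(nc), 100)
  expect_gt(mean(nc$change_preference), 0.5)
})

test_that("shift rate recovers the negative exposure slope at large n", {
  hh <- generate_households(250, seed = 18)
  tru <- make_truth(hh, seed = 19)
  cfg <- gen_config(n_households = 250, trial_count = 6, blocks = 1,
                    sample_rate_hz = 50)
  trials <- generate_gaze_trials(hh, tru, cfg, seed = 20, years = 1)
  sc <- score_dataset(trials)$scores
  pm <- aggregate(shift_rate ~ participant_id, sc, mean, na.rm = TRUE)
  pm$offset <- tru$household_offsets[sub("^p", "h", pm$participant_id)]
  expect_lt(coef(lm(shift_rate ~ offset, pm))[2], 0)
})

test_that("assessment scores carry the SES effect and a null exposure effect", {
  hh <- generate_households(400, seed = 21)
  tru <- make_truth(hh, seed = 22)
  # degenerate: no SES effect, no noise -> intercept only
  tru0 <- tru; tru0$beta_ses_assessment <- 0
  a0 <- generate_assessments(hh, tru0, seed = 23,
                             noise_sd = c(mullen = 0, asq = 0))
  m0 <- a0[a0$measure == "mullen_composite", ]
  expect_true(all(abs(m0$score - (101.3 - 0.35 *
                                    ifelse(hh$cohort == "9mo", .5, -.5))) < 1e-9))
  # SES coefficient recovered within 2 SE at large n
  a <- generate_assessments(hh, tru, seed = 24)
  d <- merge(a[a$measure == "mullen_composite", ], hh, by = "participant_id")
  d$ses_c <- d$ses_score - mean(d$ses_score)
  fit <- summary(lm(score ~ ses_c, d))$coefficients
  expect_lt(abs(fit["ses_c", 1] - tru$beta_ses_assessment),
            2 * fit["ses_c", 2])
  # exposure slope is null by construction
  d$off <- tru$household_offsets[d$household_id.y]
  p_off <- summary(lm(score ~ ses_c + off, d))$coefficients["off", 4]
  expect_gt(p_off, 0.01)
})

test_that("the truth ledger survives a JSON round trip", {
  hh <- generate_households(5, seed = 25)
  tru <- make_truth(hh, seed = 26)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(tru, f)
  back <- read_truth(f)
  expect_equal(back$household_offsets, tru$household_offsets)
  expect_equal(back$beta_aqi_shift, tru$beta_aqi_shift)
  expect_equal(unname(unlist(back$capacity_by_age)),
               unname(unlist(tru$capacity_by_age)))
})

test_that("a simulated dataset is written completely and deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- gen_config(n_households = 3, n_rounds = 1, sample_interval_s = 3600,
                    trial_count = 6, blocks = 1, sample_rate_hz = 30)
  simulate_dataset(cfg, seed = 5, out_dir = dir1, years = 1)
  simulate_dataset(cfg, seed = 5, out_dir = dir2, years = 1)
  files <- c("households.csv", "aqi_log.csv", "gaze_samples.csv",
             "trials.csv", "assessments.csv", "truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)), label = f)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = paste("determinism of", f))
  }
})
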