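cell_data <- function(n = 120, seed = 41, ...) {
  hh <- generate_households(n, seed = seed)
  tru <- make_truth(hh, seed = seed + 1)
  list(hh = hh, tru = tru,
       d = simulate_score_table(hh, tru, seed = seed + 2, ...))
}

test_that("predictor coding follows the difference / sum-to-zero scheme", {
  cd <- code_predictors(cell_data()$d)
  d <- cd$data
  expect_setequal(unique(d$Year), c(-0.5, 0.5))
  expect_setequal(unique(d$Age), c(-0.5, 0.5))
  expect_equal(mean(d$SES), 0, tolerance = 1e-10)
  cm <- contrasts(d$Load)
  expect_equal(colSums(cm), c(0, 0), ignore_attr = TRUE)  # columns sum to zero
  expect_equal(rowSums(cm), c(1, 1, -2), ignore_attr = TRUE)
  bad <- cell_data()$d; bad$load_level[1] <- "extreme"
  expect_error(code_predictors(bad), "unknown load_level")
})

test_that("forward selection keeps only candidates that improve fit", {
  cc <- cell_data(200, seed = 43)
  coded <- code_predictors(cc$d)$data
  # no candidates: main effects only
  m0 <- build_baseline(coded, "shift", main_effects = c("Year", "Load", "SES", "Age"))
  expect_equal(m0$terms, c("Year", "Load", "SES", "Age"))
  # marginality: a 3-way candidate is not tested without its 2-way parents
  m1 <- build_baseline(coded, "shift",
                       main_effects = c("Year", "Load", "SES", "Age"),
                       candidates = c("Year:SES:Age"))
  expect_true(is.na(m1$selection$p[m1$selection$candidate == "Year:SES:Age"]))
  expect_false(m1$selection$kept[1])
  # a strong true interaction is retained
  cc2 <- cell_data(200, seed = 44, beta_year_ses_std = 0.5)
  coded2 <- code_predictors(cc2$d)$data
  m2 <- build_baseline(coded2, "cp",
                       main_effects = c("Year", "Load", "SES", "Age"),
                       candidates = c("Year:SES"))
  expect_true(m2$selection$kept[m2$selection$candidate == "Year:SES"])
  expect_true("Year:SES" %in% m2$terms)
})

test_that("type-3 Wald tests match the t-statistics and an independent quadratic form", {
  cc <- cell_data(150, seed = 45)
  coded <- code_predictors(cc$d)$data
  m <- build_baseline(coded, "shift", main_effects = c("Year", "Load", "SES", "Age"))
  w <- wald_type3(m)
  ct <- coef_table(m)
  # single-df terms: chi-squared equals t^2
  for (tm in c("Year", "SES", "Age")) {
    expect_equal(w$chisq[w$term == tm],
                 ct$`t value`[ct$term == tm]^2, tolerance = 1e-8)
  }
  # multi-df Load term: brute-force quadratic form from the full covariance
  b <- lme4::fixef(m$fit)
  V <- as.matrix(vcov(m$fit))
  idx <- grep("^Load", names(b))
  chi_brute <- drop(t(b[idx]) %*% solve(V[idx, idx]) %*% b[idx])
  expect_equal(w$chisq[w$term == "Load"], chi_brute, tolerance = 1e-10)
  expect_equal(w$df[w$term == "Load"], 2)
  # cross-check against car's type-III Wald machinery
  skip_if_not_installed("car")
  ca <- car::Anova(m$fit, type = 3)
  expect_equal(w$chisq, ca[w$term, "Chisq"], tolerance = 1e-6)
})

test_that("partial eta-squared uses the term's error df", {
  cc <- cell_data(150, seed = 46)
  coded <- code_predictors(cc$d)$data
  m <- build_baseline(coded, "shift", main_effects = c("Year", "Load", "SES", "Age"))
  w <- wald_type3(m)
  i <- which(w$term == "SES")
  expect_equal(w$eta2_partial[i], w$chisq[i] / (w$chisq[i] + w$df_error[i]))
  expect_true(all(w$eta2_partial >= 0 & w$eta2_partial <= 1))
})

test_that("type-3 and sequential tests agree on a balanced orthogonal design", {
  set.seed(47)
  d <- expand.grid(Load = factor(c("low", "medium", "high"),
                                 levels = c("low", "medium", "high")),
                   Year = c(-0.5, 0.5), rep = 1:40)
  contrasts(d$Load) <- contr.sum(3)
  d$y <- 0.6 + 0.05 * (d$Load == "low") + 0.02 * d$Year + rnorm(nrow(d), 0, 0.1)
  fit <- lm(y ~ Year + Load, data = d)
  w <- wald_type3(fit)
  seq_f <- anova(fit)  # sequential; orthogonal design makes orders agree
  f_load <- seq_f["Load", "F value"]
  expect_equal(w$chisq[w$term == "Load"] / w$df[w$term == "Load"], f_load,
               tolerance = 1e-8)
})

test_that("adding air quality augments the model and records the comparison", {
  cc <- cell_data(200, seed = 48)
  coded <- code_predictors(cc$d)$data
  base <- build_baseline(coded, "shift",
                         main_effects = c("Year", "Load", "SES", "Age"))
  aug <- add_air_quality(base, coded)
  expect_true("AQI" %in% aug$terms)
  ct <- coef_table(aug)
  expect_lt(ct$Estimate[ct$term == "AQI"], 0)
  expect_gte(aug$comparison$chisq, 0)
  expect_equal(aug$comparison$df,
               1 + as.integer(isTRUE(aug$year_aqi$kept)))
  # degenerate exposure flagged
  coded0 <- coded; coded0$AQI <- 0
  expect_warning(add_air_quality(base, coded0), "constant")
})

test_that("a year-1-specific CP effect makes the Year x AQI interaction worth keeping", {
  kept <- logical(20)
  for (r in seq_len(20)) {
    hh <- generate_households(200, seed = 400 + r)
    tru <- make_truth(hh, seed = 500 + r, beta_aqi_cp_y1 = -2e-3,
                      beta_aqi_cp_y2 = 0)
    d <- simulate_score_table(hh, tru, seed = 600 + r)
    coded <- code_predictors(d)$data
    base <- build_baseline(coded, "cp",
                           main_effects = c("Year", "Load", "SES", "Age"))
    aug <- add_air_quality(base, coded)
    kept[r] <- isTRUE(aug$year_aqi$kept)
  }
  expect_gt(mean(kept), 0.5)
})

test_that("cross-covariate refits keep separate exposure channels and flag duplicates", {
  cc <- cell_data(200, seed = 49)
  coded <- code_predictors(cc$d)$data
  base_cp <- build_baseline(coded, "cp",
                            main_effects = c("Year", "Load", "SES", "Age"))
  base_sh <- build_baseline(coded, "shift",
                            main_effects = c("Year", "Load", "SES", "Age"))
  aug_cp <- add_air_quality(base_cp, coded)
  aug_sh <- add_air_quality(base_sh, coded, test_year_interaction = FALSE)
  rob <- robustness_cross_covariate(aug_cp, aug_sh, coded)
  expect_false(any(rob$collinear))
  expect_true("AQI" %in% rob$shift_wald$term)
  # orthogonal covariate leaves the AQI coefficient essentially unchanged
  sh_aqi_with <- lme4::fixef(rob$shift_fit)["AQI"]
  sh_aqi_without <- lme4::fixef(aug_sh$fit)["AQI"]
  expect_equal(unname(sh_aqi_with), unname(sh_aqi_without), tolerance = 0.25)
  # duplicated outcome is flagged collinear
  dup <- coded; dup$cp <- dup$shift
  # deliberately collinear refit; convergence chatter is expected
  rob2 <- suppressWarnings(robustness_cross_covariate(aug_cp, aug_sh, dup))
  expect_true(all(rob2$collinear))
})

test_that("the load-matched analysis uses exactly the absolute load-2 cells", {
  cc <- cell_data(120, seed = 50)
  coded <- code_predictors(cc$d)$data
  lm2 <- load_matched_analysis(coded)
  n_expect <- sum((coded$year == 1 & coded$load_level == "medium") |
                    (coded$year == 2 & coded$load_level == "low"))
  expect_equal(lm2$n, n_expect)
  expect_equal(rownames(lm2$year_aqi_f), "Year:AQI")
  only13 <- coded[coded$year == 1 & coded$load_level %in% c("low", "high"), ]
  expect_error(load_matched_analysis(only13), "load-2")
})

test_that("assessment models recover SES and keep the exposure null", {
  hh <- generate_households(300, seed = 51)
  tru <- make_truth(hh, seed = 52)
  assess <- generate_assessments(hh, tru, seed = 53)
  exposure <- data.frame(household_id = hh$household_id,
                         exposure_score = unname(tru$household_offsets -
                                                   mean(tru$household_offsets)),
                         grand_mean = 200)
  fits <- fit_assessment_models(assess, hh, exposure)
  expect_setequal(names(fits),
                  c("mullen_composite", "asq_problem_solving",
                    "asq_fine_motor", "asq_gross_motor"))
  ct <- fits$mullen_composite$baseline_coefs
  ses <- ct[ct$term == "SES", ]
  expect_lt(abs(ses$Estimate - tru$beta_ses_assessment),
            2 * ses$`Std. Error`)
  aq <- fits$asq_problem_solving$augmented_coefs
  expect_gt(aq$`Pr(>|t|)`[aq$term == "AQI"], 0.05)
  # zero-noise, zero-effect data: slopes exactly 0
  tru0 <- tru; tru0$beta_ses_assessment <- 0
  a0 <- generate_assessments(hh, tru0, seed = 54,
                             noise_sd = c(mullen = 0, asq = 0))
  a0 <- a0[a0$measure == "mullen_composite", ]
  # zero-residual fit by construction; lm warns about the perfect fit
  f0 <- suppressWarnings(fit_assessment_models(a0, hh))
  cf <- f0$mullen_composite$baseline_coefs
  expect_equal(cf$Estimate[cf$term == "SES"], 0, tolerance = 1e-10)
})
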