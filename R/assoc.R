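#' Code predictors for the association models
#'
#' Applies the coding scheme the models expect: two-level Year and Age
#' cohort are difference-coded (-0.5/+0.5, so each coefficient is the
#' between-level difference), SES is centered at the sample mean, and load
#' level enters as a three-level factor with sum-to-zero contrasts whose two
#' columns appear as `Load1`/`Load2` in model output. LookingWindow1 and the
#' exposure score pass through as `LW1` and `AQI` when present.
#'
#' @param data data.frame with columns `year` (1/2), `cohort` ("6mo"/"9mo"),
#'   `ses_score`, `load_level` ("low"/"medium"/"high"), optionally `lw1` and
#'   `aqi`.
#' @return list with `data` (coded columns added: Year, Age, SES, Load, and
#'   LW1/AQI when available) and `report` (the mappings applied).
#' @export
code_predictors <- function(data) {
  req <- c("year", "cohort", "ses_score", "load_level")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(data$year %in% c(1, 2))) stop("year must be 1 or 2")
  if (!all(data$cohort %in% c("6mo", "9mo")))
    stop("cohort must be '6mo' or '9mo'")
  if (!all(data$load_level %in% LOAD_LEVELS))
    stop("unknown load_level value(s): ",
         paste(setdiff(unique(data$load_level), LOAD_LEVELS), collapse = ", "))
  d <- data
  d$Year <- ifelse(d$year == 2, 0.5, -0.5)
  d$Age <- ifelse(d$cohort == "9mo", 0.5, -0.5)
  ses_mean <- mean(d$ses_score, na.rm = TRUE)
  d$SES <- d$ses_score - ses_mean
  d$Load <- factor(d$load_level, levels = LOAD_LEVELS)
  contrasts(d$Load) <- contr.sum(3)
  if ("lw1" %in% names(d)) d$LW1 <- d$lw1
  if ("aqi" %in% names(d)) d$AQI <- d$aqi
  report <- list(Year = c(`1` = -0.5, `2` = 0.5),
                 Age = c(`6mo` = -0.5, `9mo` = 0.5),
                 SES_center = ses_mean,
                 Load = "sum-to-zero contrasts over low/medium/high (Load1, Load2)")
  list(data = d, report = report)
}

fit_terms <- function(outcome, fe_terms, data, random = NULL, reml = TRUE) {
  rhs <- if (length(fe_terms)) paste(fe_terms, collapse = " + ") else "1"
  if (is.null(random)) {
    lm(as.formula(paste(outcome, "~", rhs)), data = data)
  } else {
    f <- as.formula(paste(outcome, "~", rhs, "+ (1 |", random, ")"))
    lmerTest::lmer(f, data = data, REML = reml)
  }
}

interaction_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

marginality_ok <- function(candidate, current_terms) {
  comp <- strsplit(candidate, ":", fixed = TRUE)[[1]]
  k <- length(comp)
  if (k < 2) return(all(comp %in% current_terms))
  subs <- utils::combn(comp, k - 1, FUN = paste, collapse = ":")
  norm <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                             function(p) paste(sort(p), collapse = ":"), "")
  all(norm(subs) %in% norm(current_terms))
}

#' Build a baseline model by forward interaction selection
#'
#' Starts from a model with all main effects and introduces candidate
#' interactions in order (all two-way before three-way before four-way),
#' retaining a candidate only when a likelihood-ratio comparison of
#' maximum-likelihood fits improves the model at `alpha`, and only testing
#' candidates whose constituent lower-order terms are already present. The
#' selected model is refit by REML (mixed models) for reporting.
#'
#' @param data Coded data (from [code_predictors()]).
#' @param outcome Outcome column name.
#' @param main_effects Character vector of main-effect terms.
#' @param candidates Character vector of candidate interaction terms (e.g.
#'   `"Year:SES"`); tested in increasing interaction order.
#' @param alpha Selection threshold for the likelihood-ratio p-value (0.05).
#' @param random Grouping variable for the participant random intercept, or
#'   NULL for a plain linear model.
#' @return An object of class `gc_model`: the reporting fit, the selected
#'   terms, and a selection log (candidate, chisq, df, p, kept).
#' @export
build_baseline <- function(data, outcome,
                           main_effects = c("Year", "Load", "SES", "LW1", "Age"),
                           candidates = character(),
                           alpha = 0.05, random = "participant_id") {
  main_effects <- intersect(main_effects, names(data))
  data <- data[complete.cases(data[, c(outcome, main_effects), drop = FALSE]), ,
               drop = FALSE]
  terms_now <- main_effects
  if (length(candidates))
    candidates <- candidates[order(interaction_order(candidates))]
  cur <- fit_terms(outcome, terms_now, data, random, reml = FALSE)
  sel <- data.frame(candidate = character(), chisq = numeric(),
                    df = numeric(), p = numeric(), kept = logical(),
                    stringsAsFactors = FALSE)
  for (cand in candidates) {
    if (!marginality_ok(cand, terms_now)) {
      sel <- rbind(sel, data.frame(candidate = cand, chisq = NA, df = NA,
                                   p = NA, kept = FALSE))
      next
    }
    trial_fit <- fit_terms(outcome, c(terms_now, cand), data, random,
                           reml = FALSE)
    # ML likelihood-ratio test; both fits are ML so logLik is comparable
    chisq <- as.numeric(2 * (logLik(trial_fit) - logLik(cur)))
    df <- attr(logLik(trial_fit), "df") - attr(logLik(cur), "df")
    p <- pchisq(max(chisq, 0), df, lower.tail = FALSE)
    kept <- is.finite(p) && p < alpha
    sel <- rbind(sel, data.frame(candidate = cand, chisq = chisq, df = df,
                                 p = p, kept = kept))
    if (kept) { terms_now <- c(terms_now, cand); cur <- trial_fit }
  }
  fit <- fit_terms(outcome, terms_now, data, random, reml = TRUE)
  structure(list(fit = fit, outcome = outcome, terms = terms_now,
                 main_effects = main_effects, selection = sel,
                 random = random, alpha = alpha, data = data),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model:", x$outcome, "~", paste(x$terms, collapse = " + "),
      if (!is.null(x$random)) paste0("+ (1|", x$random, ")"), ">\n")
  print(coef_table(x), digits = 3)
  invisible(x)
}

#' Coefficient table with Satterthwaite degrees of freedom
#'
#' The reporting layout: Estimate, Std. Error, DF, t value, Pr(>|t|).
#' Mixed-model p-values use Satterthwaite's method; plain linear models
#' report residual df.
#'
#' @param model A `gc_model` or a fitted (merMod/lm) object.
#' @return data.frame, one row per coefficient.
#' @export
coef_table <- function(model) {
  fit <- if (inherits(model, "gc_model")) model$fit else model
  if (inherits(fit, "lmerModLmerTest")) {
    ct <- as.data.frame(coef(summary(fit)))
    names(ct) <- c("Estimate", "Std. Error", "DF", "t value", "Pr(>|t|)")
  } else {
    ct <- as.data.frame(coef(summary(fit)))
    ct <- cbind(ct[, 1:2, drop = FALSE], DF = stats::df.residual(fit),
                ct[, 3:4, drop = FALSE])
    names(ct) <- c("Estimate", "Std. Error", "DF", "t value", "Pr(>|t|)")
  }
  ct$term <- rownames(ct)
  rownames(ct) <- NULL
  ct[, c("term", "Estimate", "Std. Error", "DF", "t value", "Pr(>|t|)")]
}

#' Type-3 Wald chi-squared tests and partial eta-squared per term
#'
#' For every fixed-effect term, tests all of its coefficients jointly with
#' the quadratic form `b' V^-1 b` over the term's rows of the coefficient
#' covariance — the type-3 Wald test under the package's sum-to-zero /
#' difference coding. Partial eta-squared is computed from the chi-squared
#' and the term's (Satterthwaite) error df as
#' `chi2 / (chi2 + df_error)`. Terms whose covariance block is singular are
#' flagged rather than skipped.
#'
#' @param model A `gc_model` or fitted merMod / lm.
#' @return data.frame with term, chisq, df, p, df_error, eta2_partial,
#'   singular flag.
#' @export
wald_type3 <- function(model) {
  fit <- if (inherits(model, "gc_model")) model$fit else model
  if (inherits(fit, "merMod")) {
    b <- lme4::fixef(fit)
  } else {
    b <- coef(fit)
  }
  X <- model.matrix(fit)
  V <- as.matrix(vcov(fit))
  asn <- attr(X, "assign")
  labels <- attr(terms(fit), "term.labels")
  ct <- coef_table(model)
  out <- lapply(seq_along(labels), function(ti) {
    idx <- which(asn == ti)
    bi <- b[idx]
    Vi <- V[idx, idx, drop = FALSE]
    singular <- !is.finite(rcond(Vi)) || rcond(Vi) < 1e-12
    chisq <- if (singular) NA_real_
             else as.numeric(t(bi) %*% solve(Vi) %*% bi)
    df <- length(idx)
    df_err <- mean(ct$DF[match(names(b)[idx], ct$term)])
    p <- if (singular) NA_real_ else pchisq(chisq, df, lower.tail = FALSE)
    data.frame(term = labels[ti], chisq = chisq, df = df, p = p,
               df_error = df_err,
               eta2_partial = if (singular) NA_real_
                              else chisq / (chisq + df_err),
               singular = singular, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Add the air-quality exposure term to a baseline model
#'
#' Adds the centered household exposure score (`AQI`, in AQI units) as a
#' main effect, then tests a Year x AQI interaction by likelihood-ratio
#' comparison of maximum-likelihood fits, keeping it only when it improves
#' fit at `alpha`. The returned model carries a comparison record (chisq,
#' df, p) of the full baseline-vs-augmented test — the variance-explained
#' comparison.
#'
#' @param baseline A `gc_model` from [build_baseline()].
#' @param data Coded data containing an `AQI` column (rows without exposure
#'   are dropped with a warning).
#' @param alpha Threshold for keeping Year x AQI (0.05).
#' @param test_year_interaction Whether to test Year x AQI (default TRUE).
#' @return A `gc_model` with extra fields `comparison` (baseline vs
#'   augmented) and `year_aqi` (the interaction test record).
#' @export
add_air_quality <- function(baseline, data, alpha = 0.05,
                            test_year_interaction = TRUE) {
  stopifnot(inherits(baseline, "gc_model"))
  if (!"AQI" %in% names(data)) stop("data must contain an AQI column")
  n0 <- nrow(data)
  keep <- complete.cases(data[, c(baseline$outcome, baseline$main_effects,
                                  "AQI"), drop = FALSE])
  if (any(!keep))
    warning(sum(!keep), " row(s) without exposure or outcome dropped")
  data <- data[keep, , drop = FALSE]
  if (var(data$AQI) < .Machine$double.eps)
    warning("exposure scores are constant; AQI coefficient is degenerate")
  random <- baseline$random
  m_base <- fit_terms(baseline$outcome, baseline$terms, data, random,
                      reml = FALSE)
  terms_aug <- c(baseline$terms, "AQI")
  m_aqi <- fit_terms(baseline$outcome, terms_aug, data, random, reml = FALSE)
  year_aqi <- NULL
  if (test_year_interaction && "Year" %in% baseline$terms) {
    m_int <- fit_terms(baseline$outcome, c(terms_aug, "Year:AQI"), data,
                       random, reml = FALSE)
    cmp <- anova(m_aqi, m_int)
    year_aqi <- data.frame(candidate = "Year:AQI", chisq = cmp$Chisq[2],
                           df = cmp$Df[2], p = cmp$`Pr(>Chisq)`[2],
                           kept = is.finite(cmp$`Pr(>Chisq)`[2]) &&
                             cmp$`Pr(>Chisq)`[2] < alpha)
    if (year_aqi$kept) {
      terms_aug <- c(terms_aug, "Year:AQI")
      m_aqi <- m_int
    }
  }
  cmp_full <- anova(m_base, m_aqi)
  comparison <- data.frame(chisq = cmp_full$Chisq[2], df = cmp_full$Df[2],
                           p = cmp_full$`Pr(>Chisq)`[2])
  fit <- fit_terms(baseline$outcome, terms_aug, data, random, reml = TRUE)
  structure(list(fit = fit, outcome = baseline$outcome, terms = terms_aug,
                 main_effects = c(baseline$main_effects, "AQI"),
                 selection = baseline$selection, random = random,
                 alpha = alpha, data = data,
                 comparison = comparison, year_aqi = year_aqi),
            class = "gc_model")
}

#' Cross-covariate robustness refits
#'
#' The change-preference and shift-rate scores come from the same trials and
#' are correlated; to check that their exposure associations are separate
#' effects, each model is refit with the other score as a covariate. A
#' near-duplicate covariate (|r| with the outcome > 0.99) is flagged as
#' collinear.
#'
#' @param cp_model,shift_model `gc_model`s for the two outcomes.
#' @param data Coded data containing both outcome columns.
#' @return list with `cp_fit`, `shift_fit` (refits with the cross
#'   covariate), their Wald tables, and `collinear` flags.
#' @export
robustness_cross_covariate <- function(cp_model, shift_model, data) {
  oc_cp <- cp_model$outcome; oc_sh <- shift_model$outcome
  stopifnot(all(c(oc_cp, oc_sh) %in% names(data)))
  cc <- complete.cases(data[, c(oc_cp, oc_sh)])
  d <- data[cc, , drop = FALSE]
  collinear <- c(cp = FALSE, shift = FALSE)
  r <- abs(cor(d[[oc_cp]], d[[oc_sh]]))
  if (r > 0.99) collinear[] <- TRUE
  cp_fit <- fit_terms(oc_cp, c(cp_model$terms, oc_sh), d, cp_model$random,
                      reml = TRUE)
  shift_fit <- fit_terms(oc_sh, c(shift_model$terms, oc_cp), d,
                         shift_model$random, reml = TRUE)
  list(cp_fit = cp_fit, shift_fit = shift_fit,
       cp_wald = wald_type3(cp_fit), shift_wald = wald_type3(shift_fit),
       collinear = collinear)
}

#' Load-matched (absolute load 2) change-preference analysis
#'
#' Restricts to trials with two items per display — the "medium" level in
#' year 1 and the "low" level in year 2, so the stimuli are identical across
#' years — and refits the change-preference model with a Year x AQI
#' interaction, reporting its F-type test (Satterthwaite denominator df).
#'
#' @param data Coded data with `year`, `load_level`, outcome and `AQI`.
#' @param outcome Outcome column (default "cp").
#' @param random Random-intercept grouping variable.
#' @return list with the fit, the subset size, and the Year x AQI F-test row.
#' @export
load_matched_analysis <- function(data, outcome = "cp",
                                  random = "participant_id") {
  sub <- data[(data$year == 1 & data$load_level == "medium") |
                (data$year == 2 & data$load_level == "low"), , drop = FALSE]
  sub <- sub[complete.cases(sub[, c(outcome, "Year", "SES", "Age", "AQI")]), ,
             drop = FALSE]
  if (nrow(sub) == 0)
    stop("no absolute load-2 rows in data; cannot run load-matched analysis")
  fit <- fit_terms(outcome, c("Year", "SES", "Age", "AQI", "Year:AQI"),
                   sub, random, reml = TRUE)
  an <- as.data.frame(anova(fit))  # Satterthwaite F tests (lmerTest)
  ia <- an[rownames(an) == "Year:AQI", , drop = FALSE]
  list(fit = fit, n = nrow(sub), year_aqi_f = ia)
}

#' Baseline and exposure-augmented assessment models
#'
#' Plain linear models for the standardized assessment scores: each measure
#' is modelled as `score ~ Age + SES` (baseline) and `score ~ Age + SES +
#' AQI` (augmented). One score per participant-year, no random effects.
#'
#' @param assessments data.frame with participant_id, measure, score.
#' @param households data.frame with participant_id, ses_score, cohort.
#' @param exposure Optional data.frame from [extract_exposure()] plus a
#'   household_id column in `assessments` or `households` to join on; when
#'   supplied the augmented models are fit.
#' @return named list per measure: `baseline` and (optionally) `augmented`
#'   lm fits with their coefficient tables.
#' @export
fit_assessment_models <- function(assessments, households, exposure = NULL) {
  d <- merge(assessments,
             households[, c("participant_id", "household_id", "ses_score",
                            "cohort")],
             by = "participant_id", suffixes = c("", ".hh"))
  d$Age <- ifelse(d$cohort == "9mo", 0.5, -0.5)
  d$SES <- d$ses_score - mean(d$ses_score)
  if (!is.null(exposure))
    d <- merge(d, exposure[, c("household_id", "exposure_score")],
               by = "household_id")
  out <- list()
  for (m in unique(d$measure)) {
    dm <- d[d$measure == m, , drop = FALSE]
    base <- lm(score ~ Age + SES, data = dm)
    res <- list(baseline = base, baseline_coefs = coef_table(base))
    if (!is.null(exposure)) {
      dm$AQI <- dm$exposure_score
      aug <- lm(score ~ Age + SES + AQI, data = dm)
      res$augmented <- aug
      res$augmented_coefs <- coef_table(aug)
    }
    out[[m]] <- res
  }
  out
}

#' Flatten a fitted model to a summary list (for JSON export)
#'
#' @param model A `gc_model`.
#' @return list with coefficient table, Wald table, selection log,
#'   log-likelihood, AIC, sizes, and any comparison records.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "gc_model"))
  fit <- model$fit
  n_groups <- if (inherits(fit, "merMod"))
    unname(lme4::ngrps(fit)[1]) else NA_integer_
  list(outcome = model$outcome,
       terms = model$terms,
       coefficients = coef_table(model),
       wald_type3 = wald_type3(model),
       selection = model$selection,
       comparison = model$comparison,
       year_aqi = model$year_aqi,
       loglik = as.numeric(logLik(fit)),
       aic = AIC(fit),
       n_obs = stats::nobs(fit),
       n_groups = n_groups)
}
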