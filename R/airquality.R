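# ISO-8601 instants with or without a numeric zone offset; wall-clock values
# are interpreted (and offset values displayed) in the fixed study zone.
parse_iso8601 <- function(x, tz = "Asia/Kolkata") {
  ts <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%S%z")
  noz <- is.na(ts)
  if (any(noz))
    ts[noz] <- as.POSIXct(x[noz], tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) stop("unparseable ISO-8601 timestamp(s), e.g. ",
                      x[which(is.na(ts))[1]])
  ts
}

#' Round-level coverage quality control
#'
#' A household-round is retained only if it has at least `min_hours` of
#' recorded data. Coverage is computed from the sample count at the nominal
#' device cadence (`n_samples * sample_interval_s / 3600`), so a full 3-day
#' round at 10 s cadence carries 72 h. The boundary is inclusive: exactly
#' `min_hours` is retained.
#'
#' @param records data.frame of device readings with columns `household_id`,
#'   `round_index`, `timestamp`, `aqi` (and optionally `device_id`).
#' @param min_hours Minimum recorded hours per round (default 5).
#' @param sample_interval_s Nominal sampling cadence in seconds (default 10).
#' @return list with `records` (retained rows) and `report` (one row per
#'   household-round: coverage hours and whether it was retained).
#' @export
qc_rounds <- function(records, min_hours = 5, sample_interval_s = 10) {
  stopifnot(all(c("household_id", "round_index", "aqi") %in% names(records)))
  key <- interaction(records$household_id, records$round_index, drop = TRUE)
  n <- tapply(records$aqi, key, length)
  cov_h <- as.numeric(n) * sample_interval_s / 3600
  info <- do.call(rbind, strsplit(names(n), ".", fixed = TRUE))
  report <- data.frame(household_id = info[, 1],
                       round_index = as.integer(info[, 2]),
                       coverage_hours = cov_h,
                       retained = cov_h >= min_hours,
                       stringsAsFactors = FALSE)
  keep_keys <- names(n)[cov_h >= min_hours]
  list(records = records[as.character(key) %in% keep_keys, , drop = FALSE],
       report = report)
}

#' Flag implausible readings and retire faulty devices
#'
#' Readings outside `bounds` are flagged. A device whose flagged fraction
#' within a round exceeds `max_flag_fraction` is excluded from that round
#' onward (retirement is forward-only: earlier rounds are kept).
#'
#' @param records data.frame with `device_id`, `household_id`, `round_index`,
#'   `aqi`.
#' @param bounds length-2 numeric `(min_aqi, max_aqi)` plausibility bounds.
#' @param max_flag_fraction Tolerated flagged fraction per device-round
#'   before retirement (default 0.1).
#' @return list with `records` (rows from retired device-rounds removed;
#'   remaining rows gain a logical `flagged` column), `flags` (per
#'   device-round flag counts) and `retired` (device, first excluded round).
#' @export
device_plausibility_filter <- function(records, bounds = c(1, 500),
                                       max_flag_fraction = 0.1) {
  stopifnot(all(c("device_id", "round_index", "aqi") %in% names(records)),
            length(bounds) == 2, bounds[1] < bounds[2])
  records$flagged <- records$aqi < bounds[1] | records$aqi > bounds[2]
  key <- interaction(records$device_id, records$round_index, drop = TRUE)
  frac <- tapply(records$flagged, key, mean)
  n_flag <- tapply(records$flagged, key, sum)
  info <- do.call(rbind, strsplit(names(frac), ".", fixed = TRUE))
  flags <- data.frame(device_id = info[, 1],
                      round_index = as.integer(info[, 2]),
                      n_flagged = as.integer(n_flag),
                      flag_fraction = as.numeric(frac),
                      stringsAsFactors = FALSE)
  bad <- flags[flags$flag_fraction > max_flag_fraction, , drop = FALSE]
  retired <- if (nrow(bad)) {
    aggregate(round_index ~ device_id, data = bad, FUN = min) |>
      setNames(c("device_id", "retired_from_round"))
  } else {
    data.frame(device_id = character(), retired_from_round = integer())
  }
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(retired))) {
    drop <- drop | (records$device_id == retired$device_id[i] &
                      records$round_index >= retired$retired_from_round[i])
  }
  list(records = records[!drop, , drop = FALSE], flags = flags,
       retired = retired)
}

#' Downsample 10 s device readings to hourly means
#'
#' Arithmetic mean of all readings per household, calendar date and clock
#' hour. Hours with no samples are simply absent — no imputation. Hourly
#' downsampling smooths the series and removes most short-range temporal
#' autocorrelation before exposure modelling.
#'
#' @param records data.frame with `household_id`, `timestamp` (POSIXct or
#'   ISO-8601 character), `aqi`, and optionally `round_index` (carried
#'   through for AR(1) chain bookkeeping).
#' @param tz Time zone used to interpret character timestamps
#'   (default "Asia/Kolkata").
#' @return data.frame with `household_id`, `date`, `hour`, `aqi_mean`,
#'   `n_samples` (and `round_index` when present), sorted by household and
#'   time.
#' @export
downsample_hourly <- function(records, tz = "Asia/Kolkata") {
  stopifnot(all(c("household_id", "timestamp", "aqi") %in% names(records)))
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) ts <- parse_iso8601(ts, tz)
  lt <- as.POSIXlt(ts)
  date <- format(ts, "%Y-%m-%d")
  hour <- lt$hour
  has_round <- "round_index" %in% names(records)
  g <- if (has_round) {
    data.frame(household_id = records$household_id, round_index = records$round_index,
               date = date, hour = hour, stringsAsFactors = FALSE)
  } else {
    data.frame(household_id = records$household_id, date = date, hour = hour,
               stringsAsFactors = FALSE)
  }
  agg <- aggregate(records$aqi, by = g, FUN = mean)
  names(agg)[ncol(agg)] <- "aqi_mean"
  cnt <- aggregate(records$aqi, by = g, FUN = length)
  agg$n_samples <- cnt$x
  agg <- agg[order(agg$household_id, agg$date, agg$hour), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Fit the diurnal-by-seasonal household exposure model
#'
#' Fits hourly AQI means with a generalized additive mixed model: a tensor
#' product smooth of clock hour and calendar date (cyclic cubic regression
#' spline over hours so 23:00 adjoins 00:00, cubic regression spline over
#' dates; 11 basis dimensions per margin by default) plus a shrunken
#' (random-effect) intercept per household, estimated with [mgcv::bam()].
#' Residual AR(1) autocorrelation is handled with a fixed rho (default 0.6)
#' applied within chains of consecutive hours; a gap of more than one hour,
#' or a new household-round, starts a new chain.
#'
#' @param hourly data.frame from [downsample_hourly()].
#' @param k_hour,k_date Basis dimensions for the two margins (default 11).
#' @param rho Fixed AR(1) coefficient for within-chain residuals (0.6).
#' @param tz Time zone for date arithmetic.
#' @return An object of class `exposure_model`: the `bam` fit plus centered
#'   per-household intercepts (`household_intercepts`, AQI units, mean 0)
#'   and the `grand_mean` (AQI units).
#' @export
fit_exposure_model <- function(hourly, k_hour = 11, k_date = 11, rho = 0.6,
                               tz = "Asia/Kolkata") {
  stopifnot(all(c("household_id", "date", "hour", "aqi_mean") %in% names(hourly)))
  hh <- factor(hourly$household_id)
  if (nlevels(hh) < 2)
    stop("exposure model needs at least 2 households")
  d <- data.frame(aqi_mean = hourly$aqi_mean,
                  hour = hourly$hour,
                  date_num = as.numeric(as.Date(hourly$date)),
                  household = hh)
  d$date_num <- d$date_num - min(d$date_num)
  if (length(unique(d$date_num)) < k_date || length(unique(d$hour)) < k_hour)
    stop("too few distinct dates or hours for the requested basis; ",
         "reduce k_date/k_hour")
  # order and AR(1) chain starts: new household-round or a >1 h gap
  has_round <- "round_index" %in% names(hourly)
  d$round_index <- if (has_round) hourly$round_index else 1L
  t_abs <- d$date_num * 24 + d$hour
  ord <- order(d$household, d$round_index, t_abs)
  d <- d[ord, ]
  t_abs <- t_abs[ord]
  new_chain <- c(TRUE, diff(t_abs) != 1 |
                   d$household[-1] != d$household[-nrow(d)] |
                   d$round_index[-1] != d$round_index[-nrow(d)])
  fit <- mgcv::bam(
    aqi_mean ~ te(hour, date_num, bs = c("cc", "cr"), k = c(k_hour, k_date)) +
      s(household, bs = "re"),
    data = d, knots = list(hour = seq(0, 24, length.out = k_hour)),
    rho = rho, AR.start = new_chain, discrete = TRUE)
  cf <- coef(fit)
  re_idx <- grep("^s\\(household\\)", names(cf))
  intercepts <- cf[re_idx]
  names(intercepts) <- levels(d$household)
  grand_mean <- unname(cf["(Intercept)"]) + mean(intercepts)
  intercepts <- intercepts - mean(intercepts)
  structure(list(fit = fit,
                 household_intercepts = intercepts,
                 grand_mean = grand_mean,
                 rho = rho, k_hour = k_hour, k_date = k_date,
                 date_origin = min(as.Date(hourly$date))),
            class = "exposure_model")
}

#' @export
print.exposure_model <- function(x, ...) {
  cat(sprintf(paste0("<exposure_model: %d households, grand mean %.1f AQI, ",
                     "rho %.2f, te(%d x %d)>\n"),
              length(x$household_intercepts), x$grand_mean, x$rho,
              x$k_hour, x$k_date))
  invisible(x)
}

#' Predict the fitted diurnal profile
#'
#' Evaluates the fitted hour-by-date surface at a grid of clock hours for a
#' fixed date (default: the median observed date), with the household effect
#' set to zero. Used to check that the model recovers meal-time peaks.
#'
#' @param model An `exposure_model`.
#' @param hours Numeric vector of clock hours (default 0..23).
#' @param date Date at which to slice the surface (default median observed).
#' @return data.frame with `hour` and `aqi_fit`.
#' @export
diurnal_profile <- function(model, hours = 0:23, date = NULL) {
  fit <- model$fit
  d0 <- fit$model
  date_num <- if (is.null(date)) stats::median(d0$date_num)
              else as.numeric(as.Date(date) - model$date_origin)
  nd <- data.frame(hour = hours, date_num = date_num,
                   household = d0$household[1])
  pr <- predict(fit, newdata = nd, type = "terms")
  te_col <- grep("^te\\(hour", colnames(pr))
  data.frame(hour = hours,
             aqi_fit = model$grand_mean + as.numeric(pr[, te_col]))
}

#' Extract centered household exposure scores
#'
#' One score per household: the shrunken household intercept from the
#' exposure model, centered at 0 so that a positive score means poorer air
#' quality (higher AQI) than the grand mean. Adding `grand_mean` to the
#' scores puts them back on the AQI visualization scale.
#'
#' @param model An `exposure_model` from [fit_exposure_model()].
#' @return data.frame with `household_id`, `exposure_score`, `grand_mean`.
#' @export
extract_exposure <- function(model) {
  stopifnot(inherits(model, "exposure_model"))
  data.frame(household_id = names(model$household_intercepts),
             exposure_score = as.numeric(model$household_intercepts),
             grand_mean = model$grand_mean,
             stringsAsFactors = FALSE)
}
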