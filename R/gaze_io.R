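#' Construct a gaze trial
#'
#' A trial is one 10 s presentation: an ordered AOI time series plus its
#' design metadata. Sample times are milliseconds from trial onset; each
#' sample's AOI is taken to hold over the half-open interval from its
#' timestamp to the next sample's (the final sample extends to the end of the
#' trial). Time before the first sample is treated as missing.
#'
#' @param participant_id,year,trial_index Trial identity. `year` is 1 or 2.
#' @param samples data.frame with columns `t_ms` (strictly increasing,
#'   within `[0, 10000]`) and `aoi` (one of [AOI_LEVELS]).
#' @param load Number of items per display (`NA` until metadata attached).
#' @param load_level Within-year rank of load: "low", "medium" or "high".
#' @param change_side "left" or "right".
#' @param source_used "eyetracker" or "video".
#' @param trial_duration_ms Trial length in ms.
#' @return An object of class `gaze_trial`.
#' @export
gaze_trial <- function(participant_id, year, trial_index, samples,
                       load = NA_integer_, load_level = NA_character_,
                       change_side = NA_character_, source_used = NA_character_,
                       trial_duration_ms = 10000) {
  stopifnot(is.data.frame(samples), all(c("t_ms", "aoi") %in% names(samples)))
  if (nrow(samples) > 0) {
    bad <- setdiff(unique(samples$aoi), AOI_LEVELS)
    if (length(bad))
      stop("unknown AOI label(s): ", paste(bad, collapse = ", "))
    if (any(samples$t_ms < 0 | samples$t_ms > trial_duration_ms))
      stop("sample times outside [0, ", trial_duration_ms, "] ms")
    if (is.unsorted(samples$t_ms, strictly = TRUE))
      stop("sample times must be strictly increasing within a trial")
  }
  structure(list(participant_id = as.character(participant_id),
                 year = as.integer(year),
                 trial_index = as.integer(trial_index),
                 load = as.integer(load),
                 load_level = load_level,
                 change_side = change_side,
                 source_used = source_used,
                 trial_duration_ms = trial_duration_ms,
                 samples = samples[, c("t_ms", "aoi")]),
            class = "gaze_trial")
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf("<gaze_trial %s y%d t%d: load=%s change=%s source=%s, %d samples>\n",
              x$participant_id, x$year, x$trial_index,
              x$load, x$change_side, x$source_used, nrow(x$samples)))
  invisible(x)
}

# Half-open AOI intervals [start, end) covering [0, duration); time before the
# first sample is missing.
trial_intervals <- function(trial) {
  s <- trial$samples
  dur <- trial$trial_duration_ms
  if (nrow(s) == 0)
    return(data.frame(start = 0, end = dur, aoi = "missing",
                      stringsAsFactors = FALSE))
  start <- s$t_ms
  end <- c(s$t_ms[-1], dur)
  aoi <- as.character(s$aoi)
  if (start[1] > 0) {
    start <- c(0, start); end <- c(s$t_ms[1], end); aoi <- c("missing", aoi)
  }
  keep <- end > start
  data.frame(start = start[keep], end = end[keep], aoi = aoi[keep],
             stringsAsFactors = FALSE)
}

# Clip an interval table to [lo, hi)
clip_intervals <- function(ints, lo, hi) {
  s <- pmax(ints$start, lo)
  e <- pmin(ints$end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep], aoi = ints$aoi[keep],
             stringsAsFactors = FALSE)
}

GAZE_CSV_COLS <- c("participant_id", "year", "trial_index", "t_ms", "aoi", "source")
TRIAL_CSV_COLS <- c("participant_id", "year", "trial_index", "load", "change_side")

#' Read a long-form gaze sample CSV
#'
#' Canonical interchange format: one row per gaze sample with columns
#' `participant_id, year, trial_index, t_ms, aoi, source`. AOI labels outside
#' the closed set {left, right, away, missing} are a parse error; duplicate
#' timestamps within a (participant, year, trial, source) stream are a
#' validation error. Rows are returned sorted by participant, year, trial
#' and time.
#'
#' @param path CSV file path.
#' @return data.frame of validated samples.
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character"))
  if (!identical(names(df), GAZE_CSV_COLS))
    stop("bad header in ", path, ": expected ",
         paste(GAZE_CSV_COLS, collapse = ","))
  bad <- which(!(df$aoi %in% AOI_LEVELS))
  if (length(bad))
    stop("parse error in ", path, ": unknown aoi ", dQuote(df$aoi[bad[1]]),
         " at data line ", bad[1])
  bad_src <- which(!(df$source %in% c("eyetracker", "video")))
  if (length(bad_src))
    stop("parse error in ", path, ": unknown source at data line ", bad_src[1])
  key <- paste(df$participant_id, df$year, df$trial_index, df$source)
  if (anyDuplicated(cbind(key, df$t_ms)))
    stop("validation error in ", path,
         ": duplicate (trial, t_ms, source) sample")
  df[order(df$participant_id, df$year, df$trial_index, df$t_ms), ,
     drop = FALSE]
}

#' Write gaze samples to CSV
#' @param samples data.frame with the canonical gaze columns.
#' @param path Output path.
#' @export
write_gaze_csv <- function(samples, path) {
  stopifnot(all(GAZE_CSV_COLS %in% names(samples)))
  write.csv(samples[, GAZE_CSV_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge eye-tracker and hand-coded video streams into trials
#'
#' Each trial uses its eye-tracker stream when one was recorded; otherwise
#' the hand-coded video stream is used instead. Substitution is whole-trial:
#' streams are never interleaved. When an expected-trial table is supplied,
#' trials present in neither source are dropped with a warning.
#'
#' @param eyetracker_samples,video_samples Validated sample data.frames (as
#'   from [read_gaze_csv()]); either may be empty or NULL.
#' @param expected Optional data.frame with columns participant_id, year,
#'   trial_index listing the trials that should exist.
#' @param trial_duration_ms Trial length in ms.
#' @return list of `gaze_trial` objects (metadata unattached).
#' @export
merge_sources <- function(eyetracker_samples, video_samples, expected = NULL,
                          trial_duration_ms = 10000) {
  empty <- data.frame(participant_id = character(), year = integer(),
                      trial_index = integer(), t_ms = numeric(),
                      aoi = character(), source = character())
  if (is.null(eyetracker_samples)) eyetracker_samples <- empty
  if (is.null(video_samples)) video_samples <- empty
  key_of <- function(d) paste(d$participant_id, d$year, d$trial_index, sep = "\r")
  et_split <- split(eyetracker_samples, key_of(eyetracker_samples))
  vid_split <- split(video_samples, key_of(video_samples))
  keys <- union(names(et_split), names(vid_split))
  if (!is.null(expected)) {
    exp_keys <- key_of(expected)
    absent <- setdiff(exp_keys, keys)
    if (length(absent))
      warning(length(absent), " trial(s) present in neither source: ",
              paste(gsub("\r", "/", head(absent, 5)), collapse = ", "),
              if (length(absent) > 5) " ..." else "")
    keys <- intersect(exp_keys, keys)
  }
  trials <- lapply(keys, function(k) {
    use_et <- k %in% names(et_split)
    d <- if (use_et) et_split[[k]] else vid_split[[k]]
    d <- d[order(d$t_ms), ]
    gaze_trial(d$participant_id[1], d$year[1], d$trial_index[1],
               samples = d[, c("t_ms", "aoi")],
               source_used = if (use_et) "eyetracker" else "video",
               trial_duration_ms = trial_duration_ms)
  })
  trials
}

# within-year load -> rank label
LOADS_BY_YEAR <- list(`1` = c(1L, 2L, 3L), `2` = c(2L, 4L, 6L))
LOAD_LEVELS <- c("low", "medium", "high")

#' Attach design metadata to merged trials
#'
#' Joins per-trial metadata (memory load and change side) onto merged gaze
#' trials and derives `load_level` as the within-year rank of the load:
#' year 1 uses loads 1/2/3, year 2 uses 2/4/6, so absolute load 2 is the
#' "medium" level in year 1 but the "low" level in year 2.
#'
#' @param trials list of `gaze_trial` (from [merge_sources()]).
#' @param trial_table data.frame with columns participant_id, year,
#'   trial_index, load, change_side.
#' @return list of `gaze_trial` with load, load_level and change_side set.
#' @export
attach_metadata <- function(trials, trial_table) {
  stopifnot(all(TRIAL_CSV_COLS %in% names(trial_table)))
  meta_key <- paste(trial_table$participant_id, trial_table$year,
                    trial_table$trial_index, sep = "\r")
  if (anyDuplicated(meta_key)) stop("duplicate rows in trial metadata table")
  rownames(trial_table) <- meta_key
  missing <- character()
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    k <- paste(tr$participant_id, tr$year, tr$trial_index, sep = "\r")
    if (!k %in% meta_key) { missing <- c(missing, gsub("\r", "/", k)); next }
    row <- trial_table[k, ]
    allowed <- LOADS_BY_YEAR[[as.character(tr$year)]]
    if (is.null(allowed) || !(row$load %in% allowed))
      stop("load ", row$load, " is not valid for year ", tr$year,
           " (trial ", gsub("\r", "/", k), ")")
    if (!row$change_side %in% c("left", "right"))
      stop("change_side must be left or right (trial ", gsub("\r", "/", k), ")")
    tr$load <- as.integer(row$load)
    tr$load_level <- LOAD_LEVELS[match(row$load, allowed)]
    tr$change_side <- row$change_side
    out[[i]] <- tr
  }
  if (length(missing))
    stop("missing metadata row(s) for trial(s): ",
         paste(head(missing, 10), collapse = ", "))
  out
}
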