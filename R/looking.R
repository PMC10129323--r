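#' First-look classification at change onset
#'
#' Sorts a trial by where the infant was looking at the onset of the first
#' colour change. If the AOI at `first_change_onset_ms` is a display
#' (left/right) the trial is classed as "change" or "no_change" by comparison
#' with the trial's changing side. If the sample at onset is away or missing
#' — neither answers where on the displays the infant was looking — the class
#' is taken from the first left/right sample at or before
#' `firstlook_fallback_end_ms`; if none exists, the trial is "unclassified".
#'
#' @param trial A `gaze_trial` with `change_side` set.
#' @param cfg A [task_config()].
#' @return One of "change", "no_change", "unclassified".
#' @export
classify_first_look <- function(trial, cfg = task_config()) {
  stopifnot(inherits(trial, "gaze_trial"))
  if (is.na(trial$change_side)) stop("trial has no change_side metadata")
  s <- trial$samples
  onset <- cfg$first_change_onset_ms
  side_at <- NA_character_
  i0 <- if (nrow(s)) findInterval(onset, s$t_ms) else 0L
  if (i0 >= 1) side_at <- as.character(s$aoi[i0])
  if (!is.na(side_at) && side_at %in% c("left", "right")) {
    return(if (side_at == trial$change_side) "change" else "no_change")
  }
  # fallback scan: first on-screen sample after the onset sample, within bound
  if (nrow(s)) {
    j <- which(seq_len(nrow(s)) > i0 &
                 s$t_ms <= cfg$firstlook_fallback_end_ms &
                 s$aoi %in% c("left", "right"))
    if (length(j)) {
      side <- as.character(s$aoi[j[1]])
      return(if (side == trial$change_side) "change" else "no_change")
    }
  }
  "unclassified"
}

#' Fraction of trial time spent off-screen
#'
#' Off-screen time is time not looking at either display: away samples plus
#' missing (untracked) time. Computed over the whole trial by default, or
#' over the change-preference window when the config says so.
#'
#' @inheritParams classify_first_look
#' @return Fraction in `[0, 1]`.
#' @export
away_fraction <- function(trial, cfg = task_config()) {
  ints <- trial_intervals(trial)
  if (cfg$away_fraction_window == "cp")
    ints <- clip_intervals(ints, cfg$cp_window[1], cfg$cp_window[2])
  total <- sum(ints$end - ints$start)
  if (total <= 0) return(1)
  on <- sum((ints$end - ints$start)[ints$aoi %in% c("left", "right")])
  1 - on / total
}

#' Change preference score
#'
#' Time-weighted proportion of on-display looking directed to the changing
#' display within the analysis window (default 1750-6750 ms). The denominator
#' is time on either display; away and missing time do not count. The score
#' is undefined (`NA`) when there is no on-display looking in the window, or
#' when the trial's off-screen fraction strictly exceeds the exclusion
#' threshold (default 0.75; exactly 0.75 is retained).
#'
#' @inheritParams classify_first_look
#' @return Fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
change_preference <- function(trial, cfg = task_config()) {
  stopifnot(inherits(trial, "gaze_trial"))
  if (is.na(trial$change_side)) stop("trial has no change_side metadata")
  if (away_fraction(trial, cfg) > cfg$away_exclusion_fraction)
    return(NA_real_)
  ints <- clip_intervals(trial_intervals(trial), cfg$cp_window[1], cfg$cp_window[2])
  dur <- ints$end - ints$start
  t_change <- sum(dur[ints$aoi == trial$change_side])
  other <- setdiff(c("left", "right"), trial$change_side)
  t_nochange <- sum(dur[ints$aoi == other])
  denom <- t_change + t_nochange
  if (denom <= 0) return(NA_real_)
  t_change / denom
}

# Collapse the AOI stream to its sequence of on-screen looks: left/right runs
# with intervening away/missing ignored (a gap neither breaks nor creates a
# switch). Returns the run sides in order plus total on-screen ms.
onscreen_runs <- function(trial) {
  ints <- trial_intervals(trial)
  on <- ints[ints$aoi %in% c("left", "right"), , drop = FALSE]
  if (nrow(on) == 0) return(list(sides = character(), looking_ms = 0))
  sides <- rle(on$aoi)$values
  list(sides = sides, looking_ms = sum(on$end - on$start))
}

#' Gaze shift rate (switches per looking second)
#'
#' Counts the number of switches between the two displays over the full trial
#' and divides by the number of seconds spent looking at either display.
#' Away/missing gaps between looks neither count as looking time nor break a
#' switch: L, away, R is one switch. Undefined (`NA`) when there is no
#' on-screen looking at all.
#'
#' @inheritParams classify_first_look
#' @return Shifts per second (>= 0), or `NA_real_`.
#' @export
shift_rate <- function(trial, cfg = task_config()) {
  runs <- onscreen_runs(trial)
  if (runs$looking_ms <= 0) return(NA_real_)
  switches <- sum(runs$sides[-1] != runs$sides[-length(runs$sides)])
  switches / (runs$looking_ms / 1000)
}

#' Early-window looking to the first-fixated display
#'
#' Within the pre-change window (default 1-750 ms), identifies the first
#' display the infant fixates and returns the proportion of on-display
#' looking in that window spent on it. A per-infant covariate for baseline
#' visual dynamics before any change has been introduced. Undefined (`NA`)
#' when there is no on-display looking in the window.
#'
#' @inheritParams classify_first_look
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
looking_window1 <- function(trial, cfg = task_config()) {
  ints <- clip_intervals(trial_intervals(trial),
                         cfg$lw1_window[1], cfg$lw1_window[2])
  on <- ints[ints$aoi %in% c("left", "right"), , drop = FALSE]
  if (nrow(on) == 0) return(NA_real_)
  first_side <- on$aoi[1]
  dur <- on$end - on$start
  sum(dur[on$aoi == first_side]) / sum(dur)
}

#' Cohen's kappa for two categorical codings
#'
#' Chance-corrected agreement between two equal-length coder sequences:
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the marginal
#' label frequencies. When both coders are constant and identical the
#' correction is degenerate (`p_e = 1`); this perfect-agreement special case
#' returns `NA` with a warning rather than a kappa.
#'
#' @param coding_a,coding_b Equal-length character vectors of labels.
#' @return Kappa statistic, or `NA_real_` in the degenerate case.
#' @export
cohens_kappa <- function(coding_a, coding_b) {
  stopifnot(length(coding_a) == length(coding_b), length(coding_a) > 0)
  labs <- union(unique(coding_a), unique(coding_b))
  p_o <- mean(coding_a == coding_b)
  pa <- table(factor(coding_a, levels = labs)) / length(coding_a)
  pb <- table(factor(coding_b, levels = labs)) / length(coding_b)
  p_e <- sum(pa * pb)
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("both coders constant and equal: agreement is perfect but kappa is undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Score one trial
#'
#' @inheritParams classify_first_look
#' @return One-row data.frame with first-look class, change preference (and
#'   its validity flag), shift rate, early-window looking and the off-screen
#'   fraction.
#' @export
score_trial <- function(trial, cfg = task_config()) {
  fl <- classify_first_look(trial, cfg)
  af <- away_fraction(trial, cfg)
  cp <- change_preference(trial, cfg)
  cp_valid <- !is.na(cp) && fl != "unclassified"
  data.frame(participant_id = trial$participant_id,
             year = trial$year,
             trial_index = trial$trial_index,
             load = trial$load,
             load_level = trial$load_level,
             change_side = trial$change_side,
             source_used = trial$source_used,
             first_look = fl,
             change_preference = if (cp_valid) cp else NA_real_,
             cp_valid = cp_valid,
             shift_rate = shift_rate(trial, cfg),
             looking_window1 = looking_window1(trial, cfg),
             away_fraction = af,
             stringsAsFactors = FALSE)
}

#' Score a set of trials and aggregate per analysis cell
#'
#' Applies all looking measures to every trial, reports per-filter exclusion
#' counts, and aggregates valid change-preference and shift-rate scores per
#' participant x year x load level x first-look class cell — the unit of
#' analysis for the association models.
#'
#' @param trials list of `gaze_trial` with metadata attached.
#' @param cfg A [task_config()].
#' @return list with `scores` (one row per trial), `aggregates` (one row per
#'   cell), and `exclusions` (named counts per filter).
#' @export
score_dataset <- function(trials, cfg = task_config()) {
  scores <- do.call(rbind, lapply(trials, score_trial, cfg = cfg))
  exclusions <- c(
    away_excluded = sum(scores$away_fraction > cfg$away_exclusion_fraction),
    firstlook_unclassified = sum(scores$first_look == "unclassified"),
    cp_empty_window = sum(scores$away_fraction <= cfg$away_exclusion_fraction &
                            scores$first_look != "unclassified" &
                            !scores$cp_valid),
    no_looking = sum(is.na(scores$shift_rate))
  )
  ok <- scores[scores$first_look != "unclassified", , drop = FALSE]
  if (nrow(ok)) {
    agg <- aggregate(
      cbind(change_preference, shift_rate, looking_window1) ~
        participant_id + year + load_level + first_look,
      data = ok, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
    n <- aggregate(trial_index ~ participant_id + year + load_level + first_look,
                   data = ok, FUN = length)
    names(n)[names(n) == "trial_index"] <- "n_trials"
    agg <- merge(agg, n)
    agg$change_preference[is.nan(agg$change_preference)] <- NA_real_
    agg$looking_window1[is.nan(agg$looking_window1)] <- NA_real_
    agg$shift_rate[is.nan(agg$shift_rate)] <- NA_real_
  } else {
    agg <- data.frame(participant_id = character(), year = integer(),
                      load_level = character(), first_look = character(),
                      change_preference = numeric(), shift_rate = numeric(),
                      looking_window1 = numeric(), n_trials = integer())
  }
  list(scores = scores, aggregates = agg, exclusions = exclusions)
}
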