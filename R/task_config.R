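#' Task timing configuration for the change-detection task
#'
#' Encodes the timing constants of the preferential-looking change-detection
#' task: 10 s trials in which two square arrays blink on for 500 ms and off
#' for 250 ms, the first colour change occurring 1000 ms after trial onset.
#' All scoring windows are expressed in milliseconds from trial onset and are
#' configurable.
#'
#' @param trial_duration_ms Trial length (default 10000).
#' @param on_ms,off_ms Display on/off cycle durations (500/250).
#' @param first_change_onset_ms Time of the first colour change; trials are
#'   sorted into first-look classes by the AOI occupied at this instant
#'   (default 1000).
#' @param firstlook_fallback_end_ms When the AOI at change onset is away or
#'   missing, the first-look class is taken from the first left/right sample
#'   at or before this time (default 2500).
#' @param cp_window Length-2 numeric, analysis window for the change
#'   preference score (default c(1750, 6750)).
#' @param lw1_window Length-2 numeric, early window for the first-fixated-side
#'   looking proportion, before any change has occurred (default c(1, 750)).
#' @param away_exclusion_fraction Trials whose off-screen fraction strictly
#'   exceeds this value are excluded from the change-preference analysis
#'   (default 0.75; exactly 0.75 is retained).
#' @param away_fraction_window Either "trial" (default: off-screen fraction
#'   computed over the whole trial) or "cp" (restricted to `cp_window`).
#' @return A list of class `task_config`.
#' @export
task_config <- function(trial_duration_ms = 10000,
                        on_ms = 500, off_ms = 250,
                        first_change_onset_ms = 1000,
                        firstlook_fallback_end_ms = 2500,
                        cp_window = c(1750, 6750),
                        lw1_window = c(1, 750),
                        away_exclusion_fraction = 0.75,
                        away_fraction_window = c("trial", "cp")) {
  away_fraction_window <- match.arg(away_fraction_window)
  stopifnot(trial_duration_ms > 0,
            cp_window[1] >= 0, cp_window[2] <= trial_duration_ms,
            cp_window[1] < cp_window[2],
            lw1_window[1] >= 0, lw1_window[2] <= trial_duration_ms,
            first_change_onset_ms >= 0,
            firstlook_fallback_end_ms >= first_change_onset_ms,
            away_exclusion_fraction >= 0, away_exclusion_fraction <= 1)
  structure(list(trial_duration_ms = trial_duration_ms,
                 on_ms = on_ms, off_ms = off_ms,
                 first_change_onset_ms = first_change_onset_ms,
                 firstlook_fallback_end_ms = firstlook_fallback_end_ms,
                 cp_window = cp_window,
                 lw1_window = lw1_window,
                 away_exclusion_fraction = away_exclusion_fraction,
                 away_fraction_window = away_fraction_window),
            class = "task_config")
}
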