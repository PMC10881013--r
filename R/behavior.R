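#' Search latency of one trial from beam-break events
#'
#' Latency is the time from the start of the trial to the first nose poke
#' (infrared beam break) at any odor port. Trials with no beam break (the dog
#' never searched) have missing latency.
#'
#' @param trial_start Trial start time, seconds from session start.
#' @param events data.frame of beam events with columns `box`, `break_s`
#'   (and optionally `release_s`), time-ordered.
#' @param trial_end Optional trial end time; breaks at/after it are ignored.
#' @return Latency in seconds, or `NA` when no break falls in the trial.
#' @export
trial_latency <- function(trial_start, events, trial_end = Inf) {
  b <- events$break_s
  b <- b[b >= trial_start & b < trial_end]
  if (length(b) == 0L) return(NA_real_)
  min(b) - trial_start
}

#' Inter-box intervals within one trial
#'
#' The inter-box interval (IBI) is the time between nose pokes at *different*
#' boxes — the time to travel from one olfactometer to the next. Consecutive
#' re-pokes of the same box are excluded.
#'
#' @param events data.frame of beam events (`box`, `break_s`), time-ordered.
#' @return Numeric vector of intervals in seconds (possibly empty).
#' @examples
#' ev <- data.frame(box = c(1, 2, 3), break_s = c(5.0, 6.2, 7.1))
#' inter_box_intervals(ev) # 1.2 0.9
#' @export
inter_box_intervals <- function(events) {
  if (nrow(events) < 2L) return(numeric(0))
  ord <- order(events$break_s)
  box <- events$box[ord]
  t <- events$break_s[ord]
  keep <- c(TRUE, box[-1] != box[-length(box)])
  box <- box[keep]; t <- t[keep]
  if (length(t) < 2L) return(numeric(0))
  diff(t)
}

#' Session-mean inter-box interval
#'
#' Averages the per-trial inter-box intervals over a session. Trials are
#' identified by a `trial_index` column; the session mean is the mean of the
#' per-trial mean IBIs, so it is invariant to trial order.
#'
#' @param events data.frame with `trial_index`, `box`, `break_s`.
#' @return Mean IBI in seconds, or `NA` if no trial has two pokes at
#'   different boxes.
#' @export
session_mean_ibi <- function(events) {
  per_trial <- vapply(split(events, events$trial_index), function(ev) {
    ib <- inter_box_intervals(ev)
    if (length(ib)) mean(ib) else NA_real_
  }, numeric(1))
  if (all(is.na(per_trial))) return(NA_real_)
  mean(per_trial, na.rm = TRUE)
}

#' Session-mean search latency
#'
#' Mean latency over searched trials (trials where the dog poked at least one
#' port). No-search trials carry no latency and are excluded.
#'
#' @param latencies Numeric vector of per-trial latencies, `NA` for no-search
#'   trials.
#' @return Mean in seconds, `NA` if every trial is missing.
#' @export
session_mean_latency <- function(latencies) {
  if (all(is.na(latencies))) return(NA_real_)
  mean(latencies, na.rm = TRUE)
}

#' Mean subcutaneous temperature over the start of a session
#'
#' Averages microchip temperature readings over the first `window_min` minutes
#' of the session (default 25, where most session data are captured). Series
#' flagged invalid — low-temperature conditions, where the chip readings were
#' physiologically impossible — yield a missing value.
#'
#' @param series A list or data.frame with `minute` and `temp_c` readings and
#'   an optional `valid` flag (scalar, or constant column).
#' @param window_min Averaging window in minutes.
#' @return Mean temperature in degrees C, or `NA`.
#' @export
mean_session_temperature <- function(series, window_min = 25) {
  valid <- series$valid
  if (!is.null(valid) && !all(as.logical(valid))) return(NA_real_)
  minute <- series$minute
  temp <- series$temp_c
  keep <- minute <= window_min
  if (!any(keep)) return(NA_real_)
  mean(temp[keep])
}

#' Behavioral covariates for a collection of sessions
#'
#' Extracts the session-level covariates used by the threshold regressions:
#' mean searched-trial latency, mean inter-box interval, and (when temperature
#' series are supplied) mean subcutaneous temperature over the first 25
#' minutes.
#'
#' @param sessions List of `session_result` objects.
#' @param temperatures Optional list of temperature series keyed by
#'   `dog|odor|condition` (as produced by the simulators), each a data.frame
#'   with `minute`, `temp_c`, `valid`.
#' @param window_min Temperature averaging window, minutes.
#' @return data.frame with `dog`, `odor`, `condition`, `mean_latency`,
#'   `mean_ibi`, `mean_temp`.
#' @export
session_covariates <- function(sessions, temperatures = NULL,
                               window_min = 25) {
  rows <- lapply(sessions, function(s) {
    key <- paste(s$dog, s$odor, s$condition, sep = "|")
    mt <- NA_real_
    if (!is.null(temperatures) && !is.null(temperatures[[key]])) {
      mt <- mean_session_temperature(temperatures[[key]], window_min)
    }
    data.frame(
      dog = s$dog, odor = s$odor, condition = s$condition,
      mean_latency = session_mean_latency(s$trials$latency_s),
      mean_ibi = mean(s$trials$mean_inter_box_s, na.rm = TRUE),
      mean_temp = mt,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$mean_ibi[is.nan(out$mean_ibi)] <- NA_real_
  out
}
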