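#' Pad an incomplete session's reversal list by the imputation rules
#'
#' Sessions that end before the required reversal count still yield a bounded
#' threshold: a session terminated at the floor (three consecutive correct at
#' the lowest concentration) has its missing reversal points imputed at the
#' lowest ladder fraction (0.03), and a session terminated by the welfare
#' criterion has them imputed at 0.80, marking failure to complete the task.
#' Time-capped sessions are imputed like welfare stops; this convention is
#' configurable via `fail_fraction` and recorded in provenance downstream.
#'
#' @param observed Numeric vector of observed reversal fractions (possibly
#'   empty).
#' @param reason Termination reason: `"reversals_complete"`, `"floor"`,
#'   `"welfare"` or `"time_cap"`.
#' @param n_required Required reversal count (7 or 4).
#' @param floor_fraction Imputation value for floor terminations.
#' @param fail_fraction Imputation value for welfare/time-cap terminations.
#' @return Numeric vector of length `n_required`.
#' @examples
#' impute_reversals(c(0.03, 0.03), "floor", 7)
#' impute_reversals(c(0.5, 0.25, 0.5), "welfare", 7)
#' @export
impute_reversals <- function(observed, reason, n_required,
                             floor_fraction = 0.03, fail_fraction = 0.80) {
  if (length(observed) > n_required) {
    stop("more observed reversals than required", call. = FALSE)
  }
  if (!reason %in% c("reversals_complete", "floor", "welfare", "time_cap")) {
    stop(sprintf("unknown termination reason: %s", reason), call. = FALSE)
  }
  n_missing <- n_required - length(observed)
  if (n_missing == 0L) return(observed)
  pad <- switch(reason,
    reversals_complete = stop(
      "a completed session cannot be short of reversals", call. = FALSE),
    floor = floor_fraction,
    welfare = fail_fraction,
    time_cap = fail_fraction
  )
  c(observed, rep(pad, n_missing))
}

#' Geometric-mean detection threshold from reversal fractions
#'
#' The session's detection threshold is the geometric mean of its reversal
#' concentrations; all analysis is on the log10 scale, where the geometric
#' mean is the arithmetic mean of log10 fractions.
#'
#' @param reversal_fractions Non-empty numeric vector of fractions in (0, 1].
#' @return A list with `threshold_fraction` and `log10_threshold`.
#' @examples
#' threshold_geomean(rep(0.03, 7)) # log10 threshold -1.523
#' @export
threshold_geomean <- function(reversal_fractions) {
  if (length(reversal_fractions) == 0L) {
    stop("no reversal fractions supplied", call. = FALSE)
  }
  if (any(reversal_fractions <= 0) || any(reversal_fractions > 1)) {
    stop("reversal fractions must lie in (0, 1]", call. = FALSE)
  }
  lt <- mean(log10(reversal_fractions))
  list(threshold_fraction = 10^lt, log10_threshold = lt)
}

#' Detection threshold record for one session
#'
#' Applies the imputation rules (or not) and the geometric-mean statistic to a
#' session's observed reversals, producing one tidy threshold record carrying
#' imputation provenance. A session with no observed reversals and
#' `impute = FALSE` yields a missing threshold, flagged rather than erroring.
#'
#' @param session A `session_result` from [run_session()] or [read_trials()].
#' @param rules The [termination_rules()] the session ran under (supplies the
#'   required reversal count).
#' @param impute Logical: pad incomplete sessions per [impute_reversals()]?
#' @param floor_fraction,fail_fraction Imputation values.
#' @param breed,group,day Optional design labels carried into the record.
#' @return A one-row data.frame: `dog`, `odor`, `condition`, `breed`, `group`,
#'   `day`, `log10_threshold`, `threshold_fraction`, `n_observed_reversals`,
#'   `termination_reason`, `imputation` (`"none"`, `"floor"`, `"welfare"`,
#'   `"time_cap"`), `imputed_used`.
#' @export
session_threshold <- function(session, rules, impute = TRUE,
                              floor_fraction = 0.03, fail_fraction = 0.80,
                              breed = NA_character_, group = NA_character_,
                              day = NA_integer_) {
  observed <- session$observed_reversals
  reason <- session$termination_reason
  n_req <- rules$reversals_required
  complete <- reason == "reversals_complete" || length(observed) >= n_req

  if (impute && !complete) {
    fracs <- impute_reversals(observed, reason, n_req,
                              floor_fraction, fail_fraction)
    imputation <- reason
    imputed_used <- TRUE
  } else {
    fracs <- observed
    imputation <- "none"
    imputed_used <- FALSE
  }

  if (length(fracs) == 0L) {
    gm <- list(threshold_fraction = NA_real_, log10_threshold = NA_real_)
  } else {
    gm <- threshold_geomean(fracs)
  }

  data.frame(
    dog = session$dog, odor = session$odor, condition = session$condition,
    breed = breed, group = group, day = day,
    log10_threshold = gm$log10_threshold,
    threshold_fraction = gm$threshold_fraction,
    n_observed_reversals = length(observed),
    termination_reason = reason,
    imputation = imputation,
    imputed_used = imputed_used,
    stringsAsFactors = FALSE
  )
}

#' Threshold table for a collection of sessions
#'
#' @param sessions List of `session_result` objects.
#' @param rules A [termination_rules()].
#' @param impute Logical, see [session_threshold()].
#' @param ... Passed to [session_threshold()].
#' @return A data.frame with one row per session.
#' @export
threshold_table <- function(sessions, rules, impute = TRUE, ...) {
  do.call(rbind, lapply(sessions, session_threshold, rules = rules,
                        impute = impute, ...))
}
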