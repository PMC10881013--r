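#' Initial state for a 3-down-1-up staircase session
#'
#' The staircase starts at the highest concentration (step 1). Intensity is
#' decreased by one ladder step after three consecutive correct trials and
#' increased by one step after any incorrect trial; a reversal is recorded
#' whenever the direction of realized movement changes.
#'
#' @param ladder A [dilution_ladder()].
#' @param start_step Step index at which the session starts (default 1, the
#'   highest concentration).
#' @return A `staircase_state` list with fields `current_step`,
#'   `consecutive_correct`, `last_direction` (`"none"`, `"down"` or `"up"`),
#'   `reversals` (fractions), `reversal_directions`, `trials_elapsed`,
#'   `no_search_streak` and `heat_stress`.
#' @export
staircase_state <- function(ladder, start_step = 1L) {
  start_step <- as.integer(start_step)
  if (start_step < 1L || start_step > n_steps(ladder)) {
    stop("start_step outside ladder bounds", call. = FALSE)
  }
  structure(list(
    current_step = start_step,
    consecutive_correct = 0L,
    last_direction = "none",
    reversals = numeric(0),
    reversal_directions = character(0),
    trials_elapsed = 0L,
    no_search_streak = 0L,
    heat_stress = FALSE
  ), class = "staircase_state")
}

#' Session termination rules
#'
#' A session ends when the required number of reversals is reached, when the
#' subject scores three consecutive correct responses at the lowest
#' concentration (floor), when the session time cap elapses, or when a welfare
#' criterion fires (refusing to search for several consecutive trials, reduced
#' to a single trial when signs of heat stress are present).
#'
#' @param reversals_required Reversals needed to complete a session
#'   (7 for the environmental-condition experiment, 4 for the acclimatization
#'   experiment).
#' @param floor_consecutive Consecutive correct responses at the lowest step
#'   that terminate by floor.
#' @param session_cap_min Session time cap in minutes.
#' @param welfare_no_search Consecutive no-search trials triggering the
#'   welfare stop.
#' @param welfare_no_search_heat Consecutive no-search trials triggering the
#'   welfare stop when heat stress is flagged.
#' @return A `termination_rules` list.
#' @export
termination_rules <- function(reversals_required = 7L,
                              floor_consecutive = 3L,
                              session_cap_min = 40,
                              welfare_no_search = 5L,
                              welfare_no_search_heat = 1L) {
  vals <- c(reversals_required, floor_consecutive, session_cap_min,
            welfare_no_search, welfare_no_search_heat)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all termination rule fields must be positive", call. = FALSE)
  }
  structure(list(
    reversals_required = as.integer(reversals_required),
    floor_consecutive = as.integer(floor_consecutive),
    session_cap_min = as.numeric(session_cap_min),
    welfare_no_search = as.integer(welfare_no_search),
    welfare_no_search_heat = as.integer(welfare_no_search_heat)
  ), class = "termination_rules")
}

#' Advance the staircase by one trial outcome
#'
#' Implements the 3-down-1-up transition: a correct response increments the
#' consecutive-correct counter, and on the third the concentration drops one
#' step (unless already at the floor, where the counter is held at 3 pending
#' the floor-termination check); an incorrect response resets the counter and
#' raises the concentration one step (clamped at the top); a no-search trial
#' moves nothing and increments the no-search streak. Any realized movement
#' whose direction differs from the previous realized movement records a
#' reversal at the fraction presented on the triggering trial. The counter
#' resets on every step change and on every incorrect, so partial credit never
#' carries across a step change; correct and incorrect responses reset the
#' no-search streak.
#'
#' @param state A [staircase_state()].
#' @param outcome One of `"correct"`, `"incorrect"`, `"no_search"`.
#' @param ladder The [dilution_ladder()] the state indexes into.
#' @return The updated `staircase_state`.
#' @export
update_state <- function(state, outcome, ladder) {
  if (!inherits(state, "staircase_state")) {
    stop("state must be a staircase_state", call. = FALSE)
  }
  if (length(outcome) != 1L ||
      !outcome %in% c("correct", "incorrect", "no_search")) {
    stop(sprintf("unknown outcome: %s", paste(outcome, collapse = ",")),
         call. = FALSE)
  }
  presented_fraction <- ladder_fraction(ladder, state$current_step)
  movement <- NULL # "down" or "up" when a step change is realized

  if (outcome == "correct") {
    state$no_search_streak <- 0L
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      if (state$current_step < n_steps(ladder)) {
        state$current_step <- state$current_step + 1L
        state$consecutive_correct <- 0L
        movement <- "down"
      }
      # at the lowest step the counter is held at 3 for the floor check
    }
  } else if (outcome == "incorrect") {
    state$no_search_streak <- 0L
    state$consecutive_correct <- 0L
    if (state$current_step > 1L) {
      state$current_step <- state$current_step - 1L
      movement <- "up"
    }
    # clamped at the top: no movement, and non-movement cannot reverse
  } else { # no_search: no movement, counter untouched
    state$no_search_streak <- state$no_search_streak + 1L
  }

  if (!is.null(movement)) {
    if (state$last_direction != "none" && movement != state$last_direction) {
      state$reversals <- c(state$reversals, presented_fraction)
      state$reversal_directions <- c(state$reversal_directions, movement)
    }
    state$last_direction <- movement
  }
  state$trials_elapsed <- state$trials_elapsed + 1L
  state
}

#' Check whether a staircase session should terminate
#'
#' Checks the stopping rules in priority order welfare > floor >
#' reversals_complete > time_cap. Welfare fires when the no-search streak
#' reaches its limit (or its reduced heat-stress limit); floor fires on three
#' consecutive correct responses at the lowest concentration;
#' reversals_complete when the required reversal count is reached; time_cap
#' when the elapsed session time reaches the cap.
#'
#' @param state A [staircase_state()].
#' @param rules A [termination_rules()].
#' @param ladder The session's [dilution_ladder()].
#' @param elapsed_min Elapsed session time in minutes.
#' @return One of `"welfare"`, `"floor"`, `"reversals_complete"`,
#'   `"time_cap"`, or `NULL` if the session continues.
#' @export
check_termination <- function(state, rules, ladder, elapsed_min) {
  streak_limit <- if (isTRUE(state$heat_stress)) {
    rules$welfare_no_search_heat
  } else {
    rules$welfare_no_search
  }
  if (state$no_search_streak >= streak_limit) return("welfare")
  if (state$current_step == n_steps(ladder) &&
      state$consecutive_correct >= rules$floor_consecutive) {
    return("floor")
  }
  if (length(state$reversals) >= rules$reversals_required) {
    return("reversals_complete")
  }
  if (elapsed_min >= rules$session_cap_min) return("time_cap")
  NULL
}

#' Default per-trial timing model for simulated sessions
#'
#' Supplies the durations that advance the simulated session clock: a search
#' latency, the search time spent visiting ports, and the 20 s inter-trial
#' purge interval. Latency and inter-box intervals are lognormal, with
#' locations optionally shifted upward under heat load and when the observer is
#' struggling (low accuracy), so covariate analyses have signal to recover.
#'
#' @param latency_meanlog,latency_sdlog Lognormal parameters for latency (s).
#' @param ibi_meanlog,ibi_sdlog Lognormal parameters for each inter-box
#'   interval (s).
#' @param iti_s Inter-trial purge interval, seconds.
#' @param latency_shift,ibi_shift Additive shifts (s) applied to the sampled
#'   latency and inter-box intervals, e.g. a heat/fatigue penalty.
#' @return A function `(state, outcome)` returning a list with `latency_s`,
#'   `inter_box_s` (vector), `trial_s` (total trial duration in seconds).
#'   Sampling uses the current RNG stream.
#' @export
default_timing_model <- function(latency_meanlog = log(2.5),
                                 latency_sdlog = 0.4,
                                 ibi_meanlog = log(1.5),
                                 ibi_sdlog = 0.3,
                                 iti_s = 20,
                                 latency_shift = 0,
                                 ibi_shift = 0) {
  force(latency_meanlog); force(latency_sdlog)
  force(ibi_meanlog); force(ibi_sdlog)
  force(iti_s); force(latency_shift); force(ibi_shift)
  function(state, outcome) {
    if (outcome == "no_search") {
      # dog never pokes: the trial still consumes time before it is scored
      return(list(latency_s = NA_real_, inter_box_s = numeric(0),
                  trial_s = 30 + iti_s))
    }
    latency <- stats::rlnorm(1, latency_meanlog, latency_sdlog) + latency_shift
    n_ibi <- sample(1:2, 1) # visits 2-3 ports before responding
    ibi <- stats::rlnorm(n_ibi, ibi_meanlog, ibi_sdlog) + ibi_shift
    list(latency_s = latency, inter_box_s = ibi,
         trial_s = latency + sum(ibi) + 2 + iti_s)
  }
}

#' Run a simulated staircase session against an observer
#'
#' Couples the 3-down-1-up state machine to a psychometric [observer()]:
#' starting at the highest concentration, each trial samples an outcome from
#' the observer at the currently presented fraction, advances the state, and
#' checks the termination rules. The full per-trial log is retained.
#'
#' @param observer An [observer()] (or any function of a fraction returning
#'   P(correct); no-search behavior then defaults to never).
#' @param ladder A [dilution_ladder()].
#' @param rules A [termination_rules()].
#' @param seed Optional integer seed; when supplied the session is
#'   self-contained and reproducible, otherwise the current RNG stream is used.
#' @param timing_model A per-trial duration model, see
#'   [default_timing_model()].
#' @param dog,odor,condition Session labels carried into the result.
#' @param max_trials Safety bound on trial count.
#' @return A `session_result` list: labels, `trials` (data.frame with
#'   `trial_index`, `presented_step`, `presented_fraction`, `outcome`,
#'   `latency_s`, `mean_inter_box_s`, `t_start_s`), `observed_reversals`,
#'   `reversal_directions`, `termination_reason`, `session_duration_min`.
#' @examples
#' obs <- observer(alpha = -0.9, beta = 0.1)
#' res <- run_session(obs, default_ladder(), termination_rules(7), seed = 1)
#' res$termination_reason
#' @export
run_session <- function(observer, ladder, rules, seed = NULL,
                        timing_model = default_timing_model(),
                        dog = NA_character_, odor = NA_character_,
                        condition = NA_character_, max_trials = 1000L) {
  if (rules$reversals_required <= 0L) {
    stop("reversals_required must be positive", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
  }

  state <- staircase_state(ladder)
  v_step <- integer(max_trials); v_frac <- numeric(max_trials)
  v_out <- character(max_trials); v_lat <- numeric(max_trials)
  v_ibi <- numeric(max_trials); v_start <- numeric(max_trials)
  elapsed_s <- 0
  reason <- NULL
  n_done <- 0L

  for (i in seq_len(max_trials)) {
    step <- state$current_step
    fraction <- ladder_fraction(ladder, step)
    outcome <- sample_outcome(observer, fraction)
    timing <- timing_model(state, outcome)
    v_step[i] <- step; v_frac[i] <- fraction; v_out[i] <- outcome
    v_lat[i] <- timing$latency_s
    v_ibi[i] <- if (length(timing$inter_box_s)) mean(timing$inter_box_s)
                else NA_real_
    v_start[i] <- elapsed_s
    n_done <- i
    elapsed_s <- elapsed_s + timing$trial_s
    state <- update_state(state, outcome, ladder)
    reason <- check_termination(state, rules, ladder, elapsed_s / 60)
    if (!is.null(reason)) break
  }
  if (is.null(reason)) reason <- "time_cap" # max_trials safety net

  keep <- seq_len(n_done)
  structure(list(
    dog = dog, odor = odor, condition = condition,
    trials = data.frame(
      trial_index = keep,
      presented_step = v_step[keep],
      presented_fraction = v_frac[keep],
      outcome = v_out[keep],
      latency_s = v_lat[keep],
      mean_inter_box_s = v_ibi[keep],
      t_start_s = v_start[keep]
    ),
    observed_reversals = state$reversals,
    reversal_directions = state$reversal_directions,
    termination_reason = reason,
    session_duration_min = elapsed_s / 60
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "Staircase session: dog=%s odor=%s condition=%s\n  %d trials, %d reversals, terminated by %s after %.1f min\n",
    x$dog, x$odor, x$condition, nrow(x$trials),
    length(x$observed_reversals), x$termination_reason,
    x$session_duration_min))
  invisible(x)
}
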