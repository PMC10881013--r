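ladder <- default_ladder()

test_that("third consecutive correct steps the concentration down", {
  state <- staircase_state(ladder)
  state$consecutive_correct <- 2L
  out <- update_state(state, "correct", ladder)
  expect_equal(out$current_step, 2L)
  expect_equal(out$consecutive_correct, 0L)
  expect_equal(out$last_direction, "down")
  expect_length(out$reversals, 0) # first movement is never a reversal
})

test_that("an incorrect response steps up and records a direction change", {
  state <- staircase_state(ladder)
  state$current_step <- 3L
  state$last_direction <- "down"
  out <- update_state(state, "incorrect", ladder)
  expect_equal(out$current_step, 2L)
  expect_equal(out$last_direction, "up")
  # reversal logged at the fraction presented on the triggering trial
  expect_equal(out$reversals, 0.25)
})

test_that("incorrect at the top step clamps without a reversal", {
  state <- staircase_state(ladder)
  out <- update_state(state, "incorrect", ladder)
  expect_equal(out$current_step, 1L)
  expect_equal(out$last_direction, "none")
  expect_length(out$reversals, 0)
})

test_that("no-search trials freeze the staircase but advance the streak", {
  state <- staircase_state(ladder)
  state$consecutive_correct <- 2L
  out <- update_state(state, "no_search", ladder)
  expect_equal(out$current_step, 1L)
  expect_equal(out$consecutive_correct, 2L) # counter untouched
  expect_equal(out$no_search_streak, 1L)
  # a searched trial resets the streak
  out2 <- update_state(out, "correct", ladder)
  expect_equal(out2$no_search_streak, 0L)
  expect_error(update_state(state, "banana", ladder), "unknown outcome")
})

test_that("outcome-sequence reversal counts match the independent oracle", {
  # three descents then alternating error/recovery: the replay oracle counts
  # each realized change of direction
  seq1 <- c(rep("correct", 6), "incorrect", rep("correct", 3), "incorrect")
  orc <- oracle_replay(seq1, ladder$nominal_fraction)
  mac <- machine_replay(seq1, ladder)
  expect_equal(length(mac$state$reversals), orc$n_reversals)
  expect_equal(mac$state$reversals, orc$reversals)
  expect_equal(orc$n_reversals, 3L)
  expect_equal(orc$reversals, c(0.25, 0.50, 0.25))
})

test_that("random outcome sequences (with no-search) agree with the oracle", {
  set.seed(42)
  for (i in 1:300) {
    len <- sample(3:20, 1)
    outcomes <- sample(c("correct", "incorrect", "no_search"), len,
                       replace = TRUE, prob = c(0.55, 0.35, 0.10))
    orc <- oracle_replay(outcomes, ladder$nominal_fraction)
    mac <- machine_replay(outcomes, ladder)
    expect_equal(mac$trajectory, orc$trajectory)
    expect_equal(mac$state$current_step, orc$final_pos)
    expect_equal(mac$state$reversals, orc$reversals)
    # trajectory never leaves the ladder
    expect_true(all(mac$trajectory >= 1 & mac$trajectory <= 5))
    # recorded reversal directions strictly alternate
    dirs <- mac$state$reversal_directions
    if (length(dirs) >= 2) {
      expect_true(all(dirs[-1] != dirs[-length(dirs)]))
    }
  }
})

test_that("termination rules fire in priority order", {
  rules <- termination_rules(7L)
  state <- staircase_state(ladder)

  state$reversals <- rep(0.25, 7)
  expect_equal(check_termination(state, rules, ladder, 10),
               "reversals_complete")

  floor_state <- staircase_state(ladder)
  floor_state$current_step <- 5L
  floor_state$consecutive_correct <- 3L
  expect_equal(check_termination(floor_state, rules, ladder, 10), "floor")

  welfare_state <- staircase_state(ladder)
  welfare_state$no_search_streak <- 5L
  expect_equal(check_termination(welfare_state, rules, ladder, 10),
               "welfare")
  # heat stress lowers the no-search tolerance to a single trial
  heat_state <- staircase_state(ladder)
  heat_state$heat_stress <- TRUE
  heat_state$no_search_streak <- 1L
  expect_equal(check_termination(heat_state, rules, ladder, 10), "welfare")

  slow_state <- staircase_state(ladder)
  slow_state$reversals <- rep(0.25, 6)
  expect_null(check_termination(slow_state, rules, ladder, 39.9))
  expect_equal(check_termination(slow_state, rules, ladder, 40), "time_cap")

  # welfare > floor > reversals when several fire at once
  all_state <- staircase_state(ladder)
  all_state$current_step <- 5L
  all_state$consecutive_correct <- 3L
  all_state$reversals <- rep(0.03, 7)
  expect_equal(check_termination(all_state, rules, ladder, 45), "floor")
  all_state$no_search_streak <- 5L
  expect_equal(check_termination(all_state, rules, ladder, 45), "welfare")
})

test_that("a perfect observer walks the ladder to a floor stop in 15 trials", {
  res <- run_session(function(fraction) 1, ladder, termination_rules(7L),
                     seed = 1)
  expect_equal(res$termination_reason, "floor")
  expect_equal(nrow(res$trials), 15L)
  expect_length(res$observed_reversals, 0)
  expect_equal(res$trials$presented_step, rep(1:5, each = 3))
})

test_that("a blind observer never descends and times out", {
  res <- run_session(function(fraction) 0, ladder, termination_rules(7L),
                     seed = 1)
  expect_equal(res$termination_reason, "time_cap")
  expect_true(all(res$trials$presented_step == 1L))
  expect_length(res$observed_reversals, 0)
})

test_that("a step-function observer reverses only at its boundary", {
  # always correct at steps 1-3 (fractions >= 0.25), always incorrect below
  obs <- function(fraction) as.numeric(fraction >= 0.25)
  res <- run_session(obs, ladder, termination_rules(7L), seed = 3)
  expect_equal(res$termination_reason, "reversals_complete")
  expect_true(all(res$observed_reversals %in% c(0.12, 0.25)))
  expect_length(res$observed_reversals, 7)
})

test_that("sessions are deterministic given a seed", {
  obs <- observer(alpha = -0.8, beta = 0.2)
  a <- run_session(obs, ladder, termination_rules(7L), seed = 99)
  b <- run_session(obs, ladder, termination_rules(7L), seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$observed_reversals, b$observed_reversals)
  expect_error(run_session(obs, ladder, termination_rules(7L),
                           seed = 1, max_trials = 0),
               NA) # degenerate bound still returns a (time-capped) session
  expect_error(
    run_session(obs, ladder,
                structure(list(reversals_required = 0L), class = "x"),
                seed = 1),
    "positive")
})
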