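# Independent replay oracle for the 3-down-1-up staircase.
#
# Deliberately written as a plain trial-by-trial replay over outcome vectors,
# sharing no code with the package's state machine: position moves down after
# every third consecutive correct (clamped at the lowest step, where the run
# is left standing for the floor rule), up after every incorrect (clamped at
# the top), and a reversal is counted whenever the sign of a realized move
# differs from the sign of the previous realized move, recorded at the
# fraction presented on the trial that triggered the move.
oracle_replay <- function(outcomes, fractions) {
  n_step <- length(fractions)
  pos <- 1L
  streak <- 0L
  moves <- integer(0)        # +1 = down (toward lower concentration), -1 = up
  move_fracs <- numeric(0)
  trajectory <- integer(0)
  for (o in outcomes) {
    trajectory <- c(trajectory, pos)
    here <- fractions[pos]
    if (o == "correct") {
      streak <- streak + 1L
      if (streak == 3L && pos < n_step) {
        pos <- pos + 1L
        streak <- 0L
        moves <- c(moves, 1L)
        move_fracs <- c(move_fracs, here)
      }
    } else if (o == "incorrect") {
      streak <- 0L
      if (pos > 1L) {
        pos <- pos - 1L
        moves <- c(moves, -1L)
        move_fracs <- c(move_fracs, here)
      }
    } # no_search: nothing moves
  }
  is_rev <- if (length(moves) >= 2L) {
    c(FALSE, moves[-1] != moves[-length(moves)])
  } else rep(FALSE, length(moves))
  list(
    trajectory = trajectory,
    final_pos = pos,
    reversals = move_fracs[is_rev],
    n_reversals = sum(is_rev)
  )
}

# Replay an outcome vector through the package's state machine, collecting
# the presented-step trajectory.
machine_replay <- function(outcomes, ladder) {
  state <- staircase_state(ladder)
  trajectory <- integer(length(outcomes))
  for (i in seq_along(outcomes)) {
    trajectory[i] <- state$current_step
    state <- update_state(state, outcomes[i], ladder)
  }
  list(state = state, trajectory = trajectory)
}

# All correct/incorrect outcome vectors of a given length.
all_outcome_seqs <- function(len) {
  grid <- expand.grid(rep(list(c("correct", "incorrect")), len),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ],
                                                 use.names = FALSE))
}
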