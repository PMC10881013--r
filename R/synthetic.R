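#' Environmental conditions of the threshold study
#'
#' The five chamber conditions: standard (STD, 21 degC / 50% RH), high
#' temperature at high and low humidity (HTHH 40/70, HTLH 40/40), and low
#' temperature at high and low humidity (LTHH 0/90, LTLH 0/50). Tolerance
#' windows are +/-3 degC and +/-5% RH (+/-10% RH for LTLH).
#'
#' @return data.frame with `condition`, `temp_c`, `rh`, `temp_tol`, `rh_tol`.
#' @export
condition_table <- function() {
  data.frame(
    condition = c("STD", "HTHH", "HTLH", "LTHH", "LTLH"),
    temp_c = c(21, 40, 40, 0, 0),
    rh = c(50, 70, 40, 90, 50),
    temp_tol = c(3, 3, 3, 3, 3),
    rh_tol = c(5, 5, 5, 5, 10),
    stringsAsFactors = FALSE
  )
}

# Blocked condition orders per testing group and odor. All dogs start each
# odor at standard; the remaining four conditions are counterbalanced across
# the two groups. Odors are run to completion in the order C4, SP, AN, TNT.
condition_orders <- function() {
  list(
    A = list(
      C4  = c("STD", "LTHH", "HTHH", "HTLH", "LTLH"),
      SP  = c("STD", "HTLH", "LTHH", "LTLH", "HTHH"),
      AN  = c("STD", "HTHH", "LTLH", "LTHH", "HTLH"),
      TNT = c("STD", "LTHH", "HTHH", "HTLH", "LTLH")
    ),
    B = list(
      C4  = c("STD", "HTLH", "LTLH", "LTHH", "HTHH"),
      SP  = c("STD", "LTHH", "HTLH", "HTHH", "LTLH"),
      AN  = c("STD", "LTHH", "HTHH", "LTLH", "HTLH"),
      TNT = c("STD", "HTHH", "HTLH", "LTLH", "LTHH")
    )
  )
}

#' Design descriptor for the environmental-condition experiment
#'
#' Eight dogs (four Labrador retrievers, four German Shorthaired Pointers),
#' four explosive odorants (AN, C4, SP, TNT), five environmental conditions;
#' every dog x odor x condition cell appears exactly once, with condition
#' order blocked by testing group.
#'
#' @param n_dogs Number of dogs (even; split half and half by breed and
#'   across the two order groups).
#' @param odors Odor subset (testing order preserved); the full design uses
#'   all four.
#' @param conditions Condition-label subset; scaled-down simulation studies
#'   can restrict to fewer chamber conditions.
#' @return A `design_spec` list with `dogs` (data.frame: `dog`, `breed`,
#'   `group`), `odors`, `conditions`, `orders`.
#' @export
design_spec_exp1 <- function(n_dogs = 8L,
                             odors = c("C4", "SP", "AN", "TNT"),
                             conditions = c("STD", "HTHH", "HTLH",
                                            "LTHH", "LTLH")) {
  n_dogs <- as.integer(n_dogs)
  if (n_dogs < 2L || n_dogs %% 2L != 0L) {
    stop("n_dogs must be an even count >= 2", call. = FALSE)
  }
  if (!"STD" %in% conditions) {
    stop("the standard condition must be part of the design", call. = FALSE)
  }
  dogs <- data.frame(
    dog = sprintf("dog%02d", seq_len(n_dogs)),
    breed = rep(c("Labrador", "GSP"), length.out = n_dogs),
    group = rep(c("A", "A", "B", "B"), length.out = n_dogs),
    stringsAsFactors = FALSE
  )
  cond_tab <- condition_table()
  orders <- lapply(condition_orders(), function(by_odor) {
    lapply(by_odor[odors], function(ord) ord[ord %in% conditions])
  })
  structure(list(
    experiment = 1L,
    dogs = dogs,
    odors = odors,
    conditions = cond_tab[cond_tab$condition %in% conditions, , drop = FALSE],
    orders = orders
  ), class = "design_spec")
}

#' Acclimatization schedule for the training experiment
#'
#' Day-by-day chamber setpoints for the two groups: the control group stays at
#' standard conditions throughout training, while the acclimatization group
#' ramps from standard to 40 degC / 70% RH over six days and then trains at
#' that condition. On the two test days (11 and 22) both groups are tested at
#' 40 degC / 70% RH.
#'
#' @return data.frame with `day`, `group`, `temp_c`, `rh`, `phase`
#'   (`"baseline"`, `"training"`, `"test"`), one row per group per day
#'   (day 0 is the standard-condition baseline test).
#' @export
acclimation_schedule <- function() {
  ramp_t <- c(21, 24, 28, 31, 34, 38)
  ramp_rh <- c(50, 53, 56, 59, 62, 65)
  days <- 0:22
  rows <- lapply(days, function(d) {
    phase <- if (d == 0) "baseline" else if (d %in% c(11, 22)) "test"
             else "training"
    acc <- if (d == 0) c(21, 50)
           else if (d %in% c(11, 22)) c(40, 70)
           else if (d <= 6) c(ramp_t[d], ramp_rh[d])
           else c(40, 70)
    ctl <- if (d %in% c(11, 22)) c(40, 70) else c(21, 50)
    data.frame(
      day = d,
      group = c("acclimatization", "control"),
      temp_c = c(acc[1], ctl[1]),
      rh = c(acc[2], ctl[2]),
      phase = phase,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Design descriptor for the acclimatization experiment
#'
#' The same eight dogs split into control and acclimatization groups (n = 4
#' each), tested daily on C4 for 22 days under the [acclimation_schedule()],
#' with four reversals per session instead of seven.
#'
#' @param n_per_group Dogs per group.
#' @return A `design_spec` list with `dogs` (`dog`, `breed`, `group`),
#'   `odor`, `schedule`.
#' @export
design_spec_exp2 <- function(n_per_group = 4L) {
  n_per_group <- as.integer(n_per_group)
  dogs <- data.frame(
    dog = sprintf("dog%02d", seq_len(2L * n_per_group)),
    breed = rep(c("Labrador", "GSP"), length.out = 2L * n_per_group),
    group = rep(c("control", "acclimatization"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  structure(list(
    experiment = 2L,
    dogs = dogs,
    odor = "C4",
    schedule = acclimation_schedule()
  ), class = "design_spec")
}

#' Ground-truth effect specification for the synthetic generator
#'
#' Defines the data-generating model the simulators plant: per-odor baseline
#' log10 thresholds (psychometric midpoints), additive condition shifts in
#' log10 units (standard is the zero reference), a dog random intercept, and
#' session noise. Lapse rate and no-search probability grow with heat load,
#' and latency / inter-box intervals are shifted by heat load and by how far
#' the session's true threshold sits above the odor's baseline, so the
#' covariate regressions have planted signal.
#'
#' Default baselines and shifts are set to the magnitudes the study design is
#' built around: a C4 decrement of ~0.47 log10 under hot-humid conditions,
#' smokeless powder below the ladder floor, and dog-to-dog spread of 0.15
#' log10.
#'
#' @param baseline_alpha Named per-odor log10 midpoints.
#' @param delta Named list (per odor) of named condition shifts, log10 units;
#'   missing entries are 0; the standard condition must map to 0.
#' @param sigma_dog Dog random-intercept SD, log10 units.
#' @param sigma_e Session noise SD, log10 units.
#' @param beta Psychometric slope scale, log10 units.
#' @param lapse0 Baseline lapse rate.
#' @param lapse_per_heat Added lapse per unit heat index.
#' @param p_no_search0,p_no_search_heat No-search probability, baseline and
#'   per unit heat index.
#' @param temp_slope Planted slope of log10 threshold per degC of session mean
#'   subcutaneous temperature above `temp_ref` (0 by default: the condition
#'   shifts already carry the between-condition differences).
#' @param temp_ref Reference subcutaneous temperature, degC.
#' @param latency_heat_s,ibi_heat_s Seconds added to latency / IBI per unit
#'   heat index.
#' @param latency_deficit_s,ibi_deficit_s Seconds added per log10 unit of
#'   session threshold elevation above baseline.
#' @param acclim_test_delta Log10 threshold shift for the acclimatization
#'   group on test days (negative = better detection).
#' @param acclim_latency_s,acclim_ibi_s Test-day latency / IBI shifts (s) for
#'   the acclimatization group.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(
    baseline_alpha = c(AN = -0.73, C4 = -1.40, SP = -1.70, TNT = -0.79),
    delta = list(
      AN  = c(HTHH = 0.38, HTLH = 0.28, LTHH = 0.28, LTLH = -0.17),
      C4  = c(HTHH = 0.47, HTLH = 0.38, LTHH = 0.20, LTLH = 0.01),
      SP  = c(HTHH = 0.00, HTLH = 0.00, LTHH = 0.00, LTLH = 0.30),
      TNT = c(HTHH = 0.26, HTLH = -0.09, LTHH = 0.32, LTLH = 0.00)
    ),
    sigma_dog = 0.15, sigma_e = 0.10, beta = 0.15,
    lapse0 = 0.02, lapse_per_heat = 0.02,
    p_no_search0 = 0.005, p_no_search_heat = 0.03,
    temp_slope = 0, temp_ref = 38.5,
    latency_heat_s = 2, ibi_heat_s = 0.8,
    latency_deficit_s = 8, ibi_deficit_s = 3,
    acclim_test_delta = -0.35,
    acclim_latency_s = -3, acclim_ibi_s = -1) {
  if (sigma_dog < 0 || sigma_e < 0) {
    stop("sigma_dog and sigma_e must be non-negative", call. = FALSE)
  }
  for (od in names(delta)) {
    if (!is.null(delta[[od]]["STD"]) && !is.na(delta[[od]]["STD"]) &&
        delta[[od]][["STD"]] != 0) {
      stop("the standard condition shift must be 0", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "effect_spec")
}

# Heat index of a chamber setpoint: 0 at/below standard, ~1.2 at 40C/70%.
heat_index <- function(temp_c, rh) {
  max(0, (temp_c - 21) / 19) * (1 + max(0, (rh - 50) / 100))
}

delta_for <- function(effects, odor, condition) {
  d <- effects$delta[[odor]]
  if (is.null(d) || !condition %in% names(d)) 0 else unname(d[condition])
}

#' Simulated subcutaneous temperature trajectory
#'
#' Microchip readings rise from a common pre-session baseline toward a
#' condition-dependent asymptote as an exponential approach
#' `T(t) = T_asym - (T_asym - T0) * exp(-t / tau)`, sampled every ~5 minutes
#' with reading noise. Low-temperature chamber conditions produce invalid
#' series (the chip readings there were physiologically impossible and are
#' dropped from analysis).
#'
#' @param temp_c,rh Chamber setpoint.
#' @param minutes Session length in minutes.
#' @param t0 Baseline subcutaneous temperature, degC.
#' @param tau Time constant, minutes.
#' @param noise_sd Reading noise SD, degC.
#' @param every_min Reading cadence, minutes.
#' @return data.frame with `minute`, `temp_c`, `valid`.
#' @export
temp_trajectory <- function(temp_c, rh, minutes = 25, t0 = 38.5, tau = 8,
                            noise_sd = 0.15, every_min = 5) {
  times <- seq(0, max(0, minutes), by = every_min)
  valid <- temp_c > 10 # cold-chamber chip readings are unusable
  t_asym <- t0 + 0.4 + 1.4 * heat_index(temp_c, rh)
  temp <- t_asym - (t_asym - t0) * exp(-times / tau) +
    stats::rnorm(length(times), 0, noise_sd)
  data.frame(minute = times, temp_c = temp, valid = valid)
}

# Deterministic per-session child seed below 2^31.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483647)
}

simulate_one_session <- function(effects, odor, condition_row, dog, breed,
                                 rules, ladder, seed,
                                 extra_delta = 0, extra_latency = 0,
                                 extra_ibi = 0, dog_effect = 0) {
  set.seed(seed)
  hi <- heat_index(condition_row$temp_c, condition_row$rh)
  temps <- temp_trajectory(condition_row$temp_c, condition_row$rh)
  mean_temp <- mean_session_temperature(temps)
  temp_term <- if (!is.na(mean_temp)) {
    effects$temp_slope * (mean_temp - effects$temp_ref)
  } else 0

  alpha <- unname(effects$baseline_alpha[odor]) + extra_delta + dog_effect +
    temp_term + stats::rnorm(1, 0, effects$sigma_e)
  deficit <- max(0, alpha - unname(effects$baseline_alpha[odor]))
  obs <- observer(
    alpha = alpha, beta = effects$beta,
    lapse = min(0.1, effects$lapse0 + effects$lapse_per_heat * hi),
    p_no_search = min(0.5, effects$p_no_search0 +
                        effects$p_no_search_heat * hi)
  )
  timing <- default_timing_model(
    latency_shift = max(0, effects$latency_heat_s * hi +
                          effects$latency_deficit_s * deficit +
                          extra_latency),
    ibi_shift = max(0, effects$ibi_heat_s * hi +
                      effects$ibi_deficit_s * deficit + extra_ibi)
  )
  session <- run_session(obs, ladder, rules, seed = NULL,
                         timing_model = timing, dog = dog, odor = odor,
                         condition = condition_row$condition)
  list(session = session, temps = temps, alpha = alpha,
       mean_temp = mean_temp)
}

#' Simulate the full environmental-condition experiment
#'
#' Runs one synthetic staircase session for every dog x odor x condition cell
#' of the design: the session's true log10 threshold is baseline + condition
#' shift + dog random intercept + session noise (plus any planted temperature
#' coupling), a psychometric observer with 3-AFC guess rate 1/3 responds trial
#' by trial, and the 3-down-1-up engine with seven-reversal rules produces the
#' session log. Per-session child seeds are derived from the master seed, so
#' any single session is reproducible in isolation.
#'
#' @param effects An [effect_spec()].
#' @param design A [design_spec_exp1()].
#' @param seed Master integer seed.
#' @param rules Session [termination_rules()]; default seven reversals.
#' @param ladder A [dilution_ladder()].
#' @return An `odor_simulation` list: `sessions` (list of `session_result`),
#'   `thresholds` (imputed threshold table with breed labels), `trials` (long
#'   per-trial data.frame), `temperatures` (long data.frame and keyed list),
#'   `covariates` (from [session_covariates()]), `truth` (planted parameters
#'   and per-session alphas), `rules`.
#' @export
simulate_experiment1 <- function(effects = effect_spec(),
                                 design = design_spec_exp1(),
                                 seed = 1L,
                                 rules = termination_rules(7L),
                                 ladder = default_ladder()) {
  set.seed(as.integer(seed))
  dogs <- design$dogs
  dog_effects <- stats::rnorm(nrow(dogs), 0, effects$sigma_dog)
  names(dog_effects) <- dogs$dog
  cond_tab <- design$conditions

  sessions <- list(); temps_list <- list(); truth_rows <- list()
  idx <- 0L
  for (odor in design$odors) {
    for (i in seq_len(nrow(dogs))) {
      dog <- dogs$dog[i]
      order_i <- design$orders[[dogs$group[i]]][[odor]]
      for (condition in order_i) {
        idx <- idx + 1L
        crow <- cond_tab[cond_tab$condition == condition, ]
        out <- simulate_one_session(
          effects, odor, crow, dog, dogs$breed[i], rules, ladder,
          seed = child_seed(seed, idx),
          extra_delta = delta_for(effects, odor, condition),
          dog_effect = dog_effects[[dog]]
        )
        key <- paste(dog, odor, condition, sep = "|")
        sessions[[key]] <- out$session
        temps_list[[key]] <- out$temps
        truth_rows[[key]] <- data.frame(
          dog = dog, odor = odor, condition = condition,
          true_alpha = out$alpha, mean_temp = out$mean_temp,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  thresholds <- do.call(rbind, lapply(names(sessions), function(key) {
    s <- sessions[[key]]
    breed <- dogs$breed[match(s$dog, dogs$dog)]
    session_threshold(s, rules, impute = TRUE, breed = breed)
  }))
  rownames(thresholds) <- NULL

  structure(list(
    sessions = sessions,
    thresholds = thresholds,
    trials = sessions_to_trials(sessions),
    temperatures = list(
      by_session = temps_list,
      table = temps_to_table(temps_list)
    ),
    covariates = session_covariates(sessions, temps_list),
    truth = list(
      dog_effects = dog_effects,
      sessions = do.call(rbind, truth_rows),
      effects = effects, seed = as.integer(seed)
    ),
    rules = rules
  ), class = "odor_simulation")
}

#' Simulate the acclimatization experiment
#'
#' Daily C4 staircase sessions (four-reversal rules) for two groups of dogs
#' over the [acclimation_schedule()]: the control group trains at standard
#' conditions, the acclimatization group ramps to 40 degC / 70% RH; on test
#' days (11 and 22) both groups are tested at 40 degC / 70% RH and the planted
#' group effect (`acclim_test_delta`, plus latency / IBI shifts) applies to
#' the acclimatization group.
#'
#' @inheritParams simulate_experiment1
#' @param design A [design_spec_exp2()].
#' @param rules Session rules; default four reversals.
#' @return An `odor_simulation` list as in [simulate_experiment1()], with
#'   `day`, `group` and `phase` columns on the threshold table.
#' @export
simulate_experiment2 <- function(effects = effect_spec(),
                                 design = design_spec_exp2(),
                                 seed = 1L,
                                 rules = termination_rules(4L),
                                 ladder = default_ladder()) {
  set.seed(as.integer(seed))
  dogs <- design$dogs
  dog_effects <- stats::rnorm(nrow(dogs), 0, effects$sigma_dog)
  names(dog_effects) <- dogs$dog
  sched <- design$schedule
  odor <- design$odor

  sessions <- list(); temps_list <- list(); rows <- list()
  idx <- 0L
  for (d in sort(unique(sched$day))) {
    for (i in seq_len(nrow(dogs))) {
      idx <- idx + 1L
      dog <- dogs$dog[i]; grp <- dogs$group[i]
      srow <- sched[sched$day == d & sched$group == grp, ]
      condition <- condition_label(srow$temp_c, srow$rh)
      crow <- data.frame(condition = condition, temp_c = srow$temp_c,
                         rh = srow$rh)
      on_test <- srow$phase == "test"
      acclim <- grp == "acclimatization"
      out <- simulate_one_session(
        effects, odor, crow, dog, dogs$breed[i], rules, ladder,
        seed = child_seed(seed, 100000L + idx),
        extra_delta = delta_for(effects, odor, condition) +
          if (on_test && acclim) effects$acclim_test_delta else 0,
        extra_latency = if (on_test && acclim) effects$acclim_latency_s
                        else 0,
        extra_ibi = if (on_test && acclim) effects$acclim_ibi_s else 0,
        dog_effect = dog_effects[[dog]]
      )
      key <- paste(dog, odor, condition, d, sep = "|")
      sessions[[key]] <- out$session
      temps_list[[key]] <- out$temps
      thr <- session_threshold(out$session, rules, impute = TRUE,
                               breed = dogs$breed[i], group = grp,
                               day = as.integer(d))
      thr$phase <- srow$phase
      rows[[key]] <- thr
    }
  }
  thresholds <- do.call(rbind, rows)
  rownames(thresholds) <- NULL

  structure(list(
    sessions = sessions,
    thresholds = thresholds,
    trials = sessions_to_trials(sessions),
    temperatures = list(by_session = temps_list,
                        table = temps_to_table(temps_list)),
    covariates = NULL,
    truth = list(dog_effects = dog_effects, effects = effects,
                 seed = as.integer(seed)),
    rules = rules
  ), class = "odor_simulation")
}

# Label the HTHH test condition canonically; ramp setpoints get literal
# labels so the schedule stays visible in the output tables.
condition_label <- function(temp_c, rh) {
  if (temp_c == 21 && rh == 50) "STD"
  else if (temp_c == 40 && rh == 70) "HTHH"
  else sprintf("RAMP_%dC_%dRH", temp_c, rh)
}

sessions_to_trials <- function(sessions) {
  do.call(rbind, lapply(unname(sessions), function(s) {
    cbind(data.frame(dog = s$dog, odor = s$odor, condition = s$condition,
                     stringsAsFactors = FALSE),
          s$trials)
  }))
}

temps_to_table <- function(temps_list) {
  do.call(rbind, lapply(names(temps_list), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cbind(data.frame(session_id = key, dog = parts[1],
                     condition = parts[3], stringsAsFactors = FALSE),
          temps_list[[key]])
  }))
}

#' @export
print.odor_simulation <- function(x, ...) {
  cat(sprintf("Synthetic threshold study: %d sessions, %d trials\n",
              length(x$sessions), nrow(x$trials)))
  cat("Termination reasons:\n")
  print(table(x$thresholds$termination_reason))
  invisible(x)
}
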