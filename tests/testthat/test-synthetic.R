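test_that("the 3-AFC psychometric function hits its landmarks", {
  obs <- observer(alpha = -1, beta = 0.15, lapse = 0)
  # high-concentration limit: certainty; low limit: 3-AFC guessing floor
  expect_gt(p_correct(obs, 1), 0.999)
  expect_equal(p_correct(obs, 1e-9), 1 / 3, tolerance = 1e-4)
  # midpoint: halfway between guess rate and ceiling
  expect_equal(p_correct(obs, 10^-1), 1 / 3 + (1 - 1 / 3) / 2,
               tolerance = 1e-12)
  lapsy <- observer(alpha = -1, beta = 0.15, lapse = 0.05)
  expect_lte(max(p_correct(lapsy, c(0.5, 0.9, 1))), 0.95)
  expect_error(p_correct(obs, 0), "positive")
  expect_error(observer(alpha = -1, beta = -1), "beta")
  expect_error(observer(alpha = -1, lapse = 0.5), "lapse")
})

test_that("the 3-down-1-up equilibrium accuracy solves p^3 = 1/2", {
  p <- staircase_equilibrium_accuracy()
  expect_equal(p^3, 0.5, tolerance = 1e-12)
  expect_equal(p, 0.7937, tolerance = 1e-4)
  expect_gt(p, 1 / 3)
})

test_that("the full-design simulation covers every cell exactly once", {
  sim <- simulate_experiment1(seed = 11)
  expect_equal(length(sim$sessions), 8 * 4 * 5)
  cells <- with(sim$thresholds, table(dog, odor, condition))
  expect_true(all(cells == 1))
  expect_setequal(unique(sim$thresholds$condition),
                  c("STD", "HTHH", "HTLH", "LTHH", "LTLH"))
  expect_setequal(unique(sim$thresholds$breed), c("Labrador", "GSP"))
  expect_false(any(is.na(sim$thresholds$log10_threshold)))
  # thresholds stay inside the ladder's log range
  expect_true(all(sim$thresholds$log10_threshold >= log10(0.03) - 1e-9))
  expect_true(all(sim$thresholds$log10_threshold <= log10(0.80) + 1e-9))
})

test_that("simulation is deterministic and session-reproducible", {
  a <- simulate_experiment1(seed = 5)
  b <- simulate_experiment1(seed = 5)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$trials, b$trials)
  c <- simulate_experiment1(seed = 6)
  expect_false(identical(a$thresholds$log10_threshold,
                         c$thresholds$log10_threshold))
})

test_that("a tight generator brackets its planted baseline", {
  # no condition/dog/session variation and a steep observer: every threshold
  # within one ladder step of the planted location
  effects <- effect_spec(
    baseline_alpha = c(C4 = -0.62), delta = list(),
    sigma_dog = 0, sigma_e = 0, beta = 0.05,
    lapse0 = 0, lapse_per_heat = 0,
    p_no_search0 = 0, p_no_search_heat = 0)
  design <- design_spec_exp1(n_dogs = 4, odors = "C4",
                             conditions = c("STD", "HTHH"))
  sim <- simulate_experiment1(effects, design, seed = 2)
  expect_true(all(abs(sim$thresholds$log10_threshold - (-0.62)) <= 0.61))
})

test_that("acclimatization schedule matches the ramp design", {
  sched <- acclimation_schedule()
  d1 <- sched[sched$day == 1, ]
  expect_true(all(d1$temp_c == 21) && all(d1$rh == 50))
  d6a <- sched[sched$day == 6 & sched$group == "acclimatization", ]
  expect_equal(c(d6a$temp_c, d6a$rh), c(38, 65))
  # both groups tested at 40C/70% on the two test days
  tests <- sched[sched$phase == "test", ]
  expect_setequal(unique(tests$day), c(11, 22))
  expect_true(all(tests$temp_c == 40) && all(tests$rh == 70))
  # control trains at standard throughout
  ctl <- sched[sched$group == "control" & sched$phase == "training", ]
  expect_true(all(ctl$temp_c == 21))
})

test_that("the acclimatization simulation plants its group effect", {
  sim <- simulate_experiment2(seed = 3)
  thr <- sim$thresholds
  expect_equal(nrow(thr), 8 * 23) # 8 dogs, days 0..22
  expect_setequal(unique(thr$group), c("control", "acclimatization"))
  tests <- thr[thr$phase == "test", ]
  expect_equal(nrow(tests), 16)
  expect_true(all(tests$condition == "HTHH"))
  # day 0 baseline at standard for everyone
  expect_true(all(thr$condition[thr$day == 0] == "STD"))

  # with a null group effect, test-day groups differ only by noise
  null_fx <- effect_spec(acclim_test_delta = 0, acclim_latency_s = 0,
                         acclim_ibi_s = 0)
  nsim <- simulate_experiment2(null_fx, seed = 3)
  ntests <- nsim$thresholds[nsim$thresholds$phase == "test", ]
  gap <- abs(mean(ntests$log10_threshold[ntests$group == "control"]) -
             mean(ntests$log10_threshold[ntests$group ==
                                           "acclimatization"]))
  expect_lt(gap, 0.5)
})

test_that("temperature trajectories rise toward condition asymptotes", {
  set.seed(8)
  hot <- temp_trajectory(40, 70, minutes = 60, noise_sd = 0)
  expect_equal(hot$temp_c[1], 38.5, tolerance = 1e-6) # t = 0 baseline
  expect_true(all(diff(hot$temp_c) > 0))
  asym <- function(t, rh) {
    tail(temp_trajectory(t, rh, minutes = 400, noise_sd = 0)$temp_c, 1)
  }
  # asymptote ordering: hot-humid > hot-dry > standard
  expect_gt(asym(40, 70), asym(40, 40))
  expect_gt(asym(40, 40), asym(21, 50))
  # cold chamber conditions give invalid series
  expect_false(any(temp_trajectory(0, 90, minutes = 25)$valid))
  expect_true(all(temp_trajectory(21, 50, minutes = 25)$valid))
})
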