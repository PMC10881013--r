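make_sim <- function(seed = 21) {
  # two odors a full log unit apart, no condition effects, quiet noise
  effects <- effect_spec(
    baseline_alpha = c(AN = -0.4, C4 = -1.1),
    delta = list(), sigma_dog = 0.1, sigma_e = 0.08,
    lapse_per_heat = 0, p_no_search_heat = 0)
  design <- design_spec_exp1(n_dogs = 8, odors = c("C4", "AN"),
                             conditions = c("STD", "HTHH", "HTLH"))
  simulate_experiment1(effects, design, seed = seed)
}

test_that("a planted odor effect is detected while condition stays null", {
  sim <- make_sim()
  fit <- fit_threshold_model(sim$thresholds)
  expect_s3_class(fit, "model_summary")
  odor_row <- fit$terms[fit$terms$term == "odor", ]
  cond_row <- fit$terms[fit$terms$term == "condition", ]
  expect_lt(odor_row$p, 1e-8)
  expect_equal(odor_row$df, 1)
  expect_gt(cond_row$p, 0.01)
  expect_equal(fit$n, nrow(sim$thresholds))
})

test_that("degenerate designs drop terms instead of erroring", {
  sim <- make_sim()
  one_odor <- sim$thresholds[sim$thresholds$odor == "C4", ]
  fit <- fit_threshold_model(one_odor)
  expect_false(any(grepl("odor", fit$terms$term)))
  expect_true("condition" %in% fit$terms$term)
  expect_error(
    fit_threshold_model(one_odor[one_odor$dog == "dog01", ]),
    "two dogs")
})

test_that("post-hoc contrasts are condition minus standard within odor", {
  effects <- effect_spec(
    baseline_alpha = c(C4 = -0.9, AN = -0.5),
    delta = list(C4 = c(HTHH = 0.47), AN = c(HTHH = 0)),
    sigma_dog = 0.1, sigma_e = 0.08,
    lapse_per_heat = 0, p_no_search_heat = 0)
  design <- design_spec_exp1(n_dogs = 16, odors = c("C4", "AN"),
                             conditions = c("STD", "HTHH"))
  sim <- simulate_experiment1(effects, design, seed = 31)
  fit <- fit_threshold_model(sim$thresholds)
  ph <- posthoc_condition_vs_standard(fit)
  expect_setequal(ph$condition, "HTHH")
  c4 <- ph[ph$odor == "C4", ]
  an <- ph[ph$odor == "AN", ]
  # the planted decrement is recovered; the null odor's contrast is small
  expect_equal(c4$estimate, 0.47, tolerance = 0.35)
  expect_gt(c4$estimate, an$estimate)
  expect_lt(abs(an$estimate), 0.25)
  expect_true(all(ph$p_adj >= ph$p_value - 1e-12))
})

test_that("covariate models report slopes and reject degenerate input", {
  sim <- make_sim()
  fit <- fit_covariate_model(sim$thresholds, sim$covariates, "mean_latency",
                             conditions = c("STD", "HTHH", "HTLH"))
  expect_true(is.finite(fit$slope))
  expect_true("mean_latency" %in% fit$terms$term)
  # temperature model restricts itself to the valid-chip conditions
  fit_t <- fit_covariate_model(sim$thresholds, sim$covariates, "mean_temp")
  expect_true(all(fit_t$model@frame$condition %in%
                    c("STD", "HTHH", "HTLH")))
  const <- sim$covariates
  const$mean_ibi <- 1.5
  expect_error(fit_covariate_model(sim$thresholds, const, "mean_ibi"),
               "constant")
  empty <- sim$covariates
  empty$mean_temp <- NA_real_
  expect_error(fit_covariate_model(sim$thresholds, empty, "mean_temp"),
               "missing")
})

test_that("the acclimatization model tests the treatment group", {
  sim <- simulate_experiment2(seed = 13)
  fit <- fit_acclimation_model(sim$thresholds)
  expect_equal(fit$terms$term, "group")
  expect_equal(fit$terms$df, 1)
  expect_equal(fit$n, 16)
  # companion behavioral response off the same records
  thr <- sim$thresholds
  thr$mean_dur <- vapply(sim$sessions, function(s) s$session_duration_min,
                         numeric(1))
  fit2 <- fit_acclimation_model(thr, response = "mean_dur")
  expect_equal(fit2$response, "mean_dur")
  one_group <- thr[thr$group == "control", ]
  expect_error(fit_acclimation_model(one_group), "both treatment groups")
  expect_error(fit_acclimation_model(thr, response = "nope"), "not found")
})

test_that("fold change inverts the log10 scale", {
  expect_identical(fold_change(0), 1)
  expect_equal(fold_change(0.47), 2.95, tolerance = 0.005)
  set.seed(2)
  x <- runif(20, 0.01, 50)
  expect_equal(fold_change(log10(x)), x, tolerance = 1e-10)
})

test_that("condition summaries are raw cell means with t intervals", {
  rec <- data.frame(
    dog = rep(sprintf("d%d", 1:4), 2),
    odor = "C4",
    condition = rep(c("STD", "HTHH"), each = 4),
    log10_threshold = c(rep(-1.523, 4), c(-1.0, -1.2, -0.8, -1.0))
  )
  cs <- condition_summary(rec)
  std <- cs[cs$condition == "STD", ]
  expect_equal(std$mean_log10, -1.523)
  expect_equal(std$ci_lo, std$ci_hi) # zero spread collapses the interval
  hot <- cs[cs$condition == "HTHH", ]
  expect_equal(hot$mean_log10, -1.0)
  half <- qt(0.975, 3) * sd(c(-1.0, -1.2, -0.8, -1.0)) / 2
  expect_equal(hot$ci_hi - hot$mean_log10, half, tolerance = 1e-12)
})

test_that("VOC quantification divides by the response factor", {
  curve <- calibration_curve("DMNB", slope = 5, r_squared = 0.999)
  expect_identical(voc_quantify(0, curve), 0)
  expect_identical(voc_quantify(5, curve), 1)
  expect_identical(voc_quantify(250, curve), 50)
  expect_error(calibration_curve("x", slope = -1), "positive")
  expect_error(calibration_curve("x", slope = 1, r_squared = 0.9),
               "linearity")
})

test_that("VOC-threshold regressions recover a planted positive slope", {
  voc <- simulate_voc(seed = 4)
  expect_equal(nrow(voc), 4 * 4 * 10)
  expect_true(all(table(voc$odor, voc$condition) == 10))
  # plant thresholds that rise with condition-mean VOC
  cm <- aggregate(total_voc_ppm ~ odor + condition, voc, mean)
  set.seed(9)
  rec <- do.call(rbind, lapply(1:8, function(d) {
    data.frame(dog = sprintf("d%d", d), odor = cm$odor,
               condition = cm$condition,
               log10_threshold = -1.2 + 0.0016 * cm$total_voc_ppm +
                 rnorm(nrow(cm), 0, 0.1))
  }))
  fits <- fit_voc_threshold(rec, voc)
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$slope > 0))
  expect_equal(fits$units[1], "log10 per 100 ppm")
  # per-ppm reporting rescales the same fit
  per_ppm <- fit_voc_threshold(rec, voc, per_ppm = TRUE)
  expect_equal(per_ppm$slope * 100, fits$slope, tolerance = 1e-10)
  # constant availability cannot identify a slope
  flat <- voc
  flat$total_voc_ppm <- 300
  expect_error(fit_voc_threshold(rec, flat), "distinct VOC")
})
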