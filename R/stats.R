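#' @importFrom lme4 lmer
#' @importFrom car Anova
NULL

# Wrap a fitted mixed model with its Wald Type-II chi-square table.
new_model_summary <- function(model, data, note = NULL) {
  an <- as.data.frame(car::Anova(model, type = 2))
  terms <- data.frame(
    term = rownames(an),
    chisq = an[["Chisq"]],
    df = an[["Df"]],
    p = an[["Pr(>Chisq)"]],
    stringsAsFactors = FALSE
  )
  rownames(terms) <- NULL
  fixed <- as.data.frame(summary(model)$coefficients)
  structure(list(
    model = model,
    terms = terms,
    fixed = fixed,
    n = nrow(data),
    singular = lme4::isSingular(model),
    note = note
  ), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("Linear mixed model on %d observations%s\n", x$n,
              if (x$singular) " (singular fit)" else ""))
  cat("Wald Type-II chi-square tests:\n")
  print(x$terms, row.names = FALSE, digits = 4)
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

prepare_threshold_factors <- function(records) {
  records <- records[!is.na(records$log10_threshold), , drop = FALSE]
  records$condition <- stats::relevel(
    factor(records$condition), ref = intersect("STD",
                                               unique(records$condition))[1])
  records$odor <- factor(records$odor)
  if (!is.null(records$breed)) records$breed <- factor(records$breed)
  records$dog <- factor(records$dog)
  records
}

#' Mixed-effects model of log threshold on breed, condition and odor
#'
#' Fits the study's primary model: log10 detection threshold predicted by
#' breed, environmental condition, odor and the condition x odor interaction,
#' with a random intercept per dog; REML estimation and Wald Type-II
#' chi-square tests per fixed term. Terms with fewer than two observed levels
#' (e.g. a single odor) are dropped rather than erroring, and singular fits
#' are reported through the summary's `singular` flag.
#'
#' @param records Threshold table (one row per dog x odor x condition) with
#'   columns `dog`, `odor`, `condition`, `breed`, `log10_threshold`. The
#'   standard condition `"STD"` is used as the reference level.
#' @return A `model_summary`: fitted `lmerMod`, `terms` (chi-square table),
#'   `fixed`, `n`, `singular`.
#' @export
fit_threshold_model <- function(records) {
  records <- prepare_threshold_factors(records)
  if (length(unique(records$dog)) < 2L) {
    stop("at least two dogs are required", call. = FALSE)
  }
  has_odor <- nlevels(records$odor) > 1L
  has_cond <- nlevels(records$condition) > 1L
  has_breed <- !is.null(records$breed) && nlevels(records$breed) > 1L &&
    !anyNA(records$breed)
  rhs <- c(
    if (has_breed) "breed",
    if (has_cond && has_odor) "condition * odor"
    else c(if (has_cond) "condition", if (has_odor) "odor")
  )
  if (length(rhs) == 0L) rhs <- "1"
  fml <- stats::as.formula(paste("log10_threshold ~",
                                 paste(rhs, collapse = " + "),
                                 "+ (1 | dog)"))
  model <- suppressMessages(lme4::lmer(fml, data = records, REML = TRUE))
  new_model_summary(model, records)
}

#' Post-hoc contrasts of each condition against standard, within odor
#'
#' Estimated-marginal-mean differences (condition minus standard) for every
#' non-standard condition within each odor, from the fitted interaction model.
#' Positive estimates mean poorer detection than standard. P-values are
#' reported both unadjusted and with a Dunnett-style multiplicity adjustment;
#' the two are emitted side by side because summaries of this design are
#' conventionally reported both ways.
#'
#' @param fit A `model_summary` from [fit_threshold_model()] (the model must
#'   contain the condition term; the odor term is optional).
#' @return data.frame with `odor` (when present), `condition`, `estimate`,
#'   `se`, `df`, `t_ratio`, `p_value` (unadjusted), `p_adj`.
#' @export
posthoc_condition_vs_standard <- function(fit) {
  model <- fit$model
  dat <- model@frame
  if (!"condition" %in% names(dat)) {
    stop("model has no condition term", call. = FALSE)
  }
  if (!"STD" %in% levels(dat$condition)) {
    stop("standard condition level missing", call. = FALSE)
  }
  by_odor <- "odor" %in% names(dat)
  spec <- if (by_odor) ~ condition | odor else ~ condition
  em <- emmeans::emmeans(model, spec)
  ref <- which(levels(dat$condition) == "STD")
  raw <- as.data.frame(summary(
    emmeans::contrast(em, "trt.vs.ctrl", ref = ref), adjust = "none"))
  adj <- as.data.frame(summary(
    emmeans::contrast(em, "trt.vs.ctrl", ref = ref), adjust = "dunnettx"))
  out <- data.frame(
    condition = sub(" - STD$", "", raw$contrast),
    estimate = raw$estimate,
    se = raw$SE,
    df = raw$df,
    t_ratio = raw$t.ratio,
    p_value = raw$p.value,
    p_adj = adj$p.value,
    stringsAsFactors = FALSE
  )
  if (by_odor) out <- cbind(odor = as.character(raw$odor), out)
  out
}

#' Mixed model of log threshold on a session covariate
#'
#' Fits `log10_threshold ~ covariate * odor + (1 | dog)` for one of the
#' session-level behavioral/physiological covariates: mean subcutaneous
#' temperature over the first 25 minutes (restricted to the standard and two
#' hot conditions, where the chip readings are valid), mean searched-trial
#' latency, or mean inter-box interval. Missing covariates drop their rows
#' (complete-case).
#'
#' @param records Threshold table.
#' @param covariates Covariate table from [session_covariates()] with `dog`,
#'   `odor`, `condition` keys.
#' @param covariate One of `"mean_temp"`, `"mean_latency"`, `"mean_ibi"`.
#' @param conditions Optional condition filter; defaults to
#'   `c("STD", "HTHH", "HTLH")` for `mean_temp`, all conditions otherwise.
#' @return A `model_summary`; the covariate's main-effect slope is also
#'   exposed as `$slope`.
#' @export
fit_covariate_model <- function(records, covariates,
                                covariate = c("mean_temp", "mean_latency",
                                              "mean_ibi"),
                                conditions = NULL) {
  covariate <- match.arg(covariate)
  if (is.null(conditions) && covariate == "mean_temp") {
    conditions <- c("STD", "HTHH", "HTLH")
  }
  dat <- merge(records, covariates, by = c("dog", "odor", "condition"))
  if (!is.null(conditions)) {
    dat <- dat[dat$condition %in% conditions, , drop = FALSE]
  }
  dat <- dat[!is.na(dat[[covariate]]) & !is.na(dat$log10_threshold), ,
             drop = FALSE]
  if (nrow(dat) == 0L) stop("covariate entirely missing", call. = FALSE)
  if (length(unique(dat[[covariate]])) < 2L) {
    stop("covariate is constant; slope undefined", call. = FALSE)
  }
  dat <- prepare_threshold_factors(dat)
  has_odor <- nlevels(dat$odor) > 1L
  fml <- stats::as.formula(paste(
    "log10_threshold ~", covariate,
    if (has_odor) "* odor" else "", "+ (1 | dog)"))
  model <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  out <- new_model_summary(model, dat)
  out$covariate <- covariate
  out$slope <- unname(lme4::fixef(model)[covariate])
  out
}

#' Treatment-group model for the acclimatization experiment
#'
#' Fits `response ~ group + (1 | dog)` on the two test days (both groups
#' tested at 40 degC / 70% RH), pooling the first and second test. The
#' response is the log10 threshold by default, with companion models for the
#' behavioral responses (mean subcutaneous temperature, inter-box interval,
#' search latency) selected via `response`.
#'
#' @param records Exp-2 threshold table (with `group`, `day`, `phase`
#'   columns), or any session-level table carrying the chosen response.
#' @param response Column name of the response variable.
#' @param test_days Days treated as test days; defaults to rows flagged
#'   `phase == "test"` when present, else days 11 and 22.
#' @return A `model_summary`; the treatment chi-square is the `group` row of
#'   `$terms`.
#' @export
fit_acclimation_model <- function(records, response = "log10_threshold",
                                  test_days = NULL) {
  if (!response %in% names(records)) {
    stop(sprintf("response column '%s' not found", response), call. = FALSE)
  }
  dat <- records
  if (!is.null(dat$phase) && is.null(test_days)) {
    dat <- dat[dat$phase == "test", , drop = FALSE]
  } else {
    if (is.null(test_days)) test_days <- c(11L, 22L)
    dat <- dat[dat$day %in% test_days, , drop = FALSE]
  }
  dat <- dat[!is.na(dat[[response]]), , drop = FALSE]
  groups <- unique(dat$group)
  if (length(groups) < 2L) {
    stop("both treatment groups must be present", call. = FALSE)
  }
  dat$group <- stats::relevel(factor(dat$group), ref = "control")
  dat$dog <- factor(dat$dog)
  fml <- stats::as.formula(paste(response, "~ group + (1 | dog)"))
  model <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  out <- new_model_summary(model, dat)
  out$response <- response
  out$group_estimate <- unname(lme4::fixef(model)[grep(
    "^group", names(lme4::fixef(model)))][1])
  out
}

#' Fold change corresponding to a log10 threshold difference
#'
#' @param delta_log10 Difference on the log10 threshold scale.
#' @return `10^delta_log10`: the multiplicative detection-limit change.
#' @examples
#' fold_change(0.47) # ~2.95-fold poorer detection
#' @export
fold_change <- function(delta_log10) 10^delta_log10

#' Raw per-cell summary of log thresholds
#'
#' Arithmetic mean of the per-dog log10 thresholds in every odor x condition
#' cell with a t-based 95% confidence interval — the descriptive summary a
#' threshold table is conventionally reported as.
#'
#' @param records Threshold table.
#' @return data.frame with `odor`, `condition`, `n`, `mean_log10`,
#'   `ci_lo`, `ci_hi`.
#' @export
condition_summary <- function(records) {
  records <- records[!is.na(records$log10_threshold), , drop = FALSE]
  cells <- split(records,
                 list(records$odor, records$condition), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(cell) {
    n <- nrow(cell)
    m <- mean(cell$log10_threshold)
    half <- if (n >= 2) {
      stats::qt(0.975, n - 1) * stats::sd(cell$log10_threshold) / sqrt(n)
    } else NA_real_
    data.frame(odor = cell$odor[1], condition = cell$condition[1], n = n,
               mean_log10 = m, ci_lo = m - half, ci_hi = m + half,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$odor, out$condition), ]
}
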