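#' External calibration curve for a signature volatile compound
#'
#' Headspace volatiles captured on the SPME fiber are quantified by external
#' calibration: a standard mix is run over 1--100 mg/L and the fitted line's
#' slope serves as the compound's response factor. Linearity of r-squared
#' above 0.98 over the range is required.
#'
#' @param compound Compound label.
#' @param slope Calibration slope (instrument response per mg/L); must be
#'   positive.
#' @param intercept Calibration intercept.
#' @param r_squared Linear fit r-squared; must exceed 0.98.
#' @param range_mg_l Calibrated concentration range, mg/L.
#' @return A `calibration_curve` list.
#' @export
calibration_curve <- function(compound, slope, intercept = 0,
                              r_squared = 1, range_mg_l = c(1, 100)) {
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (r_squared <= 0.98) {
    stop("calibration linearity below the 0.98 criterion", call. = FALSE)
  }
  structure(list(compound = compound, slope = slope, intercept = intercept,
                 r_squared = r_squared, range_mg_l = range_mg_l),
            class = "calibration_curve")
}

#' Quantify instrument response via a response factor
#'
#' Converts a GC-MS peak response to a concentration by dividing by the
#' compound's calibration-curve slope (its response factor).
#'
#' @param instrument_response Numeric response(s), >= 0.
#' @param curve A [calibration_curve()].
#' @return Concentration(s) on the calibration scale (ppm-equivalent).
#' @examples
#' voc_quantify(250, calibration_curve("DMNB", slope = 5))
#' @export
voc_quantify <- function(instrument_response, curve) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a calibration_curve", call. = FALSE)
  }
  instrument_response / curve$slope
}

#' Per-odor regression of threshold on odor availability
#'
#' Regresses the log10 detection threshold on condition-mean total VOC
#' accumulation (the odor-availability measure), one simple linear model per
#' odor. VOC was sampled per condition (not per session) in every extreme
#' condition but not at standard, so thresholds are joined to VOC at the
#' condition level and the standard condition is excluded; environmental
#' condition itself is not a covariate because it is collinear with VOC.
#'
#' @param records Threshold table.
#' @param voc VOC sample table with columns `odor`, `condition`,
#'   `total_voc_ppm` (replicate-level; condition means are taken here).
#' @param per_ppm Scale of the reported slope: VOC is entered in units of
#'   100 ppm by default (`per_ppm = FALSE`) so slopes are of order 0.1; set
#'   `TRUE` for raw per-ppm slopes.
#' @return data.frame with one row per odor: `odor`, `slope`, `se`,
#'   `t_value`, `p_value`, `n`, `units`.
#' @export
fit_voc_threshold <- function(records, voc, per_ppm = FALSE) {
  voc <- voc[voc$condition != "STD", , drop = FALSE]
  cond_means <- stats::aggregate(total_voc_ppm ~ odor + condition,
                                 data = voc, FUN = mean)
  names(cond_means)[names(cond_means) == "total_voc_ppm"] <- "voc_mean"
  dat <- merge(records[records$condition != "STD", , drop = FALSE],
               cond_means, by = c("odor", "condition"))
  dat <- dat[!is.na(dat$log10_threshold), , drop = FALSE]
  scale <- if (per_ppm) 1 else 100
  units <- if (per_ppm) "log10 per ppm" else "log10 per 100 ppm"

  out <- do.call(rbind, lapply(split(dat, dat$odor), function(d) {
    if (length(unique(d$voc_mean)) < 3L) {
      stop(sprintf(
        "odor %s: fewer than 3 distinct VOC values; slope undefined",
        d$odor[1]), call. = FALSE)
    }
    fit <- stats::lm(log10_threshold ~ I(voc_mean / scale), data = d)
    cf <- summary(fit)$coefficients
    data.frame(odor = d$odor[1], slope = cf[2, 1], se = cf[2, 2],
               t_value = cf[2, 3], p_value = cf[2, 4], n = nrow(d),
               units = units, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate an SPME GC-MS odor-availability table
#'
#' Generates replicate total-VOC measurements per odor x extreme condition
#' (ten replicates each by default; standard conditions were not sampled).
#' Condition-level availability follows the headspace physics the study
#' observed: hot conditions average ~501 ppm against ~101 ppm in the cold,
#' with higher availability at high humidity. Replicates are lognormal around
#' the condition x odor mean.
#'
#' @param seed Integer seed.
#' @param odors Odor labels.
#' @param n_replicates Replicates per odor x condition.
#' @param condition_means Named mean total VOC (ppm) per extreme condition.
#' @param odor_scale Named per-odor multipliers on the condition means.
#' @param sdlog Lognormal replicate spread.
#' @return data.frame with `odor`, `condition`, `replicate`,
#'   `total_voc_ppm`.
#' @export
simulate_voc <- function(seed = 1L,
                         odors = c("AN", "C4", "SP", "TNT"),
                         n_replicates = 10L,
                         condition_means = c(HTHH = 540, HTLH = 462,
                                             LTHH = 128, LTLH = 74),
                         odor_scale = c(AN = 0.8, C4 = 1.1, SP = 1.2,
                                        TNT = 0.9),
                         sdlog = 0.2) {
  set.seed(as.integer(seed))
  grid <- expand.grid(odor = odors, condition = names(condition_means),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$odor, grid$condition, grid$replicate), ]
  mu <- condition_means[grid$condition] * odor_scale[grid$odor]
  grid$total_voc_ppm <- stats::rlnorm(nrow(grid),
                                      meanlog = log(mu) - sdlog^2 / 2,
                                      sdlog = sdlog)
  rownames(grid) <- NULL
  grid
}
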