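#' Air-dilution fraction from olfactometer line flows
#'
#' The olfactometer generates each concentration step as an air dilution: a
#' regulated odor line (measured in cc/min) displaces vial headspace into a
#' mixing manifold where it is diluted by a regulated clean-air line (measured
#' in L/min). The delivered stimulus intensity is the fraction of odor-line
#' flow in the total flow.
#'
#' Flowmeter units differ between the two lines, so the clean-line flow is
#' converted to cc/min (x 1000) before the ratio is formed. Under that
#' convention the standard flow settings reproduce the nominal 80/50/25/12/3%
#' ladder after rounding to whole percent.
#'
#' @param odor_flow Odor-line flow rate in cc/min; must be positive.
#' @param clean_flow Clean (dilution) line flow rate in L/min; must be
#'   non-negative. Zero means no dilution.
#' @return Unitless dilution fraction in (0, 1]:
#'   `odor_flow / (odor_flow + 1000 * clean_flow)`.
#' @examples
#' concentration_from_flows(1000, 0.25) # 0.8
#' concentration_from_flows(90, 2.91)   # 0.03
#' @export
concentration_from_flows <- function(odor_flow, clean_flow) {
  if (!is.numeric(odor_flow) || !is.numeric(clean_flow)) {
    stop("flows must be numeric", call. = FALSE)
  }
  if (any(!is.finite(odor_flow)) || any(!is.finite(clean_flow))) {
    stop("flows must be finite", call. = FALSE)
  }
  if (any(odor_flow <= 0)) {
    stop("odor_flow must be positive", call. = FALSE)
  }
  if (any(clean_flow < 0)) {
    stop("clean_flow must be non-negative", call. = FALSE)
  }
  odor_flow / (odor_flow + 1000 * clean_flow)
}

#' Construct a dilution ladder
#'
#' A dilution ladder is the ordered series of concentration steps the staircase
#' moves through, highest concentration first (step 1). Each step carries the
#' flowmeter settings that realise it, the nominal fraction used for all
#' threshold arithmetic, and the actual flow-derived fraction.
#'
#' @param step_number Integer step indices, 1 = highest concentration.
#' @param odor_flow Odor-line flows, cc/min.
#' @param clean_flow Clean-line flows, L/min.
#' @param nominal_fraction Nominal unitless fractions in (0, 1], strictly
#'   decreasing with step number. These, not the flow-derived values, are used
#'   in threshold computation (the imputation rules are stated nominally:
#'   0.03 at the floor, 0.80 on failure).
#' @param tol Maximum allowed absolute discrepancy between the nominal and the
#'   flow-derived fraction.
#' @return A `dilution_ladder`: a data.frame with columns `step_number`,
#'   `odor_flow`, `clean_flow`, `nominal_fraction`, `actual_fraction`.
#' @seealso [default_ladder()] for the standard 5-step 80--3% ladder.
#' @export
dilution_ladder <- function(step_number, odor_flow, clean_flow,
                            nominal_fraction, tol = 0.005) {
  n <- length(step_number)
  if (n == 0L) stop("ladder must have at least one step", call. = FALSE)
  if (length(odor_flow) != n || length(clean_flow) != n ||
      length(nominal_fraction) != n) {
    stop("all ladder columns must have the same length", call. = FALSE)
  }
  step_number <- as.integer(step_number)
  if (anyDuplicated(step_number)) {
    stop("step_number values must be unique", call. = FALSE)
  }
  actual <- concentration_from_flows(odor_flow, clean_flow)
  if (any(nominal_fraction <= 0) || any(nominal_fraction > 1)) {
    stop("nominal_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(abs(actual - nominal_fraction) > tol)) {
    bad <- which(abs(actual - nominal_fraction) > tol)
    stop(sprintf(
      "flow-derived fraction disagrees with nominal beyond tol at step(s) %s",
      paste(step_number[bad], collapse = ", ")
    ), call. = FALSE)
  }
  ladder <- data.frame(
    step_number = step_number,
    odor_flow = as.numeric(odor_flow),
    clean_flow = as.numeric(clean_flow),
    nominal_fraction = as.numeric(nominal_fraction),
    actual_fraction = actual
  )
  ladder <- ladder[order(ladder$step_number), , drop = FALSE]
  rownames(ladder) <- NULL
  if (any(diff(ladder$nominal_fraction) >= 0)) {
    stop("nominal_fraction must strictly decrease with step_number",
         call. = FALSE)
  }
  class(ladder) <- c("dilution_ladder", "data.frame")
  ladder
}

#' The standard five-step 80--3% dilution ladder
#'
#' The flow settings used for threshold testing: five air-dilution steps with
#' nominal fractions 0.80, 0.50, 0.25, 0.12 and 0.03. Total delivered flow is
#' constant (~3 L/min) at every step except the 80% step, which requires a
#' lower total flow to reach that fraction.
#'
#' @return A [dilution_ladder()] with 5 steps, highest concentration first.
#' @examples
#' default_ladder()
#' @export
default_ladder <- function() {
  dilution_ladder(
    step_number = 1:5,
    odor_flow = c(1000, 1000, 750, 360, 90),
    clean_flow = c(0.25, 1.0, 2.25, 2.65, 2.91),
    nominal_fraction = c(0.80, 0.50, 0.25, 0.12, 0.03)
  )
}

#' @export
print.dilution_ladder <- function(x, ...) {
  cat(sprintf("Dilution ladder: %d steps, %.0f%% down to %.0f%%\n",
              nrow(x), 100 * x$nominal_fraction[1],
              100 * x$nominal_fraction[nrow(x)]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

n_steps <- function(ladder) nrow(ladder)

ladder_fraction <- function(ladder, step) ladder$nominal_fraction[step]
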