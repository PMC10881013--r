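#' A psychometric observer for 3-AFC simulation
#'
#' The simulated subject responds correctly with probability
#' \deqn{P(c \mid x) = \gamma + (1 - \gamma - \lambda)\,F\!\left(\frac{\log_{10} x - \alpha}{\beta}\right)}
#' where \eqn{F} is the standard logistic, \eqn{\gamma} the 3-AFC guess rate
#' (1/3), \eqn{\lambda} the lapse rate, \eqn{\alpha} the log10 fraction at the
#' psychometric midpoint, and \eqn{\beta > 0} the slope scale in log10 units.
#' An optional no-search probability models trials where the subject does not
#' engage at all.
#'
#' @param alpha Location: log10 dilution fraction at the midpoint.
#' @param beta Slope scale in log10 units (smaller = steeper).
#' @param guess_rate Chance level; 1/3 for three-alternative forced choice.
#' @param lapse Lapse rate in \[0, 0.1\].
#' @param p_no_search Per-trial probability of not searching.
#' @return An `observer` object.
#' @export
observer <- function(alpha, beta = 0.15, guess_rate = 1 / 3, lapse = 0.02,
                     p_no_search = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]",
                                     call. = FALSE)
  if (guess_rate <= 0 || guess_rate >= 1) {
    stop("guess_rate must lie in (0, 1)", call. = FALSE)
  }
  if (p_no_search < 0 || p_no_search >= 1) {
    stop("p_no_search must lie in [0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, guess_rate = guess_rate,
                 lapse = lapse, p_no_search = p_no_search),
            class = "observer")
}

#' Probability of a correct 3-AFC response at a dilution fraction
#'
#' @param observer An [observer()].
#' @param fraction Dilution fraction(s) in (0, 1].
#' @return P(correct), bounded below by the guess rate and above by
#'   1 - lapse.
#' @examples
#' obs <- observer(alpha = -1, beta = 0.15, lapse = 0)
#' p_correct(obs, 10^-1) # 2/3: midpoint of a 3-AFC psychometric function
#' @export
p_correct <- function(observer, fraction) {
  if (any(fraction <= 0)) stop("fraction must be positive", call. = FALSE)
  g <- observer$guess_rate
  l <- observer$lapse
  g + (1 - g - l) * stats::plogis((log10(fraction) - observer$alpha) /
                                    observer$beta)
}

# Sample one trial outcome from an observer (or a bare P(correct) function).
sample_outcome <- function(observer, fraction) {
  if (is.function(observer)) {
    p <- observer(fraction)
    return(if (stats::runif(1) < p) "correct" else "incorrect")
  }
  if (observer$p_no_search > 0 &&
      stats::runif(1) < observer$p_no_search) {
    return("no_search")
  }
  p <- p_correct(observer, fraction)
  if (stats::runif(1) < p) "correct" else "incorrect"
}

#' Equilibrium accuracy of the 3-down-1-up rule
#'
#' Transformed up-down staircases converge to the stimulus level where the
#' probability of descending equals the probability of ascending. Descent
#' requires three consecutive correct responses (probability \eqn{p^3});
#' setting \eqn{p^3 = 1/2} gives the tracked accuracy
#' \eqn{p^* = 0.5^{1/3} \approx 0.794}.
#'
#' @return The scalar 0.5^(1/3).
#' @export
staircase_equilibrium_accuracy <- function() 0.5^(1 / 3)
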