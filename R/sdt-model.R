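#' Sensitivity (d-prime) transducer parameters
#'
#' Bundles the parameters of the saturating d-prime psychometric function
#' \deqn{d'(c) = \beta (c/\tau)^\gamma / \sqrt{(\beta^2 - 1) + (c/\tau)^{2\gamma}},}
#' a divisive gain-control transducer in which `tau` is the sensitivity
#' threshold -- the contrast at which d' = 1 exactly -- `gamma` sets the
#' steepness of the rising limb, and `beta` is the upper asymptote
#' (d' saturates below `beta` for all finite contrast).
#'
#' @param tau Sensitivity threshold, a contrast in (0, 1) expressed as a
#'   decimal fraction of full contrast.
#' @param gamma Steepness exponent, > 0.
#' @param beta Upper d' asymptote, > 1. Fixed at 5 throughout the adaptive
#'   methods; exposed here for completeness.
#' @return An object of class `sensitivity_params`.
#' @examples
#' sp <- sensitivity_params(tau = 0.10, gamma = 2)
#' dprime(0.10, sp) # exactly 1 at threshold
#' @export
sensitivity_params <- function(tau, gamma = 2, beta = 5) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (beta <= 1) stop("`beta` must be > 1")
  structure(list(tau = tau, gamma = gamma, beta = beta),
            class = "sensitivity_params")
}

#' @export
print.sensitivity_params <- function(x, ...) {
  cat(sprintf("d' transducer: tau = %.4g (%.3g%% contrast), gamma = %.3g, beta = %.3g\n",
              x$tau, 100 * x$tau, x$gamma, x$beta))
  invisible(x)
}

#' Sensitivity as a function of signal contrast
#'
#' Evaluates the d-prime psychometric function. Monotone non-decreasing in
#' `c`, equal to 1 at `c = tau`, and strictly below `beta` for finite `c`.
#'
#' @param c Signal contrast(s), >= 0 (decimal fraction of full contrast).
#' @param params A [sensitivity_params()] object (or a list with elements
#'   `tau`, `gamma`, `beta`).
#' @return Numeric vector of d' values, in `[0, beta)`.
#' @export
dprime <- function(c, params) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("contrast `c` must be finite and >= 0")
  r <- (c / params$tau)^params$gamma
  params$beta * r / sqrt((params$beta^2 - 1) + r^2)
}

#' Probability of a Yes response in simple detection
#'
#' The empirical Yes-No psychometric function
#' \eqn{\Psi_{yes}(c) = 1 - \Phi(\lambda - d'(c))}: the d-prime function
#' shifted by a decision criterion `lam` (in z units). At `c = 0` this is the
#' false-alarm rate `1 - pnorm(lam)`. No lapse adjustment is applied here;
#' see [apply_lapse()].
#'
#' @param c Signal contrast(s), >= 0.
#' @param sens A [sensitivity_params()] object.
#' @param lam Decision criterion, z units.
#' @return Probability of responding Yes, in (0, 1).
#' @export
yes_probability <- function(c, sens, lam) {
  1 - stats::pnorm(lam - dprime(c, sens))
}

#' Decision parameters for cued or rated detection
#'
#' Cued and rated detection share one criterion layout: a strict criterion
#' `lambda_strict` and a non-negative offset `delta_lambda`, with the lax
#' criterion defined as `lambda_lax = lambda_strict - delta_lambda`. The
#' parameterisation enforces the order constraint `lambda_lax <= lambda_strict`
#' (a liberal state always says Yes at least as often).
#'
#' @param lambda_strict Strict (conservative) criterion, z units.
#' @param delta_lambda Criterion offset, z units, >= 0.
#' @return An object of class `criterion_pair` with fields `lambda_strict`,
#'   `delta_lambda`, `lambda_lax`.
#' @export
criterion_pair <- function(lambda_strict, delta_lambda) {
  stopifnot(is.numeric(lambda_strict), is.numeric(delta_lambda))
  if (delta_lambda < 0) stop("`delta_lambda` must be >= 0")
  structure(list(lambda_strict = lambda_strict,
                 delta_lambda = delta_lambda,
                 lambda_lax = lambda_strict - delta_lambda),
            class = "criterion_pair")
}

#' Yes probability in cued detection
#'
#' In cued detection a pre-trial cue instructs the observer to adopt the lax
#' or the strict criterion; each state yields a simple-detection psychometric
#' function with its own criterion. The lax curve dominates the strict curve
#' pointwise.
#'
#' @param c Signal contrast(s), >= 0.
#' @param state Response state, `"lax"` or `"strict"`.
#' @param sens A [sensitivity_params()] object.
#' @param dec A [criterion_pair()] object.
#' @return Probability of responding Yes in the cued state.
#' @export
cued_probabilities <- function(c, state, sens, dec) {
  state <- match.arg(state, c("lax", "strict"))
  lam <- if (state == "lax") dec$lambda_lax else dec$lambda_strict
  yes_probability(c, sens, lam)
}

#' Response probabilities in rated (Yes / Not Sure / No) detection
#'
#' The observer maintains both criteria simultaneously: Yes above the strict
#' criterion, No below the lax criterion, Not Sure in between. The three
#' probabilities partition 1 at every contrast; collapsing Yes + Not Sure
#' recovers the cued lax curve with the same `lambda_lax`.
#'
#' @inheritParams cued_probabilities
#' @return A matrix with one row per contrast and columns
#'   `yes`, `not_sure`, `no`.
#' @export
rated_probabilities <- function(c, sens, dec) {
  d <- dprime(c, sens)
  ps <- stats::pnorm(dec$lambda_strict - d)
  pl <- stats::pnorm(dec$lambda_lax - d)
  cbind(yes = 1 - ps, not_sure = ps - pl, no = pl)
}

#' Probability of responding Interval 2 in two-interval forced choice
#'
#' The "unwrapped" 2IFC psychometric function: the probability of reporting
#' Interval 2 as a function of the contrasts shown in the two intervals,
#' \deqn{\Psi_{I2} = 1 - \Phi(\lambda_{FC} - [d'(c_2) - d'(c_1)]/\sqrt{2}).}
#' The \eqn{\sqrt{2}} arises because the decision variable is the difference
#' of two unit-variance internal responses; with it, a signal at d' = 1
#' against a blank interval yields ~76% correct under a neutral criterion.
#' `lambda_fc = 0` is interval-unbiased (50% Interval-2 responses to a double
#' blank); its sign encodes an interval bias.
#'
#' @param c1,c2 Contrasts presented in interval 1 and interval 2, >= 0.
#' @param sens A [sensitivity_params()] object.
#' @param lambda_fc Forced-choice decision criterion, z units.
#' @return Probability of responding Interval 2.
#' @export
interval2_probability <- function(c1, c2, sens, lambda_fc) {
  dd <- (dprime(c2, sens) - dprime(c1, sens)) / sqrt(2)
  1 - stats::pnorm(lambda_fc - dd)
}

#' Lapse-adjust a response probability distribution
#'
#' Observers occasionally lapse (inattention, finger errors) at rate
#' `epsilon`, responding at random among the K response categories. The
#' adjusted distribution is `epsilon/K + (1 - epsilon) * p`, which compresses
#' every response probability into `[epsilon/K, 1 - epsilon*(K-1)/K]`; for a
#' binary task at the default 2% lapse rate the attainable maximum response
#' rate is 99%.
#'
#' @param p A probability vector over the response alphabet, or a matrix with
#'   one distribution per row.
#' @param epsilon Lapse rate in `[0, 0.1)`.
#' @param k Number of response alternatives; defaults to the length (or
#'   column count) of `p`.
#' @return Adjusted probabilities, same shape as `p`.
#' @export
apply_lapse <- function(p, epsilon = 0.02, k = NULL) {
  if (epsilon < 0 || epsilon >= 0.1) stop("`epsilon` must lie in [0, 0.1)")
  if (is.matrix(p)) {
    if (is.null(k)) k <- ncol(p)
    sums <- rowSums(p)
  } else {
    if (is.null(k)) k <- length(p)
    sums <- sum(p)
  }
  if (any(abs(sums - 1) > 1e-8) || any(p < -1e-12))
    stop("`p` must be a probability distribution summing to 1")
  epsilon / k + (1 - epsilon) * p
}
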