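# Simulated observers. States are specified by operational response rates to
# the null stimulus (false-alarm rates, Yes/No null rates, interval bias) and
# converted to z-unit criteria through the inverse normal CDF; sensitivity
# parameters are shared across tasks and states.

new_observer <- function(task_name, theta, tau, gamma, beta, epsilon, label) {
  structure(list(task_name = task_name, theta = theta, tau = tau,
                 gamma = gamma, beta = beta, epsilon = epsilon, label = label),
            class = "qsdt_observer")
}

#' @export
print.qsdt_observer <- function(x, ...) {
  cat(sprintf("<%s observer> %s; tau = %.3g, gamma = %.3g (beta %.3g, lapse %.3g)\n",
              x$task_name, x$label, x$tau, x$gamma, x$beta, x$epsilon))
  invisible(x)
}

#' Simulated observers for the four detection tasks
#'
#' Each constructor builds an observer whose responses follow the task's SDT
#' model (including the lapse process) at the given sensitivity parameters
#' and a response state defined by null-stimulus response rates:
#' \describe{
#'   \item{`yn_observer`}{simple detection; `fa_rate` is the model
#'     false-alarm rate, mapped to `lambda = qnorm(1 - fa_rate)`.}
#'   \item{`cued_observer`}{cued detection; false-alarm rates of the strict
#'     (conservative) and lax (liberal) states, `fa_strict <= fa_lax`.}
#'   \item{`rated_observer`}{rated detection; `null_yes` and `null_no` are
#'     the Yes and No response rates to the null stimulus
#'     (`null_yes + null_no <= 1`).}
#'   \item{`fc_observer`}{two-interval forced choice; `p2_null` is the
#'     probability of responding Interval 2 when both intervals are blank
#'     (0.5 = unbiased).}
#' }
#' Rates refer to the criterion stage of the model; the lapse process is
#' applied on top, exactly as the engine's likelihood assumes. Set
#' `epsilon = 0` for a lapse-free observer.
#'
#' @param tau,gamma,beta Sensitivity parameters (see [sensitivity_params()]).
#' @param fa_rate,fa_strict,fa_lax,null_yes,null_no,p2_null State-defining
#'   null-response rates, as probabilities.
#' @param epsilon Observer lapse rate.
#' @param label Optional state label; a default is derived from the rates.
#' @return A `qsdt_observer`.
#' @export
yn_observer <- function(tau = 0.10, gamma = 2, fa_rate = 0.10, beta = 5,
                        epsilon = 0.02, label = NULL) {
  stopifnot(fa_rate > 0, fa_rate < 1)
  lam <- stats::qnorm(1 - fa_rate)
  new_observer("qYN", c(tau = tau, gamma = gamma, lambda = lam),
               tau, gamma, beta, epsilon,
               label %||% sprintf("FA=%g%%", 100 * fa_rate))
}

#' @rdname yn_observer
#' @export
cued_observer <- function(tau = 0.10, gamma = 2, fa_strict = 0.025,
                          fa_lax = 0.10, beta = 5, epsilon = 0.02,
                          label = NULL) {
  stopifnot(fa_strict > 0, fa_lax < 1, fa_strict <= fa_lax)
  ls <- stats::qnorm(1 - fa_strict)
  ll <- stats::qnorm(1 - fa_lax)
  new_observer("qYNC",
               c(tau = tau, gamma = gamma, lambda_strict = ls,
                 delta_lambda = ls - ll),
               tau, gamma, beta, epsilon,
               label %||% sprintf("FA=(%g,%g)%%", 100 * fa_strict, 100 * fa_lax))
}

#' @rdname yn_observer
#' @export
rated_observer <- function(tau = 0.10, gamma = 2, null_yes = 0.025,
                           null_no = 0.90, beta = 5, epsilon = 0.02,
                           label = NULL) {
  stopifnot(null_yes > 0, null_no > 0, null_yes + null_no <= 1)
  ls <- stats::qnorm(1 - null_yes)
  ll <- stats::qnorm(null_no)
  new_observer("qYNR",
               c(tau = tau, gamma = gamma, lambda_strict = ls,
                 delta_lambda = ls - ll),
               tau, gamma, beta, epsilon,
               label %||% sprintf("Yes/No=(%g,%g)%%", 100 * null_yes, 100 * null_no))
}

#' @rdname yn_observer
#' @export
fc_observer <- function(tau = 0.10, gamma = 2, p2_null = 0.5, beta = 5,
                        epsilon = 0.02, label = NULL) {
  stopifnot(p2_null > 0, p2_null < 1)
  new_observer("qFC",
               c(tau = tau, gamma = gamma, lambda_fc = stats::qnorm(1 - p2_null)),
               tau, gamma, beta, epsilon,
               label %||% sprintf("P(I2|null)=%g%%", 100 * p2_null))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weak prior matched to a simulated observer
#'
#' The study harness's default prior: hyperbolic-secant marginals centred on
#' the observer's generating parameters ("centred on initial guess": in a
#' simulation study the initial guess is the simulated truth, the matched
#' prior of the prior-sensitivity study), with the weakly informative
#' confidences used throughout -- threshold 1.6, steepness 6.1,
#' criterion 2.1.
#'
#' @param observer A `qsdt_observer`.
#' @param tau_confidence,gamma_confidence,criterion_confidence Prior
#'   reciprocal widths (log10 units for tau and gamma, z units for criteria).
#' @return A [prior_spec()].
#' @export
matched_prior <- function(observer, tau_confidence = 1.6,
                          gamma_confidence = 6.1, criterion_confidence = 2.1) {
  th <- observer$theta
  args <- list(tau = c(observer$tau, tau_confidence),
               gamma = c(observer$gamma, gamma_confidence))
  for (p in setdiff(names(th), c("tau", "gamma")))
    args[[p]] <- c(th[[p]], criterion_confidence)
  do.call(prior_spec, args)
}

#' Canonical response-state sets for the simulation studies
#'
#' The three response states simulated per task, ordered conservative to
#' liberal, all sharing tau = 10% contrast and gamma = 2:
#' qYN false-alarm rates 2.5/10/40%; qYNC (strict, lax) false-alarm pairs
#' (2.5, 10), (2.5, 40), (10, 40)%; qYNR null-stimulus (Yes, No) rates
#' (2.5, 90), (2.5, 60), (10, 60)%; qFC null Interval-2 response rates
#' 30/50/70% (interval bias of -20%, none, +20%).
#'
#' @param task_name One of `"qYN"`, `"qYNC"`, `"qYNR"`, `"qFC"`.
#' @param tau,gamma Shared sensitivity parameters.
#' @return List of three `qsdt_observer`s.
#' @export
default_observers <- function(task_name, tau = 0.10, gamma = 2) {
  switch(match.arg(task_name, TASK_NAMES),
    qYN = lapply(c(0.025, 0.10, 0.40), function(fa)
      yn_observer(tau, gamma, fa_rate = fa)),
    qYNC = mapply(function(s, l) cued_observer(tau, gamma, s, l),
                  c(0.025, 0.025, 0.10), c(0.10, 0.40, 0.40), SIMPLIFY = FALSE),
    qYNR = mapply(function(y, n) rated_observer(tau, gamma, y, n),
                  c(0.025, 0.025, 0.10), c(0.90, 0.60, 0.60), SIMPLIFY = FALSE),
    qFC = lapply(c(0.30, 0.50, 0.70), function(p)
      fc_observer(tau, gamma, p2_null = p)))
}

#' Draw one response from a simulated observer
#'
#' Samples from the observer's lapse-adjusted response distribution for a
#' condition, by inverse-CDF lookup on a uniform deviate.
#'
#' @param observer A `qsdt_observer` for the same task.
#' @param task A [make_task()] object.
#' @param condition_id Row index into `task$conditions`.
#' @param u Uniform(0,1) deviate; defaults to a fresh `runif(1)`.
#' @return Response label (character).
#' @export
simulate_response <- function(observer, task, condition_id, u = stats::runif(1)) {
  stopifnot(observer$task_name == task$name)
  p <- response_probabilities(task, observer$theta,
                              task$conditions[condition_id, , drop = FALSE],
                              beta = observer$beta, epsilon = observer$epsilon)
  task$response_alphabet[1L + findInterval(u, cumsum(p[1, ]))]
}

#' Threshold-estimate bias in decibels
#'
#' `10 * log10(tau_hat / tau_true)`; 1 dB = 0.1 decimal log units of
#' contrast. Zero iff the estimate is exact; additive under composition of
#' ratios.
#'
#' @param tau_hat,tau_true Estimated and generating thresholds, > 0.
#' @return Bias in dB.
#' @export
bias_db <- function(tau_hat, tau_true) {
  if (any(tau_hat <= 0) || any(tau_true <= 0))
    stop("thresholds must be positive")
  10 * log10(tau_hat / tau_true)
}
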