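# Trial-wise Bayesian engine: likelihood cache, posterior update, entropy
# bookkeeping and one-step-ahead minimum-expected-entropy stimulus selection.

#' Precompute the likelihood table of a task over a grid
#'
#' Response probabilities for every (grid node, condition, response) triple.
#' The table is the only expensive object in the engine; it depends on the
#' task and grid alone, so one cache serves every trial of every session run
#' on that task. Caching is purely an evaluation strategy: the values are the
#' same `response_probabilities()` would return node by node.
#'
#' The d-prime surface is shared by all criterion nodes, so the table is
#' filled blockwise over (tau, gamma) panels rather than per node.
#'
#' @param task A [make_task()] object.
#' @param grid A [parameter_grid()] for that task.
#' @return An object of class `qsdt_cache`: matrix `L` (`n_nodes` rows, one
#'   column per (condition, response) pair, column index
#'   `(r - 1) * n_conditions + condition_id`), its entropy companion
#'   `LlogL = L * log(L)`, and dimensions `n_cond`, `n_resp`.
#' @export
likelihood_cache <- function(task, grid) {
  stopifnot(inherits(task, "qsdt_task"), inherits(grid, "qsdt_grid"))
  if (!identical(names(grid$axes), task$param_names))
    stop("grid parameters do not match task ", task$name)
  tau <- grid$axes$tau; gamma <- grid$axes$gamma
  ntg <- length(tau) * length(gamma)
  conds <- task$conditions
  C <- nrow(conds); R <- length(task$response_alphabet)
  eps <- task$epsilon; K <- R

  # d' panel over (tau x gamma) blocks for each condition's effective contrast
  tg_tau <- rep(tau, times = length(gamma))
  tg_gam <- rep(gamma, each = length(tau))
  beta <- task$beta
  dp_panel <- function(contrast) { # ntg-vector of d' at one contrast
    r <- (contrast / tg_tau)^tg_gam
    beta * r / sqrt((beta^2 - 1) + r^2)
  }
  contrast_of <- switch(task$name,
    qYN = , qYNR = , qYNC = conds$contrast,
    qFC = abs(conds$signed_contrast))
  uc <- unique(contrast_of)
  D <- vapply(uc, dp_panel, numeric(ntg))           # ntg x length(uc)
  Dc <- D[, match(contrast_of, uc), drop = FALSE]   # ntg x C
  if (task$name == "qFC")
    Dc <- sweep(Dc, 2L, sign(conds$signed_contrast), `*`) / sqrt(2)

  # criterion combinations = trailing axes; node = (tg block, crit combo)
  crit_axes <- grid$axes[-(1:2)]
  crit_grid <- do.call(expand.grid, crit_axes)
  ncrit <- nrow(crit_grid)
  L <- matrix(NA_real_, grid$n_nodes, C * R)
  lapse2 <- function(p) eps / K + (1 - eps) * p
  for (k in seq_len(ncrit)) {
    rows <- (k - 1L) * ntg + seq_len(ntg)
    P <- switch(task$name,
      qYN = {
        py <- lapse2(1 - stats::pnorm(crit_grid$lambda[k] - Dc))
        list(py, 1 - py)
      },
      qYNC = {
        lam <- ifelse(conds$cue_state == "lax",
                      crit_grid$lambda_strict[k] - crit_grid$delta_lambda[k],
                      crit_grid$lambda_strict[k])
        py <- lapse2(1 - stats::pnorm(rep(lam, each = ntg) - Dc))
        list(py, 1 - py)
      },
      qYNR = {
        ps <- stats::pnorm(crit_grid$lambda_strict[k] - Dc)
        pl <- stats::pnorm(crit_grid$lambda_strict[k] -
                             crit_grid$delta_lambda[k] - Dc)
        list(lapse2(1 - ps), lapse2(ps - pl), lapse2(pl))
      },
      qFC = {
        p2 <- lapse2(1 - stats::pnorm(crit_grid$lambda_fc[k] - Dc))
        list(p2, 1 - p2)
      })
    for (r in seq_len(R)) L[rows, (r - 1L) * C + seq_len(C)] <- P[[r]]
  }
  LlogL <- L * log(L)
  # sum over responses of L log L per condition: because the likelihood sums
  # to 1 over responses, expected entropy decomposes as
  #   E[H(s)] = H_t + sum_r m log m - sum_theta w * SLL[, s],
  # which lets the replicated-session driver skip all elementwise log(W) work
  SLL <- LlogL[, seq_len(C), drop = FALSE]
  if (R > 1) for (r in 2:R) SLL <- SLL + LlogL[, (r - 1L) * C + seq_len(C)]
  structure(list(L = L, LlogL = LlogL, SLL = SLL, n_cond = C, n_resp = R),
            class = "qsdt_cache")
}

# Likelihood columns (n_nodes x n_resp) for one condition; direct evaluation
# when no cache is supplied. The uncached path exists so small-grid users and
# tests never depend on the cache.
condition_likelihood <- function(posterior, task, condition_id, cache = NULL) {
  C <- nrow(task$conditions)
  if (!is.numeric(condition_id) || condition_id < 1 || condition_id > C)
    stop("condition_id out of range for task ", task$name)
  R <- length(task$response_alphabet)
  if (!is.null(cache))
    return(cache$L[, (seq_len(R) - 1L) * C + condition_id, drop = FALSE])
  grid <- posterior$grid
  tmp <- likelihood_cache(task_subset(task, condition_id), grid)
  tmp$L
}

# A copy of `task` restricted to one condition (keeps likelihood_cache's
# blocked evaluation as the single source of truth).
task_subset <- function(task, condition_id) {
  task$conditions <- task$conditions[condition_id, , drop = FALSE]
  task
}

#' One-trial-ahead predictive response probabilities
#'
#' The posterior-weighted response distribution for a candidate condition,
#' `p(r | s) = sum_theta P(r | s, theta) p(theta)` -- the normalising
#' constant of the Bayesian update.
#'
#' @param posterior A `qsdt_posterior`.
#' @param task A [make_task()] object.
#' @param condition_id Row index into `task$conditions`.
#' @param cache Optional [likelihood_cache()].
#' @return Named probability vector over the response alphabet.
#' @export
predictive_prob <- function(posterior, task, condition_id, cache = NULL) {
  Lc <- condition_likelihood(posterior, task, condition_id, cache)
  p <- as.vector(crossprod(Lc, posterior$weights))
  names(p) <- task$response_alphabet
  p
}

#' Bayesian update of the posterior after one trial
#'
#' Multiplies the node weights by the likelihood of the observed response
#' under the presented condition and renormalises (Bayes' rule on the grid).
#'
#' @param object A `qsdt_posterior` (the current prior).
#' @param task A [make_task()] object.
#' @param condition_id Row index into `task$conditions`.
#' @param response Response label (in `task$response_alphabet`) or index.
#' @param cache Optional [likelihood_cache()].
#' @param ... Unused.
#' @return The updated `qsdt_posterior` (the next trial's prior).
#' @export
update.qsdt_posterior <- function(object, task, condition_id, response,
                                  cache = NULL, ...) {
  r <- if (is.character(response)) match(response, task$response_alphabet)
       else as.integer(response)
  if (is.na(r) || r < 1 || r > length(task$response_alphabet))
    stop("response not in task alphabet: ", response)
  Lc <- condition_likelihood(posterior = object, task, condition_id, cache)
  w <- object$weights * Lc[, r]
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("numerically degenerate update: predictive probability is zero")
  new_posterior(object$grid, w / s)
}

#' @rdname update.qsdt_posterior
#' @param posterior A `qsdt_posterior`.
#' @export
step_posterior <- function(posterior, task, condition_id, response, cache = NULL)
  update(posterior, task, condition_id, response, cache)

#' Expected posterior entropy of a candidate condition
#'
#' Simulates both the Bayesian update for every possible response and the
#' entropy of each resulting posterior, then averages entropies under the
#' predictive response distribution. Never exceeds the current entropy
#' (information is non-negative in expectation).
#'
#' @inheritParams predictive_prob
#' @return Expected entropy in nats.
#' @export
expected_entropy <- function(posterior, task, condition_id, cache = NULL) {
  Lc <- condition_likelihood(posterior, task, condition_id, cache)
  w <- posterior$weights
  m <- as.vector(crossprod(Lc, w))                       # predictive p(r|s)
  s1 <- as.vector(crossprod(Lc, w * log(pmax(w, 1e-300))))
  s2 <- as.vector(crossprod(Lc * log(Lc), w))
  H <- log(m) - (s1 + s2) / m                            # H(posterior | s, r)
  sum(H * m)
}

#' Minimum-expected-entropy stimulus selection
#'
#' Evaluates every condition in the task's stimulus space with
#' [expected_entropy()] and returns the argmin -- the condition whose
#' outcome, on average, sharpens the posterior most. Exact ties are broken
#' uniformly at random via `u_tie` (a dedicated uniform deviate, so that
#' sessions are reproducible given their seed).
#'
#' @param posterior A `qsdt_posterior`.
#' @param task A [make_task()] object.
#' @param cache Optional [likelihood_cache()]; strongly recommended for
#'   repeated calls.
#' @param u_tie Uniform(0,1) deviate used only to break exact ties
#'   (default 0: first minimiser).
#' @return The selected `condition_id` (integer), with the vector of
#'   expected entropies attached as attribute `"expected_entropy"`.
#' @export
select_stimulus <- function(posterior, task, cache = NULL, u_tie = 0) {
  C <- nrow(task$conditions)
  eh <- if (is.null(cache)) {
    vapply(seq_len(C), function(i) expected_entropy(posterior, task, i),
           numeric(1))
  } else {
    batch_expected_entropy(cache, matrix(posterior$weights, ncol = 1))[, 1]
  }
  ties <- which(eh <= min(eh) + 1e-12)
  id <- ties[pmin(length(ties), 1L + floor(u_tie * length(ties)))]
  attr(id, "expected_entropy") <- eh
  id
}

# Vectorised expected entropy for K weight columns at once (C x K matrix).
batch_expected_entropy <- function(cache, W) {
  H_t <- -colSums(W * log(pmax(W, 1e-300)))
  sc <- batch_select_scores(cache, W)
  sweep(sc$scores, 2L, H_t, `+`)
}

# E[H(s)] - H_t per condition and weight column, plus the predictive matrix.
# Two BLAS products per trial for the whole replication batch; this is the
# engine's hot path.
batch_select_scores <- function(cache, W) {
  C <- cache$n_cond; R <- cache$n_resp; K <- ncol(W)
  M <- crossprod(cache$L, W)      # predictive p(r|s), (C*R) x K
  T2 <- crossprod(cache$SLL, W)   # C x K
  S <- matrix(0, C, K)
  for (r in seq_len(R)) {
    Mr <- M[(r - 1L) * C + seq_len(C), , drop = FALSE]
    S <- S + Mr * log(Mr)
  }
  list(scores = S - T2, M = M)
}

#' Session stop rules
#'
#' Adaptive runs terminate either after a fixed number of trials or once the
#' threshold credible interval is narrow enough.
#'
#' @param session A session record (see [run_session()]): needs `n_trials`
#'   completed and, for the precision rule, the latest tau credible interval.
#' @param rule A list: `list(fixed_trials = N)` or `list(ci_width = w)` with
#'   `w` the maximum acceptable width of the tau credible interval in dB
#'   (10 * log10 of the bound ratio).
#' @return `TRUE` if the session should stop.
#' @export
should_stop <- function(session, rule) {
  if (!is.list(rule) || length(rule) != 1L)
    stop("`rule` must be list(fixed_trials = N) or list(ci_width = w)")
  if (!is.null(rule$fixed_trials)) {
    session$n_trials >= rule$fixed_trials
  } else if (!is.null(rule$ci_width)) {
    est <- session$final_estimate
    tau <- est[est$parameter == "tau", ]
    10 * log10(tau$ci_hi / tau$ci_lo) <= rule$ci_width
  } else stop("unknown stop rule: ", names(rule))
}
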