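# Adaptive sessions and the replicated Monte-Carlo study harness.
#
# Replications of the same (task, observer) cell share one likelihood cache
# and are advanced in lock-step as columns of a node-by-replication weight
# matrix, so each trial costs two BLAS products for the whole batch. Each
# replication still has its own uniform stream, derived from the master seed,
# so results are independent across replications and reproducible.

# Per-replication uniform deviates: rows = trials, cols = replications;
# stream k is fully determined by rep_seeds[k].
rep_uniforms <- function(seed, n_trials, n_reps) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  u_resp <- matrix(0, n_trials, n_reps)
  u_tie <- matrix(0, n_trials, n_reps)
  for (k in seq_len(n_reps)) {
    set.seed(rep_seeds[k])
    u <- stats::runif(2L * n_trials)
    u_resp[, k] <- u[seq_len(n_trials)]
    u_tie[, k] <- u[n_trials + seq_len(n_trials)]
  }
  list(resp = u_resp, tie = u_tie)
}

# Core batch driver. Returns presented conditions, responses, tau estimates
# at checkpoints, optional per-trial tau trajectories, and optional final
# posterior expectations of arbitrary node statistics (N x J matrix).
run_sessions_batch <- function(task, observer, n_trials, n_reps, seed,
                               grid = parameter_grid(task),
                               prior = prior_spec(), cache = NULL,
                               checkpoints = n_trials, track_tau = FALSE,
                               node_stats = NULL) {
  stopifnot(n_trials >= 1, n_reps >= 1, all(checkpoints <= n_trials),
            all(checkpoints >= 0))
  post0 <- build_prior(grid, prior)
  if (is.null(cache)) cache <- likelihood_cache(task, grid)
  N <- grid$n_nodes; C <- cache$n_cond; R <- cache$n_resp; K <- n_reps
  u <- rep_uniforms(seed, n_trials, K)
  PO <- response_probabilities(task, observer$theta,
                               beta = observer$beta, epsilon = observer$epsilon)
  POcum <- t(apply(PO, 1L, cumsum))                    # C x R
  lt <- log10(node_values(grid, "tau"))
  W <- matrix(post0$weights, N, K)
  conds <- matrix(NA_integer_, n_trials, K)
  resps <- matrix(NA_integer_, n_trials, K)
  tau_traj <- if (track_tau) matrix(NA_real_, n_trials, K)
  tau_cp <- matrix(NA_real_, length(checkpoints), K)
  if (0 %in% checkpoints) # zero-trial checkpoint: the prior estimate
    tau_cp[match(0, checkpoints), ] <- 10^sum(post0$weights * lt)
  for (t in seq_len(n_trials)) {
    sc <- batch_select_scores(cache, W) # argmin of E[H] per replication
    sel <- integer(K)
    for (k in seq_len(K)) {
      eh <- sc$scores[, k]
      ties <- which(eh <= min(eh) + 1e-12)
      sel[k] <- ties[min(length(ties), 1L + floor(u$tie[t, k] * length(ties)))]
    }
    r <- 1L + rowSums(u$resp[t, ] > POcum[sel, -R, drop = FALSE])
    col <- (r - 1L) * C + sel
    # in-place Bayes update; normaliser = predictive prob of the response
    update_weights_inplace(W, cache$L, col, 1 / sc$M[cbind(col, seq_len(K))])
    conds[t, ] <- sel
    resps[t, ] <- r
    if (track_tau || t %in% checkpoints) {
      th <- 10^as.vector(crossprod(W, lt) / 1)
      if (track_tau) tau_traj[t, ] <- th
      if (t %in% checkpoints) tau_cp[match(t, checkpoints), ] <- th
    }
  }
  out <- list(conditions = conds, responses = resps,
              checkpoints = checkpoints, tau_hat = tau_cp,
              tau_traj = tau_traj, n_reps = K, seed = seed)
  if (!is.null(node_stats))
    out$final_stats <- crossprod(W, node_stats)          # K x J
  out
}

#' Run a single adaptive session against a simulated observer
#'
#' Runs one full adaptive run: minimum-expected-entropy stimulus selection,
#' simulated response, Bayesian update, repeated for `n_trials` trials (or
#' until `stop_rule` fires), logging per-trial state. Sessions are
#' bit-reproducible given `seed`.
#'
#' @param task A [make_task()] object.
#' @param observer A matching `qsdt_observer`.
#' @param n_trials Maximum number of trials.
#' @param seed Integer seed for the session's response and tie-break streams.
#' @param grid A [parameter_grid()].
#' @param prior A [prior_spec()].
#' @param cache Optional precomputed [likelihood_cache()].
#' @param ci_level Credible level for the logged tau interval.
#' @param stop_rule Optional [should_stop()] rule checked after each trial.
#' @return An object of class `qsdt_session`: `trials` (data.frame, one row
#'   per trial), `final_estimate` (see [estimate()]), `posterior`, plus the
#'   run configuration.
#' @export
run_session <- function(task, observer, n_trials, seed = 1,
                        grid = parameter_grid(task), prior = prior_spec(),
                        cache = NULL, ci_level = 0.682, stop_rule = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(cache)) cache <- likelihood_cache(task, grid)
  post <- build_prior(grid, prior)
  u <- rep_uniforms(seed, n_trials, 1L)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    sel <- select_stimulus(post, task, cache, u_tie = u$tie[t, 1])
    resp <- simulate_response(observer, task, sel, u = u$resp[t, 1])
    post <- update(post, task, sel, resp, cache)
    est <- estimate(post, ci_level)
    cond <- task$conditions[sel, setdiff(names(task$conditions), "condition_id"),
                            drop = FALSE]
    ests <- as.list(stats::setNames(est$estimate, paste0(est$parameter, "_hat")))
    tau_row <- est[est$parameter == "tau", ]
    rows[[t]] <- data.frame(
      trial_index = t, condition_id = sel, cond, response = resp, ests,
      tau_ci_lo = tau_row$ci_lo, tau_ci_hi = tau_row$ci_hi,
      entropy = attr(est, "entropy"),
      expected_entropy = attr(sel, "expected_entropy")[sel],
      row.names = NULL)
    if (!is.null(stop_rule) &&
        should_stop(list(n_trials = t,
                         final_estimate = est), stop_rule)) break
  }
  trials <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(list(task_name = task$name, trials = trials,
                 n_trials = nrow(trials), seed = seed, ci_level = ci_level,
                 observer_label = observer$label,
                 final_estimate = estimate(post, ci_level), posterior = post),
            class = "qsdt_session")
}

#' @export
print.qsdt_session <- function(x, ...) {
  tau <- x$final_estimate[x$final_estimate$parameter == "tau", ]
  cat(sprintf("<%s session> %d trials (observer %s, seed %d)\n",
              x$task_name, x$n_trials, x$observer_label, x$seed))
  cat(sprintf("  tau: %.4g [%.4g, %.4g] (%.1f%% CI)\n",
              tau$estimate, tau$ci_lo, tau$ci_hi, 100 * x$ci_level))
  invisible(x)
}

#' Replicated accuracy/precision study of an adaptive method
#'
#' Runs `n_reps` independent adaptive sessions per observer state and
#' summarises, at each checkpoint trial count, the accuracy (mean and median
#' threshold bias in dB, see [bias_db()]) and precision (standard deviation
#' of threshold estimates, in dB and in decimal log units) across
#' replications.
#'
#' @param task A [make_task()] object.
#' @param observers List of `qsdt_observer` states (default: the task's
#'   canonical conservative/intermediate/liberal states,
#'   [default_observers()]).
#' @param n_reps Replications per state (>= 2).
#' @param checkpoints Trial counts at which estimates are scored; the run
#'   length is `max(checkpoints)`.
#' @param seed Master seed; every replication derives its own stream.
#' @param grid A [parameter_grid()] (default: the coarse study grid).
#' @param prior A [prior_spec()], or `NULL` (default) for the weak prior
#'   matched to each observer state ([matched_prior()]).
#' @param keep_trials Keep per-trial presented conditions and responses
#'   (needed by [stimulus_histograms()]).
#' @return data.frame of class `qsdt_study`, one row per (state, checkpoint):
#'   `state`, `checkpoint`, `bias_db` (mean), `median_bias_db`, `sd_db`,
#'   `sd_log10`, `n_reps`.
#' @export
run_study <- function(task, observers = default_observers(task$name),
                      n_reps = 300, checkpoints = c(10, 25, 50, 100),
                      seed = 1, grid = parameter_grid(task),
                      prior = NULL, keep_trials = FALSE) {
  stopifnot(n_reps >= 2)
  cache <- likelihood_cache(task, grid)
  set.seed(seed)
  state_seeds <- sample.int(.Machine$integer.max - 1L, length(observers))
  trials <- list()
  out <- list()
  for (i in seq_along(observers)) {
    ob <- observers[[i]]
    b <- run_sessions_batch(task, ob, n_trials = max(checkpoints, 1),
                            n_reps = n_reps, seed = state_seeds[i],
                            grid = grid, prior = prior %||% matched_prior(ob),
                            cache = cache, checkpoints = sort(checkpoints))
    bias <- bias_db(b$tau_hat, ob$tau)      # checkpoints x reps
    out[[i]] <- data.frame(
      state = ob$label, checkpoint = b$checkpoints,
      bias_db = rowMeans(bias),
      median_bias_db = apply(bias, 1L, stats::median),
      sd_db = apply(bias, 1L, stats::sd),
      sd_log10 = apply(bias / 10, 1L, stats::sd),
      n_reps = n_reps)
    if (keep_trials)
      trials[[ob$label]] <- list(conditions = b$conditions,
                                 responses = b$responses)
  }
  res <- do.call(rbind, out)
  attr(res, "task") <- task
  attr(res, "seed") <- seed
  if (keep_trials) attr(res, "trials") <- trials
  class(res) <- c("qsdt_study", "data.frame")
  res
}

#' Stimulus-sampling histograms of a study
#'
#' Ordinary and cumulative histograms of the stimulus conditions presented
#' over all replications of each observer state, at each checkpoint (first
#' `checkpoint` trials of every replication pooled). Cumulative proportions
#' run within cue state (qYNC) or interval (qFC), ordered by contrast.
#'
#' @param study A [run_study()] result built with `keep_trials = TRUE`.
#' @param checkpoints Trial counts to tabulate (default: the study's).
#' @return Tidy data.frame: `state`, `checkpoint`, condition columns,
#'   `count`, `prop`, `cum_prop`.
#' @export
stimulus_histograms <- function(study, checkpoints = unique(study$checkpoint)) {
  trials <- attr(study, "trials")
  if (is.null(trials)) stop("study was run without keep_trials = TRUE")
  task <- attr(study, "task")
  conds <- task$conditions
  group <- switch(task$name,
    qYNC = conds$cue_state,
    qFC = ifelse(conds$signed_contrast < 0, "interval1",
                 ifelse(conds$signed_contrast > 0, "interval2", "null")),
    rep("all", nrow(conds)))
  rows <- list()
  for (state in names(trials)) {
    cm <- trials[[state]]$conditions
    for (cp in checkpoints) {
      counts <- tabulate(cm[seq_len(cp), , drop = FALSE], nbins = nrow(conds))
      df <- cbind(data.frame(state = state, checkpoint = cp), conds,
                  count = counts, prop = counts / sum(counts))
      df$group <- group
      df <- df[order(df$group, df$condition_id), ]
      df$cum_prop <- stats::ave(df$count, df$group, FUN = function(x)
        cumsum(x) / max(1, sum(x)))
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recovery of decision behaviour at d' = 0
#'
#' Runs replicated sessions and reports the posterior-mean estimate of each
#' state-defining null-stimulus response rate (the lapse-adjusted response
#' probability at d' = 0 implied by the criterion marginals), averaged over
#' replications -- the quantity that shows whether the method separates
#' response states of differing criterion.
#'
#' @inheritParams run_study
#' @param at_trial Session length at which rates are read out.
#' @return data.frame: `state`, `rate` (which null-response rate), `true`
#'   (generating value), `estimate` (mean over replications), `sd`.
#' @export
criterion_recovery <- function(task, observers = default_observers(task$name),
                               n_reps = 300, at_trial = 25, seed = 1,
                               grid = parameter_grid(task),
                               prior = NULL) {
  cache <- likelihood_cache(task, grid)
  eps <- task$epsilon
  lapse_up <- function(p, k) eps / k + (1 - eps) * p
  ns <- switch(task$name,
    qYN = cbind(yes_null = lapse_up(1 - stats::pnorm(node_values(grid, "lambda")), 2)),
    qYNC = {
      ls <- node_values(grid, "lambda_strict")
      ll <- ls - node_values(grid, "delta_lambda")
      cbind(strict_yes_null = lapse_up(1 - stats::pnorm(ls), 2),
            lax_yes_null = lapse_up(1 - stats::pnorm(ll), 2))
    },
    qYNR = {
      ls <- node_values(grid, "lambda_strict")
      ll <- ls - node_values(grid, "delta_lambda")
      cbind(yes_null = lapse_up(1 - stats::pnorm(ls), 3),
            no_null = lapse_up(stats::pnorm(ll), 3))
    },
    qFC = cbind(interval2_null = lapse_up(
      1 - stats::pnorm(node_values(grid, "lambda_fc")), 2)))
  set.seed(seed)
  state_seeds <- sample.int(.Machine$integer.max - 1L, length(observers))
  out <- list()
  for (i in seq_along(observers)) {
    ob <- observers[[i]]
    b <- run_sessions_batch(task, ob, n_trials = at_trial, n_reps = n_reps,
                            seed = state_seeds[i], grid = grid,
                            prior = prior %||% matched_prior(ob),
                            cache = cache, node_stats = ns)
    truth <- true_null_rates(task, ob)
    out[[i]] <- data.frame(state = ob$label, rate = colnames(ns),
                           true = truth[colnames(ns)],
                           estimate = colMeans(b$final_stats),
                           sd = apply(b$final_stats, 2L, stats::sd),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

# Lapse-adjusted null-stimulus response rates implied by an observer's theta.
true_null_rates <- function(task, ob) {
  eps <- ob$epsilon
  lp <- function(p, k) eps / k + (1 - eps) * p
  th <- ob$theta
  switch(task$name,
    qYN = c(yes_null = lp(1 - stats::pnorm(th[["lambda"]]), 2)),
    qYNC = c(strict_yes_null = lp(1 - stats::pnorm(th[["lambda_strict"]]), 2),
             lax_yes_null = lp(1 - stats::pnorm(
               th[["lambda_strict"]] - th[["delta_lambda"]]), 2)),
    qYNR = c(yes_null = lp(1 - stats::pnorm(th[["lambda_strict"]]), 3),
             no_null = lp(stats::pnorm(
               th[["lambda_strict"]] - th[["delta_lambda"]]), 3)),
    qFC = c(interval2_null = lp(1 - stats::pnorm(th[["lambda_fc"]]), 2)))
}

#' Effect of the threshold prior: matched vs mismatched, weak vs strict
#'
#' Replicates the prior-sensitivity simulation: a simple-detection observer
#' (tau = 10%, gamma = 2, false-alarm rate 10%) estimated under four
#' threshold priors -- weak matched (mode 10%, confidence 1.6), weak
#' mismatched (0.9%, 1.6), strict matched (10%, 11.5) and strict mismatched
#' (0.9%, 11.5) -- with broad gamma (2.0, 6.1) and criterion (1, 2.1) priors
#' throughout. Reports the mean threshold-estimate trajectory per variant.
#'
#' @param variants Named list of [prior_spec()]s (default: the four above).
#' @param n_reps Replications per variant.
#' @param n_trials Session length.
#' @param seed Master seed.
#' @param observer The simulated observer.
#' @param grid A [parameter_grid()] for qYN.
#' @return data.frame: `variant`, `trial`, `mean_tau`, `bias_db` (mean bias
#'   of the per-replication estimates), `sd_log10`.
#' @export
prior_mismatch_study <- function(variants = NULL, n_reps = 300, n_trials = 50,
                                 seed = 1, observer = yn_observer(fa_rate = 0.10),
                                 grid = parameter_grid("qYN")) {
  if (is.null(variants))
    variants <- list(
      weak_matched = prior_spec(tau = c(0.10, 1.6)),
      weak_mismatched = prior_spec(tau = c(0.009, 1.6)),
      strict_matched = prior_spec(tau = c(0.10, 11.5)),
      strict_mismatched = prior_spec(tau = c(0.009, 11.5)))
  task <- make_task("qYN", contrast_grid(n = 60))
  cache <- likelihood_cache(task, grid)
  set.seed(seed)
  vseeds <- sample.int(.Machine$integer.max - 1L, length(variants))
  out <- list()
  for (i in seq_along(variants)) {
    b <- run_sessions_batch(task, observer, n_trials = n_trials,
                            n_reps = n_reps, seed = vseeds[i], grid = grid,
                            prior = variants[[i]], cache = cache,
                            track_tau = TRUE)
    bias <- bias_db(b$tau_traj, observer$tau)   # trials x reps
    out[[i]] <- data.frame(variant = names(variants)[i],
                           trial = seq_len(n_trials),
                           mean_tau = rowMeans(b$tau_traj),
                           bias_db = rowMeans(bias),
                           sd_log10 = apply(bias / 10, 1L, stats::sd))
  }
  do.call(rbind, out)
}
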