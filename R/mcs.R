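# Joint maximum-likelihood SDT fit to method-of-constant-stimuli count data:
# a single d' psychometric function (tau, gamma) shared across tasks, with
# task-specific decision criteria, plus parametric-bootstrap goodness-of-fit
# and standard errors.

#' Method-of-constant-stimuli design
#'
#' A fixed-levels design mirroring the package's validation layout: Yes-No
#' style tasks test the null stimulus plus log-linearly spaced contrasts
#' (default 8--60%, 7 levels); forced choice tests each of `fc_levels`
#' contrasts in either interval plus the double-blank condition.
#'
#' @param tasks Tasks to include (subset of qYN/qYNC/qYNR/qFC).
#' @param contrasts Non-null contrast levels for the YN-style tasks.
#' @param fc_contrasts Contrast levels for forced choice.
#' @param n_per_condition Trials per condition.
#' @return data.frame with one row per condition: `task`, `condition_id`,
#'   `contrast`, `cue_state`, `signed_contrast`, `n`.
#' @export
mcs_design <- function(tasks = TASK_NAMES,
                       contrasts = 10^seq(log10(0.08), log10(0.60), length.out = 7),
                       fc_contrasts = 10^seq(log10(0.08), log10(0.60), length.out = 5),
                       n_per_condition = 50) {
  rows <- list()
  add <- function(task, contrast = NA, cue_state = NA, signed_contrast = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      task = task, contrast = contrast, cue_state = cue_state,
      signed_contrast = signed_contrast)
  if ("qYN" %in% tasks) for (c in c(0, contrasts)) add("qYN", contrast = c)
  if ("qYNC" %in% tasks)
    for (st in c("strict", "lax")) for (c in c(0, contrasts))
      add("qYNC", contrast = c, cue_state = st)
  if ("qYNR" %in% tasks) for (c in c(0, contrasts)) add("qYNR", contrast = c)
  if ("qFC" %in% tasks)
    for (s in c(-rev(fc_contrasts), 0, fc_contrasts)) add("qFC", signed_contrast = s)
  out <- do.call(rbind, rows)
  out$condition_id <- seq_len(nrow(out))
  out$n <- n_per_condition
  out
}

mcs_alphabet <- function(task)
  switch(task, qYN = , qYNC = c("Yes", "No"),
         qYNR = c("Yes", "NotSure", "No"), qFC = c("Interval2", "Interval1"))

# Joint-fit parameter layout for the tasks present in a design/table.
mcs_param_names <- function(tasks) {
  c("tau", "gamma",
    if ("qYN" %in% tasks) "lambda",
    if ("qYNC" %in% tasks) c("lambda_strict_cued", "delta_cued"),
    if ("qYNR" %in% tasks) c("lambda_strict_rated", "delta_rated"),
    if ("qFC" %in% tasks) "lambda_fc")
}

# Model response probabilities for the rows of an MCS design under one
# joint parameter vector (natural scale, named as mcs_param_names()).
# Vectorised per task group -- this sits inside the optimiser's objective.
mcs_probs <- function(design, params, beta = 5, epsilon = 0.02) {
  sens <- sensitivity_params(params[["tau"]], params[["gamma"]], beta)
  out <- vector("list", nrow(design))
  for (tn in unique(design$task)) {
    idx <- which(design$task == tn)
    sub <- design[idx, , drop = FALSE]
    P <- switch(tn,
      qYN = {
        py <- yes_probability(sub$contrast, sens, params[["lambda"]])
        cbind(py, 1 - py)
      },
      qYNC = {
        dec <- criterion_pair(params[["lambda_strict_cued"]], params[["delta_cued"]])
        lam <- ifelse(sub$cue_state == "lax", dec$lambda_lax, dec$lambda_strict)
        py <- yes_probability(sub$contrast, sens, lam)
        cbind(py, 1 - py)
      },
      qYNR = {
        dec <- criterion_pair(params[["lambda_strict_rated"]], params[["delta_rated"]])
        rated_probabilities(sub$contrast, sens, dec)
      },
      qFC = {
        p2 <- interval2_probability(pmax(-sub$signed_contrast, 0),
                                    pmax(sub$signed_contrast, 0), sens,
                                    params[["lambda_fc"]])
        cbind(p2, 1 - p2)
      })
    P <- apply_lapse(P, epsilon)
    for (j in seq_along(idx)) out[[idx[j]]] <- unname(P[j, ])
  }
  out # list of probability vectors, aligned with mcs_alphabet(task)
}

#' Simulate a method-of-constant-stimuli count table
#'
#' Draws multinomial response counts per condition of an [mcs_design()] from
#' the joint SDT model, the synthetic stand-in for a multi-task MCS dataset.
#'
#' @param params Named parameter vector (see [joint_nll()]).
#' @param design An [mcs_design()] data.frame.
#' @param seed Integer seed.
#' @param beta,epsilon Fixed asymptote and lapse rate.
#' @return Count table: one row per (condition, response) with columns of
#'   the design plus `response` and `count`.
#' @export
simulate_mcs <- function(params, design = mcs_design(), seed = 1,
                         beta = 5, epsilon = 0.02) {
  set.seed(seed)
  probs <- mcs_probs(design, params, beta, epsilon)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    alpha <- mcs_alphabet(design$task[i])
    k <- as.vector(stats::rmultinom(1, design$n[i], probs[[i]]))
    cbind(design[rep(i, length(alpha)), , drop = FALSE],
          data.frame(response = alpha, count = k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Split a count table back into (design, count list) form; validates totals.
mcs_table_parts <- function(table) {
  need <- c("task", "condition_id", "response", "count")
  if (!all(need %in% names(table)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  if (any(table$count < 0)) stop("counts must be >= 0")
  ids <- unique(table$condition_id)
  design <- table[match(ids, table$condition_id),
                  setdiff(names(table), c("response", "count")), drop = FALSE]
  design$n <- vapply(ids, function(i) sum(table$count[table$condition_id == i]), 1)
  counts <- lapply(ids, function(i) {
    sub <- table[table$condition_id == i, ]
    alpha <- mcs_alphabet(sub$task[1])
    k <- sub$count[match(alpha, sub$response)]
    if (any(is.na(k))) stop("condition ", i, " lacks counts for every response")
    k
  })
  # per-task split with plain vectors, for the optimiser's hot path
  split <- lapply(unique(design$task), function(tn) {
    idx <- which(design$task == tn)
    list(task = tn,
         contrast = design$contrast[idx],
         lax = if (tn == "qYNC") design$cue_state[idx] == "lax",
         signed = design$signed_contrast[idx],
         K = do.call(rbind, counts[idx]))  # conditions x responses
  })
  list(design = design, counts = counts, split = split)
}

#' Joint negative log-likelihood of the unified SDT model
#'
#' Multinomial negative log-likelihood of a count table under a single
#' d-prime psychometric function shared across tasks and task-specific
#' decision criteria: `-sum count * log(model probability)` over every
#' (condition, response) cell. Rated cells use the full trinomial.
#'
#' @param params Named numeric vector on the natural scale: `tau`, `gamma`,
#'   plus the criteria of the tasks present -- `lambda` (simple),
#'   `lambda_strict_cued`/`delta_cued`, `lambda_strict_rated`/`delta_rated`,
#'   `lambda_fc`.
#' @param table A count table (see [simulate_mcs()] for the format).
#' @param beta,epsilon Fixed asymptote and lapse rate.
#' @return The scalar negative log-likelihood (0 for an empty table).
#' @export
joint_nll <- function(params, table, beta = 5, epsilon = 0.02) {
  if (is.null(table) || nrow(table) == 0L) return(0)
  mcs_nll_parts(params, mcs_table_parts(table), beta, epsilon)
}

mcs_nll_parts <- function(params, parts, beta, epsilon) {
  if (params[["tau"]] <= 0 || params[["tau"]] >= 1 || params[["gamma"]] <= 0)
    stop("sensitivity parameters out of domain")
  sens <- list(tau = params[["tau"]], gamma = params[["gamma"]], beta = beta)
  nll <- 0
  for (sp in parts$split) {
    P <- switch(sp$task,
      qYN = {
        py <- yes_probability(sp$contrast, sens, params[["lambda"]])
        cbind(py, 1 - py)
      },
      qYNC = {
        ls <- params[["lambda_strict_cued"]]
        dl <- params[["delta_cued"]]
        if (dl < 0) stop("delta_cued must be >= 0")
        py <- yes_probability(sp$contrast, sens, ifelse(sp$lax, ls - dl, ls))
        cbind(py, 1 - py)
      },
      qYNR = {
        d <- dprime(sp$contrast, sens)
        ps <- stats::pnorm(params[["lambda_strict_rated"]] - d)
        pl <- stats::pnorm(params[["lambda_strict_rated"]] -
                             params[["delta_rated"]] - d)
        if (params[["delta_rated"]] < 0) stop("delta_rated must be >= 0")
        cbind(1 - ps, ps - pl, pl)
      },
      qFC = {
        dd <- (dprime(pmax(sp$signed, 0), sens) -
                 dprime(pmax(-sp$signed, 0), sens)) / sqrt(2)
        p2 <- 1 - stats::pnorm(params[["lambda_fc"]] - dd)
        cbind(p2, 1 - p2)
      })
    P <- epsilon / ncol(P) + (1 - epsilon) * P
    nll <- nll - sum(ifelse(sp$K > 0, sp$K * log(P), 0)) # 0 log 0 = 0
  }
  nll
}

# log-likelihood of the saturated multinomial model (one free distribution
# per condition); 0 log 0 = 0.
saturated_ll <- function(table) {
  parts <- mcs_table_parts(table)
  sum(vapply(seq_along(parts$counts), function(i) {
    k <- parts$counts[[i]]; n <- sum(k)
    if (n == 0) return(0)
    sum(ifelse(k > 0, k * log(k / n), 0))
  }, numeric(1)))
}

# transform between natural and unconstrained optimisation coordinates:
# log10 for tau, gamma and the delta offsets; raw for criteria.
mcs_to_opt <- function(params) {
  x <- params
  for (p in intersect(names(x), c("tau", "gamma", "delta_cued", "delta_rated")))
    x[p] <- log10(max(x[p], 1e-6))
  x
}
mcs_from_opt <- function(x) {
  for (p in intersect(names(x), c("tau", "gamma", "delta_cued", "delta_rated")))
    x[p] <- 10^x[p]
  x
}

#' Fit the joint SDT model to MCS count data by maximum likelihood
#'
#' Minimises [joint_nll()] over shared sensitivity parameters and the
#' criteria of every task present in the table, in transformed coordinates
#' (log10 tau and gamma; log10 criterion offsets, enforcing the lax < strict
#' order; raw criteria). Multi-start: a data-driven start (null-condition
#' response rates mapped through the inverse normal CDF) plus `n_restarts`
#' seeded jitters; the best converged optimum is returned.
#'
#' @param table Count table.
#' @param n_restarts Additional jittered starts (>= 0).
#' @param seed Seed for the jitters.
#' @param beta,epsilon Fixed asymptote and lapse rate.
#' @return Object of class `qsdt_mcs_fit`: `params` (natural scale), `nll`,
#'   `converged`, `n_restarts`, `beta`, `epsilon`.
#' @export
fit_mcs <- function(table, n_restarts = 5, seed = 1, beta = 5, epsilon = 0.02) {
  parts <- mcs_table_parts(table)
  tasks <- unique(parts$design$task)
  pn <- mcs_param_names(tasks)
  start <- mcs_start(parts, epsilon)[pn]
  names(start) <- pn
  fallback <- c(tau = 0.1, gamma = 2, lambda = 1, lambda_strict_cued = 1.5,
                delta_cued = 0.5, lambda_strict_rated = 1.5, delta_rated = 0.5,
                lambda_fc = 0)
  miss <- !is.finite(start)
  start[miss] <- fallback[pn][miss]
  obj <- function(x) {
    names(x) <- pn
    v <- tryCatch(mcs_nll_parts(mcs_from_opt(x), parts, beta, epsilon),
                  error = function(e) Inf) # e.g. tau proposals outside (0, 1)
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(seed)
  best <- NULL
  starts <- c(list(mcs_to_opt(start)),
              lapply(seq_len(n_restarts), function(i)
                mcs_to_opt(start) + stats::rnorm(length(pn), 0, 0.25)))
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  params <- mcs_from_opt(stats::setNames(best$par, pn))
  structure(list(params = params, nll = best$value,
                 converged = best$convergence == 0, n_restarts = n_restarts,
                 beta = beta, epsilon = epsilon, tasks = tasks),
            class = "qsdt_mcs_fit")
}

# data-driven start: thresholds near the middle of the tested contrasts,
# criteria from observed null-stimulus response rates.
mcs_start <- function(parts, epsilon) {
  d <- parts$design
  inv_rate <- function(task, select, response) {
    i <- which(d$task == task & select)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    k <- parts$counts[[i]]; n <- sum(k)
    r <- match(response, mcs_alphabet(task))
    p <- min(max((k[r] + 0.5) / (n + 1), 0.01), 0.99)
    stats::qnorm(1 - p)
  }
  cs <- d$contrast[!is.na(d$contrast) & d$contrast > 0]
  if (!length(cs)) cs <- abs(d$signed_contrast[!is.na(d$signed_contrast) &
                                                 d$signed_contrast != 0])
  tau0 <- stats::median(cs)
  ls_c <- inv_rate("qYNC", !is.na(d$cue_state) & d$cue_state == "strict" &
                     d$contrast == 0, "Yes")
  ll_c <- inv_rate("qYNC", !is.na(d$cue_state) & d$cue_state == "lax" &
                     d$contrast == 0, "Yes")
  ls_r <- inv_rate("qYNR", d$contrast == 0, "Yes")
  no_r <- {
    i <- which(d$task == "qYNR" & d$contrast == 0)
    if (length(i)) {
      k <- parts$counts[[i[1]]]
      stats::qnorm(min(max((k[3] + 0.5) / (sum(k) + 1), 0.01), 0.99))
    } else NA_real_
  }
  c(tau = tau0, gamma = 2,
    lambda = inv_rate("qYN", d$contrast == 0, "Yes"),
    lambda_strict_cued = ls_c,
    delta_cued = max(ls_c - ll_c, 0.05),
    lambda_strict_rated = ls_r,
    delta_rated = max(ls_r - no_r, 0.05),
    lambda_fc = inv_rate("qFC", d$signed_contrast == 0, "Interval2"))
}

#' @export
print.qsdt_mcs_fit <- function(x, ...) {
  cat(sprintf("<joint SDT fit> tasks: %s; NLL = %.3f (%s)\n",
              paste(x$tasks, collapse = ", "), x$nll,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$params, 4))
  invisible(x)
}

# Deviance of the joint fit against the saturated multinomial model.
mcs_deviance <- function(fit, table)
  2 * (saturated_ll(table) + joint_nll(fit$params, table, fit$beta, fit$epsilon))

#' Parametric-bootstrap goodness-of-fit for the joint SDT fit
#'
#' Compares the observed deviance (joint fit vs the saturated multinomial
#' model) with the deviance distribution obtained by simulating `n_boot`
#' count tables at the fitted parameters and refitting each. The p-value is
#' the fraction of bootstrap deviances at least as large as the observed
#' one; small p rejects the unified-sensitivity model.
#'
#' @param fit A converged [fit_mcs()] result.
#' @param table The fitted count table.
#' @param n_boot Bootstrap replicates (warns below 50).
#' @param seed Seed for the bootstrap stream.
#' @param n_restarts Restarts per refit (refits start at the fitted optimum).
#' @return The bootstrap p-value, with the observed deviance and the
#'   bootstrap deviances attached as attributes.
#' @export
bootstrap_gof <- function(fit, table, n_boot = 200, seed = 1, n_restarts = 1) {
  if (!fit$converged) stop("goodness-of-fit requires a converged fit")
  if (n_boot < 50) warning("n_boot < 50 gives a very coarse p-value")
  dev_obs <- mcs_deviance(fit, table)
  devs <- unlist(bootstrap_refits(fit, table, n_boot, seed, n_restarts,
                                  function(f, tb) mcs_deviance(f, tb)))
  p <- mean(devs >= dev_obs - 1e-9)
  attr(p, "deviance") <- dev_obs
  attr(p, "boot_deviances") <- devs
  p
}

#' Parametric-bootstrap standard errors for the joint SDT fit
#'
#' Simulates count tables at the fitted parameters, refits each, and reports
#' the standard deviation of the replicate estimates per parameter; the
#' threshold SE is also given in dB (sd of `10 * log10` of the replicate
#' thresholds). A degenerate zero-variance resample (e.g. deterministic
#' responses) is flagged rather than silently reported as 0.
#'
#' @inheritParams bootstrap_gof
#' @return data.frame: `parameter`, `estimate`, `se`; attributes
#'   `"tau_se_db"` and `"degenerate"`.
#' @export
bootstrap_se <- function(fit, table, n_boot = 100, seed = 1, n_restarts = 1) {
  ests <- bootstrap_refits(fit, table, n_boot, seed, n_restarts,
                           function(f, tb) f$params)
  E <- do.call(rbind, ests)
  se <- apply(E, 2L, stats::sd)
  out <- data.frame(parameter = names(fit$params),
                    estimate = unname(fit$params), se = unname(se))
  attr(out, "tau_se_db") <- stats::sd(10 * log10(E[, "tau"]))
  attr(out, "degenerate") <- any(se == 0)
  if (any(se == 0))
    warning("zero-variance bootstrap for: ",
            paste(names(se)[se == 0], collapse = ", "),
            " (degenerate data?)")
  out
}

bootstrap_refits <- function(fit, table, n_boot, seed, n_restarts, stat) {
  parts <- mcs_table_parts(table)
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  lapply(seq_len(n_boot), function(b) {
    tb <- simulate_mcs(fit$params, parts$design, seed = boot_seeds[b],
                       beta = fit$beta, epsilon = fit$epsilon)
    f <- fit_mcs(tb, n_restarts = n_restarts, seed = boot_seeds[b],
                 beta = fit$beta, epsilon = fit$epsilon)
    stat(f, tb)
  })
}
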