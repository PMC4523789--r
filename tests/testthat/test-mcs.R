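# Generating parameters for the synthetic multi-task MCS datasets: shared
# sensitivity, one criterion per simple/FC task, two per cued/rated task.
gen_params <- c(tau = 0.14, gamma = 2.3, lambda = qnorm(0.90),
                lambda_strict_cued = qnorm(0.975),
                delta_cued = qnorm(0.975) - qnorm(0.90),
                lambda_strict_rated = qnorm(0.975),
                delta_rated = qnorm(0.975) - qnorm(0.60),
                lambda_fc = 0)

test_that("joint NLL: hand-computed cell, empty table, row-order invariance", {
  tb <- data.frame(task = "qYN", condition_id = 1L, contrast = 0,
                   cue_state = NA, signed_contrast = NA,
                   response = c("Yes", "No"), count = c(5L, 45L))
  p_yes <- 0.01 + 0.98 * (1 - pnorm(1.28))
  expect_equal(joint_nll(c(tau = 0.10, gamma = 2, lambda = 1.28), tb),
               -5 * log(p_yes) - 45 * log(1 - p_yes), tolerance = 1e-12)
  expect_equal(joint_nll(gen_params, tb[0, ]), 0)
  tb2 <- simulate_mcs(gen_params, seed = 3)
  perm <- tb2[sample(nrow(tb2)), ]
  expect_equal(joint_nll(gen_params, perm), joint_nll(gen_params, tb2))
})

test_that("simulated tables respect the design margins", {
  d <- mcs_design()
  tb <- simulate_mcs(gen_params, d, seed = 1)
  expect_true(all(tb$count >= 0))
  totals <- tapply(tb$count, tb$condition_id, sum)
  expect_true(all(totals == 50))
  # per-condition response labels span the task's alphabet
  expect_equal(sum(d$task == "qFC"), 11)
  expect_equal(sum(d$task == "qYNC"), 16)
})

test_that("joint fit recovers shared sensitivity from a study-scale dataset", {
  tb <- simulate_mcs(gen_params, seed = 21) # 46 conditions x 50 trials
  fit <- fit_mcs(tb, n_restarts = 3, seed = 1)
  expect_true(fit$converged)
  # optimiser sanity: fitted NLL no worse than at the generating parameters
  expect_lte(fit$nll, joint_nll(gen_params, tb) + 1e-6)
  expect_lt(abs(bias_db(fit$params[["tau"]], gen_params[["tau"]])), 0.5)
  expect_gt(fit$params[["delta_cued"]], 0)
  expect_gt(fit$params[["delta_rated"]], 0)
  # row order does not affect the fit
  set.seed(5)
  fit2 <- fit_mcs(tb[sample(nrow(tb)), ], n_restarts = 3, seed = 1)
  expect_equal(fit2$params, fit$params, tolerance = 1e-6)
})

test_that("fitted NLL beats the truth across several synthetic datasets", {
  for (seed in 1:4) {
    tb <- simulate_mcs(gen_params, mcs_design(tasks = c("qYN", "qFC")),
                       seed = seed)
    fit <- fit_mcs(tb, n_restarts = 1, seed = seed)
    expect_lte(fit$nll, joint_nll(gen_params[mcs_param_names(c("qYN", "qFC"))],
                                  tb) + 1e-6)
  }
})

test_that("shared threshold is recovered across repeated seeded datasets", {
  hits <- 0L
  n_rep <- 20L
  for (seed in seq_len(n_rep)) {
    tb <- simulate_mcs(gen_params, seed = 100 + seed)
    fit <- fit_mcs(tb, n_restarts = 1, seed = seed)
    if (abs(bias_db(fit$params[["tau"]], gen_params[["tau"]])) < 0.5)
      hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_rep))
})

test_that("bootstrap goodness-of-fit is calibrated and detects gross misfit", {
  d <- mcs_design(tasks = "qYN")
  ok <- 0L
  for (seed in 1:5) {
    tb <- simulate_mcs(gen_params[c("tau", "gamma", "lambda")], d,
                       seed = 200 + seed)
    fit <- fit_mcs(tb, n_restarts = 1, seed = seed)
    p <- bootstrap_gof(fit, tb, n_boot = 60, seed = seed)
    if (p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 4L) # well-specified data rarely rejected
  # grossly non-monotone data (criterion jump) must be rejected
  tb_bad <- simulate_mcs(gen_params[c("tau", "gamma", "lambda")], d, seed = 9)
  ones <- tb_bad$task == "qYN" & tb_bad$contrast < 0.1
  tb_bad$count[ones] <- ifelse(tb_bad$response[ones] == "Yes", 45L, 5L)
  fit_bad <- fit_mcs(tb_bad, n_restarts = 1, seed = 1)
  p_bad <- bootstrap_gof(fit_bad, tb_bad, n_boot = 60, seed = 1)
  expect_lt(p_bad, 0.05)
  expect_warning(bootstrap_gof(fit_bad, tb_bad, n_boot = 20, seed = 1),
                 "coarse")
})

test_that("deviance vanishes when observed proportions equal the model's", {
  d <- mcs_design(tasks = "qFC", fc_contrasts = c(0.1, 0.3),
                  n_per_condition = 100)
  pars <- c(tau = 0.1, gamma = 2, lambda_fc = 0)
  probs <- quickSDT:::mcs_probs(d, pars)
  # expected (non-integer) counts: observed proportions equal model probs
  tb <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    cbind(d[rep(i, 2), ], data.frame(response = c("Interval2", "Interval1"),
                                     count = 100 * probs[[i]]))))
  fit <- list(params = pars, beta = 5, epsilon = 0.02)
  expect_equal(quickSDT:::mcs_deviance(fit, tb), 0, tolerance = 1e-6)
})

test_that("bootstrap SEs scale roughly with 1/sqrt(n) and stay small at scale", {
  d50 <- mcs_design(tasks = "qYN", n_per_condition = 50)
  d500 <- mcs_design(tasks = "qYN", n_per_condition = 500)
  g <- gen_params[c("tau", "gamma", "lambda")]
  f50 <- fit_mcs(simulate_mcs(g, d50, seed = 31), n_restarts = 1, seed = 1)
  f500 <- fit_mcs(simulate_mcs(g, d500, seed = 31), n_restarts = 1, seed = 1)
  se50 <- bootstrap_se(f50, simulate_mcs(g, d50, seed = 31), n_boot = 30, seed = 2)
  se500 <- bootstrap_se(f500, simulate_mcs(g, d500, seed = 31), n_boot = 30,
                        seed = 2)
  ratio <- attr(se500, "tau_se_db") / attr(se50, "tau_se_db")
  expect_lt(ratio, 1 / sqrt(10) * 1.5)
  expect_gt(ratio, 1 / sqrt(10) / 2.2)
  expect_false(attr(se50, "degenerate"))
})

test_that("full-design bootstrap threshold SE is below 0.3 dB", {
  tb <- simulate_mcs(gen_params, seed = 77) # ~2300 trials across four tasks
  fit <- fit_mcs(tb, n_restarts = 1, seed = 1)
  se <- bootstrap_se(fit, tb, n_boot = 30, seed = 3)
  expect_lt(attr(se, "tau_se_db"), 0.3)
})

test_that("degenerate deterministic counts are flagged, not silently zero", {
  # lapse-free fit to all-No data: every bootstrap table is identical, so the
  # replicate estimates have zero variance and must be flagged
  d <- mcs_design(tasks = "qYN", n_per_condition = 50)
  tb <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    cbind(d[rep(i, 2), ], data.frame(response = c("Yes", "No"),
                                     count = c(0L, 50L)))))
  fit <- suppressWarnings(fit_mcs(tb, n_restarts = 0, seed = 1, epsilon = 0))
  expect_warning(se <- bootstrap_se(fit, tb, n_boot = 10, seed = 1),
                 "zero-variance")
  expect_true(attr(se, "degenerate"))
})
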