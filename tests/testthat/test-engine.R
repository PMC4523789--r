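test_that("priors: normalisation, mode placement, symmetry, flat limit", {
  pb <- tiny_problem("qYN")
  post <- build_prior(pb$grid, prior_spec(tau = c(0.1, 1.6)))
  expect_equal(sum(post$weights), 1, tolerance = 1e-10)
  m <- marginal(post, "tau")
  expect_equal(m$value[which.max(m$weight)], 0.1)
  # near-flat limit of the sech prior
  flat <- build_prior(pb$grid, prior_spec(tau = c(0.1, 1e-8), gamma = c(2, 1e-8),
                                          lambda = c(1.3, 1e-8)))
  expect_equal(flat$weights, rep(1 / pb$grid$n_nodes, pb$grid$n_nodes),
               tolerance = 1e-6)
  # log-symmetry of the tau marginal on a log-symmetric toy grid
  g2 <- parameter_grid("qYN", axes = list(tau = 0.1 * 10^seq(-1, 1, length.out = 9),
                                          gamma = c(2), lambda = c(1)))
  pr <- build_prior(g2, prior_spec(tau = c(0.1, 1.6)))
  mw <- marginal(pr, "tau")$weight
  expect_equal(mw, rev(mw), tolerance = 1e-12)
  expect_error(build_prior(pb$grid, prior_spec(tau = c(0.9999, 1.6))),
               "outside")
})

test_that("entropy: uniform, point mass, and a hand-computed two-pointer", {
  g <- parameter_grid("qYN", axes = list(tau = c(0.05, 0.2), gamma = 2,
                                         lambda = 1))
  flat <- build_prior(g, prior_spec(tau = c(0.1, 1e-9)))
  expect_equal(entropy(flat), log(2), tolerance = 1e-6)
  p09 <- structure(list(grid = g, weights = c(0.9, 0.1)),
                   class = "qsdt_posterior")
  expect_equal(entropy(p09), -(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_equal(entropy(p09), 0.3251, tolerance = 1e-4)
  p10 <- structure(list(grid = g, weights = c(1, 0)), class = "qsdt_posterior")
  expect_equal(entropy(p10), 0)
})

test_that("predictive probabilities: degenerate and two-node posteriors", {
  pb <- tiny_problem("qYN")
  lik <- oracle_lik(pb$task, pb$grid)
  N <- pb$grid$n_nodes
  w <- rep(0, N); w[13] <- 1
  post <- structure(list(grid = pb$grid, weights = w), class = "qsdt_posterior")
  for (s in c(1L, 3L))
    expect_equal(unname(predictive_prob(post, pb$task, s)), lik[13, s, ],
                 tolerance = 1e-12)
  w2 <- rep(0, N); w2[c(2, 20)] <- 0.5
  post2 <- structure(list(grid = pb$grid, weights = w2), class = "qsdt_posterior")
  expect_equal(unname(predictive_prob(post2, pb$task, 2)),
               (lik[2, 2, ] + lik[20, 2, ]) / 2, tolerance = 1e-12)
  p <- predictive_prob(post2, pb$task, 1)
  expect_true(all(p >= 0.01 & p <= 0.99))
})

test_that("update matches brute-force Bayes and composes sequentially", {
  for (tn in c("qYN", "qYNR", "qFC")) {
    pb <- tiny_problem(tn)
    lik <- oracle_lik(pb$task, pb$grid)
    post <- build_prior(pb$grid, tiny_prior(pb$grid))
    for (s in c(1L, nrow(pb$task$conditions))) {
      for (r in seq_along(pb$task$response_alphabet)) {
        up <- update(post, pb$task, s, r)
        expect_equal(up$weights, oracle_update(post$weights, lik, s, r),
                     tolerance = 1e-12)
        expect_equal(sum(up$weights), 1, tolerance = 1e-10)
      }
    }
    # two successive updates equal one update with the product likelihood
    a <- update(update(post, pb$task, 1, 1), pb$task, 2, 2)
    wprod <- post$weights * lik[, 1, 1] * lik[, 2, 2]
    expect_equal(a$weights, wprod / sum(wprod), tolerance = 1e-12)
  }
  # a theta-independent likelihood leaves the posterior unchanged; a null
  # qFC condition at fixed criterion axis is nearly so, so test directly:
  pb <- tiny_problem("qYN")
  post <- build_prior(pb$grid, tiny_prior(pb$grid))
  expect_error(update(post, pb$task, 1, "Maybe"), "alphabet")
})

test_that("expected entropy matches enumeration and never exceeds current entropy", {
  for (tn in c("qYN", "qYNC")) {
    pb <- tiny_problem(tn, n_contrast = 3)
    lik <- oracle_lik(pb$task, pb$grid)
    post <- build_prior(pb$grid, tiny_prior(pb$grid))
    post <- update(post, pb$task, 1, 1) # make it non-uniformly interesting
    H <- entropy(post)
    for (s in seq_len(nrow(pb$task$conditions))) {
      eh <- expected_entropy(post, pb$task, s)
      expect_equal(eh, oracle_expected_entropy(post$weights, lik, s),
                   tolerance = 1e-10)
      expect_lte(eh, H + 1e-12)
    }
  }
})

test_that("a more separating likelihood yields lower expected entropy", {
  # two-node toy: contrasts near threshold discriminate the nodes more than
  # a very low contrast, so their expected entropy must be lower
  g <- parameter_grid("qYN", axes = list(tau = c(0.05, 0.2), gamma = 2,
                                         lambda = 1.3))
  task <- make_task("qYN", c(0.001, 0.1))
  post <- build_prior(g, prior_spec(tau = c(0.1, 1e-6), lambda = c(1.3, 1)))
  eh_low <- expected_entropy(post, task, 1)
  eh_mid <- expected_entropy(post, task, 2)
  expect_lt(eh_mid, eh_low)
})

test_that("stimulus selection agrees with exhaustive search on small problems", {
  for (tn in c("qYN", "qYNR", "qYNC", "qFC")) {
    pb <- tiny_problem(tn, n_contrast = 3)
    lik <- oracle_lik(pb$task, pb$grid)
    cache <- likelihood_cache(pb$task, pb$grid)
    post <- build_prior(pb$grid, tiny_prior(pb$grid))
    for (step in 1:4) {
      sel <- select_stimulus(post, pb$task, cache)
      # the selection attains the oracle's minimum expected entropy (exact
      # numerical ties may resolve to either member)
      eh_o <- vapply(seq_len(nrow(pb$task$conditions)), function(s)
        oracle_expected_entropy(post$weights, lik, s), numeric(1))
      expect_lte(eh_o[as.integer(sel)], min(eh_o) + 1e-10)
      expect_equal(attr(sel, "expected_entropy"), eh_o, tolerance = 1e-10)
      # cached and direct paths agree
      sel2 <- select_stimulus(post, pb$task, cache = NULL)
      expect_equal(as.integer(sel2), as.integer(sel))
      expect_equal(attr(sel2, "expected_entropy"), attr(sel, "expected_entropy"),
                   tolerance = 1e-10)
      post <- update(post, pb$task, sel, 1L + step %% 2, cache)
    }
  }
})

test_that("likelihood cache reproduces direct model probabilities", {
  for (tn in c("qYN", "qYNC", "qYNR", "qFC")) {
    pb <- tiny_problem(tn, n_contrast = 4)
    cache <- likelihood_cache(pb$task, pb$grid)
    nodes <- oracle_nodes(pb$grid)
    C <- nrow(pb$task$conditions)
    set.seed(42)
    for (i in sample(nrow(nodes), 5)) {
      th <- nodes[i, ]; names(th) <- names(pb$grid$axes)
      p <- response_probabilities(pb$task, th)
      for (r in seq_along(pb$task$response_alphabet))
        expect_equal(cache$L[i, (r - 1) * C + seq_len(C)], unname(p[, r]),
                     tolerance = 1e-12)
    }
  }
})

test_that("single-condition space is always selected", {
  task <- make_task("qYN", 0.1)
  g <- parameter_grid(task, axes = list(tau = c(0.05, 0.1, 0.2),
                                        gamma = c(2, 3), lambda = c(1, 2)))
  expect_equal(as.integer(select_stimulus(build_prior(g), task)), 1L)
})

test_that("estimates: point mass, geometric mid-point, CI ordering", {
  g <- parameter_grid("qYN", axes = list(tau = c(0.05, 0.1, 0.2),
                                         gamma = c(1.5, 2, 3),
                                         lambda = c(0.5, 1.3, 2)))
  w <- rep(0, 27); w[14] <- 1 # middle node (tau 0.1, gamma 2, lambda 1.3)
  post <- structure(list(grid = g, weights = w), class = "qsdt_posterior")
  est <- estimate(post)
  expect_equal(est$estimate[est$parameter == "tau"], 0.1)
  expect_equal(est$estimate[est$parameter == "gamma"], 2)
  expect_equal(est$estimate[est$parameter == "lambda"], 1.3)
  expect_true(all(est$ci_hi - est$ci_lo == 0))
  # symmetric two-node tau posterior: geometric mid-point
  w2 <- rep(0, 27); w2[13] <- 0.5; w2[15] <- 0.5 # tau 0.05 and 0.2
  post2 <- structure(list(grid = g, weights = w2), class = "qsdt_posterior")
  est2 <- estimate(post2)
  tau2 <- est2[est2$parameter == "tau", ]
  expect_equal(tau2$estimate, sqrt(0.05 * 0.2), tolerance = 1e-12)
  expect_true(tau2$ci_lo <= tau2$estimate && tau2$estimate <= tau2$ci_hi)
})

test_that("stop rules fire exactly at their criteria", {
  expect_false(should_stop(list(n_trials = 99), list(fixed_trials = 100)))
  expect_true(should_stop(list(n_trials = 100), list(fixed_trials = 100)))
  zero_ci <- data.frame(parameter = "tau", estimate = 0.1,
                        ci_lo = 0.1, ci_hi = 0.1)
  expect_true(should_stop(list(n_trials = 5, final_estimate = zero_ci),
                          list(ci_width = 1)))
  wide_ci <- data.frame(parameter = "tau", estimate = 0.1,
                        ci_lo = 0.05, ci_hi = 0.2)
  expect_false(should_stop(list(n_trials = 5, final_estimate = wide_ci),
                           list(ci_width = 1)))
  expect_error(should_stop(list(n_trials = 5), list(bogus = 1)), "rule")
})

test_that("posterior stays normalised and information inequality holds on runs", {
  task <- make_task("qYN", contrast_grid(lo = 0.005, hi = 0.9, n = 15))
  g <- parameter_grid(task, axes = list(
    tau = 10^seq(log10(0.01), log10(0.8), length.out = 10),
    gamma = 10^seq(log10(0.8), log10(6), length.out = 6),
    lambda = seq(-0.5, 2.5, length.out = 8)))
  cache <- likelihood_cache(task, g)
  for (seed in 1:3) {
    s <- run_session(task, yn_observer(fa_rate = 0.10), n_trials = 25,
                     seed = seed, grid = g, cache = cache)
    expect_false(any(!is.finite(s$trials$entropy)))
    expect_equal(sum(s$posterior$weights), 1, tolerance = 1e-10)
    expect_true(all(s$posterior$weights >= 0))
    prevH <- c(entropy(build_prior(g)), s$trials$entropy[-25])
    expect_true(all(s$trials$expected_entropy <= prevH + 1e-9))
  }
})

test_that("threshold estimator is consistent over long sessions", {
  # 200 replicated 500-trial qYN sessions at FA = 10%
  task <- study_task("qYN")
  st <- run_study(task, observers = list(yn_observer(fa_rate = 0.10)),
                  n_reps = 200, checkpoints = 500, seed = 11)
  expect_lt(abs(st$bias_db), 0.25)
  expect_lt(st$sd_db, 0.5)
})
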