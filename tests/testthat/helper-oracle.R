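# Independent brute-force reference for the Bayesian engine, written as
# plain loops over nodes, conditions and responses so that it shares no code
# path with the package's cached matrix implementation.

# Enumerate all grid nodes of a qsdt_grid as a matrix (rows = nodes), in the
# package's node order (first axis fastest).
oracle_nodes <- function(grid) {
  as.matrix(do.call(expand.grid, grid$axes))
}

# P(response r | condition s, node i) via the public model surface.
oracle_lik <- function(task, grid) {
  nodes <- oracle_nodes(grid)
  C <- nrow(task$conditions)
  R <- length(task$response_alphabet)
  arr <- array(NA_real_, c(nrow(nodes), C, R))
  for (i in seq_len(nrow(nodes))) {
    th <- nodes[i, ]
    names(th) <- names(grid$axes)
    arr[i, , ] <- response_probabilities(task, th)
  }
  arr
}

oracle_update <- function(weights, lik, cond, r) {
  w <- numeric(length(weights))
  for (i in seq_along(weights)) w[i] <- weights[i] * lik[i, cond, r]
  w / sum(w)
}

oracle_entropy <- function(w) {
  h <- 0
  for (wi in w) if (wi > 0) h <- h - wi * log(wi)
  h
}

oracle_expected_entropy <- function(weights, lik, cond) {
  R <- dim(lik)[3]
  eh <- 0
  for (r in seq_len(R)) {
    pr <- 0
    for (i in seq_along(weights)) pr <- pr + weights[i] * lik[i, cond, r]
    eh <- eh + pr * oracle_entropy(oracle_update(weights, lik, cond, r))
  }
  eh
}

oracle_select <- function(weights, lik) {
  C <- dim(lik)[2]
  eh <- vapply(seq_len(C), function(s) oracle_expected_entropy(weights, lik, s),
               numeric(1))
  which.min(eh)
}

# Weak prior with every mode at the middle of its (toy) axis.
tiny_prior <- function(grid) {
  args <- lapply(grid$axes, function(ax) c(ax[ceiling(length(ax) / 2)], 1.0))
  do.call(prior_spec, args)
}

# Small 27-node qYN problem shared by the oracle-equivalence tests.
tiny_problem <- function(task_name = "qYN", n_contrast = 4) {
  task <- make_task(task_name, contrast_grid(lo = 0.02, hi = 0.5, n = n_contrast))
  axes <- switch(task_name,
    qYN = list(tau = c(0.05, 0.1, 0.2), gamma = c(1.5, 2, 3),
               lambda = c(0.5, 1.3, 2)),
    qFC = list(tau = c(0.05, 0.1, 0.2), gamma = c(1.5, 2, 3),
               lambda_fc = c(-0.5, 0, 0.5)),
    list(tau = c(0.05, 0.1, 0.2), gamma = c(1.5, 2.5),
         lambda_strict = c(1, 2), delta_lambda = c(0.2, 0.9)))
  grid <- parameter_grid(task, axes = axes)
  list(task = task, grid = grid)
}
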