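# Parameter grids and priors for the grid-based Bayesian engine.
#
# Node layout convention (used everywhere): nodes are the cartesian product
# of the per-parameter axes in task parameter order, with the FIRST parameter
# varying fastest (expand.grid order). tau and gamma axes are log-spaced,
# criterion axes linear.

.axis_scale <- c(tau = "log", gamma = "log", lambda = "linear",
                 lambda_strict = "linear", delta_lambda = "linear",
                 lambda_fc = "linear")

.axis_defaults <- list(
  # full-resolution ("simstudy") axis: range + sample count
  tau           = list(lo = 0.0025, hi = 1.25, n_full = 59, n_coarse = 30),
  gamma         = list(lo = 0.4,    hi = 10,   n_full = 58, n_coarse = 29),
  lambda        = list(lo = -1,     hi = 3,    n_full = 56, n_coarse = 28),
  lambda_strict = list(lo = -1,     hi = 3,    n_full = 56, n_coarse = 20),
  delta_lambda  = list(lo = 0,      hi = 2.5,  n_full = 25, n_coarse = 12),
  lambda_fc     = list(lo = -2,     hi = 2,    n_full = 56, n_coarse = 28)
)

.make_axis <- function(param, lo, hi, n) {
  if (.axis_scale[[param]] == "log") 10^seq(log10(lo), log10(hi), length.out = n)
  else seq(lo, hi, length.out = n)
}

#' Parameter grid for a task
#'
#' The gridded joint parameter space over which the posterior is maintained.
#' Two presets:
#' \describe{
#'   \item{`"simstudy"`}{full resolution: tau 0.0025--1.25 (59 log-spaced),
#'     gamma 0.4--10 (58 log-spaced), criterion -1--3 z units (56 linear);
#'     the 4-parameter tasks add delta_lambda 0--2.5 (25 linear), and qFC
#'     uses lambda_fc -2--2 (56 linear).}
#'   \item{`"coarse"`}{every axis at half resolution (e.g. 30 x 29 x 28 for
#'     qYN); the default for replicated simulation studies, where the
#'     posterior after tens of trials is much broader than the grid step.}
#' }
#'
#' @param task A [make_task()] object, or a task name.
#' @param preset `"coarse"` (default) or `"simstudy"`.
#' @param axes Optional named list of explicit axis sample vectors, each
#'   strictly increasing; overrides the preset per parameter.
#' @return An object of class `qsdt_grid`: named list of axes plus scale
#'   metadata; `n_nodes` is the product of axis lengths.
#' @export
parameter_grid <- function(task, preset = c("coarse", "simstudy"), axes = list()) {
  preset <- match.arg(preset)
  params <- if (inherits(task, "qsdt_task")) task$param_names
            else make_task(task, contrast_grid(n = 2))$param_names
  ax <- lapply(params, function(p) {
    if (!is.null(axes[[p]])) {
      a <- axes[[p]]
      stopifnot(is.numeric(a), !is.unsorted(a, strictly = TRUE))
      a
    } else {
      d <- .axis_defaults[[p]]
      .make_axis(p, d$lo, d$hi, if (preset == "simstudy") d$n_full else d$n_coarse)
    }
  })
  names(ax) <- params
  structure(list(axes = ax,
                 scale = .axis_scale[params],
                 n_nodes = prod(vapply(ax, length, 1L))),
            class = "qsdt_grid")
}

#' @export
print.qsdt_grid <- function(x, ...) {
  cat(sprintf("<parameter grid> %s nodes: %s\n",
              format(x$n_nodes, big.mark = ","),
              paste(sprintf("%s[%d]", names(x$axes),
                            vapply(x$axes, length, 1L)), collapse = " x ")))
  invisible(x)
}

# Index of each node along axis i (expand.grid order, axis 1 fastest).
axis_index <- function(grid, i) {
  lens <- vapply(grid$axes, length, 1L)
  inner <- if (i == 1L) 1L else prod(lens[seq_len(i - 1L)])
  outer <- if (i == length(lens)) 1L else prod(lens[seq(i + 1L, length(lens))])
  rep(rep(seq_len(lens[i]), each = inner), times = outer)
}

# Value of parameter `name` at every node.
node_values <- function(grid, name) {
  i <- match(name, names(grid$axes))
  grid$axes[[i]][axis_index(grid, i)]
}

#' Prior specification
#'
#' Each parameter's prior marginal is a hyperbolic secant,
#' `sech(confidence * u)`, where `u = log10(x / mode)` for the log-scaled
#' sensitivity parameters (tau, gamma) and `u = x - mode` (z units) for the
#' criterion parameters. `confidence` is the reciprocal width in those units:
#' larger values concentrate the prior, values near 0 approach a flat prior.
#' The joint prior is the normalised product of the marginals.
#'
#' @param ... Named `c(mode, confidence)` pairs, e.g.
#'   `tau = c(0.10, 1.6)`. Parameters not named get the package defaults:
#'   tau (0.10, 1.6), gamma (2.0, 6.1), lambda and lambda_strict (1, 2.1),
#'   delta_lambda (1, 1.0), lambda_fc (0, 2.1).
#' @return An object of class `qsdt_prior_spec` (named list of
#'   `list(mode, confidence)`).
#' @export
prior_spec <- function(...) {
  defaults <- list(tau = c(0.10, 1.6), gamma = c(2.0, 6.1),
                   lambda = c(1, 2.1), lambda_strict = c(1, 2.1),
                   delta_lambda = c(1, 1.0), lambda_fc = c(0, 2.1))
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == "")))
    stop("prior_spec() arguments must be named per parameter")
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown prior parameter(s): ", paste(bad, collapse = ", "))
  for (p in names(user)) {
    v <- user[[p]]
    stopifnot(is.numeric(v), length(v) == 2L)
    if (v[2] <= 0) stop("prior confidence must be > 0")
    defaults[[p]] <- v
  }
  structure(lapply(defaults, function(v) list(mode = v[1], confidence = v[2])),
            class = "qsdt_prior_spec")
}

#' Build the prior posterior object over a grid
#'
#' Evaluates the product-of-sech prior of [prior_spec()] on every node of a
#' [parameter_grid()] and normalises it. The result is the engine's central
#' state: a `qsdt_posterior` holding the grid and one non-negative weight per
#' node, summing to 1.
#'
#' @param grid A [parameter_grid()].
#' @param spec A [prior_spec()]; defaults to the package's weakly
#'   informative settings.
#' @return An object of class `qsdt_posterior` with fields `grid`, `weights`.
#' @export
build_prior <- function(grid, spec = prior_spec()) {
  logw <- 0
  for (i in seq_along(grid$axes)) {
    p <- names(grid$axes)[i]
    sp <- spec[[p]]
    if (is.null(sp)) stop("prior spec lacks parameter ", p)
    ax <- grid$axes[[i]]
    if (sp$mode < min(ax) || sp$mode > max(ax))
      stop("prior mode for ", p, " (", sp$mode, ") lies outside its grid range")
    u <- if (grid$scale[[p]] == "log") log10(ax / sp$mode) else ax - sp$mode
    # log sech(k u) = -log cosh(k u), computed stably for large |k u|
    ku <- abs(sp$confidence * u)
    lmarg <- -(ku + log1p(exp(-2 * ku)) - log(2))
    logw <- logw + lmarg[axis_index(grid, i)]
  }
  w <- exp(logw - max(logw))
  new_posterior(grid, w / sum(w))
}

new_posterior <- function(grid, weights) {
  stopifnot(length(weights) == grid$n_nodes, all(weights >= 0))
  structure(list(grid = grid, weights = weights), class = "qsdt_posterior")
}

#' @export
print.qsdt_posterior <- function(x, ...) {
  cat(sprintf("<posterior> %s nodes over (%s); entropy %.3f nats\n",
              format(x$grid$n_nodes, big.mark = ","),
              paste(names(x$grid$axes), collapse = ", "),
              entropy(x)))
  est <- estimate(x)
  tau <- est$estimate[est$parameter == "tau"]
  cat(sprintf("  tau estimate: %.4g (%.3g%% contrast)\n", tau, 100 * tau))
  invisible(x)
}

#' Shannon entropy of a gridded posterior
#'
#' Natural-log entropy `-sum(w log w)` over grid nodes, with the `0 log 0 = 0`
#' convention (weights are floored at 1e-300 inside the log only).
#'
#' @param posterior A `qsdt_posterior`.
#' @return Entropy in nats, between 0 and `log(n_nodes)`.
#' @export
entropy <- function(posterior) {
  w <- posterior$weights
  -sum(w * log(pmax(w, 1e-300)))
}

#' Marginal posterior of one parameter
#'
#' @param posterior A `qsdt_posterior`.
#' @param param Parameter name.
#' @return data.frame with columns `value` (axis samples) and `weight`.
#' @export
marginal <- function(posterior, param) {
  i <- match(param, names(posterior$grid$axes))
  if (is.na(i)) stop("no such parameter: ", param)
  m <- rowsum(posterior$weights, axis_index(posterior$grid, i))
  data.frame(value = posterior$grid$axes[[i]], weight = as.vector(m))
}

weighted_quantile <- function(x, w, probs) {
  cw <- cumsum(w)
  cw <- cw / cw[length(cw)]
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    x[which(cw >= p - 1e-12)[1]]
  }, numeric(1))
}

#' Point estimates and credible intervals from the posterior
#'
#' tau and gamma are estimated as the geometric (log10-domain) marginal
#' means; criterion parameters as linear marginal means. Credible intervals
#' are central marginal quantile intervals at `ci_level` (default 68.2%,
#' i.e. +/- one standard deviation for a normal marginal).
#'
#' @param posterior A `qsdt_posterior`.
#' @param ci_level Credible-interval coverage probability.
#' @return data.frame of class `qsdt_estimate`, one row per parameter, with
#'   columns `parameter`, `estimate`, `ci_lo`, `ci_hi`; posterior entropy is
#'   attached as attribute `"entropy"`.
#' @export
estimate <- function(posterior, ci_level = 0.682) {
  stopifnot(ci_level > 0, ci_level < 1)
  alpha <- (1 - ci_level) / 2
  rows <- lapply(names(posterior$grid$axes), function(p) {
    m <- marginal(posterior, p)
    if (posterior$grid$scale[[p]] == "log") {
      est <- 10^sum(m$weight * log10(m$value))
    } else {
      est <- sum(m$weight * m$value)
    }
    ci <- weighted_quantile(m$value, m$weight, c(alpha, 1 - alpha))
    data.frame(parameter = p, estimate = est,
               ci_lo = min(ci[1], est), ci_hi = max(ci[2], est))
  })
  out <- do.call(rbind, rows)
  attr(out, "entropy") <- entropy(posterior)
  class(out) <- c("qsdt_estimate", "data.frame")
  out
}
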