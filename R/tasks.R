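#' Stimulus (contrast) grids
#'
#' Discrete contrast spaces over which the adaptive methods search. Two
#' presets are provided:
#' \describe{
#'   \item{`"simstudy"`}{0.001 to 0.99 contrast, 120 log-spaced samples --
#'     the simulation-study stimulus space. The default.}
#'   \item{`"demo"`}{0.001 to 0.99 contrast at 0.25 dB resolution
#'     (1 dB = 0.1 decimal log units), the demonstration configuration.}
#' }
#'
#' @param preset `"simstudy"` or `"demo"`, ignored if `n` is given.
#' @param lo,hi Contrast range endpoints (decimal fractions in (0, 1)).
#' @param n Optional number of log-spaced samples between `lo` and `hi`.
#' @return Increasing numeric vector of contrasts.
#' @export
contrast_grid <- function(preset = c("simstudy", "demo"), lo = 0.001, hi = 0.99,
                          n = NULL) {
  stopifnot(lo > 0, hi < 1, lo < hi)
  if (!is.null(n)) return(10^seq(log10(lo), log10(hi), length.out = n))
  preset <- match.arg(preset)
  if (preset == "simstudy") {
    10^seq(log10(lo), log10(hi), length.out = 120)
  } else {
    g <- 10^seq(log10(lo), log10(hi), by = 0.025) # 0.25 dB steps
    if (max(g) < hi) g <- c(g, hi)
    g
  }
}

TASK_NAMES <- c("qYN", "qYNC", "qYNR", "qFC")

#' Task with the study-scale stimulus grid
#'
#' Convenience constructor for replicated simulation studies: the simstudy
#' contrast range with 60 log-spaced levels for the 3-parameter tasks and 40
#' for the 4-parameter tasks (whose condition spaces are doubled by the cue
#' state or the interval sign).
#'
#' @param name Task name.
#' @return A [make_task()] object.
#' @export
study_task <- function(name)
  make_task(name, contrast_grid(n = if (name %in% c("qYN", "qFC")) 60 else 40))

#' Define a detection task
#'
#' Builds the declarative specification binding together, for one of the four
#' adaptive methods, its parameter layout, response alphabet and stimulus
#' condition space:
#' \describe{
#'   \item{qYN}{simple Yes-No detection; parameters (tau, gamma, lambda);
#'     conditions are single contrasts.}
#'   \item{qYNC}{cued detection; parameters (tau, gamma, lambda_strict,
#'     delta_lambda); conditions are (contrast, cue state) pairs -- the
#'     method selects both.}
#'   \item{qYNR}{rated detection with a ternary Yes / Not Sure / No response;
#'     same four parameters as qYNC; conditions are single contrasts.}
#'   \item{qFC}{two-interval forced choice; parameters (tau, gamma,
#'     lambda_fc); conditions are signed relative contrasts (negative =
#'     signal in interval 1, positive = interval 2, zero = both blank).}
#' }
#'
#' @param name Task name, one of `"qYN"`, `"qYNC"`, `"qYNR"`, `"qFC"`.
#' @param contrasts Contrast levels, see [contrast_grid()].
#' @param include_null For qFC, include the both-blank condition (signed
#'   contrast 0) in the stimulus space (default `TRUE`).
#' @param beta Fixed d' asymptote (not estimated).
#' @param epsilon Fixed lapse rate (not estimated).
#' @return An object of class `qsdt_task` with fields `name`, `param_names`,
#'   `response_alphabet`, `conditions` (a data.frame, one row per presentable
#'   condition), `beta`, `epsilon`.
#' @examples
#' tk <- make_task("qYN", contrast_grid(n = 20))
#' nrow(tk$conditions)
#' @export
make_task <- function(name, contrasts = contrast_grid("simstudy"),
                      include_null = TRUE, beta = 5, epsilon = 0.02) {
  if (!is.character(name) || length(name) != 1L || !(name %in% TASK_NAMES))
    stop("unknown task name: ", paste(name, collapse = ", "),
         " (expected one of ", paste(TASK_NAMES, collapse = ", "), ")")
  stopifnot(is.numeric(contrasts), all(contrasts > 0), all(contrasts < 1),
            !is.unsorted(contrasts, strictly = TRUE))
  conditions <- switch(name,
    qYN = ,
    qYNR = data.frame(contrast = contrasts),
    qYNC = data.frame(contrast = rep(contrasts, 2L),
                      cue_state = rep(c("lax", "strict"), each = length(contrasts)),
                      stringsAsFactors = FALSE),
    qFC = data.frame(signed_contrast = c(-rev(contrasts),
                                         if (include_null) 0,
                                         contrasts))
  )
  conditions$condition_id <- seq_len(nrow(conditions))
  structure(list(
    name = name,
    param_names = switch(name,
      qYN = c("tau", "gamma", "lambda"),
      qYNC = ,
      qYNR = c("tau", "gamma", "lambda_strict", "delta_lambda"),
      qFC = c("tau", "gamma", "lambda_fc")),
    response_alphabet = switch(name,
      qYN = ,
      qYNC = c("Yes", "No"),
      qYNR = c("Yes", "NotSure", "No"),
      qFC = c("Interval2", "Interval1")),
    conditions = conditions,
    beta = beta,
    epsilon = epsilon
  ), class = "qsdt_task")
}

#' @export
print.qsdt_task <- function(x, ...) {
  cat(sprintf("<%s task> %d parameters (%s), %d conditions, responses: %s\n",
              x$name, length(x$param_names),
              paste(x$param_names, collapse = ", "),
              nrow(x$conditions),
              paste(x$response_alphabet, collapse = "/")))
  cat(sprintf("  fixed: beta = %g, lapse epsilon = %g\n", x$beta, x$epsilon))
  invisible(x)
}

#' Model response probabilities for a task
#'
#' Maps a parameter vector to the lapse-adjusted probability of every
#' response, for one or more stimulus conditions of a task. This is the
#' single likelihood surface shared by the Bayesian engine, the simulated
#' observers and the MCS fitter.
#'
#' @param task A [make_task()] object.
#' @param theta Named numeric vector of task parameters (see
#'   `task$param_names`); unnamed vectors are taken in that order.
#' @param conditions Data frame of conditions (rows of `task$conditions`);
#'   defaults to all conditions of the task.
#' @param beta,epsilon Optional overrides of the task's fixed asymptote and
#'   lapse rate (used by simulated observers with non-default lapse).
#' @return Matrix, one row per condition, one named column per response;
#'   rows sum to 1 and every entry is at least `epsilon / K`.
#' @export
response_probabilities <- function(task, theta, conditions = NULL,
                                   beta = task$beta, epsilon = task$epsilon) {
  if (is.null(conditions)) conditions <- task$conditions
  if (is.null(names(theta))) names(theta) <- task$param_names
  if (!all(task$param_names %in% names(theta)))
    stop("`theta` must supply parameters: ",
         paste(task$param_names, collapse = ", "))
  sens <- sensitivity_params(theta[["tau"]], theta[["gamma"]], beta)
  raw <- switch(task$name,
    qYN = {
      py <- yes_probability(conditions$contrast, sens, theta[["lambda"]])
      cbind(Yes = py, No = 1 - py)
    },
    qYNC = {
      dec <- criterion_pair(theta[["lambda_strict"]], theta[["delta_lambda"]])
      lam <- ifelse(conditions$cue_state == "lax", dec$lambda_lax, dec$lambda_strict)
      py <- yes_probability(conditions$contrast, sens, lam)
      cbind(Yes = py, No = 1 - py)
    },
    qYNR = {
      dec <- criterion_pair(theta[["lambda_strict"]], theta[["delta_lambda"]])
      p <- rated_probabilities(conditions$contrast, sens, dec)
      colnames(p) <- c("Yes", "NotSure", "No")
      p
    },
    qFC = {
      s <- conditions$signed_contrast
      p2 <- interval2_probability(pmax(-s, 0), pmax(s, 0), sens,
                                  theta[["lambda_fc"]])
      cbind(Interval2 = p2, Interval1 = 1 - p2)
    })
  apply_lapse(raw, epsilon = epsilon)
}
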