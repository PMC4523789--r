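# Configuration and session persistence. Configs round-trip through YAML or
# JSON (by file extension); sessions are written as a purely tabular CSV with
# a JSON sidecar carrying the run metadata and final estimates.

#' Parse a contrast value
#'
#' Contrasts are handled internally as decimal fractions in (0, 1); at I/O
#' boundaries a percent string is also accepted (`"10%"` is 0.10).
#'
#' @param x Numeric fraction or string with a `%` suffix.
#' @return Numeric contrast fraction.
#' @export
parse_contrast <- function(x) {
  if (is.character(x)) {
    pct <- grepl("%\\s*$", x)
    v <- suppressWarnings(as.numeric(sub("%\\s*$", "", x)))
    if (any(is.na(v))) stop("cannot parse contrast: ", paste(x, collapse = ", "))
    ifelse(pct, v / 100, v)
  } else as.numeric(x)
}

.config_keys <- c("task", "stimulus", "grid", "prior", "observer", "stop",
                  "seed", "n_trials", "ci_level")
.stimulus_keys <- c("preset", "lo", "hi", "n", "include_null")
.grid_keys <- c("preset", "axes")

#' Run configuration
#'
#' Validates and normalises a configuration list for an adaptive run. Known
#' keys: `task` (required), `stimulus` (`preset`/`lo`/`hi`/`n`/
#' `include_null`), `grid` (`preset`/`axes`), `prior` (per-parameter
#' `[mode, confidence]`), `observer` (simulated-observer rates:
#' `tau`, `gamma`, `epsilon` and the state rates of [yn_observer()] and
#' friends), `stop` (`fixed_trials` or `ci_width`), `seed`, `n_trials`,
#' `ci_level`. Unknown keys are rejected by name.
#'
#' @param x A named list (e.g. from [load_config()]).
#' @return Object of class `qsdt_config`.
#' @export
run_config <- function(x) {
  if (!is.list(x)) stop("config must be a named list")
  bad <- setdiff(names(x), .config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(x$task)) stop("config field `task` is required")
  if (!x$task %in% TASK_NAMES)
    stop("config field `task` must be one of ", paste(TASK_NAMES, collapse = ", "))
  for (sub in list(c("stimulus", list(.stimulus_keys)), c("grid", list(.grid_keys)))) {
    key <- sub[[1]]
    bad <- setdiff(names(x[[key]]), sub[[2]])
    if (length(bad)) stop("unknown `", key, "` key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(x$stimulus$lo)) x$stimulus$lo <- parse_contrast(x$stimulus$lo)
  if (!is.null(x$stimulus$hi)) x$stimulus$hi <- parse_contrast(x$stimulus$hi)
  x$seed <- as.integer(x$seed %||% 1L)
  x$n_trials <- as.integer(x$n_trials %||% 50L)
  structure(x, class = "qsdt_config")
}

config_task <- function(cfg) {
  st <- cfg$stimulus
  contrasts <- if (!is.null(st$n))
    contrast_grid(lo = st$lo %||% 0.001, hi = st$hi %||% 0.99, n = st$n)
  else contrast_grid(st$preset %||% "simstudy",
                     lo = st$lo %||% 0.001, hi = st$hi %||% 0.99)
  make_task(cfg$task, contrasts, include_null = st$include_null %||% TRUE)
}

config_grid <- function(cfg, task) {
  axes <- lapply(cfg$grid$axes %||% list(), as.numeric)
  parameter_grid(task, preset = cfg$grid$preset %||% "coarse", axes = axes)
}

config_prior <- function(cfg) {
  pr <- cfg$prior %||% list()
  if (!is.null(pr$tau)) pr$tau[1] <- parse_contrast(pr$tau[1])
  do.call(prior_spec, lapply(pr, as.numeric))
}

config_observer <- function(cfg) {
  ob <- cfg$observer %||% list()
  ob <- lapply(ob, function(v) if (is.character(v)) parse_contrast(v) else v)
  common <- list(tau = ob$tau %||% 0.10, gamma = ob$gamma %||% 2,
                 epsilon = ob$epsilon %||% 0.02)
  switch(cfg$task,
    qYN = do.call(yn_observer, c(common, list(fa_rate = ob$fa_rate %||% 0.10))),
    qYNC = do.call(cued_observer, c(common,
      list(fa_strict = ob$fa_strict %||% 0.025, fa_lax = ob$fa_lax %||% 0.10))),
    qYNR = do.call(rated_observer, c(common,
      list(null_yes = ob$null_yes %||% 0.025, null_no = ob$null_no %||% 0.90))),
    qFC = do.call(fc_observer, c(common, list(p2_null = ob$p2_null %||% 0.5))))
}

#' Read or write a run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON (anything else) by extension; the loaded
#' config is validated by [run_config()] and round-trips losslessly.
#'
#' @param path File path.
#' @param config A `qsdt_config` (or plain list, validated on save).
#' @return `load_config()`: a `qsdt_config`. `save_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(x)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  config <- run_config(unclass(config))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA, pretty = TRUE)
  invisible(path)
}

# Polynomial rolling hash of a config's canonical serialisation (stamped on
# outputs so a result file identifies the configuration that produced it).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 268435399 # prime < 2^28: exact double arithmetic
  sprintf("%08x", h)
}

output_stamp <- function(config = NULL)
  list(package = "quickSDT",
       version = as.character(utils::packageVersion("quickSDT")),
       config_hash = if (!is.null(config)) config_hash(config) else NA)

#' Write or read a session log
#'
#' The per-trial log goes to `path` as plain CSV; run metadata (task, seed,
#' observer, final estimates, package version, config hash) goes to a JSON
#' sidecar at the same path with extension `.json`. The pair round-trips
#' losslessly; reading a log whose trial count disagrees with its sidecar
#' raises a truncation error.
#'
#' @param session A [run_session()] result.
#' @param path CSV path for the trial table.
#' @param config Optional `qsdt_config` to snapshot in the sidecar.
#' @return `write_session()`: `path`, invisibly. `read_session()`: a
#'   `qsdt_session` (without the posterior object).
#' @export
write_session <- function(session, path, config = NULL) {
  stopifnot(inherits(session, "qsdt_session"))
  utils::write.csv(session$trials, path, row.names = FALSE)
  side <- c(output_stamp(config),
            list(task = session$task_name, seed = session$seed,
                 n_trials = session$n_trials, ci_level = session$ci_level,
                 observer = session$observer_label,
                 final_estimate = session$final_estimate,
                 config = if (!is.null(config)) unclass(config)))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  trials <- tryCatch(utils::read.csv(path),
                     error = function(e) stop("malformed session CSV at ", path,
                                              ": ", conditionMessage(e)))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing session sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (nrow(trials) != side$n_trials)
    stop("truncated session log: ", nrow(trials), " trials on line ",
         nrow(trials) + 1L, " of ", path, ", sidecar declares ", side$n_trials)
  fe <- side$final_estimate
  class(fe) <- c("qsdt_estimate", "data.frame")
  structure(list(task_name = side$task, trials = trials,
                 n_trials = side$n_trials, seed = side$seed,
                 ci_level = side$ci_level, observer_label = side$observer,
                 final_estimate = fe, posterior = NULL),
            class = "qsdt_session")
}
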