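# File-format plumbing: tidy CSV trial logs, parameter tables, and a flat
# YAML run configuration. Lever ids are 0-based on disk and in memory.

TRIAL_COLS <- c("subject", "condition", "session", "block", "trial_in_block",
                "action", "reward", "target", "risk")

#' Read / write trial logs
#'
#' Trial logs are plain CSV, one row per trial, with the header columns
#' `subject, condition, session, block, trial_in_block, action, reward,
#' target, risk` (lever ids 0-based, reward 0/1). `read_trials()` validates
#' the header and value ranges.
#'
#' @param trials trial data frame.
#' @param path file path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLS, names(trials))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  write.csv(trials[, c(TRIAL_COLS, setdiff(names(trials), TRIAL_COLS))],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLS, names(trials))
  if (length(miss))
    stop("trial log ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(trials$reward %in% c(0, 1)))
    stop("trial log ", path, ": 'reward' must be 0/1", call. = FALSE)
  trials$reward <- as.numeric(trials$reward)
  if (any(trials$action < 0) || any(trials$target < 0))
    stop("trial log ", path, ": lever ids must be 0-based non-negative",
         call. = FALSE)
  trials
}

#' Read / write fitted-parameter tables
#'
#' Long-format CSV with columns `subject, condition, parameter, value`
#' (extra columns such as `log_lik` are preserved).
#'
#' @param tab parameter table, e.g. from [params_table()].
#' @param path file path.
#' @export
write_params <- function(tab, path) {
  stopifnot(all(c("subject", "condition", "parameter", "value") %in% names(tab)))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "parameter", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

RUN_CONFIG_KEYS <- c("n_levers", "block_length", "blocks_per_session",
                     "n_sessions", "low_risk_target", "low_risk_other",
                     "high_risk_target", "high_risk_other", "model", "seed",
                     "n_reps")

#' Read a flat run configuration file
#'
#' A flat YAML key-value file mapping onto [task_config()] plus run
#' settings. Recognized keys: `n_levers`, `block_length`,
#' `blocks_per_session`, `n_sessions`, `low_risk_target`, `low_risk_other`,
#' `high_risk_target`, `high_risk_other` (probabilities as decimals or
#' fraction strings like `"7/8"`), `model`, `seed`, `n_reps`. Unknown keys
#' raise an error naming the offending key.
#'
#' @param path YAML file path.
#' @return list with `config` (a [task_config()]), `model`, `seed`,
#'   `n_reps`.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "banditfit"))
#' cfg$config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  num <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    if (is.character(v) && grepl("/", v)) {
      parts <- as.numeric(strsplit(v, "/", fixed = TRUE)[[1]])
      return(parts[1] / parts[2])
    }
    as.numeric(v)
  }
  cfg <- task_config(
    n_levers = num("n_levers", 3),
    block_length = num("block_length", 24),
    risk_probs = list(
      low  = c(target = num("low_risk_target", 7 / 8),
               other = num("low_risk_other", 1 / 16)),
      high = c(target = num("high_risk_target", 5 / 8),
               other = num("high_risk_other", 3 / 16))),
    blocks_per_session = num("blocks_per_session", 12),
    n_sessions = num("n_sessions", 4))
  list(config = cfg,
       model = if (is.null(raw$model)) "fql" else raw$model,
       seed = as.integer(num("seed", 1)),
       n_reps = as.integer(num("n_reps", 100)))
}

#' End-to-end analysis pipeline
#'
#' Mirrors the full analysis sequence on a synthetic cohort: simulate (or
#' ingest) trial logs, fit the requested model families per subject x
#' condition, compare the first two families, rerun unconstrained
#' simulations from the fitted parameters, and compute behavioral index
#' curves for both the input data and the simulations. When `out_dir` is
#' given, every table is written as CSV alongside a JSON metadata record
#' (seed, configuration, model list).
#'
#' @param true_params data frame of generating parameters (see
#'   [simulate_cohort()]); ignored when `trials` is supplied.
#' @param trials optional pre-existing trial log to analyse instead of
#'   simulating one.
#' @param config a [task_config()].
#' @param models model family names to fit (first two are compared).
#' @param seed master integer seed.
#' @param n_reps unconstrained simulation replicates per fit.
#' @param out_dir optional output directory.
#' @return list with `trials`, `fits` (per family), `comparison`,
#'   `simulated`, `curves_data`, `curves_sim`, invisibly.
#' @export
run_pipeline <- function(true_params = NULL, trials = NULL,
                         config = task_config(), models = c("ql", "fql"),
                         seed = 1, n_reps = 10, out_dir = NULL) {
  if (is.null(trials)) {
    if (is.null(true_params))
      stop("supply either 'trials' or 'true_params'", call. = FALSE)
    trials <- simulate_cohort(true_params, config, seed = seed)
  }
  fits <- lapply(models, function(m) fit_population(m, trials))
  names(fits) <- models
  comparison <- if (length(models) >= 2)
    compare_models(fits[[1]], fits[[2]]) else NULL
  main_fits <- fits[[length(fits)]]
  simulated <- simulate_fitted(main_fits, config, n_reps = n_reps,
                               seed = derive_seed(seed, 777L))
  curves_data <- block_curves(trials)
  curves_sim <- block_curves(simulated)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    for (m in models)
      write_params(params_table(fits[[m]]),
                   file.path(out_dir, paste0("params_", m, ".csv")))
    if (!is.null(comparison))
      write.csv(comparison$totals, file.path(out_dir, "model_comparison.csv"),
                row.names = FALSE)
    write.csv(curves_data, file.path(out_dir, "curves_data.csv"),
              row.names = FALSE)
    write.csv(curves_sim, file.path(out_dir, "curves_simulated.csv"),
              row.names = FALSE)
    meta <- list(seed = seed, models = models, n_reps = n_reps,
                 config = unclass(config))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(trials = trials, fits = fits, comparison = comparison,
                 simulated = simulated, curves_data = curves_data,
                 curves_sim = curves_sim))
}
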