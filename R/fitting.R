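# Maximum-likelihood fitting of per-subject x per-condition parameters.
#
# The likelihood of a choice history is evaluated by constrained replay: the
# model is walked through the subject's actual choices and rewards and the
# probability it assigned to each observed choice is accumulated. The inner
# loop lives in C++ (src/likelihood.cpp); a pure-R path using the exported
# step/probability operations is kept for reference and cross-checking.

# transformed-scale boxes used by the optimizer; inverse temperatures are
# searched on a log10 scale because their fitted distributions are
# heavy-tailed
is_beta_par <- function(p) p %in% c("beta", "beta0", "beta1")

trans_par <- function(params, names) {
  ifelse(is_beta_par(names), log10(pmax(params, 1e-6)), params)
}
untrans_par <- function(theta, names) {
  ifelse(is_beta_par(names), 10^theta, theta)
}
trans_lower <- function(names) {
  ifelse(is_beta_par(names), -2, ifelse(names == "phi", -10, 1e-3))
}
trans_upper <- function(names) {
  ifelse(is_beta_par(names), 3, ifelse(names == "phi", 10, 1 - 1e-3))
}

split_histories <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "condition", "action", "reward") %in% names(trials)))
  key <- paste(trials$subject, trials$condition, sep = "|")
  split(trials, factor(key, levels = unique(key)))
}

check_single_history <- function(trials) {
  if (length(unique(trials$subject)) != 1L ||
      length(unique(trials$condition)) != 1L)
    stop("expected a single subject x condition history; use fit_population()",
         call. = FALSE)
  if (nrow(trials) == 0L) stop("empty history", call. = FALSE)
  trials
}

#' Log-likelihood of a choice history under a model
#'
#' Constrained replay: the model is driven by the subject's actual choices
#' and rewards, its latent state starting from zero at the beginning of the
#' sequence, and the log-probabilities of the observed choices are summed.
#' Probabilities are floored at 1e-12 inside the log to guard against
#' underflow at extreme parameters.
#'
#' @param spec a `model_spec` (or family name).
#' @param params named parameter vector/list, within bounds (error otherwise).
#' @param trials one subject x condition trial data frame in chronological
#'   order (columns `action` 0-based and `reward`; `subject`/`condition` if
#'   present must be single-valued).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference path built
#'   on [model_step()] and [action_probs()]); both give identical results.
#' @param per_trial if `TRUE`, also return the per-trial probability of each
#'   chosen action.
#' @return the summed log-likelihood in nats, or (with `per_trial = TRUE`) a
#'   list with `log_lik` and `per_trial_p`.
#' @examples
#' h <- data.frame(subject = "s", condition = "c",
#'                 action = c(0, 1, 0), reward = c(1, 0, 1))
#' log_likelihood("fql", c(alpha = .5, alpha2 = .1, beta = 2), h)
#' @export
log_likelihood <- function(spec, params, trials, engine = c("cpp", "r"),
                           per_trial = FALSE) {
  spec <- as_model_spec(spec)
  engine <- match.arg(engine)
  params <- validate_params(spec, params)
  if (all(c("subject", "condition") %in% names(trials)))
    check_single_history(trials)
  n_levers <- max(3L, max(trials$action) + 1L)
  if (engine == "cpp") {
    lp <- ll_trials_cpp(spec$code, unname(params[spec$params]),
                        as.integer(trials$action), as.numeric(trials$reward),
                        n_levers, spec$update_on_loss)
    p <- exp(lp)
  } else {
    st <- init_state(spec, params, n_levers)
    p <- numeric(nrow(trials))
    for (t in seq_len(nrow(trials))) {
      pr <- action_probs(spec, st, params)
      p[t] <- pr[trials$action[t] + 1L]
      st <- model_step(spec, st, trials$action[t], trials$reward[t], params)
    }
  }
  ll <- sum(log(pmax(p, 1e-12)))
  if (per_trial) list(log_lik = ll, per_trial_p = p) else ll
}

#' Per-trial predicted choice probabilities (all levers)
#'
#' Same constrained replay as [log_likelihood()], returning the full
#' trial x lever probability matrix (the state before each trial).
#'
#' @inheritParams log_likelihood
#' @return numeric matrix, one row per trial, one column per lever
#'   (column `j` = lever `j - 1`).
#' @export
predicted_probs <- function(spec, params, trials) {
  spec <- as_model_spec(spec)
  params <- validate_params(spec, params)
  n_levers <- max(3L, max(trials$action) + 1L)
  probs_trials_cpp(spec$code, unname(params[spec$params]),
                   as.integer(trials$action), as.numeric(trials$reward),
                   n_levers, spec$update_on_loss)
}

#' Default multi-start grid for a model family
#'
#' Three starting values per free parameter — rates at 0.1/0.5/0.9, inverse
#' temperatures at 1/5/20, the uncertainty weight at -1/0/1 — crossed into
#' `3^k` starting points for a k-parameter family.
#'
#' @param spec a `model_spec` (or family name).
#' @return data frame of starting points (natural scale), one column per
#'   parameter.
#' @export
default_start_grid <- function(spec) {
  spec <- as_model_spec(spec)
  vals <- lapply(spec$params, function(p) {
    if (is_beta_par(p)) c(1, 5, 20) else if (p == "phi") c(-1, 0, 1)
    else c(0.1, 0.5, 0.9)
  })
  names(vals) <- spec$params
  expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
}

#' Fit one subject x condition history by maximum likelihood
#'
#' Runs a bounded quasi-Newton search (`L-BFGS-B`) of the negative
#' log-likelihood from every point of the start grid (by default `3^k`
#' combinations, see [default_start_grid()]) and keeps the best optimum.
#' Inverse temperatures are searched on a log10 scale with an upper bound of
#' 1000. Deterministic given the history and grid.
#'
#' @inheritParams log_likelihood
#' @param start_grid data frame of starting points (natural scale); default
#'   [default_start_grid()].
#' @return object of class `fit_result`: fitted `params`, `log_lik`, `aic`,
#'   `bic`, `n_trials`, `n_par`, `n_starts`, `best_start`, `n_converged`,
#'   `per_trial_p`, and the subject/condition ids.
#' @export
fit_subject <- function(spec, trials, start_grid = NULL) {
  spec <- as_model_spec(spec)
  trials <- check_single_history(trials)
  if (is.null(start_grid)) start_grid <- default_start_grid(spec)
  stopifnot(all(spec$params %in% names(start_grid)))
  n_levers <- max(3L, max(trials$action) + 1L)
  actions <- as.integer(trials$action)
  rewards <- as.numeric(trials$reward)

  nll <- function(theta) {
    par <- untrans_par(theta, spec$params)
    -sum(ll_trials_cpp(spec$code, par, actions, rewards, n_levers,
                       spec$update_on_loss))
  }
  lo <- trans_lower(spec$params)
  hi <- trans_upper(spec$params)

  best <- NULL; best_i <- NA_integer_; n_conv <- 0L; n_fail <- 0L
  for (i in seq_len(nrow(start_grid))) {
    th0 <- trans_par(as.numeric(start_grid[i, spec$params]), spec$params)
    th0 <- pmin(pmax(th0, lo), hi)
    res <- tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) { best <- res; best_i <- i }
  }
  if (is.null(best))
    stop("optimization failed from every starting point", call. = FALSE)

  params <- setNames(untrans_par(best$par, spec$params), spec$params)
  ll <- -best$value
  k <- length(spec$params)
  n <- nrow(trials)
  per_p <- log_likelihood(spec, params, trials, per_trial = TRUE)$per_trial_p
  structure(
    list(family = spec$family, spec = spec,
         subject = trials$subject[1], condition = trials$condition[1],
         params = params, log_lik = ll, n_trials = n, n_par = k,
         aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
         n_starts = nrow(start_grid), best_start = best_i,
         n_converged = n_conv, n_failed = n_fail,
         per_trial_p = per_p),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  subject %s / condition %s\n", x$family,
              x$subject, x$condition))
  print(round(x$params, 4))
  cat(sprintf("  logLik %.2f  AIC %.1f  BIC %.1f  (%d trials, %d/%d starts converged)\n",
              x$log_lik, x$aic, x$bic, x$n_trials, x$n_converged, x$n_starts))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$params

#' Fit every subject x condition history in a trial log
#'
#' @inheritParams fit_subject
#' @param trials trial data frame covering one or more subject x condition
#'   sequences (split on those two columns, in order of appearance).
#' @param progress print one line per fit.
#' @return object of class `fit_population`: a list of [fit_subject()]
#'   results.
#' @export
fit_population <- function(spec, trials, start_grid = NULL, progress = FALSE) {
  spec <- as_model_spec(spec)
  hists <- split_histories(trials)
  fits <- vector("list", length(hists))
  for (i in seq_along(hists)) {
    fits[[i]] <- fit_subject(spec, hists[[i]], start_grid)
    if (progress)
      cat(sprintf("fit %d/%d  %s %s  logLik %.1f\n", i, length(hists),
                  fits[[i]]$subject, fits[[i]]$condition, fits[[i]]$log_lik))
  }
  names(fits) <- names(hists)
  structure(fits, class = "fit_population")
}

#' @export
print.fit_population <- function(x, ...) {
  cat(sprintf("<fit_population> %d fits (%s)\n", length(x), x[[1]]$family))
  print(utils::head(params_table(x)), row.names = FALSE)
  if (length(x) > 2) cat("  ...\n")
  invisible(x)
}

#' Tidy table of fitted parameters
#'
#' @param fits a `fit_population` (or list of `fit_result`s).
#' @return data frame with columns `subject`, `condition`, `parameter`,
#'   `value`, plus `log_lik`, `aic`, `bic` repeated per parameter row.
#' @export
params_table <- function(fits) {
  do.call(rbind, lapply(unclass(fits), function(f)
    data.frame(subject = f$subject, condition = f$condition,
               parameter = names(f$params), value = unname(f$params),
               log_lik = f$log_lik, aic = f$aic, bic = f$bic,
               stringsAsFactors = FALSE)))
}

#' Subjects x conditions matrix of one fitted parameter
#'
#' Convenience reshape for complete-block tests such as [friedman_test()].
#'
#' @param fits a `fit_population`.
#' @param parameter parameter name.
#' @return numeric matrix, rows = subjects, columns = conditions.
#' @export
params_matrix <- function(fits, parameter) {
  tab <- params_table(fits)
  tab <- tab[tab$parameter == parameter, ]
  if (nrow(tab) == 0L) stop("unknown parameter '", parameter, "'", call. = FALSE)
  subj <- unique(tab$subject); cond <- unique(tab$condition)
  m <- matrix(NA_real_, length(subj), length(cond),
              dimnames = list(subj, cond))
  m[cbind(match(tab$subject, subj), match(tab$condition, cond))] <- tab$value
  m
}

#' Population-level model comparison by AIC / BIC
#'
#' Sums AIC, BIC and log-likelihood over the whole population of fits for
#' each model (lower AIC/BIC is better) and tabulates per-fit differences.
#' The two populations must cover the same subject x condition cells.
#'
#' @param fits_a,fits_b two `fit_population` objects fitted to the same
#'   histories.
#' @return object of class `model_comparison`: `totals` (per-model summed
#'   AIC/BIC/logLik), `per_fit` (per-cell deltas, B minus A), and the family
#'   names.
#' @export
compare_models <- function(fits_a, fits_b) {
  key <- function(f) paste(f$subject, f$condition, sep = "|")
  ka <- vapply(unclass(fits_a), key, character(1))
  kb <- vapply(unclass(fits_b), key, character(1))
  if (!setequal(ka, kb) || length(ka) != length(kb))
    stop("the two fit populations cover different subject x condition sets",
         call. = FALSE)
  fb <- unclass(fits_b)[match(ka, kb)]
  fa <- unclass(fits_a)
  tot <- data.frame(
    family = c(fa[[1]]$family, fb[[1]]$family),
    n_par = c(fa[[1]]$n_par, fb[[1]]$n_par),
    log_lik = c(sum(vapply(fa, `[[`, 0, "log_lik")),
                sum(vapply(fb, `[[`, 0, "log_lik"))),
    aic = c(sum(vapply(fa, `[[`, 0, "aic")), sum(vapply(fb, `[[`, 0, "aic"))),
    bic = c(sum(vapply(fa, `[[`, 0, "bic")), sum(vapply(fb, `[[`, 0, "bic"))),
    stringsAsFactors = FALSE)
  per <- data.frame(
    subject = vapply(fa, `[[`, "", "subject"),
    condition = vapply(fa, `[[`, "", "condition"),
    d_log_lik = vapply(seq_along(fa), function(i) fb[[i]]$log_lik - fa[[i]]$log_lik, 0),
    d_aic = vapply(seq_along(fa), function(i) fb[[i]]$aic - fa[[i]]$aic, 0),
    d_bic = vapply(seq_along(fa), function(i) fb[[i]]$bic - fa[[i]]$bic, 0),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(list(totals = tot, per_fit = per), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> population totals (lower AIC/BIC wins):\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test for nested models
#'
#' `d = 2 * (ll_complex - ll_simple)` is referred to a chi-squared
#' distribution with `df` degrees of freedom (the number of added
#' parameters). A negative `d` — possible only as an optimizer artifact —
#' is clamped to 0 with a warning.
#'
#' @param ll_simple,ll_complex maximized log-likelihoods of the nested and
#'   the larger model (vectors allowed, paired).
#' @param df number of added parameters in the larger model.
#' @return data frame with columns `d`, `df`, `p_value`.
#' @examples
#' lrt_nested(-100, -97.5)         # d = 5, p ~ 0.025
#' @export
lrt_nested <- function(ll_simple, ll_complex, df = 1) {
  d <- 2 * (ll_complex - ll_simple)
  if (any(d < 0)) {
    warning("negative likelihood-ratio statistic clamped to 0 ",
            "(optimizer artifact)")
    d <- pmax(d, 0)
  }
  data.frame(d = d, df = df, p_value = pchisq(d, df, lower.tail = FALSE))
}

#' Constrained-prediction check of a fitted model
#'
#' Validates a fit by comparing observed choice frequencies with the
#' model's predicted probabilities under constrained replay. Trials are
#' grouped into cells (subject x condition x risk x within-block bin x
#' lever role, where the role distinguishes the block's target lever from
#' the others); within each cell the observed choice rate of the role is
#' regressed on the mean predicted probability through the origin,
#' `observed = b1 * predicted`.
#'
#' @param fits a `fit_population`.
#' @param trials the trial data the models were fitted to.
#' @param trial_range optional restriction to a range of `trial_in_block`
#'   positions (e.g. `2:6` to isolate the relearning phase right after a
#'   target switch); each position is then its own bin.
#' @return object of class `prediction_check`: `b1`, `adj_r2`, `n_cells`,
#'   `degenerate` (TRUE when the predictions carry no variance, in which
#'   case the regression is meaningless), and the cell-level `data`.
#' @export
constrained_prediction_check <- function(fits, trials, trial_range = NULL) {
  hists <- split_histories(trials)
  key <- function(f) paste(f$subject, f$condition, sep = "|")
  rows <- list()
  for (f in unclass(fits)) {
    h <- hists[[key(f)]]
    if (is.null(h)) stop("no trials found for fit ", key(f), call. = FALSE)
    P <- predicted_probs(f$spec, f$params, h)
    keep <- if (is.null(trial_range)) rep(TRUE, nrow(h)) else
      h$trial_in_block %in% trial_range
    if (!any(keep)) next
    bin <- if (is.null(trial_range)) ceiling(h$trial_in_block / 4) else
      h$trial_in_block
    n_lev <- ncol(P)
    for (lev in seq_len(n_lev) - 1L) {
      role <- ifelse(h$target == lev, "target", "nontarget")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = f$subject, condition = f$condition,
        risk = h$risk[keep], bin = bin[keep], role = role[keep],
        observed = as.numeric(h$action[keep] == lev),
        predicted = P[keep, lev + 1L], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  cells <- aggregate(cbind(observed, predicted) ~ subject + condition + risk +
                       bin + role, data = long, FUN = mean)
  cells$n <- aggregate(observed ~ subject + condition + risk + bin + role,
                       data = long, FUN = length)$observed
  degenerate <- var(cells$predicted) < 1e-10
  if (degenerate) {
    b1 <- NA_real_; r2 <- NA_real_
    warning("predicted probabilities are constant; regression is degenerate")
  } else {
    fit <- lm(observed ~ 0 + predicted, data = cells)
    b1 <- unname(coef(fit)[1])
    r2 <- summary(fit)$adj.r.squared
  }
  structure(list(b1 = b1, adj_r2 = r2, n_cells = nrow(cells),
                 degenerate = degenerate, data = cells),
            class = "prediction_check")
}

#' @export
print.prediction_check <- function(x, ...) {
  cat(sprintf("<prediction_check> b1 = %.3f, adj R^2 = %.3f (%d cells)\n",
              x$b1, x$adj_r2, x$n_cells))
  invisible(x)
}

#' Unconstrained simulations from fitted parameters
#'
#' Replays the experiment generatively: every fit is run `n_reps` times
#' through fresh schedules with its own fitted parameters, each run with an
#' independent derived seed. Downstream behavioral indices are typically
#' averaged over replicates.
#'
#' @param fits a `fit_population`.
#' @param config a [task_config()].
#' @param n_reps independent runs per fit.
#' @param seed master integer seed.
#' @return combined trial data frame with an extra `rep` column.
#' @export
simulate_fitted <- function(fits, config = task_config(), n_reps = 100,
                            seed = 1) {
  fits <- unclass(fits)
  out <- vector("list", length(fits) * n_reps)
  k <- 0L
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      idx <- 2L * ((i - 1L) * n_reps + r)
      sch <- build_schedule(config, derive_seed(seed, idx))
      h <- run_agent(f$spec, f$params, sch, config,
                     seed = derive_seed(seed, idx + 1L),
                     subject = f$subject, condition = f$condition)
      h$rep <- r
      out[[k]] <- h
    }
  }
  do.call(rbind, out)
}
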