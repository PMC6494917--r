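#' Task configuration for the non-stationary bandit
#'
#' Describes a three-armed bandit task organized in unsignaled fixed-length
#' blocks. Within a block one lever (the target) is rewarded with a high
#' probability and the others with a low one; the pair of probabilities
#' depends on the block's risk level. Defaults follow the standard rodent
#' protocol: 24-trial blocks, low-risk blocks rewarding the target at 7/8 and
#' the others at 1/16, high-risk blocks at 5/8 and 3/16, and 12 blocks per
#' session so that every (target, risk) combination occurs twice per session.
#'
#' @param n_levers number of levers (>= 2).
#' @param block_length trials per block.
#' @param risk_probs named list; each element is `c(target = p, other = p)`
#'   with `target > other`, both in \[0, 1\]. Names are the risk labels.
#' @param blocks_per_session blocks per session; must be a multiple of
#'   `n_levers * length(risk_probs)` for counterbalancing.
#' @param n_sessions number of sessions per subject x condition.
#' @return object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$risk_probs$low
#' @export
task_config <- function(n_levers = 3,
                        block_length = 24,
                        risk_probs = list(low  = c(target = 7 / 8, other = 1 / 16),
                                          high = c(target = 5 / 8, other = 3 / 16)),
                        blocks_per_session = 12,
                        n_sessions = 4) {
  n_levers <- stopifnot_scalar_int(n_levers, "n_levers")
  if (n_levers < 2) stop("'n_levers' must be >= 2", call. = FALSE)
  block_length <- stopifnot_scalar_int(block_length, "block_length")
  blocks_per_session <- stopifnot_scalar_int(blocks_per_session, "blocks_per_session")
  n_sessions <- stopifnot_scalar_int(n_sessions, "n_sessions")
  if (is.null(names(risk_probs)) || any(!nzchar(names(risk_probs))))
    stop("'risk_probs' must be a named list of risk levels", call. = FALSE)
  for (rk in names(risk_probs)) {
    p <- risk_probs[[rk]]
    if (!all(c("target", "other") %in% names(p)))
      stop("risk level '", rk, "' must name 'target' and 'other' probabilities",
           call. = FALSE)
    if (any(p < 0) || any(p > 1))
      stop("probabilities for risk '", rk, "' must lie in [0, 1]", call. = FALSE)
    if (p[["target"]] <= p[["other"]])
      stop("risk '", rk, "': target probability must exceed the others'",
           call. = FALSE)
  }
  structure(list(n_levers = n_levers, block_length = block_length,
                 risk_probs = risk_probs,
                 blocks_per_session = blocks_per_session,
                 n_sessions = n_sessions),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>", x$n_levers, "levers,", x$block_length,
      "trials/block,", x$blocks_per_session, "blocks/session,",
      x$n_sessions, "session(s)\n")
  for (rk in names(x$risk_probs))
    cat(sprintf("  risk %-5s target %.4f  other %.4f\n", rk,
                x$risk_probs[[rk]][["target"]], x$risk_probs[[rk]][["other"]]))
  invisible(x)
}

#' Build a counterbalanced pseudo-random block schedule
#'
#' Within every session each (target lever, risk level) combination occurs
#' equally often, and no two consecutive blocks (including across session
#' boundaries) share a target lever, so the subject must relearn the target
#' on every block. Ordering is by rejection sampling: the multiset of
#' combinations is shuffled until the no-repeat constraint holds.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @return data frame of class `task_schedule` with columns `session`,
#'   `block` (global ordinal), `target` (0-based lever id), `risk`.
#' @examples
#' sch <- build_schedule(task_config(n_sessions = 1), seed = 1)
#' table(sch$target, sch$risk)
#' @export
build_schedule <- function(config, seed) {
  stopifnot(inherits(config, "task_config"))
  seed <- stopifnot_scalar_int(seed, "seed")
  n_comb <- config$n_levers * length(config$risk_probs)
  if (config$blocks_per_session %% n_comb != 0)
    stop("counterbalancing impossible: 'blocks_per_session' (",
         config$blocks_per_session, ") is not a multiple of n_levers x ",
         "n_risk_levels (", n_comb, ")", call. = FALSE)
  reps <- config$blocks_per_session %/% n_comb
  combs <- expand.grid(target = seq_len(config$n_levers) - 1L,
                       risk = names(config$risk_probs),
                       stringsAsFactors = FALSE)
  pool <- combs[rep(seq_len(nrow(combs)), reps), ]

  with_seed_(seed, {
    out <- vector("list", config$n_sessions)
    prev_target <- -1L
    for (s in seq_len(config$n_sessions)) {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        ord <- pool[sample.int(nrow(pool)), ]
        tg <- ord$target
        if (tg[1] != prev_target && all(diff(tg) != 0L)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not order blocks without consecutive repeated targets",
             call. = FALSE)
      out[[s]] <- data.frame(session = s, target = as.integer(ord$target),
                             risk = ord$risk, stringsAsFactors = FALSE)
      prev_target <- tg[length(tg)]
    }
    sch <- do.call(rbind, out)
    sch$block <- seq_len(nrow(sch))
    rownames(sch) <- NULL
    sch <- sch[, c("session", "block", "target", "risk")]
    class(sch) <- c("task_schedule", "data.frame")
    sch
  })
}

#' Sample a reward for one lever press
#'
#' Bernoulli draw with the target probability if the pressed lever is the
#' block's target, else with the non-target probability of the block's risk
#' level. Consumes one uniform draw from the current RNG stream.
#'
#' @param action 0-based lever id pressed.
#' @param target 0-based id of the block's target lever.
#' @param risk risk label of the block (a name of `config$risk_probs`).
#' @param config a [task_config()].
#' @return 0 or 1.
#' @export
sample_reward <- function(action, target, risk, config) {
  p <- config$risk_probs[[risk]]
  if (is.null(p)) stop("unknown risk level '", risk, "'", call. = FALSE)
  pr <- if (action == target) p[["target"]] else p[["other"]]
  as.integer(runif(1) < pr)
}

#' Run an agent through a task schedule
#'
#' Simulates one subject x condition: on every trial the agent's
#' action-probability map is sampled, a reward is drawn from the block's
#' contingencies, and the agent's latent state is advanced by its own update
#' rule. Latent state is reset at the start of the run (not at block
#' boundaries — blocks are unsignaled).
#'
#' @param spec a `model_spec` (or family name).
#' @param params named parameter vector/list for the model.
#' @param schedule a [build_schedule()] result.
#' @param config the [task_config()] the schedule was built from.
#' @param seed integer seed; the same seed gives a bit-identical history.
#' @param subject,condition labels stamped on the rows.
#' @return data frame with one row per trial: `subject`, `condition`,
#'   `session`, `block`, `trial_in_block`, `action` (0-based), `reward`
#'   (0/1), `target` (0-based), `risk`.
#' @examples
#' cfg <- task_config(n_sessions = 1)
#' sch <- build_schedule(cfg, seed = 1)
#' h <- run_agent("fql", c(alpha = 0.4, alpha2 = 0.5, beta = 6), sch, cfg, seed = 2)
#' mean(h$action == h$target)
#' @export
run_agent <- function(spec, params, schedule, config, seed,
                      subject = "s1", condition = "c1") {
  spec <- as_model_spec(spec)
  params <- validate_params(spec, params)
  seed <- stopifnot_scalar_int(seed, "seed")
  n_trials <- nrow(schedule) * config$block_length
  action <- integer(n_trials); reward <- numeric(n_trials)
  blk <- integer(n_trials); tib <- integer(n_trials)
  sess <- integer(n_trials); targ <- integer(n_trials)
  rk <- character(n_trials)

  with_seed_(seed, {
    st <- init_state(spec, params, config$n_levers)
    t <- 0L
    for (b in seq_len(nrow(schedule))) {
      b_target <- schedule$target[b]
      b_risk <- schedule$risk[b]
      for (i in seq_len(config$block_length)) {
        t <- t + 1L
        p <- action_probs(spec, st, params)
        a <- sample.int(config$n_levers, 1L, prob = p) - 1L
        r <- sample_reward(a, b_target, b_risk, config)
        st <- model_step(spec, st, a, r, params)
        action[t] <- a; reward[t] <- r
        sess[t] <- schedule$session[b]; blk[t] <- schedule$block[b]
        tib[t] <- i; targ[t] <- b_target; rk[t] <- b_risk
      }
    }
  })

  data.frame(subject = subject, condition = condition, session = sess,
             block = blk, trial_in_block = tib, action = action,
             reward = reward, target = targ, risk = rk,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of subjects from a parameter table
#'
#' One run per row of `true_params` (a subject x condition grid). Every run
#' gets its own schedule and agent stream, derived deterministically from the
#' master seed, so cohorts are reproducible and runs are independent.
#'
#' @param true_params data frame with columns `subject`, `condition`,
#'   optionally `family` (default `"fql"`), and one column per model
#'   parameter.
#' @param config a [task_config()].
#' @param seed master integer seed.
#' @return combined trial data frame (see [run_agent()]).
#' @export
simulate_cohort <- function(true_params, config = task_config(), seed = 1) {
  stopifnot(is.data.frame(true_params),
            all(c("subject", "condition") %in% names(true_params)))
  fam <- if ("family" %in% names(true_params)) true_params$family else
    rep("fql", nrow(true_params))
  out <- vector("list", nrow(true_params))
  for (i in seq_len(nrow(true_params))) {
    spec <- model_spec(fam[i])
    par_cols <- intersect(spec$params, names(true_params))
    pars <- setNames(as.numeric(true_params[i, par_cols]), par_cols)
    sch <- build_schedule(config, derive_seed(seed, 2L * i))
    out[[i]] <- run_agent(spec, pars, sch, config,
                          seed = derive_seed(seed, 2L * i + 1L),
                          subject = true_params$subject[i],
                          condition = true_params$condition[i])
  }
  do.call(rbind, out)
}
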