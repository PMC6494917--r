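# Two executable methodological guarantees:
#
# 1. Reward-rescaling / inverse-temperature-rescaling equivalence. With
#    binary rewards, value updates proportional to the reward prediction
#    error, and multiplicative forgetting, scaling every reward by kappa
#    scales every Q-value by kappa throughout learning; plugged into the
#    softmax this is exactly a scaling of the inverse temperature by kappa.
#    A pharmacological downscaling of reward signals is therefore
#    indistinguishable from an increase in random exploration and touches
#    neither the learning nor the forgetting rate.
#
# 2. Parameter recovery: fitting all parameters freely to cohorts simulated
#    with only one parameter varying across conditions must single out that
#    parameter (Friedman test across conditions), establishing that learning
#    rate and inverse temperature are identifiable despite their well-known
#    interaction.

#' Reward-rescaling vs inverse-temperature-rescaling equivalence
#'
#' Replays one fixed choice history twice under a forgetting Q-learning
#' model: once with all rewards multiplied by `kappa` (inverse temperature
#' `beta` unchanged), once with the original rewards and `beta * kappa`.
#' The theorem asserts that the per-trial Q-values of the first replay equal
#' `kappa` times those of the second, and the per-trial choice probabilities
#' are identical — exactly, up to floating-point tolerance. With the
#' `"egreedy"` policy the probabilities are identical even without rescaling
#' `epsilon`, because the argmax is invariant under positive scaling.
#'
#' @param params named vector with `alpha`, `alpha2`, and `beta`
#'   (softmax policy) or `epsilon` (egreedy policy).
#' @param trials a trial data frame (columns `action`, `reward`) giving the
#'   fixed history to replay.
#' @param kappa reward scale factor in (0, 1].
#' @param policy `"softmax"` (default) or `"egreedy"`.
#' @return list with `max_prob_diff` (largest absolute per-trial
#'   choice-probability discrepancy), `max_q_diff` (largest absolute
#'   deviation of scaled-reward Q-values from `kappa` x original-reward
#'   Q-values), and the two probability matrices.
#' @examples
#' cfg <- task_config(n_sessions = 1)
#' h <- run_agent("fql", c(alpha = .4, alpha2 = .5, beta = 6),
#'                build_schedule(cfg, 1), cfg, seed = 2)
#' equivalence_check(c(alpha = .4, alpha2 = .5, beta = 6), h, kappa = 0.5)$max_prob_diff
#' @export
equivalence_check <- function(params, trials, kappa, policy = c("softmax", "egreedy")) {
  policy <- match.arg(policy)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0 || kappa > 1)
    stop("'kappa' must be a single value in (0, 1]", call. = FALSE)
  actions <- as.integer(trials$action)
  rewards <- as.numeric(trials$reward)
  alpha <- params[["alpha"]]; alpha2 <- params[["alpha2"]]

  replay <- function(rw, sel) {
    n <- max(3L, max(actions) + 1L)
    Q <- numeric(n)
    P <- matrix(NA_real_, length(actions), n)
    Qmat <- matrix(NA_real_, length(actions), n)
    for (t in seq_along(actions)) {
      P[t, ] <- sel(Q)
      a <- actions[t] + 1L
      Q[a] <- Q[a] + alpha * (rw[t] - Q[a])
      Q[-a] <- (1 - alpha2) * Q[-a]
      Qmat[t, ] <- Q
    }
    list(P = P, Q = Qmat)
  }

  if (policy == "softmax") {
    beta <- params[["beta"]]
    scaled <- replay(rewards * kappa, function(q) softmax_probs(q, beta))
    base   <- replay(rewards,         function(q) softmax_probs(q, beta * kappa))
  } else {
    eps <- params[["epsilon"]]
    scaled <- replay(rewards * kappa, function(q) egreedy_probs(q, eps))
    base   <- replay(rewards,         function(q) egreedy_probs(q, eps))
  }
  list(max_prob_diff = max(abs(scaled$P - base$P)),
       max_q_diff = max(abs(scaled$Q - kappa * base$Q)),
       probs_scaled_reward = scaled$P, probs_scaled_beta = base$P)
}

#' Design of a parameter-recovery experiment
#'
#' Specifies a synthetic cohort in which exactly one forgetting-Q-learning
#' parameter varies across conditions while the others are held constant
#' within subject. Per-subject individual differences are drawn once per
#' subject (the same offset in every condition, so they do not confound the
#' within-subject condition contrast): additive Gaussian jitter (sd 0.03)
#' for rates, multiplicative log-normal jitter (sdlog 0.15) for the inverse
#' temperature.
#'
#' Default condition profiles emulate a dose manipulation: the varying
#' learning rate spans 0.20–0.50 and the varying inverse temperature falls
#' from 8 to 2, with the non-varying parameters at `alpha = 0.3`,
#' `alpha2 = 0.5`, `beta = 5`.
#'
#' @param vary which parameter differs across conditions, `"alpha"` or
#'   `"beta"`.
#' @param n_subjects cohort size.
#' @param conditions condition labels (one per dose).
#' @param values per-condition values of the varying parameter.
#' @param fixed named vector of values for the non-varying parameters.
#' @param config a [task_config()] (default: 4 sessions of 12 blocks, i.e.
#'   48 blocks per subject x condition).
#' @param seed master integer seed for the subject-level jitter.
#' @return object of class `recovery_design` containing the per-subject x
#'   condition true-parameter table.
#' @export
recovery_design <- function(vary = c("alpha", "beta"),
                            n_subjects = 23,
                            conditions = c("d0", "d1", "d2", "d3"),
                            values = NULL,
                            fixed = c(alpha = 0.3, alpha2 = 0.5, beta = 5),
                            config = task_config(),
                            seed = 1) {
  vary <- match.arg(vary)
  if (is.null(values))
    values <- switch(vary,
                     alpha = c(0.20, 0.28, 0.38, 0.50),
                     beta  = c(8, 5, 3, 2))
  if (length(values) != length(conditions))
    stop("'values' must give one value per condition", call. = FALSE)

  truth <- with_seed_(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      jit_rate <- rnorm(2, 0, 0.03)   # alpha, alpha2 offsets
      jit_beta <- exp(rnorm(1, 0, 0.15))
      for (ci in seq_along(conditions)) {
        p <- fixed
        p[vary] <- values[ci]
        p[["alpha"]]  <- min(max(p[["alpha"]] + jit_rate[1], 0.02), 0.98)
        p[["alpha2"]] <- min(max(p[["alpha2"]] + jit_rate[2], 0.02), 0.98)
        p[["beta"]]   <- p[["beta"]] * jit_beta
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("s%02d", s), condition = conditions[ci],
          alpha = p[["alpha"]], alpha2 = p[["alpha2"]], beta = p[["beta"]],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  structure(list(vary = vary, conditions = conditions, values = values,
                 fixed = fixed, config = config, seed = seed,
                 truth = truth),
            class = "recovery_design")
}

#' @export
print.recovery_design <- function(x, ...) {
  cat(sprintf("<recovery_design> %s varies over %s: %s\n", x$vary,
              paste(x$conditions, collapse = "/"),
              paste(x$values, collapse = ", ")))
  invisible(x)
}

#' Run a parameter-recovery experiment
#'
#' Simulates the cohort specified by the design, refits the forgetting
#' Q-learning model with all three parameters free to every subject x
#' condition history, and tests each fitted parameter for a condition
#' effect with a Friedman rank test. A successful recovery flags only the
#' parameter that truly varied as significant (p < 0.05).
#'
#' @param design a [recovery_design()].
#' @param seed master integer seed for the simulated cohort.
#' @return object of class `recovery_result`: `friedman` (per-parameter
#'   test results), `significant` (parameter names with p < 0.05), the
#'   `fits`, and the design.
#' @export
recovery_experiment <- function(design, seed = 1) {
  stopifnot(inherits(design, "recovery_design"))
  trials <- simulate_cohort(design$truth, design$config, seed = seed)
  fits <- fit_population("fql", trials)
  fr <- lapply(c(alpha = "alpha", alpha2 = "alpha2", beta = "beta"),
               function(p) friedman_test(params_matrix(fits, p)))
  sig <- names(fr)[vapply(fr, function(x) x$p_value < 0.05, logical(1))]
  structure(list(friedman = fr, significant = sig, fits = fits,
                 design = design),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> varying parameter: %s\n", x$design$vary))
  for (p in names(x$friedman))
    cat(sprintf("  %-7s chi2(%d) = %6.2f   p = %.4g%s\n", p,
                x$friedman[[p]]$df, x$friedman[[p]]$statistic,
                x$friedman[[p]]$p_value,
                if (x$friedman[[p]]$p_value < 0.05) "  *" else ""))
  invisible(x)
}
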