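# Shared fixtures and an independent likelihood oracle.

# Random single-sequence history (choices and rewards only).
rand_history <- function(n_trials = 10, seed = 1, n_levers = 3) {
  set.seed(seed)
  data.frame(subject = "s1", condition = "c1",
             action = sample(0:(n_levers - 1), n_trials, replace = TRUE),
             reward = rbinom(n_trials, 1, 0.5),
             stringsAsFactors = FALSE)
}

# Hand-assembled trial log with full task annotation, for the behavioral
# indices. `block` is a vector of block ids parallel to `action`.
make_trials <- function(action, reward, target, block, risk = "low",
                        subject = "s1", condition = "c1") {
  n <- length(action)
  stopifnot(length(reward) == n, length(target) == n, length(block) == n)
  data.frame(subject = subject, condition = condition, session = 1L,
             block = block,
             trial_in_block = stats::ave(seq_len(n), block, FUN = seq_along),
             action = action, reward = reward, target = target,
             risk = rep(risk, length.out = n), stringsAsFactors = FALSE)
}

# Independent per-trial likelihood oracle: a direct transcription of the
# model equations (prediction error, value update, forgetting, uncertainty
# bonus, meta inverse temperature), written without any package function so
# it cannot share a defect with the implementation it checks.
oracle_loglik <- function(family, par, action, reward, n_levers = 3) {
  Q <- rep(0, n_levers)
  v <- rep(0, n_levers)
  R <- 0
  beta_t <- if (family == "meta") par[["beta0"]] else NA
  ll <- 0
  for (t in seq_along(action)) {
    p <- switch(family,
      ql = exp(par[["beta"]] * Q) / sum(exp(par[["beta"]] * Q)),
      fql = exp(par[["beta"]] * Q) / sum(exp(par[["beta"]] * Q)),
      fql_egreedy = {
        eps <- par[["epsilon"]]
        mx <- Q == max(Q)
        pp <- rep(eps / (n_levers - 1), n_levers)
        pp[mx] <- (1 - sum(pp[!mx])) / sum(mx)
        pp
      },
      directed = {
        x <- par[["beta"]] * (Q + par[["phi"]] * v)
        exp(x) / sum(exp(x))
      },
      meta = exp(beta_t * Q) / sum(exp(beta_t * Q)))
    a <- action[t] + 1
    r <- reward[t]
    ll <- ll + log(p[a])
    d <- r - Q[a]
    Q[a] <- Q[a] + par[["alpha"]] * d
    if (family != "ql")
      for (j in seq_len(n_levers)) if (j != a) Q[j] <- (1 - par[["alpha2"]]) * Q[j]
    if (family == "directed" && r > 0)
      v[a] <- v[a] + par[["alpha_phi"]] * (d^2 - v[a])
    if (family == "meta") {
      R <- R + par[["alpha_r"]] * d
      beta_t <- max(0, par[["beta0"]] + (par[["beta1"]] - par[["beta0"]]) * R)
    }
  }
  ll
}

# One reference parameter set per family, used across tests.
example_params <- list(
  ql          = c(alpha = 0.4, beta = 3),
  fql         = c(alpha = 0.5, alpha2 = 0.1, beta = 2),
  fql_egreedy = c(alpha = 0.5, alpha2 = 0.3, epsilon = 0.2),
  directed    = c(alpha = 0.4, alpha2 = 0.2, beta = 2, alpha_phi = 0.3, phi = 0.7),
  meta        = c(alpha = 0.4, alpha2 = 0.2, alpha_r = 0.15, beta0 = 2, beta1 = 6))

# Minimal stand-in for a fitted result, letting prediction checks run with
# known (true) parameters.
make_fit <- function(family, params, subject = "s1", condition = "c1") {
  structure(list(spec = model_spec(family), family = family,
                 params = params, subject = subject, condition = condition),
            class = "fit_result")
}
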