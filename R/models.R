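#' @name models
#' @title Trial-by-trial learning models for the three-armed bandit task
#'
#' @description
#' Five agent models share a common interface: a latent state (action values
#' `Q`, plus model-specific components), an action-probability map, and a
#' per-trial state update driven by the chosen action and the obtained reward.
#'
#' * `ql` — standard Q-learning: the chosen action's value moves toward the
#'   reward by a fraction `alpha` of the reward prediction error; action
#'   selection is softmax with inverse temperature `beta`.
#' * `fql` — forgetting Q-learning: additionally, the values of the
#'   non-chosen actions decay multiplicatively toward 0 at rate `alpha2`
#'   every trial.
#' * `fql_egreedy` — forgetting Q-learning with epsilon-greedy selection:
#'   the highest-valued action is chosen with probability `1 - epsilon`, the
#'   others with probability `epsilon/2` each.
#' * `directed` — uncertainty-bonus model: each action also carries an
#'   expected uncertainty `v` learned from squared reward prediction errors
#'   (learning rate `alpha_phi`); the softmax operates on
#'   `beta * (Q + phi * v)` so positive `phi` biases choice toward uncertain
#'   options (directed exploration).
#' * `meta` — meta-learning model: the inverse temperature is itself dynamic,
#'   a linear function `beta0 + (beta1 - beta0) * R` of an accumulator `R` of
#'   past reward prediction errors (rate `alpha_r`), clamped at 0.
#'
#' Levers are identified by 0-based ids (`0 .. n_levers - 1`), matching the
#' on-disk trial-log format; state vectors index lever `i` at position
#' `i + 1`.
#'
#' @param family model family name.
#' @param update_on_loss for `directed` only: if `FALSE` (default) the
#'   uncertainty of the chosen action is updated only on rewarded trials; if
#'   `TRUE`, on every trial.
#' @return `model_spec()` returns an object of class `model_spec` with the
#'   family name, parameter names, and parameter bounds.
#' @examples
#' spec <- model_spec("fql")
#' spec$params
#' @export
model_spec <- function(family = c("ql", "fql", "fql_egreedy", "directed", "meta"),
                       update_on_loss = FALSE) {
  family <- match.arg(family)
  params <- switch(family,
    ql          = c("alpha", "beta"),
    fql         = c("alpha", "alpha2", "beta"),
    fql_egreedy = c("alpha", "alpha2", "epsilon"),
    directed    = c("alpha", "alpha2", "beta", "alpha_phi", "phi"),
    meta        = c("alpha", "alpha2", "alpha_r", "beta0", "beta1"))
  structure(
    list(family = family,
         params = params,
         lower = vapply(params, param_lower_1, numeric(1)),
         upper = vapply(params, param_upper_1, numeric(1)),
         update_on_loss = isTRUE(update_on_loss),
         code = match(family, c("ql", "fql", "fql_egreedy", "directed", "meta"))),
    class = "model_spec")
}

# natural bounds per parameter: learning/forgetting/exploration rates live in
# [0,1]; inverse temperatures are non-negative (generous fitting cap at 1e3
# because fitted beta distributions are heavy-tailed); phi is a free real.
param_lower_1 <- function(p) if (p == "phi") -Inf else 0
param_upper_1 <- function(p) {
  if (p %in% c("beta", "beta0", "beta1")) 1000 else if (p == "phi") Inf else 1
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, "\n  parameters:",
      paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) x else model_spec(x)
}

validate_params <- function(spec, params) {
  spec <- as_model_spec(spec)
  miss <- setdiff(spec$params, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  v <- unlist(params[spec$params])
  out <- is.na(v) | v < spec$lower - 1e-12 | v > spec$upper + 1e-12
  if (any(out))
    stop("parameter(s) out of bounds: ",
         paste(spec$params[out], collapse = ", "), call. = FALSE)
  setNames(as.numeric(v), spec$params)
}

#' Initial latent state of a model
#'
#' Q-values (and, where applicable, expected uncertainties `v` and the
#' prediction-error accumulator `R`) start at 0; the meta-learning model's
#' inverse temperature starts at `beta0`.
#'
#' @param spec a `model_spec` (or family name).
#' @param params named parameter vector/list (needed by `meta` for `beta0`).
#' @param n_levers number of levers.
#' @return list with components `Q` (and `v`, `R`, `beta` as applicable).
#' @export
init_state <- function(spec, params = NULL, n_levers = 3) {
  spec <- as_model_spec(spec)
  st <- list(Q = numeric(n_levers))
  if (spec$family == "directed") st$v <- numeric(n_levers)
  if (spec$family == "meta") {
    st$R <- 0
    st$beta <- as.numeric(params[["beta0"]])
  }
  st
}

# ---- elementary update / policy operations ---------------------------------

#' Reward prediction error
#'
#' `delta = reward - Q[action]`: the discrepancy between the obtained reward
#' and the current value estimate of the chosen action.
#'
#' @param q numeric vector of action values.
#' @param action 0-based lever id.
#' @param reward obtained reward.
#' @return the prediction error (scalar).
#' @export
rpe <- function(q, action, reward) {
  reward - q[action + 1L]
}

#' Q-learning value update
#'
#' Moves the chosen action's value by `alpha * delta`; other values are left
#' untouched (forgetting is a separate operation, [forget_update()]).
#'
#' @inheritParams rpe
#' @param delta reward prediction error.
#' @param alpha learning rate in \[0, 1\].
#' @return updated value vector.
#' @export
q_update <- function(q, action, delta, alpha) {
  q[action + 1L] <- q[action + 1L] + alpha * delta
  q
}

#' Forgetting update of non-chosen action values
#'
#' Values of all actions except the chosen one decay toward 0:
#' `Q(a) <- (1 - alpha2) * Q(a)` for `a != action`.
#'
#' @inheritParams rpe
#' @param alpha2 forgetting rate in \[0, 1\].
#' @return updated value vector.
#' @export
forget_update <- function(q, action, alpha2) {
  keep <- q[action + 1L]
  q <- (1 - alpha2) * q
  q[action + 1L] <- keep
  q
}

#' Softmax choice probabilities
#'
#' `p(a) ∝ exp(beta * Q(a))`, computed with max-subtraction for overflow
#' safety. `beta = 0` gives the uniform distribution; large `beta`
#' concentrates mass on the highest-valued action.
#'
#' @param q numeric vector of action values.
#' @param beta inverse temperature, `>= 0`.
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(q, beta) {
  x <- beta * q
  e <- exp(x - max(x))
  e / sum(e)
}

#' Epsilon-greedy choice probabilities
#'
#' With a unique maximum, the greedy action gets `1 - epsilon` and each other
#' action `epsilon / (n - 1)`. Under ties the non-maximal actions keep
#' `epsilon / (n - 1)` each and the tied maxima share the remaining mass
#' equally, so all-equal values give the uniform distribution.
#'
#' @param q numeric vector of action values.
#' @param epsilon exploration probability in \[0, 1\].
#' @return probability vector summing to 1.
#' @export
egreedy_probs <- function(q, epsilon) {
  n <- length(q)
  is_max <- q >= max(q) - 1e-12
  m <- sum(is_max)
  p_other <- epsilon / (n - 1)
  p <- rep(p_other, n)
  p[is_max] <- (1 - (n - m) * p_other) / m
  p
}

#' Uncertainty update (directed-exploration model)
#'
#' The uncertainty prediction error is `xi = delta^2 - v[action]`; the chosen
#' action's expected uncertainty moves by `alpha_phi * xi`, the others stay.
#'
#' @param v numeric vector of expected uncertainties.
#' @param action 0-based lever id.
#' @param delta reward prediction error of the trial.
#' @param alpha_phi uncertainty learning rate in \[0, 1\].
#' @return updated uncertainty vector.
#' @export
uncertainty_update <- function(v, action, delta, alpha_phi) {
  v[action + 1L] <- v[action + 1L] + alpha_phi * (delta^2 - v[action + 1L])
  v
}

#' Directed-exploration choice probabilities
#'
#' Softmax over `beta * (Q + phi * v)`: positive `phi` biases choice toward
#' actions with uncertain outcomes.
#'
#' @inheritParams softmax_probs
#' @param v expected-uncertainty vector.
#' @param phi uncertainty weight (any real).
#' @return probability vector summing to 1.
#' @export
directed_probs <- function(q, v, beta, phi) {
  softmax_probs(q + phi * v, beta)
}

#' Meta-learning update of the inverse temperature
#'
#' Accumulates reward prediction errors, `R <- R + alpha_r * delta`, and sets
#' the next trial's inverse temperature to the linear interpolation
#' `beta0 + (beta1 - beta0) * R`, clamped at 0 (a negative inverse
#' temperature would invert preferences).
#'
#' @param R current accumulator value.
#' @param delta reward prediction error of the trial.
#' @param alpha_r accumulation rate in \[0, 1\].
#' @param beta0 inverse temperature when `R = 0`.
#' @param beta1 inverse temperature when `R = 1`.
#' @return list with updated `R` and `beta`.
#' @export
meta_update <- function(R, delta, alpha_r, beta0, beta1) {
  R <- R + alpha_r * delta
  list(R = R, beta = max(0, beta0 + (beta1 - beta0) * R))
}

# ---- model interface -------------------------------------------------------

#' Action probabilities of a model in a given state
#'
#' @param spec a `model_spec` (or family name).
#' @param state latent state as returned by [init_state()] / [model_step()].
#' @param params named parameter vector/list.
#' @return probability vector over levers (position `i + 1` = lever `i`).
#' @export
action_probs <- function(spec, state, params) {
  spec <- as_model_spec(spec)
  switch(spec$family,
    ql          = softmax_probs(state$Q, params[["beta"]]),
    fql         = softmax_probs(state$Q, params[["beta"]]),
    fql_egreedy = egreedy_probs(state$Q, params[["epsilon"]]),
    directed    = directed_probs(state$Q, state$v, params[["beta"]],
                                 params[["phi"]]),
    meta        = softmax_probs(state$Q, state$beta))
}

#' One learning step of a model
#'
#' Applies, in order: reward prediction error, Q-value update of the chosen
#' action, forgetting of the other actions (families with `alpha2`),
#' uncertainty update (`directed`; by default only when the trial was
#' rewarded), and the inverse-temperature update (`meta`).
#'
#' @inheritParams action_probs
#' @param action 0-based lever id chosen on the trial.
#' @param reward obtained reward.
#' @return the updated latent state.
#' @examples
#' spec <- model_spec("fql")
#' p <- c(alpha = 0.5, alpha2 = 0.1, beta = 2)
#' st <- init_state(spec, p)
#' model_step(spec, st, action = 0, reward = 1, params = p)$Q
#' @export
model_step <- function(spec, state, action, reward, params) {
  spec <- as_model_spec(spec)
  delta <- rpe(state$Q, action, reward)
  state$Q <- q_update(state$Q, action, delta, params[["alpha"]])
  if (spec$family != "ql")
    state$Q <- forget_update(state$Q, action, params[["alpha2"]])
  if (spec$family == "directed" && (reward > 0 || spec$update_on_loss))
    state$v <- uncertainty_update(state$v, action, delta, params[["alpha_phi"]])
  if (spec$family == "meta") {
    up <- meta_update(state$R, delta, params[["alpha_r"]],
                      params[["beta0"]], params[["beta1"]])
    state$R <- up$R
    state$beta <- up$beta
  }
  state
}
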