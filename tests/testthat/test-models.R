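test_that("prediction error and value updates match closed forms", {
  expect_equal(rpe(c(0, 0, 0), 0, 1), 1)
  expect_equal(rpe(c(1, 0, 0), 0, 1), 0)
  expect_equal(rpe(c(0.5, 0, 0), 0, 0), -0.5)

  expect_equal(q_update(c(0, 0, 0), 0, 1, 0.5), c(0.5, 0, 0))
  expect_equal(q_update(c(0.3, 0.2, 0), 1, -0.2, 0), c(0.3, 0.2, 0))

  # repeated rewarded choices approach 1 as Q_n = 1 - (1 - alpha)^n
  q <- c(0, 0, 0)
  alpha <- 0.3
  for (n in 1:20) {
    q <- q_update(q, 0, rpe(q, 0, 1), alpha)
    expect_equal(q[1], 1 - (1 - alpha)^n)
  }

  expect_equal(forget_update(c(0, 0.8, 0), 0, 0.25), c(0, 0.6, 0))
  expect_equal(forget_update(c(0.4, 0.8, 0.1), 0, 0), c(0.4, 0.8, 0.1))
  # a never-chosen lever decays geometrically: Q0 * (1 - alpha2)^n
  q <- c(0, 0.9, 0)
  for (n in 1:15) {
    q <- forget_update(q, 0, 0.2)
    expect_equal(q[2], 0.9 * 0.8^n)
  }
})

test_that("choice-probability maps match hand-computed values and limits", {
  expect_equal(softmax_probs(c(0.4, 0.4, 0.4), 5), rep(1 / 3, 3))
  e <- exp(1)
  expect_equal(softmax_probs(c(1, 0, 0), 1),
               c(e, 1, 1) / (e + 2), tolerance = 1e-12)
  expect_equal(softmax_probs(c(1, 0.2, -3), 0), rep(1 / 3, 3))

  expect_equal(egreedy_probs(c(1, 0, 0), 0.3), c(0.7, 0.15, 0.15))
  expect_equal(egreedy_probs(c(1, 0, 0), 1), c(0, 0.5, 0.5))
  expect_equal(egreedy_probs(c(0.2, 0.2, 0.2), 0.4), rep(1 / 3, 3))

  expect_equal(uncertainty_update(c(0, 0, 0), 0, 1, 0.5), c(0.5, 0, 0))
  expect_equal(uncertainty_update(c(0.25, 0, 0), 0, 0.5, 0.9), c(0.25, 0, 0))
  # constant squared-error stream: v approaches delta^2 geometrically
  v <- c(0, 0, 0)
  for (n in 1:12) {
    v <- uncertainty_update(v, 1, 0.8, 0.25)
    expect_equal(v[2], 0.64 * (1 - 0.75^n))
  }

  expect_equal(directed_probs(c(1, 0, 0), c(0, 0, 0), 2, 0),
               softmax_probs(c(1, 0, 0), 2))
  # equal exponents for levers 0 and 1: beta*(Q + phi*v) = (1, 1, 0)
  p <- directed_probs(c(1, 0, 0), c(0, 1, 0), 1, 1)
  expect_equal(p[1], p[2])
  expect_lt(p[3], p[1])
  expect_equal(p, c(e <- exp(1), e, 1) / (2 * e + 1), tolerance = 1e-12)
  # uncertainty bonus attracts choice when values are flat
  p <- directed_probs(c(0.5, 0.5, 0.5), c(1, 0, 0), 2, 0.8)
  expect_equal(which.max(p), 1L)

  up <- meta_update(0, 1, 0.2, beta0 = 2, beta1 = 6)
  expect_equal(up$R, 0.2)
  expect_equal(up$beta, 2 + 0.2 * 4)
  expect_equal(meta_update(1, 0, 0.5, 2, 6)$beta, 6)
  expect_equal(meta_update(0, 0, 0.5, 2, 6)$beta, 2)
  # clamped at zero rather than inverting preferences
  expect_equal(meta_update(-2, 0, 0.5, 1, 5)$beta, 0)
})

test_that("probability maps return valid distributions for every family", {
  set.seed(42)
  for (fam in c("ql", "fql", "fql_egreedy", "directed", "meta")) {
    spec <- model_spec(fam)
    params <- example_params[[fam]]
    for (i in 1:50) {
      st <- init_state(spec, params)
      st$Q <- runif(3)
      if (fam == "directed") st$v <- runif(3)
      if (fam == "meta") st$beta <- runif(1, 0, 10)
      p <- action_probs(spec, st, params)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("model_step composes the updates in the documented order", {
  spec <- model_spec("fql")
  p <- c(alpha = 0.5, alpha2 = 0.1, beta = 2)
  st <- init_state(spec, p)
  st <- model_step(spec, st, 0, 1, p)
  expect_equal(st$Q, c(0.5, 0, 0))

  st$Q <- c(0.5, 0.4, 0)
  p2 <- c(alpha = 0.5, alpha2 = 0.5, beta = 2)
  st <- model_step(spec, st, 0, 0, p2)
  expect_equal(st$Q, c(0.25, 0.2, 0))

  # directed model: uncertainty is updated only on rewarded trials by default
  dspec <- model_spec("directed")
  dp <- example_params$directed
  st <- init_state(dspec, dp)
  st <- model_step(dspec, st, 0, 0, dp)   # unrewarded: v untouched
  expect_equal(st$v, c(0, 0, 0))
  st <- model_step(dspec, st, 0, 1, dp)   # rewarded: v moves
  expect_gt(st$v[1], 0)
  dspec2 <- model_spec("directed", update_on_loss = TRUE)
  st2 <- init_state(dspec2, dp)
  st2$Q <- c(0.5, 0, 0)          # nonzero value so the loss carries a RPE
  st2 <- model_step(dspec2, st2, 0, 0, dp)
  expect_gt(st2$v[1], 0)
})

test_that("model nesting yields identical per-trial probabilities", {
  h <- rand_history(40, seed = 7)
  fql <- c(alpha = 0.45, alpha2 = 0.3, beta = 4)
  # standard Q-learning = forgetting model with alpha2 = 0
  expect_equal(
    predicted_probs("ql", c(alpha = 0.45, beta = 4), h),
    predicted_probs("fql", c(alpha = 0.45, alpha2 = 0, beta = 4), h),
    tolerance = 1e-14)
  # forgetting model = directed model with phi = 0 (any alpha_phi)
  expect_equal(
    predicted_probs("fql", fql, h),
    predicted_probs("directed",
                    c(fql, alpha_phi = 0.6, phi = 0), h),
    tolerance = 1e-14)
  # forgetting model = meta model with beta0 = beta1 = beta
  expect_equal(
    predicted_probs("fql", fql, h),
    predicted_probs("meta",
                    c(alpha = 0.45, alpha2 = 0.3, alpha_r = 0.2,
                      beta0 = 4, beta1 = 4), h),
    tolerance = 1e-14)
})

test_that("Q-values stay in [0,1] for binary rewards and the softmax is scale invariant", {
  set.seed(11)
  for (i in 1:30) {
    fam <- sample(c("ql", "fql", "fql_egreedy", "directed", "meta"), 1)
    spec <- model_spec(fam)
    params <- example_params[[fam]]
    st <- init_state(spec, params)
    for (t in 1:60) {
      a <- sample(0:2, 1)
      r <- rbinom(1, 1, 0.5)
      st <- model_step(spec, st, a, r, params)
      expect_true(all(st$Q >= 0 & st$Q <= 1))
      if (fam == "directed") expect_true(all(st$v >= 0 & st$v <= 1))
    }
  }
  # multiplying Q by kappa and beta by 1/kappa leaves the softmax unchanged
  set.seed(12)
  for (i in 1:20) {
    q <- runif(3); beta <- runif(1, 0, 20); kappa <- runif(1, 0.05, 1)
    expect_equal(softmax_probs(kappa * q, beta / kappa),
                 softmax_probs(q, beta), tolerance = 1e-12)
  }
})

test_that("out-of-bounds or missing parameters are rejected", {
  h <- rand_history(5)
  expect_error(log_likelihood("fql", c(alpha = 1.2, alpha2 = 0.1, beta = 2), h),
               "out of bounds")
  expect_error(log_likelihood("fql", c(alpha = 0.5, beta = 2), h), "missing")
  expect_error(log_likelihood("fql", c(alpha = 0.5, alpha2 = 0.1, beta = -1), h),
               "out of bounds")
})
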