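test_that("log-likelihood matches an independent per-trial recomputation", {
  # symmetric limits
  h1 <- rand_history(1, seed = 1)
  expect_equal(log_likelihood("fql", c(alpha = .5, alpha2 = .1, beta = 2), h1),
               log(1 / 3))
  hT <- rand_history(25, seed = 2)
  expect_equal(log_likelihood("fql", c(alpha = .5, alpha2 = .1, beta = 0), hT),
               25 * log(1 / 3))

  # hand-size histories, all five families, against the oracle transcription
  for (fam in c("ql", "fql", "fql_egreedy", "directed", "meta")) {
    for (seed in 1:5) {
      h <- rand_history(10, seed = 100 + seed)
      p <- example_params[[fam]]
      expect_equal(log_likelihood(fam, p, h),
                   oracle_loglik(fam, p, h$action, h$reward),
                   tolerance = 1e-10)
    }
  }

  # a fixed 5-trial forgetting-model history, likewise
  h5 <- data.frame(subject = "s", condition = "c",
                   action = c(0, 0, 1, 2, 0), reward = c(1, 0, 1, 0, 1))
  p5 <- c(alpha = 0.5, alpha2 = 0.1, beta = 2)
  expect_equal(log_likelihood("fql", p5, h5),
               oracle_loglik("fql", p5, h5$action, h5$reward),
               tolerance = 1e-10)
})

test_that("compiled and reference likelihood engines agree", {
  for (fam in c("ql", "fql", "fql_egreedy", "directed", "meta")) {
    h <- rand_history(200, seed = match(fam, c("ql", "fql", "fql_egreedy",
                                               "directed", "meta")))
    p <- example_params[[fam]]
    expect_equal(log_likelihood(fam, p, h, engine = "cpp"),
                 log_likelihood(fam, p, h, engine = "r"),
                 tolerance = 1e-12)
  }
  # update_on_loss variant too
  spec <- model_spec("directed", update_on_loss = TRUE)
  h <- rand_history(100, seed = 9)
  expect_equal(log_likelihood(spec, example_params$directed, h, engine = "cpp"),
               log_likelihood(spec, example_params$directed, h, engine = "r"),
               tolerance = 1e-12)
})

test_that("fit_subject recovers generating parameters and is a fixed point", {
  cfg <- task_config(n_sessions = 2)   # 24 blocks, 576 trials
  truth <- c(alpha = 0.35, alpha2 = 0.5, beta = 5)
  h <- run_agent("fql", truth, build_schedule(cfg, 31), cfg, seed = 32)
  fit <- fit_subject("fql", h)
  expect_lt(abs(fit$params[["alpha"]] - truth[["alpha"]]), 0.12)
  expect_lt(abs(fit$params[["alpha2"]] - truth[["alpha2"]]), 0.20)
  expect_lt(abs(log(fit$params[["beta"]] / truth[["beta"]])), log(1.6))
  expect_true(all(fit$per_trial_p > 0 & fit$per_trial_p <= 1))
  expect_lte(fit$log_lik, 0)

  # generating parameters cannot beat the MLE
  expect_gte(fit$log_lik, log_likelihood("fql", truth, h) - 1e-6)

  # restarting from the optimum brings no further improvement
  refit <- fit_subject("fql", h, start_grid = as.data.frame(t(fit$params)))
  expect_lt(abs(refit$log_lik - fit$log_lik), 1e-4)

  # on data without forgetting, the forgetting rate is estimated near 0
  hq <- run_agent("ql", c(alpha = 0.35, beta = 5),
                  build_schedule(cfg, 33), cfg, seed = 34)
  fq <- fit_subject("fql", hq)
  expect_lt(fq$params[["alpha2"]], 0.1)
})

test_that("information criteria follow their definitions and comparisons sum them", {
  h <- rand_history(120, seed = 41)
  f <- fit_subject("ql", h)
  expect_equal(f$aic, 2 * 2 - 2 * f$log_lik)
  expect_equal(f$bic, 2 * log(120) - 2 * f$log_lik)

  cfg <- task_config(n_sessions = 1)
  truth <- data.frame(subject = c("r1", "r2", "r3"), condition = "c0",
                      alpha = 0.35, alpha2 = 0.45, beta = 5,
                      stringsAsFactors = FALSE)
  trials <- simulate_cohort(truth, cfg, seed = 42)
  fits_ql <- fit_population("ql", trials)
  fits_fql <- fit_population("fql", trials)

  same <- compare_models(fits_ql, fits_ql)
  expect_true(all(same$per_fit$d_aic == 0))
  expect_true(all(same$per_fit$d_log_lik == 0))

  cmp <- compare_models(fits_ql, fits_fql)
  expect_equal(cmp$totals$aic[1],
               sum(vapply(unclass(fits_ql), `[[`, 0, "aic")))
  # forgetting was in the generator: the forgetting model must win
  expect_lt(cmp$totals$aic[2], cmp$totals$aic[1])
  expect_lt(cmp$totals$bic[2], cmp$totals$bic[1])

  # mismatched populations are refused
  expect_error(compare_models(fits_ql, structure(unclass(fits_fql)[1:2],
                                                 class = "fit_population")),
               "different subject")
})

test_that("likelihood-ratio test matches the chi-squared reference", {
  expect_equal(lrt_nested(-100, -100)$p_value, 1)
  expect_equal(lrt_nested(-100, -100)$d, 0)
  # the 95% quantile of chi-squared(1) maps back to p = 0.05
  d05 <- qchisq(0.95, df = 1)
  expect_equal(lrt_nested(-100, -100 + d05 / 2)$p_value, 0.05,
               tolerance = 1e-12)
  expect_equal(lrt_nested(-100, -95, df = 2)$p_value,
               pchisq(10, 2, lower.tail = FALSE))
  expect_warning(res <- lrt_nested(-100, -100.5), "clamped")
  expect_equal(res$d, 0)
})

test_that("constrained predictions track observed choice frequencies", {
  cfg <- task_config(n_sessions = 2)
  truth <- c(alpha = 0.35, alpha2 = 0.5, beta = 5)
  trials <- do.call(rbind, lapply(1:4, function(i)
    run_agent("fql", truth, build_schedule(cfg, 50 + i), cfg, seed = 60 + i,
              subject = paste0("s", i))))
  fits <- structure(lapply(1:4, function(i)
    make_fit("fql", truth, subject = paste0("s", i))),
    class = "fit_population")

  chk <- constrained_prediction_check(fits, trials)
  expect_false(chk$degenerate)
  expect_lt(abs(chk$b1 - 1), 0.1)
  expect_gt(chk$adj_r2, 0.7)

  # the relearning window alone still shows the linear relationship
  chk26 <- constrained_prediction_check(fits, trials, trial_range = 2:6)
  expect_lt(abs(chk26$b1 - 1), 0.2)

  # permutation control: decoupling predictions from observations across
  # cells destroys the explained variance
  cells <- chk$data
  set.seed(71)
  cells$predicted <- sample(cells$predicted)
  r2_perm <- summary(lm(observed ~ 0 + predicted, data = cells))$adj.r.squared
  expect_lt(r2_perm, chk$adj_r2 - 0.2)

  # flat predictions (beta = 0) are flagged as degenerate
  fits0 <- structure(lapply(1:4, function(i)
    make_fit("fql", c(alpha = 0.35, alpha2 = 0.5, beta = 0),
             subject = paste0("s", i))), class = "fit_population")
  expect_warning(chk0 <- constrained_prediction_check(fits0, trials),
                 "degenerate")
  expect_true(chk0$degenerate)
})

test_that("unconstrained simulations from fits are reproducible", {
  fits <- structure(list(make_fit("fql", c(alpha = .4, alpha2 = .5, beta = 5))),
                    class = "fit_population")
  cfg <- task_config(n_sessions = 1)
  s1 <- simulate_fitted(fits, cfg, n_reps = 2, seed = 5)
  s2 <- simulate_fitted(fits, cfg, n_reps = 2, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1$rep)), 1:2)
  expect_equal(nrow(s1), 2 * 288)
  # replicates differ from one another
  expect_false(identical(s1$action[s1$rep == 1], s1$action[s1$rep == 2]))
})
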