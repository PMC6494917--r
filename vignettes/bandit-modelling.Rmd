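---
title: "Modelling exploration and exploitation in a non-stationary three-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exploration and exploitation in a non-stationary three-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditfit)
```

## The task and what the package computes

`banditfit` analyses trial-by-trial choice behavior in non-stationary
multi-armed bandit tasks of the kind used to dissociate *learning* from
*exploration* in rodents. A subject faces three levers; in every unsignaled
24-trial block one lever (the target) is rewarded with high probability and
the other two with a low probability. Under low risk the probabilities are
7/8 vs 1/16, under high risk 5/8 vs 3/16, which makes the target much harder
to discriminate. The target changes on every block, so the subject must
periodically abandon a previously good option and re-explore. Within each
session all six (target, risk) combinations appear equally often (twice in
the default 12-block sessions), ordered pseudo-randomly under the constraint
that consecutive blocks never share a target.

The package provides, as one pipeline:

1. a task generator (`task_config()`, `build_schedule()`, `run_agent()`,
   `simulate_cohort()`) producing tidy trial logs;
2. five learning models fitted by maximum likelihood per subject and
   condition (`fit_subject()`, `fit_population()`);
3. model comparison by population AIC/BIC and nested likelihood-ratio tests
   (`compare_models()`, `lrt_nested()`), plus a constrained-prediction
   regression (`constrained_prediction_check()`) and generative replication
   (`simulate_fitted()`);
4. behavioral exploration indices and their within-block curves
   (`behavior_indices()`, `block_curves()`, `asymptote_indices()`);
5. two methodological validations: the reward-scaling equivalence theorem
   (`equivalence_check()`) and parameter-recovery experiments
   (`recovery_design()`, `recovery_experiment()`).

## The models

All models maintain an action value \(Q(a)\) per lever, initialized at 0.
After choosing \(a_t\) and observing the binary reward \(r_t\):

\[\delta_t = r_t - Q_t(a_t), \qquad Q_{t+1}(a_t) = Q_t(a_t) + \alpha\,\delta_t\]

with learning rate \(\alpha \in [0,1]\). The *forgetting* variants
additionally decay the non-chosen values toward 0,

\[Q_{t+1}(a \neq a_t) = (1 - \alpha_2)\, Q_t(a \neq a_t),\]

a perseverance mechanism: what is not chosen is gradually forgotten, so a
subject can stay on a lever even through unrewarded trials. Action selection
is softmax,

\[P(a_{t+1} = a_i) = \frac{e^{\beta Q_t(a_i)}}{\sum_j e^{\beta Q_t(a_j)}},\]

where the inverse temperature \(\beta \ge 0\) sets the level of *random
(undirected) exploration*: \(\beta = 0\) is uniform choice, large \(\beta\)
is strict exploitation.

The five families are:

| family | free parameters | selection rule |
|---|---|---|
| `ql` | \(\alpha, \beta\) | softmax |
| `fql` | \(\alpha, \alpha_2, \beta\) | softmax |
| `fql_egreedy` | \(\alpha, \alpha_2, \varepsilon\) | best lever w.p. \(1-\varepsilon\), others \(\varepsilon/2\) |
| `directed` | \(\alpha, \alpha_2, \beta, \alpha^{\varphi}, \varphi\) | softmax over \(\beta(Q + \varphi\,\upsilon)\) |
| `meta` | \(\alpha, \alpha_2, \alpha^R, \beta_0, \beta_1\) | softmax with \(\beta_t\) |

The `directed` model tracks an expected uncertainty \(\upsilon(a)\) from
squared prediction errors, \(\xi_t = \delta_t^2 - \upsilon(a_t)\),
\(\upsilon(a_t) \mathrel{+}= \alpha^{\varphi} \xi_t\); \(\varphi > 0\) biases
choice toward uncertain options (directed exploration). The `meta` model
makes \(\beta\) dynamic through an accumulator of past prediction errors,
\(R_t = R_{t-1} + \alpha^R \delta_t\) and
\(\beta_{t+1} = \beta_0 + (\beta_1 - \beta_0) R_t\) — a stand-in for tonic
dopamine tracking recent success.

### Decisions the equations do not fix

* **Epsilon-greedy ties.** The stated rule assumes a unique maximum. We let
  non-maximal levers keep \(\varepsilon/(n-1)\) each and the tied maxima
  share the remaining mass equally, so an all-tied state (e.g. the first
  trial) yields the uniform distribution.
* **Uncertainty update trigger.** The `directed` model's uncertainty is
  updated only on *rewarded* choices of a lever by default, reading the rule
  literally; losses also carry information through \(\delta^2\), so a
  `model_spec("directed", update_on_loss = TRUE)` switch updates on every
  chosen trial instead. Both paths are tested.
* **Dynamic \(\beta\) timing.** In `meta`, the choice on trial \(t\) uses
  \(\beta_t\); the update after trial \(t\) produces \(\beta_{t+1}\) used
  from the next trial on. \(R_0 = 0\), so the initial inverse temperature is
  \(\beta_0\). Since the linear map is unbounded below, \(\beta_t\) is
  clamped at 0 — a negative inverse temperature would invert preferences
  rather than merely flatten them.
* **\(\varphi\) bounds.** Unbounded real in principle; the optimizer searches
  \([-10, 10]\), generous relative to value magnitudes in \([0,1]\).

## Likelihood and fitting

The likelihood of a subject's history \(H\) under parameters \(\Theta\) is
the product over trials of the probability the model assigned to the choice
actually made, with the model replayed through the subject's own choices and
rewards (*constrained replay*) and latent state reset to zero at the start of
each subject-by-condition sequence. Numerically, per-trial probabilities are
floored at \(10^{-12}\) inside the log, and the softmax uses max-subtraction;
both are invisible at realistic parameters.

`fit_subject()` maximizes the log-likelihood with bounded L-BFGS-B from a
grid of \(3^k\) starting points (three per parameter: rates at 0.1/0.5/0.9,
inverse temperatures at 1/5/20, \(\varphi\) at −1/0/1), keeping the best
optimum. Inverse temperatures are searched on a log10 scale up to \(10^3\)
because their fitted distributions are heavy-tailed — occasional
near-deterministic subjects are expected and should not saturate a linear
search. Rates are boxed to \([10^{-3}, 1-10^{-3}]\); the compiled likelihood
clamps the finite-difference excursions just outside the box. The inner loop
is C++; an R path built from the exported step operations is retained and the
two are tested to agree to \(10^{-12}\), with a further independent
trial-by-trial transcription of the equations as oracle.

Model comparison sums AIC (\(2k - 2\ell\)) and BIC (\(k\ln n - 2\ell\))
over the population (lower wins) and applies the likelihood-ratio test
\(d = 2(\ell_2 - \ell_1) \sim \chi^2_{df}\) per subject for nested pairs.
Note one caveat the package deliberately does not hide: for the
`ql`-inside-`fql` pair the null value \(\alpha_2 = 0\) lies on the boundary
of its parameter space, so the \(\chi^2_1\) reference is conservative
(asymptotically the statistic is a 50:50 mixture of a point mass at 0 and
\(\chi^2_1\), giving a true false-positive rate near 2.5% at the nominal 5%);
the test is implemented exactly as stated because that is the field's
standard usage.

`constrained_prediction_check()` validates a fit the way the field expects:
observed choice frequencies are regressed through the origin on the model's
predicted probabilities. The equations do not fix an aggregation, so cells
are subject × condition × risk × within-block bin × lever role (the block's
target vs the others); the role distinction is what gives the cells their
spread — pooling by physical lever identity would wash every cell to 1/3 by
the counterbalancing. An optional restriction to trials 2–6 of each block
isolates the relearning phase right after a contingency switch.

## Behavioral indices

* **performance** — proportion of trials on the target lever;
* **win-shift** — of trials immediately following a *rewarded target* press,
  the proportion where the choice changed (the exploration index);
* **lose-shift** — of trials immediately following any unrewarded trial, the
  proportion where the choice changed (a correction/persistence index).

A shift is only counted within a block (the first trial of a block has no
predecessor — blocks are the analysis unit), and a group with no qualifying
trial yields `NA` rather than 0, mirroring the exclusion of subjects with no
win in a window. Within-block curves use six bins of four trials (24-trial
blocks are required for binning); asymptotes use the last six trials, or the
last eight for win-shift once the target has been identified. For uniform
random choice the closed forms are performance 1/3 and both shift indices
2/3 — the lose-shift ceiling that makes drug effects on lose-shift hard to
detect in practice.

Parameter-by-condition effects are tested with Friedman's rank ANOVA
(`friedman_test()`), appropriate because fitted \(\beta\) distributions are
heavy-tailed enough to violate normality; a fully tied design is reported as
statistic 0, p = 1.

## The equivalence theorem

With binary rewards, prediction-error-proportional updates, and
multiplicative forgetting, scaling every reward by \(\kappa\) scales the
*entire* Q trajectory by \(\kappa\): the chosen action's update is linear in
\((r, Q)\) and forgetting is linear in \(Q\). Plugged into the softmax,
\(\beta(\kappa Q) = (\kappa\beta) Q\) — a pharmacological down-scaling of
reward signals is *exactly* equivalent to lowering the inverse temperature,
i.e. to more random exploration, and touches neither \(\alpha\) nor
\(\alpha_2\). `equivalence_check()` replays a fixed history both ways and
reports the maximal per-trial probability and Q discrepancies (zero up to
floating-point accumulation; the tests require \(< 10^{-12}\)). Under
epsilon-greedy selection the equivalence is even stronger — the argmax is
invariant under positive scaling, so probabilities match without touching
\(\varepsilon\). The theorem's scope matters: if rewards could be negative
and only *positive* prediction errors were rescaled, proportionality would
fail — a property test documents this boundary.

## Parameter recovery

Because learning rate and inverse temperature trade off against each other in
finite data, the package ships the identifiability experiment as a function.
`recovery_design()` builds a synthetic cohort (default 23 subjects × 4
dose-like conditions × 48 blocks, matching a two-series test phase) in which
exactly one forgetting-model parameter varies across conditions: the learning
rate over 0.20/0.28/0.38/0.50, or the inverse temperature over 8/5/3/2 —
plausible dose profiles chosen once for this package, since the original
animal estimates are not publicly deposited. Per-subject individual
differences (additive sd 0.03 on rates, log-normal sdlog 0.15 on \(\beta\))
are drawn once per subject and held constant across conditions, so they model
heterogeneity without confounding the within-subject contrast.
`recovery_experiment()` simulates the cohort, refits all three parameters
freely, and Friedman-tests each fitted parameter across conditions: a sound
pipeline flags only the parameter that truly varied.

## What the synthetic cohorts do and do not emulate

The generator reproduces the task's reward statistics, counterbalancing, and
block structure, and cohorts driven by per-condition parameter sets reproduce
the qualitative signatures of the published curves: performance rising within
blocks to a risk-dependent asymptote, win-shift falling within blocks and
sitting higher under high risk, and — when only \(\beta\) decreases across
conditions — a whole-curve upward shift of win-shift with unchanged learning.
They do not emulate satiety or motivational drift within sessions, inter-trial
timing, magazine behavior, or any within-block adaptation of parameters
(parameters are constant within a run by construction). Passing tests
therefore validate the estimation machinery and the internal consistency of
the models, not any claim about a particular animal dataset.

## Problem sizes and runtime choices

Defaults were chosen so a full analysis runs comfortably on a laptop: fitting
one subject × condition (1152 trials, 27 starts) takes on the order of a
second thanks to the compiled likelihood. The shipped validation suite uses
23-subject recovery cohorts (as in the design above), a 23-subject cohort for
the model-comparison sanity check, 200 null replicates of 576 trials for the
likelihood-ratio calibration, and a 12-subject, 24-block-per-condition cohort
for the behavioral-curve signatures; reward-probability calibrations use at
least 10,000 draws per case. Unconstrained replication uses 100 runs per fit
in production (`simulate_fitted(n_reps = 100)`), and fewer in examples.

## A worked example

```{r, eval = FALSE}
cfg <- task_config(n_sessions = 2)
truth <- expand.grid(subject = sprintf("r%02d", 1:6),
                     condition = c("vehicle", "drug"),
                     stringsAsFactors = FALSE)
truth$alpha <- 0.35; truth$alpha2 <- 0.5
truth$beta <- ifelse(truth$condition == "vehicle", 7, 2.5)

trials <- simulate_cohort(truth, cfg, seed = 1)
fits <- fit_population("fql", trials)
compare_models(fit_population("ql", trials), fits)
friedman_test(params_matrix(fits, "beta"))
block_curves(trials)
```

## Known limitations

* The likelihood-ratio boundary issue above: the nested test is conservative
  for rate parameters whose null is 0.
* The constrained-prediction aggregation is one defensible choice among
  several; its `b1` and explained variance should be compared across analyses
  only under the same binning.
* Fits are independent per subject × condition (no hierarchical pooling);
  with short histories, \(\alpha_2\) and \(\beta\) estimates are noticeably
  noisier than \(\alpha\).
* The meta-learning model's \(\beta_t\) clamp at 0 is a modelling choice; an
  accumulator driven strongly negative parks the model at uniform choice.
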