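---
title: "Models and methods behind crowdtruth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crowdtruth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdtruth)
```

`crowdtruth` assesses the quality of crowd-generated labels for
public-health surveillance tasks and infers the latent true label of each
task. This vignette explains the generative model behind the synthetic
campaign simulator, the statistical models used for truth inference, the
supervised and active-learning layers, the attribution machinery, and the
numerical and design choices a maintainer should know about.

## The labeling campaign being modeled

The unit of work is a HIT: three short texts (tasks), each answered with one
of five choices, plus one easy qualification question used to catch
inattentive workers. Each task has a latent four-class label built from two
binary conditions — self-reported? recent? — written `11`, `10`, `01`, `00`;
workers may also answer `unclear`, which is excluded from inference. The
binary view dichotomizes to 1 iff both conditions hold (`11`). Each HIT is
answered by 3 workers, so each task collects 3 labels. Campaigns of this
shape show a very heavy-tailed worker-activity distribution (most workers
complete a handful of HITs, a few complete thousands) and contain a small
fraction of spammers (uniform answers) and occasionally adversarial workers
(systematically wrong answers).

## The simulator

`sim_config()` + `generate_workers()` / `generate_tasks()` /
`simulate_labeling()` draw a campaign with known ground truth. Key
parameters, defaults, and rationale:

- `class_prevalences` (default .38/.20/.03/.39 over `11/10/01/00`): mild
  imbalance with one rare class, matching what dichotomizable
  condition-pairs typically look like in surveillance corpora.
- `worker_quality_range` (default [0.60, 0.95]): reliable workers' diagonal
  accuracy, drawn uniformly; off-diagonal mass is spread evenly. Spammers
  (`spammer_fraction`, default 5%) answer uniformly (`1/L` everywhere);
  adversarial workers (default 2%) have diagonal accuracy 0.02–0.10.
- Ability for the logistic noise mode: `alpha = qlogis(accuracy)`, so at
  median task clarity (`beta = 1`) the two noise modes agree on the
  probability of a correct answer. `alpha = 0` is a worker who cannot
  distinguish labels; adversarial workers get `alpha` in [−2.5, −0.75].
- `activity_tail_exponent` (default 1.1): worker activity is Pareto(1, a)
  via inverse-CDF sampling. At 1.1 the top 1% of workers hold a large share
  of all HITs while most workers complete few — the empirical heavy-tail
  pattern.
- Task clarity `beta` is log-normal (`meanlog 0`, `sdlog 0.7`); difficulty
  is `1/beta`. In the logistic mode a worker answers correctly with
  probability `plogis(alpha * beta)` and otherwise uniformly at random
  among the `L − 1` wrong labels (the standard assumption for this model
  family).
- `meta_informativeness` (default 1): each metadata field (daytime,
  weekday, month, gender, age group, source) is drawn from a
  class-conditional distribution obtained by exponentially tilting the
  field's base marginal with per-class standard-normal scores scaled by
  this parameter. Zero yields exact independence between metadata and
  class, which is the lever the supervised-layer ablation uses. A single
  scalar was chosen over per-field controls because only the overall
  supervised headroom matters for the experiments.
- Worker-to-HIT assignment samples `labels_per_task` distinct workers per
  HIT without replacement, with probability proportional to activity
  weight. Sampling per HIT (not per task) preserves the HIT structure —
  a worker answers all three tasks of a HIT plus its qualification
  question — while still giving every task exactly `labels_per_task`
  distinct workers.
- Tasks are grouped into HITs of three within each category; when a
  category count is not a multiple of three the last HIT is smaller. HIT
  validation therefore checks response validity, not HIT length.
- `tokens` is a category-keyword bag with noise words. It exists only to
  exercise the text-cleaning rules; no attempt is made to model language,
  and text features are excluded from the default supervised layer.

What the simulator deliberately does not emulate: real tweet semantics,
worker learning/fatigue over time, task-worker affinity (a worker who is
good at sleep tasks but poor at exercise tasks), or platform-side assignment
dynamics. Passing tests on synthetic data therefore demonstrate correctness
of the estimators under their generative assumptions and realistic sparsity —
not performance on any particular real corpus.

## Quality control and label consistency

`validate_hits()` applies the campaign approval rules: a submission with a
response carrying zero or more than one selection is rejected
(`selection_count`), a repeated task within a submission is rejected
(`duplicate_task`), and a wrong qualification answer either flags the
submission (default) or rejects it (`reject_hit` policy). Qualification
failure defaults to flagging because the worker, not the single HIT, is the
natural unit of consequence; `worker_report()` aggregates failure rates,
majority-agreement, and accuracy-versus-reference per worker, and flags
workers under a configurable agreement threshold once they have enough
volume (default 9 labels) to judge.

Label consistency is reported per category as
`LC = mean_i (1 − H_i / log 3)` with
`H_i = −Σ_j (n_ij/3) log(n_ij/3)`. The normalization constant is `log 3`
because three annotators can choose at most three distinct labels. LC is 1
when every task is unanimous and 0 when every task's three labels all
differ. Coarsening labels (multiclass → binary) can only merge distinct
choices, so binary LC is never below multiclass LC — a property the tests
check on random matrices.

Text cleaning expands a fixed table of ~40 English contractions first
(case-preserved), then removes weblinks, digits, apostrophes and the
characters `#` and `@` in place (so hashtag word content survives), and
turns remaining punctuation into token boundaries. Case and stop words are
untouched.

## Truth inference

All methods operate on the sparse `label_matrix` (task, worker, label).

**Majority vote** takes the modal label; posteriors are vote shares. Ties
are always flagged, and resolved by a seeded coin (default), alphabet
order, or abstention. For binary labels this is the usual 2-of-3 rule.

**Dawid–Skene** runs EM over per-worker row-stochastic confusion matrices
`π^k` and class priors. The E-step computes task posteriors; the M-step
re-estimates priors and confusion rows with an additive pseudo-count
(default 0.01) so that workers with few labels — ubiquitous under
heavy-tailed activity — keep proper distributions. This smoothing is a
Dirichlet prior, so the iteration is MAP-EM and `loglik_trace` records the
penalized objective, which provably never decreases; the raw observed
log-likelihood is reported alongside. One consequence worth knowing: when a
worker's labels carry no redundancy at all (a single worker labeling each
task once), the confusion matrix is unidentified and the prior legitimately
pulls it toward uniform; with three labels per task the likelihood
dominates and this effect is negligible.

**GLAD** models the probability that worker *k* answers task *i* correctly
as `plogis(alpha_k * beta_i)`, wrong answers uniform over the remaining
labels. The M-step ascends `(alpha, log beta)` jointly by bounded
quasi-Newton (L-BFGS-B, default 25 iterations per M-step) under Gaussian
priors (`alpha ~ N(1, 1)`, `log beta ~ N(0, 1)`); optimizing `log beta`
enforces `beta > 0`. Because the M-step starts from the current parameters
and line-searches, it cannot decrease the objective, preserving the
monotone trace. Priors here are configuration, not estimates from any
external dataset.

**Raykar** comes in two forms: the multiclass form is confusion-matrix EM
with a Dirichlet pseudo-count and reduces *exactly* to Dawid–Skene when its
prior equals the DS smoothing (the tests assert bitwise-equal traces); the
binary form models per-worker sensitivity and specificity with Beta priors,
MAP-updated in closed form each M-step together with the prevalence.

Initialization is `mv_soft` (posteriors = vote shares) by default; uniform
initialization is available. Convergence is declared when the relative
change of the penalized objective falls below `tol` (default 1e-6) within
`max_iter` (default 100); non-convergence warns and still returns the
result with `converged = FALSE`.

## The supervised layer

`assemble_features()` builds one row per task from the quintuple
`(W, I, M, t, l)`: the three crowd labels in matrix row order, the four
inferred labels, and six metadata fields, all one-hot over fixed domains
(column count `7L + 53`); tokens are carried but not encoded. Class
weights follow the balanced heuristic `n / (L_present * n_c)`.
`train_eval()` wraps five families — multinomial logistic regression
(`nnet`), kNN (`caret::knn3`, class weights via weighted resampling), RBF
SVM (`e1071`), random forest (`ranger`), gradient-boosted trees
(`xgboost`) — in nested cross-validation: stratified outer folds (default
10, configurable down to 3) estimate performance; an inner 3-fold seeded
randomized search over a fixed, versioned grid selects hyperparameters.
Randomized search replaces Bayesian optimization deliberately: at these
problem sizes the nesting structure (inner selection, outer estimate) is
what matters, and a seeded search is fully reproducible with no opaque
dependency. Macro averaging is used for multiclass metrics and is labeled
as such in outputs; the PR curve uses the interpolation-free
average-precision step sum, with the positive class's AP reported for
binary problems and the one-vs-rest macro for multiclass.

## Active learning

`active_learn()` implements pool-based uncertainty sampling: from a small
stratified seed set (default 2% of the pool), each iteration fits the base
learner, scores the remaining pool by `1 − max p`, moves the top
`batch_size` (default 5) into the labeled set, and records accuracy and
macro-F1 on a fixed truth-labeled holdout (default 100 iterations).
Queried points keep their given labels — querying does not correct
mislabeled samples, and the mislabel probe reports how over-represented
known-mislabeled points are among queries without fixing them; an
oracle-label mode exists for contrast experiments.

For the accuracy-curve experiment the package uses a truth-labeled pool
(the classic "annotator answers each query" setting) and drops the
inferred-label columns from the learner's features. The reason is
structural: with DS/GLAD columns present, a learner trained on a dozen
examples already sits at the majority-vote ceiling, and feeding it MV
labels can only pull its truth-accuracy *down* toward that ceiling — the
curve's direction would measure the feature layout, not the sampling
strategy. Stabilization is assessed on the mean curve across simulation
seeds (last-20-iteration range), since a single run's late curve moves in
steps of one holdout task.

## Shapley attribution

`exact_shapley()` enumerates all `2^g` coalitions of at most 12 feature
groups; a coalition's value is the model output averaged over a background
sample with coalition features set to the instance (marginal
background averaging, default 100 stratified rows). One-hot columns of a
categorical field form one group, and the four inferred-label fields are
attributed as a single "inference" group so the assembled space stays
within the enumeration budget (3 crowd labels + 1 inference + 6 metadata =
10 groups). Exactness makes the implementation its own oracle surface: the
tests verify efficiency, null-player, and symmetry axioms to 1e-8 and
agreement with an independent permutation-averaging oracle for up to 6
groups. Global importance is `I_j = Σ_i |φ_ij|`, summed rather than
averaged — a constant factor that cannot change the ranking.

## Numerical choices and degenerate inputs

- All E-steps work in log space with log-sum-exp normalization;
  probabilities are clamped to `[1e-12, 1 − 1e-12]` before logs.
- Ties in hard labels (equal posteriors) are flagged, never silently
  resolved; `max.col(ties.method = "first")` makes unflagged paths
  deterministic.
- A single global seed derives per-stage seeds through a fixed integer
  hash, so stages are reproducible independently of call order; all
  sampling goes through `withr::with_seed`.
- Degenerate inputs: an empty approved set yields an empty matrix
  (reported, not an error); single-class training sets produce a constant
  predictor; pool exhaustion truncates an active-learning run and marks it.
- Problem sizes in the test suite (up to 3,000 tasks × 40 workers for
  confusion recovery, 2,000 × 60 for ability/difficulty recovery, 20-seed
  paired comparisons elsewhere) were chosen so that parameter-recovery
  standard errors sit comfortably inside the asserted tolerances.

## Known limitations

- The simulator's independence assumptions (worker errors independent
  across tasks and workers, metadata conditionally independent given
  class) are exactly the assumptions of the inference models; real crowds
  violate them in correlated ways the package does not model.
- GLAD's difficulty estimates from 3 labels per task are information-
  starved; rank recovery is only assessed under 5-fold redundancy.
- No Bayesian samplers, no streaming inference, no deep-learning or text
  models; the token field exists only for the cleaning rules.
- `label_consistency()` assumes exactly 3 labels per task, matching the
  campaign design; other redundancies would need a different entropy
  normalization.
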