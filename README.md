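# crowdtruth

Quality assessment and truth inference for crowdsourced labels in public
health surveillance.

## The problem

Crowdsourcing platforms such as Amazon Mechanical Turk make it cheap to
collect labels for large social-media corpora — for example, whether a tweet
self-reports a recent physical-activity, sedentary-behavior, or sleep-quality
experience. But workers vary enormously in diligence and skill, each task is
typically labeled by only three workers, and a handful of spammers or
adversarial annotators can silently corrupt a training set. Before such
labels can feed a machine-learning model, two questions must be answered:
*how consistent are the workers*, and *what is the most plausible true label
for each task*?

`crowdtruth` implements a complete, testable workflow for these questions:

- **Synthetic campaign simulator** — generates workers (with per-worker
  confusion matrices or logistic ability, heavy-tailed Pareto activity,
  configurable spammer/adversarial fractions), tasks (four-class labels
  built from two binary conditions, log-normal task clarity,
  class-informative metadata), and HIT-structured assignments, all with
  known ground truth, so every downstream method can be validated.
- **Label quality control** — HIT approval rules (selection counts,
  qualification question, duplicate detection), label-matrix construction
  with exclusion tallies, binary dichotomization, text cleaning, and
  per-worker quality reports.
- **Label consistency (LC)** — per category, `LC = mean(1 - H_i / log 3)`
  where `H_i = -Σ_j (n_ij/3) log(n_ij/3)` is the entropy of task *i*'s
  label counts; 1 means unanimous workers, 0 means maximal disagreement.
- **Four unsupervised truth-inference models** over the sparse
  task × worker label matrix:
  - majority vote (MV), with explicit tie flagging;
  - Dawid–Skene (DS): EM over per-worker L×L confusion matrices π^k and
    class priors;
  - GLAD: worker ability α ∈ (−∞, ∞) and task difficulty d = 1/β with
    correctness probability `plogis(α·β)`;
  - Raykar (RY): confusion-matrix EM with Dirichlet priors, and a binary
    variant with Beta-prior sensitivity/specificity.
- **Supervised meta-feature layer** — the quintuple **F = (W, I, M, t, l)**
  (three crowd labels, four inferred labels, task metadata, tokens, truth)
  one-hot encoded and fed to five classifier families (logistic regression,
  kNN, SVM, random forest, gradient-boosted trees) with class weighting and
  nested cross-validation (inner seeded randomized search, outer estimate).
- **Pool-based active learning** with uncertainty sampling
  (`score = 1 − max p`), batch querying, and a mislabeled-sample probe.
- **Exact Shapley attribution** — coalition enumeration over ≤ 12 feature
  groups with background marginalization, plus the global importance
  `I_j = Σ_i |φ_ij|` and the unanimous-label subset analysis.

## Worked example

```r
library(crowdtruth)

cfg        <- sim_config(n_tasks_per_category = 150, n_workers = 80, seed = 1)
workers    <- generate_workers(cfg)
tasks      <- generate_tasks(cfg)
assignments <- simulate_labeling(tasks, workers, cfg)

qc     <- validate_hits(assignments)
matrix <- build_label_matrix(qc$approved)
matrix
#> <label_matrix> 1230 labels, 410 tasks, 73 workers, alphabet {11, 10, 01, 00}

label_consistency(matrix, tasks[c("task_id", "category")])
#> # A tibble: 3 × 3
#>   category           lc_value n_tasks
#> 1 physical_activity     0.532     136
#> 2 sedentary_behavior    0.631     137
#> 3 sleep_quality         0.670     137
```

LC around 0.5–0.7 on the multiclass view says the three workers often
disagree — exactly the regime where truth inference matters. Infer the
latent labels and score them against the (here known) ground truth:

```r
ds    <- dawid_skene(matrix)
#> <crowd_inference:ds> 410 tasks, 73 workers, 51 iteration(s), converged
truth <- setNames(tasks$true_label, tasks$task_id)
evaluate_inference(ds, truth)
#>   precision recall    f1 auc_pr     n
#> 1     0.746  0.812 0.757  0.801   410

mvb <- majority_vote(binarize_matrix(matrix))
evaluate_inference(mvb, setNames(dichotomize(tasks$true_label), tasks$task_id))
#>   precision recall    f1 auc_pr     n
#> 1     0.934  0.921 0.927  0.910   410
```

The four-class problem is much harder (macro-F1 0.76) than its binary
dichotomization (F1 0.93) — coarsening absorbs most worker disagreement.
`tidy()` returns per-task posteriors, `glance()` a one-row summary, and
`autoplot()` the EM convergence trace. `run_experiment(experiment_config())`
chains simulation → QC → all four inference models → the supervised layer →
active learning → Shapley attribution into one reproducible report bundle.

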