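# Synthetic crowd generator: construction rules, calibration oracles,
# determinism, and the end-to-end perfect-worker smoke property.

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(n_tasks_per_category = 0), "n_tasks_per_category")
  expect_error(sim_config(n_workers = -3), "n_workers")
  expect_error(sim_config(class_prevalences = c("11" = 1.2, "10" = -0.2)),
               "negative")
  expect_error(sim_config(worker_quality_range = numeric(0)), "interval")
  expect_error(sim_config(worker_quality_range = c(0.9, 0.5)), "interval")
  expect_error(sim_config(spammer_fraction = 0.7, adversarial_fraction = 0.5),
               "<= 1")
})

test_that("worker construction follows the spammer/quality rules", {
  cfg <- sim_config(n_workers = 30, spammer_fraction = 1,
                    adversarial_fraction = 0, seed = 7)
  w <- generate_workers(cfg)
  for (m in w$confusion) expect_equal(unname(m), matrix(0.25, 4, 4))
  expect_true(all(abs(sapply(w$confusion, function(m) rowSums(m)) - 1) < 1e-12))

  cfg2 <- sim_config(n_workers = 25, worker_quality_range = c(0.9, 0.9),
                     spammer_fraction = 0, adversarial_fraction = 0, seed = 7)
  w2 <- generate_workers(cfg2)
  for (m in w2$confusion) {
    expect_equal(unname(diag(m)), rep(0.9, 4))
    expect_equal(unname(m[1, 2]), 0.1 / 3)
  }
  expect_true(all(w2$activity_weight > 0))
})

test_that("activity heavy tail matches an independent Pareto sampling oracle", {
  a <- 1.1
  n <- 600
  top_share <- function(w) {
    k <- max(1, floor(0.01 * length(w)))
    sum(sort(w, decreasing = TRUE)[1:k]) / sum(w)
  }
  gen_shares <- vapply(1:200, function(s) {
    cfg <- sim_config(n_workers = n, activity_tail_exponent = a,
                      spammer_fraction = 0, adversarial_fraction = 0,
                      seed = s)
    top_share(generate_workers(cfg)$activity_weight)
  }, numeric(1))
  oracle_shares <- withr::with_seed(991, vapply(1:200, function(s) {
    top_share(runif(n)^(-1 / a))
  }, numeric(1)))
  se <- sqrt(stats::var(gen_shares) / 200 + stats::var(oracle_shares) / 200)
  expect_lt(abs(mean(gen_shares) - mean(oracle_shares)), 2 * se)
})

test_that("degenerate prevalence forces all labels to one class", {
  cfg <- sim_config(n_tasks_per_category = 30,
                    class_prevalences = c("11" = 1, "10" = 0,
                                          "01" = 0, "00" = 0), seed = 2)
  expect_true(all(generate_tasks(cfg)$true_label == "11"))
})

test_that("empirical class prevalence matches configuration within 2 s.e.", {
  cfg <- sim_config(n_tasks_per_category = 2000, seed = 11)
  tasks <- generate_tasks(cfg)
  n <- nrow(tasks)
  for (cl in names(cfg$class_prevalences)) {
    p <- cfg$class_prevalences[[cl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(tasks$true_label == cl) - p), 2 * se + 1e-12)
  }
})

test_that("zero meta informativeness gives class-independent metadata", {
  cfg <- sim_config(n_tasks_per_category = c(16667, 16667, 16666),
                    meta_informativeness = 0, seed = 5)
  tasks <- generate_tasks(cfg)
  mi <- function(x, y) {
    tab <- table(x, y)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    keep <- p > 0
    sum(p[keep] * log(p[keep] / outer(px, py)[keep]))
  }
  obs <- mi(tasks$true_label, tasks$daytime)
  null <- withr::with_seed(42, vapply(1:99, function(i) {
    mi(sample(tasks$true_label), tasks$daytime)
  }, numeric(1)))
  expect_lt(obs, stats::quantile(null, 0.95))
})

test_that("positive meta informativeness couples metadata to class", {
  cfg <- sim_config(n_tasks_per_category = 3000, meta_informativeness = 1,
                    seed = 5)
  tasks <- generate_tasks(cfg)
  tab <- table(tasks$true_label, tasks$daytime)
  expect_lt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-6)
})

test_that("labeling structure: 3 distinct workers per task, identity is exact", {
  cfg <- sim_config(n_tasks_per_category = 30, n_workers = 25,
                    worker_quality_range = c(1, 1), p_unclear = 0,
                    p_qual_fail = 0, spammer_fraction = 0,
                    adversarial_fraction = 0, seed = 3)
  tasks <- generate_tasks(cfg)
  workers <- generate_workers(cfg)
  asg <- simulate_labeling(tasks, workers, cfg)
  per_task <- dplyr::count(asg, task_id)
  expect_true(all(per_task$n == 3))
  dup <- asg %>% dplyr::count(task_id, worker_id) %>% dplyr::pull(n)
  expect_true(all(dup == 1))
  truth <- stats::setNames(tasks$true_label, tasks$task_id)
  expect_true(all(asg$choice == truth[asg$task_id]))
  expect_true(all(asg$qual_answer == "correct"))
})

test_that("labeling requires enough workers", {
  cfg <- sim_config(n_tasks_per_category = 3, n_workers = 2, seed = 1)
  tasks <- generate_tasks(cfg)
  workers <- generate_workers(cfg)
  expect_error(simulate_labeling(tasks, workers, cfg), "exceeds")
})

test_that("GLAD-mode zero-ability worker labels binary tasks at chance", {
  n_tasks <- 10000
  cfg <- sim_config(n_tasks_per_category = c(n_tasks, 0, 0) + c(0, 1, 1),
                    n_workers = 1, labels_per_task = 1,
                    class_prevalences = c("0" = 0.5, "1" = 0.5),
                    noise_mode = "glad", p_unclear = 0, p_qual_fail = 0,
                    spammer_fraction = 0, adversarial_fraction = 0, seed = 9)
  tasks <- generate_tasks(cfg)
  workers <- generate_workers(cfg)
  workers$ability_alpha <- 0
  asg <- simulate_labeling(tasks, workers, cfg)
  truth <- stats::setNames(tasks$true_label, tasks$task_id)
  acc <- mean(asg$choice == truth[asg$task_id])
  se <- sqrt(0.25 / nrow(asg))
  expect_lt(abs(acc - 0.5), 2 * se)
})

test_that("empirical confusion converges to the specified matrix", {
  cfg <- sim_config(n_tasks_per_category = 4000, n_workers = 1,
                    labels_per_task = 1,
                    class_prevalences = c("11" = 0.25, "10" = 0.25,
                                          "01" = 0.25, "00" = 0.25),
                    p_unclear = 0, p_qual_fail = 0,
                    spammer_fraction = 0, adversarial_fraction = 0, seed = 13)
  tasks <- generate_tasks(cfg)
  workers <- make_workers(list(diag_confusion(0.8, 4)),
                          crowdtruth:::MULTICLASS_ALPHABET)
  asg <- simulate_labeling(tasks, workers, cfg)
  truth <- stats::setNames(tasks$true_label, tasks$task_id)
  emp <- prop.table(table(factor(truth[asg$task_id],
                                 crowdtruth:::MULTICLASS_ALPHABET),
                          factor(asg$choice,
                                 crowdtruth:::MULTICLASS_ALPHABET)), 1)
  expect_lt(max(abs(emp - workers$confusion[[1]])), 0.02)
  # per-class accuracy within 2 binomial s.e. of the 0.8 diagonal
  for (cl in crowdtruth:::MULTICLASS_ALPHABET) {
    n_cl <- sum(truth[asg$task_id] == cl)
    se <- sqrt(0.8 * 0.2 / n_cl)
    expect_lt(abs(emp[cl, cl] - 0.8), 2.5 * se)
  }
})

test_that("equal seeds reproduce byte-identical data; different seeds differ", {
  cfg <- sim_config(n_tasks_per_category = 40, n_workers = 25, seed = 21)
  s1 <- simulate_labeling(generate_tasks(cfg), generate_workers(cfg), cfg)
  s2 <- simulate_labeling(generate_tasks(cfg), generate_workers(cfg), cfg)
  expect_identical(s1, s2)
  cfg2 <- sim_config(n_tasks_per_category = 40, n_workers = 25, seed = 22)
  s3 <- simulate_labeling(generate_tasks(cfg2), generate_workers(cfg2), cfg2)
  expect_false(identical(s1$choice, s3$choice))
})

test_that("perfect workers give accuracy 1 for all four inference methods", {
  st <- small_study(seed = 4, n_per_cat = 30, n_workers = 25,
                    worker_quality_range = c(1, 1), p_unclear = 0,
                    p_qual_fail = 0, spammer_fraction = 0,
                    adversarial_fraction = 0)
  inf <- infer_all(st$matrix, em_settings(), seed = 1)
  for (nm in names(inf)) {
    m <- suppressWarnings(evaluate_inference(inf[[nm]], st$truth))
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$f1, 1)
  }
})

test_that("tasks and assignments round-trip through CSV/JSONL", {
  st <- small_study(seed = 6, n_per_cat = 20, n_workers = 15)
  tf <- withr::local_tempfile(fileext = ".csv")
  af <- withr::local_tempfile(fileext = ".jsonl")
  write_tasks(st$tasks, tf)
  t2 <- read_tasks(tf)
  expect_equal(as.data.frame(t2), as.data.frame(st$tasks))
  write_assignments(st$assignments, af)
  a2 <- read_assignments(af)
  expect_equal(as.data.frame(dplyr::arrange(a2, hit_id, worker_id, task_id)),
               as.data.frame(st$assignments))
})
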