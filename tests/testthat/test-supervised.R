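# Feature assembly, class weighting, nested-CV training, and the
# label-quality downstream experiment.

make_feature_fixture <- function(seed = 19, n_per_cat = 80, ...) {
  st <- small_study(seed = seed, n_per_cat = n_per_cat, n_workers = 50, ...)
  inf <- suppressWarnings(infer_all(st$matrix, em_settings(max_iter = 40),
                                    seed = 1))
  list(st = st,
       feats = suppressWarnings(
         assemble_features(st$matrix, inf, st$tasks)),
       feats_bin = suppressWarnings(
         assemble_features(st$matrix, inf, st$tasks, binary = TRUE)),
       inf = inf)
}

test_that("class weights follow the balanced formula", {
  expect_equal(class_weights(rep(c("1", "0"), c(25, 75))),
               c("0" = 2 / 3, "1" = 2))
  expect_equal(unname(class_weights(rep(c("a", "b"), 10))), c(1, 1))
  w4 <- class_weights(rep(c("a", "b", "c", "d"), c(40, 30, 20, 10)))
  expect_equal(unname(w4), c(0.625, 100 / 120, 1.25, 2.5))
  # scale invariance under dataset duplication
  labs <- rep(c("x", "y"), c(30, 10))
  expect_equal(class_weights(labs), class_weights(rep(labs, 3)))
  expect_error(class_weights(character(0)), "empty")
})

test_that("feature assembly matches the closed-form one-hot column count", {
  fx <- make_feature_fixture()
  feats <- fx$feats
  L <- 4
  meta_cols <- sum(lengths(crowdtruth:::META_DOMAINS))  # 24+7+12+3+5+2 = 53
  expect_equal(meta_cols, 53)
  n_feature_cols <- ncol(feats) - 3L  # task_id, l, tokens
  expect_equal(n_feature_cols, 7 * L + 53)
  fb <- fx$feats_bin
  expect_equal(ncol(fb) - 3L, 7 * 2 + 53)
  # every row fully observed, one-hot blocks sum to 1
  X <- crowdtruth:::feature_matrix(feats)
  expect_false(anyNA(X))
  groups <- attr(feats, "feature_groups")
  expect_equal(length(groups), 10)
  # each one-hot field in a group contributes exactly one active column
  fields_per_group <- c(l_1 = 1, l_2 = 1, l_3 = 1, inference = 4,
                        daytime = 1, weekday = 1, month = 1, gender = 1,
                        age_group = 1, source = 1)
  for (gn in names(groups)) {
    expect_equal(unname(rowSums(X[, groups[[gn]], drop = FALSE])),
                 rep(unname(fields_per_group[gn]), nrow(X)))
  }
})

test_that("identical tasks produce identical rows; W permutation is local", {
  fx <- make_feature_fixture()
  m <- fx$st$matrix
  # duplicate one task under a new id
  t1 <- m$task_id[1]
  dup <- dplyr::filter(m, .data$task_id == t1)
  dup$task_id <- "t_dup"
  m2 <- crowdtruth:::new_label_matrix(dplyr::bind_rows(m, dup),
                                      crowdtruth:::lm_alphabet(m))
  tasks2 <- dplyr::bind_rows(
    fx$st$tasks,
    dplyr::mutate(dplyr::filter(fx$st$tasks, .data$task_id == t1),
                  task_id = "t_dup"))
  inf2 <- suppressWarnings(infer_all(m2, em_settings(max_iter = 40),
                                     seed = 1))
  f2 <- suppressWarnings(assemble_features(m2, inf2, tasks2))
  r1 <- f2[f2$task_id == t1, setdiff(names(f2), "task_id")]
  r2 <- f2[f2$task_id == "t_dup", setdiff(names(f2), "task_id")]
  expect_equal(as.data.frame(r1), as.data.frame(r2))

  # swapping the first two workers' rows for one task changes only W columns
  i12 <- which(m$task_id == t1)[1:2]
  m3 <- m
  m3[i12, ] <- m3[rev(i12), ]
  m3 <- crowdtruth:::new_label_matrix(m3, crowdtruth:::lm_alphabet(m))
  f3 <- suppressWarnings(assemble_features(m3, fx$inf, fx$st$tasks))
  groups <- attr(fx$feats, "feature_groups")
  w_cols <- unlist(groups[c("l_1", "l_2")])
  other <- setdiff(names(fx$feats), c(w_cols, "tokens"))
  expect_equal(as.data.frame(f3[other]), as.data.frame(fx$feats[other]))
})

test_that("assembly demands all four inference methods and full metadata", {
  fx <- make_feature_fixture()
  expect_error(
    assemble_features(fx$st$matrix, fx$inf[c("mv", "ds")], fx$st$tasks),
    "must contain")
  expect_error(
    assemble_features(fx$st$matrix, fx$inf, fx$st$tasks[-1, ]),
    "missing metadata")
})

test_that("stratified folds balance classes within one example", {
  y <- rep(c("a", "b", "c"), c(40, 25, 11))
  fold <- crowdtruth:::stratified_folds(y, 4, seed = 3)
  tab <- table(y, fold)
  for (cl in rownames(tab)) {
    expect_lte(max(tab[cl, ]) - min(tab[cl, ]), 1)
  }
})

test_that("a feature that equals the target is learned almost perfectly", {
  fx <- make_feature_fixture(seed = 23, n_per_cat = 60,
                             worker_quality_range = c(1, 1),
                             spammer_fraction = 0, adversarial_fraction = 0,
                             p_unclear = 0, p_qual_fail = 0,
                             class_prevalences = c("11" = 0.4, "10" = 0.25,
                                                   "01" = 0.15, "00" = 0.2))
  fit <- train_eval(fx$feats, "logreg", cv_folds = 3, search_budget = 2,
                    seed = 1)
  expect_gte(fit$metrics$f1, 0.99)
})

test_that("training is reproducible given a seed", {
  fx <- make_feature_fixture()
  f1 <- train_eval(fx$feats_bin, "logreg", cv_folds = 3, search_budget = 2,
                   seed = 9)
  f2 <- train_eval(fx$feats_bin, "logreg", cv_folds = 3, search_budget = 2,
                   seed = 9)
  expect_equal(f1$metrics, f2$metrics)
  expect_equal(f1$predictions, f2$predictions)
})

test_that("every classifier family trains and predicts probabilities", {
  fx <- make_feature_fixture(seed = 29, n_per_cat = 50,
                             class_prevalences = c("11" = 0.4, "10" = 0.25,
                                                   "01" = 0.15, "00" = 0.2))
  X <- crowdtruth:::feature_matrix(fx$feats_bin)
  y <- fx$feats_bin$l
  for (fam in crowdtruth:::SUPERVISED_FAMILIES) {
    m <- crowdtruth:::fit_learner(fam, X, y,
                                  crowdtruth:::default_hyper(fam, ncol(X)),
                                  seed = 2)
    p <- crowdtruth:::predict_learner(m, X[1:7, , drop = FALSE])
    expect_equal(dim(p), c(7L, 2L))
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  }
})

test_that("dropping the crowd-label columns degrades macro-F1", {
  fx <- make_feature_fixture(seed = 31, n_per_cat = 120)
  full <- train_eval(fx$feats, "logreg", cv_folds = 3, search_budget = 2,
                     seed = 4)
  groups <- attr(fx$feats, "feature_groups")
  w_cols <- unlist(groups[c("l_1", "l_2", "l_3")])
  no_w <- fx$feats[setdiff(names(fx$feats), w_cols)]
  reduced <- train_eval(no_w, "logreg", cv_folds = 3, search_budget = 2,
                        seed = 4)
  expect_gt(full$metrics$f1, reduced$metrics$f1)
})

test_that("downstream experiment: identical labels give zero gap", {
  fx <- make_feature_fixture(seed = 37, n_per_cat = 60)
  same <- stats::setNames(as.character(fx$feats_bin$l),
                          fx$feats_bin$task_id)
  res <- downstream_label_quality_experiment(fx$feats_bin, same,
                                             family = "logreg", seed = 5)
  expect_equal(res$gap, rep(0, 4))
})

test_that("downstream experiment: noisy labels lose to truth labels", {
  fx <- make_feature_fixture(seed = 41, n_per_cat = 150)
  y <- as.character(fx$feats_bin$l)
  noisy <- withr::with_seed(11, {
    flip <- runif(length(y)) < 0.25
    ifelse(flip, ifelse(y == "1", "0", "1"), y)
  })
  res <- downstream_label_quality_experiment(
    fx$feats_bin, stats::setNames(noisy, fx$feats_bin$task_id),
    family = "logreg", seed = 5)
  expect_gt(res$gap[res$metric == "auc_pr"], 0)
})
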