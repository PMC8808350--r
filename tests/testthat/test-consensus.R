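# Unsupervised truth inference: majority vote behavior, EM fixed points,
# parameter recovery, definitional reductions, and structural invariants.

test_that("majority vote picks the modal label and flags ties", {
  m <- make_matrix(list(c("11", "11", "00")))
  mv <- majority_vote(m)
  expect_equal(tidy(mv)$hard_label, "11")
  expect_false(tidy(mv)$tie)
  expect_equal(unname(mv$posteriors[1, ]), c(2 / 3, 0, 0, 1 / 3))

  mb <- make_matrix(list(c("1", "1", "0")), alphabet = c("0", "1"))
  expect_equal(tidy(majority_vote(mb))$hard_label, "1")
})

test_that("tie policies behave as declared", {
  m <- make_matrix(list(c("11", "10", "00")))
  ab <- majority_vote(m, tie_policy = "abstain")
  expect_true(tidy(ab)$tie)
  expect_true(is.na(tidy(ab)$hard_label))
  lo <- majority_vote(m, tie_policy = "lowest_index")
  expect_equal(tidy(lo)$hard_label, "11")
  r1 <- majority_vote(m, tie_policy = "random_seeded", seed = 5)
  r2 <- majority_vote(m, tie_policy = "random_seeded", seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_true(tidy(r1)$hard_label %in% c("11", "10", "00"))
})

test_that("majority vote matches the brute-force oracle on all 5^3 triples", {
  symbols <- c(crowdtruth:::MULTICLASS_ALPHABET, "unclear")
  triples <- expand.grid(l1 = symbols, l2 = symbols, l3 = symbols,
                         stringsAsFactors = FALSE)
  m <- make_matrix(purrr::pmap(triples, function(l1, l2, l3) c(l1, l2, l3)),
                   alphabet = symbols)
  mv <- majority_vote(m, tie_policy = "lowest_index")
  td <- tidy(mv)
  n_tie <- 0
  for (i in seq_len(nrow(triples))) {
    oracle <- mode_oracle(unlist(triples[i, ]), symbols)
    expect_true(td$hard_label[i] %in% oracle$modes)
    expect_equal(td$tie[i], oracle$tie)
    n_tie <- n_tie + oracle$tie
  }
  expect_equal(sum(td$tie), 60)
  expect_equal(n_tie, 60)
})

test_that("DS fixed point: agreeing data returns the labels confidently", {
  # single worker: labels are reproduced even though the confusion matrix
  # itself is unidentified without redundancy
  labs <- c("11", "10", "00", "01", "11", "00")
  df <- tibble::tibble(task_id = sprintf("t%02d", seq_along(labs)),
                       worker_id = "w1", label = labs)
  m <- crowdtruth:::new_label_matrix(df, crowdtruth:::MULTICLASS_ALPHABET)
  ds <- suppressWarnings(dawid_skene(m, em_settings(max_iter = 50)))
  expect_equal(tidy(ds)$hard_label, labs)
  conf <- ds$worker_quality$confusion[[1]]
  expect_true(all(diag(conf) == apply(conf, 1, max)))

  # with three unanimous workers the likelihood pins the confusion
  # diagonals near 1 (up to the smoothing pseudo-counts)
  m3 <- make_matrix(lapply(rep(labs, 3), function(l) rep(l, 3)))
  ds3 <- suppressWarnings(dawid_skene(m3, em_settings(max_iter = 50)))
  expect_equal(tidy(ds3)$hard_label, rep(labs, 3))
  for (conf in ds3$worker_quality$confusion) {
    expect_true(all(diag(conf) > 0.95))
  }
})

test_that("DS recovers worker confusion diagonals on simulated data", {
  st <- small_study(seed = 17, n_per_cat = 500, n_workers = 30,
                    worker_quality_range = c(0.55, 0.95),
                    class_prevalences = c("11" = 0.35, "10" = 0.25,
                                          "01" = 0.15, "00" = 0.25),
                    spammer_fraction = 0, adversarial_fraction = 0,
                    p_unclear = 0, p_qual_fail = 0,
                    activity_tail_exponent = 3)
  ds <- suppressWarnings(dawid_skene(st$matrix, em_settings(max_iter = 60)))
  est <- ds$worker_quality
  truth_diag <- st$workers$accuracy[match(est$worker_id,
                                          st$workers$worker_id)]
  est_diag <- vapply(est$confusion, function(m) mean(diag(m)), numeric(1))
  expect_gt(stats::cor(est_diag, truth_diag), 0.85)
  expect_lt(mean(abs(est_diag - truth_diag)), 0.06)
})

test_that("multiclass Raykar reduces exactly to DS at equal pseudo-counts", {
  m <- random_matrix(150, seed = 23)
  s <- em_settings(max_iter = 40)
  ds <- suppressWarnings(dawid_skene(m, s))
  ry <- suppressWarnings(raykar_multiclass(m, s, dirichlet_prior = s$smoothing))
  expect_equal(ry$posteriors, ds$posteriors)
  expect_equal(ry$loglik_trace, ds$loglik_trace)
  expect_equal(ry$worker_quality$confusion, ds$worker_quality$confusion)
})

test_that("a huge Dirichlet prior flattens confusion toward uniform", {
  m <- random_matrix(80, seed = 29)
  ry <- suppressWarnings(
    raykar_multiclass(m, em_settings(max_iter = 10), dirichlet_prior = 1e6))
  for (conf in ry$worker_quality$confusion) {
    expect_lt(max(abs(conf - 0.25)), 1e-3)
  }
})

test_that("binary Raykar demands a binary alphabet", {
  m <- random_matrix(10, seed = 1)
  expect_error(raykar_binary(m), "raykar_multiclass")
})

test_that("binary Raykar: perfect workers reach near-1 sensitivity/specificity", {
  labs <- list(c("1", "1", "1"), c("0", "0", "0"), c("1", "1", "1"),
               c("0", "0", "0"), c("1", "1", "1"))
  m <- make_matrix(labs, alphabet = c("0", "1"))
  ry <- suppressWarnings(raykar_binary(m, em_settings(max_iter = 50)))
  expect_true(all(ry$worker_quality$sensitivity > 0.99))
  expect_true(all(ry$worker_quality$specificity > 0.99))
  expect_equal(tidy(ry)$hard_label, vapply(labs, `[`, character(1), 1))
})

test_that("a strong Beta prior shrinks the MAP estimate toward the prior mean", {
  # one weak worker (empirical sensitivity 0.6) amid accurate anchors
  set.seed(41)
  n_pos <- 10; n_neg <- 10
  truth <- c(rep("1", n_pos), rep("0", n_neg))
  weak <- c(rep("1", 6), rep("0", 4), rep("0", n_neg))  # 6/10 on positives
  df <- purrr::map_dfr(seq_along(truth), function(i) {
    tibble::tibble(
      task_id = sprintf("t%02d", i),
      worker_id = c("weak", "a1", "a2"),
      label = c(weak[i], truth[i], truth[i]))
  })
  m <- crowdtruth:::new_label_matrix(df, c("0", "1"))
  ry <- suppressWarnings(
    raykar_binary(m, em_settings(max_iter = 60),
                  beta_prior_sens = c(50, 1), beta_prior_spec = c(1, 1)))
  est <- ry$worker_quality$sensitivity[ry$worker_quality$worker_id == "weak"]
  prior_mean <- 50 / 51
  expect_gt(est, 0.6)
  expect_lt(est, prior_mean)
  # MAP closed form given the (pinned) posteriors
  mu <- ry$posteriors[, "1"]
  expected <- (49 + sum(mu * (weak == "1"))) / (49 + sum(mu))
  expect_equal(est, expected, tolerance = 1e-4)
})

test_that("GLAD ranks an always-correct worker highest", {
  withr::with_seed(53, {
    truth <- sample(crowdtruth:::MULTICLASS_ALPHABET, 60, replace = TRUE)
    df <- purrr::map_dfr(seq_along(truth), function(i) {
      noisy <- function() {
        if (stats::runif(1) < 0.65) truth[i]
        else sample(setdiff(crowdtruth:::MULTICLASS_ALPHABET, truth[i]), 1)
      }
      tibble::tibble(task_id = sprintf("t%02d", i),
                     worker_id = c("perfect", "n1", "n2"),
                     label = c(truth[i], noisy(), noisy()))
    })
  })
  m <- crowdtruth:::new_label_matrix(df, crowdtruth:::MULTICLASS_ALPHABET)
  g <- suppressWarnings(glad(m, em_settings(max_iter = 30)))
  wq <- g$worker_quality
  expect_gt(wq$ability_alpha[wq$worker_id == "perfect"], 0)
  expect_equal(wq$worker_id[which.max(wq$ability_alpha)], "perfect")
})

test_that("EM traces are monotone on random matrices", {
  for (s in 1:15) {
    m <- random_matrix(60, n_workers = 12, seed = 100 + s)
    st <- em_settings(max_iter = 25)
    for (res in list(suppressWarnings(dawid_skene(m, st)),
                     suppressWarnings(glad(m, st)),
                     suppressWarnings(raykar_multiclass(m, st, 0.05)))) {
      expect_true(all(diff(res$loglik_trace) >= -1e-9))
    }
    mb <- binarize_matrix(m)
    rb <- suppressWarnings(raykar_binary(mb, st))
    expect_true(all(diff(rb$loglik_trace) >= -1e-9))
  }
})

test_that("posteriors are simplexes and DS is permutation-equivariant", {
  m <- random_matrix(100, seed = 61)
  st <- em_settings(max_iter = 30)
  ds <- suppressWarnings(dawid_skene(m, st))
  expect_true(all(abs(rowSums(ds$posteriors) - 1) < 1e-9))

  perm <- c(3L, 1L, 4L, 2L)   # new order of the old alphabet
  alphabet2 <- crowdtruth:::MULTICLASS_ALPHABET[perm]
  m2 <- crowdtruth:::new_label_matrix(
    m[c("task_id", "worker_id", "label")], alphabet2)
  ds2 <- suppressWarnings(dawid_skene(m2, st))
  expect_equal(unname(ds2$posteriors[, crowdtruth:::MULTICLASS_ALPHABET]),
               unname(ds$posteriors), tolerance = 1e-8)
  c1 <- ds$worker_quality$confusion[[1]]
  c2 <- ds2$worker_quality$confusion[[1]]
  expect_equal(c2[crowdtruth:::MULTICLASS_ALPHABET,
                  crowdtruth:::MULTICLASS_ALPHABET], c1, tolerance = 1e-8)
})

test_that("DS agrees with MV when workers are homogeneous and accurate", {
  st <- small_study(seed = 67, n_per_cat = 300, n_workers = 40,
                    worker_quality_range = c(0.95, 0.95),
                    spammer_fraction = 0, adversarial_fraction = 0,
                    p_unclear = 0, p_qual_fail = 0)
  mv <- majority_vote(st$matrix, seed = 1)
  ds <- suppressWarnings(dawid_skene(st$matrix))
  untied <- !tidy(mv)$tie   # tied tasks are flagged so they can be excluded
  agree <- mean((tidy(mv)$hard_label == tidy(ds)$hard_label)[untied])
  expect_gte(agree, 0.99)
})

test_that("the DS advantage over MV grows with worker heterogeneity", {
  gap <- function(lo, hi, seed) {
    st <- small_study(seed = seed, n_per_cat = 170, n_workers = 25,
                      worker_quality_range = c(lo, hi),
                      spammer_fraction = 0, adversarial_fraction = 0,
                      p_unclear = 0, p_qual_fail = 0)
    mv <- majority_vote(st$matrix, seed = 1)
    ds <- suppressWarnings(dawid_skene(st$matrix, em_settings(max_iter = 60)))
    tr <- st$truth[tidy(mv)$task_id]
    mean(tidy(ds)$hard_label == tr) - mean(tidy(mv)$hard_label == tr)
  }
  # mean accuracy fixed at 0.75; variance low vs high
  gaps_low <- vapply(1:20, function(s) gap(0.70, 0.80, 300 + s), numeric(1))
  gaps_high <- vapply(1:20, function(s) gap(0.40, 1.00, 300 + s), numeric(1))
  expect_gt(mean(gaps_high), mean(gaps_low))
})

test_that("glance and tidy summarize inference objects", {
  m <- random_matrix(30, seed = 71)
  ds <- suppressWarnings(dawid_skene(m, em_settings(max_iter = 20)))
  g <- glance(ds)
  expect_equal(g$method, "ds")
  expect_equal(g$n_tasks, 30)
  td <- tidy(ds)
  expect_true(all(c("task_id", "hard_label", "tie", "p_11") %in% names(td)))
})
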