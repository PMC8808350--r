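# Supervised truth inference over the quintuple (W, I, M, t, l): ordered
# crowd labels, the four unsupervised inferred labels, task metadata, the
# (unused by default) token text, and the truth label. Five standard
# classifier families trained with class weighting and nested
# cross-validation (inner seeded randomized search, outer estimate).

SUPERVISED_FAMILIES <- c("logreg", "knn", "svm", "random_forest",
                         "gradient_boosted_trees")

#' Assemble the supervised feature table
#'
#' Builds one row per task from the quintuple: the task's three crowd labels
#' in matrix row order (`w1`, `w2`, `w3`), the four inferred labels
#' (`mv`, `ds`, `ry`, `glad`), and the six metadata fields, all one-hot
#' encoded over their full fixed domains in a stable documented column
#' order. The truth label is carried in column `l`; token text is carried in
#' `tokens` but not encoded (text models are out of scope).
#'
#' @param matrix A `label_matrix` (3 labels per task).
#' @param inference Named list of `crowd_inference` objects; must contain
#'   `mv`, `ds`, `ry`, `glad`.
#' @param tasks Task tibble with `task_id`, `true_label`, and the metadata
#'   columns; every matrix task must be present.
#' @param binary Encode crowd/inferred/truth labels on the dichotomized
#'   binary alphabet instead of the multiclass one.
#' @return A tibble with `task_id`, `l` (factor), one-hot feature columns,
#'   and attribute `"feature_groups"`: a named list mapping the attribution
#'   groups (`l_1`, `l_2`, `l_3`, `inference`, `daytime`, `weekday`,
#'   `month`, `gender`, `age_group`, `source`) to their columns.
#' @export
assemble_features <- function(matrix, inference, tasks, binary = FALSE) {
  need <- c("mv", "ds", "ry", "glad")
  if (!all(need %in% names(inference))) {
    abort(sprintf("`inference` must contain all of: %s.",
                  paste(need, collapse = ", ")))
  }
  task_ids <- unique(matrix$task_id)
  missing <- setdiff(task_ids, tasks$task_id)
  if (length(missing) > 0L) {
    abort(sprintf("Tasks missing metadata: %s",
                  paste(utils::head(missing, 10), collapse = ", ")))
  }
  alphabet <- if (binary) BINARY_ALPHABET else lm_alphabet(matrix)

  # W: crowd labels in matrix row order per task
  W <- matrix %>%
    dplyr::group_by(.data$task_id) %>%
    dplyr::mutate(pos = dplyr::row_number()) %>%
    dplyr::ungroup()
  if (max(W$pos) != 3L || min(tabulate(match(W$task_id, task_ids))) != 3L) {
    abort("Every task must carry exactly 3 crowd labels.")
  }
  W <- tidyr::pivot_wider(W, id_cols = "task_id",
                          names_from = "pos", values_from = "label",
                          names_prefix = "w")
  W <- W[match(task_ids, W$task_id), ]

  get_hard <- function(m) {
    h <- tidy(inference[[m]])
    lab <- h$hard_label[match(task_ids, h$task_id)]
    if (anyNA(lab)) abort(sprintf("Inference '%s' missing some tasks.", m))
    lab
  }
  I <- lapply(need, get_hard)
  names(I) <- need

  tk <- tasks[match(task_ids, tasks$task_id), ]
  truth <- as.character(tk$true_label)

  if (binary) {
    W$w1 <- dichotomize(W$w1); W$w2 <- dichotomize(W$w2)
    W$w3 <- dichotomize(W$w3)
    I <- lapply(I, function(x) {
      if (all(x %in% MULTICLASS_ALPHABET)) dichotomize(x) else x
    })
    truth <- dichotomize(truth)
  }

  blocks <- list(
    l_1 = one_hot(W$w1, alphabet, "w1"),
    l_2 = one_hot(W$w2, alphabet, "w2"),
    l_3 = one_hot(W$w3, alphabet, "w3"),
    inference = do.call(cbind, lapply(need, function(m) {
      one_hot(I[[m]], alphabet, paste0("inf_", m))
    }))
  )
  for (field in names(META_DOMAINS)) {
    blocks[[field]] <- one_hot(as.character(tk[[field]]),
                               META_DOMAINS[[field]],
                               paste0("meta_", field))
  }
  X <- do.call(cbind, blocks)
  groups <- lapply(blocks, colnames)

  out <- dplyr::bind_cols(
    tibble::tibble(task_id = task_ids,
                   l = factor(truth, levels = alphabet)),
    tibble::as_tibble(X)
  )
  if ("tokens" %in% names(tk)) out$tokens <- tk$tokens
  attr(out, "feature_groups") <- groups
  attr(out, "alphabet") <- alphabet
  out
}

#' Balanced class weights
#'
#' `weight_c = n / (L_present * n_c)`: minority classes receive larger
#' weights; duplicating the dataset leaves weights unchanged.
#'
#' @param labels Vector of class labels (each present class needs at least
#'   one example).
#' @return Named numeric vector of per-class weights.
#' @export
#' @examples
#' class_weights(rep(c("1", "0"), c(25, 75)))
class_weights <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) abort("`labels` is empty.")
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

# Feature matrix (numeric columns only) from an assembled table.
feature_matrix <- function(table) {
  drop <- intersect(c("task_id", "l", "tokens"), names(table))
  as.matrix(table[setdiff(names(table), drop)])
}

# ---- classifier family wrappers -----------------------------------------

# Fixed, versioned hyperparameter grids per family.
family_grid <- function(family, p) {
  switch(family,
    logreg = expand.grid(decay = c(0, 0.01, 0.1, 1)),
    knn = expand.grid(k = c(3, 5, 7, 11, 15, 25)),
    svm = expand.grid(cost = c(1, 10), gamma = c(1 / p, 4 / p, 16 / p)),
    random_forest = expand.grid(mtry = pmax(1, round(c(sqrt(p), 0.3 * p))),
                                min_node = c(1, 5, 10)),
    gradient_boosted_trees = expand.grid(eta = c(0.1, 0.3),
                                         max_depth = c(2, 4, 6),
                                         nrounds = c(50, 150)),
    abort(sprintf("Unknown family '%s'.", family))
  )
}

default_hyper <- function(family, p) {
  g <- family_grid(family, p)
  as.list(g[min(2L, nrow(g)), , drop = FALSE])
}

# Fit one classifier; class weights applied through the family's loss where
# supported (logreg, svm, random_forest, xgboost) and by weighted bootstrap
# resampling for knn.
fit_learner <- function(family, x, y, hyper, seed = 1L, class_wt = NULL) {
  y <- droplevels(factor(y))
  lev <- levels(y)
  if (length(lev) < 2L) {
    # degenerate single-class training set: constant predictor
    return(structure(list(family = "constant", fit = lev, levels = lev,
                          hyper = hyper), class = "crowd_learner_fit"))
  }
  class_wt <- class_wt %||% class_weights(y)
  class_wt <- class_wt[lev]
  obj <- withr::with_seed(seed, switch(family,
    logreg = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      cw <- class_wt[as.character(y)]
      utils::capture.output(
        m <- nnet::multinom(.y ~ ., data = df, weights = cw,
                            decay = hyper$decay %||% 0.01, trace = FALSE,
                            maxit = 200, MaxNWts = 5000))
      m
    },
    knn = {
      if (max(class_wt) / min(class_wt) > 1.05) {
        pr <- class_wt[as.character(y)]
        idx <- sample.int(nrow(x), nrow(x), replace = TRUE,
                          prob = pr / sum(pr))
        x <- x[idx, , drop = FALSE]; y <- y[idx]
      }
      caret::knn3(x, y, k = hyper$k %||% 7)
    },
    svm = e1071::svm(x, y, probability = TRUE, scale = FALSE,
                     cost = hyper$cost %||% 1,
                     gamma = hyper$gamma %||% (1 / ncol(x)),
                     class.weights = class_wt, kernel = "radial"),
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = 200,
      mtry = min(hyper$mtry %||% floor(sqrt(ncol(x))), ncol(x)),
      min.node.size = hyper$min_node %||% 5,
      class.weights = as.numeric(class_wt), seed = seed, num.threads = 1L),
    gradient_boosted_trees = {
      yi <- as.integer(y) - 1L
      nc <- length(lev)
      params <- list(eta = hyper$eta %||% 0.3,
                     max_depth = hyper$max_depth %||% 4,
                     nthread = 1L)
      if (nc == 2L) {
        params$objective <- "binary:logistic"
      } else {
        params$objective <- "multi:softprob"
        params$num_class <- nc
      }
      dtr <- xgboost::xgb.DMatrix(x, label = yi,
                                  weight = class_wt[as.character(y)])
      xgboost::xgb.train(params, dtr, nrounds = hyper$nrounds %||% 50,
                         verbose = 0)
    }
  ))
  structure(list(family = family, fit = obj, levels = lev, hyper = hyper),
            class = "crowd_learner_fit")
}

# Probability matrix (n x levels) on new data.
predict_learner <- function(model, newx) {
  lev <- model$levels
  if (model$family == "constant") {
    p <- matrix(1, nrow(newx), 1L, dimnames = list(NULL, lev))
    return(p)
  }
  p <- switch(model$family,
    logreg = {
      df <- data.frame(newx, check.names = FALSE)
      pr <- stats::predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(pr))) {
        if (length(lev) == 2L) cbind(1 - pr, pr)
        else matrix(pr, nrow = 1L)
      } else pr
    },
    knn = stats::predict(model$fit, newx, type = "prob"),
    svm = {
      pr <- attr(stats::predict(model$fit, newx, probability = TRUE),
                 "probabilities")
      pr[, lev, drop = FALSE]
    },
    random_forest = stats::predict(model$fit, data = newx,
                                   num.threads = 1L)$predictions,
    gradient_boosted_trees = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(newx))
      if (length(lev) == 2L) cbind(1 - pr, pr)
      else matrix(pr, ncol = length(lev), byrow = TRUE)
    }
  )
  p <- as.matrix(p)
  colnames(p) <- lev
  p
}

predict_hard <- function(model, newx) {
  p <- predict_learner(model, newx)
  model$levels[max.col(p, ties.method = "first")]
}

#' Train and evaluate a classifier family with nested cross-validation
#'
#' Outer stratified k-fold cross-validation estimates performance; inside
#' each outer training fold a seeded randomized search over the family's
#' fixed hyperparameter grid (inner 3-fold CV, macro-F1 criterion) selects
#' hyperparameters. Class weights enter the loss where the family supports
#' them and by weighted resampling otherwise. Outer-fold metrics are
#' averaged. Fully reproducible given `seed`.
#'
#' @param table Assembled feature table from [assemble_features()] (or any
#'   tibble with factor column `l` and numeric features).
#' @param family One of `"logreg"`, `"knn"`, `"svm"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`.
#' @param cv_folds Outer folds (default 10; reduce for speed).
#' @param search_budget Randomized-search draws from the grid (default 25;
#'   capped at the grid size).
#' @param seed Integer seed.
#' @return A `crowd_learner` object: final model refit on all data with the
#'   most frequently selected hyperparameters, averaged outer metrics,
#'   per-fold metrics, and pooled outer-fold predictions.
#' @export
train_eval <- function(table, family = SUPERVISED_FAMILIES,
                       cv_folds = 10L, search_budget = 25L, seed = 1L) {
  family <- match.arg(family)
  if (cv_folds < 2L) abort("`cv_folds` must be >= 2.")
  y <- table$l
  if (min(table(y)) < cv_folds) {
    abort(sprintf(
      "Stratified %d-fold CV impossible: rarest class has %d example(s).",
      cv_folds, min(table(y))))
  }
  X <- feature_matrix(table)
  p <- ncol(X)
  grid <- family_grid(family, p)
  fold <- stratified_folds(y, cv_folds, seed = derive_seed(seed, "outer"))

  fold_out <- purrr::map(seq_len(cv_folds), function(k) {
    tr <- fold != k
    hyper <- tune_inner(family, X[tr, , drop = FALSE], y[tr], grid,
                        search_budget, derive_seed(seed, paste0("inner", k)))
    model <- fit_learner(family, X[tr, , drop = FALSE], y[tr], hyper,
                         seed = derive_seed(seed, paste0("fit", k)))
    probs <- predict_learner(model, X[!tr, , drop = FALSE])
    pred <- model$levels[max.col(probs, ties.method = "first")]
    m <- compute_metrics(as.character(y[!tr]), pred, scores = probs,
                         classes = levels(y))
    list(hyper = hyper, metrics = m,
         pred = tibble::tibble(task_id = table$task_id[!tr],
                               truth = as.character(y[!tr]), pred = pred),
         probs = probs)
  })

  fold_metrics <- purrr::map_dfr(fold_out, "metrics")
  metrics <- dplyr::summarise(fold_metrics, dplyr::across(
    c("precision", "recall", "f1", "auc_pr"), ~mean(.x, na.rm = TRUE)),
    n = sum(.data$n))
  hypers <- purrr::map(fold_out, "hyper")
  key <- vapply(hypers, function(h) paste(unlist(h), collapse = "|"),
                character(1))
  best_hyper <- hypers[[which.max(tabulate(match(key, unique(key))))[1]]]
  final <- fit_learner(family, X, y, best_hyper,
                       seed = derive_seed(seed, "final"))

  structure(list(
    family = family,
    model = final,
    metrics = metrics,
    fold_metrics = fold_metrics,
    best_hyper = best_hyper,
    predictions = purrr::map_dfr(fold_out, "pred"),
    cv_folds = cv_folds,
    search_budget = search_budget,
    seed = seed
  ), class = "crowd_learner")
}

# Inner randomized search: seeded draws from the grid, 3-fold CV, macro-F1.
tune_inner <- function(family, x, y, grid, budget, seed) {
  budget <- min(budget, nrow(grid))
  draws <- withr::with_seed(seed, sample.int(nrow(grid), budget))
  if (budget == 1L) return(as.list(grid[draws, , drop = FALSE]))
  k_in <- min(3L, min(table(y)))
  if (k_in < 2L) return(as.list(grid[draws[1], , drop = FALSE]))
  fold <- stratified_folds(y, k_in, seed = seed)
  scores <- vapply(draws, function(d) {
    hyper <- as.list(grid[d, , drop = FALSE])
    mean(vapply(seq_len(k_in), function(k) {
      tr <- fold != k
      m <- fit_learner(family, x[tr, , drop = FALSE], y[tr], hyper,
                       seed = seed + k)
      pred <- predict_hard(m, x[!tr, , drop = FALSE])
      suppressWarnings(
        compute_metrics(as.character(y[!tr]), pred,
                        classes = levels(droplevels(y)))$f1)
    }, numeric(1)))
  }, numeric(1))
  as.list(grid[draws[which.max(scores)], , drop = FALSE])
}

#' @export
print.crowd_learner <- function(x, ...) {
  cat(sprintf("<crowd_learner:%s> %d-fold CV, macro-F1 %.3f\n",
              x$family, x$cv_folds, x$metrics$f1))
  invisible(x)
}

#' @rdname tidy.crowd_inference
#' @export
tidy.crowd_learner <- function(x, ...) x$fold_metrics

#' @rdname tidy.crowd_inference
#' @export
glance.crowd_learner <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(family = x$family,
                                  cv_folds = x$cv_folds), x$metrics)
}

#' Effect of label quality on a downstream classifier
#'
#' Trains the same classifier family twice on one training split -- once
#' with reference (truth) labels, once with an alternative (for example
#' crowd-inferred or noise-injected) label set -- and evaluates both on a
#' held-out truth-labeled split, reporting the per-metric gap.
#'
#' @param table Assembled feature table (column `l` holds truth labels).
#' @param alt_labels Named character vector (by `task_id`) or vector aligned
#'   with `table` rows, giving the alternative labels.
#' @param family Classifier family as in [train_eval()].
#' @param seed Integer seed (controls the split and the fits).
#' @param holdout_frac Fraction of tasks held out for evaluation.
#' @return A tibble with one row per metric: `truth_trained`,
#'   `alt_trained`, `gap` (truth minus alternative).
#' @export
downstream_label_quality_experiment <- function(table, alt_labels,
                                                family = "logreg",
                                                seed = 1L,
                                                holdout_frac = 0.3) {
  y <- table$l
  if (!is.null(names(alt_labels))) {
    alt <- alt_labels[table$task_id]
  } else {
    if (length(alt_labels) != nrow(table)) {
      abort("`alt_labels` must be named by task_id or aligned with rows.")
    }
    alt <- as.character(alt_labels)
  }
  alt <- factor(alt, levels = levels(y))
  X <- feature_matrix(table)
  fold <- stratified_folds(y, round(1 / holdout_frac),
                           seed = derive_seed(seed, "split"))
  eval_idx <- fold == 1L
  if (sum(eval_idx) == 0L || sum(!eval_idx) == 0L) {
    abort("Degenerate train/eval split.")
  }
  hyper <- default_hyper(family, ncol(X))
  fit_eval <- function(lab) {
    m <- fit_learner(family, X[!eval_idx, , drop = FALSE],
                     droplevels(lab[!eval_idx]), hyper,
                     seed = derive_seed(seed, "fit"))
    probs <- predict_learner(m, X[eval_idx, , drop = FALSE])
    # score columns for the full alphabet (absent classes scored 0)
    full <- matrix(0, nrow(probs), nlevels(y),
                   dimnames = list(NULL, levels(y)))
    full[, colnames(probs)] <- probs
    pred <- colnames(full)[max.col(full, ties.method = "first")]
    suppressWarnings(
      compute_metrics(as.character(y[eval_idx]), pred, scores = full,
                      classes = levels(y)))
  }
  m_truth <- fit_eval(y)
  m_alt <- fit_eval(alt)
  tibble::tibble(
    metric = c("precision", "recall", "f1", "auc_pr"),
    truth_trained = as.numeric(m_truth[1, 1:4]),
    alt_trained = as.numeric(m_alt[1, 1:4]),
    gap = as.numeric(m_truth[1, 1:4]) - as.numeric(m_alt[1, 1:4])
  )
}
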