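# Pool-based active learning with uncertainty sampling: iteratively query
# the most ambivalent pool samples, add them (with their given, possibly
# noisy, labels) to the labeled set, and track held-out accuracy.

#' Uncertainty score of a posterior
#'
#' `1 - max(p)`: 0 for a certain prediction, maximal for the most
#' ambivalent one (0.5 at a 50/50 binary posterior, `1 - 1/L` at the
#' uniform L-class posterior).
#'
#' @param posterior A probability vector, or a matrix with one posterior
#'   per row.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' uncertainty_score(c(0.5, 0.5))
uncertainty_score <- function(posterior) {
  if (is.matrix(posterior)) {
    bad <- abs(rowSums(posterior) - 1) > 1e-6 | apply(posterior, 1, min) < -1e-9
    if (any(bad)) abort("Each posterior row must be a probability simplex.")
    return(1 - apply(posterior, 1, max))
  }
  if (abs(sum(posterior) - 1) > 1e-6 || any(posterior < -1e-9)) {
    abort("`posterior` must be a probability simplex.")
  }
  1 - max(posterior)
}

#' Pool-based active learning loop
#'
#' Starts from a small stratified seed set, then per iteration fits the
#' base learner on the labeled set, scores the remaining pool, moves the
#' top-`batch_size` most uncertain samples (or a random batch) into the
#' labeled set with their given labels, and records accuracy and macro-F1
#' on a fixed truth-labeled holdout never touched by querying. Queried
#' points keep their given -- possibly noisy -- labels; set
#' `oracle_labels` to supply corrected labels for contrast experiments.
#'
#' @param pool Assembled feature table whose `l` column holds the
#'   (possibly noisy) labels available to the learner.
#' @param holdout Assembled feature table whose `l` column holds truth
#'   labels, used only for evaluation.
#' @param family Base learner family (see [train_eval()]); fixed default
#'   hyperparameters are used inside the loop.
#' @param batch_size Samples queried per iteration (default 5).
#' @param n_iterations Query iterations (default 100). If the pool runs
#'   out the run stops early and is marked truncated.
#' @param strategy `"uncertainty"` or `"random"`.
#' @param seed Integer seed.
#' @param initial_frac Stratified fraction of the pool used as the seed
#'   labeled set (default 0.02); ignored when `initial_ids` given.
#' @param initial_ids Optional explicit seed-set task ids.
#' @param oracle_labels Optional named vector (by task id) of labels to
#'   assign to queried points instead of their pool labels.
#' @param mislabeled_ids Optional task ids known to be mislabeled; when
#'   given, the run reports the fraction of mislabeled points among all
#'   queried samples against their pool prevalence.
#' @return An `al_run` object with `curve` (tibble of `iteration`,
#'   `accuracy`, `macro_f1`, `mean_batch_uncertainty`,
#'   `mean_pool_uncertainty`), `queried_ids` (list per iteration),
#'   `seed_set_ids`, `truncated`, and optionally `mislabel_summary`.
#' @export
active_learn <- function(pool, holdout, family = "logreg",
                         batch_size = 5L, n_iterations = 100L,
                         strategy = c("uncertainty", "random"),
                         seed = 1L, initial_frac = 0.02,
                         initial_ids = NULL, oracle_labels = NULL,
                         mislabeled_ids = NULL) {
  strategy <- match.arg(strategy)
  check_count(batch_size, "batch_size")
  check_count(n_iterations, "n_iterations")
  ids <- pool$task_id
  X <- feature_matrix(pool)
  Xh <- feature_matrix(holdout)
  y_pool <- as.character(pool$l)
  if (!is.null(oracle_labels)) {
    y_assign <- as.character(oracle_labels[ids])
  } else {
    y_assign <- y_pool
  }
  levels_all <- levels(pool$l)
  truth_h <- as.character(holdout$l)
  hyper <- default_hyper(family, ncol(X))

  if (is.null(initial_ids)) {
    n_init <- max(length(levels_all),
                  round(initial_frac * nrow(pool)))
    fold <- stratified_folds(y_pool, max(2L, round(nrow(pool) / n_init)),
                             seed = derive_seed(seed, "al_init"))
    initial_ids <- ids[fold == 1L]
  }
  labeled <- ids %in% initial_ids
  lab_y <- ifelse(labeled, y_pool, NA_character_)

  curve <- vector("list", n_iterations + 1L)
  queried <- vector("list", n_iterations)
  truncated <- FALSE

  eval_point <- function(model, iter, batch_unc, pool_unc) {
    probs <- predict_learner(model, Xh)
    full <- matrix(0, nrow(probs), length(levels_all),
                   dimnames = list(NULL, levels_all))
    full[, colnames(probs)] <- probs
    pred <- levels_all[max.col(full, ties.method = "first")]
    m <- suppressWarnings(compute_metrics(truth_h, pred, classes = levels_all))
    tibble::tibble(iteration = iter, accuracy = mean(pred == truth_h),
                   macro_f1 = m$f1,
                   mean_batch_uncertainty = batch_unc,
                   mean_pool_uncertainty = pool_unc)
  }

  fit_current <- function(it) {
    fit_learner(family, X[labeled, , drop = FALSE],
                factor(lab_y[labeled],
                       levels = intersect(levels_all,
                                          unique(lab_y[labeled]))),
                hyper, seed = derive_seed(seed, paste0("al_fit", it)))
  }

  model <- fit_current(0L)
  curve[[1L]] <- eval_point(model, 0L, NA_real_, NA_real_)

  for (it in seq_len(n_iterations)) {
    open <- which(!labeled)
    if (length(open) == 0L) { truncated <- TRUE; break }
    b <- min(batch_size, length(open))
    if (b < batch_size) truncated <- TRUE

    probs <- predict_learner(model, X[open, , drop = FALSE])
    unc <- 1 - apply(probs, 1L, max)
    if (strategy == "uncertainty") {
      pick <- open[order(-unc, open)[seq_len(b)]]
      batch_unc <- mean(unc[match(pick, open)])
    } else {
      pick <- withr::with_seed(derive_seed(seed, paste0("al_rand", it)),
                               open[sample.int(length(open), b)])
      batch_unc <- mean(unc[match(pick, open)])
    }
    pool_unc <- mean(unc)

    labeled[pick] <- TRUE
    lab_y[pick] <- y_assign[pick]
    queried[[it]] <- ids[pick]

    model <- fit_current(it)
    curve[[it + 1L]] <- eval_point(model, it, batch_unc, pool_unc)
    if (truncated) break
  }

  res <- structure(list(
    family = family,
    strategy = strategy,
    batch_size = batch_size,
    n_iterations = n_iterations,
    curve = dplyr::bind_rows(curve),
    queried_ids = queried[!vapply(queried, is.null, logical(1))],
    seed_set_ids = initial_ids,
    truncated = truncated,
    seed = seed
  ), class = "al_run")

  if (!is.null(mislabeled_ids)) {
    q <- unlist(res$queried_ids)
    res$mislabel_summary <- tibble::tibble(
      n_queried = length(q),
      queried_mislabel_frac = mean(q %in% mislabeled_ids),
      pool_mislabel_frac = mean(ids %in% mislabeled_ids)
    )
  }
  res
}

#' @export
print.al_run <- function(x, ...) {
  cat(sprintf(
    "<al_run:%s/%s> %d iteration(s), batch %d, final accuracy %.3f%s\n",
    x$family, x$strategy, nrow(x$curve) - 1L, x$batch_size,
    dplyr::last(x$curve$accuracy), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' @rdname tidy.crowd_inference
#' @export
tidy.al_run <- function(x, ...) x$curve

#' @rdname tidy.crowd_inference
#' @export
glance.al_run <- function(x, ...) {
  tibble::tibble(
    family = x$family, strategy = x$strategy,
    n_iterations = nrow(x$curve) - 1L, batch_size = x$batch_size,
    initial_accuracy = x$curve$accuracy[1],
    final_accuracy = dplyr::last(x$curve$accuracy),
    truncated = x$truncated
  )
}
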