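# Model-agnostic local attribution by exact Shapley-value enumeration over
# feature coalitions, plus global-importance aggregation and the
# label-agreement subset analysis.

#' Exact Shapley attribution for one instance
#'
#' Computes the Shapley value of each feature group by full enumeration of
#' the `2^g` coalitions with exact Shapley weights. A coalition's value is
#' the model output averaged over the background sample with the
#' coalition's features taken from the instance and all other features from
#' the background row (marginal background averaging). One-hot columns of a
#' single categorical field should be attributed as one group.
#'
#' @param predict_fn Vectorized function mapping a feature data frame to a
#'   numeric output per row (for example a positive-class probability).
#' @param instance One-row data frame of features.
#' @param background Data frame of background rows (non-empty).
#' @param feature_groups Named list mapping group names to column names; at
#'   most 12 groups (beyond that, group features further).
#' @param chunk_size Coalitions evaluated per `predict_fn` call.
#' @return A `shapley` object: tibble `phi` (`group`, `phi`), `base_value`
#'   (mean model output over the background), and `fx` (output at the
#'   instance); `sum(phi) == fx - base_value` up to numerical error.
#' @export
exact_shapley <- function(predict_fn, instance, background, feature_groups,
                          chunk_size = 256L) {
  g <- length(feature_groups)
  if (g < 1L) abort("`feature_groups` is empty.")
  if (g > 12L) {
    abort(sprintf(
      "%d feature groups require 2^%d coalition evaluations; group related features to reach <= 12.",
      g, g))
  }
  if (is.null(names(feature_groups)) || any(names(feature_groups) == "")) {
    abort("`feature_groups` must be named.")
  }
  if (nrow(background) == 0L) abort("`background` is empty.")
  instance <- as.data.frame(instance)
  if (nrow(instance) != 1L) abort("`instance` must be a single row.")
  cols <- unlist(feature_groups, use.names = FALSE)
  missing <- setdiff(cols, names(background))
  if (length(missing) > 0L) {
    abort(sprintf("Columns not in background: %s",
                  paste(missing, collapse = ", ")))
  }

  nB <- nrow(background)
  n_coal <- 2L^g
  masks <- matrix(FALSE, n_coal, g)
  for (j in seq_len(g)) {
    masks[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }

  v <- numeric(n_coal)
  for (start in seq(1L, n_coal, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_coal)
    big <- background[rep(seq_len(nB), times = length(idx)), , drop = FALSE]
    coal_of_row <- rep(idx, each = nB)
    for (j in seq_len(g)) {
      on <- masks[coal_of_row, j]
      if (any(on)) {
        for (cn in feature_groups[[j]]) {
          big[[cn]][on] <- instance[[cn]][1]
        }
      }
    }
    out <- predict_fn(big)
    v[idx] <- rowsum(as.numeric(out), coal_of_row)[, 1] / nB
  }

  sizes <- rowSums(masks)
  lw <- lgamma(seq(0, g - 1) + 1) + lgamma(g - seq(0, g - 1)) - lgamma(g + 1)
  phi <- numeric(g)
  for (j in seq_len(g)) {
    without <- which(!masks[, j])
    s <- sizes[without]
    with_j <- without + bitwShiftL(1L, j - 1L)
    phi[j] <- sum(exp(lw[s + 1]) * (v[with_j] - v[without]))
  }

  structure(list(
    phi = tibble::tibble(group = names(feature_groups), phi = phi),
    base_value = v[1L],
    fx = v[n_coal]
  ), class = "shapley")
}

#' @export
print.shapley <- function(x, ...) {
  cat(sprintf("<shapley> f(x) = %.4f, base = %.4f\n", x$fx, x$base_value))
  print(dplyr::arrange(x$phi, dplyr::desc(abs(.data$phi))))
  invisible(x)
}

#' @rdname tidy.crowd_inference
#' @export
tidy.shapley <- function(x, ...) x$phi

#' Shapley attributions for many samples
#'
#' Runs [exact_shapley()] on each row of `samples` and stacks the results
#' into a samples x groups matrix of local Shapley values.
#'
#' @inheritParams exact_shapley
#' @param samples Data frame of instances to explain.
#' @return A numeric matrix (rows = samples, columns = groups).
#' @export
shapley_matrix <- function(predict_fn, samples, background, feature_groups) {
  out <- t(vapply(seq_len(nrow(samples)), function(i) {
    exact_shapley(predict_fn, samples[i, , drop = FALSE], background,
                  feature_groups)$phi$phi
  }, numeric(length(feature_groups))))
  colnames(out) <- names(feature_groups)
  rownames(out) <- rownames(samples)
  out
}

#' Global feature importance from local Shapley values
#'
#' Aggregates a samples x features matrix of local Shapley values into the
#' global contribution `I_j = sum_i |phi_ij|`, ranked descending with ties
#' broken by stable input order.
#'
#' @param phi A numeric matrix or data frame of local Shapley values
#'   (columns = features/groups).
#' @return A tibble (`group`, `importance`, `rank`) sorted by rank.
#' @export
global_importance <- function(phi) {
  phi <- as.matrix(phi)
  if (is.null(colnames(phi))) colnames(phi) <- paste0("f", seq_len(ncol(phi)))
  imp <- colSums(abs(phi))
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(group = colnames(phi)[ord],
                 importance = unname(imp[ord]),
                 rank = seq_along(imp))
}

#' Evaluation restricted to unanimously labeled tasks
#'
#' Restricts evaluation to tasks whose three crowd labels are unanimous and
#' reports each inference method's macro metrics on that subset alongside
#' the full set. Conditioning on full agreement screens out ambiguous
#' tasks, so subset scores are typically far higher than full-set scores.
#'
#' @param matrix A `label_matrix` (3 labels per task).
#' @param truth Tibble (`task_id`, `label`) or named vector of truth labels.
#' @param inferred Named list of `crowd_inference` objects.
#' @return A tibble with one row per (method, subset in
#'   `{unanimous, full}`): `n`, `precision`, `recall`, `f1`, `auc_pr`. When
#'   no task is unanimous the unanimous rows carry `n = 0` and `NA` metrics.
#' @export
unanimity_subset_analysis <- function(matrix, truth, inferred) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$label), truth$task_id)
  }
  unam <- matrix %>%
    dplyr::group_by(.data$task_id) %>%
    dplyr::summarise(unanimous = dplyr::n_distinct(.data$label) == 1L,
                     .groups = "drop")
  unam_ids <- unam$task_id[unam$unanimous]

  purrr::map_dfr(names(inferred), function(m) {
    h <- tidy(inferred[[m]])
    full <- suppressWarnings(
      compute_metrics(truth[h$task_id], h$hard_label,
                      scores = inferred[[m]]$posteriors,
                      classes = inferred[[m]]$alphabet))
    hs <- h[h$task_id %in% unam_ids, ]
    if (nrow(hs) == 0L) {
      sub <- tibble::tibble(precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_, auc_pr = NA_real_, n = 0L)
    } else {
      sub <- suppressWarnings(
        compute_metrics(truth[hs$task_id], hs$hard_label,
                        scores = inferred[[m]]$posteriors[
                          match(hs$task_id, h$task_id), , drop = FALSE],
                        classes = inferred[[m]]$alphabet))
    }
    dplyr::bind_rows(
      dplyr::mutate(sub, method = m, subset = "unanimous"),
      dplyr::mutate(full, method = m, subset = "full")
    )
  }) %>%
    dplyr::select("method", "subset", "n", "precision", "recall",
                  "f1", "auc_pr")
}
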