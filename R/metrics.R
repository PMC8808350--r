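# Evaluation metrics shared by the unsupervised and supervised layers:
# per-class precision/recall/F1 from confusion counts, macro averages, and
# the precision-recall area under the curve in its average-precision
# (interpolation-free step-sum) form.

# Average precision for one binary problem. `y` is 0/1, `s` a score.
# Items are grouped by unique descending threshold; AP = sum over thresholds
# of (recall step) x (precision at threshold).
average_precision <- function(y, s) {
  if (sum(y) == 0) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  grp_end <- cumsum(rle(s)$lengths)   # last index at each unique threshold
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics report
#'
#' Computes per-class precision, recall, and F1 from confusion counts, their
#' macro averages over the classes present in the truth, and the area under
#' the precision-recall curve in average-precision form. For binary problems
#' (alphabet `{0, 1}`) AUC_PR is the positive-class average precision; for
#' multiclass it is the macro one-vs-rest average. Classes absent from the
#' truth are skipped with a warning.
#'
#' @param truth Character/factor vector of true labels.
#' @param pred Character/factor vector of predicted labels.
#' @param scores Optional numeric matrix of class scores (columns named by
#'   class) or, for binary problems, a vector of positive-class scores.
#'   When missing, `auc_pr` is `NA`.
#' @param classes Optional ordered class alphabet; defaults to the classes
#'   seen in `truth` or `pred`.
#' @return A one-row tibble (`precision`, `recall`, `f1`, `auc_pr`, `n`)
#'   with the per-class table in attribute `"per_class"`.
#' @export
#' @examples
#' compute_metrics(c("1", "1", "0", "0"), c("1", "0", "0", "0"))
compute_metrics <- function(truth, pred, scores = NULL, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) abort("truth/pred lengths differ.")
  classes <- classes %||% sort(unique(c(truth, pred)))
  absent <- setdiff(classes, unique(truth))
  if (length(absent) > 0L) {
    warn(sprintf("Class(es) absent from truth skipped in macro average: %s",
                 paste(absent, collapse = ", ")))
  }
  present <- setdiff(classes, absent)

  per_class <- purrr::map_dfr(present, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    ap <- NA_real_
    if (!is.null(scores)) {
      s <- class_scores(scores, cl, classes)
      if (!is.null(s)) ap <- average_precision(as.numeric(truth == cl), s)
    }
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1,
                   auc_pr = ap)
  })

  is_binary <- setequal(classes, BINARY_ALPHABET)
  auc <- if (is.null(scores)) {
    NA_real_
  } else if (is_binary && "1" %in% per_class$class) {
    per_class$auc_pr[per_class$class == "1"]
  } else {
    mean(per_class$auc_pr)
  }
  out <- tibble::tibble(
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    f1 = mean(per_class$f1),
    auc_pr = auc,
    n = length(truth)
  )
  attr(out, "per_class") <- per_class
  out
}

# Extract the score column for one class; NULL if unavailable.
class_scores <- function(scores, cl, classes) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    if (!is.null(colnames(scores)) && cl %in% colnames(scores)) {
      return(scores[, cl])
    }
    idx <- match(cl, classes)
    if (!is.na(idx) && idx <= ncol(scores)) return(scores[, idx])
    return(NULL)
  }
  # vector: positive-class score for binary problems
  if (cl == "1") return(as.numeric(scores))
  if (cl == "0") return(1 - as.numeric(scores))
  NULL
}

#' Evaluate an inference result against known truth
#'
#' @param inference A `crowd_inference` object.
#' @param truth Tibble (`task_id`, `label`) or named character vector of
#'   true labels.
#' @return A metrics tibble as from [compute_metrics()].
#' @export
evaluate_inference <- function(inference, truth) {
  stopifnot(inherits(inference, "crowd_inference"))
  hard <- tidy(inference)
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.character(truth$label), truth$task_id)
  }
  missing <- setdiff(hard$task_id, names(truth))
  if (length(missing) > 0L) {
    abort(sprintf("Truth missing for %d task(s).", length(missing)))
  }
  tr <- truth[hard$task_id]
  compute_metrics(tr, hard$hard_label,
                  scores = inference$posteriors,
                  classes = inference$alphabet)
}
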