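# HIT validation, label-matrix construction, dichotomization, label
# consistency, worker quality reporting, and text cleaning.

#' Validate raw HIT submissions
#'
#' Applies the campaign's approval rules to a flat table of assignment
#' records (one row per worker x HIT x task). A submission (one `hit_id`,
#' `worker_id` pair) is rejected when any of its responses carries zero or
#' more than one selected choice (`"selection_count"`), when it lists the
#' same task twice (`"duplicate_task"`), or -- under the `reject_hit`
#' policy -- when its qualification answer is wrong (`"qualification"`).
#' Under the default `flag_only` policy a wrong qualification answer only
#' flags the submission (`qual_flag`), leaving worker-level consequences to
#' [worker_report()].
#'
#' A (hit, worker) group with more rows than `hit_size` indicates a corrupt
#' export (the same submission present twice) and raises an error.
#'
#' @param records Tibble with columns `hit_id`, `worker_id`, `task_id`,
#'   `choice`, `qual_answer`. A malformed selection is an `NA`/empty choice
#'   (zero selections) or a comma-joined string (multiple selections).
#' @param qual_policy `"flag_only"` (default) or `"reject_hit"`.
#' @param alphabet Valid label choices, excluding `"unclear"` which is
#'   always a valid selection here.
#' @param hit_size Maximum content responses per submission (default 3).
#' @return A list with `approved` (records plus `qual_flag`) and `rejected`
#'   (one row per rejected submission with `reason`).
#' @export
validate_hits <- function(records,
                          qual_policy = c("flag_only", "reject_hit"),
                          alphabet = MULTICLASS_ALPHABET,
                          hit_size = 3L) {
  qual_policy <- match.arg(qual_policy)
  if (nrow(records) == 0L) abort("`records` is empty.")
  valid_choices <- c(alphabet, UNCLEAR)

  grp <- dplyr::group_by(records, .data$hit_id, .data$worker_id)
  sizes <- dplyr::summarise(grp, n = dplyr::n(), .groups = "drop")
  if (any(sizes$n > hit_size)) {
    bad <- sizes[sizes$n > hit_size, ]
    abort(sprintf(
      "Corrupt export: duplicate submission(s) for %s.",
      paste(paste0(bad$hit_id, "/", bad$worker_id), collapse = ", ")))
  }

  verdict <- dplyr::summarise(
    grp,
    bad_selection = any(is.na(.data$choice) | .data$choice == "" |
                          !(.data$choice %in% valid_choices)),
    dup_task = anyDuplicated(.data$task_id) > 0L,
    qual_bad = .data$qual_answer[1] == "incorrect",
    .groups = "drop"
  )
  verdict$reason <- dplyr::case_when(
    verdict$dup_task ~ "duplicate_task",
    verdict$bad_selection ~ "selection_count",
    verdict$qual_bad & qual_policy == "reject_hit" ~ "qualification",
    TRUE ~ NA_character_
  )

  rejected <- dplyr::filter(verdict, !is.na(.data$reason)) %>%
    dplyr::select("hit_id", "worker_id", "reason")
  keep <- dplyr::filter(verdict, is.na(.data$reason)) %>%
    dplyr::select("hit_id", "worker_id", qual_flag = "qual_bad")
  approved <- dplyr::inner_join(records, keep,
                                by = c("hit_id", "worker_id"))
  list(approved = approved, rejected = rejected)
}

#' Construct a label matrix
#'
#' Builds the sparse (task, worker) -> label mapping underlying all truth
#' inference. `"unclear"` responses are dropped (when `drop_unclear`), and
#' tasks left with fewer than `required_labels` valid labels are excluded
#' and tallied. Tasks with more than `required_labels` labels (possible only
#' with irregular inputs) keep the earliest submissions.
#'
#' @param approved Approved records from [validate_hits()].
#' @param required_labels Valid labels a task must have (default 3).
#' @param drop_unclear Drop `"unclear"` responses before counting.
#' @param alphabet Ordered label alphabet.
#' @return A `label_matrix`: a tibble (`task_id`, `worker_id`, `label`) with
#'   attributes `alphabet`, `required_labels`, and `exclusions` (a tally
#'   tibble with reasons `unclear_responses_dropped` in label units and
#'   `tasks_excluded_insufficient_labels` in task units).
#' @export
build_label_matrix <- function(approved, required_labels = 3L,
                               drop_unclear = TRUE,
                               alphabet = MULTICLASS_ALPHABET) {
  df <- dplyr::select(approved, "task_id", "worker_id", label = "choice")
  n_unclear <- 0L
  if (drop_unclear) {
    n_unclear <- sum(df$label == UNCLEAR)
    df <- dplyr::filter(df, .data$label != UNCLEAR)
  }
  bad <- setdiff(unique(df$label), alphabet)
  if (length(bad) > 0L) {
    abort(sprintf("Labels outside the alphabet: %s. Run validate_hits() first.",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df[c("task_id", "worker_id")]) > 0L) {
    abort("The same (task, worker) pair appears twice; corrupt input.")
  }
  counts <- dplyr::count(df, .data$task_id)
  short <- counts$task_id[counts$n < required_labels]
  df <- dplyr::filter(df, !(.data$task_id %in% short))
  df <- df %>%
    dplyr::group_by(.data$task_id) %>%
    dplyr::slice_head(n = required_labels) %>%
    dplyr::ungroup()

  exclusions <- tibble::tibble(
    reason = c("unclear_responses_dropped",
               "tasks_excluded_insufficient_labels"),
    n = c(n_unclear, length(short))
  )
  new_label_matrix(df, alphabet = alphabet,
                   required_labels = as.integer(required_labels),
                   exclusions = exclusions)
}

new_label_matrix <- function(df, alphabet, required_labels = 3L,
                             exclusions = NULL) {
  structure(
    tibble::as_tibble(df),
    alphabet = alphabet,
    required_labels = required_labels,
    exclusions = exclusions %||%
      tibble::tibble(reason = character(), n = integer()),
    class = c("label_matrix", class(tibble::tibble()))
  )
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d labels, %d tasks, %d workers, alphabet {%s}\n",
              nrow(x), dplyr::n_distinct(x$task_id),
              dplyr::n_distinct(x$worker_id),
              paste(attr(x, "alphabet"), collapse = ", ")))
  NextMethod()
}

#' Label-matrix attribute accessors
#'
#' @param matrix A `label_matrix`.
#' @return `lm_alphabet()` the ordered alphabet; `lm_exclusions()` the
#'   exclusion tally recorded by [build_label_matrix()].
#' @export
lm_alphabet <- function(matrix) attr(matrix, "alphabet")

#' @rdname lm_alphabet
#' @export
lm_exclusions <- function(matrix) attr(matrix, "exclusions")

#' Dichotomize multiclass labels
#'
#' The binary label is 1 when both underlying conditions are met (`"11"`)
#' and 0 otherwise. `"unclear"` must have been dropped upstream and is an
#' error here.
#'
#' @param label Character vector over `{11, 10, 01, 00}`.
#' @return Character vector over `{"0", "1"}`.
#' @export
#' @examples
#' dichotomize(c("11", "10", "00"))
dichotomize <- function(label) {
  if (any(label == UNCLEAR, na.rm = TRUE)) {
    abort("\"unclear\" labels must be dropped before dichotomization.")
  }
  if (any(!label %in% MULTICLASS_ALPHABET)) {
    abort("Labels must be in {11, 10, 01, 00}.")
  }
  ifelse(label == "11", "1", "0")
}

#' Binary view of a label matrix
#'
#' @param matrix A multiclass `label_matrix`.
#' @return A `label_matrix` over the alphabet `{0, 1}`.
#' @export
binarize_matrix <- function(matrix) {
  df <- matrix
  df$label <- dichotomize(df$label)
  new_label_matrix(df[c("task_id", "worker_id", "label")],
                   alphabet = BINARY_ALPHABET,
                   required_labels = attr(matrix, "required_labels"),
                   exclusions = attr(matrix, "exclusions"))
}

#' Label consistency (LC)
#'
#' Scores inter-annotator consistency per category as one minus the
#' normalized mean entropy of each task's label counts. With 3 labels per
#' task, a task's entropy is `H = -sum_j (n_j/3) log(n_j/3)` over its chosen
#' labels and is normalized by `log(3)`, the maximum achievable with three
#' annotators; LC is the mean of `1 - H/log(3)` over tasks. LC is 1 when
#' every task is unanimous and 0 when every task's three labels all differ.
#'
#' @param matrix A `label_matrix` where every task has exactly the required
#'   number of labels (3).
#' @param categories Optional tibble (`task_id`, `category`) to score per
#'   category; when `NULL` all tasks form one `"all"` category.
#' @return A tibble with `category`, `lc_value`, `n_tasks`.
#' @export
label_consistency <- function(matrix, categories = NULL) {
  req <- attr(matrix, "required_labels") %||% 3L
  counts <- dplyr::count(matrix, .data$task_id, name = "n_labels")
  if (any(counts$n_labels != req)) {
    abort(sprintf("Every task must have exactly %d labels.", req))
  }
  per_task <- matrix %>%
    dplyr::count(.data$task_id, .data$label) %>%
    dplyr::group_by(.data$task_id) %>%
    dplyr::summarise(
      consistency = {
        p <- .data$n / req
        1 - (-sum(p * log(p))) / log(req)
      },
      .groups = "drop"
    )
  if (is.null(categories)) {
    categories <- tibble::tibble(task_id = per_task$task_id,
                                 category = "all")
  }
  per_task %>%
    dplyr::inner_join(categories, by = "task_id") %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(lc_value = mean(.data$consistency),
                     n_tasks = dplyr::n(), .groups = "drop")
}

#' Per-worker quality report
#'
#' Summarizes each worker's volume, qualification-failure rate (when
#' assignment records are supplied), agreement with the majority-vote label,
#' and accuracy against reference labels when available. Workers whose
#' majority agreement falls below `agreement_threshold` are flagged for
#' access revocation, except when their volume is below `min_volume` labels
#' (too little evidence).
#'
#' @param matrix A `label_matrix`.
#' @param reference Optional tibble (`task_id`, `label`) of reference labels.
#' @param assignments Optional raw records carrying `qual_answer`.
#' @param agreement_threshold Flag threshold on majority agreement.
#' @param min_volume Minimum labels before a flag can fire.
#' @param seed Seed for majority-vote tie-breaking.
#' @return A tibble per worker: `worker_id`, `n_labels`, `qual_fail_rate`,
#'   `mv_agreement`, `accuracy`, `flagged`.
#' @export
worker_report <- function(matrix, reference = NULL, assignments = NULL,
                          agreement_threshold = 0.5, min_volume = 9L,
                          seed = 1L) {
  mv <- majority_vote(matrix, tie_policy = "random_seeded", seed = seed)
  mv_labels <- tidy(mv)[c("task_id", "hard_label")]

  rep <- matrix %>%
    dplyr::left_join(mv_labels, by = "task_id") %>%
    dplyr::group_by(.data$worker_id) %>%
    dplyr::summarise(
      n_labels = dplyr::n(),
      mv_agreement = mean(.data$label == .data$hard_label),
      .groups = "drop"
    )
  if (!is.null(reference)) {
    acc <- matrix %>%
      dplyr::inner_join(dplyr::rename(reference, ref = "label"),
                        by = "task_id") %>%
      dplyr::group_by(.data$worker_id) %>%
      dplyr::summarise(accuracy = mean(.data$label == .data$ref),
                       .groups = "drop")
    rep <- dplyr::left_join(rep, acc, by = "worker_id")
  } else {
    rep$accuracy <- NA_real_
  }
  if (!is.null(assignments)) {
    qf <- assignments %>%
      dplyr::distinct(.data$hit_id, .data$worker_id, .data$qual_answer) %>%
      dplyr::group_by(.data$worker_id) %>%
      dplyr::summarise(qual_fail_rate = mean(.data$qual_answer == "incorrect"),
                       .groups = "drop")
    rep <- dplyr::left_join(rep, qf, by = "worker_id")
  } else {
    rep$qual_fail_rate <- NA_real_
  }
  rep$flagged <- rep$mv_agreement < agreement_threshold &
    rep$n_labels >= min_volume
  dplyr::select(rep, "worker_id", "n_labels", "qual_fail_rate",
                "mv_agreement", "accuracy", "flagged")
}

# Fixed contraction table applied before character stripping.
CONTRACTIONS <- c(
  "i'll" = "i will", "i'm" = "i am", "i've" = "i have", "i'd" = "i would",
  "you'll" = "you will", "you're" = "you are", "you've" = "you have",
  "you'd" = "you would", "he'll" = "he will", "he's" = "he is",
  "he'd" = "he would", "she'll" = "she will", "she's" = "she is",
  "she'd" = "she would", "it'll" = "it will", "it's" = "it is",
  "we'll" = "we will", "we're" = "we are", "we've" = "we have",
  "we'd" = "we would", "they'll" = "they will", "they're" = "they are",
  "they've" = "they have", "they'd" = "they would", "that's" = "that is",
  "there's" = "there is", "what's" = "what is", "who's" = "who is",
  "can't" = "cannot", "won't" = "will not", "don't" = "do not",
  "doesn't" = "does not", "didn't" = "did not", "isn't" = "is not",
  "aren't" = "are not", "wasn't" = "was not", "weren't" = "were not",
  "haven't" = "have not", "hasn't" = "has not", "couldn't" = "could not",
  "shouldn't" = "should not", "wouldn't" = "would not", "let's" = "let us"
)

#' Clean and tokenize task text
#'
#' Applies the campaign's cleaning rules: expand a fixed table of common
#' English contractions (case-insensitively, preserving the first
#' character's case), then remove weblinks, digits, and the characters
#' `#`, `&`, `@` and other punctuation. `#` and `@` are stripped in place so
#' hashtag/mention word content survives; separator punctuation becomes a
#' token boundary. Case is preserved and no stop words are removed.
#'
#' @param raw Character vector of raw texts.
#' @return A list of character token vectors, one per input element.
#' @export
#' @examples
#' clean_text("I'll run 5k http://t.co/x")[[1]]
clean_text <- function(raw) {
  lapply(raw, function(x) {
    if (is.na(x) || x == "") return(character(0))
    # weblinks first
    x <- stringr::str_replace_all(x, "(https?://|www\\.)\\S+", " ")
    # contractions (match case-insensitively on word boundaries)
    for (i in seq_along(CONTRACTIONS)) {
      pat <- stringr::regex(paste0("\\b", stringr::str_replace(
        names(CONTRACTIONS)[i], stringr::fixed("'"), "['’]"), "\\b"),
        ignore_case = TRUE)
      x <- stringr::str_replace_all(x, pat, function(m) {
        rep <- CONTRACTIONS[[i]]
        if (substr(m, 1, 1) == toupper(substr(m, 1, 1)) &&
            grepl("^[A-Za-z]", m)) {
          rep <- paste0(toupper(substr(rep, 1, 1)), substr(rep, 2, nchar(rep)))
        }
        rep
      })
    }
    # strip in place: digits, #, @, apostrophes
    x <- stringr::str_replace_all(x, "[0-9#@'’]", "")
    # remaining punctuation/specials become separators
    x <- stringr::str_replace_all(x, "[^\\p{L}\\p{M}\\p{So}\\s]", " ")
    tokens <- stringr::str_split(stringr::str_squish(x), " ")[[1]]
    tokens[tokens != ""]
  })
}
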