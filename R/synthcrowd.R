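# Synthetic crowd-labeling simulator.
#
# Emulates the statistical structure of a microtask labeling campaign on a
# platform such as Amazon Mechanical Turk: HITs of 3 content tasks plus one
# qualification question, each HIT answered by 3 workers, a heavy-tailed
# distribution of per-worker activity, a small fraction of spammer and
# adversarial workers, and task metadata whose association with the true
# class is controlled by a single informativeness dial.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic crowd-labeling
#' generator. The defaults emulate a three-category public-health
#' surveillance labeling campaign: every task carries one of four true
#' classes built from two binary conditions (self-reported, recent), each
#' task is labeled by 3 workers, workers may answer `"unclear"`, and worker
#' activity follows a heavy-tailed (Pareto) law so that most workers complete
#' few HITs while a handful complete very many.
#'
#' @param n_tasks_per_category Number of tasks per surveillance category;
#'   either one count (recycled) or one per category.
#' @param n_workers Number of workers in the pool.
#' @param labels_per_task Distinct workers assigned to each HIT (default 3).
#' @param class_prevalences Named simplex over the label alphabet; names
#'   define the alphabet (default the four-class scheme `11,10,01,00`).
#' @param worker_quality_range Interval for reliable workers' per-class
#'   accuracy (confusion-matrix diagonal), each drawn uniformly.
#' @param spammer_fraction Fraction of workers answering uniformly at random.
#' @param adversarial_fraction Fraction of workers whose answers concentrate
#'   off the true label (negative ability in the logistic noise model).
#' @param meta_informativeness Strength (>= 0) of the class-to-metadata
#'   association; 0 makes metadata independent of the true class.
#' @param activity_tail_exponent Pareto tail exponent for activity weights;
#'   smaller means heavier tail.
#' @param noise_mode `"confusion"` (per-worker confusion matrix) or `"glad"`
#'   (logistic worker-ability x task-clarity correctness model).
#' @param p_unclear Probability a reliable worker answers `"unclear"`.
#' @param p_qual_fail Probability a reliable worker fails the qualification
#'   question; spammers use `spammer_p_qual_fail`.
#' @param spammer_p_qual_fail Qualification failure probability for spammers.
#' @param beta_meanlog,beta_sdlog Log-normal parameters for task clarity
#'   `beta` (difficulty is `1/beta`).
#' @param seed Integer seed; all generator stages are deterministic given it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_tasks_per_category = 30, n_workers = 20, seed = 1)
#' tasks <- generate_tasks(cfg)
sim_config <- function(n_tasks_per_category = 300,
                       n_workers = 120,
                       labels_per_task = 3,
                       class_prevalences = c("11" = 0.38, "10" = 0.20,
                                             "01" = 0.03, "00" = 0.39),
                       worker_quality_range = c(0.60, 0.95),
                       spammer_fraction = 0.05,
                       adversarial_fraction = 0.02,
                       meta_informativeness = 1,
                       activity_tail_exponent = 1.1,
                       noise_mode = c("confusion", "glad"),
                       p_unclear = 0.03,
                       p_qual_fail = 0.02,
                       spammer_p_qual_fail = 0.25,
                       beta_meanlog = 0,
                       beta_sdlog = 0.7,
                       seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  check_count(n_tasks_per_category, "n_tasks_per_category")
  if (!length(n_tasks_per_category) %in% c(1L, length(PASS_CATEGORIES))) {
    abort("`n_tasks_per_category` must have length 1 or one per category.")
  }
  check_count(n_workers, "n_workers")
  check_count(labels_per_task, "labels_per_task")
  if (is.null(names(class_prevalences)) || any(names(class_prevalences) == "")) {
    abort("`class_prevalences` must be named by label.")
  }
  if (any(class_prevalences < 0)) {
    abort("`class_prevalences` has a negative entry.")
  }
  check_simplex(class_prevalences, "class_prevalences")
  if (length(worker_quality_range) != 2L ||
      any(!is.finite(worker_quality_range)) ||
      worker_quality_range[1] > worker_quality_range[2] ||
      worker_quality_range[1] <= 0 || worker_quality_range[2] > 1) {
    abort("`worker_quality_range` must be an interval [lo, hi] inside (0, 1].")
  }
  check_prob(spammer_fraction, "spammer_fraction")
  check_prob(adversarial_fraction, "adversarial_fraction")
  if (spammer_fraction + adversarial_fraction > 1) {
    abort("spammer_fraction + adversarial_fraction must be <= 1.")
  }
  if (meta_informativeness < 0) abort("`meta_informativeness` must be >= 0.")
  if (activity_tail_exponent <= 0) abort("`activity_tail_exponent` must be > 0.")
  check_prob(p_unclear, "p_unclear")
  check_prob(p_qual_fail, "p_qual_fail")
  check_prob(spammer_p_qual_fail, "spammer_p_qual_fail")
  if (beta_sdlog < 0) abort("`beta_sdlog` must be >= 0.")

  structure(list(
    n_tasks_per_category = rep_len(as.integer(n_tasks_per_category),
                                   length(PASS_CATEGORIES)),
    n_workers = as.integer(n_workers),
    labels_per_task = as.integer(labels_per_task),
    class_prevalences = class_prevalences,
    alphabet = names(class_prevalences),
    worker_quality_range = worker_quality_range,
    spammer_fraction = spammer_fraction,
    adversarial_fraction = adversarial_fraction,
    meta_informativeness = meta_informativeness,
    activity_tail_exponent = activity_tail_exponent,
    noise_mode = noise_mode,
    p_unclear = p_unclear,
    p_qual_fail = p_qual_fail,
    spammer_p_qual_fail = spammer_p_qual_fail,
    beta_meanlog = beta_meanlog,
    beta_sdlog = beta_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Ability alpha chosen so that at median task clarity (beta = 1) the logistic
# correctness probability equals the worker's diagonal accuracy.
accuracy_to_alpha <- function(acc) stats::qlogis(pmin(pmax(acc, 1e-6), 1 - 1e-6))

#' Generate the worker pool
#'
#' Draws `n_workers` worker specifications. Reliable workers get a diagonal
#' confusion-matrix accuracy uniform in `worker_quality_range` with the
#' remaining mass spread evenly over wrong labels, and a matching positive
#' ability `ability_alpha`. Spammers answer uniformly (every confusion row
#' `1/L`, ability 0); adversarial workers concentrate mass off the diagonal
#' (negative ability). Activity weights follow a Pareto law with the
#' configured tail exponent, reproducing the empirical pattern that most
#' workers complete few HITs while a few complete thousands.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per worker: `worker_id`, `kind`
#'   (`reliable`/`spammer`/`adversarial`), `accuracy`, `ability_alpha`,
#'   `activity_weight`, `p_unclear`, `p_qual_fail`, and a `confusion`
#'   list-column of row-stochastic L x L matrices.
#' @export
generate_workers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- length(config$alphabet)
  n <- config$n_workers
  n_spam <- round(config$spammer_fraction * n)
  n_adv <- round(config$adversarial_fraction * n)
  if (n_spam + n_adv > n) n_adv <- n - n_spam
  n_rel <- n - n_spam - n_adv

  withr::with_seed(derive_seed(config$seed, "workers"), {
    kind <- sample(c(rep("spammer", n_spam), rep("adversarial", n_adv),
                     rep("reliable", n_rel)))
    acc <- numeric(n)
    acc[kind == "reliable"] <- stats::runif(n_rel,
                                            config$worker_quality_range[1],
                                            config$worker_quality_range[2])
    acc[kind == "spammer"] <- 1 / L
    # adversarial: almost never report the truth
    acc[kind == "adversarial"] <- stats::runif(n_adv, 0.02, 0.10)

    alpha <- numeric(n)
    alpha[kind == "reliable"] <- accuracy_to_alpha(acc[kind == "reliable"])
    alpha[kind == "spammer"] <- 0
    alpha[kind == "adversarial"] <- stats::runif(n_adv, -2.5, -0.75)

    # Pareto(x_m = 1, shape = a) via inverse CDF.
    activity <- stats::runif(n)^(-1 / config$activity_tail_exponent)

    confusion <- lapply(seq_len(n), function(i) {
      d <- acc[i]
      m <- matrix((1 - d) / (L - 1), L, L,
                  dimnames = list(config$alphabet, config$alphabet))
      diag(m) <- d
      m
    })

    tibble::tibble(
      worker_id = sprintf("w%04d", seq_len(n)),
      kind = kind,
      accuracy = acc,
      ability_alpha = alpha,
      activity_weight = activity,
      p_unclear = config$p_unclear,
      p_qual_fail = ifelse(kind == "spammer", config$spammer_p_qual_fail,
                           config$p_qual_fail),
      confusion = confusion
    )
  })
}

# Per-category keyword bags used only to exercise text cleaning downstream.
CATEGORY_KEYWORDS <- list(
  physical_activity = c("run", "gym", "workout", "bike", "steps",
                        "marathon", "training", "fitness"),
  sedentary_behavior = c("couch", "netflix", "sitting", "desk", "binge",
                         "gaming", "screen", "chair"),
  sleep_quality = c("sleep", "insomnia", "nap", "tired", "dream",
                    "awake", "bed", "rest")
)
NOISE_WORDS <- c("today", "lol", "really", "just", "time", "day",
                 "week", "good", "new", "going")

# Base marginal metadata distributions (loosely realistic for tweets).
meta_base_marginals <- function() {
  daytime <- stats::dnorm(0:23, mean = 14, sd = 5)
  list(
    daytime = daytime / sum(daytime),
    weekday = rep(1 / 7, 7),
    month = rep(1 / 12, 12),
    gender = c(0.28, 0.42, 0.30),
    age_group = c(0.06, 0.18, 0.18, 0.26, 0.32),
    source = c(0.10, 0.90)
  )
}

#' Generate tasks with known ground truth
#'
#' Draws tasks for each surveillance category. True labels come from the
#' configured class prevalences; clarity `beta` is log-normal (difficulty is
#' `1/beta`); each metadata field is drawn from a class-conditional
#' categorical distribution produced by exponentially tilting the field's
#' base marginal with per-class scores scaled by `meta_informativeness`
#' (0 gives metadata independent of class). A small keyword-bag `tokens`
#' string is attached to exercise text cleaning.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per task: `task_id`, `category`,
#'   `true_label`, `beta`, metadata columns (`daytime`, `weekday`, `month`,
#'   `gender`, `age_group`, `source`) and `tokens`.
#' @export
generate_tasks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- length(config$alphabet)
  n_cat <- config$n_tasks_per_category
  n <- sum(n_cat)
  base <- meta_base_marginals()

  withr::with_seed(derive_seed(config$seed, "tasks"), {
    category <- rep(PASS_CATEGORIES, times = n_cat)
    true_label <- sample(config$alphabet, n, replace = TRUE,
                         prob = config$class_prevalences)
    beta <- stats::rlnorm(n, config$beta_meanlog, config$beta_sdlog)

    # Class-conditional tilt scores, one per (field, class, value).
    lambda <- config$meta_informativeness
    meta <- lapply(names(META_DOMAINS), function(field) {
      p0 <- base[[field]]
      nv <- length(p0)
      scores <- matrix(stats::rnorm(L * nv), L, nv)
      P <- t(vapply(seq_len(L), function(c) {
        q <- p0 * exp(lambda * scores[c, ])
        q / sum(q)
      }, numeric(nv)))
      cls <- match(true_label, config$alphabet)
      u <- stats::runif(n)
      cum <- t(apply(P, 1L, cumsum))
      idx <- rowSums(u > cum[cls, , drop = FALSE]) + 1L
      META_DOMAINS[[field]][idx]
    })
    names(meta) <- names(META_DOMAINS)

    tokens <- vapply(seq_len(n), function(i) {
      kw <- CATEGORY_KEYWORDS[[category[i]]]
      nk <- sample(2:4, 1)
      nn <- sample(2:4, 1)
      paste(c(sample(kw, nk), sample(NOISE_WORDS, nn)), collapse = " ")
    }, character(1))

    tibble::tibble(
      task_id = sprintf("t%05d", seq_len(n)),
      category = category,
      true_label = true_label,
      beta = beta,
      daytime = meta$daytime,
      weekday = meta$weekday,
      month = meta$month,
      gender = meta$gender,
      age_group = meta$age_group,
      source = meta$source,
      tokens = tokens
    )
  })
}

#' Simulate workers labeling HITs
#'
#' Groups tasks into HITs of 3 within each category (a final smaller HIT is
#' allowed when the category count is not a multiple of 3), assigns each HIT
#' to `labels_per_task` distinct workers sampled without replacement with
#' probability proportional to activity weight, and draws each worker's
#' choice for every task in the HIT plus a qualification answer.
#'
#' In `"confusion"` mode the choice is drawn from the worker's confusion-
#' matrix row for the task's true label; in `"glad"` mode the worker answers
#' correctly with probability `plogis(alpha * beta)` and otherwise picks a
#' uniformly random wrong label. Either way the worker first answers
#' `"unclear"` with their `p_unclear`.
#'
#' @param tasks Tibble from [generate_tasks()] (needs `task_id`, `category`,
#'   `true_label`, `beta`).
#' @param workers Tibble from [generate_workers()].
#' @param config A [sim_config()].
#' @return A tibble of assignment records: `hit_id`, `worker_id`, `task_id`,
#'   `choice`, `qual_answer` (`"correct"`/`"incorrect"`).
#' @export
simulate_labeling <- function(tasks, workers, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$labels_per_task > nrow(workers)) {
    abort("labels_per_task exceeds the number of workers.")
  }
  L <- length(config$alphabet)

  withr::with_seed(derive_seed(config$seed, "labeling"), {
    # HIT grouping: consecutive triples within category.
    tasks <- dplyr::arrange(tasks, .data$category, .data$task_id)
    grp <- unlist(lapply(split(seq_len(nrow(tasks)), tasks$category),
                         function(idx) ceiling(seq_along(idx) / 3)))
    hit_key <- paste(tasks$category, grp, sep = "/")
    hit_id <- sprintf("h%05d", match(hit_key, unique(hit_key)))
    n_hits <- length(unique(hit_id))
    hit_of_task <- match(hit_id, unique(hit_id))

    # labels_per_task workers per HIT, weighted without replacement.
    w_per_hit <- lapply(seq_len(n_hits), function(h) {
      sample_weighted(nrow(workers), config$labels_per_task,
                      workers$activity_weight)
    })

    tasks_by_hit <- split(seq_len(nrow(tasks)), hit_of_task)
    rows <- lapply(seq_len(n_hits), function(h) {
      ti <- tasks_by_hit[[h]]
      wi <- w_per_hit[[h]]
      expand.grid(w = wi, t = ti, KEEP.OUT.ATTRS = FALSE)
    })
    rows <- do.call(rbind, rows)
    w <- rows$w
    t_idx <- rows$t
    nobs <- nrow(rows)

    truth_idx <- match(tasks$true_label[t_idx], config$alphabet)
    choice <- character(nobs)

    u_unclear <- stats::runif(nobs)
    is_unclear <- u_unclear < workers$p_unclear[w]

    if (config$noise_mode == "confusion") {
      # cumulative confusion rows per (worker, truth) pair
      pair <- (w - 1L) * L + truth_idx
      upairs <- sort(unique(pair))
      cum <- t(vapply(upairs, function(p) {
        wk <- (p - 1L) %/% L + 1L
        tr <- (p - 1L) %% L + 1L
        cumsum(workers$confusion[[wk]][tr, ])
      }, numeric(L)))
      u <- stats::runif(nobs)
      li <- rowSums(u > cum[match(pair, upairs), , drop = FALSE]) + 1L
      choice <- config$alphabet[li]
    } else {
      p_corr <- stats::plogis(workers$ability_alpha[w] * tasks$beta[t_idx])
      u <- stats::runif(nobs)
      correct <- u < p_corr
      wrong_off <- sample.int(L - 1L, nobs, replace = TRUE)
      li <- ifelse(correct, truth_idx,
                   ((truth_idx - 1L + wrong_off) %% L) + 1L)
      choice <- config$alphabet[li]
    }
    choice[is_unclear] <- UNCLEAR

    # qualification answer per (hit, worker)
    hw <- paste(hit_id[t_idx], w)
    uh <- !duplicated(hw)
    qual_fail_hw <- stats::runif(sum(uh)) < workers$p_qual_fail[w[uh]]
    qual <- ifelse(qual_fail_hw[match(hw, hw[uh])], "incorrect", "correct")

    out <- tibble::tibble(
      hit_id = hit_id[t_idx],
      worker_id = workers$worker_id[w],
      task_id = tasks$task_id[t_idx],
      choice = choice,
      qual_answer = qual
    )
    dplyr::arrange(out, .data$hit_id, .data$worker_id, .data$task_id)
  })
}

#' Write and read simulator outputs
#'
#' Tasks round-trip through a plain CSV; assignments through JSONL with one
#' record per (worker, HIT) holding the per-task choices and the
#' qualification answer.
#'
#' @param tasks,assignments Tibbles as produced by the generator.
#' @param path File path.
#' @return The input (writers, invisibly) or the re-read tibble (readers).
#' @export
write_tasks <- function(tasks, path) {
  readr::write_csv(tasks, path)
  invisible(tasks)
}

#' @rdname write_tasks
#' @export
read_tasks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    daytime = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname write_tasks
#' @export
write_assignments <- function(assignments, path) {
  recs <- assignments %>%
    dplyr::group_by(.data$hit_id, .data$worker_id) %>%
    dplyr::summarise(
      qual_answer = .data$qual_answer[1],
      responses = list(purrr::map2(.data$task_id, .data$choice,
                                   ~list(task_id = .x, choice = .y))),
      .groups = "drop"
    )
  lines <- purrr::pmap_chr(recs, function(hit_id, worker_id, qual_answer,
                                          responses) {
    jsonlite::toJSON(list(hit_id = hit_id, worker_id = worker_id,
                          qual_answer = qual_answer, responses = responses),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(assignments)
}

#' @rdname write_tasks
#' @export
read_assignments <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    tibble::tibble(
      hit_id = rec$hit_id,
      worker_id = rec$worker_id,
      task_id = purrr::map_chr(rec$responses, function(r) r$task_id %||% NA_character_),
      choice = purrr::map_chr(rec$responses, function(r) {
        ch <- r$choice
        if (is.null(ch)) NA_character_ else as.character(ch)
      }),
      qual_answer = rec$qual_answer
    )
  })
}
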