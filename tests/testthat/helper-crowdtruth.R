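# Shared fixture builders and independent oracles.

# Build a label_matrix from a list of per-task label vectors.
make_matrix <- function(label_list, alphabet = crowdtruth:::MULTICLASS_ALPHABET) {
  df <- purrr::imap_dfr(label_list, function(labs, i) {
    tibble::tibble(task_id = sprintf("t%03d", i),
                   worker_id = sprintf("w%03d", seq_along(labs)),
                   label = labs)
  })
  crowdtruth:::new_label_matrix(df, alphabet = alphabet)
}

# Random label matrix: n_tasks x 3 labels drawn uniformly, workers drawn
# from a fixed pool.
random_matrix <- function(n_tasks, n_workers = 20,
                          alphabet = crowdtruth:::MULTICLASS_ALPHABET,
                          seed = 1) {
  withr::with_seed(seed, {
    df <- purrr::map_dfr(seq_len(n_tasks), function(i) {
      tibble::tibble(task_id = sprintf("t%04d", i),
                     worker_id = sprintf("w%03d",
                                         sample.int(n_workers, 3)),
                     label = sample(alphabet, 3, replace = TRUE))
    })
    crowdtruth:::new_label_matrix(df, alphabet = alphabet)
  })
}

# Worker tibble with explicit confusion matrices (binary or multiclass).
make_workers <- function(confusions, alphabet, p_unclear = 0,
                         p_qual_fail = 0) {
  L <- length(alphabet)
  tibble::tibble(
    worker_id = sprintf("w%04d", seq_along(confusions)),
    kind = "custom",
    accuracy = vapply(confusions, function(m) mean(diag(m)), numeric(1)),
    ability_alpha = 0,
    activity_weight = 1,
    p_unclear = p_unclear,
    p_qual_fail = p_qual_fail,
    confusion = lapply(confusions, function(m) {
      dimnames(m) <- list(alphabet, alphabet)
      m
    })
  )
}

diag_confusion <- function(acc, L) {
  m <- matrix((1 - acc) / (L - 1), L, L)
  diag(m) <- acc
  m
}

# Brute-force mode-count oracle for majority vote over one label multiset.
mode_oracle <- function(labels, alphabet) {
  counts <- vapply(alphabet, function(a) sum(labels == a), numeric(1))
  winners <- alphabet[counts == max(counts)]
  list(modes = winners, tie = length(winners) > 1L)
}

# Brute-force per-class confusion-count metrics oracle.
metrics_oracle <- function(truth, pred, classes) {
  rows <- lapply(classes, function(cl) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    c(precision = pr, recall = rc, f1 = f1)
  })
  colMeans(do.call(rbind, rows))
}

# Permutation-averaging Shapley oracle: average marginal contribution of
# each group over all g! orderings (g <= 6).
shapley_permutation_oracle <- function(predict_fn, instance, background,
                                       feature_groups) {
  g <- length(feature_groups)
  stopifnot(g <= 6)
  perms <- gtools_permutations(g)
  coal_value <- function(on) {
    df <- background
    for (j in which(on)) {
      for (cn in feature_groups[[j]]) df[[cn]] <- instance[[cn]][1]
    }
    mean(predict_fn(df))
  }
  phi <- numeric(g)
  for (r in seq_len(nrow(perms))) {
    on <- rep(FALSE, g)
    v_prev <- coal_value(on)
    for (j in perms[r, ]) {
      on[j] <- TRUE
      v_new <- coal_value(on)
      phi[j] <- phi[j] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / nrow(perms)
}

# All permutations of 1:n (small n).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Small simulated study: tasks, workers, assignments, matrix, truth.
small_study <- function(seed = 1, n_per_cat = 100, n_workers = 60, ...) {
  cfg <- sim_config(n_tasks_per_category = n_per_cat, n_workers = n_workers,
                    seed = seed, ...)
  tasks <- generate_tasks(cfg)
  workers <- generate_workers(cfg)
  asg <- simulate_labeling(tasks, workers, cfg)
  qc <- validate_hits(asg)
  mat <- build_label_matrix(qc$approved)
  list(cfg = cfg, tasks = tasks, workers = workers, assignments = asg,
       qc = qc, matrix = mat,
       truth = stats::setNames(tasks$true_label, tasks$task_id))
}
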