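# End-to-end orchestration: simulate -> QC -> four unsupervised inferences
# -> supervised train/eval -> active learning -> attribution, with one
# global seed deterministically deriving every stage seed, and a plain-text
# report bundle (CSV/JSON) that byte-reproduces under the same seed.

#' Experiment configuration
#'
#' One validated configuration object for [run_experiment()]. A single
#' global `seed` deterministically derives every stage's seed, so a full
#' run is reproducible from one integer.
#'
#' @param sim A [sim_config()]; its seed is overridden by the derived
#'   simulation stage seed.
#' @param qual_policy HIT qualification policy (see [validate_hits()]).
#' @param required_labels Valid labels per task (see
#'   [build_label_matrix()]).
#' @param em An [em_settings()] shared by the EM methods.
#' @param families Supervised families to train.
#' @param cv_folds,search_budget Nested-CV controls (see [train_eval()]).
#' @param al_family,al_batch_size,al_iterations,al_strategy Active-learning
#'   controls (see [active_learn()]).
#' @param shap_background,shap_samples Background size and number of
#'   explained samples for attribution.
#' @param seed Global integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              qual_policy = "flag_only",
                              required_labels = 3L,
                              em = em_settings(),
                              families = SUPERVISED_FAMILIES,
                              cv_folds = 3L,
                              search_budget = 5L,
                              al_family = "logreg",
                              al_batch_size = 5L,
                              al_iterations = 100L,
                              al_strategy = "uncertainty",
                              shap_background = 100L,
                              shap_samples = 40L,
                              seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(em, "em_settings"))
  families <- match.arg(families, SUPERVISED_FAMILIES, several.ok = TRUE)
  sim$seed <- derive_seed(seed, "sim")
  structure(list(
    sim = sim, qual_policy = qual_policy,
    required_labels = as.integer(required_labels),
    em = em, families = families,
    cv_folds = as.integer(cv_folds),
    search_budget = as.integer(search_budget),
    al_family = al_family, al_batch_size = as.integer(al_batch_size),
    al_iterations = as.integer(al_iterations), al_strategy = al_strategy,
    shap_background = as.integer(shap_background),
    shap_samples = as.integer(shap_samples),
    seed = as.integer(seed)
  ), class = "experiment_config")
}

# Out-of-scope deep-learning comparison rows kept as table placeholders so
# the report layout matches the 11-method comparison protocol.
PLACEHOLDER_METHODS <- c("dl_meta", "dl_text_and_meta")

#' Run a full experiment
#'
#' Simulates a crowd-labeling campaign, validates HITs, builds per-category
#' label matrices, runs the four unsupervised inference methods and the
#' supervised families on both multiclass and binary views, evaluates
#' everything against the known ground truth, runs pool-based active
#' learning on the pooled binary problem, computes Shapley attributions and
#' global importance for a trained classifier, and (optionally) writes a
#' plain-text report bundle. Two runs with the same config produce
#' byte-identical bundles.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for the report bundle (created if
#'   needed): `metrics.csv`, `lc.csv`, `al_curve.csv`, `importance.csv`,
#'   `worker_report.csv`, `report.json`.
#' @return (Invisibly) a list with all stage outputs: `tasks`, `workers`,
#'   `assignments`, `qc`, `matrices`, `inference`, `metrics_table`, `lc`,
#'   `al`, `attribution`, `unanimity`, `paths`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed

  workers <- generate_workers(config$sim)
  tasks <- generate_tasks(config$sim)
  assignments <- simulate_labeling(tasks, workers, config$sim)
  qc <- validate_hits(assignments, qual_policy = config$qual_policy)
  truth_mc <- stats::setNames(tasks$true_label, tasks$task_id)
  truth_bin <- stats::setNames(dichotomize(tasks$true_label), tasks$task_id)

  per_cat <- lapply(PASS_CATEGORIES, function(cat) {
    cat_tasks <- tasks$task_id[tasks$category == cat]
    appr <- dplyr::filter(qc$approved, .data$task_id %in% cat_tasks)
    mat <- build_label_matrix(appr, required_labels = config$required_labels)
    if (nrow(mat) == 0L) return(NULL)
    mat_bin <- binarize_matrix(mat)
    inf_mc <- infer_all(mat, config$em, seed = derive_seed(seed, paste0("mv_", cat)))
    inf_bin <- infer_all(mat_bin, config$em,
                         seed = derive_seed(seed, paste0("mvb_", cat)))

    unsup_rows <- purrr::map_dfr(names(inf_mc), function(m) {
      mm <- suppressWarnings(evaluate_inference(inf_mc[[m]], truth_mc))
      mb <- suppressWarnings(evaluate_inference(inf_bin[[m]], truth_bin))
      tibble::tibble(category = cat, method = m,
                     precision_multiclass = mm$precision,
                     recall_multiclass = mm$recall,
                     f1_multiclass = mm$f1, auc_pr_multiclass = mm$auc_pr,
                     precision_binary = mb$precision,
                     recall_binary = mb$recall,
                     f1_binary = mb$f1, auc_pr_binary = mb$auc_pr)
    })

    feats_mc <- assemble_features(mat, inf_mc, tasks, binary = FALSE)
    feats_bin <- assemble_features(mat, inf_mc, tasks, binary = TRUE)
    sup_rows <- purrr::map_dfr(config$families, function(fam) {
      fit_mc <- try(train_eval(feats_mc, fam, cv_folds = config$cv_folds,
                               search_budget = config$search_budget,
                               seed = derive_seed(seed, paste0(fam, cat))),
                    silent = TRUE)
      fit_bin <- try(train_eval(feats_bin, fam, cv_folds = config$cv_folds,
                                search_budget = config$search_budget,
                                seed = derive_seed(seed, paste0(fam, cat, "b"))),
                     silent = TRUE)
      gm <- function(f, suffix) {
        if (inherits(f, "try-error")) {
          stats::setNames(rep(NA_real_, 4),
                          paste0(c("precision_", "recall_", "f1_", "auc_pr_"),
                                 suffix))
        } else {
          stats::setNames(as.numeric(f$metrics[1, 1:4]),
                          paste0(c("precision_", "recall_", "f1_", "auc_pr_"),
                                 suffix))
        }
      }
      dplyr::bind_cols(tibble::tibble(category = cat, method = fam),
                       tibble::as_tibble(as.list(c(gm(fit_mc, "multiclass"),
                                                   gm(fit_bin, "binary")))))
    })

    ph_rows <- tibble::tibble(
      category = cat, method = PLACEHOLDER_METHODS,
      precision_multiclass = NA_real_, recall_multiclass = NA_real_,
      f1_multiclass = NA_real_, auc_pr_multiclass = NA_real_,
      precision_binary = NA_real_, recall_binary = NA_real_,
      f1_binary = NA_real_, auc_pr_binary = NA_real_
    )
    ph_rows$note <- "out_of_scope"
    rows <- dplyr::bind_rows(
      dplyr::mutate(unsup_rows, note = ""),
      dplyr::mutate(sup_rows, note = ""), ph_rows)

    list(matrix = mat, matrix_binary = mat_bin, inference = inf_mc,
         inference_binary = inf_bin, features = feats_mc,
         features_binary = feats_bin, rows = rows)
  })
  names(per_cat) <- PASS_CATEGORIES
  per_cat <- per_cat[!vapply(per_cat, is.null, logical(1))]
  metrics_table <- purrr::map_dfr(per_cat, "rows")

  # label consistency per category, multiclass and binary views
  cat_map <- tasks[c("task_id", "category")]
  lc <- purrr::map_dfr(names(per_cat), function(cat) {
    m <- per_cat[[cat]]$matrix
    dplyr::bind_rows(
      dplyr::mutate(label_consistency(m, cat_map), view = "multiclass"),
      dplyr::mutate(label_consistency(binarize_matrix(m), cat_map),
                    view = "binary"))
  })

  # active learning on the pooled binary problem
  feats_all <- purrr::map_dfr(per_cat, "features_binary")
  al_seed <- derive_seed(seed, "al")
  n_hold <- max(20L, round(0.25 * nrow(feats_all)))
  hold_fold <- stratified_folds(feats_all$l, max(2L, round(nrow(feats_all) / n_hold)),
                                seed = derive_seed(seed, "al_hold"))
  holdout <- feats_all[hold_fold == 1L, ]
  pool <- feats_all[hold_fold != 1L, ]
  max_iter <- min(config$al_iterations,
                  floor((nrow(pool) * 0.9) / config$al_batch_size))
  al <- active_learn(pool, holdout, family = config$al_family,
                     batch_size = config$al_batch_size,
                     n_iterations = max(1L, max_iter),
                     strategy = config$al_strategy, seed = al_seed)

  # attribution on the first category's binary problem
  first <- per_cat[[1L]]
  fb <- first$features_binary
  groups <- attr(fb, "feature_groups")
  attr_fit <- fit_learner("logreg", feature_matrix(fb), fb$l,
                          default_hyper("logreg", ncol(feature_matrix(fb))),
                          seed = derive_seed(seed, "shap_fit"))
  predict_fn <- function(df) {
    predict_learner(attr_fit, as.matrix(df))[, "1"]
  }
  Xdf <- tibble::as_tibble(feature_matrix(fb))
  nb <- min(config$shap_background, nrow(Xdf))
  ns <- min(config$shap_samples, nrow(Xdf))
  bg_idx <- withr::with_seed(derive_seed(seed, "shap_bg"),
                             sample.int(nrow(Xdf), nb))
  sm_idx <- withr::with_seed(derive_seed(seed, "shap_sm"),
                             sample.int(nrow(Xdf), ns))
  phi <- shapley_matrix(predict_fn, Xdf[sm_idx, ], Xdf[bg_idx, ], groups)
  importance <- global_importance(phi)

  unanimity <- unanimity_subset_analysis(
    first$matrix, tibble::tibble(task_id = tasks$task_id,
                                 label = tasks$true_label),
    first$inference)

  wrep <- worker_report(
    purrr::reduce(purrr::map(per_cat, "matrix"), dplyr::bind_rows),
    reference = tibble::tibble(task_id = tasks$task_id,
                               label = tasks$true_label),
    assignments = assignments,
    seed = derive_seed(seed, "wrep"))

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_report_bundle(out_dir, metrics_table, lc, al, importance,
                                 wrep, unanimity, config, qc)
  }

  invisible(list(
    config = config, tasks = tasks, workers = workers,
    assignments = assignments, qc = qc,
    matrices = purrr::map(per_cat, "matrix"),
    inference = purrr::map(per_cat, "inference"),
    features = purrr::map(per_cat, "features"),
    metrics_table = metrics_table, lc = lc, al = al,
    attribution = list(phi = phi, importance = importance),
    unanimity = unanimity, worker_report = wrep, paths = paths
  ))
}

write_report_bundle <- function(out_dir, metrics_table, lc, al, importance,
                                wrep, unanimity, config, qc) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(metrics_table, p("metrics.csv"))
  readr::write_csv(lc, p("lc.csv"))
  readr::write_csv(al$curve, p("al_curve.csv"))
  readr::write_csv(importance, p("importance.csv"))
  readr::write_csv(wrep, p("worker_report.csv"))
  readr::write_csv(unanimity, p("unanimity.csv"))
  report <- list(
    seed = config$seed,
    n_tasks = sum(config$sim$n_tasks_per_category),
    n_workers = config$sim$n_workers,
    n_hits_rejected = nrow(qc$rejected),
    al_final_accuracy = dplyr::last(al$curve$accuracy),
    top_feature = importance$group[1]
  )
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stats::setNames(
    file.path(out_dir, c("metrics.csv", "lc.csv", "al_curve.csv",
                         "importance.csv", "worker_report.csv",
                         "unanimity.csv", "report.json")),
    c("metrics", "lc", "al_curve", "importance", "worker_report",
      "unanimity", "report"))
}

#' Generate the packaged test fixtures
#'
#' Writes the small deterministic datasets used by the test suite: a
#' 20-HIT QC fixture with 6 seeded defects plus its defect manifest, the
#' 125-row enumeration of ordered label triples over the 5-symbol choice
#' set, and a 200-task mini dataset (tasks CSV + assignments JSONL).
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (default a temporary directory).
#' @return Named list of file paths plus the in-memory `manifest`.
#' @export
make_fixtures <- function(seed = 1L, out_dir = tempfile("fixtures")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- QC fixture: 20 HITs, defects in known submissions -----------------
  cfg <- sim_config(n_tasks_per_category = 20, n_workers = 15,
                    p_unclear = 0, p_qual_fail = 0,
                    spammer_fraction = 0, adversarial_fraction = 0,
                    seed = derive_seed(seed, "qcfix"))
  tasks <- generate_tasks(cfg)
  workers <- generate_workers(cfg)
  asg <- simulate_labeling(tasks, workers, cfg)
  hits <- asg %>%
    dplyr::distinct(.data$hit_id, .data$worker_id) %>%
    dplyr::slice_head(n = 20)
  asg <- dplyr::semi_join(asg, hits, by = c("hit_id", "worker_id"))
  key <- paste(asg$hit_id, asg$worker_id)
  ukey <- paste(hits$hit_id, hits$worker_id)
  # defects: 3 selection-count, 2 qualification, 1 duplicate task
  defect <- c("selection_count", "selection_count", "selection_count",
              "qualification", "qualification", "duplicate_task")
  target <- ukey[seq_along(defect)]
  first_row <- match(target, key)
  asg$choice[first_row[1]] <- NA_character_          # zero selections
  asg$choice[first_row[2]] <- "11,00"                # multiple selections
  asg$choice[first_row[3]] <- ""                     # zero selections
  asg$qual_answer[key %in% target[4:5]] <- "incorrect"
  rows6 <- which(key == target[6])
  asg$task_id[rows6[2]] <- asg$task_id[rows6[1]]     # duplicate task in HIT
  manifest <- tibble::tibble(
    hit_id = hits$hit_id[seq_along(defect)],
    worker_id = hits$worker_id[seq_along(defect)],
    defect = defect)

  qc_path <- file.path(out_dir, "qc_fixture.jsonl")
  write_assignments(asg, qc_path)
  manifest_path <- file.path(out_dir, "qc_manifest.csv")
  readr::write_csv(manifest, manifest_path)

  # --- 125 ordered label triples over the 5-symbol choice set ------------
  symbols <- c(MULTICLASS_ALPHABET, UNCLEAR)
  triples <- expand.grid(l1 = symbols, l2 = symbols, l3 = symbols,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  triples_path <- file.path(out_dir, "mv_triples.csv")
  readr::write_csv(tibble::as_tibble(triples), triples_path)

  # --- 200-task mini dataset ---------------------------------------------
  mini_cfg <- sim_config(n_tasks_per_category = c(67, 67, 66),
                         n_workers = 40, seed = derive_seed(seed, "mini"))
  mini_tasks <- generate_tasks(mini_cfg)
  mini_workers <- generate_workers(mini_cfg)
  mini_asg <- simulate_labeling(mini_tasks, mini_workers, mini_cfg)
  tasks_path <- file.path(out_dir, "mini_tasks.csv")
  asg_path <- file.path(out_dir, "mini_assignments.jsonl")
  write_tasks(mini_tasks, tasks_path)
  write_assignments(mini_asg, asg_path)

  list(qc_fixture = qc_path, qc_manifest = manifest_path,
       mv_triples = triples_path, mini_tasks = tasks_path,
       mini_assignments = asg_path, manifest = manifest)
}
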