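# Unsupervised truth inference over a label matrix: majority vote,
# Dawid-Skene, GLAD (worker ability x task clarity), and Raykar variants.
#
# All EM methods are MAP-EM: confusion rows carry a Dirichlet pseudo-count,
# GLAD's ability/log-clarity carry Gaussian priors, and the binary Raykar
# model carries Beta priors on sensitivity/specificity. `loglik_trace`
# records the penalized (MAP) objective, the quantity EM provably does not
# decrease; the raw observed-data log-likelihood is reported alongside.

#' EM settings
#'
#' @param tol Relative penalized log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param smoothing Dirichlet pseudo-count added to confusion rows and class
#'   priors at each M-step (survives matrix sparsity).
#' @param init `"mv_soft"` (posteriors initialized to vote shares, default)
#'   or `"uniform"`.
#' @param seed Seed for tie-breaking and any randomized initialization.
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(tol = 1e-6, max_iter = 100L, smoothing = 0.01,
                        init = c("mv_soft", "uniform"), seed = 1L) {
  init <- match.arg(init)
  if (tol <= 0) abort("`tol` must be > 0.")
  check_count(max_iter, "max_iter")
  if (smoothing <= 0) abort("`smoothing` must be > 0.")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 smoothing = smoothing, init = init, seed = as.integer(seed)),
            class = "em_settings")
}

# Encode a label matrix into integer index vectors.
encode_matrix <- function(matrix) {
  alphabet <- lm_alphabet(matrix)
  task_ids <- unique(matrix$task_id)
  worker_ids <- unique(matrix$worker_id)
  list(
    t = match(matrix$task_id, task_ids),
    w = match(matrix$worker_id, worker_ids),
    l = match(matrix$label, alphabet),
    task_ids = task_ids,
    worker_ids = worker_ids,
    alphabet = alphabet,
    L = length(alphabet),
    n_tasks = length(task_ids),
    n_workers = length(worker_ids)
  )
}

# Vote-share posterior matrix (tasks x L).
vote_shares <- function(enc) {
  counts <- unclass(table(factor(enc$t, seq_len(enc$n_tasks)),
                          factor(enc$l, seq_len(enc$L))))
  counts / rowSums(counts)
}

new_inference <- function(method, enc, posteriors, worker_quality,
                          class_priors, loglik_trace, observed_loglik,
                          n_iterations, converged, settings,
                          task_difficulty = NULL, seed = NA_integer_,
                          tie = NULL) {
  dimnames(posteriors) <- list(enc$task_ids, enc$alphabet)
  hard_idx <- max.col(posteriors, ties.method = "first")
  mx <- posteriors[cbind(seq_len(nrow(posteriors)), hard_idx)]
  if (is.null(tie)) {
    tie <- rowSums(abs(posteriors - mx) < 1e-12) > 1L
  }
  tie <- unname(tie)
  structure(list(
    method = method,
    alphabet = enc$alphabet,
    task_ids = enc$task_ids,
    worker_ids = enc$worker_ids,
    posteriors = posteriors,
    hard_labels = tibble::tibble(task_id = enc$task_ids,
                                 hard_label = enc$alphabet[hard_idx],
                                 tie = tie),
    worker_quality = worker_quality,
    class_priors = class_priors,
    loglik_trace = loglik_trace,
    observed_loglik = observed_loglik,
    n_iterations = n_iterations,
    converged = converged,
    settings = settings,
    task_difficulty = task_difficulty,
    seed = seed
  ), class = "crowd_inference")
}

#' @export
print.crowd_inference <- function(x, ...) {
  cat(sprintf("<crowd_inference:%s> %d tasks, %d workers, %d iteration(s)%s\n",
              x$method, length(x$task_ids), length(x$worker_ids),
              x$n_iterations,
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Tidy/glance methods for inference results
#'
#' `tidy()` returns one row per task with the hard label, tie flag, and the
#' posterior probability of each class (columns `p_<label>`); `glance()`
#' returns a one-row model summary.
#'
#' @param x A `crowd_inference` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crowd_inference <- function(x, ...) {
  p <- tibble::as_tibble(x$posteriors, .name_repair = "minimal")
  names(p) <- paste0("p_", x$alphabet)
  dplyr::bind_cols(x$hard_labels, p)
}

#' @rdname tidy.crowd_inference
#' @export
glance.crowd_inference <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_tasks = length(x$task_ids),
    n_workers = length(x$worker_ids),
    n_iterations = x$n_iterations,
    converged = x$converged,
    loglik = if (length(x$loglik_trace)) dplyr::last(x$loglik_trace) else NA_real_
  )
}

#' Majority vote
#'
#' Assigns each task its modal label; posteriors are vote shares. For binary
#' labels this matches the threshold rule (label 1 iff at least 2 of the 3
#' workers said 1). Tied tasks are always flagged; the tie is resolved by
#' the chosen policy.
#'
#' @param matrix A `label_matrix`.
#' @param tie_policy `"random_seeded"` (default; seeded uniform choice among
#'   tied modes), `"lowest_index"` (first tied label in alphabet order), or
#'   `"abstain"` (hard label `NA` for ties).
#' @param seed Seed for `random_seeded` tie-breaking.
#' @return A `crowd_inference` object.
#' @export
majority_vote <- function(matrix,
                          tie_policy = c("random_seeded", "lowest_index",
                                         "abstain"),
                          seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  enc <- encode_matrix(matrix)
  shares <- vote_shares(enc)
  mx <- apply(shares, 1L, max)
  tie <- rowSums(abs(shares - mx) < 1e-12) > 1L
  hard_idx <- max.col(shares, ties.method = "first")
  if (any(tie)) {
    if (tie_policy == "random_seeded") {
      withr::with_seed(seed, {
        for (i in which(tie)) {
          cand <- which(abs(shares[i, ] - mx[i]) < 1e-12)
          hard_idx[i] <- cand[sample.int(length(cand), 1L)]
        }
      })
    } else if (tie_policy == "abstain") {
      hard_idx[tie] <- NA_integer_
    } # lowest_index: max.col "first" already picks alphabet order
  }
  res <- new_inference("mv", enc, shares, worker_quality = NULL,
                       class_priors = colSums(shares) / nrow(shares),
                       loglik_trace = numeric(0), observed_loglik = NA_real_,
                       n_iterations = 0L, converged = TRUE,
                       settings = list(tie_policy = tie_policy, seed = seed),
                       seed = seed, tie = tie)
  res$hard_labels$hard_label <- ifelse(is.na(hard_idx), NA_character_,
                                       enc$alphabet[hard_idx])
  res
}

# ---- Dawid-Skene / multiclass Raykar engine ------------------------------

ds_engine <- function(matrix, settings, smoothing, method) {
  enc <- encode_matrix(matrix)
  if (enc$L < 2L) abort("Alphabet must have at least 2 labels.")
  L <- enc$L
  nobs <- length(enc$t)

  post <- switch(settings$init,
                 mv_soft = vote_shares(enc),
                 uniform = matrix(1 / L, enc$n_tasks, L))

  obs_group <- (enc$w - 1L) * L + enc$l     # (worker, observed label) cell
  trace <- numeric(0)
  obs_ll <- NA_real_
  converged <- FALSE
  iter <- 0L
  pi_arr <- NULL
  priors <- NULL

  for (iter in seq_len(settings$max_iter)) {
    # M-step from current posteriors
    priors <- colSums(post) + smoothing
    priors <- priors / sum(priors)
    cellsum <- rowsum(post[enc$t, , drop = FALSE], obs_group)
    # pi_arr[w, true, obs]
    pi_arr <- array(smoothing, dim = c(enc$n_workers, L, L))
    gidx <- as.integer(rownames(cellsum))
    wk <- (gidx - 1L) %/% L + 1L
    ob <- (gidx - 1L) %% L + 1L
    for (r in seq_along(gidx)) {
      pi_arr[wk[r], , ob[r]] <- pi_arr[wk[r], , ob[r]] + cellsum[r, ]
    }
    tot <- apply(pi_arr, c(1, 2), sum)
    pi_arr <- pi_arr / array(tot, dim = dim(pi_arr))

    # E-step
    logpi <- log(pi_arr)
    O <- matrix(0, nobs, L)
    for (c in seq_len(L)) {
      O[, c] <- logpi[cbind(enc$w, c, enc$l)]
    }
    logpost <- rowsum(O, enc$t) +
      matrix(log(priors), enc$n_tasks, L, byrow = TRUE)
    lse <- row_lse(logpost)
    obs_ll <- sum(lse)
    pen <- obs_ll + smoothing * sum(logpi) + smoothing * sum(log(priors))
    post <- exp(logpost - lse)

    trace <- c(trace, pen)
    if (iter > 1L &&
        abs(trace[iter] - trace[iter - 1L]) <
          settings$tol * (abs(trace[iter - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("%s did not converge in %d iterations.", method,
                 settings$max_iter))
  }

  wq <- tibble::tibble(
    worker_id = enc$worker_ids,
    confusion = lapply(seq_len(enc$n_workers), function(k) {
      m <- pi_arr[k, , ]
      dimnames(m) <- list(enc$alphabet, enc$alphabet)
      m
    })
  )
  new_inference(method, enc, post, worker_quality = wq,
                class_priors = stats::setNames(priors, enc$alphabet),
                loglik_trace = trace, observed_loglik = obs_ll,
                n_iterations = iter, converged = converged,
                settings = settings)
}

#' Dawid-Skene truth inference
#'
#' EM jointly estimating per-task label posteriors, class priors, and each
#' worker's L x L confusion matrix. The E-step computes task posteriors from
#' current priors and confusion matrices; the M-step re-estimates priors and
#' row-stochastic confusion matrices with additive (Dirichlet pseudo-count)
#' smoothing. Stops when the penalized log-likelihood improves by less than
#' `tol` (relative) or at `max_iter`; a non-converged run still returns its
#' result with `converged = FALSE`.
#'
#' @param matrix A `label_matrix`.
#' @param settings An [em_settings()].
#' @return A `crowd_inference` with a `worker_quality` tibble holding the
#'   estimated confusion matrices.
#' @export
dawid_skene <- function(matrix, settings = em_settings()) {
  ds_engine(matrix, settings, smoothing = settings$smoothing, method = "ds")
}

#' Multiclass Raykar truth inference
#'
#' Dawid-Skene EM with Dirichlet-MAP confusion-row updates whose
#' pseudo-count is `dirichlet_prior`; reduces exactly to [dawid_skene()]
#' when `dirichlet_prior` equals the DS smoothing.
#'
#' @inheritParams dawid_skene
#' @param dirichlet_prior Positive pseudo-count on confusion rows.
#' @return A `crowd_inference`.
#' @export
raykar_multiclass <- function(matrix, settings = em_settings(),
                              dirichlet_prior = 0.01) {
  if (dirichlet_prior <= 0) abort("`dirichlet_prior` must be > 0.")
  ds_engine(matrix, settings, smoothing = dirichlet_prior, method = "ry")
}

# ---- GLAD ----------------------------------------------------------------

#' GLAD truth inference (worker ability x task clarity)
#'
#' Generative model in which worker `k` labels task `i` correctly with
#' probability `plogis(alpha_k * beta_i)` and otherwise picks uniformly
#' among the L-1 wrong labels. Ability `alpha` is unconstrained (negative =
#' adversarial, 0 = cannot distinguish); clarity `beta > 0` is optimized on
#' the log scale, and difficulty is `d = 1/beta`. The E-step computes task
#' posteriors under the logistic correctness model; the M-step runs bounded
#' quasi-Newton ascent on `(alpha, log beta)` under Gaussian priors, which
#' never decreases the penalized objective.
#'
#' @param matrix A `label_matrix`.
#' @param settings An [em_settings()].
#' @param prior_alpha `(mean, sd)` of the Gaussian prior on ability.
#' @param prior_log_beta `(mean, sd)` of the Gaussian prior on log clarity.
#' @param mstep_maxit Quasi-Newton iterations per M-step.
#' @return A `crowd_inference` with per-worker `ability_alpha` and a
#'   `task_difficulty` tibble (`task_id`, `beta`, `difficulty`).
#' @export
glad <- function(matrix, settings = em_settings(),
                 prior_alpha = c(1, 1), prior_log_beta = c(0, 1),
                 mstep_maxit = 25L) {
  enc <- encode_matrix(matrix)
  if (enc$L < 2L) abort("Alphabet must have at least 2 labels.")
  L <- enc$L
  nobs <- length(enc$t)
  nW <- enc$n_workers
  nT <- enc$n_tasks

  alpha <- rep(prior_alpha[1], nW)
  logbeta <- rep(prior_log_beta[1], nT)
  priors <- rep(1 / L, L)
  sm <- settings$smoothing

  prior_pen <- function(alpha, logbeta) {
    -sum((alpha - prior_alpha[1])^2) / (2 * prior_alpha[2]^2) -
      sum((logbeta - prior_log_beta[1])^2) / (2 * prior_log_beta[2]^2)
  }

  e_step <- function(alpha, logbeta, priors) {
    p <- stats::plogis(alpha[enc$w] * exp(logbeta[enc$t]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    lp_corr <- log(p)
    lp_wrong <- log1p(-p) - log(L - 1)
    O <- matrix(lp_wrong, nobs, L)
    O[cbind(seq_len(nobs), enc$l)] <- lp_corr
    logpost <- rowsum(O, enc$t) + matrix(log(priors), nT, L, byrow = TRUE)
    lse <- row_lse(logpost)
    list(post = exp(logpost - lse), obs_ll = sum(lse))
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  obs_ll <- NA_real_

  for (iter in seq_len(settings$max_iter)) {
    es <- e_step(alpha, logbeta, priors)
    post <- es$post
    obs_ll <- es$obs_ll
    pen <- obs_ll + prior_pen(alpha, logbeta) + sm * sum(log(priors))
    if (!is.finite(pen)) abort("GLAD objective became non-finite.")
    trace <- c(trace, pen)
    if (iter > 1L &&
        abs(trace[iter] - trace[iter - 1L]) <
          settings$tol * (abs(trace[iter - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }

    # M-step: class priors, then (alpha, log beta)
    priors <- colSums(post) + sm
    priors <- priors / sum(priors)

    q <- post[cbind(enc$t, enc$l)]   # P(true label = observed label)
    neg_q_fn <- function(par) {
      a <- par[seq_len(nW)]
      lb <- par[nW + seq_len(nT)]
      x <- a[enc$w] * exp(lb[enc$t])
      p <- stats::plogis(x)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      val <- sum(q * log(p) + (1 - q) * (log1p(-p) - log(L - 1))) +
        prior_pen(a, lb)
      -val
    }
    neg_q_gr <- function(par) {
      a <- par[seq_len(nW)]
      lb <- par[nW + seq_len(nT)]
      b <- exp(lb[enc$t])
      x <- a[enc$w] * b
      p <- stats::plogis(x)
      g <- q * (1 - p) - (1 - q) * p      # dQ/dx per observation
      ga <- rowsum(g * b, enc$w, reorder = TRUE)[, 1]
      ga <- ga[order(as.integer(names(ga)))]
      gb <- rowsum(g * a[enc$w] * b, enc$t, reorder = TRUE)[, 1]
      gb <- gb[order(as.integer(names(gb)))]
      ga_full <- numeric(nW); ga_full[as.integer(names(ga))] <- ga
      gb_full <- numeric(nT); gb_full[as.integer(names(gb))] <- gb
      ga_full <- ga_full - (a - prior_alpha[1]) / prior_alpha[2]^2
      gb_full <- gb_full - (lb - prior_log_beta[1]) / prior_log_beta[2]^2
      -c(ga_full, gb_full)
    }
    opt <- stats::optim(c(alpha, logbeta), neg_q_fn, neg_q_gr,
                        method = "L-BFGS-B",
                        control = list(maxit = mstep_maxit))
    if (!is.finite(opt$value)) {
      abort("GLAD M-step diverged (non-finite objective for alpha/beta).")
    }
    alpha <- opt$par[seq_len(nW)]
    logbeta <- opt$par[nW + seq_len(nT)]
  }
  if (!converged) {
    warn(sprintf("glad did not converge in %d iterations.",
                 settings$max_iter))
  }

  wq <- tibble::tibble(worker_id = enc$worker_ids, ability_alpha = alpha)
  td <- tibble::tibble(task_id = enc$task_ids, beta = exp(logbeta),
                       difficulty = exp(-logbeta))
  new_inference("glad", enc, post, worker_quality = wq,
                class_priors = stats::setNames(priors, enc$alphabet),
                loglik_trace = trace, observed_loglik = obs_ll,
                n_iterations = iter, converged = converged,
                settings = settings, task_difficulty = td)
}

# ---- Binary Raykar -------------------------------------------------------

#' Binary Raykar truth inference
#'
#' EM for binary labels modeling each worker's sensitivity (bias toward the
#' positive class) and specificity (toward the negative class) with Beta
#' priors, MAP-updated each M-step together with the prevalence.
#'
#' @param matrix A `label_matrix` over the binary alphabet `{0, 1}`.
#' @param settings An [em_settings()].
#' @param beta_prior_sens,beta_prior_spec `(a, b)` Beta prior parameters.
#' @return A `crowd_inference` with per-worker `sensitivity`/`specificity`.
#' @export
raykar_binary <- function(matrix, settings = em_settings(),
                          beta_prior_sens = c(1, 1),
                          beta_prior_spec = c(1, 1)) {
  enc <- encode_matrix(matrix)
  if (enc$L != 2L || !setequal(enc$alphabet, BINARY_ALPHABET)) {
    abort(paste0("raykar_binary requires the binary alphabet {0, 1}; ",
                 "use raykar_multiclass() for multiclass matrices."))
  }
  pos <- match("1", enc$alphabet)
  y <- as.numeric(enc$l == pos)   # observed label is positive
  nW <- enc$n_workers
  nT <- enc$n_tasks
  eps <- 1e-6

  mu <- switch(settings$init,
               mv_soft = vote_shares(enc)[, pos],
               uniform = rep(0.5, nT))
  a_s <- beta_prior_sens[1]; b_s <- beta_prior_sens[2]
  a_p <- beta_prior_spec[1]; b_p <- beta_prior_spec[2]

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  sens <- spec <- NULL
  prev <- NULL
  obs_ll <- NA_real_

  for (iter in seq_len(settings$max_iter)) {
    # M-step (MAP)
    mu_obs <- mu[enc$t]
    s_num <- rowsum(mu_obs * y, enc$w)[, 1] + (a_s - 1)
    s_den <- rowsum(mu_obs, enc$w)[, 1] + (a_s + b_s - 2)
    sens <- pmin(pmax(s_num / pmax(s_den, 1e-12), eps), 1 - eps)
    p_num <- rowsum((1 - mu_obs) * (1 - y), enc$w)[, 1] + (a_p - 1)
    p_den <- rowsum(1 - mu_obs, enc$w)[, 1] + (a_p + b_p - 2)
    spec <- pmin(pmax(p_num / pmax(p_den, 1e-12), eps), 1 - eps)
    prev <- pmin(pmax(mean(mu), eps), 1 - eps)

    # E-step
    lpos <- y * log(sens[enc$w]) + (1 - y) * log1p(-sens[enc$w])
    lneg <- (1 - y) * log(spec[enc$w]) + y * log1p(-spec[enc$w])
    Lp <- rowsum(lpos, enc$t)[, 1] + log(prev)
    Ln <- rowsum(lneg, enc$t)[, 1] + log1p(-prev)
    mx <- pmax(Lp, Ln)
    lse <- mx + log(exp(Lp - mx) + exp(Ln - mx))
    obs_ll <- sum(lse)
    mu <- exp(Lp - lse)

    pen <- obs_ll +
      sum((a_s - 1) * log(sens) + (b_s - 1) * log1p(-sens)) +
      sum((a_p - 1) * log(spec) + (b_p - 1) * log1p(-spec))
    trace <- c(trace, pen)
    if (iter > 1L &&
        abs(trace[iter] - trace[iter - 1L]) <
          settings$tol * (abs(trace[iter - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("raykar_binary did not converge in %d iterations.",
                 settings$max_iter))
  }

  post <- matrix(0, nT, 2L)
  post[, pos] <- mu
  post[, 3L - pos] <- 1 - mu
  wq <- tibble::tibble(worker_id = enc$worker_ids,
                       sensitivity = unname(sens),
                       specificity = unname(spec))
  cp <- numeric(2L); cp[pos] <- prev; cp[3L - pos] <- 1 - prev
  new_inference("ry_binary", enc, post, worker_quality = wq,
                class_priors = stats::setNames(cp, enc$alphabet),
                loglik_trace = trace, observed_loglik = obs_ll,
                n_iterations = iter, converged = converged,
                settings = settings)
}

#' Run all four unsupervised inference methods
#'
#' Convenience wrapper returning majority vote, Dawid-Skene, multiclass
#' Raykar (or binary Raykar on a binary matrix), and GLAD on one matrix.
#'
#' @param matrix A `label_matrix`.
#' @param settings An [em_settings()].
#' @param seed Seed for majority-vote tie-breaking.
#' @return A named list of `crowd_inference` objects
#'   (`mv`, `ds`, `ry`, `glad`).
#' @export
infer_all <- function(matrix, settings = em_settings(), seed = 1L) {
  binary <- setequal(lm_alphabet(matrix), BINARY_ALPHABET)
  list(
    mv = majority_vote(matrix, seed = seed),
    ds = dawid_skene(matrix, settings),
    ry = if (binary) raykar_binary(matrix, settings)
         else raykar_multiclass(matrix, settings,
                                dirichlet_prior = settings$smoothing * 2),
    glad = glad(matrix, settings)
  )
}
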