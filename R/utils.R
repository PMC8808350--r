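# Internal helpers shared across modules.

# Multiclass label alphabet: two binary conditions (self-reported, recent),
# concatenated. "unclear" is a worker escape option, never a true label.
MULTICLASS_ALPHABET <- c("11", "10", "01", "00")
BINARY_ALPHABET <- c("0", "1")
UNCLEAR <- "unclear"

PASS_CATEGORIES <- c("physical_activity", "sedentary_behavior", "sleep_quality")

# Fixed metadata domains; one-hot encoding always spans the full domain.
META_DOMAINS <- list(
  daytime   = as.character(0:23),
  weekday   = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
  month     = c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec"),
  gender    = c("female", "male", "unknown"),
  age_group = c("<=18", "19-29", "30-39", ">=40", "unknown"),
  source    = c("organization", "user")
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

# Row-wise log-sum-exp.
row_lse <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Deterministic per-stage seed derived from one global seed; keeps stages
# independent of call order and below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629) + 1L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) < 1L || any(is.na(x)) || any(x < min) ||
      any(x != floor(x))) {
    abort(sprintf("`%s` must be integer(s) >= %d.", name, min))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_simplex <- function(p, name, tol = 1e-8) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be non-negative with no missing values.", name))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.6f).", name, sum(p)))
  }
  invisible(p)
}

# One-hot encode a character/factor vector over a fixed domain; returns a
# numeric matrix with columns `<prefix>_<value>` in domain order.
one_hot <- function(x, domain, prefix) {
  m <- vapply(domain, function(v) as.numeric(x == v), numeric(length(x)))
  if (length(x) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste0(prefix, "_", domain)
  m
}

# Stratified k-fold assignment: within each class, units are dealt to folds
# round-robin after a seeded shuffle, so fold class counts differ by <= 1.
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.character(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Weighted sampling of `size` distinct indices, probability proportional to w.
sample_weighted <- function(n, size, w) {
  sample.int(n, size = size, replace = FALSE, prob = w)
}
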