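# Evaluation statistics for binary risk models.

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores)))
    stop("scores must be finite")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Computes the AUROC (equivalently, the c-statistic for binary
#' classification): the probability that a randomly chosen positive case
#' receives a higher score than a randomly chosen negative case, with
#' ties counted as one half.  Implemented through the rank-sum identity,
#' so it is exact, deterministic and handles tied scores without any
#' interpolation.
#'
#' @param scores Numeric vector of risk scores (higher = more positive).
#' @param labels Binary outcome vector (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1
#' auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))     # 0.5, all ties
#' @export
auroc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step-curve area (average precision): precision at
#' each distinct score threshold weighted by the recall increment at
#' that threshold.  For a constant score vector the curve collapses to a
#' single point at recall 1 and precision equal to the outcome
#' prevalence, so the area equals the prevalence -- the baseline of a
#' prevalence-based classifier.
#'
#' @inheritParams auroc
#' @return AUCPR in \[0, 1\].
#' @export
aucpr <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  n_pos <- sum(y)
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # thresholds at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Stratified bootstrap confidence interval for a metric
#'
#' Resamples positives and negatives separately with replacement (so
#' every replicate keeps the observed prevalence), recomputes the metric
#' on each replicate, and returns percentile bounds.
#'
#' @param metric_fn Function of (scores, labels) returning a scalar,
#'   e.g. [auroc] or [aucpr].
#' @inheritParams auroc
#' @param n_boot Number of bootstrap replicates (minimum 10).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `n_boot`, `seed`.
#' @export
stratified_bootstrap_ci <- function(metric_fn, scores, labels,
                                    n_boot = 2000, seed = 1, conf = 0.95) {
  labels <- check_scores_labels(scores, labels)
  if (n_boot < 10) stop("n_boot must be at least 10")
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == 0L)
  est <- metric_fn(scores, labels)
  old <- .Random.seed_safe_set(seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  vals <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
           sample(idx_neg, length(idx_neg), replace = TRUE))
    metric_fn(scores[i], labels[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = est, lower = q[1], upper = q[2],
       n_boot = n_boot, seed = seed)
}

# Scoped seed helpers: set the RNG deterministically without clobbering the
# caller's stream.
.Random.seed_safe_set <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.Random.seed_safe_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' DeLong test for paired AUROC comparison
#'
#' Compares two AUROCs measured on the same cases using the DeLong
#' structural-components estimator of the covariance of the two
#' (correlated) AUROCs, with a two-tailed normal p-value.
#'
#' @param scores_a,scores_b Paired score vectors from two models.
#' @inheritParams auroc
#' @return List with `delta` (AUROC a minus AUROC b), `auroc_a`,
#'   `auroc_b`, `z`, `p`, and `degenerate` (TRUE when the variance of
#'   the difference is numerically zero, in which case `p` is 1 for a
#'   zero difference).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_scores_labels(scores_a, labels)
  check_scores_labels(scores_b, labels)
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)

  comp <- function(s) {
    x <- s[pos]
    y <- s[!pos]
    # V10[i] = P(x_i > Y) + 0.5 P(x_i = Y); V01[j] likewise against X
    r_all <- rank(c(x, y), ties.method = "average")
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    v10 <- (r_all[seq_len(m)] - rx) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  s10 <- stats::var(cbind(a$v10, b$v10))
  s01 <- stats::var(cbind(a$v01, b$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- a$auc - b$auc
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else NA_real_
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(delta = delta, auroc_a = a$auc, auroc_b = b$auc,
       z = z, p = p, degenerate = degenerate)
}

#' Bootstrap comparison of paired AUCPR values
#'
#' Two-tailed p-value for the difference in AUCPR between two models
#' evaluated on the same cases, from the stratified-bootstrap
#' distribution of the paired difference.
#'
#' @inheritParams delong_test
#' @inheritParams stratified_bootstrap_ci
#' @return List with `delta` (observed AUCPR difference), `p`, `n_boot`.
#' @export
bootstrap_compare_aucpr <- function(scores_a, scores_b, labels,
                                    n_boot = 2000, seed = 1) {
  labels <- check_scores_labels(scores_a, labels)
  check_scores_labels(scores_b, labels)
  if (n_boot < 10) stop("n_boot must be at least 10")
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == 0L)
  delta <- aucpr(scores_a, labels) - aucpr(scores_b, labels)
  old <- .Random.seed_safe_set(seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  d <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
           sample(idx_neg, length(idx_neg), replace = TRUE))
    aucpr(scores_a[i], labels[i]) - aucpr(scores_b[i], labels[i])
  }, numeric(1))
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(delta = delta, p = p, n_boot = n_boot, seed = seed)
}

#' Operating point at the Youden-index threshold
#'
#' Sweeps all distinct score values as thresholds (prediction positive
#' when score >= threshold), picks the threshold maximizing Youden's
#' J = sensitivity + specificity - 1, breaking ties toward the lowest
#' threshold (which maximizes sensitivity at equal J), and reports the
#' confusion-matrix summaries there.
#'
#' @inheritParams auroc
#' @return List with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `youden_j`.
#' @export
youden_operating_point <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  thr <- sort(unique(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  best <- NULL
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    sens <- tp / n_pos
    spec <- (n_neg - fp) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      tn <- n_neg - fp
      fn <- n_pos - tp
      npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   ppv = ppv, npv = npv, youden_j = j)
    }
  }
  best
}

#' Evaluate scores with AUROC/AUCPR and bootstrap intervals
#'
#' @inheritParams stratified_bootstrap_ci
#' @return List with `auroc`, `aucpr`, each carrying `estimate`,
#'   `lower`, `upper`; plus `n`, `n_pos`.
#' @export
evaluate_scores <- function(scores, labels, n_boot = 2000, seed = 1) {
  labels <- check_scores_labels(scores, labels)
  list(auroc = stratified_bootstrap_ci(auroc, scores, labels, n_boot, seed),
       aucpr = stratified_bootstrap_ci(aucpr, scores, labels, n_boot,
                                       seed + 1L),
       n = length(labels), n_pos = sum(labels == 1L))
}

#' Per-subgroup evaluation
#'
#' Evaluates a score vector within declared subgroups.  Groups smaller
#' than `min_size` (or with a single outcome class) are flagged in the
#' output rather than silently dropped.
#'
#' @inheritParams stratified_bootstrap_ci
#' @param groups Factor or character vector of group membership, same
#'   length as `scores`.
#' @param min_size Minimum group size for metrics to be reported.
#' @return data.frame with one row per group: n, n_pos, auroc and aucpr
#'   with CI bounds, and a `flagged` column.
#' @export
subgroup_eval <- function(scores, labels, groups, n_boot = 500, seed = 1,
                          min_size = 20) {
  labels <- check_scores_labels(scores, labels)
  groups <- as.factor(groups)
  rows <- lapply(levels(groups), function(g) {
    i <- groups == g
    n <- sum(i)
    n_pos <- sum(labels[i] == 1L)
    ok <- n >= min_size && n_pos > 0 && n_pos < n
    if (ok) {
      ev <- evaluate_scores(scores[i], labels[i], n_boot, seed)
      data.frame(group = g, n = n, n_pos = n_pos, flagged = FALSE,
                 auroc = ev$auroc$estimate, auroc_lo = ev$auroc$lower,
                 auroc_hi = ev$auroc$upper,
                 aucpr = ev$aucpr$estimate, aucpr_lo = ev$aucpr$lower,
                 aucpr_hi = ev$aucpr$upper)
    } else {
      data.frame(group = g, n = n, n_pos = n_pos, flagged = TRUE,
                 auroc = NA_real_, auroc_lo = NA_real_, auroc_hi = NA_real_,
                 aucpr = NA_real_, aucpr_lo = NA_real_, aucpr_hi = NA_real_)
    }
  })
  do.call(rbind, rows)
}
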