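# Independent brute-force oracles: naive enumerations kept deliberately
# separate from the package's rank/cumsum implementations.

bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

bf_aucpr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

bf_youden <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, youden_j = best_j)
}

# Label-preserving paired permutation oracle for the DeLong comparison:
# under H0 the two score vectors are exchangeable per subject.
perm_delong_p <- function(scores_a, scores_b, labels, n_perm = 2000,
                          seed = 1) {
  set.seed(seed)
  obs <- abs(auroc(scores_a, labels) - auroc(scores_b, labels))
  hits <- 0
  n <- length(labels)
  for (b in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, scores_b, scores_a)
    bb <- ifelse(swap, scores_a, scores_b)
    d <- abs(auroc(a, labels) - auroc(bb, labels))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Random score/label vector with both classes present.
random_scored_labels <- function(n, tie_prob = 0.3) {
  labels <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
  scores <- if (runif(1) < tie_prob)
    sample(seq(0, 1, 0.25), n, replace = TRUE)
  else
    round(runif(n), 3)
  list(scores = scores, labels = labels)
}

# Tiny phantom spec used across image tests (coarse grid keeps runtimes
# low while all five classes stay populated).
small_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(image_size = 96, pixel_spacing_mm = c(4, 4), seed = seed,
               ...)
}
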