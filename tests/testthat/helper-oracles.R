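# Independent oracles and fixture builders used across the suite.

# Direct double-sum 2-D DFT: O(N^2 M^2), the definition itself.
dft2_bruteforce <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0 + 0i, n, m)
  for (u in seq_len(n)) {
    for (v in seq_len(m)) {
      acc <- 0 + 0i
      for (a in seq_len(n)) {
        for (b in seq_len(m)) {
          acc <- acc + x[a, b] *
            exp(-2i * pi * ((u - 1) * (a - 1) / n + (v - 1) * (b - 1) / m))
        }
      }
      out[u, v] <- acc
    }
  }
  out
}

# Brute-force fairness metrics by explicit record counting.
fairness_bruteforce <- function(y_true, y_score, y_pred, group) {
  groups <- sort(unique(group))
  rate <- fpr <- fnr <- acc <- auc <- setNames(rep(NA_real_, length(groups)),
                                               groups)
  for (g in groups) {
    i <- group == g
    rate[g] <- sum(y_pred[i] == 1) / sum(i)
    neg <- i & y_true == 0
    pos <- i & y_true == 1
    if (sum(neg) > 0) fpr[g] <- sum(y_pred[neg] == 1) / sum(neg)
    if (sum(pos) > 0) fnr[g] <- sum(y_pred[pos] == 0) / sum(pos)
    acc[g] <- sum(y_pred[i] == y_true[i]) / sum(i)
    auc[g] <- auc_pairs(y_true[i], y_score[i])
  }
  list(
    rate = rate, fpr = fpr, fnr = fnr, acc = acc, auc = auc,
    dp = max(rate) - min(rate),
    fpr_diff = if (all(is.na(fpr))) NA_real_ else
      diff(range(fpr, na.rm = TRUE)),
    fnr_diff = if (all(is.na(fnr))) NA_real_ else
      diff(range(fnr, na.rm = TRUE)),
    overall_acc = mean(y_pred == y_true)
  )
}

# AUC by explicit pair counting, ties counted half.
auc_pairs <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]
  neg <- y_score[y_true == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Entropy (log10) by explicit tally of a discrete vector.
entropy_tally <- function(values) {
  p <- as.numeric(table(values)) / length(values)
  -sum(p * log10(p))
}

random_prediction_set <- function(n, n_groups) {
  y_true <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
  y_score <- round(runif(n), 3)
  prediction_set(
    y_true = y_true,
    y_score = y_score,
    group = sample(LETTERS[seq_len(n_groups)], n, replace = TRUE),
    y_pred = as.integer(y_score >= 0.5)
  )
}

# Small cohort spec used where full-size generation would be wasteful.
small_cohort_spec <- function(seed = 1L, n = 400L) {
  cohort_spec(n_patients = n, n_features = 20L, seed = seed)
}

# 2-D Gaussian bump: the smooth fixture for the structure-preservation
# diagnostic.
gaussian_bump <- function(n = 16L, m = 12L, center = c(6, 8), sd = 2.5) {
  outer(seq_len(n), seq_len(m), function(i, j) {
    exp(-((i - center[1])^2 + (j - center[2])^2) / (2 * sd^2))
  })
}
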