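# Independent brute-force oracles, written deliberately as literal double
# loops so they share no code path with the package implementations.

# Auto-covariance of each profile column: for column j and lag d,
# mean over i of (P[i,j] - colmean_j) * (P[i+d,j] - colmean_j), i = 1..n-d,
# emitted column-by-column with lag varying fastest.
oracle_pssm_ac <- function(scores, lg) {
  n <- nrow(scores)
  out <- numeric(0)
  for (j in seq_len(ncol(scores))) {
    mj <- sum(scores[, j]) / n
    for (d in seq_len(lg)) {
      acc <- 0
      for (i in seq_len(n - d)) {
        acc <- acc + (scores[i, j] - mj) * (scores[i + d, j] - mj)
      }
      out <- c(out, acc / (n - d))
    }
  }
  out
}

# Group-by-residue row means in canonical residue order; absent residues
# give a zero block.
oracle_pssm_400 <- function(scores, residues) {
  res <- strsplit(residues, "")[[1]]
  out <- numeric(0)
  for (a in lumipred::AA_ORDER) {
    rows <- which(res == a)
    block <- numeric(20)
    if (length(rows) > 0) {
      for (j in 1:20) block[j] <- mean(scores[rows, j])
    }
    out <- c(out, block)
  }
  out
}

# Confusion tally by plain enumeration.
oracle_confusion <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == -1 && pred[i] == -1) tn <- tn + 1L
    if (truth[i] == -1 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && pred[i] == -1) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# AUC as the normalised Mann-Whitney statistic: all positive/negative score
# pairs compared, ties counted one half.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) wins <- wins + 1
      else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

# Random integer profile in the log-odds range, residues uniform over the
# canonical alphabet.
random_profile <- function(n, id = "rnd") {
  pssm_profile(id = id,
               residues = paste(sample(lumipred::AA_ORDER, n, replace = TRUE),
                                collapse = ""),
               scores = matrix(sample(-10:10, n * 20, replace = TRUE),
                               nrow = n, ncol = 20))
}

# Two well-separated Gaussian blobs in feature space: linearly separable
# instances for sanity-checking the SVM protocol without any encoding.
separable_blobs <- function(n_per_class, dim = 5, gap = 6) {
  x <- rbind(matrix(stats::rnorm(n_per_class * dim), ncol = dim),
             matrix(stats::rnorm(n_per_class * dim, mean = gap), ncol = dim))
  rownames(x) <- sprintf("b%03d", seq_len(2 * n_per_class))
  list(x = x, labels = c(rep(1, n_per_class), rep(-1, n_per_class)))
}
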