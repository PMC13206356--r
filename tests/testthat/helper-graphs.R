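# Graph generators and independent oracles used across the suite.

rBinaryGraph <- function(n, p) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.numeric(runif(sum(ut)) < p)
  A + t(A)
}

rWeightedGraph <- function(n, p, logSd = 0.4) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  e <- runif(sum(ut)) < p
  w <- numeric(sum(ut))
  w[e] <- rlnorm(sum(e), 0, logSd)
  A[ut] <- w
  A + t(A)
}

# Brute-force pairwise AUROC: fraction of (positive, negative) pairs the
# score orders correctly, ties counted half.
bruteForceAuroc <- function(score, labels) {
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- labels[ok]
  P <- which(labels == 1); N <- which(labels == 0)
  if (!length(P) || !length(N)) return(NA_real_)
  tot <- 0
  for (i in P) for (j in N)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(P) * length(N))
}

# 0/1 dilation without the package's EventSeries machinery.
plainDilate <- function(lab, L) {
  out <- lab
  for (i in which(lab == 1))
    for (d in -L:L) {
      j <- i + d
      if (j >= 1 && j <= length(lab)) out[j] <- 1
    }
  out
}
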