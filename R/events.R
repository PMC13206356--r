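#' @include AllClasses.R AllGenerics.R
NULL

#' Label low-SSIM reconfiguration events
#'
#' A transition is labeled as a reconfiguration event when its SSIM falls
#' strictly below the empirical \code{qS}-quantile of the subject's own
#' SSIM series (quantile type 7).  A constant series yields no positives
#' and is flagged degenerate.
#'
#' @param ssim numeric SSIM series over transition indices.
#' @param qS event-rate quantile in (0, 1); the main settings are 0.05,
#'   0.07 and 0.10.
#' @return An \linkS4class{EventSeries}.
#' @examples
#' set.seed(1)
#' ev <- labelLowSsimEvents(runif(100), 0.05)
#' sum(eventLabels(ev))   # 5
#' @export
labelLowSsimEvents <- function(ssim, qS) {
  if (qS <= 0 || qS >= 1) stop("qS must be in (0, 1)", call. = FALSE)
  if (length(ssim) < 2L) stop("need at least 2 transitions", call. = FALSE)
  cut <- stats::quantile(ssim, qS, type = 7, names = FALSE)
  EventSeries(as.integer(ssim < cut), quantile = qS, tolerance = 0L)
}

#' Dilate event labels by a lag tolerance
#'
#' Marks every transition within \code{L} indices of an original
#' positive, implementing the lag-aware criterion that a high score
#' within a +/- L neighbourhood of an event counts as a detection.
#'
#' @param e an \linkS4class{EventSeries}.
#' @param L tolerance in windows (\code{L = 0} is the identity).
#' @return An \linkS4class{EventSeries} with updated labels and
#'   tolerance metadata.
#' @export
dilateEvents <- function(e, L) {
  L <- as.integer(L)
  if (L < 0L) stop("tolerance must be >= 0", call. = FALSE)
  lab <- e@labels
  if (L > 0L && any(lab == 1L)) {
    n <- length(lab)
    out <- integer(n)
    for (i in which(lab == 1L)) {
      lo <- max(1L, i - L); hi <- min(n, i + L)
      out[lo:hi] <- 1L
    }
    lab <- out
  }
  new("EventSeries", labels = lab, quantile = e@quantile,
      tolerance = L, degenerate = !any(lab == 1L))
}

#' Rank-based AUROC with midrank tie handling
#'
#' \code{NA} score entries and their labels are dropped pairwise.  A
#' constant score yields 0.5 under the midrank convention; degenerate
#' labels (one class absent after masking) yield \code{NA}.
#'
#' @param score numeric score vector (higher = more event-like).
#' @param labels 0/1 vector of the same length.
#' @return AUROC in [0, 1], or \code{NA} if undefined.
#' @export
aurocScore <- function(score, labels) {
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)  # midranks
  (mean(r[labels == 1]) - (n1 + 1) / 2) / n0
}

#' Average precision of a score against binary labels
#'
#' Step-wise average precision: recall increments weighted by the
#' precision at each score threshold, descending through unique score
#' values (ties are handled by grouping equal scores).
#'
#' @inheritParams aurocScore
#' @return AP in [0, 1], or \code{NA} if the labels are degenerate.
#' @export
averagePrecision <- function(score, labels) {
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- labels[ok]
  nPos <- sum(labels == 1)
  if (nPos == 0L || all(labels == 1)) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

#' Lag-aware threshold-free detection of events by a score
#'
#' Dilates the event labels by the tolerance, removes transitions whose
#' score is \code{NA} (degenerate temperature entries), and computes
#' rank-based AUROC and average precision of the score against the
#' dilated labels.
#'
#' @param score numeric score series over transition indices (e.g.
#'   \code{abs(temperatureIndex(traj)[-1])}).
#' @param events an \linkS4class{EventSeries} aligned with the score, or
#'   a plain 0/1 vector.
#' @param tolerance lag tolerance L; when \code{events} already carries a
#'   nonzero tolerance it is used as-is.
#' @return A \linkS4class{DetectionSummary} with \code{auroc} and
#'   \code{ap} filled in (\code{NA} when the labels are degenerate after
#'   dilation and masking).
#' @export
lagAwareDetection <- function(score, events, tolerance = 0L) {
  if (!is(events, "EventSeries")) events <- EventSeries(events)
  if (length(score) != length(events@labels))
    stop(sprintf("score has %d entries but labels have %d",
                 length(score), length(events@labels)), call. = FALSE)
  if (events@tolerance == 0L && tolerance > 0L)
    events <- dilateEvents(events, tolerance)
  lab <- events@labels
  ok <- !is.na(score)
  new("DetectionSummary",
      auroc = aurocScore(score[ok], lab[ok]),
      ap = averagePrecision(score[ok], lab[ok]),
      nEvents = sum(lab[ok] == 1L), nValid = sum(ok))
}

#' Binarize a score at a matched spike rate
#'
#' Marks the top-\code{rate} fraction of \code{|score|} as spikes, so
#' that when \code{rate} equals the event rate both binary vectors have
#' matched positive counts (the Matthews correlation is rate-sensitive).
#' Ties beyond the quota are broken by series order.
#'
#' @param score numeric score series; \code{NA} entries stay \code{NA}
#'   (excluded pairwise downstream).
#' @param rate fraction in (0, 1).
#' @return Integer 0/1 vector of the same length.
#' @export
spikeBinarize <- function(score, rate) {
  if (rate <= 0 || rate >= 1) stop("rate must be in (0, 1)", call. = FALSE)
  if (all(is.na(score))) stop("score is all NA", call. = FALSE)
  a <- abs(score)
  n <- sum(!is.na(a))
  k <- max(1L, round(rate * n))
  out <- integer(length(score))
  out[order(a, decreasing = TRUE, na.last = TRUE)[seq_len(k)]] <- 1L
  out[is.na(a)] <- NA_integer_   # degenerate transitions stay excluded
  out
}

#' Matthews correlation coefficient of two binary vectors
#'
#' \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' defined as 0 when any factor of the denominator vanishes.  Pairs with
#' an \code{NA} on either side are dropped.
#'
#' @param a,b 0/1 vectors of equal length (\code{a} is the prediction,
#'   \code{b} the reference; the statistic is symmetric).
#' @return Value in [-1, 1].
#' @export
matthewsCorr <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tp <- sum(a == 1 & b == 1); tn <- sum(a == 0 & b == 0)
  fp <- sum(a == 1 & b == 0); fn <- sum(a == 0 & b == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Permutation test for the spike--event Matthews correlation
#'
#' Permutes the first vector and recomputes the MCC; the p-value uses
#' the add-one estimator \eqn{p = (1 + \#\{MCC^{perm} \ge MCC\}) /
#' (n_{perm} + 1)}.  Uniform shuffles are the default; circular shifts
#' are available for autocorrelation-robust checks.
#'
#' @param a,b 0/1 vectors (\code{a} is permuted).
#' @param nPerm number of permutations (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @param scheme \code{"shuffle"} (uniform permutation) or
#'   \code{"circular"} (random cyclic shifts).
#' @return List with \code{observed} (the MCC) and \code{pValue}.
#' @export
permutationTest <- function(a, b, nPerm = 2000L, seed = NULL,
                            scheme = c("shuffle", "circular")) {
  scheme <- match.arg(scheme)
  nPerm <- as.integer(nPerm)
  if (nPerm < 99L) stop("need at least 99 permutations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- matthewsCorr(a, b)
  n <- length(a)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    ap <- if (scheme == "shuffle") {
      sample(a)
    } else {
      k <- sample.int(n, 1L)
      a[((seq_len(n) - 1L + k) %% n) + 1L]
    }
    if (matthewsCorr(ap, b) >= obs) hits <- hits + 1L
  }
  list(observed = obs, pValue = (1 + hits) / (nPerm + 1))
}
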