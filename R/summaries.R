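#' @include AllClasses.R AllGenerics.R
NULL

#' Spearman alignment of two series after first-differencing
#'
#' Spearman rank correlation between \eqn{\{\Delta a_t\}} and
#' \eqn{\{\Delta b_t\}}; used to quantify how the truncated spectral-core
#' entropy tracks (or anti-tracks) full-spectrum von Neumann entropy
#' dynamics.
#'
#' @param a,b numeric series of equal length.
#' @return Spearman rho of the first differences.
#' @export
diffAlignment <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  da <- diff(a); db <- diff(b)
  ok <- !is.na(da) & !is.na(db)
  if (sum(ok) < 3L)
    stop("need at least 4 windows after differencing and masking",
         call. = FALSE)
  stats::cor(da[ok], db[ok], method = "spearman")
}

#' Subject-level variability summary
#'
#' Sample standard deviations (denominator n - 1) of the internal-energy
#' and entropy series of one subject's trajectory; the subject-level
#' summary used for group comparison.
#'
#' @param traj a \linkS4class{ThermoTrajectory} with at least 2 windows.
#' @return Named numeric vector \code{c(sdU = , sdS = )}.
#' @export
subjectVariability <- function(traj) {
  if (length(traj@U) < 2L) stop("need at least 2 windows", call. = FALSE)
  c(sdU = stats::sd(traj@U), sdS = stats::sd(traj@S))
}

#' Two-group comparison of subject-level summaries
#'
#' Two-sample Kolmogorov-Smirnov test plus a descriptive Kullback-Leibler
#' divergence estimated from histogram densities on shared equal-width
#' bins spanning the pooled range, with additive smoothing and natural
#' logarithm.  KL is reported as a descriptive complement only; the KS
#' test carries the inference.
#'
#' @param valuesA,valuesB numeric vectors (>= 5 subjects each).
#' @param bins number of shared histogram bins (default 20).
#' @param smooth additive smoothing added to each bin mass.
#' @return List with \code{ksStat}, \code{ksP} and \code{kl}.
#' @export
groupCompare <- function(valuesA, valuesB, bins = 20L, smooth = 1e-9) {
  if (length(valuesA) < 5L || length(valuesB) < 5L)
    stop("need at least 5 subjects per group", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(valuesA, valuesB))
  rng <- range(c(valuesA, valuesB))
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  pa <- tabulate(findInterval(valuesA, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + smooth
  pb <- tabulate(findInterval(valuesB, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + smooth
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  list(ksStat = unname(ks$statistic), ksP = unname(ks$p.value),
       kl = sum(pa * log(pa / pb)))
}

#' Ranked node-level group differences in node energy
#'
#' Per-node difference of group means of per-subject node-energy
#' summaries, ranked by absolute difference; optionally joined against a
#' lookup table of region labels.
#'
#' @param groupA,groupB numeric matrices, subjects x nodes, of
#'   per-subject node-energy means (see [nodeEnergy()] on a trajectory;
#'   the per-subject summary is the mean over windows).
#' @param labels optional lookup \code{data.frame} with columns
#'   \code{index} (0-based node index) and any annotation columns (e.g.
#'   \code{label}, \code{region}, \code{function}); joined by index.
#' @return \code{data.frame} with columns \code{index} (0-based),
#'   \code{mean_a}, \code{mean_b}, \code{diff}, \code{abs_diff},
#'   \code{rank}, plus any annotation columns, ordered by decreasing
#'   absolute difference.
#' @export
nodeEnergyGroupDiff <- function(groupA, groupB, labels = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB))
    stop("node counts differ between groups", call. = FALSE)
  ma <- colMeans(groupA); mb <- colMeans(groupB)
  out <- data.frame(index = seq_along(ma) - 1L,
                    mean_a = ma, mean_b = mb, diff = ma - mb,
                    abs_diff = abs(ma - mb))
  out <- out[order(-out$abs_diff), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(labels)) {
    if (!"index" %in% names(labels))
      stop("labels must have an 'index' column", call. = FALSE)
    out <- merge(out, labels, by = "index", all.x = TRUE, sort = FALSE)
    out <- out[order(out$rank), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
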