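#' @include AllClasses.R AllGenerics.R
NULL

#' Segment a multivariate time series into sliding windows
#'
#' Window \eqn{k} (0-based) covers rows \eqn{k s, \ldots, k s + w - 1};
#' there are \eqn{\lfloor (T - w)/s \rfloor + 1} windows.
#'
#' @param x numeric matrix, time points x regions.
#' @param windowLength window length \eqn{w \ge 2} (rows).
#' @param stride step size \eqn{s \ge 1}.
#' @return List of \eqn{w \times N} matrices.
#' @examples
#' length(segmentWindows(matrix(rnorm(176 * 3), 176), 5, 1))  # 172
#' @export
segmentWindows <- function(x, windowLength, stride = 1L) {
  x <- as.matrix(x)
  w <- as.integer(windowLength); s <- as.integer(stride)
  if (w < 2L) stop("window length must be >= 2", call. = FALSE)
  if (s < 1L) stop("stride must be >= 1", call. = FALSE)
  Tn <- nrow(x)
  if (Tn < w)
    stop(sprintf("series has %d time points but the window length is %d",
                 Tn, w), call. = FALSE)
  starts <- seq.int(0L, Tn - w, by = s)
  lapply(starts, function(t0) x[(t0 + 1L):(t0 + w), , drop = FALSE])
}

#' Pearson correlation graph of one window
#'
#' Pairwise Pearson correlations with the diagonal set to zero.  Columns
#' with zero variance inside the window have undefined correlations; all
#' their incident entries are set to 0 (a constant region is treated as
#' disconnected for that window) and the number of such columns is
#' attached as attribute \code{nConstant}.
#'
#' @param segment numeric matrix with at least 2 rows.
#' @return Symmetric \eqn{N \times N} matrix, zero diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @export
correlationGraph <- function(segment) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 2L)
    stop("need at least 2 rows to correlate", call. = FALSE)
  sds <- apply(segment, 2L, stats::sd)
  nConst <- sum(sds == 0)
  A <- suppressWarnings(stats::cor(segment))
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2   # symmetrize round-off
  attr(A, "nConstant") <- nConst
  A
}

#' Binarize a weighted graph at a strict threshold
#'
#' Edges are kept where the weight is strictly greater than the
#' threshold (a correlation of exactly 0.5 does not pass the default
#' cutoff); negative correlations never become edges.
#'
#' @param adj symmetric weighted matrix with zero diagonal.
#' @param threshold strict cutoff (default 0.5).
#' @return Binary adjacency matrix.
#' @export
binarizeGraph <- function(adj, threshold = 0.5) {
  .stopIfBadAdjacency(adj)
  B <- (adj > threshold) * 1
  diag(B) <- 0
  B
}

#' Structural similarity between two adjacency matrices
#'
#' Global (single-window) SSIM over all matrix entries, treating the
#' full adjacency matrix (both symmetric halves and the zero diagonal)
#' as a gray-scale image:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                   {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}, \eqn{L} the data
#' range (1 for binary graphs, max minus min of the pair otherwise).
#' A locally windowed variant (uniform \code{windowSize} x
#' \code{windowSize} patches, mean over valid positions) is available for
#' sensitivity checks.
#'
#' @param a,b matrices of identical shape.
#' @param dataRange dynamic range L; default 1 for binary inputs,
#'   max - min of the pooled entries otherwise (1 if that range is 0).
#' @param windowed use the locally windowed variant instead of the
#'   global formula.
#' @param windowSize patch side for the windowed variant.
#' @return Similarity in \eqn{[-1, 1]}; 1 for identical inputs.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' ssimPair(A, A)   # 1
#' @export
ssimPair <- function(a, b, dataRange = NULL, windowed = FALSE,
                     windowSize = 7L) {
  if (!all(dim(a) == dim(b)))
    stop("matrices must have identical shape", call. = FALSE)
  if (is.null(dataRange)) {
    if (all(a %in% c(0, 1)) && all(b %in% c(0, 1))) {
      dataRange <- 1
    } else {
      dataRange <- max(a, b) - min(a, b)
      if (dataRange == 0) dataRange <- 1
    }
  }
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  if (!windowed) return(.ssimStat(a, b, C1, C2))
  k <- as.integer(windowSize)
  n <- nrow(a); m <- ncol(a)
  if (k > min(n, m)) k <- min(n, m)
  vals <- c()
  for (i in seq_len(n - k + 1L))
    for (j in seq_len(m - k + 1L)) {
      ii <- i:(i + k - 1L); jj <- j:(j + k - 1L)
      vals <- c(vals, .ssimStat(a[ii, jj], b[ii, jj], C1, C2))
    }
  mean(vals)
}

.ssimStat <- function(x, y, C1, C2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Build a time-varying graph sequence from a regional time series
#'
#' Sliding-window composition: [segmentWindows()] then
#' [correlationGraph()] per window, then [binarizeGraph()] unless
#' \code{keepWeighted}.  In weighted mode the raw Pearson correlations
#' (including negative entries) are stored as-is; the thermodynamic
#' descriptors use those stored weights directly and require them to be
#' non-negative, so binary mode is the default analysis pipeline.
#'
#' @param x numeric matrix, time points x regions (see
#'   [readTimeSeries()]).
#' @param windowLength,stride sliding-window parameters (defaults 5, 1).
#' @param threshold binarization cutoff (default 0.5, strict).
#' @param keepWeighted store raw correlation graphs instead of
#'   binarizing.
#' @return A \linkS4class{WindowedGraphSequence}.
#' @examples
#' x <- matrix(rnorm(30 * 6), 30)
#' gs <- buildDynamicGraph(x)
#' nWindows(gs)            # 26
#' length(ssimSeries(gs))  # 25
#' @export
buildDynamicGraph <- function(x, windowLength = 5L, stride = 1L,
                              threshold = 0.5, keepWeighted = FALSE) {
  x <- as.matrix(x)
  segs <- segmentWindows(x, windowLength, stride)
  gl <- lapply(segs, function(s) {
    A <- correlationGraph(s)
    attr(A, "nConstant") <- NULL
    if (keepWeighted) A else binarizeGraph(A, threshold)
  })
  labels <- colnames(x)
  WindowedGraphSequence(
    gl, windowLength = windowLength, stride = stride,
    binary = !keepWeighted,
    threshold = if (keepWeighted) NA_real_ else threshold,
    nodeLabels = if (is.null(labels)) character() else labels)
}

#' @rdname ssimSeries
#' @export
setMethod("ssimSeries", "WindowedGraphSequence", function(x, ...) {
  g <- x@graphs
  if (length(g) < 2L) return(numeric())
  vapply(seq_len(length(g) - 1L),
         function(i) ssimPair(g[[i]], g[[i + 1L]], ...), numeric(1))
})
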