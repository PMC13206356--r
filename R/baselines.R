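#' @include AllClasses.R AllGenerics.R
NULL

#' Default log-spaced heat-trace grid
#'
#' 250 points log-spaced in [1e-2, 1e2].
#'
#' @return Numeric vector of diffusion times.
#' @export
netlsdTimeGrid <- function()
  exp(seq(log(1e-2), log(1e2), length.out = 250L))

#' Heat-trace (NetLSD) signature of a graph
#'
#' \eqn{h(t) = \sum_i e^{-t \lambda_i}} over the full normalized-Laplacian
#' spectrum.  As \eqn{t \to 0}, \eqn{h \to N}; as \eqn{t \to \infty},
#' \eqn{h} tends to the number of zero eigenvalues (connected components
#' plus isolated nodes).
#'
#' @param adj adjacency matrix, or a precomputed eigenvalue vector.
#' @param tGrid diffusion times (default [netlsdTimeGrid()]).
#' @return Numeric vector of \code{length(tGrid)}.
#' @export
netlsdSignature <- function(adj, tGrid = netlsdTimeGrid()) {
  ev <- if (is.matrix(adj) && nrow(adj) > 1L && ncol(adj) == nrow(adj)) {
    graphSpectrum(adj)$eigenvalues
  } else {
    as.numeric(adj)
  }
  colSums(exp(-outer(ev, tGrid)))
}

#' NetLSD change score of a graph sequence
#'
#' Per-transition Euclidean distance between consecutive heat-trace
#' signatures; identical consecutive graphs score 0.
#'
#' @param seq a \linkS4class{WindowedGraphSequence} or list of adjacency
#'   matrices.
#' @param tGrid diffusion times.
#' @return Numeric series of length \code{nWindows - 1}.
#' @export
netlsdScore <- function(seq, tGrid = netlsdTimeGrid()) {
  gl <- if (is(seq, "WindowedGraphSequence")) seq@graphs else seq
  sig <- lapply(gl, netlsdSignature, tGrid = tGrid)
  vapply(seq_len(length(sig) - 1L),
         function(i) sqrt(sum((sig[[i + 1L]] - sig[[i]])^2)), numeric(1))
}

#' K-means cluster-switch baseline
#'
#' Clusters the vectorized upper triangles of the (weighted) per-window
#' correlation matrices with k-means and scores a transition 1 when the
#' cluster assignment changes between consecutive windows.
#'
#' @param seq a \linkS4class{WindowedGraphSequence} (weighted) or list of
#'   matrices.
#' @param k number of clusters (default 4).
#' @param seed integer seed (k-means is stochastic).
#' @param nstart restarts passed to [stats::kmeans()].
#' @return Integer 0/1 switch series of length \code{nWindows - 1}.
#' @export
kmeansSwitchEvents <- function(seq, k = 4L, seed = NULL, nstart = 5L) {
  gl <- if (is(seq, "WindowedGraphSequence")) seq@graphs else seq
  if (length(gl) <= k)
    stop("need more windows than clusters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  feat <- t(vapply(gl, function(A) A[upper.tri(A)],
                   numeric(sum(upper.tri(gl[[1L]])))))
  k <- min(k, nrow(unique(feat)))   # repeated windows: fewer clusters
  if (k == 1L) return(integer(length(gl) - 1L))
  cl <- stats::kmeans(feat, centers = k, nstart = nstart,
                      iter.max = 50L)$cluster
  as.integer(cl[-1L] != cl[-length(cl)])
}

#' Edge-count-preserving surrogate of a binary graph sequence
#'
#' Per window, keeps only the number of edges of the binarized graph and
#' reassigns their positions uniformly at random (an Erdos-Renyi G(n, m)
#' draw).  Higher-order structure is destroyed while the internal-energy
#' series is preserved exactly, giving a null model that tests whether a
#' result depends on density alone.
#'
#' @param seq a binary \linkS4class{WindowedGraphSequence}.
#' @param seed optional integer seed.
#' @return A \linkS4class{WindowedGraphSequence} with the same per-window
#'   edge counts.
#' @export
edgePreservingSurrogate <- function(seq, seed = NULL) {
  if (!seq@binary)
    stop("the surrogate is defined on binary sequences", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nNodes(seq)
  ut <- which(upper.tri(matrix(0, n, n)))
  gl <- lapply(seq@graphs, function(A) {
    m <- sum(A) / 2
    B <- matrix(0, n, n)
    if (m > 0) {
      B[sample(ut, m)] <- 1
      B <- B + t(B)
    }
    B
  })
  initialize(seq, graphs = gl)
}
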