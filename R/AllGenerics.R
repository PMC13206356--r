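#' @include AllClasses.R
NULL

#' Number of nodes in a graph container
#'
#' @param x a \linkS4class{WindowedGraphSequence} or \linkS4class{ThermoTrajectory}.
#' @return Integer scalar.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of graph windows
#'
#' @param x a \linkS4class{WindowedGraphSequence} or \linkS4class{ThermoTrajectory}.
#' @return Integer scalar.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' Extract the list of adjacency matrices
#'
#' @param x a \linkS4class{WindowedGraphSequence}.
#' @return List of symmetric adjacency matrices.
#' @export
setGeneric("graphs", function(x) standardGeneric("graphs"))

#' Internal energy (total edge mass)
#'
#' For a single adjacency matrix, the internal energy is the total edge
#' mass \eqn{U = \sum_{i<j} w_{ij}} (the edge count for a binary graph).
#' For a \linkS4class{WindowedGraphSequence} it is the per-window series;
#' for a \linkS4class{ThermoTrajectory} the stored series is returned.
#'
#' @param x adjacency matrix, \linkS4class{WindowedGraphSequence} or
#'   \linkS4class{ThermoTrajectory}.
#' @return Numeric scalar or numeric vector of per-window values.
#' @examples
#' A <- matrix(1, 4, 4) - diag(4)   # K4
#' internalEnergy(A)                # 6 edges
#' @export
setGeneric("internalEnergy", function(x) standardGeneric("internalEnergy"))

#' Node energy
#'
#' Allocates the total edge mass locally: node \eqn{i} receives
#' \eqn{U_i = \sum_j w_{ij}\, d_i/(d_i+d_j)} over its neighbours, where
#' \eqn{d_i} is the (weighted) degree.  Each unit of edge weight is split
#' between its endpoints in proportion to their degrees, so
#' \eqn{\sum_i U_i} equals the internal energy exactly.
#'
#' @param x adjacency matrix or \linkS4class{ThermoTrajectory}.
#' @return Numeric vector of length \code{nNodes} (for a matrix), or the
#'   windows-by-nodes matrix stored in a trajectory.
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' nodeEnergy(star)   # centre 2.25, leaves 0.25; sums to |E| = 3
#' @export
setGeneric("nodeEnergy", function(x) standardGeneric("nodeEnergy"))

#' Spectral Core Entropy
#'
#' Shannon-type entropy over the top-\code{alpha} eigenvalues of the
#' normalized Laplacian, with micro-state probabilities
#' \eqn{p_i = \tilde\lambda_i / |V|} (or renormalized within the retained
#' set when \code{renormalize = TRUE}).  With \code{alpha = nNodes} and no
#' renormalization this equals the full von Neumann graph entropy.
#'
#' @param x adjacency matrix, \linkS4class{WindowedGraphSequence} or
#'   \linkS4class{ThermoTrajectory}.
#' @param alpha number of leading eigenvalues retained (default 20).
#' @param renormalize rescale probabilities within the retained set.
#' @param solver eigenvalue solver, see [graphSpectrum()].
#' @return Numeric scalar (matrix input) or per-window numeric series.
#' @examples
#' K4 <- matrix(1, 4, 4) - diag(4)
#' spectralCoreEntropy(K4, alpha = 4)   # log(3)
#' @export
setGeneric("spectralCoreEntropy",
  function(x, alpha = 20L, renormalize = FALSE, solver = "auto")
    standardGeneric("spectralCoreEntropy"))

#' Von Neumann graph entropy
#'
#' Full-spectrum entropy \eqn{-\sum_i p_i \log p_i} with
#' \eqn{p_i = \tilde\lambda_i/|V|} over all normalized-Laplacian
#' eigenvalues; the untruncated limit of [spectralCoreEntropy()].
#'
#' @param x adjacency matrix, \linkS4class{WindowedGraphSequence} or
#'   \linkS4class{ThermoTrajectory} (computed with \code{withVne = TRUE}).
#' @return Numeric scalar or per-window series.
#' @export
setGeneric("vonNeumannEntropy", function(x) standardGeneric("vonNeumannEntropy"))

#' Temperature-like reconfiguration index of a trajectory
#'
#' Accessor for the stored series \eqn{T_n = \Delta U_n / \Delta S_n}
#' (first element 0 by convention; \code{NaN} where \eqn{|\Delta S|} fell
#' below the degeneracy guard).
#'
#' @param x a \linkS4class{ThermoTrajectory}.
#' @return Numeric series of length \code{nWindows}.
#' @seealso [temperatureSeries()] for the underlying computation.
#' @export
setGeneric("temperatureIndex", function(x) standardGeneric("temperatureIndex"))

#' SSIM series between consecutive windows
#'
#' @param x a \linkS4class{WindowedGraphSequence}.
#' @param ... passed to [ssimPair()].
#' @return Numeric vector of length \code{nWindows - 1}; entry \eqn{t}
#'   compares windows \eqn{t} and \eqn{t+1}.
#' @export
setGeneric("ssimSeries", function(x, ...) standardGeneric("ssimSeries"))

#' Event labels of an EventSeries
#'
#' @param x an \linkS4class{EventSeries}.
#' @return Integer 0/1 vector over transition indices.
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' Ground-truth change points of a benchmark scenario
#'
#' @param x a \linkS4class{DCSBMScenario}.
#' @return Integer vector of 0-based window indices at which a new
#'   segment starts.
#' @export
setGeneric("changePoints", function(x) standardGeneric("changePoints"))
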