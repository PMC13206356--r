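# Central S4 containers. Adjacency matrices are plain base matrices
# (symmetric, zero diagonal, finite); the classes below hold sequences of
# them and the derived per-window descriptor series.

.checkAdjacency <- function(A, requireNonNegative = FALSE) {
  if (!is.matrix(A) || !is.numeric(A))
    return("adjacency must be a numeric matrix")
  if (nrow(A) != ncol(A))
    return(sprintf("adjacency must be square (got %d x %d)", nrow(A), ncol(A)))
  if (any(!is.finite(A)))
    return("adjacency contains non-finite entries")
  if (max(abs(A - t(A))) > 1e-8)
    return("adjacency must be symmetric")
  if (any(diag(A) != 0))
    return("adjacency diagonal must be zero")
  if (requireNonNegative && any(A < 0))
    return("adjacency entries must be non-negative")
  NULL
}

.stopIfBadAdjacency <- function(A, requireNonNegative = FALSE) {
  msg <- .checkAdjacency(A, requireNonNegative)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  invisible(A)
}

#' WindowedGraphSequence: ordered adjacency matrices over a fixed node set
#'
#' The container consumed by all per-window descriptors.  Graphs are
#' symmetric matrices with zero diagonal sharing one node set; binary
#' sequences additionally have entries in \{0, 1\}.  Weighted sequences
#' built from Pearson correlations may carry negative weights; the
#' thermodynamic descriptors require non-negative weights and check this
#' at call time.
#'
#' @slot graphs list of adjacency matrices.
#' @slot windowLength,stride sliding-window parameters used to build the
#'   sequence from a time series (\code{NA} for externally supplied
#'   sequences).
#' @slot startIndices 0-based start row of each window in the source
#'   series (\code{k * stride}).
#' @slot binary whether the graphs are binarized.
#' @slot threshold binarization threshold used (\code{NA} if none).
#' @slot nodeLabels optional region labels.
#' @export
setClass("WindowedGraphSequence",
  representation(
    graphs = "list",
    windowLength = "integer",
    stride = "integer",
    startIndices = "integer",
    binary = "logical",
    threshold = "numeric",
    nodeLabels = "character"
  ),
  prototype(
    windowLength = NA_integer_, stride = NA_integer_,
    startIndices = integer(), binary = FALSE, threshold = NA_real_,
    nodeLabels = character()
  )
)

setValidity("WindowedGraphSequence", function(object) {
  g <- object@graphs
  if (length(g) == 0L) return("sequence must contain at least one graph")
  n <- nrow(g[[1L]])
  for (i in seq_along(g)) {
    msg <- .checkAdjacency(g[[i]])
    if (!is.null(msg)) return(sprintf("graph %d: %s", i, msg))
    if (nrow(g[[i]]) != n)
      return(sprintf("graph %d has %d nodes, expected %d", i, nrow(g[[i]]), n))
    if (object@binary && !all(g[[i]] %in% c(0, 1)))
      return(sprintf("graph %d is not binary", i))
  }
  if (length(object@nodeLabels) && length(object@nodeLabels) != n)
    return("nodeLabels length does not match node count")
  TRUE
})

#' Construct a WindowedGraphSequence
#'
#' @param graphs list of symmetric zero-diagonal adjacency matrices.
#' @param windowLength,stride sliding-window metadata (optional).
#' @param startIndices 0-based window start rows; defaults to
#'   \code{(k - 1) * stride} when a stride is given.
#' @param binary logical flag; inferred from the matrices if missing.
#' @param threshold binarization threshold metadata.
#' @param nodeLabels optional character vector of node labels.
#' @return A \linkS4class{WindowedGraphSequence}.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
#' gs <- WindowedGraphSequence(list(A, A))
#' nWindows(gs)
#' @export
WindowedGraphSequence <- function(graphs, windowLength = NA_integer_,
                                  stride = NA_integer_,
                                  startIndices = NULL,
                                  binary = NA, threshold = NA_real_,
                                  nodeLabels = character()) {
  if (is.matrix(graphs)) graphs <- list(graphs)
  if (is.na(binary))
    binary <- all(vapply(graphs, function(A) all(A %in% c(0, 1)), logical(1)))
  if (is.null(startIndices)) {
    startIndices <- if (!is.na(stride))
      as.integer((seq_along(graphs) - 1L) * stride) else integer()
  }
  new("WindowedGraphSequence", graphs = graphs,
      windowLength = as.integer(windowLength), stride = as.integer(stride),
      startIndices = as.integer(startIndices), binary = isTRUE(binary),
      threshold = as.numeric(threshold), nodeLabels = nodeLabels)
}

#' ThermoTrajectory: per-window thermodynamic descriptors
#'
#' Houses the time-indexed quantities of a graph sequence: internal
#' energy U, Spectral Core Entropy S, optional full von Neumann entropy,
#' the temperature-like index T = dU/dS, and the windows-by-nodes node
#' energy matrix.
#'
#' @slot U internal-energy series (edge mass per window).
#' @slot S Spectral Core Entropy series (nats).
#' @slot VNE optional full von Neumann entropy series (length 0 if not
#'   computed).
#' @slot T temperature-like reconfiguration index; first element 0,
#'   \code{NaN} where the entropy increment was degenerate.
#' @slot nodeEnergy numeric matrix, windows x nodes.
#' @slot alpha,renormalize spectral configuration used.
#' @slot nDegenerate number of transitions with \eqn{|\Delta S|} below the
#'   degeneracy guard.
#' @export
setClass("ThermoTrajectory",
  representation(
    U = "numeric", S = "numeric", VNE = "numeric", T = "numeric",
    nodeEnergy = "matrix", alpha = "integer", renormalize = "logical",
    nDegenerate = "integer"
  )
)

setValidity("ThermoTrajectory", function(object) {
  n <- length(object@U)
  if (length(object@S) != n || length(object@T) != n)
    return("U, S and T must have equal length")
  if (length(object@VNE) && length(object@VNE) != n)
    return("VNE length must match U")
  if (nrow(object@nodeEnergy) != n)
    return("nodeEnergy must have one row per window")
  if (n >= 1L && !identical(object@T[1L], 0))
    return("T[1] must be 0")
  TRUE
})

#' EventSeries: binary reconfiguration labels over transition indices
#'
#' @slot labels integer 0/1 vector; entry \eqn{t} refers to the
#'   transition between windows \eqn{t} and \eqn{t+1}.
#' @slot quantile the SSIM quantile used for labeling (\code{NA} if the
#'   labels were supplied directly).
#' @slot tolerance lag tolerance (windows) already applied by dilation.
#' @slot degenerate flag set when labeling produced no positives.
#' @export
setClass("EventSeries",
  representation(labels = "integer", quantile = "numeric",
                 tolerance = "integer", degenerate = "logical"),
  prototype(quantile = NA_real_, tolerance = 0L, degenerate = FALSE)
)

setValidity("EventSeries", function(object) {
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (object@tolerance < 0L) return("tolerance must be >= 0")
  TRUE
})

#' Construct an EventSeries from explicit labels
#'
#' @param labels 0/1 vector over transition indices.
#' @param quantile,tolerance metadata (see class slots).
#' @return An \linkS4class{EventSeries}.
#' @export
EventSeries <- function(labels, quantile = NA_real_, tolerance = 0L) {
  new("EventSeries", labels = as.integer(labels),
      quantile = as.numeric(quantile), tolerance = as.integer(tolerance),
      degenerate = !any(labels == 1L))
}

#' DetectionSummary: metrics for one score--label pairing
#'
#' @slot auroc,ap rank-based AUROC and average precision (NA when the
#'   labels are degenerate after masking).
#' @slot mcc,pValue Matthews correlation and permutation p-value (NA
#'   unless computed).
#' @slot nEvents number of positive labels used.
#' @slot nValid number of transitions remaining after NaN masking.
#' @export
setClass("DetectionSummary",
  representation(auroc = "numeric", ap = "numeric", mcc = "numeric",
                 pValue = "numeric", nEvents = "integer", nValid = "integer"),
  prototype(auroc = NA_real_, ap = NA_real_, mcc = NA_real_,
            pValue = NA_real_, nEvents = 0L, nValid = 0L)
)

#' DCSBMScenario: generative parameters for one benchmark regime
#'
#' Degree-corrected stochastic block model scenario: n nodes in k equal
#' blocks; a series is three equal segments of windows whose wiring
#' probabilities and/or global gain change at segment boundaries.
#'
#' @slot regime one of "R1" (structure-only rewiring with exact edge-mass
#'   preservation), "R2" (strength-only gain modulation on a frozen
#'   pattern), "R3" (modest rewiring plus gain).
#' @slot nNodes,nBlocks graph size and block count.
#' @slot blocks integer block membership of each node.
#' @slot windowsPerSegment,nSegments temporal layout.
#' @slot wiringGrid matrix with columns p_in, p_out: the wiring cells a
#'   series draws its segments from.
#' @slot gainLevels per-segment multiplicative gain levels (R2/R3).
#' @slot thetaRange range of the uniform node-propensity draw (theta is
#'   renormalized to mean 1 within each block).
#' @slot weightLogSd log-sd of the LogNormal(0, sd) edge-weight draw.
#' @slot r2Wiring the fixed (p_in, p_out) cell used for the frozen R2
#'   pattern.
#' @slot weightRedraw redraw edge weights every window (default TRUE);
#'   FALSE gives the literal pure-gain variant in which SCE is exactly
#'   constant within segments.
#' @export
setClass("DCSBMScenario",
  representation(
    regime = "character", nNodes = "integer", nBlocks = "integer",
    blocks = "integer", windowsPerSegment = "integer", nSegments = "integer",
    wiringGrid = "matrix", gainLevels = "numeric", thetaRange = "numeric",
    weightLogSd = "numeric", r2Wiring = "numeric", weightRedraw = "logical"
  )
)

setValidity("DCSBMScenario", function(object) {
  if (!object@regime %in% c("R1", "R2", "R3"))
    return("regime must be one of R1, R2, R3")
  if (object@nNodes < object@nBlocks) return("need nNodes >= nBlocks")
  if (length(object@blocks) != object@nNodes)
    return("blocks must assign every node")
  g <- object@wiringGrid
  if (ncol(g) != 2L) return("wiringGrid must have columns p_in, p_out")
  if (any(g <= 0) || any(g > 1)) return("wiring probabilities must be in (0, 1]")
  if (any(g[, 1L] < g[, 2L])) return("require p_out <= p_in in every cell")
  if (any(object@gainLevels <= 0)) return("gains must be positive")
  if (object@thetaRange[1L] <= 0) return("theta must be positive")
  TRUE
})

#' Construct a DCSBMScenario
#'
#' Defaults reproduce the benchmark conditions: 80 nodes, 4 equal blocks,
#' three 15-window segments (45 windows, change points at windows 15 and
#' 30), wiring grid \{(0.25,0.05), (0.30,0.05), (0.35,0.08), (0.40,0.10)\},
#' gain levels \{1.2, 1.5, 2.0\}, theta ~ U(0.5, 1.5) block-normalized,
#' LogNormal(0, 0.25) edge weights.
#'
#' @param regime "R1", "R2" or "R3".
#' @param nNodes,nBlocks,windowsPerSegment,nSegments layout parameters.
#' @param wiringGrid 2-column matrix of (p_in, p_out) cells.
#' @param gainLevels per-segment gains for R2/R3.
#' @param thetaRange,weightLogSd,r2Wiring,weightRedraw see class slots.
#' @return A \linkS4class{DCSBMScenario}.
#' @examples
#' scn <- DCSBMScenario("R2")
#' changePoints(scn)
#' @export
DCSBMScenario <- function(regime = c("R1", "R2", "R3"),
                          nNodes = 80L, nBlocks = 4L,
                          windowsPerSegment = 15L, nSegments = 3L,
                          wiringGrid = cbind(
                            p_in  = c(0.25, 0.30, 0.35, 0.40),
                            p_out = c(0.05, 0.05, 0.08, 0.10)),
                          gainLevels = c(1.2, 1.5, 2.0),
                          thetaRange = c(0.5, 1.5),
                          weightLogSd = 0.25,
                          r2Wiring = c(0.30, 0.05),
                          weightRedraw = TRUE) {
  regime <- match.arg(regime)
  nNodes <- as.integer(nNodes); nBlocks <- as.integer(nBlocks)
  blocks <- rep(seq_len(nBlocks), length.out = nNodes)
  blocks <- sort(blocks)
  new("DCSBMScenario", regime = regime, nNodes = nNodes, nBlocks = nBlocks,
      blocks = as.integer(blocks),
      windowsPerSegment = as.integer(windowsPerSegment),
      nSegments = as.integer(nSegments),
      wiringGrid = wiringGrid, gainLevels = gainLevels,
      thetaRange = thetaRange, weightLogSd = weightLogSd,
      r2Wiring = r2Wiring, weightRedraw = isTRUE(weightRedraw))
}
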