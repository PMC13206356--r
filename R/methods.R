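#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nNodes
#' @export
setMethod("nNodes", "WindowedGraphSequence",
          function(x) nrow(x@graphs[[1L]]))

#' @rdname nNodes
#' @export
setMethod("nNodes", "ThermoTrajectory", function(x) ncol(x@nodeEnergy))

#' @rdname nWindows
#' @export
setMethod("nWindows", "WindowedGraphSequence", function(x) length(x@graphs))

#' @rdname nWindows
#' @export
setMethod("nWindows", "ThermoTrajectory", function(x) length(x@U))

#' @rdname graphs
#' @export
setMethod("graphs", "WindowedGraphSequence", function(x) x@graphs)

#' @describeIn WindowedGraphSequence number of windows.
#' @param x a \code{WindowedGraphSequence}.
#' @export
setMethod("length", "WindowedGraphSequence", function(x) length(x@graphs))

#' @describeIn WindowedGraphSequence extract one adjacency matrix.
#' @param i window index.
#' @export
setMethod("[[", "WindowedGraphSequence", function(x, i) x@graphs[[i]])

setMethod("show", "WindowedGraphSequence", function(object) {
  cat(sprintf("WindowedGraphSequence: %d windows, %d nodes, %s\n",
              length(object@graphs), nrow(object@graphs[[1L]]),
              if (object@binary) "binary" else "weighted"))
  if (!is.na(object@windowLength))
    cat(sprintf("  window length %d, stride %d\n",
                object@windowLength, object@stride))
  if (!is.na(object@threshold))
    cat(sprintf("  binarization threshold %.3g (strict >)\n", object@threshold))
  invisible(NULL)
})

#' @rdname temperatureIndex
#' @export
setMethod("temperatureIndex", "ThermoTrajectory", function(x) x@T)

#' @rdname internalEnergy
#' @export
setMethod("internalEnergy", "ThermoTrajectory", function(x) x@U)

#' @rdname nodeEnergy
#' @export
setMethod("nodeEnergy", "ThermoTrajectory", function(x) x@nodeEnergy)

#' @rdname vonNeumannEntropy
#' @export
setMethod("vonNeumannEntropy", "ThermoTrajectory", function(x) {
  if (!length(x@VNE))
    stop("trajectory was computed without the full von Neumann entropy; ",
         "rerun thermoTrajectory() with withVne = TRUE", call. = FALSE)
  x@VNE
})

#' @rdname spectralCoreEntropy
#' @export
setMethod("spectralCoreEntropy", "ThermoTrajectory",
          function(x, alpha, renormalize, solver) x@S)

setMethod("show", "ThermoTrajectory", function(object) {
  cat(sprintf(
    "ThermoTrajectory: %d windows, %d nodes (alpha = %d%s)\n",
    length(object@U), ncol(object@nodeEnergy), object@alpha,
    if (object@renormalize) ", renormalized" else ""))
  cat(sprintf("  U: [%.4g, %.4g]  S: [%.4g, %.4g]\n",
              min(object@U), max(object@U), min(object@S), max(object@S)))
  if (object@nDegenerate > 0L)
    cat(sprintf("  %d degenerate dS transition(s) set to NaN\n",
                object@nDegenerate))
  invisible(NULL)
})

#' Coerce a ThermoTrajectory to a data.frame
#'
#' Columns \code{window_index} (0-based), \code{U}, \code{S}, \code{VNE}
#' (NA if not computed) and \code{T}; the serialization schema used by
#' [writeTrajectory()].
#'
#' @param x a \linkS4class{ThermoTrajectory}.
#' @param ... ignored.
#' @return A \code{data.frame} with one row per window.
#' @export
as.data.frame.ThermoTrajectory <- function(x, ...) {
  data.frame(
    window_index = seq_along(x@U) - 1L,
    U = x@U, S = x@S,
    VNE = if (length(x@VNE)) x@VNE else NA_real_,
    T = x@T
  )
}

setMethod("as.data.frame", "ThermoTrajectory", as.data.frame.ThermoTrajectory)

#' @rdname eventLabels
#' @export
setMethod("eventLabels", "EventSeries", function(x) x@labels)

#' @describeIn EventSeries number of transition indices covered.
#' @param x an \code{EventSeries}.
#' @export
setMethod("length", "EventSeries", function(x) length(x@labels))

setMethod("show", "EventSeries", function(object) {
  cat(sprintf(
    "EventSeries: %d transitions, %d positive(s)%s, tolerance +/-%d\n",
    length(object@labels), sum(object@labels),
    if (is.na(object@quantile)) "" else
      sprintf(" (SSIM quantile %.3g)", object@quantile),
    object@tolerance))
  if (object@degenerate) cat("  degenerate: no positives\n")
  invisible(NULL)
})

setMethod("show", "DetectionSummary", function(object) {
  cat("DetectionSummary\n")
  cat(sprintf("  AUROC %.4f  AP %.4f  MCC %s  p %s\n",
              object@auroc, object@ap,
              ifelse(is.na(object@mcc), "NA", sprintf("%.4f", object@mcc)),
              ifelse(is.na(object@pValue), "NA",
                     sprintf("%.4g", object@pValue))))
  cat(sprintf("  %d event(s), %d valid transition(s)\n",
              object@nEvents, object@nValid))
  invisible(NULL)
})

#' Coerce a DetectionSummary to a data.frame row
#'
#' @param x a \linkS4class{DetectionSummary}.
#' @param ... ignored.
#' @return One-row \code{data.frame} with columns auroc, ap, mcc, p,
#'   n_events, n_valid.
#' @export
as.data.frame.DetectionSummary <- function(x, ...) {
  data.frame(auroc = x@auroc, ap = x@ap, mcc = x@mcc, p = x@pValue,
             n_events = x@nEvents, n_valid = x@nValid)
}

setMethod("as.data.frame", "DetectionSummary", as.data.frame.DetectionSummary)

#' @rdname changePoints
#' @export
setMethod("changePoints", "DCSBMScenario", function(x)
  seq_len(x@nSegments - 1L) * x@windowsPerSegment)

setMethod("show", "DCSBMScenario", function(object) {
  cat(sprintf(
    "DCSBMScenario %s: %d nodes, %d blocks, %d x %d windows\n",
    object@regime, object@nNodes, object@nBlocks,
    object@nSegments, object@windowsPerSegment))
  cat(sprintf("  change points (0-based windows): %s\n",
              paste(changePoints(object), collapse = ", ")))
  invisible(NULL)
})
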