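#' @include AllClasses.R AllGenerics.R
NULL

#' Synthetic fixture subject with planted connectivity switches
#'
#' Generates a regional time-series matrix emulating a short
#' resting-state acquisition (defaults: 176 time points, 40 regions)
#' whose correlation structure switches at the planted event times.
#' Regions load a shared latent factor with a fixed sign pattern
#' (\code{corStrength} of the variance); at each event the sign of
#' exactly half the regions flips, so roughly half of all region pairs
#' change their correlation sign.  Under the default pipeline (window 5,
#' stride 1, threshold 0.5) this produces a deep SSIM trough centred at
#' transition index \code{eventTime - floor(w/2)}; see
#' [expectedEventTransition()].
#'
#' This is a synthetic stand-in for an extracted fMRI time series: it
#' reproduces the pipeline-relevant features (block-structured
#' correlations, abrupt regime switches, short windows) but none of the
#' autocorrelation, drift or motion artifacts of real data.
#'
#' @param nRegions number of regions (columns).
#' @param nTimepoints number of time points (rows).
#' @param eventTimes 0-based row indices at which a new correlation
#'   regime starts (empty for a stationary subject).
#' @param corStrength share of variance carried by the latent factor,
#'   in (0, 1); default 0.98.
#' @param seed integer seed; the subject is deterministic given it.
#' @param subjectId optional identifier stored as an attribute.
#' @return Numeric matrix \code{nTimepoints x nRegions} with attributes
#'   \code{eventTimes} and \code{subjectId}.
#' @examples
#' x <- makeFixtureSubject(seed = 1)
#' dim(x)   # 176 x 40
#' @export
makeFixtureSubject <- function(nRegions = 40L, nTimepoints = 176L,
                               eventTimes = c(88L), corStrength = 0.98,
                               seed = NULL, subjectId = NA_character_) {
  if (length(eventTimes) &&
      (any(eventTimes <= 0L) || any(eventTimes >= nTimepoints)))
    stop("eventTimes must lie strictly inside the series", call. = FALSE)
  if (corStrength <= 0 || corStrength >= 1)
    stop("corStrength must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bounds <- c(0L, sort(as.integer(eventTimes)), nTimepoints)
  X <- matrix(0, nTimepoints, nRegions)
  sgn <- sample(c(-1, 1), nRegions, replace = TRUE)
  for (segIdx in seq_len(length(bounds) - 1L)) {
    if (segIdx > 1L) {   # flip exactly half the region signs
      flip <- sample.int(nRegions, nRegions %/% 2L)
      sgn[flip] <- -sgn[flip]
    }
    rows <- (bounds[segIdx] + 1L):bounds[segIdx + 1L]
    f <- stats::rnorm(length(rows))
    X[rows, ] <- sqrt(corStrength) * outer(f, sgn) +
      sqrt(1 - corStrength) *
      matrix(stats::rnorm(length(rows) * nRegions), length(rows))
  }
  colnames(X) <- sprintf("R%03d", seq_len(nRegions))
  attr(X, "eventTimes") <- as.integer(eventTimes)
  attr(X, "subjectId") <- subjectId
  X
}

#' Transition index at which a planted switch is expected
#'
#' For a switch at 0-based time point \code{eventTime} and sliding
#' windows of length \code{w} with stride 1, the windows mixing both
#' regimes span transitions \code{eventTime - w + 1} to
#' \code{eventTime}; the centre of that zone,
#' \code{eventTime - floor(w/2)}, is the canonical location of the SSIM
#' trough (1-based index into the transition series).
#'
#' @param eventTime 0-based switch time point.
#' @param windowLength sliding-window length.
#' @return 1-based transition index.
#' @export
expectedEventTransition <- function(eventTime, windowLength = 5L)
  as.integer(eventTime) - as.integer(windowLength) %/% 2L
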