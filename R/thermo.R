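#' @include AllClasses.R AllGenerics.R
NULL

#' Normalized Laplacian of a graph
#'
#' Returns \eqn{\tilde L = D^{-1/2} (D - A) D^{-1/2}} with the convention
#' that rows and columns of isolated nodes (weighted degree 0) are zero,
#' so the diagonal entry is 1 exactly where the degree is positive.  The
#' trace therefore equals the number of non-isolated nodes, and all
#' eigenvalues lie in [0, 2].
#'
#' @param adj symmetric non-negative adjacency matrix with zero diagonal;
#'   for weighted graphs the degree is the weighted degree
#'   \eqn{d_i = \sum_j w_{ij}}.
#' @return A symmetric positive semi-definite matrix of the same size.
#' @examples
#' K2 <- matrix(c(0, 1, 1, 0), 2, 2)
#' normalizedLaplacian(K2)   # [[1,-1],[-1,1]]
#' @export
normalizedLaplacian <- function(adj) {
  .stopIfBadAdjacency(adj, requireNonNegative = TRUE)
  d <- rowSums(adj)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -adj * outer(s, s)
  diag(L) <- as.numeric(d > 0)
  L
}

# Top-k eigenvalues of a dense symmetric matrix through ARPACK
# (implicitly restarted Lanczos); falls back to a dense decomposition
# with a warning if the iteration does not converge.
.lanczosTop <- function(M, k, tol = 1e-10) {
  n <- nrow(M)
  res <- tryCatch({
    out <- igraph::arpack(
      function(x, extra = NULL) as.numeric(M %*% x),
      options = list(n = n, nev = k, ncv = min(n, max(2L * k + 1L, 20L)),
                     which = "LA", maxiter = 3000L, tol = tol),
      sym = TRUE)
    sort(out$values, decreasing = TRUE)[seq_len(k)]
  }, error = function(e) e)
  if (inherits(res, "error")) {
    warning("Lanczos iteration failed (", conditionMessage(res),
            "); falling back to dense decomposition", call. = FALSE)
    res <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)[seq_len(k)]
  }
  res
}

#' Eigenvalue spectrum and micro-state probabilities of a graph
#'
#' Computes the leading \code{alpha} eigenvalues of the normalized
#' Laplacian, in decreasing order, together with the micro-state
#' probabilities \eqn{p_i = \tilde\lambda_i / |V|} (plain) or
#' \eqn{p_i = \tilde\lambda_i / \sum_{top-\alpha} \tilde\lambda}
#' (renormalized).  The solver is chosen automatically: a dense
#' decomposition for graphs up to 512 nodes or when more than half the
#' spectrum is requested, ARPACK Lanczos otherwise.
#'
#' @param adj adjacency matrix (symmetric, non-negative, zero diagonal).
#' @param alpha number of leading eigenvalues to retain; \code{NULL}
#'   means the full spectrum.
#' @param renormalize rescale probabilities within the retained set.
#' @param solver \code{"auto"}, \code{"dense"} or \code{"lanczos"}.
#' @param lanczosTol convergence tolerance of the Lanczos iteration.
#' @return List with components \code{eigenvalues} (decreasing) and
#'   \code{probabilities}.
#' @examples
#' K4 <- matrix(1, 4, 4) - diag(4)
#' graphSpectrum(K4)$eigenvalues   # 4/3, 4/3, 4/3, 0
#' @export
graphSpectrum <- function(adj, alpha = NULL, renormalize = FALSE,
                          solver = c("auto", "dense", "lanczos"),
                          lanczosTol = 1e-10) {
  solver <- match.arg(solver)
  .stopIfBadAdjacency(adj, requireNonNegative = TRUE)
  n <- nrow(adj)
  if (is.null(alpha)) alpha <- n
  alpha <- as.integer(alpha)
  if (alpha < 1L || alpha > n)
    stop(sprintf("alpha must be in [1, %d], got %d", n, alpha), call. = FALSE)
  L <- normalizedLaplacian(adj)
  if (solver == "auto")
    solver <- if (n <= 512L || alpha > n %/% 2L) "dense" else "lanczos"
  ev <- if (solver == "dense" || alpha == n) {
    sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)[seq_len(alpha)]
  } else {
    .lanczosTop(L, alpha, tol = lanczosTol)
  }
  ev <- pmax(ev, 0)  # clip tiny negative round-off
  p <- if (renormalize) {
    tot <- sum(ev)
    if (tot > 0) ev / tot else rep(0, alpha)
  } else {
    ev / n
  }
  list(eigenvalues = ev, probabilities = p)
}

.entropyFromProbs <- function(p) {
  p <- p[p > 0]          # 0 * log(0) := 0
  if (!length(p)) return(0)
  -sum(p * log(p))
}

#' @rdname spectralCoreEntropy
#' @export
setMethod("spectralCoreEntropy", "matrix",
  function(x, alpha = 20L, renormalize = FALSE, solver = "auto") {
    alpha <- min(as.integer(alpha), nrow(x))
    sp <- graphSpectrum(x, alpha = alpha, renormalize = renormalize,
                        solver = solver)
    .entropyFromProbs(sp$probabilities)
  })

#' @rdname spectralCoreEntropy
#' @export
setMethod("spectralCoreEntropy", "WindowedGraphSequence",
  function(x, alpha = 20L, renormalize = FALSE, solver = "auto") {
    vapply(x@graphs, function(A)
      spectralCoreEntropy(A, alpha = alpha, renormalize = renormalize,
                          solver = solver), numeric(1))
  })

#' @rdname vonNeumannEntropy
#' @export
setMethod("vonNeumannEntropy", "matrix", function(x)
  spectralCoreEntropy(x, alpha = nrow(x), renormalize = FALSE,
                      solver = "dense"))

#' @rdname vonNeumannEntropy
#' @export
setMethod("vonNeumannEntropy", "WindowedGraphSequence", function(x)
  vapply(x@graphs, vonNeumannEntropy, numeric(1)))

#' @rdname internalEnergy
#' @export
setMethod("internalEnergy", "matrix", function(x) {
  .stopIfBadAdjacency(x)
  sum(x[upper.tri(x)])
})

#' @rdname internalEnergy
#' @export
setMethod("internalEnergy", "WindowedGraphSequence", function(x)
  vapply(x@graphs, function(A) sum(A[upper.tri(A)]), numeric(1)))

#' @rdname nodeEnergy
#' @export
setMethod("nodeEnergy", "matrix", function(x) {
  .stopIfBadAdjacency(x, requireNonNegative = TRUE)
  d <- rowSums(x)
  # share matrix d_i / (d_i + d_j) over connected pairs; isolated nodes 0
  denom <- outer(d, d, "+")
  share <- ifelse(x > 0 & denom > 0, d / denom, 0)   # d recycled by row
  rowSums(share * x)
})

#' Temperature-like reconfiguration series from U and S
#'
#' \eqn{T_1 = 0}; for \eqn{n \ge 2},
#' \eqn{T_n = (U_n - U_{n-1}) / (S_n - S_{n-1})}.  Where the entropy
#' increment is degenerate (\eqn{|\Delta S| <} \code{dsEps}) the entry is
#' \code{NaN}; the number of such transitions is attached as attribute
#' \code{nDegenerate} and excluded from downstream scoring.
#'
#' @param U,S equal-length numeric series of internal energy and entropy.
#' @param dsEps degeneracy guard on \eqn{|\Delta S|} (default 1e-12; the
#'   ratio itself is never regularized).
#' @return Numeric series of \code{length(U)} with attribute
#'   \code{nDegenerate}.
#' @examples
#' temperatureSeries(c(3, 5, 5), c(1, 1.5, 2))   # 0, 4, 0
#' @export
temperatureSeries <- function(U, S, dsEps = 1e-12) {
  if (length(U) != length(S))
    stop(sprintf("length mismatch: U has %d entries, S has %d",
                 length(U), length(S)), call. = FALSE)
  n <- length(U)
  out <- numeric(n)
  if (n >= 2L) {
    dU <- diff(U); dS <- diff(S)
    bad <- abs(dS) < dsEps
    tn <- dU / dS
    tn[bad] <- NaN
    out[-1L] <- tn
    attr(out, "nDegenerate") <- sum(bad)
  } else {
    attr(out, "nDegenerate") <- 0L
  }
  out
}

#' Thermodynamic trajectory of a graph sequence
#'
#' Per window: internal energy U, Spectral Core Entropy S (top-`alpha`
#' normalized-Laplacian eigenvalues), node energy, optionally the full
#' von Neumann entropy, and the temperature-like index T derived from U
#' and S via [temperatureSeries()].  Deterministic given the sequence and
#' configuration.
#'
#' @param seq a \linkS4class{WindowedGraphSequence} (or plain list of
#'   adjacency matrices).
#' @param alpha retained spectral core size (default 20).
#' @param renormalize rescale probabilities within the retained set.
#' @param withVne also compute the full von Neumann entropy per window.
#' @param solver eigenvalue solver, see [graphSpectrum()].
#' @param dsEps degeneracy guard for the temperature denominator.
#' @return A \linkS4class{ThermoTrajectory}.
#' @examples
#' A <- matrix(1, 4, 4) - diag(4)
#' B <- A; B[1, 2] <- B[2, 1] <- 0
#' tr <- thermoTrajectory(WindowedGraphSequence(list(A, B)), alpha = 4)
#' internalEnergy(tr)   # 6, 5
#' @export
thermoTrajectory <- function(seq, alpha = 20L, renormalize = FALSE,
                             withVne = FALSE, solver = "auto",
                             dsEps = 1e-12) {
  if (is.list(seq)) seq <- WindowedGraphSequence(seq)
  gl <- seq@graphs
  n <- nrow(gl[[1L]])
  alpha <- min(as.integer(alpha), n)
  U <- vapply(gl, function(A) sum(A[upper.tri(A)]), numeric(1))
  S <- vapply(gl, function(A)
    spectralCoreEntropy(A, alpha = alpha, renormalize = renormalize,
                        solver = solver), numeric(1))
  VNE <- if (withVne) vapply(gl, vonNeumannEntropy, numeric(1)) else numeric()
  NE <- t(vapply(gl, function(A) nodeEnergy(A), numeric(n)))
  Tn <- temperatureSeries(U, S, dsEps = dsEps)
  nDeg <- attr(Tn, "nDegenerate")
  attributes(Tn) <- NULL
  new("ThermoTrajectory", U = U, S = S, VNE = VNE, T = Tn,
      nodeEnergy = NE, alpha = alpha, renormalize = renormalize,
      nDegenerate = as.integer(nDeg))
}
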