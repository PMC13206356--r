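#' @include AllClasses.R AllGenerics.R
NULL

#' Read a regional time-series matrix from delimited text
#'
#' Expects a T x N numeric body (time points in rows, regions in
#' columns), comma- or tab-delimited, with an optional header row of
#' region labels.  Any non-finite cell is a hard error naming the first
#' offending row and column.
#'
#' @param path file path.
#' @param sep field separator; \code{"auto"} detects comma vs tab from
#'   the first line.
#' @param header \code{TRUE}, \code{FALSE}, or \code{"auto"} (detected:
#'   a first line that does not parse as numbers is taken as labels).
#' @return Numeric matrix with region labels as column names when a
#'   header is present.
#' @export
readTimeSeries <- function(path, sep = "auto", header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (identical(sep, "auto"))
    sep <- if (grepl("\t", first)) "\t" else ","
  if (identical(header, "auto")) {
    cells <- strsplit(first, sep, fixed = TRUE)[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(cells))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE)
  x <- as.matrix(df)
  if (!is.numeric(x)) x <- matrix(as.numeric(x), nrow(df), ncol(df),
                                  dimnames = dimnames(df))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-finite value at row %d, column %d (%s) of %s",
      bad[1L, 1L], bad[1L, 2L],
      if (!is.null(colnames(x))) colnames(x)[bad[1L, 2L]] else "unnamed",
      path), call. = FALSE)
  }
  if (ncol(x) < 2L) stop("need at least 2 regions", call. = FALSE)
  x
}

#' Write / read a thermodynamic trajectory as CSV
#'
#' Columns \code{window_index}, \code{U}, \code{S}, \code{VNE},
#' \code{T}, written with full double precision so that the round trip
#' is lossless to 1e-12.
#'
#' @param traj a \linkS4class{ThermoTrajectory}.
#' @param path output CSV path.
#' @return \code{writeTrajectory} returns \code{path} invisibly;
#'   \code{readTrajectory} returns the \code{data.frame}.
#' @export
writeTrajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path)
  df[] <- lapply(df, as.numeric)
  df
}

#' Persist a graph sequence as delimited text plus a JSON sidecar
#'
#' Writes the non-zero upper-triangle entries of every window in long
#' form (\code{window_index}, \code{i}, \code{j}, \code{weight}; 0-based
#' node indices) to \code{edges.csv}, and the metadata (node count,
#' window length, stride, binary flag, threshold, node labels) to
#' \code{meta.json} in \code{dir}.
#'
#' @param seq a \linkS4class{WindowedGraphSequence}.
#' @param dir output directory (created if missing).
#' @return \code{writeGraphSequence} returns \code{dir} invisibly;
#'   \code{readGraphSequence} reconstructs the
#'   \linkS4class{WindowedGraphSequence}.
#' @export
writeGraphSequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(seq@graphs), function(k) {
    A <- seq@graphs[[k]]
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    if (!nrow(idx))
      return(data.frame(window_index = integer(), i = integer(),
                        j = integer(), weight = character()))
    data.frame(window_index = k - 1L, i = idx[, 1L] - 1L,
               j = idx[, 2L] - 1L,
               weight = sprintf("%.17g", A[idx]))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    n_nodes = nNodes(seq), n_windows = length(seq@graphs),
    window_length = seq@windowLength, stride = seq@stride,
    start_indices = seq@startIndices, binary = seq@binary,
    threshold = seq@threshold, node_labels = seq@nodeLabels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' @rdname writeGraphSequence
#' @export
readGraphSequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  n <- meta$n_nodes
  gl <- lapply(seq_len(meta$n_windows) - 1L, function(k) {
    A <- matrix(0, n, n)
    e <- edges[edges$window_index == k, , drop = FALSE]
    if (nrow(e)) {
      A[cbind(e$i + 1L, e$j + 1L)] <- e$weight
      A <- A + t(A)
    }
    A
  })
  WindowedGraphSequence(
    gl,
    windowLength = if (is.null(meta$window_length)) NA_integer_
                   else meta$window_length,
    stride = if (is.null(meta$stride)) NA_integer_ else meta$stride,
    startIndices = meta$start_indices,
    binary = isTRUE(meta$binary),
    threshold = if (is.null(meta$threshold)) NA_real_ else meta$threshold,
    nodeLabels = if (length(meta$node_labels)) meta$node_labels
                 else character())
}

#' Write a cohort detection summary as JSON
#'
#' @param summary named list of scalar summaries (e.g. cohort medians).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
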