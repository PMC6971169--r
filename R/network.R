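#' Pearson/Fisher-z connectivity matrix from ROI time series
#'
#' Pearson correlation between every pair of ROI time series over the full
#' analysed run (optionally restricted to task-block volumes), Fisher
#' transformed with z = atanh(r) after clipping r just inside +/-1. Constant
#' ROI rows yield zero correlations with a warning rather than an error.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 volumes.
#' @param volumes optional integer vector of volume indices to use (e.g. the
#'   task-block volumes); default all.
#' @return a [ZConnectivity-class]; diagonals are NA (masked).
#' @export
roiCorrelationMatrix <- function(ts, volumes = NULL) {
  x <- ts@data
  if (!is.null(volumes)) x <- x[, volumes, drop = FALSE]
  if (ncol(x) < 3) stop("at least 3 volumes are required for correlations")
  sds <- apply(x, 1, stats::sd)
  const <- sds == 0
  r <- matrix(0, nrow(x), nrow(x))
  if (any(const))
    warning(sum(const), " constant ROI row(s); their correlations set to 0")
  ok <- which(!const)
  if (length(ok) >= 2) r[ok, ok] <- stats::cor(t(x[ok, , drop = FALSE]))
  r <- (r + t(r)) / 2
  z <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  diag(r) <- NA_real_
  diag(z) <- NA_real_
  new("ZConnectivity", r = r, z = z,
      subjectId = ts@subjectId, group = ts@group, session = ts@session,
      nodeLabels = ts@roiLabels)
}

#' Construct a ZConnectivity from a correlation (or z) matrix
#'
#' For users with precomputed connectivity: symmetrises the input, derives
#' the matching r/z pair and masks the diagonal.
#'
#' @param m square symmetric numeric matrix.
#' @param what whether `m` holds Pearson `"r"` (default) or Fisher `"z"`
#'   values.
#' @param subjectId,group,session labels to attach.
#' @param nodeLabels optional node names.
#' @return a [ZConnectivity-class].
#' @export
zConnectivity <- function(m, what = c("r", "z"), subjectId = "sub",
                          group = "", session = "", nodeLabels = NULL) {
  what <- match.arg(what)
  m <- unname(as.matrix(m))
  m <- (m + t(m)) / 2
  if (is.null(nodeLabels)) nodeLabels <- sprintf("n%02d", seq_len(nrow(m)))
  if (what == "r") {
    r <- m
    z <- atanh(pmin(pmax(m, -(1 - 1e-12)), 1 - 1e-12))
  } else {
    z <- m
    r <- tanh(m)
  }
  diag(r) <- NA_real_
  diag(z) <- NA_real_
  new("ZConnectivity", r = r, z = z, subjectId = subjectId, group = group,
      session = session, nodeLabels = nodeLabels)
}

#' Edge count at a sparsity level
#'
#' Number of edges a binary network holds at sparsity `s`:
#' `floor(s * n(n-1)/2)`. At 90 nodes, s = 0.05 gives 200 edges and s = 0.50
#' gives 2002.
#'
#' @param nNodes number of nodes (>= 2).
#' @param s sparsity fraction in (0, 1].
#' @return integer edge count.
#' @export
#' @examples
#' edgeCountForSparsity(90, 0.05)
edgeCountForSparsity <- function(nNodes, s) {
  if (nNodes < 2) stop("nNodes must be >= 2")
  if (s <= 0 || s > 1) stop("s must lie in (0, 1]")
  as.integer(floor(s * nNodes * (nNodes - 1) / 2))
}

#' Construct a BinaryNetwork from an adjacency matrix
#'
#' Convenience constructor (used mainly for canonical test graphs): validates
#' symmetry and computes the achieved sparsity.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param nodeLabels optional node names.
#' @param sparsity requested sparsity to record (defaults to the achieved one).
#' @return a [BinaryNetwork-class].
#' @export
BinaryNetwork <- function(adjacency, nodeLabels = NULL, sparsity = NULL) {
  adjacency <- unname(as.matrix(adjacency)) * 1
  n <- nrow(adjacency)
  if (is.null(nodeLabels)) nodeLabels <- sprintf("n%02d", seq_len(n))
  achieved <- if (n >= 2) sum(adjacency) / (n * (n - 1)) else 0
  if (is.null(sparsity)) sparsity <- achieved
  new("BinaryNetwork", adjacency = adjacency, sparsity = sparsity,
      achievedSparsity = achieved, nodeLabels = nodeLabels)
}

#' Threshold a connectivity matrix at a sparsity level
#'
#' Ranks the positive off-diagonal z values (upper triangle) in descending
#' order and keeps the strongest [edgeCountForSparsity()] of them as edges;
#' negative and zero correlations are never edges. Ties at the cut-off break
#' deterministically by (smaller row index, smaller column index). When fewer
#' positive entries exist than requested, all are kept and the achieved
#' sparsity is recorded with a warning.
#'
#' @param zc a [ZConnectivity-class].
#' @param s target sparsity in (0, 1].
#' @return a [BinaryNetwork-class].
#' @export
thresholdBySparsity <- function(zc, s) {
  n <- nrow(zc@z)
  want <- edgeCountForSparsity(n, s)
  ut <- which(upper.tri(zc@z), arr.ind = TRUE)
  vals <- zc@z[ut]
  pos <- vals > 0
  ut <- ut[pos, , drop = FALSE]
  vals <- vals[pos]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(want, length(ord)))]
  if (length(keep) < want)
    warning(sprintf(
      "only %d positive correlations available for %d requested edges; achieved sparsity %.4f",
      length(keep), want, length(keep) / (n * (n - 1) / 2)))
  a <- matrix(0, n, n)
  a[ut[keep, , drop = FALSE]] <- 1
  a <- a + t(a)
  new("BinaryNetwork", adjacency = a, sparsity = s,
      achievedSparsity = sum(a) / (n * (n - 1)),
      nodeLabels = zc@nodeLabels)
}

#' Binary networks along a sparsity ladder
#'
#' One [thresholdBySparsity()] network per sparsity in
#' `seq(sMin, sMax, step)`; the defaults (5% to 50%, step 5%) give 10
#' networks. Thanks to the deterministic tie-break, edge sets are nested
#' along the ladder.
#'
#' @param zc a [ZConnectivity-class].
#' @param sMin,sMax,step ladder limits and spacing.
#' @return named list of [BinaryNetwork-class] (names = sparsity values).
#' @export
sparsityLadder <- function(zc, sMin = 0.05, sMax = 0.50, step = 0.05) {
  if (sMin <= 0 || sMin > sMax || sMax > 1 || step <= 0)
    stop("require 0 < sMin <= sMax <= 1 and step > 0")
  ss <- seq(sMin, sMax, by = step)
  nets <- lapply(ss, function(s) thresholdBySparsity(zc, s))
  names(nets) <- formatC(ss, format = "g")
  nets
}

#' Write a connectivity matrix as labelled TSV
#'
#' @param zc a [ZConnectivity-class].
#' @param path output file.
#' @param what `"z"` (default) or `"r"`.
#' @return invisibly, `path`.
#' @export
writeConnectivity <- function(zc, path, what = c("z", "r")) {
  what <- match.arg(what)
  m <- if (what == "z") zc@z else zc@r
  df <- data.frame(roi = zc@nodeLabels, m, check.names = FALSE)
  names(df) <- c("roi", zc@nodeLabels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [writeConnectivity()]
#'
#' @param path TSV file with a leading `roi` label column.
#' @param subjectId,group,session labels to attach.
#' @param what whether the file holds `"z"` or `"r"` values.
#' @return a [ZConnectivity-class].
#' @export
readConnectivity <- function(path, subjectId = "sub", group = "",
                             session = "", what = c("z", "r")) {
  what <- match.arg(what)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- df$roi
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m <- (m + t(m)) / 2  # guard against decimal round-trip asymmetry
  if (what == "z") {
    z <- m; r <- tanh(m)
  } else {
    r <- m; z <- atanh(pmin(pmax(m, -(1 - 1e-12)), 1 - 1e-12))
  }
  diag(r) <- NA_real_; diag(z) <- NA_real_
  new("ZConnectivity", r = r, z = z, subjectId = subjectId, group = group,
      session = session, nodeLabels = as.character(labels))
}

#' Export a binary network as an edge list
#'
#' Two-column text file (`node_i`, `node_j`) with one row per undirected
#' edge, suitable for surface-viewer import.
#'
#' @param net a [BinaryNetwork-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
  idx <- which(upper.tri(net@adjacency) & net@adjacency == 1, arr.ind = TRUE)
  df <- data.frame(node_i = net@nodeLabels[idx[, 1]],
                   node_j = net@nodeLabels[idx[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
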