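# All-pairs shortest-path lengths of a binary undirected graph by levelwise
# expansion (one boolean matrix product per distance level). Inf where
# unreachable, 0 on the diagonal.
allPairsDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (n == 0 || sum(a) == 0) return(d)
  reach <- a > 0
  d[reach] <- 1
  cum <- reach | diag(TRUE, n)
  frontier <- reach
  lev <- 1
  repeat {
    nxt <- ((frontier %*% a) > 0) & !cum
    if (!any(nxt)) break
    lev <- lev + 1
    d[nxt] <- lev
    cum <- cum | nxt
    frontier <- nxt
  }
  d
}

effFromAdj <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- allPairsDistances(a)
  inv <- 1 / d[upper.tri(d)]
  mean(inv)                      # 1/Inf = 0 handles unreachable pairs
}

#' Clustering coefficient
#'
#' Nodal clustering `C_i = 2 T_i / (k_i (k_i - 1))` where `T_i` counts edges
#' among the neighbours of node i; `C_i = 0` for degree < 2. `Cp` is the mean
#' over all nodes — the network's functional-segregation summary.
#'
#' @param net a [BinaryNetwork-class].
#' @return list with `Cp` (scalar mean) and `nodal` (per-node values).
#' @export
clusteringCoefficient <- function(net) {
  a <- net@adjacency
  k <- rowSums(a)
  tri <- rowSums((a %*% a) * a) / 2
  nodal <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  list(Cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over the node pairs with a finite distance
#' (the reachable pairs), together with the fraction of pairs that are
#' reachable. A graph with no edges has no finite pair: `Lp` is `NA` and the
#' reachable fraction 0.
#'
#' @param net a [BinaryNetwork-class].
#' @return list with `Lp` and `reachableFraction`.
#' @export
characteristicPathLength <- function(net) {
  d <- allPairsDistances(net@adjacency)
  up <- d[upper.tri(d)]
  fin <- is.finite(up)
  list(Lp = if (any(fin)) mean(up[fin]) else NA_real_,
       reachableFraction = if (length(up)) mean(fin) else 0)
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over all unordered node pairs,
#' with 1/infinity = 0 for unreachable pairs — the network-integration
#' counterpart of [characteristicPathLength()].
#'
#' @param net a [BinaryNetwork-class].
#' @return scalar in \[0, 1\].
#' @export
globalEfficiency <- function(net) effFromAdj(net@adjacency)

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (0 for degree < 2).
#'
#' @param net a [BinaryNetwork-class].
#' @return scalar in \[0, 1\].
#' @export
localEfficiency <- function(net) {
  a <- net@adjacency
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    effFromAdj(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Degree centrality
#'
#' Per-node edge counts (adjacency row sums).
#'
#' @param net a [BinaryNetwork-class].
#' @return named numeric vector.
#' @export
degreeCentrality <- function(net) {
  stats::setNames(rowSums(net@adjacency), net@nodeLabels)
}

#' Betweenness centrality (Brandes)
#'
#' Unnormalised betweenness by Brandes' accumulation: for every node v, the
#' sum over source-target pairs of the fraction of shortest s-t paths passing
#' through v, with each unordered pair counted once (undirected convention).
#'
#' @param net a [BinaryNetwork-class].
#' @return named numeric vector of per-node values.
#' @export
betweennessCentrality <- function(net) {
  a <- net@adjacency
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- vector("list", n)
    order_ <- integer(0)
    queue <- c(s); qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      order_ <- c(order_, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, net@nodeLabels)  # each unordered pair once
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Repeated double-edge swaps (a-b, c-d becomes a-d, c-b), rejecting proposals
#' that would create self-loops or multi-edges, so the degree sequence is
#' preserved exactly. A complete graph admits no legal swap and is returned
#' unchanged with a warning.
#'
#' @param net a [BinaryNetwork-class] with at least 2 edges.
#' @param nSwaps number of attempted swaps (default 10x the edge count).
#' @param seed integer seed.
#' @return a rewired [BinaryNetwork-class] with the same degree sequence.
#' @export
rewireDegreePreserving <- function(net, nSwaps = 10 * edgeCount(net),
                                   seed = 1L) {
  a <- net@adjacency
  n <- nrow(a)
  m <- sum(a) / 2
  if (m < 2) stop("rewiring requires at least 2 edges")
  if (m == n * (n - 1) / 2) {
    warning("complete graph: no legal degree-preserving swap; returned unchanged")
    return(net)
  }
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  ei <- idx[, 1]; ej <- idx[, 2]
  adj <- a > 0
  set.seed(seed)
  picks <- matrix(sample.int(m, 2 * nSwaps, replace = TRUE), ncol = 2)
  flips <- stats::runif(nSwaps) < 0.5
  for (t in seq_len(nSwaps)) {
    e1 <- picks[t, 1]; e2 <- picks[t, 2]
    if (e1 == e2) next
    x1 <- ei[e1]; y1 <- ej[e1]
    x2 <- ei[e2]; y2 <- ej[e2]
    if (flips[t]) { tmp <- x2; x2 <- y2; y2 <- tmp }
    # proposal: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1) next
    if (adj[x1, y2] || adj[x2, y1]) next
    adj[x1, y1] <- adj[y1, x1] <- FALSE
    adj[x2, y2] <- adj[y2, x2] <- FALSE
    adj[x1, y2] <- adj[y2, x1] <- TRUE
    adj[x2, y1] <- adj[y1, x2] <- TRUE
    ei[e1] <- min(x1, y2); ej[e1] <- max(x1, y2)
    ei[e2] <- min(x2, y1); ej[e2] <- max(x2, y1)
  }
  out <- adj * 1
  new("BinaryNetwork", adjacency = out, sparsity = net@sparsity,
      achievedSparsity = net@achievedSparsity, nodeLabels = net@nodeLabels)
}

#' Small-world normalisation against degree-preserving nulls
#'
#' `gamma = Cp / <Cp_rand>`, `lambda = Lp / <Lp_rand>` and
#' `sigma = gamma / lambda`, where the reference values are means over
#' `nNull` independently rewired degree-matched random networks. Null `Lp`
#' uses the same reachable-pairs convention as the observed one.
#'
#' @param net a [BinaryNetwork-class] with at least 2 edges.
#' @param nNull number of null networks.
#' @param seed integer seed (each null uses a derived sub-seed).
#' @param nSwaps attempted swaps per null (default 10x the edge count).
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
normalizedMetrics <- function(net, nNull = 100, seed = 1L,
                              nSwaps = 10 * edgeCount(net)) {
  cp <- clusteringCoefficient(net)$Cp
  lp <- characteristicPathLength(net)$Lp
  nullCp <- numeric(nNull)
  nullLp <- numeric(nNull)
  isComplete <- edgeCount(net) ==
    nrow(net@adjacency) * (nrow(net@adjacency) - 1) / 2
  for (i in seq_len(nNull)) {
    rnet <- if (isComplete) net else
      suppressWarnings(
        rewireDegreePreserving(net, nSwaps, seed = deriveSeed(seed, "null", i)))
    nullCp[i] <- clusteringCoefficient(rnet)$Cp
    nullLp[i] <- characteristicPathLength(rnet)$Lp
  }
  mCp <- mean(nullCp)
  mLp <- mean(nullLp, na.rm = TRUE)
  gamma <- if (mCp > 0) cp / mCp else {
    warning("null clustering mean is zero; gamma undefined")
    NA_real_
  }
  lambda <- if (is.finite(mLp) && mLp > 0) lp / mLp else NA_real_
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Global metric records across a sparsity ladder
#'
#' For each subject-session connectivity matrix and each sparsity, computes
#' the global topology metrics: Cp, Lp (with reachable fraction and
#' isolated-node count), global and local efficiency, and — when `nNull > 0`
#' — gamma, lambda and sigma from degree-preserving nulls.
#'
#' @param zcs list of [ZConnectivity-class] objects.
#' @param sparsities numeric vector of sparsity levels
#'   (default `seq(0.05, 0.5, 0.05)`).
#' @param metrics character subset of
#'   `c("Cp", "Lp", "Eglob", "Eloc")` to compute (all by default); smaller
#'   subsets speed up large simulation studies.
#' @param nNull number of rewired nulls for gamma/lambda/sigma; 0 skips them
#'   (columns NA).
#' @param seed seed for the null models.
#' @return data.frame, one row per subject-session x sparsity.
#' @export
computeMetricRecords <- function(zcs, sparsities = seq(0.05, 0.5, by = 0.05),
                                 metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                                 nNull = 0, seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  for (zc in zcs) {
    for (s in sparsities) {
      net <- suppressWarnings(thresholdBySparsity(zc, s))
      deg <- rowSums(net@adjacency)
      cp <- if ("Cp" %in% metrics) clusteringCoefficient(net)$Cp else NA_real_
      if ("Lp" %in% metrics) {
        pl <- characteristicPathLength(net)
      } else pl <- list(Lp = NA_real_, reachableFraction = NA_real_)
      eg <- if ("Eglob" %in% metrics) globalEfficiency(net) else NA_real_
      el <- if ("Eloc" %in% metrics) localEfficiency(net) else NA_real_
      if (nNull > 0) {
        nm <- normalizedMetrics(net, nNull = nNull,
                                seed = deriveSeed(seed, zc@subjectId,
                                                  zc@session, round(s * 100)))
      } else nm <- list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = zc@subjectId, group = zc@group, session = zc@session,
        sparsity = s, achieved_sparsity = net@achievedSparsity,
        Cp = cp, Lp = pl$Lp, reachable_fraction = pl$reachableFraction,
        n_isolated = sum(deg == 0),
        Eglob = eg, Eloc = el,
        gamma = nm$gamma, lambda = nm$lambda, sigma = nm$sigma)
    }
  }
  do.call(rbind, rows)
}

#' Nodal centrality records at one sparsity
#'
#' Per-node degree and unnormalised betweenness centrality for every
#' subject-session, at a single sparsity (conventionally the sparsest ladder
#' point, 5%).
#'
#' @param zcs list of [ZConnectivity-class] objects.
#' @param s sparsity level (default 0.05).
#' @return long data.frame, one row per subject-session x node.
#' @export
computeNodalRecords <- function(zcs, s = 0.05) {
  rows <- lapply(zcs, function(zc) {
    net <- suppressWarnings(thresholdBySparsity(zc, s))
    data.frame(subject_id = zc@subjectId, group = zc@group,
               session = zc@session, sparsity = s,
               node = net@nodeLabels,
               degree = unname(degreeCentrality(net)),
               betweenness = unname(betweennessCentrality(net)))
  })
  do.call(rbind, rows)
}

#' Connectivity matrices for every subject-session of a cohort
#'
#' @param cohort a [Cohort-class].
#' @param volumes optional volume subset passed to [roiCorrelationMatrix()].
#' @return list of [ZConnectivity-class].
#' @export
cohortConnectivity <- function(cohort, volumes = NULL) {
  lapply(cohort@subjects, roiCorrelationMatrix, volumes = volumes)
}
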