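# Canonical graph builders and independent brute-force oracles used across
# the metric tests. The oracles deliberately use different algorithms from
# the package (Floyd-Warshall, exhaustive path enumeration, triple counting).

adjFromEdges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

completeAdj <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}

starAdj <- function(n) {  # node 1 is the hub
  a <- matrix(0, n, n)
  a[1, 2:n] <- 1; a[2:n, 1] <- 1
  a
}

pathAdj <- function(n) {
  adjFromEdges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

cycleAdj <- function(n) {
  a <- pathAdj(n); a[1, n] <- a[n, 1] <- 1; a
}

# Ring lattice: each node connected to its k/2 nearest neighbours per side.
ringLatticeAdj <- function(n, k) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}

erAdj <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

randomConnectedAdj <- function(n, p = 0.5, maxTries = 100) {
  for (i in seq_len(maxTries)) {
    a <- erAdj(n, p)
    d <- fwDistances(a)
    if (all(is.finite(d))) return(a)
  }
  # fall back: connect via a random spanning path
  perm <- sample(n)
  for (i in seq_len(n - 1)) a[perm[i], perm[i + 1]] <- a[perm[i + 1], perm[i]] <- 1
  a
}

# --- Oracles ---------------------------------------------------------------

fwDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

fwLp <- function(a) {
  d <- fwDistances(a)
  up <- d[upper.tri(d)]
  fin <- is.finite(up)
  if (any(fin)) mean(up[fin]) else NA_real_
}

fwEglob <- function(a) {
  d <- fwDistances(a)
  mean(1 / d[upper.tri(d)])
}

# All simple paths s -> t by depth-first enumeration.
allSimplePaths <- function(a, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(a[v, ] > 0)) if (!(w %in% path)) rec(c(path, w))
  }
  rec(s)
  paths
}

bruteBetweenness <- function(a) {
  n <- nrow(a)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- allSimplePaths(a, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, integer(1))
    sp <- ps[lens == min(lens)]
    for (p in sp) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(sp)
    }
  }
  bc
}

# Clustering by explicit triple counting.
bruteClustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- combn(nb, 2)
    closed <- sum(a[cbind(pairs[1, ], pairs[2, ])])
    closed / ncol(pairs)
  }, numeric(1))
}
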