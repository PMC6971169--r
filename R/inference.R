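#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2` (the form implied
#' by 16 + 16 subjects reporting t with 30 df). Sign convention:
#' `mean_a - mean_b`. With zero pooled variance, equal means give t = 0 and
#' unequal means an infinite flagged t.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' twoSampleT(c(0, 0, 1, 1), c(1, 1, 2, 2))
twoSampleT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  se <- sqrt(pooled * (1 / na + 1 / nb))
  delta <- mean(a) - mean(b)
  t <- if (se > 0) delta / se else if (delta == 0) 0 else Inf * sign(delta)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}

#' Pooled-variance t-test from summary statistics
#'
#' Identical to [twoSampleT()] but computed from printed group summaries
#' (mean, SD, n). The reading-score summaries 115.75 +/- 13.57 vs
#' 35.63 +/- 13.59 at n = 16 per group give t = 16.69 on 30 df; the Raven
#' summaries 68.44 +/- 15.78 vs 75 +/- 16.73 give t = -1.141.
#'
#' @param meanA,sdA,nA first group summary.
#' @param meanB,sdB,nB second group summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' tFromSummary(115.75, 13.57, 16, 35.63, 13.59, 16)
tFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (sdA < 0 || sdB < 0) stop("standard deviations must be non-negative")
  if (nA < 2 || nB < 2) stop("need at least 2 observations per group")
  df <- nA + nB - 2
  pooled <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  se <- sqrt(pooled * (1 / nA + 1 / nB))
  delta <- meanA - meanB
  t <- if (se > 0) delta / se else if (delta == 0) 0 else Inf * sign(delta)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

comparisonRow <- function(target, session, s, va, vb) {
  tt <- twoSampleT(va, vb)
  data.frame(target = target, session = session, sparsity = s,
             mean_a = mean(va), sd_a = stats::sd(va),
             mean_b = mean(vb), sd_b = stats::sd(vb),
             t = tt$t, df = tt$df, p = tt$p)
}

#' Group comparison of global network metrics across the sparsity ladder
#'
#' One pooled-variance two-sample t-test per (metric, session, sparsity),
#' with group A minus group B sign convention. The Bonferroni family is the
#' number of sparsity levels tested per metric per session; both the
#' uncorrected (alpha) and the corrected flag are reported. Rows where a
#' metric is missing for any subject (e.g. Lp of a fully disconnected graph)
#' are dropped with a warning and the family shrinks accordingly.
#'
#' @param records data.frame from [computeMetricRecords()].
#' @param metrics metric columns to test.
#' @param groupA,groupB group labels; the reported t is `groupA - groupB`.
#' @param alpha family-wise significance level.
#' @return data.frame with columns `target` (metric), `session`, `sparsity`,
#'   group means/SDs, `t`, `df`, `p`, `significant_uncorrected`,
#'   `significant_bonferroni`, `family_size`.
#' @export
compareGlobalMetrics <- function(records,
                                 metrics = c("Cp", "Lp", "Eglob", "Eloc",
                                             "gamma", "lambda", "sigma"),
                                 groupA = "good", groupB = "poor",
                                 alpha = 0.05) {
  metrics <- intersect(metrics, names(records))
  out <- list()
  for (ses in unique(records$session)) {
    rs <- records[records$session == ses, ]
    for (metric in metrics) {
      if (all(is.na(rs[[metric]]))) next
      rows <- list()
      for (s in sort(unique(rs$sparsity))) {
        rss <- rs[rs$sparsity == s, ]
        va <- rss[[metric]][rss$group == groupA]
        vb <- rss[[metric]][rss$group == groupB]
        if (anyNA(va) || anyNA(vb)) {
          warning(sprintf(
            "%s at sparsity %.2f (%s): missing values for some subjects; row dropped",
            metric, s, ses))
          next
        }
        rows[[length(rows) + 1L]] <- comparisonRow(metric, ses, s, va, vb)
      }
      if (!length(rows)) next
      tab <- do.call(rbind, rows)
      fam <- nrow(tab)
      tab$significant_uncorrected <- tab$p < alpha
      tab$significant_bonferroni <- tab$p < bonferroniThreshold(alpha, fam)
      tab$family_size <- fam
      out[[length(out) + 1L]] <- tab
    }
  }
  if (!length(out)) stop("no testable metric rows")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "groups") <- c(A = groupA, B = groupB)
  attr(res, "alpha") <- alpha
  res
}

#' Group comparison of nodal centralities at one sparsity
#'
#' Per-node pooled-variance t-tests for degree and betweenness centrality,
#' with a Bonferroni family equal to the node count per measure. Both the
#' uncorrected and corrected flags are reported (reported nodal effects in
#' this literature are typically uncorrected).
#'
#' @param nodal data.frame from [computeNodalRecords()], single sparsity.
#' @param measures which centrality columns to test.
#' @param groupA,groupB group labels (sign: `groupA - groupB`).
#' @param alpha family-wise significance level.
#' @return data.frame, one row per node x measure, columns as in
#'   [compareGlobalMetrics()] with `target` = "measure:node".
#' @export
compareNodal <- function(nodal, measures = c("degree", "betweenness"),
                         groupA = "good", groupB = "poor", alpha = 0.05) {
  if (length(unique(nodal$sparsity)) != 1)
    stop("nodal comparisons require records at a single sparsity")
  s <- nodal$sparsity[1]
  ses <- unique(nodal$session)
  if (length(ses) != 1)
    return(do.call(rbind, lapply(ses, function(x)
      compareNodal(nodal[nodal$session == x, ], measures, groupA, groupB, alpha))))
  nodes <- unique(nodal$node)
  fam <- length(nodes)
  out <- list()
  for (measure in measures) {
    for (nd in nodes) {
      rs <- nodal[nodal$node == nd, ]
      va <- rs[[measure]][rs$group == groupA]
      vb <- rs[[measure]][rs$group == groupB]
      out[[length(out) + 1L]] <-
        comparisonRow(paste(measure, nd, sep = ":"), ses, s, va, vb)
    }
  }
  res <- do.call(rbind, out)
  res$significant_uncorrected <- res$p < alpha
  res$significant_bonferroni <- res$p < bonferroniThreshold(alpha, fam)
  res$family_size <- fam
  rownames(res) <- NULL
  attr(res, "groups") <- c(A = groupA, B = groupB)
  attr(res, "alpha") <- alpha
  res
}

#' Write a comparison table with its provenance header
#'
#' TSV preceded by `#`-comment lines recording the group ordering, alpha and
#' family sizes.
#'
#' @param tab comparison table from [compareGlobalMetrics()],
#'   [compareNodal()] or [groupActivationTTest()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeComparisonTable <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- attr(tab, "groups")
  if (!is.null(g))
    writeLines(sprintf("# groups: A = %s, B = %s (t is A - B)", g["A"], g["B"]), con)
  if (!is.null(attr(tab, "alpha")))
    writeLines(sprintf("# alpha: %g", attr(tab, "alpha")), con)
  if ("family_size" %in% names(tab))
    writeLines(sprintf("# bonferroni family sizes: %s",
                       paste(sort(unique(tab$family_size)), collapse = ", ")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
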