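#' Canonical double-gamma haemodynamic response function
#'
#' The conventional double-gamma HRF: a positive gamma response (delay 6 s,
#' dispersion 1) minus an undershoot gamma (delay 16 s, dispersion 1) at 1/6
#' amplitude, sampled every `tr` seconds over `duration` seconds and
#' peak-normalised to a maximum of 1. The peak sits near 5 s and a negative
#' undershoot follows between roughly 10 and 30 s.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration support length in seconds (>= 32).
#' @param responseDelay,undershootDelay gamma shape parameters (seconds).
#' @param responseDispersion,undershootDispersion gamma rate divisors.
#' @param ratio response-to-undershoot amplitude ratio.
#' @return numeric vector of samples at t = 0, tr, 2 tr, ...
#' @export
#' @examples
#' h <- canonicalHrf(0.5)
#' plot(seq(0, by = 0.5, length.out = length(h)), h, type = "l")
canonicalHrf <- function(tr, duration = 32,
                         responseDelay = 6, undershootDelay = 16,
                         responseDispersion = 1, undershootDispersion = 1,
                         ratio = 6) {
  if (tr <= 0) stop("tr must be positive")
  if (duration < 32) stop("duration must be at least 32 s")
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = responseDelay / responseDispersion,
                     rate = 1 / responseDispersion) -
    stats::dgamma(t, shape = undershootDelay / undershootDispersion,
                  rate = 1 / undershootDispersion) / ratio
  h / max(h)
}

# Discrete cosine high-pass basis: K columns with periods above the cut-off,
# K = floor(2 * D / cutoff) for analysed duration D.
dctBasis <- function(nVol, tr, cutoffS) {
  if (is.infinite(cutoffS)) return(matrix(numeric(0), nVol, 0))
  k <- floor(2 * nVol * tr / cutoffS)
  if (k < 1) return(matrix(numeric(0), nVol, 0))
  n <- seq_len(nVol) - 0.5
  b <- sapply(seq_len(k), function(j) cos(pi * j * n / nVol))
  b <- matrix(b, nVol, k)
  colnames(b) <- sprintf("dct_%d", seq_len(k))
  b
}

#' Build a block-design GLM design matrix
#'
#' Task and instruction boxcars convolved with the canonical HRF (16x
#' oversampled, then sampled at acquisition times), optional nuisance columns,
#' discrete-cosine high-pass columns with periods above `hpCutoffS`, and an
#' intercept last. Rows correspond to analysed volumes (dummies removed).
#' When `globalSignal` is supplied (e.g. the mean across ROIs) it is added as
#' a nuisance regressor.
#'
#' @param schedule a [StimulusSchedule-class].
#' @param nuisance optional numeric matrix of nuisance regressors with one row
#'   per analysed volume (e.g. motion surrogates).
#' @param hpCutoffS high-pass cut-off period in seconds (default 128;
#'   `Inf` disables filtering).
#' @param globalSignal optional numeric vector (one value per analysed
#'   volume) regressed out as `global` column.
#' @return numeric matrix `[nAnalysed x nRegressors]` with column names
#'   (`task`, `instruction`, nuisance..., `dct_k`..., `intercept`) and
#'   attribute `tr`.
#' @export
buildDesignMatrix <- function(schedule, nuisance = NULL, hpCutoffS = 128,
                              globalSignal = NULL) {
  validObject(schedule)
  nAna <- schedule@nVolumes - schedule@nDummy
  drop <- seq_len(schedule@nDummy)
  task <- taskRegressorFull(schedule, "task")
  instr <- taskRegressorFull(schedule, "instruction")
  if (schedule@nDummy > 0) {
    task <- task[-drop]; instr <- instr[-drop]
  }
  cols <- list(task = task, instruction = instr)
  if (!is.null(globalSignal)) {
    if (length(globalSignal) != nAna)
      stop("globalSignal length must match the analysed volume count")
    cols$global <- globalSignal
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nAna)
      stop("nuisance rows must match the analysed volume count")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
    for (j in seq_len(ncol(nuisance))) cols[[colnames(nuisance)[j]]] <- nuisance[, j]
  }
  dct <- dctBasis(nAna, schedule@tr, hpCutoffS)
  for (j in seq_len(ncol(dct))) cols[[colnames(dct)[j]]] <- dct[, j]
  cols$intercept <- rep(1, nAna)
  x <- do.call(cbind, cols)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  attr(x, "tr") <- schedule@tr
  x
}

#' Fit the ROI-level GLM by ordinary least squares
#'
#' Solves the least-squares problem for every ROI time series at once and
#' returns per-ROI coefficients and residual variances. No autocorrelation
#' modelling is applied.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param design design matrix from [buildDesignMatrix()].
#' @return a [GlmFit-class].
#' @export
fitGlm <- function(ts, design) {
  y <- t(ts@data)                       # volumes x ROIs
  if (nrow(y) != nrow(design))
    stop("time-series length (", nrow(y),
         ") does not match design rows (", nrow(design), ")")
  qrx <- qr(design)
  dof <- nrow(design) - qrx$rank
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  beta <- qr.coef(qrx, y)
  beta[is.na(beta)] <- 0
  resid <- qr.resid(qrx, y)
  rss <- colSums(resid^2)
  rv <- pmax(rss / dof, 0)
  # an exact interpolation leaves only rounding error: call that zero variance
  msq <- colMeans(y^2)
  rv[rv <= 1e-16 * pmax(msq, .Machine$double.xmin)] <- 0
  new("GlmFit", betas = beta, residualVariance = rv,
      dofResid = as.integer(dof), roiLabels = ts@roiLabels)
}

#' Contrast t-statistics from a GLM fit
#'
#' Computes `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` per ROI with a
#' two-sided p-value on the residual degrees of freedom. ROIs with zero
#' residual variance and a non-zero effect are flagged with an infinite t and
#' p = 0 (warning); a zero effect gives t = 0.
#'
#' @param fit a [GlmFit-class].
#' @param design the design matrix used for the fit.
#' @param contrast numeric weight vector, one entry per regressor (or a named
#'   vector matched against the design's column names, unnamed regressors 0).
#' @return data.frame (`roi`, `effect`, `t`, `p`, `zero_variance`).
#' @export
contrastT <- function(fit, design, contrast) {
  if (!is.null(names(contrast)) && !is.null(colnames(design))) {
    cvec <- stats::setNames(numeric(ncol(design)), colnames(design))
    unknown <- setdiff(names(contrast), colnames(design))
    if (length(unknown))
      stop("unknown contrast regressors: ", paste(unknown, collapse = ", "))
    cvec[names(contrast)] <- contrast
    contrast <- cvec
  }
  if (length(contrast) != ncol(design))
    stop("contrast length must equal the number of regressors")
  xtxInv <- chol2inv(chol(crossprod(design)))
  cvar <- drop(t(contrast) %*% xtxInv %*% contrast)
  effect <- drop(t(fit@betas) %*% contrast)
  se <- sqrt(fit@residualVariance * cvar)
  zero <- se <= 0
  t <- numeric(length(effect))
  t[!zero] <- effect[!zero] / se[!zero]
  t[zero & effect != 0] <- Inf * sign(effect[zero & effect != 0])
  if (any(zero & effect != 0))
    warning("zero residual variance with non-zero effect: t flagged infinite")
  p <- 2 * stats::pt(-abs(t), df = fit@dofResid)
  p[is.infinite(t)] <- 0
  data.frame(roi = fit@roiLabels, effect = effect, t = t, p = p,
             zero_variance = zero, row.names = NULL)
}

#' Group comparison of per-subject contrast effects
#'
#' Pooled-variance two-sample t-test per ROI on subject-level contrast
#' effects (rows = subjects, columns = ROIs), the ROI-scale analogue of a
#' second-level activation analysis.
#'
#' @param effectsA,effectsB numeric matrices of contrast effects
#'   `[nSubjects x nRois]` with identical column (ROI) sets.
#' @param alpha significance level.
#' @return a comparison table (see [compareGlobalMetrics()] for columns);
#'   Bonferroni family = number of ROIs.
#' @export
groupActivationTTest <- function(effectsA, effectsB, alpha = 0.05) {
  effectsA <- as.matrix(effectsA); effectsB <- as.matrix(effectsB)
  if (ncol(effectsA) != ncol(effectsB) ||
      !identical(colnames(effectsA), colnames(effectsB)))
    stop("the two groups must share an identical ROI set")
  rois <- colnames(effectsA)
  if (is.null(rois)) rois <- sprintf("ROI_%03d", seq_len(ncol(effectsA)))
  m <- ncol(effectsA)
  rows <- lapply(seq_len(m), function(j) {
    tt <- twoSampleT(effectsA[, j], effectsB[, j])
    data.frame(target = rois[j], session = NA_character_,
               sparsity = NA_real_,
               mean_a = mean(effectsA[, j]), sd_a = stats::sd(effectsA[, j]),
               mean_b = mean(effectsB[, j]), sd_b = stats::sd(effectsB[, j]),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$significant_uncorrected <- out$p < alpha
  out$significant_bonferroni <- out$p < bonferroniThreshold(alpha, m)
  out
}
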