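test_that("canonical HRF has the conventional double-gamma shape", {
  h <- canonicalHrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)                       # both gamma densities vanish at 0
  expect_equal(max(h), 1)                     # peak-normalised
  expect_lt(abs(t[which.max(h)] - 5), 0.15)   # peak near 5 s
  late <- h[t > 10 & t < 30]
  expect_lt(min(late), 0)                     # negative undershoot exists
  expect_error(canonicalHrf(0), "positive")
  expect_error(canonicalHrf(1, duration = 10), "32")
})

test_that("design matrix has the stated columns and DCT count", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  expect_equal(nrow(X), 79L)
  # K = floor(2 * 158 / 128) = 2 high-pass columns
  expect_equal(colnames(X), c("task", "instruction", "dct_1", "dct_2", "intercept"))
  Xinf <- buildDesignMatrix(sch, hpCutoffS = Inf)
  expect_equal(colnames(Xinf), c("task", "instruction", "intercept"))
  # nuisance columns are carried through; duplicated intercept is rejected
  nuis <- matrix(rnorm(79 * 2), 79, dimnames = list(NULL, c("mot_1", "mot_2")))
  Xn <- buildDesignMatrix(sch, nuisance = nuis)
  expect_true(all(c("mot_1", "mot_2") %in% colnames(Xn)))
  expect_error(buildDesignMatrix(sch, nuisance = matrix(1, 79, 1)),
               "rank deficient")
  expect_error(buildDesignMatrix(sch, nuisance = matrix(0, 10, 1)),
               "analysed volume count")
})

test_that("OLS recovers noiseless coefficients exactly and flags zero variance", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  set.seed(1)
  beta <- matrix(rnorm(ncol(X) * 4), ncol(X), 4)
  ts <- RoiTimeSeries(t(X %*% beta), subjectId = "noiseless")
  fit <- fitGlm(ts, X)
  expect_lt(max(abs(fit@betas - beta)), 1e-8)
  expect_lt(max(fit@residualVariance), 1e-16)
  expect_equal(fit@dofResid, 79L - 5L)
  expect_warning(ct <- contrastT(fit, X, c(task = 1)), "infinite")
  expect_true(all(is.infinite(ct$t) | ct$effect == 0))
  expect_true(all(ct$p[is.infinite(ct$t)] == 0))
})

test_that("single-ROI fits work and zero contrasts give zero statistics", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  set.seed(2)
  ts <- RoiTimeSeries(matrix(rnorm(79), 1), subjectId = "one")
  fit <- fitGlm(ts, X)
  expect_equal(dim(fit@betas), c(5L, 1L))
  ct0 <- contrastT(fit, X, rep(0, 5))
  expect_equal(ct0$effect, 0)
  expect_equal(ct0$t, 0)
})

test_that("null simulation calibrates the task beta and its t statistic", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  qx <- qr(X)
  crit <- qt(0.975, df = 79 - 5)
  set.seed(42)
  nrep <- 1000
  betas <- numeric(nrep)
  ts <- numeric(nrep)
  xtxInv <- chol2inv(chol(crossprod(X)))
  cvar <- xtxInv[1, 1]
  for (i in seq_len(nrep)) {
    y <- rnorm(79)
    b <- qr.coef(qx, y)
    r <- qr.resid(qx, y)
    betas[i] <- b[1]
    ts[i] <- b[1] / sqrt(sum(r^2) / (79 - 5) * cvar)
  }
  expect_lt(abs(mean(betas)), 0.5)                  # centred on zero
  rej <- mean(abs(ts) > crit)
  expect_lt(abs(rej - 0.05), 0.02)                  # nominal type-I rate
})

test_that("residuals are orthogonal to the design and t is scale invariant", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  set.seed(3)
  y <- matrix(rnorm(79 * 3), 3, 79)
  y <- y / max(abs(y))                              # unit-scaled data
  ts <- RoiTimeSeries(y, subjectId = "orth")
  fit <- fitGlm(ts, X)
  resid <- t(y) - X %*% fit@betas
  expect_lt(max(abs(crossprod(X, resid))), 1e-6)
  ct1 <- contrastT(fit, X, c(task = 1))
  fit2 <- fitGlm(RoiTimeSeries(7.3 * y, subjectId = "scaled"), X)
  ct2 <- contrastT(fit2, X, c(task = 1))
  expect_equal(ct1$t, ct2$t, tolerance = 1e-10)
})

test_that("DCT filtering removes slow drifts and spares task-band signal", {
  sch <- makeBlockDesign()
  X <- buildDesignMatrix(sch)
  hp <- X[, c("dct_1", "dct_2", "intercept")]
  tVol <- ((seq_len(82) - 1) * 2)[-(1:3)]
  atten <- function(x) {
    f <- hp %*% qr.coef(qr(hp), x)
    sum(f^2) / sum(x^2)
  }
  for (p in c(200, 316)) {                          # well above the 128 s cut-off
    expect_gt(atten(cos(2 * pi * tVol / p)), 0.90)
    expect_gt(atten(sin(2 * pi * tVol / p)), 0.90)
  }
  for (p in c(40, 50, 64)) {                        # at or below 64 s
    expect_lt(atten(cos(2 * pi * tVol / p)), 0.10)
    expect_lt(atten(sin(2 * pi * tVol / p)), 0.15)
  }
})

test_that("group activation tests localise an injected ROI effect", {
  set.seed(11)
  nRoi <- 10
  hits <- 0L
  for (rep in 1:200) {
    a <- matrix(rnorm(16 * nRoi), 16, dimnames = list(NULL, sprintf("R%02d", 1:nRoi)))
    b <- matrix(rnorm(16 * nRoi), 16, dimnames = list(NULL, sprintf("R%02d", 1:nRoi)))
    a[, 3] <- a[, 3] + 2
    tab <- groupActivationTTest(a, b)
    if (which.max(abs(tab$t)) == 3) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
  # df column reflects 16 + 16 subjects
  a <- matrix(rnorm(16 * 3), 16, dimnames = list(NULL, c("x", "y", "z")))
  tab <- groupActivationTTest(a, a + 0)
  expect_true(all(tab$df == 30))
  expect_true(all(tab$t == 0))
  colnames(a) <- c("x", "y", "w")
  expect_error(groupActivationTTest(a, matrix(rnorm(48), 16,
    dimnames = list(NULL, c("x", "y", "z")))), "identical ROI set")
})
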