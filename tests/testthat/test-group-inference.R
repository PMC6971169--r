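test_that("pooled two-sample t matches hand-computed and degenerate cases", {
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$p, 1)
  tt <- twoSampleT(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(tt$t, -sqrt(6), tolerance = 1e-12)   # pooled s^2 = 1/3
  expect_equal(tt$df, 6)
  # zero pooled variance branches
  expect_equal(twoSampleT(c(2, 2), c(2, 2))$t, 0)
  degenerate <- twoSampleT(c(2, 2), c(3, 3))
  expect_true(is.infinite(degenerate$t) && degenerate$t < 0)
  expect_equal(degenerate$p, 0)
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
  expect_error(twoSampleT(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("summary-based t is algebraically identical to the raw-data t", {
  set.seed(30)
  for (i in 1:50) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    t1 <- twoSampleT(a, b)
    t2 <- tFromSummary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    expect_equal(t1$t, t2$t, tolerance = 1e-10)
    expect_equal(t1$df, t2$df)
    expect_equal(t1$p, t2$p, tolerance = 1e-10)
    # sign anti-symmetry
    t3 <- twoSampleT(b, a)
    expect_equal(t3$t, -t1$t, tolerance = 1e-10)
    expect_equal(t3$p, t1$p, tolerance = 1e-10)
  }
  expect_equal(tFromSummary(5, 1, 10, 5, 2, 12)$t, 0)
})

test_that("printed group summaries reproduce the reported t statistics", {
  reading <- tFromSummary(115.75, 13.57, 16, 35.63, 13.59, 16)
  expect_equal(reading$t, 16.69, tolerance = 0.01 / 16.69)
  expect_equal(reading$df, 30)
  expect_lt(reading$p, 0.001)
  raven <- tFromSummary(68.44, 15.78, 16, 75, 16.73, 16)
  expect_equal(raven$t, -1.141, tolerance = 0.001 / 1.141)
  expect_equal(raven$df, 30)
  expect_gt(raven$p, 0.05)
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroniThreshold(0.05, 10), 0.005)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 90), 0.000556, tolerance = 1e-3)
  expect_error(bonferroniThreshold(0.05, 0), "m must be")
})

makeRecords <- function(values, metric = "Cp", sparsities = c(0.05, 0.10),
                        sessions = "phonological") {
  grid <- expand.grid(subject = seq_len(nrow(values)), session = sessions,
                      sparsity = sparsities, stringsAsFactors = FALSE)
  out <- data.frame(
    subject_id = sprintf("s%02d", grid$subject),
    group = rep(c("good", "poor"), each = nrow(values) / 2)[grid$subject],
    session = grid$session, sparsity = grid$sparsity)
  out[[metric]] <- values[cbind(grid$subject, match(grid$sparsity, sparsities))]
  out
}

test_that("global metric comparisons emit flags, families, and drop missing rows", {
  set.seed(31)
  vals <- matrix(rnorm(16 * 2), 16, 2)
  vals[9:16, ] <- vals[9:16, ] + 3                   # strong group difference
  rec <- makeRecords(vals)
  cmp <- compareGlobalMetrics(rec, metrics = "Cp")
  expect_equal(nrow(cmp), 2L)                        # one row per sparsity
  expect_equal(unique(cmp$family_size), 2L)
  expect_true(all(cmp$df == 14))
  expect_true(all(cmp$significant_bonferroni))
  expect_true(all(cmp$significant_bonferroni <= cmp$significant_uncorrected))
  expect_true(all(cmp$t < 0))                        # good - poor with poor higher

  # identical groups: all t exactly 0
  same <- makeRecords(matrix(rep(seq_len(16), 2), 16, 2))
  same$Cp[same$group == "poor"] <- same$Cp[same$group == "good"]
  cmp0 <- compareGlobalMetrics(same, metrics = "Cp")
  expect_true(all(cmp0$t == 0))

  # a missing value drops that sparsity row and shrinks the family
  recNA <- rec
  recNA$Cp[recNA$sparsity == 0.05][1] <- NA
  expect_warning(cmpNA <- compareGlobalMetrics(recNA, metrics = "Cp"),
                 "row dropped")
  expect_equal(nrow(cmpNA), 1L)
  expect_equal(unique(cmpNA$family_size), 1L)
})

test_that("nodal comparisons test every node for both centrality measures", {
  set.seed(32)
  nodes <- sprintf("R%02d", 1:6)
  nod <- expand.grid(subject = 1:16, node = nodes, stringsAsFactors = FALSE)
  nod <- data.frame(
    subject_id = sprintf("s%02d", nod$subject),
    group = rep(c("good", "poor"), each = 8)[nod$subject],
    session = "orthographic", sparsity = 0.05, node = nod$node,
    degree = rpois(nrow(nod), 5), betweenness = runif(nrow(nod), 0, 20))
  nod$degree[nod$node == "R03"] <- 4                 # constant across everyone
  cmp <- compareNodal(nod)
  expect_equal(nrow(cmp), 6L * 2L)                   # nodes x measures
  expect_equal(unique(cmp$family_size), 6L)
  expect_equal(cmp$t[cmp$target == "degree:R03"], 0) # constant node retained, t = 0
  expect_error(compareNodal(rbind(nod, within(nod, sparsity <- 0.1))),
               "single sparsity")
})

test_that("an injected degree shift is localised to the right node", {
  set.seed(33)
  nodes <- sprintf("R%02d", 1:8)
  hits <- 0L
  for (rep in 1:200) {
    nod <- expand.grid(subject = 1:32, node = nodes, stringsAsFactors = FALSE)
    nod <- data.frame(
      subject_id = sprintf("s%02d", nod$subject),
      group = rep(c("good", "poor"), each = 16)[nod$subject],
      session = "orthographic", sparsity = 0.05, node = nod$node,
      degree = rnorm(nrow(nod), 10, 2), betweenness = 0)
    nod$degree[nod$node == "R05" & nod$group == "good"] <-
      nod$degree[nod$node == "R05" & nod$group == "good"] + 3
    cmp <- compareNodal(nod, measures = "degree")
    if (cmp$target[which.max(abs(cmp$t))] == "degree:R05") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})
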