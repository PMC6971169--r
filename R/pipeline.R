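#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [runPipeline()]:
#' either a simulation spec or a manifest of on-disk time series, the
#' sparsity ladder, the null-model size, significance level, group ordering
#' and stage toggles. The resolved configuration is written beside every
#' run's outputs.
#'
#' @param spec a [CohortSpec-class] for simulate mode (ignored when
#'   `manifest` is given).
#' @param manifest optional path to a time-series manifest CSV; switches the
#'   pipeline to load mode.
#' @param sparsityMin,sparsityMax,sparsityStep the ladder (defaults 5%-50%
#'   step 5%).
#' @param nodalSparsity sparsity for the nodal centrality comparisons
#'   (default 0.05, the sparsest ladder point).
#' @param nNull rewired nulls per network for gamma/lambda/sigma (0 skips).
#' @param alpha significance level.
#' @param groupOrder two group labels; t statistics are first minus second.
#' @param runGlm whether to run the ROI-level GLM activation stage.
#' @param globalSignalInGlm include a mean-across-ROIs regressor in the GLM
#'   (activation analysis convention; never applied to network construction).
#' @param taskBlocksOnly compute correlations on task-block volumes only
#'   instead of the full analysed run.
#' @param seed master seed.
#' @return a validated list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(spec = cohortSpec(), manifest = NULL,
                           sparsityMin = 0.05, sparsityMax = 0.50,
                           sparsityStep = 0.05, nodalSparsity = 0.05,
                           nNull = 100, alpha = 0.05,
                           groupOrder = c("good", "poor"),
                           runGlm = TRUE, globalSignalInGlm = TRUE,
                           taskBlocksOnly = FALSE, seed = 1L) {
  cfg <- list(spec = spec, manifest = manifest,
              sparsityMin = sparsityMin, sparsityMax = sparsityMax,
              sparsityStep = sparsityStep, nodalSparsity = nodalSparsity,
              nNull = nNull, alpha = alpha, groupOrder = groupOrder,
              runGlm = runGlm, globalSignalInGlm = globalSignalInGlm,
              taskBlocksOnly = taskBlocksOnly, seed = as.integer(seed))
  if (cfg$sparsityMin <= 0 || cfg$sparsityMin > cfg$sparsityMax ||
      cfg$sparsityMax > 1 || cfg$sparsityStep <= 0)
    stop("invalid sparsity ladder")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(cfg$groupOrder) != 2) stop("groupOrder must name two groups")
  if (cfg$nNull < 0) stop("nNull must be >= 0")
  if (is.null(manifest)) validObject(spec)
  class(cfg) <- "pipelineConfig"
  cfg
}

configAsYaml <- function(cfg) {
  lst <- cfg
  class(lst) <- NULL
  if (!is.null(lst$spec)) {
    sp <- lst$spec
    lst$spec <- list(nPerGroup = sp@nPerGroup, nRois = sp@nRois,
                     nModules = sp@nModules,
                     withinModuleR = sp@withinModuleR,
                     betweenModuleR = sp@betweenModuleR,
                     deltaWithinR = sp@deltaWithinR,
                     effectGroup = sp@effectGroup,
                     effectSession = sp@effectSession,
                     activationAmplitude = sp@activationAmplitude,
                     noiseSd = sp@noiseSd, seed = sp@seed)
  }
  yaml::as.yaml(lst)
}

#' Read a time-series manifest
#'
#' Loads per-subject ROI time-series TSVs listed in a manifest CSV with
#' columns `subject_id`, `group`, `session`, `file` (paths relative to the
#' manifest). Each TSV must have a leading `roi` label column whose entries
#' match the expected label list, row for row.
#'
#' @param path manifest CSV path.
#' @param labels expected ROI labels (default the AAL-90 list).
#' @param tr repetition time recorded on the loaded series (seconds).
#' @param groups optional allowed group labels; unknown labels are an error.
#' @return list of [RoiTimeSeries-class].
#' @export
readTimeSeriesManifest <- function(path, labels = aalLabels(), tr = 2,
                                   groups = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "session", "file")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (nrow(man) == 0) stop("no subjects in manifest")
  dup <- duplicated(man[, c("subject_id", "session")])
  if (any(dup))
    stop("duplicate (subject, session) at manifest row(s) ",
         paste(which(dup), collapse = ", "))
  if (!is.null(groups)) {
    bad <- which(!man$group %in% groups)
    if (length(bad))
      stop("unknown group label at manifest row(s) ",
           paste(bad, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(base, man$file[i])
    if (!file.exists(f))
      stop("manifest row ", i, ": file not found: ", man$file[i])
    df <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
    if (nrow(df) != length(labels))
      stop("manifest row ", i, ": ", man$file[i], " has ", nrow(df),
           " rows; expected ", length(labels))
    if (!identical(as.character(df$roi), labels))
      stop("manifest row ", i, ": ROI labels in ", man$file[i],
           " do not match the expected label list")
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- NULL
    new("RoiTimeSeries", data = m, subjectId = man$subject_id[i],
        group = man$group[i], session = man$session[i], tr = tr,
        roiLabels = labels)
  })
}

# Volume indices (in the analysed run) falling inside task blocks.
taskBlockVolumes <- function(schedule) {
  tVol <- (seq_len(schedule@nVolumes) - 1L) * schedule@tr
  ev <- schedule@events
  inTask <- rep(FALSE, schedule@nVolumes)
  for (i in which(ev$condition == "task"))
    inTask <- inTask | (tVol >= ev$onset[i] - 1e-9 &
                          tVol < ev$onset[i] + ev$duration[i] - 1e-9)
  keep <- which(inTask)
  keep <- keep[keep > schedule@nDummy] - schedule@nDummy
  keep
}

#' Run the full network-comparison pipeline
#'
#' simulate (or load) -> optional ROI GLM -> connectivity -> sparsity ladder
#' -> global and nodal metrics -> group comparisons. Every stage writes its
#' table under `outDir`, alongside the resolved configuration and a run log,
#' so stages can be inspected or re-used independently. A fixed
#' (config, seed) pair reproduces identical tables.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created; contents overwritten).
#' @return invisibly, a list with the in-memory tables (`metrics`, `nodal`,
#'   `globalComparisons`, `nodalComparisons`, and `activation*` when the GLM
#'   stage ran) plus `outDir`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("readnet %s | R %s",
                        as.character(utils::packageVersion("readnet")),
                        paste(R.version$major, R.version$minor, sep = ".")),
                sprintf("seed: %d", config$seed))
  schedule <- makeBlockDesign()

  if (is.null(config$manifest)) {
    spec <- config$spec
    spec@seed <- deriveSeed(config$seed, spec@seed)
    cohort <- simulateCohort(spec, schedule)
    subjects <- cohort@subjects
    utils::write.csv(cohort@behavior, file.path(outDir, "behavior.csv"),
                     row.names = FALSE, quote = FALSE)
    beh <- cohort@behavior
    behTab <- do.call(rbind, lapply(c("reading_score", "raven_score"),
      function(mCol) {
        comparisonRow(mCol, NA_character_, NA_real_,
                      beh[[mCol]][beh$group == config$groupOrder[1]],
                      beh[[mCol]][beh$group == config$groupOrder[2]])
      }))
    writeComparisonTable(behTab, file.path(outDir, "behavior_comparison.tsv"))
    logLines <- c(logLines, "mode: simulate")
  } else {
    subjects <- readTimeSeriesManifest(config$manifest,
                                       groups = config$groupOrder)
    logLines <- c(logLines, paste("mode: load", config$manifest))
  }

  writeLines(configAsYaml(config), file.path(outDir, "config_resolved.yaml"))

  if (isTRUE(config$runGlm)) {
    nAna <- schedule@nVolumes - schedule@nDummy
    if (all(vapply(subjects, nVolumes, integer(1)) == nAna)) {
      sessions <- unique(vapply(subjects, sessionLabel, character(1)))
      actRows <- list()
      for (ses in sessions) {
        effects <- list()
        for (ts in subjects[vapply(subjects, sessionLabel, character(1)) == ses]) {
          gs <- if (isTRUE(config$globalSignalInGlm)) colMeans(ts@data) else NULL
          design <- buildDesignMatrix(schedule, globalSignal = gs)
          fit <- fitGlm(ts, design)
          ct <- contrastT(fit, design, c(task = 1))
          effects[[length(effects) + 1L]] <-
            data.frame(subject_id = ts@subjectId, group = ts@group,
                       roi = ct$roi, effect = ct$effect)
        }
        eff <- do.call(rbind, effects)
        mat <- function(g) {
          sub <- eff[eff$group == g, ]
          m <- tapply(sub$effect, list(sub$subject_id, sub$roi), mean)
          m[, unique(eff$roi), drop = FALSE]
        }
        tab <- groupActivationTTest(mat(config$groupOrder[1]),
                                    mat(config$groupOrder[2]),
                                    alpha = config$alpha)
        tab$session <- ses
        actRows[[ses]] <- tab
      }
      activation <- do.call(rbind, actRows)
      writeComparisonTable(activation, file.path(outDir, "activation_comparison.tsv"))
      logLines <- c(logLines, sprintf("glm: task contrast, global signal %s",
                                      if (isTRUE(config$globalSignalInGlm)) "on" else "off"))
    } else {
      warning("GLM stage skipped: series length does not match the block design")
      activation <- NULL
      logLines <- c(logLines, "glm: skipped (length mismatch)")
    }
  } else {
    activation <- NULL
    logLines <- c(logLines, "glm: off")
  }

  volumes <- if (isTRUE(config$taskBlocksOnly)) taskBlockVolumes(schedule) else NULL
  zcs <- lapply(subjects, roiCorrelationMatrix, volumes = volumes)
  matDir <- file.path(outDir, "connectivity")
  dir.create(matDir, showWarnings = FALSE)
  for (zc in zcs)
    writeConnectivity(zc, file.path(matDir,
      sprintf("%s_%s_z.tsv", zc@subjectId, zc@session)))
  logLines <- c(logLines, sprintf(
    "connectivity: %d matrices (%s volumes)", length(zcs),
    if (is.null(volumes)) "all analysed" else "task-block"))

  sparsities <- seq(config$sparsityMin, config$sparsityMax,
                    by = config$sparsityStep)
  records <- computeMetricRecords(zcs, sparsities, nNull = config$nNull,
                                  seed = config$seed)
  utils::write.table(records, file.path(outDir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodal <- computeNodalRecords(zcs, s = config$nodalSparsity)
  utils::write.table(nodal, file.path(outDir, "nodal_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  globalCmp <- compareGlobalMetrics(records, groupA = config$groupOrder[1],
                                    groupB = config$groupOrder[2],
                                    alpha = config$alpha)
  writeComparisonTable(globalCmp, file.path(outDir, "global_comparison.tsv"))
  nodalCmp <- compareNodal(nodal, groupA = config$groupOrder[1],
                           groupB = config$groupOrder[2], alpha = config$alpha)
  writeComparisonTable(nodalCmp, file.path(outDir, "nodal_comparison.tsv"))
  logLines <- c(logLines, sprintf(
    "metrics: %d global rows, %d nodal rows; comparisons at alpha %g",
    nrow(records), nrow(nodal), config$alpha))
  writeLines(logLines, file.path(outDir, "run_log.txt"))

  invisible(list(metrics = records, nodal = nodal,
                 globalComparisons = globalCmp, nodalComparisons = nodalCmp,
                 activationComparisons = activation, outDir = outDir))
}

#' Metric-versus-sparsity group line plot
#'
#' Base-graphics plot of group mean +/- SD of one global metric across the
#' sparsity ladder, one panel per session.
#'
#' @param records data.frame from [computeMetricRecords()].
#' @param metric metric column to plot.
#' @param groups group labels to draw.
#' @return invisibly, the plotted summary data.frame.
#' @export
plotMetricBySparsity <- function(records, metric = "Cp",
                                 groups = c("good", "poor")) {
  sessions <- unique(records$session)
  agg <- stats::aggregate(records[[metric]],
                          by = list(group = records$group,
                                    session = records$session,
                                    sparsity = records$sparsity),
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  agg <- cbind(agg[1:3], as.data.frame(agg$x))
  oldPar <- graphics::par(mfrow = c(1, length(sessions)))
  on.exit(graphics::par(oldPar))
  for (ses in sessions) {
    sub <- agg[agg$session == ses, ]
    graphics::plot(NULL, xlim = range(sub$sparsity),
                   ylim = range(c(sub$mean - sub$sd, sub$mean + sub$sd)),
                   xlab = "sparsity", ylab = metric, main = ses)
    for (i in seq_along(groups)) {
      g <- sub[sub$group == groups[i], ]
      graphics::lines(g$sparsity, g$mean, col = i, type = "b", pch = i)
      graphics::arrows(g$sparsity, g$mean - g$sd, g$sparsity, g$mean + g$sd,
                       length = 0.02, angle = 90, code = 3, col = i)
    }
    graphics::legend("topleft", legend = groups, col = seq_along(groups),
                     pch = seq_along(groups), bty = "n")
  }
  invisible(agg)
}
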