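#' AAL-90 region labels
#'
#' The 90 cortical and subcortical region names (45 per hemisphere) of the
#' Automated Anatomical Labeling parcellation, in standard atlas order
#' (left/right interleaved). These are the network node labels.
#'
#' @return character vector of length 90.
#' @export
#' @examples
#' head(aalLabels())
aalLabels <- function() {
  readLines(system.file("extdata", "aal90_labels.txt", package = "readnet"))
}

#' Construct a RoiTimeSeries
#'
#' For users bringing their own ROI-by-volume signal matrices.
#'
#' @param data numeric matrix, one row per ROI, one column per analysed
#'   volume.
#' @param subjectId,group,session labels.
#' @param tr repetition time in seconds.
#' @param roiLabels ROI names (default generic, or AAL-90 for 90 rows).
#' @return a [RoiTimeSeries-class].
#' @export
RoiTimeSeries <- function(data, subjectId = "sub", group = "", session = "",
                          tr = 2, roiLabels = NULL) {
  data <- unname(as.matrix(data))
  if (is.null(roiLabels))
    roiLabels <- if (nrow(data) == 90) aalLabels() else
      sprintf("ROI_%03d", seq_len(nrow(data)))
  new("RoiTimeSeries", data = data, subjectId = subjectId, group = group,
      session = session, tr = tr, roiLabels = roiLabels)
}

#' Build a block-design stimulus schedule
#'
#' Lays out one run as fixation blocks flanking every experimental block
#' (F E F E ... E F). Each experimental block is an instruction period followed
#' by `nTrials` trials. With the defaults (TR 2 s, 4 blocks of 2 s instruction
#' + 8 trials of 3 s, 12 s fixation, 3 dummy scans) the run lasts
#' 5x12 + 4x26 = 164 s = 82 volumes, of which 79 are analysed.
#'
#' @param tr repetition time in seconds.
#' @param nBlocks number of experimental blocks.
#' @param instructionS instruction duration at the start of each block (s).
#' @param nTrials trials per block.
#' @param trialS duration of one trial (s).
#' @param fixationS duration of each fixation block (s).
#' @param nDummy leading volumes discarded before analysis.
#' @return a [StimulusSchedule-class].
#' @export
#' @examples
#' makeBlockDesign()
makeBlockDesign <- function(tr = 2, nBlocks = 4, instructionS = 2,
                            nTrials = 8, trialS = 3, fixationS = 12,
                            nDummy = 3) {
  if (nBlocks < 1) stop("nBlocks must be a positive count")
  if (nTrials < 1) stop("nTrials must be a positive count")
  if (tr <= 0 || instructionS <= 0 || trialS <= 0 || fixationS <= 0)
    stop("all durations must be positive")
  taskS <- nTrials * trialS
  total <- (nBlocks + 1) * fixationS + nBlocks * (instructionS + taskS)
  nVol <- total / tr
  if (abs(nVol - round(nVol)) > 1e-9)
    stop("tr does not evenly divide the total run duration (", total, " s)")
  nVol <- as.integer(round(nVol))
  if (nDummy < 0 || nDummy >= nVol)
    stop("nDummy must be non-negative and smaller than the volume count")

  onset <- 0
  rows <- list()
  add <- function(cond, dur) {
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = onset, duration = dur, condition = cond)
    onset <<- onset + dur
  }
  add("fixation", fixationS)
  for (b in seq_len(nBlocks)) {
    add("instruction", instructionS)
    add("task", taskS)
    add("fixation", fixationS)
  }
  new("StimulusSchedule",
      events = do.call(rbind, rows),
      totalDuration = total, tr = tr,
      nVolumes = nVol, nDummy = as.integer(nDummy))
}

#' Construct a synthetic cohort specification
#'
#' Defaults reproduce the study design being emulated: two groups of 16
#' subjects, 90 AAL ROIs in 6 modules of 15, and a within-module correlation
#' increase of 0.15 confined to the poor group's orthographic session (so the
#' topological group difference exists in one session and not the other).
#' Behavioural defaults are the printed summaries: reading score
#' 115.75 +/- 13.57 (good) vs 35.63 +/- 13.59 (poor); Raven score
#' 68.44 +/- 15.78 vs 75 +/- 16.73.
#'
#' @param nPerGroup subjects per group.
#' @param nRois number of ROIs.
#' @param nModules number of contiguous modules; must divide evenly into
#'   blocks of at least 2 ROIs.
#' @param withinModuleR,betweenModuleR baseline module correlations.
#' @param deltaWithinR within-module correlation offset for the affected
#'   group-session cell; set to 0 for a null cohort.
#' @param effectGroup,effectSession the affected cell.
#' @param activationAmplitude amplitude of the task response in active ROIs.
#' @param noiseSd white-noise standard deviation.
#' @param behavior data.frame (`group`, `measure`, `mean`, `sd`).
#' @param seed integer master seed.
#' @return a [CohortSpec-class].
#' @export
#' @examples
#' cohortSpec(seed = 1)
cohortSpec <- function(nPerGroup = 16, nRois = 90, nModules = 6,
                       withinModuleR = 0.35, betweenModuleR = 0.10,
                       deltaWithinR = 0.15,
                       effectGroup = "poor", effectSession = "orthographic",
                       activationAmplitude = 1, noiseSd = 0.5,
                       behavior = defaultBehaviorSpec(), seed = 1L) {
  new("CohortSpec",
      nPerGroup = as.integer(nPerGroup), nRois = as.integer(nRois),
      nModules = as.integer(nModules),
      withinModuleR = withinModuleR, betweenModuleR = betweenModuleR,
      deltaWithinR = deltaWithinR,
      effectGroup = effectGroup, effectSession = effectSession,
      activationAmplitude = activationAmplitude, noiseSd = noiseSd,
      behavior = behavior, seed = as.integer(seed))
}

#' @rdname cohortSpec
#' @export
defaultBehaviorSpec <- function() {
  data.frame(
    group   = c("good", "poor", "good", "poor"),
    measure = c("reading", "reading", "raven", "raven"),
    mean    = c(115.75, 35.63, 68.44, 75),
    sd      = c(13.57, 13.59, 15.78, 16.73)
  )
}

# Contiguous module assignment: first modules get the extra ROIs when nRois
# is not an exact multiple of nModules.
moduleAssignment <- function(nRois, nModules) {
  sizes <- rep(nRois %/% nModules, nModules)
  extra <- nRois %% nModules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(nModules), times = sizes)
}

# Block-structured correlation matrix; optionally perturbed within modules.
moduleCorrelation <- function(spec, perturbed = FALSE) {
  mod <- moduleAssignment(spec@nRois, spec@nModules)
  within <- spec@withinModuleR + if (perturbed) spec@deltaWithinR else 0
  same <- outer(mod, mod, "==")
  r <- ifelse(same, within, spec@betweenModuleR)
  diag(r) <- 1
  r
}

# Repair a correlation matrix that lost positive semi-definiteness: clip
# eigenvalues at a small floor, reconstruct, rescale to unit diagonal.
repairPsd <- function(r, floorEv = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floorEv) return(r)
  warning("correlation matrix not positive semi-definite; ",
          "repaired by eigenvalue clipping")
  v <- pmax(e$values, floorEv)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r2))
  if (any(d <= 0)) stop("covariance repair failed")
  r2 <- r2 / outer(d, d)
  (r2 + t(r2)) / 2
}

# Upper-triangular Cholesky factor of the (repaired) target correlation.
cholFactor <- function(r) {
  u <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(u)) u <- chol(repairPsd(r) + diag(1e-10, nrow(r)))
  u
}

# Deterministic subject seed derived from the master seed and the
# (group, session, subject) coordinates; documented mixing keeps results
# reproducible while decorrelating subjects. Stays below 2^31. Components
# keep their type: strings are folded in character by character, numbers
# enter the recurrence directly.
deriveSeed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647L)
  for (x in list(...)) {
    parts <- if (is.character(x)) utf8ToInt(x) else as.double(x)
    for (xi in parts) s <- (s * 69069 + xi + 1) %% 2147483647
  }
  as.integer(s)
}

# HRF-convolved task regressor over the full run (one value per acquired
# volume, dummies included unless dropDummies).
taskRegressorFull <- function(schedule, condition = "task", oversample = 16L) {
  tr <- schedule@tr
  dt <- tr / oversample
  nFine <- as.integer(round(schedule@totalDuration / dt))
  tFine <- (seq_len(nFine) - 1L) * dt
  box <- numeric(nFine)
  ev <- schedule@events
  for (i in which(ev$condition == condition)) {
    box[tFine >= ev$onset[i] - 1e-9 & tFine < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
  }
  h <- canonicalHrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(nFine)]
  if (max(conv) > 0) conv <- conv / max(conv)
  idx <- (seq_len(schedule@nVolumes) - 1L) * oversample + 1L
  conv[idx]
}

# The designated "active" ROIs receiving task signal: the first ROI of each
# module (round-robin); the identity is immaterial to the network claims.
activeRois <- function(spec) {
  mod <- moduleAssignment(spec@nRois, spec@nModules)
  match(seq_len(spec@nModules), mod)
}

#' Simulate one subject-session of ROI BOLD data
#'
#' Generates `nRois x nVolumes` BOLD signal as task activation (canonical-HRF
#' convolved boxcar, injected into one ROI per module) plus correlated
#' Gaussian noise with the module-structured target correlation matrix (the
#' perturbed matrix when `group`/`session` match the spec's effect cell) plus
#' white noise. The leading dummy volumes are removed before return. Identical
#' inputs give identical output.
#'
#' @param spec a [CohortSpec-class].
#' @param schedule a [StimulusSchedule-class].
#' @param group,session labels for this run.
#' @param subjectSeed integer seed for this run.
#' @param subjectId subject identifier stored in the result.
#' @param roiLabels optional ROI names (defaults to AAL-90 when `nRois` is 90).
#' @param cholCache optional precomputed list of Cholesky factors
#'   (`base`, `perturbed`), used by [simulateCohort()] to avoid refactoring.
#' @return a [RoiTimeSeries-class] with dummy volumes removed.
#' @export
simulateSubjectTimeSeries <- function(spec, schedule, group, session,
                                      subjectSeed, subjectId = "sub",
                                      roiLabels = NULL, cholCache = NULL) {
  validObject(spec); validObject(schedule)
  n <- spec@nRois
  if (is.null(roiLabels))
    roiLabels <- if (n == 90) aalLabels() else sprintf("ROI_%03d", seq_len(n))
  perturbed <- identical(group, spec@effectGroup) &&
    identical(session, spec@effectSession) && spec@deltaWithinR != 0
  u <- if (!is.null(cholCache)) {
    if (perturbed) cholCache$perturbed else cholCache$base
  } else {
    cholFactor(moduleCorrelation(spec, perturbed))
  }
  nVol <- schedule@nVolumes
  set.seed(subjectSeed)
  x <- crossprod(u, matrix(stats::rnorm(n * nVol), n, nVol))
  if (spec@noiseSd > 0)
    x <- x + spec@noiseSd * matrix(stats::rnorm(n * nVol), n, nVol)
  if (spec@activationAmplitude != 0) {
    reg <- taskRegressorFull(schedule)
    act <- activeRois(spec)
    x[act, ] <- x[act, ] + spec@activationAmplitude *
      matrix(reg, length(act), nVol, byrow = TRUE)
  }
  if (schedule@nDummy > 0) x <- x[, -seq_len(schedule@nDummy), drop = FALSE]
  dimnames(x) <- NULL
  new("RoiTimeSeries", data = x, subjectId = subjectId,
      group = group, session = session, tr = schedule@tr,
      roiLabels = roiLabels)
}

#' Draw behavioural scores for a cohort
#'
#' One row per subject with reading and Raven scores drawn from the per-group
#' normal distributions of the spec's behaviour table.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed (defaults to a value derived from the spec seed).
#' @return data.frame (`subject_id`, `group`, `reading_score`, `raven_score`).
#' @export
simulateBehavior <- function(spec, seed = deriveSeed(spec@seed, "behavior")) {
  set.seed(seed)
  beh <- spec@behavior
  rows <- lapply(c("good", "poor"), function(g) {
    rd <- beh[beh$group == g & beh$measure == "reading", ]
    rv <- beh[beh$group == g & beh$measure == "raven", ]
    data.frame(
      subject_id = sprintf("%s_%02d", g, seq_len(spec@nPerGroup)),
      group = g,
      reading_score = stats::rnorm(spec@nPerGroup, rd$mean, rd$sd),
      raven_score = stats::rnorm(spec@nPerGroup, rv$mean, rv$sd)
    )
  })
  do.call(rbind, rows)
}

#' Simulate a full two-group, two-session cohort
#'
#' Generates 2 groups x `nPerGroup` subjects x 2 sessions of ROI time series
#' plus a behavioural score table. Per-run seeds derive deterministically from
#' the spec seed and the (group, session, subject) coordinates, so the whole
#' cohort is a pure function of its spec.
#'
#' @param spec a [CohortSpec-class].
#' @param schedule a [StimulusSchedule-class]; default [makeBlockDesign()].
#' @param sessions session labels to generate.
#' @return a [Cohort-class].
#' @export
#' @examples
#' coh <- simulateCohort(cohortSpec(nPerGroup = 2, nRois = 12, nModules = 3))
#' length(cohortSubjects(coh))
simulateCohort <- function(spec, schedule = makeBlockDesign(),
                           sessions = c("phonological", "orthographic")) {
  validObject(spec)
  n <- spec@nRois
  labels <- if (n == 90) aalLabels() else sprintf("ROI_%03d", seq_len(n))
  cache <- list(base = cholFactor(moduleCorrelation(spec, FALSE)),
                perturbed = cholFactor(moduleCorrelation(spec, TRUE)))
  subjects <- list()
  for (g in c("good", "poor")) {
    for (i in seq_len(spec@nPerGroup)) {
      sid <- sprintf("%s_%02d", g, i)
      for (ses in sessions) {
        seed <- deriveSeed(spec@seed, g, ses, i)
        subjects[[length(subjects) + 1L]] <-
          simulateSubjectTimeSeries(spec, schedule, g, ses, seed,
                                    subjectId = sid, roiLabels = labels,
                                    cholCache = cache)
      }
    }
  }
  new("Cohort", subjects = subjects, behavior = simulateBehavior(spec),
      spec = spec, schedule = schedule)
}

#' Write a cohort to disk as plain-text tables
#'
#' Per subject-session TSV (rows = ROI labels, columns = volumes), a manifest
#' CSV (`subject_id`, `group`, `session`, `file`) and a behavioural CSV,
#' matching what [readTimeSeriesManifest()] consumes.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort@subjects, function(ts) {
    file <- sprintf("%s_%s.tsv", ts@subjectId, ts@session)
    df <- data.frame(roi = ts@roiLabels, ts@data, check.names = FALSE)
    names(df) <- c("roi", sprintf("vol_%03d", seq_len(ncol(ts@data))))
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    data.frame(subject_id = ts@subjectId, group = ts@group,
               session = ts@session, file = file)
  })
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort@behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifestPath)
}
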