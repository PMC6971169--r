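#' @import methods
NULL

#' Block-design stimulus schedule
#'
#' Timing of a single fMRI run: an ordered, non-overlapping event table
#' (fixation / instruction / task), the repetition time, the total number of
#' acquired volumes and the number of leading dummy volumes discarded before
#' analysis.
#'
#' @slot events data.frame with columns `onset`, `duration` (seconds) and
#'   `condition` (one of `"fixation"`, `"instruction"`, `"task"`), sorted by
#'   onset and gap-free.
#' @slot totalDuration total run duration in seconds.
#' @slot tr repetition time in seconds.
#' @slot nVolumes number of acquired volumes (`totalDuration / tr`).
#' @slot nDummy number of initial volumes discarded for T1 saturation.
#' @seealso [makeBlockDesign()]
#' @export
setClass("StimulusSchedule",
  representation(
    events = "data.frame",
    totalDuration = "numeric",
    tr = "numeric",
    nVolumes = "integer",
    nDummy = "integer"
  )
)

setValidity("StimulusSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("onset", "duration", "condition") %in% names(ev)))
    msg <- c(msg, "events must have columns onset, duration, condition")
  else {
    if (is.unsorted(ev$onset, strictly = TRUE))
      msg <- c(msg, "event onsets must be strictly increasing")
    if (nrow(ev) > 1 &&
        any(abs(ev$onset[-1] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])) > 1e-9))
      msg <- c(msg, "events must be contiguous and non-overlapping")
    if (abs(sum(ev$duration) - object@totalDuration) > 1e-9)
      msg <- c(msg, "totalDuration must equal the sum of event durations")
    if (!all(ev$condition %in% c("fixation", "instruction", "task")))
      msg <- c(msg, "unknown event condition")
  }
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (abs(object@totalDuration / object@tr - object@nVolumes) > 1e-9)
    msg <- c(msg, "tr must evenly divide totalDuration into nVolumes")
  if (object@nDummy < 0 || object@nDummy >= object@nVolumes)
    msg <- c(msg, "nDummy must be in [0, nVolumes)")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Parameters of the two-group, two-session synthetic BOLD cohort: a modular
#' (community-structured) ROI correlation matrix, a group-by-session
#' perturbation of the within-module correlations, task activation injected
#' into one ROI per module, white measurement noise, and per-group behavioural
#' score distributions.
#'
#' @slot nPerGroup subjects per group.
#' @slot nRois number of ROIs (network nodes).
#' @slot nModules number of equally sized contiguous modules.
#' @slot withinModuleR baseline correlation between ROIs of the same module.
#' @slot betweenModuleR baseline correlation between ROIs of different modules.
#' @slot deltaWithinR additive offset applied to the within-module
#'   correlations of `effectGroup` in `effectSession`; 0 disables the group
#'   effect.
#' @slot effectGroup,effectSession where the perturbation applies.
#' @slot activationAmplitude amplitude (signal units) of the HRF-convolved
#'   task response added to the active ROIs.
#' @slot noiseSd standard deviation of additive white noise.
#' @slot behavior data.frame with columns `group`, `measure`, `mean`, `sd`
#'   giving the per-group behavioural score distributions.
#' @slot seed integer master seed; all subject-level seeds derive from it.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPerGroup = "integer",
    nRois = "integer",
    nModules = "integer",
    withinModuleR = "numeric",
    betweenModuleR = "numeric",
    deltaWithinR = "numeric",
    effectGroup = "character",
    effectSession = "character",
    activationAmplitude = "numeric",
    noiseSd = "numeric",
    behavior = "data.frame",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@nRois < 2) msg <- c(msg, "nRois must be >= 2")
  if (object@nModules < 1 || object@nModules > object@nRois)
    msg <- c(msg, "nModules must be in [1, nRois]")
  if (abs(object@withinModuleR) >= 1 || abs(object@betweenModuleR) >= 1)
    msg <- c(msg, "module correlations must lie in (-1, 1)")
  if (abs(object@withinModuleR + object@deltaWithinR) >= 1)
    msg <- c(msg, "perturbed within-module correlation must stay in (-1, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!all(c("group", "measure", "mean", "sd") %in% names(object@behavior)))
    msg <- c(msg, "behavior must have columns group, measure, mean, sd")
  if (length(msg)) msg else TRUE
})

#' Per-subject ROI time-series set
#'
#' One subject-session worth of ROI-level BOLD signal: a numeric matrix with
#' one row per ROI and one column per analysed volume (dummy scans already
#' removed), plus subject, group and session labels.
#'
#' @slot data numeric matrix `[nRois x nVolumes]`, no missing values.
#' @slot subjectId subject identifier.
#' @slot group group label (e.g. `"good"` / `"poor"`).
#' @slot session session label (e.g. `"phonological"` / `"orthographic"`).
#' @slot tr repetition time in seconds.
#' @slot roiLabels ROI names, one per data row.
#' @export
setClass("RoiTimeSeries",
  representation(
    data = "matrix",
    subjectId = "character",
    group = "character",
    session = "character",
    tr = "numeric",
    roiLabels = "character"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (anyNA(object@data)) msg <- c(msg, "data must not contain missing values")
  if (nrow(object@data) != length(object@roiLabels))
    msg <- c(msg, "data row count must equal length(roiLabels)")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulated cohort container
#'
#' Holds all subject-session time series of a simulated cohort together with
#' the behavioural score table, the generating specification and the stimulus
#' schedule.
#'
#' @slot subjects list of [RoiTimeSeries-class] objects
#'   (2 groups x nPerGroup x 2 sessions).
#' @slot behavior data.frame with one row per subject
#'   (`subject_id`, `group`, `reading_score`, `raven_score`).
#' @slot spec the generating [CohortSpec-class].
#' @slot schedule the [StimulusSchedule-class] shared by all runs.
#' @export
setClass("Cohort",
  representation(
    subjects = "list",
    behavior = "data.frame",
    spec = "CohortSpec",
    schedule = "StimulusSchedule"
  )
)

setValidity("Cohort", function(object) {
  if (!all(vapply(object@subjects, is, logical(1), "RoiTimeSeries")))
    return("subjects must all be RoiTimeSeries objects")
  TRUE
})

#' Fisher-z functional connectivity matrix
#'
#' Symmetric ROI-by-ROI Pearson correlation matrix for one subject-session,
#' together with its Fisher variance-stabilising transform z = atanh(r).
#' Diagonals are masked (NA) and take no part in edge operations.
#'
#' @slot r symmetric Pearson correlation matrix, diagonal NA.
#' @slot z elementwise atanh of `r` (clipped just inside +/-1), diagonal NA.
#' @slot subjectId,group,session labels carried from the time series.
#' @slot nodeLabels ROI names.
#' @seealso [roiCorrelationMatrix()]
#' @export
setClass("ZConnectivity",
  representation(
    r = "matrix",
    z = "matrix",
    subjectId = "character",
    group = "character",
    session = "character",
    nodeLabels = "character"
  )
)

setValidity("ZConnectivity", function(object) {
  msg <- character()
  if (nrow(object@r) != ncol(object@r)) msg <- c(msg, "r must be square")
  if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 0,
                        check.attributes = FALSE)))
    msg <- c(msg, "r must be exactly symmetric")
  if (!isTRUE(all.equal(object@z, t(object@z), tolerance = 0,
                        check.attributes = FALSE)))
    msg <- c(msg, "z must be exactly symmetric")
  off <- upper.tri(object@r)
  if (any(abs(object@r[off]) > 1)) msg <- c(msg, "off-diagonal r out of [-1, 1]")
  if (length(object@nodeLabels) != nrow(object@r))
    msg <- c(msg, "nodeLabels length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Binary undirected network
#'
#' Unweighted, undirected adjacency matrix obtained by sparsity thresholding a
#' connectivity matrix: only positive correlations are eligible, and the
#' strongest `floor(s * N(N-1)/2)` of them become edges.
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal.
#' @slot sparsity requested edge fraction.
#' @slot achievedSparsity realised edge fraction (may be lower when too few
#'   positive correlations exist).
#' @slot nodeLabels node (ROI) names.
#' @seealso [thresholdBySparsity()], [BinaryNetwork()]
#' @export
setClass("BinaryNetwork",
  representation(
    adjacency = "matrix",
    sparsity = "numeric",
    achievedSparsity = "numeric",
    nodeLabels = "character"
  )
)

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  if (!identical(a, t(a))) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
  if (length(object@nodeLabels) != nrow(a))
    msg <- c(msg, "nodeLabels length must match adjacency dimension")
  if (length(msg)) msg else TRUE
})

#' ROI-level GLM fit
#'
#' Ordinary-least-squares fit of one design matrix to every ROI time series of
#' a subject-session.
#'
#' @slot betas coefficient matrix `[nRegressors x nRois]`.
#' @slot residualVariance per-ROI residual variance, RSS / dofResid.
#' @slot dofResid residual degrees of freedom, volumes minus design rank.
#' @slot roiLabels ROI names (column order of `betas`).
#' @seealso [fitGlm()], [contrastT()]
#' @export
setClass("GlmFit",
  representation(
    betas = "matrix",
    residualVariance = "numeric",
    dofResid = "integer",
    roiLabels = "character"
  )
)

setValidity("GlmFit", function(object) {
  msg <- character()
  if (object@dofResid <= 0) msg <- c(msg, "dofResid must be positive")
  if (any(object@residualVariance < -1e-12))
    msg <- c(msg, "residual variance must be non-negative")
  if (length(msg)) msg else TRUE
})
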