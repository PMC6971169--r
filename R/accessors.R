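#' Accessors for readnet classes
#'
#' Slot accessors for the S4 containers: adjacency matrices, sparsity values,
#' node/ROI labels, time-series matrices, correlation matrices and schedule
#' fields. Always use these rather than `@` slot access.
#'
#' @param x a readnet S4 object.
#' @return the corresponding slot value; `edgeCount` returns the number of
#'   undirected edges of a [BinaryNetwork-class].
#' @name accessors
NULL

#' @rdname accessors
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)

#' @rdname accessors
setMethod("sparsity", "BinaryNetwork", function(x) x@sparsity)

#' @rdname accessors
setMethod("achievedSparsity", "BinaryNetwork", function(x) x@achievedSparsity)

#' @rdname accessors
setMethod("nodeLabels", "BinaryNetwork", function(x) x@nodeLabels)

#' @rdname accessors
setMethod("nodeLabels", "ZConnectivity", function(x) x@nodeLabels)

#' @rdname accessors
setMethod("edgeCount", "BinaryNetwork",
          function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname accessors
setMethod("roiLabels", "RoiTimeSeries", function(x) x@roiLabels)

#' @rdname accessors
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)

#' @rdname accessors
setMethod("subjectId", "ZConnectivity", function(x) x@subjectId)

#' @rdname accessors
setMethod("groupLabel", "RoiTimeSeries", function(x) x@group)

#' @rdname accessors
setMethod("groupLabel", "ZConnectivity", function(x) x@group)

#' @rdname accessors
setMethod("sessionLabel", "RoiTimeSeries", function(x) x@session)

#' @rdname accessors
setMethod("sessionLabel", "ZConnectivity", function(x) x@session)

#' @rdname accessors
setMethod("tsMatrix", "RoiTimeSeries", function(x) x@data)

#' @rdname accessors
setMethod("rMatrix", "ZConnectivity", function(x) x@r)

#' @rdname accessors
setMethod("zMatrix", "ZConnectivity", function(x) x@z)

#' @rdname accessors
setMethod("nVolumes", "RoiTimeSeries", function(x) ncol(x@data))

#' @rdname accessors
setMethod("nVolumes", "StimulusSchedule", function(x) x@nVolumes)

#' @rdname accessors
setMethod("trSeconds", "RoiTimeSeries", function(x) x@tr)

#' @rdname accessors
setMethod("trSeconds", "StimulusSchedule", function(x) x@tr)

#' @rdname accessors
setMethod("scheduleEvents", "StimulusSchedule", function(x) x@events)

#' @rdname accessors
setMethod("cohortSubjects", "Cohort", function(x) x@subjects)

#' @rdname accessors
setMethod("behaviorTable", "Cohort", function(x) x@behavior)

setMethod("show", "StimulusSchedule", function(object) {
  ev <- object@events
  cat("StimulusSchedule:", nrow(ev), "events,",
      object@totalDuration, "s total, TR =", object@tr, "s\n")
  cat("  volumes:", object@nVolumes,
      sprintf("(%d dummy discarded, %d analysed)\n",
              object@nDummy, object@nVolumes - object@nDummy))
  cat("  conditions:",
      paste(sprintf("%s x%d", names(table(ev$condition)),
                    as.integer(table(ev$condition))), collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: 2 groups x", object@nPerGroup, "subjects x 2 sessions,",
      object@nRois, "ROIs in", object@nModules, "modules\n")
  cat(sprintf("  correlations: within %.2f, between %.2f, delta %+.2f on %s/%s\n",
              object@withinModuleR, object@betweenModuleR, object@deltaWithinR,
              object@effectGroup, object@effectSession))
  cat(sprintf("  activation %.2f, noise sd %.2f, seed %d\n",
              object@activationAmplitude, object@noiseSd, object@seed))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries %s [%s, %s]: %d ROIs x %d volumes, TR = %g s\n",
              object@subjectId, object@group, object@session,
              nrow(object@data), ncol(object@data), object@tr))
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", length(object@subjects), "subject-sessions,",
      nrow(object@behavior), "subjects with behavioural scores\n")
})

setMethod("show", "ZConnectivity", function(object) {
  cat(sprintf("ZConnectivity %s [%s, %s]: %d x %d Fisher-z matrix\n",
              object@subjectId, object@group, object@session,
              nrow(object@z), ncol(object@z)))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (sparsity %.3f requested, %.3f achieved)\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              object@sparsity, object@achievedSparsity))
})

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit: %d regressors x %d ROIs, %d residual df\n",
              nrow(object@betas), ncol(object@betas), object@dofResid))
})
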