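#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' @rdname accessors
#' @export
setGeneric("achievedSparsity", function(x) standardGeneric("achievedSparsity"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))

#' @rdname accessors
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @rdname accessors
#' @export
setGeneric("rMatrix", function(x) standardGeneric("rMatrix"))

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("scheduleEvents", function(x) standardGeneric("scheduleEvents"))

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname accessors
#' @export
setGeneric("behaviorTable", function(x) standardGeneric("behaviorTable"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
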