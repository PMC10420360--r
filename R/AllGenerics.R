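#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the smellbench S4 classes.
#'
#' @param x an object.
#' @return The slot value documented on each class.
#' @name smellbench-generics
#' @keywords internal
NULL

#' @rdname smellbench-generics
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname smellbench-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname smellbench-generics
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname smellbench-generics
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname smellbench-generics
#' @export
setGeneric("channelCount", function(x) standardGeneric("channelCount"))

#' @rdname smellbench-generics
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname smellbench-generics
#' @export
setGeneric("shutterOpenIndex", function(x) standardGeneric("shutterOpenIndex"))

#' @rdname smellbench-generics
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' @rdname smellbench-generics
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname smellbench-generics
#' @export
setGeneric("varianceRatios", function(x) standardGeneric("varianceRatios"))

#' @rdname smellbench-generics
#' @export
setGeneric("meanF1", function(x) standardGeneric("meanF1"))

#' @rdname smellbench-generics
#' @export
setGeneric("meanRecall", function(x) standardGeneric("meanRecall"))

#' @rdname smellbench-generics
#' @export
setGeneric("foldF1", function(x) standardGeneric("foldF1"))

#' @rdname smellbench-generics
#' @export
setGeneric("foldRecall", function(x) standardGeneric("foldRecall"))

#' @rdname smellbench-generics
#' @export
setGeneric("foldCounts", function(x) standardGeneric("foldCounts"))

#' @rdname smellbench-generics
#' @export
setGeneric("cvPlan", function(x) standardGeneric("cvPlan"))

#' @rdname smellbench-generics
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname smellbench-generics
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
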