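#' @rdname ModalityPool-class
#' @param x an object.
#' @export
setGeneric("poolSamples", function(x) standardGeneric("poolSamples"))

#' @rdname ModalityPool-class
#' @export
setGeneric("poolLabels", function(x) standardGeneric("poolLabels"))

#' @rdname ModalityPool-class
#' @export
setGeneric("poolModality", function(x) standardGeneric("poolModality"))

#' @rdname StimulusSet-class
#' @param x an object.
#' @export
setGeneric("visualInputs", function(x) standardGeneric("visualInputs"))

#' @rdname StimulusSet-class
#' @export
setGeneric("auditoryInputs", function(x) standardGeneric("auditoryInputs"))

#' @rdname StimulusSet-class
#' @export
setGeneric("visualTargets", function(x) standardGeneric("visualTargets"))

#' @rdname StimulusSet-class
#' @export
setGeneric("auditoryTargets", function(x) standardGeneric("auditoryTargets"))

#' @rdname StimulusSet-class
#' @export
setGeneric("visualLabels", function(x) standardGeneric("visualLabels"))

#' @rdname StimulusSet-class
#' @export
setGeneric("auditoryLabels", function(x) standardGeneric("auditoryLabels"))

#' @rdname StimulusSet-class
#' @export
setGeneric("pairConditions", function(x) standardGeneric("pairConditions"))

#' @rdname StimulusSet-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname StimulusSet-class
#' @export
setGeneric("consistencyType", function(x) standardGeneric("consistencyType"))

#' @rdname ActivationMatrix-class
#' @param x an object.
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname ActivationMatrix-class
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname ActivationMatrix-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname ActivationMatrix-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname BinnedResponseTable-class
#' @param x an object.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname BinnedResponseTable-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname BinnedResponseTable-class
#' @export
setGeneric("conditionalProb", function(x) standardGeneric("conditionalProb"))

#' @rdname BinnedResponseTable-class
#' @export
setGeneric("marginalProb", function(x) standardGeneric("marginalProb"))

#' @rdname InfoTable-class
#' @param x an object.
#' @export
setGeneric("infoValues", function(x) standardGeneric("infoValues"))

#' @rdname InfoTable-class
#' @export
setGeneric("infoCondition", function(x) standardGeneric("infoCondition"))

#' @rdname UnitTypology-class
#' @param x an object.
#' @export
setGeneric("typologyTable", function(x) standardGeneric("typologyTable"))

#' @rdname UnitTypology-class
#' @export
setGeneric("typeCounts", function(x) standardGeneric("typeCounts"))

#' @rdname UnitTypology-class
#' @export
setGeneric("typologyThresholds",
           function(x) standardGeneric("typologyThresholds"))

#' @rdname TrainedModel-class
#' @param x an object.
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))

#' @rdname TrainedModel-class
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
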