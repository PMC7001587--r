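#' Construct an ActivationMatrix
#'
#' @param responses units x samples numeric matrix (rownames become unit
#'   ids; generated when absent).
#' @param labels integer digit label per sample.
#' @param condition per-sample presentation condition.
#' @param layerIndex optional index of the encoding layer the responses
#'   came from.
#' @return an [ActivationMatrix-class].
#' @export
activationMatrix <- function(responses, labels, condition,
                             layerIndex = NA_integer_) {
  if (is.null(rownames(responses)))
    rownames(responses) <- sprintf("unit%03d", seq_len(nrow(responses)))
  se <- SummarizedExperiment(
    assays = list(activations = responses),
    colData = DataFrame(label = as.integer(labels), condition = condition))
  metadata(se) <- list(layerIndex = as.integer(layerIndex))
  out <- as(se, "ActivationMatrix")
  validObject(out)
  out
}

#' @describeIn ActivationMatrix-class samples x units response matrix (one
#'   row per stimulus pair, one column per unit).
#' @export
setMethod("responses", "ActivationMatrix",
          function(x) t(assay(x, "activations")))

#' @describeIn ActivationMatrix-class unit identifiers.
#' @export
setMethod("unitIds", "ActivationMatrix", function(x) rownames(x))

#' @describeIn ActivationMatrix-class per-sample digit labels.
#' @export
setMethod("sampleLabels", "ActivationMatrix", function(x) colData(x)$label)

#' @describeIn ActivationMatrix-class per-sample presentation conditions.
#' @export
setMethod("sampleConditions", "ActivationMatrix",
          function(x) colData(x)$condition)

setMethod("show", "ActivationMatrix", function(object) {
  cat(sprintf("ActivationMatrix: %d units x %d samples (layer %s)\n",
              nrow(object), ncol(object),
              as.character(metadata(object)$layerIndex)))
})
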