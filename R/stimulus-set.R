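#' Construct a StimulusSet
#'
#' Low-level constructor; most users build stimulus sets with
#' [pairConsistent()], [pairInconsistent()] and
#' [augmentModalityDropout()].
#'
#' @param visual,auditory pixel x pair input matrices in [0, 1].
#' @param labelVisual,labelAudio integer digit labels per pair.
#' @param condition per-pair presentation condition (`"both"`,
#'   `"visual_only"`, `"audio_only"`).
#' @param role `"train"` or `"test"`.
#' @param consistency `"consistent"` or `"inconsistent"`.
#' @param seed seed the pairing was drawn with.
#' @param visualTarget,auditoryTarget reconstruction targets; default the
#'   inputs themselves (the pre-dropout arrays).
#' @param gridShapeVisual,gridShapeAuditory array shapes of the two
#'   modalities.
#' @return a [StimulusSet-class].
#' @export
stimulusSet <- function(visual, auditory, labelVisual, labelAudio,
                        condition = "both", role = "train",
                        consistency = "consistent", seed = NA_integer_,
                        visualTarget = visual, auditoryTarget = auditory,
                        gridShapeVisual = .VISUAL_GRID,
                        gridShapeAuditory = .AUDITORY_GRID) {
  n <- ncol(visual)
  condition <- rep_len(condition, n)
  cd <- DataFrame(labelVisual = as.integer(labelVisual),
                  labelAudio = as.integer(labelAudio),
                  condition = condition)
  se <- SummarizedExperiment(
    assays = list(visual = visual, auditory = auditory,
                  visualTarget = visualTarget,
                  auditoryTarget = auditoryTarget),
    colData = cd)
  metadata(se) <- list(role = role, consistency = consistency,
                       seed = as.integer(seed),
                       gridShapeVisual = as.integer(gridShapeVisual),
                       gridShapeAuditory = as.integer(gridShapeAuditory),
                       augmented = !all(condition == "both"))
  out <- as(se, "StimulusSet")
  validObject(out)
  out
}

#' @describeIn StimulusSet-class visual input matrix (pixels x pairs).
#' @export
setMethod("visualInputs", "StimulusSet",
          function(x) assay(x, "visual"))

#' @describeIn StimulusSet-class auditory input matrix (pixels x pairs).
#' @export
setMethod("auditoryInputs", "StimulusSet",
          function(x) assay(x, "auditory"))

#' @describeIn StimulusSet-class visual reconstruction targets.
#' @export
setMethod("visualTargets", "StimulusSet",
          function(x) assay(x, "visualTarget"))

#' @describeIn StimulusSet-class auditory reconstruction targets.
#' @export
setMethod("auditoryTargets", "StimulusSet",
          function(x) assay(x, "auditoryTarget"))

#' @describeIn StimulusSet-class per-pair visual digit labels.
#' @export
setMethod("visualLabels", "StimulusSet",
          function(x) colData(x)$labelVisual)

#' @describeIn StimulusSet-class per-pair auditory digit labels.
#' @export
setMethod("auditoryLabels", "StimulusSet",
          function(x) colData(x)$labelAudio)

#' @describeIn StimulusSet-class per-pair presentation conditions.
#' @export
setMethod("pairConditions", "StimulusSet",
          function(x) colData(x)$condition)

#' @describeIn StimulusSet-class number of stimulus pairs.
#' @export
setMethod("nPairs", "StimulusSet", function(x) ncol(x))

#' @describeIn StimulusSet-class `"consistent"` or `"inconsistent"`.
#' @export
setMethod("consistencyType", "StimulusSet",
          function(x) metadata(x)$consistency)

setMethod("show", "StimulusSet", function(object) {
  cond <- table(factor(pairConditions(object), levels = .CONDITIONS))
  cat(sprintf(
    "StimulusSet: %d pairs (%s, %s)\n  conditions: both=%d visual_only=%d audio_only=%d\n",
    ncol(object), metadata(object)$role, metadata(object)$consistency,
    cond[["both"]], cond[["visual_only"]], cond[["audio_only"]]))
})
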