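#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IntegerList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

.MODALITIES <- c("visual", "auditory")
.CONDITIONS <- c("both", "visual_only", "audio_only")
.CELL_TYPES <- c("visual", "auditory", "inconsistent", "consistent",
                 "non_selective")
.VISUAL_GRID <- c(28L, 28L)
.AUDITORY_GRID <- c(14L, 56L)

#' Configuration for the synthetic paired-digit generator
#'
#' Holds the sampling design of the synthetic two-modality digit pools:
#' class count, per-class sample counts for the visual train/test pools and
#' the auditory pool, the number of auditory sub-prototypes ("speakers"),
#' the additive noise level and the prototype separation.
#'
#' @slot nClasses number of digit categories (default 10).
#' @slot visualTrain visual training variations per class (default 500).
#' @slot visualTest visual test variations per class (default 50).
#' @slot audioPerClass auditory variations per class in each half of the
#'   pool after the train/test split (default 50, i.e. a 100-per-class pool
#'   halved).
#' @slot nSources number of auditory sub-prototypes per class (default 2).
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise.
#' @slot protoSep separation of the class-specific pattern component;
#'   larger values give more distinct, near-saturated class prototypes.
#' @slot seed master seed; all substreams are derived from it.
#' @export
setClass("GeneratorConfig",
  representation(nClasses = "integer", visualTrain = "integer",
                 visualTest = "integer", audioPerClass = "integer",
                 nSources = "integer", noiseSd = "numeric",
                 protoSep = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  for (s in c("nClasses", "visualTrain", "visualTest", "audioPerClass",
              "nSources"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)) ||
        slot(object, s) < 1L)
      msg <- c(msg, sprintf("'%s' must be a single count >= 1", s))
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be non-negative")
  if (object@protoSep < 0) msg <- c(msg, "'protoSep' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A pool of single-modality samples
#'
#' Raw per-modality samples: one row per sample over a fixed pixel grid,
#' values in [0, 1], with digit labels and the sub-prototype ("speaker")
#' index each sample was drawn from. Visual grids are 28 x 28; auditory
#' grids are 14 x 56 spectrogram-shaped arrays.
#'
#' @slot modality `"visual"` or `"auditory"`.
#' @slot samples numeric matrix, samples x pixels (row-major flattening).
#' @slot labels integer digit labels in `0:(nClasses - 1)`.
#' @slot sourceId integer sub-prototype index per sample.
#' @slot gridShape integer (rows, cols) of the unflattened array.
#' @slot nClasses number of digit categories.
#' @slot seed seed the pool was generated with.
#' @export
setClass("ModalityPool",
  representation(modality = "character", samples = "matrix",
                 labels = "integer", sourceId = "integer",
                 gridShape = "integer", nClasses = "integer",
                 seed = "integer"))

setValidity("ModalityPool", function(object) {
  msg <- character()
  if (!object@modality %in% .MODALITIES)
    msg <- c(msg, "'modality' must be 'visual' or 'auditory'")
  expected <- if (identical(object@modality, "visual")) .VISUAL_GRID
              else .AUDITORY_GRID
  if (!identical(object@gridShape, expected))
    msg <- c(msg, sprintf("%s gridShape must be (%d, %d)", object@modality,
                          expected[1L], expected[2L]))
  if (ncol(object@samples) != prod(object@gridShape))
    msg <- c(msg, "sample width does not match gridShape")
  if (nrow(object@samples) != length(object@labels) ||
      nrow(object@samples) != length(object@sourceId))
    msg <- c(msg, "labels/sourceId length must match the sample count")
  rng <- range(object@samples)
  if (rng[1L] < 0 || rng[2L] > 1)
    msg <- c(msg, "sample values must lie in [0, 1]")
  if (!setequal(unique(object@labels), 0:(object@nClasses - 1L)))
    msg <- c(msg, "every class label must be present in the pool")
  if (length(msg)) msg else TRUE
})

#' Planted per-unit response distributions
#'
#' An oracle fixture: for each synthetic unit, a bin-probability matrix
#' (classes x bins) per modality from which activations are sampled, plus
#' the digit sets the unit was planted to be selective for. The
#' stimulus-specific information of every planted unit is available in
#' closed form, which makes the information analysis and the unit
#' classifier testable against exact expected values.
#'
#' @slot nClasses,nBins design of the planted distributions.
#' @slot visualDigits,auditoryDigits `IntegerList`, planted selective digit
#'   sets per unit.
#' @slot distributions per-unit list of `list(visual=, auditory=)`
#'   classes x bins probability matrices (rows sum to 1).
#' @export
setClass("PlantedActivationSpec",
  representation(nClasses = "integer", nBins = "integer",
                 visualDigits = "IntegerList", auditoryDigits = "IntegerList",
                 distributions = "list"))

setValidity("PlantedActivationSpec", function(object) {
  msg <- character()
  n <- length(object@distributions)
  if (length(object@visualDigits) != n || length(object@auditoryDigits) != n)
    msg <- c(msg, "digit lists and distributions must have one entry per unit")
  digits <- 0:(object@nClasses - 1L)
  if (!all(unlist(object@visualDigits) %in% digits) ||
      !all(unlist(object@auditoryDigits) %in% digits))
    msg <- c(msg, "planted digit sets must be subsets of the class range")
  for (u in seq_len(n)) {
    for (m in .MODALITIES) {
      d <- object@distributions[[u]][[m]]
      if (!is.matrix(d) || !identical(dim(d),
          c(as.integer(object@nClasses), as.integer(object@nBins)))) {
        msg <- c(msg, sprintf("unit %d %s distribution has wrong shape", u, m))
        next
      }
      if (any(d < 0) || any(abs(rowSums(d) - 1) > 1e-8))
        msg <- c(msg, sprintf(
          "unit %d %s distribution rows must be probability vectors", u, m))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Paired two-modality stimuli
#'
#' A `SummarizedExperiment` of paired visual/auditory stimuli. Columns are
#' stimulus pairs; the assays hold the flattened pixel arrays:
#' `visual`/`auditory` are the network inputs (zeroed under modality
#' dropout) and `visualTarget`/`auditoryTarget` the reconstruction targets,
#' which always retain the original arrays. `colData` carries the per-pair
#' digit labels of each modality and the presentation condition.
#'
#' @export
setClass("StimulusSet", contains = "SummarizedExperiment")

setValidity("StimulusSet", function(object) {
  msg <- character()
  need <- c("visual", "auditory", "visualTarget", "auditoryTarget")
  if (!all(need %in% names(SummarizedExperiment::assays(object))))
    return("assays 'visual', 'auditory', 'visualTarget', 'auditoryTarget' are required")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("labelVisual", "labelAudio", "condition"))
    if (!f %in% names(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if (length(msg)) return(msg)
  if (!all(cd$condition %in% .CONDITIONS))
    msg <- c(msg, "unknown presentation condition")
  xv <- SummarizedExperiment::assay(object, "visual")
  xa <- SummarizedExperiment::assay(object, "auditory")
  for (a in need) {
    rng <- range(SummarizedExperiment::assay(object, a))
    if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1)) {
      msg <- c(msg, "stimulus values must lie in [0, 1]")
      break
    }
  }
  vo <- cd$condition == "visual_only"
  ao <- cd$condition == "audio_only"
  if (any(ao) && any(xv[, ao, drop = FALSE] != 0))
    msg <- c(msg, "audio_only pairs must have an all-zero visual input")
  if (any(vo) && any(xa[, vo, drop = FALSE] != 0))
    msg <- c(msg, "visual_only pairs must have an all-zero auditory input")
  cons <- metadata(object)$consistency
  if (identical(cons, "consistent") && any(cd$labelVisual != cd$labelAudio))
    msg <- c(msg, "consistent sets require labelVisual == labelAudio")
  if (identical(cons, "inconsistent") && any(cd$labelVisual == cd$labelAudio))
    msg <- c(msg, "inconsistent sets require labelVisual != labelAudio")
  if (length(msg)) msg else TRUE
})

#' Unit responses to a stimulus set
#'
#' A `SummarizedExperiment` of hidden-unit activations: rows are units of
#' one encoding layer, columns are stimulus pairs. `colData` carries the
#' digit label and presentation condition of each pair.
#'
#' @export
setClass("ActivationMatrix", contains = "SummarizedExperiment")

setValidity("ActivationMatrix", function(object) {
  msg <- character()
  if (!"activations" %in% names(SummarizedExperiment::assays(object)))
    return("assay 'activations' is required")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("label", "condition"))
    if (!f %in% names(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if (length(msg)) return(msg)
  if (!all(is.finite(SummarizedExperiment::assay(object, "activations"))))
    msg <- c(msg, "activations must be finite")
  if (!all(cd$condition %in% .CONDITIONS))
    msg <- c(msg, "unknown presentation condition")
  if (length(msg)) msg else TRUE
})

#' Binned response counts for one unit
#'
#' A categories x bins count table for a single unit, with the bin edges
#' used. Conditional response probabilities P(r|s) are the row-normalised
#' counts; the marginal P(r) is the presentation-weighted column total.
#'
#' @slot unitId identifier of the unit.
#' @slot counts integer-valued matrix, categories x bins; rownames are the
#'   category labels.
#' @slot binEdges numeric vector of length bins + 1.
#' @export
setClass("BinnedResponseTable",
  representation(unitId = "character", counts = "matrix",
                 binEdges = "numeric"))

setValidity("BinnedResponseTable", function(object) {
  msg <- character()
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@binEdges) != ncol(object@counts) + 1L)
    msg <- c(msg, "binEdges must have one more entry than bins")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-unit, per-category stimulus-specific information
#'
#' Units x categories matrix of stimulus-specific single-cell information
#' in bits, with the binning and the condition subset it was computed on.
#'
#' @slot info numeric matrix, units x categories, in bits.
#' @slot nBins number of response bins used.
#' @slot condition condition subset the activations were restricted to
#'   (`"all"`, `"visual_only"` or `"audio_only"`).
#' @export
setClass("InfoTable",
  representation(info = "matrix", nBins = "integer", condition = "character"))

setValidity("InfoTable", function(object) {
  msg <- character()
  if (!all(is.finite(object@info)))
    msg <- c(msg, "information values must be finite")
  else if (any(object@info < -1e-12))
    msg <- c(msg, "information values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Selectivity typology of a layer's units
#'
#' Assignment of each unit to one of the five selectivity categories
#' (visual, auditory, inconsistent, consistent, non_selective) together
#' with its selective digit sets per modality and the thresholds used.
#'
#' @slot typology `DataFrame` with columns `unit`, `type`, `visualDigits`
#'   (`IntegerList`) and `auditoryDigits` (`IntegerList`).
#' @slot thresholds named numeric, `c(visual=, auditory=)`, in bits.
#' @export
setClass("UnitTypology",
  representation(typology = "DataFrame", thresholds = "numeric"))

setValidity("UnitTypology", function(object) {
  msg <- character()
  for (f in c("unit", "type", "visualDigits", "auditoryDigits"))
    if (!f %in% names(object@typology))
      msg <- c(msg, sprintf("typology lacks '%s'", f))
  if (!length(msg) && !all(object@typology$type %in% .CELL_TYPES))
    msg <- c(msg, "unknown cell type")
  if (!identical(sort(names(object@thresholds)), c("auditory", "visual")))
    msg <- c(msg, "thresholds must be named 'visual' and 'auditory'")
  if (length(msg)) msg else TRUE
})

#' Architecture of a bimodal autoencoder
#'
#' The mixed-input framework concatenates the two modalities at the input
#' and encodes them through `encoderDepth` (1-4) dense sigmoid layers of
#' `width` units. The two-stage framework encodes each modality separately
#' through 3 sigmoid layers of `width` units and merges them at a fourth,
#' modality-combined layer. Both decode through two parallel 3-layer paths,
#' one per modality, ending at that modality's input dimension.
#'
#' @slot framework `"mixed"` or `"two_stage"`.
#' @slot encoderDepth encoding layers (mixed: 1-4; two_stage: fixed 4 =
#'   3 per-modality + 1 merged).
#' @slot width hidden units per layer (64).
#' @slot inputDims integer (visual, auditory) input dimensions.
#' @slot decoderDepth layers per decoder path (3).
#' @export
setClass("NetworkSpec",
  representation(framework = "character", encoderDepth = "integer",
                 width = "integer", inputDims = "integer",
                 decoderDepth = "integer"))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (!object@framework %in% c("mixed", "two_stage"))
    msg <- c(msg, "'framework' must be 'mixed' or 'two_stage'")
  if (identical(object@framework, "mixed") &&
      !(object@encoderDepth %in% 1:4))
    msg <- c(msg, "mixed encoderDepth must be in 1..4")
  if (identical(object@framework, "two_stage") && object@encoderDepth != 4L)
    msg <- c(msg, "two_stage networks have 4 encoding stages (3 + 1 merged)")
  if (object@width < 1L) msg <- c(msg, "'width' must be positive")
  if (length(object@inputDims) != 2L || any(object@inputDims < 1L))
    msg <- c(msg, "'inputDims' must be two positive dimensions")
  if (object@decoderDepth < 1L) msg <- c(msg, "'decoderDepth' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) bimodal autoencoder
#'
#' Weights of the network plus its per-epoch training log. The log records
#' the binary cross-entropy loss optimised during training and, for
#' monitoring, the summed squared reconstruction error over the two
#' modality branches.
#'
#' @slot spec the [NetworkSpec-class].
#' @slot weights named list of layer parameter lists (`W`, `b`).
#' @slot trainingLog data.frame with columns `epoch`, `bce`, `mse`.
#' @slot seed integer seed the weights were initialised (and trained) with.
#' @slot epochsTrained total epochs of training applied so far.
#' @export
setClass("TrainedModel",
  representation(spec = "NetworkSpec", weights = "list",
                 trainingLog = "data.frame", seed = "integer",
                 epochsTrained = "integer"))

setValidity("TrainedModel", function(object) {
  if (nrow(object@trainingLog) &&
      !all(is.finite(object@trainingLog$bce)))
    "training log contains a non-finite loss" else TRUE
})

#' Result of frozen-encoder supervised head training
#'
#' The trained classification head (two 64-unit rectified-linear layers
#' with 20% dropout and a 10-way softmax), the modality it was trained on,
#' and its per-epoch training accuracy. The encoder is frozen throughout.
#'
#' @slot head list of head layer weights.
#' @slot trainModality condition the head was trained on
#'   (`"visual_only"` or `"audio_only"`).
#' @slot history data.frame with columns `epoch`, `accuracy` (training
#'   categorical accuracy per epoch).
#' @slot nClasses number of output classes.
#' @slot seed head training seed.
#' @export
setClass("TransferResult",
  representation(head = "list", trainModality = "character",
                 history = "data.frame", nClasses = "integer",
                 seed = "integer"))
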