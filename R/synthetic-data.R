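#' Create a generator configuration
#'
#' The defaults mirror the sampling design of the study the package
#' implements: 10 digit classes, 500 visual training and 50 visual test
#' variations per class, an auditory pool of 100 variations per class
#' (drawn from 2 sub-prototype "speakers") halved into 50 train and 50
#' test, and additive Gaussian pixel noise clipped to [0, 1].
#'
#' @param nClasses number of digit categories.
#' @param visualTrain visual training variations per class.
#' @param visualTest visual test variations per class.
#' @param audioPerClass auditory variations per class in each half of the
#'   pool (the raw pool holds `2 * audioPerClass` per class before the
#'   train/test split).
#' @param nSources auditory sub-prototypes ("speakers") per class.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param protoSep separation of the class pattern component; larger gives
#'   more distinct prototypes.
#' @param seed master seed.
#' @return a [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(visualTrain = 20, audioPerClass = 10, seed = 1)
#' @export
generatorConfig <- function(nClasses = 10L, visualTrain = 500L,
                            visualTest = 50L, audioPerClass = 50L,
                            nSources = 2L, noiseSd = 0.3,
                            protoSep = 1.2, seed = 1L) {
  new("GeneratorConfig",
      nClasses = .assertCount(nClasses, "nClasses"),
      visualTrain = .assertCount(visualTrain, "visualTrain"),
      visualTest = .assertCount(visualTest, "visualTest"),
      audioPerClass = .assertCount(audioPerClass, "audioPerClass"),
      nSources = .assertCount(nSources, "nSources"),
      noiseSd = noiseSd, protoSep = protoSep, seed = as.integer(seed))
}

# Class (and, for auditory, speaker) prototypes: smoothed standard-normal
# random fields pushed through a logistic squashing whose gain is the
# prototype-separation knob. Deterministic given (seed, modality).
.classPrototypes <- function(config, modality) {
  shape <- if (identical(modality, "visual")) .VISUAL_GRID else .AUDITORY_GRID
  nSrc <- if (identical(modality, "visual")) 1L else config@nSources
  .withSeed(.deriveSeed(config@seed, match(modality, .MODALITIES), 101L), {
    protos <- vector("list", config@nClasses)
    for (cls in seq_len(config@nClasses)) {
      classField <- .smoothField(matrix(stats::rnorm(prod(shape)), shape[1L]))
      classField <- classField / stats::sd(classField)
      protos[[cls]] <- lapply(seq_len(nSrc), function(src) {
        srcField <- .smoothField(matrix(stats::rnorm(prod(shape)), shape[1L]))
        srcField <- srcField / stats::sd(srcField)
        # sub-prototypes share the class field, perturbed by a weaker
        # source-specific component (the two "speakers" of one digit)
        .sigmoid(config@protoSep * (classField + 0.5 * srcField))
      })
    }
    protos
  })
}

#' Generate a single-modality sample pool
#'
#' Draws per-class samples as the class (sub-)prototype plus additive
#' Gaussian noise, clipped to [0, 1]. Visual pools use one prototype per
#' class; auditory pools cycle over `nSources` sub-prototypes per class.
#' Bit-identical output for identical seeds; with `noiseSd = 0` every
#' sample equals its prototype.
#'
#' @param config a [GeneratorConfig-class].
#' @param modality `"visual"` or `"auditory"`.
#' @param perClass samples per class; defaults to `visualTrain` for visual
#'   pools and `2 * audioPerClass` (the raw pool before splitting) for
#'   auditory pools.
#' @param seed overrides the config seed when given.
#' @return a [ModalityPool-class].
#' @examples
#' pool <- generatePool(generatorConfig(seed = 7), "visual", perClass = 5)
#' dim(poolSamples(pool))
#' @export
generatePool <- function(config, modality = c("visual", "auditory"),
                         perClass = NULL, seed = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  modality <- match.arg(modality)
  validObject(config)
  if (is.null(perClass))
    perClass <- if (identical(modality, "visual")) config@visualTrain
                else 2L * config@audioPerClass
  perClass <- .assertCount(perClass, "perClass")
  if (is.null(seed)) seed <- config@seed
  shape <- if (identical(modality, "visual")) .VISUAL_GRID else .AUDITORY_GRID
  protos <- .classPrototypes(config, modality)
  n <- config@nClasses * perClass
  npix <- prod(shape)
  labels <- rep(0:(config@nClasses - 1L), each = perClass)
  nSrc <- length(protos[[1L]])
  sourceId <- rep(rep_len(seq_len(nSrc), perClass), config@nClasses)
  samples <- matrix(0, n, npix)
  .withSeed(.deriveSeed(seed, match(modality, .MODALITIES), 202L), {
    for (i in seq_len(n)) {
      proto <- protos[[labels[i] + 1L]][[sourceId[i]]]
      x <- as.vector(t(proto))  # row-major flattening
      if (config@noiseSd > 0)
        x <- .clip01(x + stats::rnorm(npix, sd = config@noiseSd))
      samples[i, ] <- x
    }
  })
  new("ModalityPool", modality = modality, samples = samples,
      labels = labels, sourceId = sourceId, gridShape = shape,
      nClasses = config@nClasses, seed = as.integer(seed))
}

#' Split a pool into train and test halves per class
#'
#' Seeded random split of each class's samples into two halves, used to
#' divide the raw auditory pool into training and test stimuli.
#'
#' @param pool a [ModalityPool-class].
#' @param seed split seed.
#' @return list with elements `train` and `test`, both [ModalityPool-class].
#' @export
splitPool <- function(pool, seed) {
  stopifnot(is(pool, "ModalityPool"))
  idxTrain <- integer(0)
  .withSeed(.deriveSeed(seed, 303L), {
    for (cls in 0:(pool@nClasses - 1L)) {
      i <- which(pool@labels == cls)
      idxTrain <- c(idxTrain, sort(sample(i, length(i) %/% 2L)))
    }
  })
  take <- function(idx) new("ModalityPool", modality = pool@modality,
    samples = pool@samples[idx, , drop = FALSE],
    labels = pool@labels[idx], sourceId = pool@sourceId[idx],
    gridShape = pool@gridShape, nClasses = pool@nClasses, seed = pool@seed)
  list(train = take(idxTrain),
       test = take(setdiff(seq_len(nrow(pool@samples)), idxTrain)))
}

#' @describeIn ModalityPool-class the samples x pixels matrix.
#' @export
setMethod("poolSamples", "ModalityPool", function(x) x@samples)

#' @describeIn ModalityPool-class the per-sample digit labels.
#' @export
setMethod("poolLabels", "ModalityPool", function(x) x@labels)

#' @describeIn ModalityPool-class the pool's modality.
#' @export
setMethod("poolModality", "ModalityPool", function(x) x@modality)

setMethod("show", "ModalityPool", function(object) {
  cat(sprintf("ModalityPool: %s, %d samples (%d x %d grid), %d classes\n",
              object@modality, nrow(object@samples), object@gridShape[1L],
              object@gridShape[2L], object@nClasses))
})

#' Construct planted per-unit response distributions
#'
#' Builds an oracle fixture in which each unit's bin-response distribution
#' per (digit, modality) is known exactly, so the stimulus-specific
#' information of every unit is available in closed form. By default a
#' unit responds in the top bin for its planted digits and in the bottom
#' bin otherwise (maximally selective); pass `onDist`/`offDist` for graded
#' plants, or `distributions` for fully custom per-unit matrices.
#'
#' @param visualDigits,auditoryDigits lists (one entry per unit) of integer
#'   digit vectors the unit is selective for in that modality; `integer(0)`
#'   for none.
#' @param nClasses,nBins design of the distributions.
#' @param onDist,offDist probability vectors of length `nBins` used for
#'   planted resp. unplanted digits.
#' @param distributions optional list (per unit) of
#'   `list(visual=, auditory=)` classes x bins matrices overriding the
#'   on/off construction.
#' @return a [PlantedActivationSpec-class].
#' @examples
#' spec <- plantedActivationSpec(list(0L, integer(0)), list(0L, 3L))
#' plantedInformation(spec, "visual")[, 1]
#' @export
plantedActivationSpec <- function(visualDigits, auditoryDigits,
                                  nClasses = 10L, nBins = 10L,
                                  onDist = NULL, offDist = NULL,
                                  distributions = NULL) {
  nClasses <- .assertCount(nClasses, "nClasses")
  nBins <- .assertCount(nBins, "nBins")
  stopifnot(length(visualDigits) == length(auditoryDigits))
  nUnits <- length(visualDigits)
  if (is.null(onDist)) onDist <- c(rep(0, nBins - 1L), 1)
  if (is.null(offDist)) offDist <- c(1, rep(0, nBins - 1L))
  .checkDist <- function(p, what) {
    if (length(p) != nBins || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("'%s' must be a probability vector over %d bins",
                   what, nBins), call. = FALSE)
  }
  .checkDist(onDist, "onDist"); .checkDist(offDist, "offDist")
  if (is.null(distributions)) {
    distributions <- lapply(seq_len(nUnits), function(u) {
      one <- function(digits) {
        m <- matrix(rep(offDist, each = nClasses), nClasses, nBins)
        if (length(digits))
          m[digits + 1L, ] <- matrix(rep(onDist, each = length(digits)),
                                     length(digits), nBins)
        m
      }
      list(visual = one(visualDigits[[u]]),
           auditory = one(auditoryDigits[[u]]))
    })
  }
  new("PlantedActivationSpec", nClasses = nClasses, nBins = nBins,
      visualDigits = IntegerList(lapply(visualDigits, as.integer)),
      auditoryDigits = IntegerList(lapply(auditoryDigits, as.integer)),
      distributions = distributions)
}

#' Closed-form information of planted units
#'
#' Evaluates the stimulus-specific information of each planted unit
#' directly from its exact bin distributions under equal class priors:
#' for each digit s, the Kullback-Leibler divergence (base 2) between the
#' unit's planted P(r|s) and the prior-weighted marginal P(r).
#'
#' @param spec a [PlantedActivationSpec-class].
#' @param modality `"visual"` or `"auditory"`.
#' @return units x classes matrix in bits.
#' @export
plantedInformation <- function(spec, modality = c("visual", "auditory")) {
  stopifnot(is(spec, "PlantedActivationSpec"))
  modality <- match.arg(modality)
  nU <- length(spec@distributions)
  info <- matrix(0, nU, spec@nClasses,
                 dimnames = list(sprintf("unit%03d", seq_len(nU)),
                                 as.character(0:(spec@nClasses - 1L))))
  for (u in seq_len(nU)) {
    d <- spec@distributions[[u]][[modality]]
    pr <- colMeans(d)  # equal priors
    for (s in seq_len(spec@nClasses)) {
      prs <- d[s, ]
      ok <- prs > 0
      info[u, s] <- sum(prs[ok] * log2(prs[ok] / pr[ok]))
    }
  }
  info
}

#' Sample an activation matrix from planted distributions
#'
#' For every unit, modality condition and digit, draws `nPerClass` bin
#' indices from the planted distribution and maps them to bin-centre
#' activation values. The resulting [ActivationMatrix-class] carries
#' `visual_only` and `audio_only` condition tags so the information
#' analysis and the unit classifier can be run against it, with
#' [plantedInformation()] as the exact expected value at large
#' `nPerClass`.
#'
#' @param spec a [PlantedActivationSpec-class].
#' @param nPerClass presentations per (digit, modality condition).
#' @param seed sampling seed.
#' @return an [ActivationMatrix-class] of `units x (2 * nClasses *
#'   nPerClass)` activations.
#' @export
plantActivations <- function(spec, nPerClass, seed = 1L) {
  stopifnot(is(spec, "PlantedActivationSpec"))
  validObject(spec)
  nPerClass <- .assertCount(nPerClass, "nPerClass")
  nU <- length(spec@distributions)
  nPerCond <- spec@nClasses * nPerClass
  centers <- (seq_len(spec@nBins) - 0.5) / spec@nBins
  act <- matrix(0, nU, 2L * nPerCond)
  labels <- rep(rep(0:(spec@nClasses - 1L), each = nPerClass), 2L)
  condition <- rep(c("visual_only", "audio_only"), each = nPerCond)
  .withSeed(.deriveSeed(seed, 404L), {
    for (u in seq_len(nU)) {
      col <- 0L
      for (m in .MODALITIES) {
        d <- spec@distributions[[u]][[if (m == "visual") "visual" else
                                      "auditory"]]
        for (s in seq_len(spec@nClasses)) {
          bins <- sample.int(spec@nBins, nPerClass, replace = TRUE,
                             prob = d[s, ])
          act[u, col + seq_len(nPerClass)] <- centers[bins]
          col <- col + nPerClass
        }
      }
    }
  })
  rownames(act) <- sprintf("unit%03d", seq_len(nU))
  activationMatrix(act, labels, condition)
}
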