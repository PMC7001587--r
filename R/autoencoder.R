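# Dense bimodal autoencoders in two frameworks (mixed-input and two-stage),
# trained by backpropagation with AdaDelta and binary cross-entropy, in
# plain BLAS-backed matrix algebra. Samples are rows throughout.

#' Construct a network specification
#'
#' @param framework `"mixed"` (modality-concatenated input, 1-4 encoding
#'   layers) or `"two_stage"` (3 per-modality encoding layers followed by
#'   one modality-combined layer).
#' @param encoderDepth encoding layers for the mixed framework (1-4);
#'   fixed at 4 stages for `two_stage`.
#' @param width hidden units per layer.
#' @param inputDims integer (visual, auditory) input dimensions.
#' @return a [NetworkSpec-class].
#' @examples
#' networkSpec("mixed", encoderDepth = 4)
#' @export
networkSpec <- function(framework = c("mixed", "two_stage"),
                        encoderDepth = 4L, width = 64L,
                        inputDims = c(784L, 784L)) {
  framework <- match.arg(framework)
  if (identical(framework, "two_stage")) encoderDepth <- 4L
  new("NetworkSpec", framework = framework,
      encoderDepth = as.integer(encoderDepth), width = as.integer(width),
      inputDims = as.integer(inputDims), decoderDepth = 3L)
}

# --- layer primitives -------------------------------------------------------

.initLayer <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))  # Glorot uniform
  list(W = matrix(stats::runif(din * dout, -lim, lim), din, dout),
       b = numeric(dout))
}

.initStack <- function(dims) {
  lapply(seq_len(length(dims) - 1L),
         function(i) .initLayer(dims[i], dims[i + 1L]))
}

.addBias <- function(z, b) z + rep(b, each = nrow(z))

# Forward through a stack of sigmoid layers; returns activations per layer
# (input first) for backprop.
.forwardStack <- function(stack, x) {
  acts <- vector("list", length(stack) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(stack)) {
    acts[[i + 1L]] <- .sigmoid(.addBias(acts[[i]] %*% stack[[i]]$W,
                                        stack[[i]]$b))
  }
  acts
}

# Backward through a sigmoid stack. `dTop` is dL/dZ at the top layer when
# `topIsdZ` (sigmoid + cross-entropy outputs), else dL/dA.
.backwardStack <- function(stack, acts, dTop, topIsdZ = FALSE) {
  grads <- vector("list", length(stack))
  dA <- NULL
  for (i in rev(seq_along(stack))) {
    if (i == length(stack) && topIsdZ) {
      dZ <- dTop
    } else {
      a <- acts[[i + 1L]]
      dZ <- if (is.null(dA)) dTop * a * (1 - a) else dA * (a * (1 - a))
    }
    grads[[i]] <- list(W = crossprod(acts[[i]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, stack[[i]]$W)
  }
  list(grads = grads, dInput = dA)
}

.adadeltaInit <- function(stacks) {
  rapply(stacks, function(p) list(Eg = p * 0, Ed = p * 0),
         how = "replace", classes = c("matrix", "numeric"))
}

# One AdaDelta update of a parameter given its gradient and state.
.adadeltaStep <- function(p, g, st, rho = 0.95, eps = 1e-6) {
  st$Eg <- rho * st$Eg + (1 - rho) * g^2
  dx <- -sqrt((st$Ed + eps) / (st$Eg + eps)) * g
  st$Ed <- rho * st$Ed + (1 - rho) * dx^2
  list(p = p + dx, st = st)
}

.applyGrads <- function(stack, grads, state, rho, eps) {
  for (i in seq_along(stack)) {
    for (nm in c("W", "b")) {
      u <- .adadeltaStep(stack[[i]][[nm]], grads[[i]][[nm]],
                         state[[i]][[nm]], rho, eps)
      stack[[i]][[nm]] <- u$p
      state[[i]][[nm]] <- u$st
    }
  }
  list(stack = stack, state = state)
}

# --- model construction -----------------------------------------------------

#' Build an untrained bimodal autoencoder
#'
#' Initialises all weights with seeded fan-based (Glorot) uniform draws.
#' Two builds with the same spec and seed have identical weights.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed weight-initialisation (and later training) seed.
#' @return an untrained [TrainedModel-class].
#' @examples
#' m <- buildModel(networkSpec("mixed", 2), seed = 1)
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  w <- spec@width
  dv <- spec@inputDims[1L]; da <- spec@inputDims[2L]
  weights <- .withSeed(.deriveSeed(seed, 700L), {
    if (identical(spec@framework, "mixed")) {
      list(encoder = .initStack(c(dv + da, rep(w, spec@encoderDepth))),
           decoderVisual = .initStack(c(rep(w, spec@decoderDepth), dv)),
           decoderAuditory = .initStack(c(rep(w, spec@decoderDepth), da)))
    } else {
      list(encoderVisual = .initStack(c(dv, rep(w, 3L))),
           encoderAuditory = .initStack(c(da, rep(w, 3L))),
           merge = .initStack(c(2L * w, w)),
           decoderVisual = .initStack(c(rep(w, spec@decoderDepth), dv)),
           decoderAuditory = .initStack(c(rep(w, spec@decoderDepth), da)))
    }
  })
  new("TrainedModel", spec = spec, weights = weights,
      trainingLog = data.frame(epoch = integer(), bce = numeric(),
                               mse = numeric()),
      seed = as.integer(seed), epochsTrained = 0L)
}

# Full forward pass; returns the encoder code and both reconstructions,
# plus all cached activations for backprop. `xMix` may carry the
# precomputed concatenated input for the mixed framework.
.forwardModel <- function(weights, spec, xv, xa, xMix = NULL) {
  if (identical(spec@framework, "mixed")) {
    enc <- .forwardStack(weights$encoder,
                         if (is.null(xMix)) cbind(xv, xa) else xMix)
    code <- enc[[length(enc)]]
    list(enc = enc, code = code,
         decV = .forwardStack(weights$decoderVisual, code),
         decA = .forwardStack(weights$decoderAuditory, code))
  } else {
    encV <- .forwardStack(weights$encoderVisual, xv)
    encA <- .forwardStack(weights$encoderAuditory, xa)
    mrg <- .forwardStack(weights$merge,
                         cbind(encV[[length(encV)]], encA[[length(encA)]]))
    code <- mrg[[length(mrg)]]
    list(encV = encV, encA = encA, mrg = mrg, code = code,
         decV = .forwardStack(weights$decoderVisual, code),
         decA = .forwardStack(weights$decoderAuditory, code))
  }
}

# Binary cross-entropy summed over output dimensions (the structure of the
# reconstruction objective), averaged over the batch.
.bce <- function(y, t) {
  -sum(t * log(y + 1e-12) + (1 - t) * log(1 - y + 1e-12)) / nrow(y)
}

#' Train a bimodal autoencoder
#'
#' Backpropagation with AdaDelta (rho = 0.95, eps = 1e-6, no learning-rate
#' scaling) on the binary cross-entropy of both modality reconstructions
#' against the pre-dropout target arrays, averaged over samples and output
#' dimensions and summed over the two branches. The squared reconstruction
#' error (summed over both branches, averaged over samples) is logged per
#' epoch alongside the optimised loss. Sample order is reshuffled every
#' epoch under a seed derived from the model seed, so training is fully
#' deterministic.
#'
#' @param model a [TrainedModel-class] (untrained or previously trained).
#' @param data a train-role [StimulusSet-class].
#' @param epochs training epochs; `0` returns the model unchanged.
#' @param batchSize minibatch size; batches of at most this many samples.
#' @return the trained [TrainedModel-class] with an extended training log.
#' @export
trainModel <- function(model, data, epochs, batchSize = 128L) {
  stopifnot(is(model, "TrainedModel"), is(data, "StimulusSet"))
  epochs <- as.integer(epochs)
  stopifnot(length(epochs) == 1L, !is.na(epochs), epochs >= 0L)
  if (epochs == 0L) return(model)
  spec <- model@spec
  xv <- t(visualInputs(data)); xa <- t(auditoryInputs(data))
  tv <- t(visualTargets(data)); ta <- t(auditoryTargets(data))
  if (ncol(xv) != spec@inputDims[1L] || ncol(xa) != spec@inputDims[2L])
    stop("stimulus dimensions do not match the network spec", call. = FALSE)
  n <- nrow(xv)
  # epoch-wise shuffles drawn from the model's seeded substream, then the
  # numerical inner loop runs in compiled code
  perms <- .withSeed(.deriveSeed(model@seed, 710L, model@epochsTrained), {
    vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
  })
  fit <- .cppTrainBimodal(model@weights, spec@framework, xv, xa, tv, ta,
                          perms, as.integer(batchSize),
                          model@epochsTrained, 0.95, 1e-6)
  log <- rbind(model@trainingLog,
               data.frame(epoch = model@epochsTrained + seq_len(epochs),
                          bce = as.vector(fit$bce),
                          mse = as.vector(fit$mse)))
  initialize(model, weights = fit$weights, trainingLog = log,
             epochsTrained = model@epochsTrained + epochs)
}

#' Hidden-layer responses to a stimulus set
#'
#' Propagates every pair of a stimulus set through the encoder and returns
#' the activations of one encoding layer. For the mixed framework,
#' `layerIndex` selects among the 1-4 modality-combined layers. For the
#' two-stage framework, layers 1-3 return the two per-modality layers
#' side by side (2 x width units) and layer 4 the modality-combined
#' layer. Untrained models are allowed (pre-training baselines). Each
#' sample is tagged with its digit label (the visual label except for
#' `audio_only` pairs) and its presentation condition.
#'
#' @param model a [TrainedModel-class].
#' @param data a [StimulusSet-class].
#' @param layerIndex encoding layer, `1:encoderDepth`.
#' @return an [ActivationMatrix-class], units x pairs.
#' @export
encodeLayer <- function(model, data, layerIndex) {
  stopifnot(is(model, "TrainedModel"), is(data, "StimulusSet"))
  spec <- model@spec
  layerIndex <- as.integer(layerIndex)
  if (length(layerIndex) != 1L || is.na(layerIndex) || layerIndex < 1L ||
      layerIndex > spec@encoderDepth)
    stop(sprintf("'layerIndex' must be in 1..%d", spec@encoderDepth),
         call. = FALSE)
  xv <- t(visualInputs(data)); xa <- t(auditoryInputs(data))
  act <- if (identical(spec@framework, "mixed")) {
    enc <- .forwardStack(model@weights$encoder[seq_len(layerIndex)],
                         cbind(xv, xa))
    t(enc[[layerIndex + 1L]])
  } else if (layerIndex <= 3L) {
    ev <- .forwardStack(model@weights$encoderVisual[seq_len(layerIndex)], xv)
    ea <- .forwardStack(model@weights$encoderAuditory[seq_len(layerIndex)],
                        xa)
    t(cbind(ev[[layerIndex + 1L]], ea[[layerIndex + 1L]]))
  } else {
    fw <- .forwardModel(model@weights, spec, xv, xa)
    t(fw$code)
  }
  cond <- pairConditions(data)
  labels <- ifelse(cond == "audio_only", auditoryLabels(data),
                   visualLabels(data))
  activationMatrix(act, labels, cond, layerIndex)
}

#' Reconstruct both modalities
#'
#' @param model a [TrainedModel-class].
#' @param data a [StimulusSet-class].
#' @return list with `visual` and `auditory` reconstruction matrices
#'   (pixels x pairs), values in (0, 1).
#' @export
reconstruct <- function(model, data) {
  stopifnot(is(model, "TrainedModel"), is(data, "StimulusSet"))
  fw <- .forwardModel(model@weights, model@spec,
                      t(visualInputs(data)), t(auditoryInputs(data)))
  list(visual = t(fw$decV[[length(fw$decV)]]),
       auditory = t(fw$decA[[length(fw$decA)]]))
}

#' Index of the final (modality-combined) encoding layer
#'
#' @param spec a [NetworkSpec-class].
#' @return the layer index whose activations feed the supervised head.
#' @export
finalLayerIndex <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  spec@encoderDepth
}

#' @describeIn TrainedModel-class the architecture of the model.
#' @export
setMethod("modelSpec", "TrainedModel", function(x) x@spec)

#' @describeIn TrainedModel-class per-epoch loss log (`epoch`, `bce`,
#'   `mse`).
#' @export
setMethod("trainingLog", "TrainedModel", function(x) x@trainingLog)

setMethod("show", "TrainedModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "TrainedModel: %s framework, %d encoding layer(s) x %d units, %d epoch(s) trained\n",
    s@framework, s@encoderDepth, s@width, object@epochsTrained))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf(
    "NetworkSpec: %s, encoderDepth=%d, width=%d, inputDims=(%d, %d)\n",
    object@framework, object@encoderDepth, object@width,
    object@inputDims[1L], object@inputDims[2L]))
})
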