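# Shared-representation learning: a supervised classification head (two
# rectified-linear layers with dropout and a softmax output) trained on the
# frozen final encoding layer using one modality's examples, then evaluated
# on the other modality, on which it was never trained.

.relu <- function(x) pmax(x, 0)

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.initHead <- function(dIn, width, nClasses) {
  # He-uniform for the rectified-linear layers, Glorot for the softmax
  heLim <- function(fi) sqrt(6 / fi)
  list(
    list(W = matrix(stats::runif(dIn * width, -heLim(dIn), heLim(dIn)),
                    dIn, width), b = numeric(width)),
    list(W = matrix(stats::runif(width * width, -heLim(width), heLim(width)),
                    width, width), b = numeric(width)),
    .initLayer(width, nClasses))
}

# Forward pass of the head; dropout masks (inverted dropout) only during
# training.
.forwardHead <- function(head, x, dropout = 0, train = FALSE) {
  acts <- list(x)
  masks <- list(NULL, NULL)
  for (i in 1:2) {
    z <- sweep(acts[[i]] %*% head[[i]]$W, 2L, head[[i]]$b, "+")
    a <- .relu(z)
    if (train && dropout > 0) {
      m <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                  nrow(a), ncol(a))
      a <- a * m
      masks[[i]] <- m
    }
    acts[[i + 1L]] <- a
  }
  z <- sweep(acts[[3L]] %*% head[[3L]]$W, 2L, head[[3L]]$b, "+")
  list(acts = acts, probs = .softmax(z), masks = masks)
}

.headAccuracy <- function(probs, labels) {
  mean(max.col(probs, ties.method = "first") - 1L == labels)
}

#' Train a supervised head on the frozen final encoding layer
#'
#' Encodes the requested single-modality subset of a training stimulus set
#' with the (immutable) autoencoder, then trains a classification head —
#' two 64-unit rectified-linear layers with 20% dropout and a 10-way
#' softmax — on the digit labels with AdaDelta and categorical
#' cross-entropy. The autoencoder weights are never touched.
#'
#' @param model a [TrainedModel-class]; its weights stay frozen.
#' @param data a train-role [StimulusSet-class] containing the head's
#'   training condition (typically an augmented training set).
#' @param trainModality `"visual_only"` or `"audio_only"` — the only
#'   condition the head sees during training.
#' @param epochs head training epochs; `0` returns the untrained head.
#' @param width head hidden width.
#' @param dropout dropout fraction in the two hidden layers.
#' @param batchSize minibatch size.
#' @param seed head initialisation/training seed.
#' @param labels optional label override (e.g. a shuffled-label null);
#'   defaults to the subset's digit labels.
#' @return a [TransferResult-class].
#' @export
trainHead <- function(model, data, trainModality = c("visual_only",
                      "audio_only"), epochs = 100L, width = 64L,
                      dropout = 0.2, batchSize = 128L, seed = 1L,
                      labels = NULL) {
  stopifnot(is(model, "TrainedModel"), is(data, "StimulusSet"))
  trainModality <- match.arg(trainModality)
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 0L)
  keep <- pairConditions(data) == trainModality
  if (!any(keep))
    stop(sprintf("no '%s' pairs in the training set", trainModality),
         call. = FALSE)
  code <- encodeLayer(model, data[, keep], finalLayerIndex(model@spec))
  x <- responses(code)                       # samples x units
  if (is.null(labels)) labels <- sampleLabels(code)
  nClasses <- length(unique(labels))
  nClasses <- max(nClasses, max(labels) + 1L)
  n <- nrow(x)
  hist <- data.frame(epoch = integer(), accuracy = numeric())
  head <- .withSeed(.deriveSeed(seed, 810L),
                    .initHead(ncol(x), as.integer(width), nClasses))
  if (epochs > 0L) {
    state <- .adadeltaInit(head)
    rho <- 0.95; eps <- 1e-6
    tOne <- diag(nClasses)[labels + 1L, , drop = FALSE]
    .withSeed(.deriveSeed(seed, 820L), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        correct <- 0
        for (s in seq(1L, n, by = batchSize)) {
          idx <- ord[s:min(s + batchSize - 1L, n)]
          nb <- length(idx)
          fw <- .forwardHead(head, x[idx, , drop = FALSE], dropout,
                             train = TRUE)
          correct <- correct + sum(
            max.col(fw$probs, ties.method = "first") - 1L == labels[idx])
          # softmax + cross-entropy: dL/dZ = (p - t) / n
          dZ <- (fw$probs - tOne[idx, , drop = FALSE]) / nb
          grads <- vector("list", 3L)
          grads[[3L]] <- list(W = crossprod(fw$acts[[3L]], dZ),
                              b = colSums(dZ))
          dA <- tcrossprod(dZ, head[[3L]]$W)
          for (i in 2:1) {
            a <- fw$acts[[i + 1L]]
            dZi <- dA * (a > 0)
            if (!is.null(fw$masks[[i]])) dZi <- dZi * fw$masks[[i]]
            grads[[i]] <- list(W = crossprod(fw$acts[[i]], dZi),
                               b = colSums(dZi))
            dA <- tcrossprod(dZi, head[[i]]$W)
          }
          u <- .applyGrads(head, grads, state, rho, eps)
          head <- u$stack
          state <- u$state
        }
        hist <- rbind(hist, data.frame(epoch = ep, accuracy = correct / n))
      }
    })
  }
  new("TransferResult", head = head, trainModality = trainModality,
      history = hist, nClasses = as.integer(nClasses),
      seed = as.integer(seed))
}

#' Cross-modal transfer accuracy of a trained head
#'
#' Evaluates the head's top-1 categorical accuracy separately on the
#' visual-only and audio-only subsets of a test set. The subset matching
#' the head's training modality gives the same-modality accuracy; the
#' other subset gives the cross-modal transfer accuracy, the test of
#' whether the frozen code is modality-invariant.
#'
#' @param model the frozen [TrainedModel-class] used during head training.
#' @param result a [TransferResult-class] from [trainHead()].
#' @param test a test-role [StimulusSet-class].
#' @return data.frame with columns `subset`, `accuracy` and `transfer`
#'   (`"same"` or `"cross"`).
#' @export
evaluateCrossModal <- function(model, result, test) {
  stopifnot(is(model, "TrainedModel"), is(result, "TransferResult"),
            is(test, "StimulusSet"))
  out <- lapply(c("visual_only", "audio_only"), function(cond) {
    keep <- pairConditions(test) == cond
    if (!any(keep)) return(NULL)
    code <- encodeLayer(model, test[, keep], finalLayerIndex(model@spec))
    fw <- .forwardHead(result@head, responses(code))
    data.frame(subset = cond,
               accuracy = .headAccuracy(fw$probs, sampleLabels(code)),
               transfer = if (cond == result@trainModality) "same"
                          else "cross")
  })
  do.call(rbind, out)
}

setMethod("show", "TransferResult", function(object) {
  cat(sprintf(
    "TransferResult: head trained on %s, %d epoch(s), final training accuracy %s\n",
    object@trainModality, nrow(object@history),
    if (nrow(object@history))
      sprintf("%.3f", object@history$accuracy[nrow(object@history)])
    else "NA"))
})
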