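# Assembly of training and test sets from modality pools: label-matched
# ("consistent") or label-mismatched ("inconsistent") pairing, one-third
# modality-dropout augmentation, and seeded replicate generation.

.checkPoolsMatch <- function(visual, audio) {
  stopifnot(is(visual, "ModalityPool"), is(audio, "ModalityPool"))
  if (!identical(visual@modality, "visual") ||
      !identical(audio@modality, "auditory"))
    stop("expected a visual and an auditory pool", call. = FALSE)
  if (!setequal(unique(visual@labels), unique(audio@labels)))
    stop("pools do not cover the same class set", call. = FALSE)
}

.pairFromIdx <- function(visual, audio, vIdx, aIdx, consistency, role, seed) {
  stimulusSet(
    visual = t(visual@samples[vIdx, , drop = FALSE]),
    auditory = t(audio@samples[aIdx, , drop = FALSE]),
    labelVisual = visual@labels[vIdx], labelAudio = audio@labels[aIdx],
    condition = "both", role = role, consistency = consistency, seed = seed,
    gridShapeVisual = visual@gridShape, gridShapeAuditory = audio@gridShape)
}

#' Pair pools with matching digit labels
#'
#' Every visual sample of digit d is paired with an auditory sample of the
#' same digit drawn uniformly (with replacement) from that digit's
#' auditory candidates. All pairs carry condition `"both"`; apply
#' [augmentModalityDropout()] afterwards for the single-modality thirds.
#'
#' @param visual,audio [ModalityPool-class] objects covering the same
#'   classes.
#' @param seed pairing seed (identical seeds give identical pairings).
#' @param role `"train"` or `"test"`.
#' @return a consistent [StimulusSet-class] with one pair per visual
#'   sample.
#' @export
pairConsistent <- function(visual, audio, seed = 1L, role = "train") {
  .checkPoolsMatch(visual, audio)
  vIdx <- seq_len(nrow(visual@samples))
  aIdx <- integer(length(vIdx))
  .withSeed(.deriveSeed(seed, 510L), {
    for (cls in unique(visual@labels)) {
      v <- which(visual@labels == cls)
      cand <- which(audio@labels == cls)
      aIdx[v] <- cand[sample.int(length(cand), length(v), replace = TRUE)]
    }
  })
  .pairFromIdx(visual, audio, vIdx, aIdx, "consistent", role, seed)
}

#' Pair pools with mismatching digit labels
#'
#' Control pairing: each visual sample of digit d is paired with an
#' auditory sample drawn uniformly from the classes other than d, so
#' `labelVisual != labelAudio` holds for every pair.
#'
#' @inheritParams pairConsistent
#' @return an inconsistent [StimulusSet-class].
#' @export
pairInconsistent <- function(visual, audio, seed = 1L, role = "train") {
  .checkPoolsMatch(visual, audio)
  if (length(unique(visual@labels)) < 2L)
    stop("inconsistent pairing needs at least 2 classes", call. = FALSE)
  vIdx <- seq_len(nrow(visual@samples))
  aIdx <- integer(length(vIdx))
  .withSeed(.deriveSeed(seed, 520L), {
    for (cls in unique(visual@labels)) {
      v <- which(visual@labels == cls)
      cand <- which(audio@labels != cls)
      aIdx[v] <- cand[sample.int(length(cand), length(v), replace = TRUE)]
    }
  })
  .pairFromIdx(visual, audio, vIdx, aIdx, "inconsistent", role, seed)
}

#' Triple a paired set with single-modality examples
#'
#' Returns the union of three copies of the input set: unchanged, with the
#' visual input zeroed (`audio_only`), and with the auditory input zeroed
#' (`visual_only`). Reconstruction targets always retain the original,
#' non-zeroed arrays, so the network must reconstruct both modalities from
#' one. A base of n pairs yields exactly 3n pairs in equal thirds.
#'
#' @param base a [StimulusSet-class] whose pairs are all condition
#'   `"both"`.
#' @return the augmented [StimulusSet-class].
#' @export
augmentModalityDropout <- function(base) {
  stopifnot(is(base, "StimulusSet"))
  if (!all(pairConditions(base) == "both"))
    stop("input is already augmented (non-'both' conditions present)",
         call. = FALSE)
  xv <- visualInputs(base); xa <- auditoryInputs(base)
  zv <- matrix(0, nrow(xv), ncol(xv)); za <- matrix(0, nrow(xa), ncol(xa))
  lv <- visualLabels(base); la <- auditoryLabels(base)
  md <- metadata(base)
  stimulusSet(
    visual = cbind(xv, xv, zv),
    auditory = cbind(xa, za, xa),
    visualTarget = cbind(xv, xv, xv),
    auditoryTarget = cbind(xa, xa, xa),
    labelVisual = rep(lv, 3L), labelAudio = rep(la, 3L),
    condition = rep(c("both", "visual_only", "audio_only"), each = ncol(xv)),
    role = md$role, consistency = md$consistency, seed = md$seed,
    gridShapeVisual = md$gridShapeVisual,
    gridShapeAuditory = md$gridShapeAuditory)
}

#' Build seeded replicate datasets
#'
#' For each replicate, generates fresh visual train/test pools and a raw
#' auditory pool (split per class into train and test halves) under a
#' replicate-specific seed, then assembles an augmented consistent
#' training set, an augmented inconsistent training set, and an augmented
#' test set in which each visual test sample of a digit is paired with one
#' auditory test sample of the same digit.
#'
#' @param nReplicates number of replicates.
#' @param config a [GeneratorConfig-class]; its seed is the master seed
#'   from which per-replicate seeds are derived.
#' @return list of length `nReplicates`; each element is a list with
#'   `trainConsistent`, `trainInconsistent`, `test` ([StimulusSet-class])
#'   and `seed`.
#' @export
makeReplicates <- function(nReplicates, config) {
  nReplicates <- .assertCount(nReplicates, "nReplicates")
  stopifnot(is(config, "GeneratorConfig"))
  lapply(seq_len(nReplicates), function(r) {
    rseed <- .deriveSeed(config@seed, 600L, r)
    visTrain <- generatePool(config, "visual", config@visualTrain,
                             seed = .deriveSeed(rseed, 1L))
    visTest <- generatePool(config, "visual", config@visualTest,
                            seed = .deriveSeed(rseed, 2L))
    audioRaw <- generatePool(config, "auditory", 2L * config@audioPerClass,
                             seed = .deriveSeed(rseed, 3L))
    audio <- splitPool(audioRaw, .deriveSeed(rseed, 4L))
    list(
      trainConsistent = augmentModalityDropout(
        pairConsistent(visTrain, audio$train, .deriveSeed(rseed, 5L))),
      trainInconsistent = augmentModalityDropout(
        pairInconsistent(visTrain, audio$train, .deriveSeed(rseed, 6L))),
      test = augmentModalityDropout(
        pairConsistent(visTest, audio$test, .deriveSeed(rseed, 7L),
                       role = "test")),
      seed = rseed)
  })
}
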