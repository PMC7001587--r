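# Orchestration of the two experiments (encoder-depth sweep and framework
# comparison) over seeded replicates, plus the standard statistical
# comparisons used to summarise them.

#' Experiment profiles
#'
#' A profile bundles the dataset design and training lengths of a run.
#' `fullProfile()` reproduces the reference conditions: 500 visual
#' training and 50 test variations per class, a 100-per-class auditory
#' pool halved into train/test, and 5,000 epochs of autoencoder training.
#' `deskProfile()` is the package's reduced configuration for interactive
#' use and continuous testing: 10 visual training and 25 test variations
#' per class, 10 auditory variations per class per half, 80 autoencoder
#' epochs (minibatches of 32) and 60 head epochs, with the same topology
#' (64-unit layers, 28 x 28 and 14 x 56 inputs) and the same analysis
#' settings (10 bins, 80th-percentile thresholds).
#'
#' @param seed master seed for the generator config.
#' @return a named list with elements `config` ([GeneratorConfig-class]),
#'   `epochs`, `headEpochs`, `nBins`, `batchSize` and `percentile`.
#' @export
deskProfile <- function(seed = 1L) {
  list(config = generatorConfig(visualTrain = 10L, visualTest = 25L,
                                audioPerClass = 10L, seed = seed),
       epochs = 80L, headEpochs = 60L, nBins = 10L, batchSize = 32L,
       percentile = 80)
}

#' @rdname deskProfile
#' @export
fullProfile <- function(seed = 1L) {
  list(config = generatorConfig(seed = seed),
       epochs = 5000L, headEpochs = 100L, nBins = 10L, batchSize = 128L,
       percentile = 80)
}

# Train one autoencoder and classify its final-layer units. Thresholds
# are taken from the consistent-trained reference run, mirroring the
# reference analysis; returns typologies for both training conditions.
.classifyReplicate <- function(rep, depth, framework, profile, repSeed,
                               conditions = c("consistent",
                                              "inconsistent")) {
  train <- function(data, tag) {
    spec <- networkSpec(framework, depth)
    m <- buildModel(spec, seed = .deriveSeed(repSeed, depth, tag,
                                             match(framework,
                                                   c("mixed", "two_stage"))))
    trainModel(m, data, profile$epochs, profile$batchSize)
  }
  info2 <- function(model) {
    act <- encodeLayer(model, rep$test, finalLayerIndex(model@spec))
    list(v = infoMatrix(act, profile$nBins, "visual_only"),
         a = infoMatrix(act, profile$nBins, "audio_only"))
  }
  mCons <- train(rep$trainConsistent, 1L)
  iCons <- info2(mCons)
  thetaV <- percentileThreshold(iCons$v, profile$percentile)
  thetaA <- percentileThreshold(iCons$a, profile$percentile)
  out <- list(consistent = classifyUnits(iCons$v, iCons$a, thetaV, thetaA),
              thetaV = thetaV, thetaA = thetaA, modelConsistent = mCons)
  if ("inconsistent" %in% conditions) {
    mIncons <- train(rep$trainInconsistent, 2L)
    iIncons <- info2(mIncons)
    out$inconsistent <- classifyUnits(iIncons$v, iIncons$a, thetaV, thetaA)
    out$modelInconsistent <- mIncons
  }
  out
}

.typologyRow <- function(ty, replicate, depth, framework, consistency) {
  cnt <- typeCounts(ty)
  data.frame(replicate = replicate, depth = depth, framework = framework,
             consistency = consistency,
             visual = cnt[["visual"]], auditory = cnt[["auditory"]],
             inconsistentCells = cnt[["inconsistent"]],
             consistentCells = cnt[["consistent"]],
             nonSelective = cnt[["non_selective"]])
}

#' Encoder-depth sweep
#'
#' Trains mixed-input autoencoders of depth 1-4 on the consistent and the
#' inconsistent training set of each replicate, classifies the final
#' encoding layer's units (thresholds from the consistent run of the same
#' replicate), and aggregates the consistent-cell counts. With at least
#' two replicates, a Welch two-sample comparison of consistent vs
#' inconsistent training per depth and a one-way analysis of variance of
#' the consistent-trained counts across depths are reported.
#'
#' @param depths encoder depths to sweep.
#' @param nReplicates replicate datasets/networks per condition.
#' @param profile a profile list from [deskProfile()] or [fullProfile()].
#' @param seed master seed overriding the profile config seed.
#' @return list with `summary` (per replicate x depth x consistency type
#'   counts), `thresholds`, and `stats` (`NULL` when `nReplicates < 2`).
#' @export
runDepthSweep <- function(depths = 1:4, nReplicates = 10L,
                          profile = deskProfile(), seed = NULL) {
  if (!is.null(seed)) profile$config@seed <- as.integer(seed)
  nReplicates <- .assertCount(nReplicates, "nReplicates")
  reps <- makeReplicates(nReplicates, profile$config)
  rows <- list(); thr <- list()
  for (r in seq_len(nReplicates)) {
    for (d in depths) {
      cl <- .classifyReplicate(reps[[r]], d, "mixed", profile,
                               reps[[r]]$seed)
      rows <- c(rows, list(
        .typologyRow(cl$consistent, r, d, "mixed", "consistent"),
        .typologyRow(cl$inconsistent, r, d, "mixed", "inconsistent")))
      thr <- c(thr, list(data.frame(replicate = r, depth = d,
                                    thetaV = cl$thetaV, thetaA = cl$thetaA)))
    }
  }
  summary <- do.call(rbind, rows)
  stats <- NULL
  if (nReplicates >= 2L) {
    perDepth <- lapply(depths, function(d) {
      g1 <- summary$consistentCells[summary$depth == d &
                                    summary$consistency == "consistent"]
      g2 <- summary$consistentCells[summary$depth == d &
                                    summary$consistency == "inconsistent"]
      c(depth = d, compareGroups(list(g1, g2), "two_sample"))
    })
    groups <- lapply(depths, function(d)
      summary$consistentCells[summary$depth == d &
                              summary$consistency == "consistent"])
    stats <- list(consVsIncons = perDepth,
                  depthEffect = if (length(depths) >= 2L)
                    compareGroups(groups, "oneway") else NULL)
  }
  list(summary = summary, thresholds = do.call(rbind, thr), stats = stats)
}

#' Mixed-input vs two-stage framework comparison
#'
#' Trains both frameworks at matched total encoder stages (4) on each
#' replicate's consistent training set, classifies final-layer units
#' (thresholds from each framework's own run), and optionally measures
#' cross-modal transfer accuracy of a visually trained head. Reports a
#' Welch comparison of the consistent-cell counts between frameworks.
#'
#' @param nReplicates replicates per framework.
#' @param profile a profile list.
#' @param seed master seed overriding the profile config seed.
#' @param transfer also run the frozen-encoder transfer evaluation.
#' @return list with `summary`, `transfer` (or `NULL`) and `stats`.
#' @export
runFrameworkComparison <- function(nReplicates = 10L,
                                   profile = deskProfile(), seed = NULL,
                                   transfer = FALSE) {
  if (!is.null(seed)) profile$config@seed <- as.integer(seed)
  nReplicates <- .assertCount(nReplicates, "nReplicates")
  reps <- makeReplicates(nReplicates, profile$config)
  rows <- list(); tr <- list()
  for (r in seq_len(nReplicates)) {
    for (fw in c("mixed", "two_stage")) {
      cl <- .classifyReplicate(reps[[r]], 4L, fw, profile, reps[[r]]$seed,
                               conditions = "consistent")
      rows <- c(rows, list(
        .typologyRow(cl$consistent, r, 4L, fw, "consistent")))
      if (transfer) {
        head <- trainHead(cl$modelConsistent, reps[[r]]$trainConsistent,
                          "visual_only", profile$headEpochs,
                          batchSize = profile$batchSize,
                          seed = .deriveSeed(reps[[r]]$seed, 900L))
        ev <- evaluateCrossModal(cl$modelConsistent, head, reps[[r]]$test)
        ev$replicate <- r; ev$framework <- fw
        tr <- c(tr, list(ev))
      }
    }
  }
  summary <- do.call(rbind, rows)
  stats <- NULL
  if (nReplicates >= 2L) {
    g <- split(summary$consistentCells, summary$framework)
    stats <- list(mixedVsTwoStage =
                    compareGroups(list(g$mixed, g$two_stage), "two_sample"))
  }
  list(summary = summary,
       transfer = if (transfer) do.call(rbind, tr) else NULL,
       stats = stats)
}

#' Standard group comparisons
#'
#' Thin wrappers over the standard tests used to summarise replicate
#' outcomes: a Welch two-sample t-test for two groups, or a classic
#' one-way analysis of variance for k groups.
#'
#' @param groups list of numeric vectors (each of length >= 2).
#' @param design `"two_sample"` or `"oneway"`.
#' @return list with `statistic`, `p.value`, `df` and `design`.
#' @examples
#' compareGroups(list(c(1, 2, 3), c(7, 8, 9)), "two_sample")
#' @export
compareGroups <- function(groups, design = c("two_sample", "oneway")) {
  design <- match.arg(design)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (identical(design, "two_sample")) {
    if (length(groups) != 2L)
      stop("'two_sample' needs exactly 2 groups", call. = FALSE)
    # degenerate zero-variance pairs: identical groups compare equal
    if (stats::sd(c(groups[[1]], groups[[2]])) == 0)
      return(list(statistic = 0, p.value = 1, df = NA_real_,
                  design = design))
    ht <- stats::t.test(groups[[1]], groups[[2]])
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), design = design)
  } else {
    value <- unlist(groups)
    grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
    if (stats::sd(value) == 0)
      return(list(statistic = 0, p.value = 1, df = NA_real_,
                  design = design))
    ht <- stats::oneway.test(value ~ grp, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), design = design)
  }
}
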