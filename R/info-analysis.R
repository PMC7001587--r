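# Binned stimulus-specific single-cell information. For a unit with binned
# response r and stimulus category s,
#   I(s, R) = sum_r P(r|s) log2( P(r|s) / P(r) ),
# the Kullback-Leibler divergence between the unit's response distribution
# given s and its marginal response distribution, in bits.

#' Construct a binned response table from raw counts
#'
#' @param counts categories x bins matrix of presentation counts (rownames
#'   are category labels).
#' @param binEdges bin edges, length `ncol(counts) + 1`; defaults to
#'   equally spaced edges over [0, 1].
#' @param unitId identifier.
#' @return a [BinnedResponseTable-class].
#' @examples
#' tab <- binnedResponseTable(rbind(A = c(3, 17, 80), B = c(68, 31, 1),
#'                                  C = c(73, 25, 2), D = c(65, 12, 23)))
#' singleCellInformation(tab, "A")
#' @export
binnedResponseTable <- function(counts, binEdges = NULL, unitId = "unit") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)) - 1L)
  if (is.null(binEdges))
    binEdges <- seq(0, 1, length.out = ncol(counts) + 1L)
  new("BinnedResponseTable", unitId = as.character(unitId),
      counts = counts, binEdges = as.numeric(binEdges))
}

#' Bin one unit's responses by category
#'
#' Divides the activation range into `nBins` equally spaced bins
#' (left-closed, right-open, with the last bin closed at the upper edge)
#' and counts, per stimulus category, how many presentations fall in each
#' bin. Values outside the range are clipped into the edge bins with a
#' warning.
#'
#' @param activations an [ActivationMatrix-class].
#' @param unit unit id (rowname) or index.
#' @param nBins number of bins (>= 2); 10 matches the main analysis.
#' @param range activation range to bin over; the sigmoid output range
#'   [0, 1] by default.
#' @param conditionFilter `"all"` or one of the presentation conditions to
#'   restrict the samples to.
#' @return a [BinnedResponseTable-class].
#' @export
binResponses <- function(activations, unit, nBins = 10L, range = c(0, 1),
                         conditionFilter = "all") {
  stopifnot(is(activations, "ActivationMatrix"))
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L) stop("'nBins' must be >= 2", call. = FALSE)
  if (!(range[2L] > range[1L])) stop("'range' must be increasing",
                                     call. = FALSE)
  keep <- .conditionIndex(activations, conditionFilter)
  r <- assay(activations, "activations")[unit, keep]
  s <- sampleLabels(activations)[keep]
  if (any(r < range[1L]) || any(r > range[2L])) {
    warning("responses outside the bin range were clipped")
    r <- pmin(pmax(r, range[1L]), range[2L])
  }
  edges <- seq(range[1L], range[2L], length.out = nBins + 1L)
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  cats <- sort(unique(s))
  counts <- matrix(0L, length(cats), nBins,
                   dimnames = list(as.character(cats), NULL))
  tab <- table(factor(s, levels = cats), factor(bin, levels = seq_len(nBins)))
  counts[] <- as.integer(tab)
  unitId <- if (is.character(unit)) unit else unitIds(activations)[unit]
  new("BinnedResponseTable", unitId = unitId, counts = counts,
      binEdges = edges)
}

.conditionIndex <- function(activations, conditionFilter) {
  if (identical(conditionFilter, "all"))
    return(rep(TRUE, ncol(activations)))
  if (!conditionFilter %in% .CONDITIONS)
    stop("unknown condition filter", call. = FALSE)
  keep <- sampleConditions(activations) == conditionFilter
  if (!any(keep))
    stop(sprintf("condition filter '%s' matches no samples",
                 conditionFilter), call. = FALSE)
  keep
}

#' @describeIn BinnedResponseTable-class the categories x bins count
#'   matrix.
#' @export
setMethod("binCounts", "BinnedResponseTable", function(x) x@counts)

#' @describeIn BinnedResponseTable-class the bin edges.
#' @export
setMethod("binEdges", "BinnedResponseTable", function(x) x@binEdges)

#' @describeIn BinnedResponseTable-class row-normalised conditional
#'   response probabilities P(r|s).
#' @export
setMethod("conditionalProb", "BinnedResponseTable", function(x) {
  sweep(x@counts, 1L, pmax(rowSums(x@counts), 1L), "/")
})

#' @describeIn BinnedResponseTable-class marginal response probabilities
#'   P(r) = sum_s P(r, s), estimated from the pooled histogram.
#' @export
setMethod("marginalProb", "BinnedResponseTable", function(x) {
  colSums(x@counts) / sum(x@counts)
})

setMethod("show", "BinnedResponseTable", function(object) {
  cat(sprintf("BinnedResponseTable: unit '%s', %d categories x %d bins\n",
              object@unitId, nrow(object@counts), ncol(object@counts)))
})

#' Stimulus-specific single-cell information
#'
#' Computes I(s, R) = sum_r P(r|s) log2(P(r|s) / P(r)) for one category
#' from a binned response table, in bits. Bins with P(r|s) = 0 contribute
#' zero; the result is non-negative and, under equal category priors,
#' bounded by `maxInformation(nCat)`.
#'
#' @param table a [BinnedResponseTable-class].
#' @param s category (rowname or index).
#' @return information in bits.
#' @examples
#' tab <- binnedResponseTable(rbind(A = c(3, 17, 80), B = c(68, 31, 1),
#'                                  C = c(73, 25, 2), D = c(65, 12, 23)))
#' round(singleCellInformation(tab, "A"), 3)
#' @export
singleCellInformation <- function(table, s) {
  stopifnot(is(table, "BinnedResponseTable"))
  validObject(table)
  row <- table@counts[s, ]
  if (sum(row) == 0)
    stop(sprintf("category '%s' has no presentations", as.character(s)),
         call. = FALSE)
  prs <- row / sum(row)
  pr <- marginalProb(table)
  ok <- prs > 0
  sum(prs[ok] * log2(prs[ok] / pr[ok]))
}

#' Per-unit, per-category information table
#'
#' Applies [binResponses()] and [singleCellInformation()] to every unit
#' and category of an activation matrix, optionally restricted to one
#' presentation condition (e.g. the visual-only or audio-only third of a
#' test set).
#'
#' @param activations an [ActivationMatrix-class].
#' @param nBins response bins.
#' @param conditionFilter `"all"`, `"both"`, `"visual_only"` or
#'   `"audio_only"`.
#' @param range activation range to bin over.
#' @return an [InfoTable-class], units x categories, in bits.
#' @export
infoMatrix <- function(activations, nBins = 10L, conditionFilter = "all",
                       range = c(0, 1)) {
  stopifnot(is(activations, "ActivationMatrix"))
  keep <- .conditionIndex(activations, conditionFilter)
  resp <- assay(activations, "activations")[, keep, drop = FALSE]
  s <- sampleLabels(activations)[keep]
  cats <- sort(unique(s))
  edges <- seq(range[1L], range[2L], length.out = as.integer(nBins) + 1L)
  info <- matrix(0, nrow(resp), length(cats),
                 dimnames = list(rownames(resp), as.character(cats)))
  sFac <- factor(s, levels = cats)
  for (u in seq_len(nrow(resp))) {
    r <- pmin(pmax(resp[u, ], range[1L]), range[2L])
    bin <- findInterval(r, edges, rightmost.closed = TRUE)
    counts <- table(sFac, factor(bin, levels = seq_len(length(edges) - 1L)))
    pr <- colSums(counts) / sum(counts)
    prs <- sweep(unclass(counts), 1L, pmax(rowSums(counts), 1L), "/")
    lg <- log2(sweep(prs, 2L, pr, "/"))
    lg[prs == 0] <- 0
    info[u, ] <- rowSums(prs * lg)
  }
  new("InfoTable", info = info, nBins = as.integer(nBins),
      condition = conditionFilter)
}

#' Maximum single-cell information
#'
#' The upper bound log2(nCat) bits attained by a unit perfectly selective
#' for one of `nCat` equiprobable categories.
#'
#' @param nCat number of stimulus categories.
#' @return bits.
#' @examples
#' maxInformation(10)  # ~3.32 bits
#' @export
maxInformation <- function(nCat) {
  nCat <- .assertCount(nCat, "nCat")
  log2(nCat)
}

#' Rank-ordered per-unit information maxima
#'
#' For each unit, the maximum information over categories, sorted in
#' decreasing order — the curve used to compare layers and training
#' conditions at a glance.
#'
#' @param info an [InfoTable-class].
#' @return named numeric vector, decreasing.
#' @export
rankOrderCurve <- function(info) {
  stopifnot(is(info, "InfoTable"))
  if (!nrow(info@info)) stop("empty information table", call. = FALSE)
  sort(apply(info@info, 1L, max), decreasing = TRUE)
}

#' @describeIn InfoTable-class units x categories information matrix
#'   (bits).
#' @export
setMethod("infoValues", "InfoTable", function(x) x@info)

#' @describeIn InfoTable-class the condition subset the table was computed
#'   on.
#' @export
setMethod("infoCondition", "InfoTable", function(x) x@condition)

setMethod("show", "InfoTable", function(object) {
  cat(sprintf(
    "InfoTable: %d units x %d categories (%d bins, condition '%s')\n",
    nrow(object@info), ncol(object@info), object@nBins, object@condition))
})
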