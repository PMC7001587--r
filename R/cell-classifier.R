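# Four-way selectivity typology of encoder units. A unit is "selective"
# for a digit in a modality when its stimulus-specific information about
# that digit, computed on the single-modality test subset, exceeds a
# threshold taken as a percentile of a reference information table.

#' Percentile threshold over an information table
#'
#' Pools all unit x digit information values of a table and returns the
#' requested percentile (linear-interpolation definition). Following the
#' reference analysis, the threshold is computed once from the final
#' encoding layer of the consistent-trained network and then applied to
#' every condition.
#'
#' @param info an [InfoTable-class].
#' @param percentile percentile in (0, 100); 80 in the reference analysis.
#' @return threshold in bits.
#' @export
percentileThreshold <- function(info, percentile = 80) {
  stopifnot(is(info, "InfoTable"))
  if (!nrow(info@info)) stop("empty information table", call. = FALSE)
  if (length(percentile) != 1L || is.na(percentile) ||
      percentile <= 0 || percentile >= 100)
    stop("'percentile' must lie in (0, 100)", call. = FALSE)
  unname(stats::quantile(as.vector(info@info), percentile / 100, type = 7))
}

#' Digits a unit is selective for
#'
#' @param infoRow named per-digit information values (bits) of one unit.
#' @param theta selectivity threshold in bits (>= 0).
#' @return integer vector of digits whose information strictly exceeds
#'   `theta`.
#' @export
selectiveDigits <- function(infoRow, theta) {
  if (theta < 0) stop("'theta' must be non-negative", call. = FALSE)
  d <- names(infoRow)
  if (is.null(d)) d <- as.character(seq_along(infoRow) - 1L)
  as.integer(d[infoRow > theta])
}

#' Classify units into the selectivity typology
#'
#' Units selective (per [selectiveDigits()]) in only one modality are
#' `visual` or `auditory` cells; units selective in both modalities are
#' `consistent` when their digit sets share at least one digit (the
#' shared-representation cells) and `inconsistent` otherwise; units
#' selective in neither are `non_selective` and excluded from the
#' four-type counts.
#'
#' @param visualInfo,audioInfo [InfoTable-class] objects over the same
#'   units, computed on the visual-only resp. audio-only test subsets.
#' @param thetaV,thetaA selectivity thresholds in bits.
#' @return a [UnitTypology-class].
#' @export
classifyUnits <- function(visualInfo, audioInfo, thetaV, thetaA) {
  stopifnot(is(visualInfo, "InfoTable"), is(audioInfo, "InfoTable"))
  vi <- visualInfo@info; ai <- audioInfo@info
  if (!identical(rownames(vi), rownames(ai)))
    stop("information tables cover different unit sets", call. = FALSE)
  n <- nrow(vi)
  vDig <- vector("list", n); aDig <- vector("list", n)
  type <- character(n)
  for (u in seq_len(n)) {
    vDig[[u]] <- selectiveDigits(vi[u, ], thetaV)
    aDig[[u]] <- selectiveDigits(ai[u, ], thetaA)
    hasV <- length(vDig[[u]]) > 0L; hasA <- length(aDig[[u]]) > 0L
    type[u] <-
      if (hasV && hasA) {
        if (length(intersect(vDig[[u]], aDig[[u]]))) "consistent"
        else "inconsistent"
      } else if (hasV) "visual"
      else if (hasA) "auditory"
      else "non_selective"
  }
  new("UnitTypology",
      typology = DataFrame(unit = rownames(vi),
                           type = factor(type, levels = .CELL_TYPES),
                           visualDigits = IntegerList(vDig),
                           auditoryDigits = IntegerList(aDig)),
      thresholds = c(visual = thetaV, auditory = thetaA))
}

#' @describeIn UnitTypology-class per-unit typology `DataFrame`.
#' @export
setMethod("typologyTable", "UnitTypology", function(x) x@typology)

#' @describeIn UnitTypology-class unit counts per selectivity type.
#' @export
setMethod("typeCounts", "UnitTypology", function(x) {
  table(x@typology$type)
})

#' @describeIn UnitTypology-class the thresholds used (bits).
#' @export
setMethod("typologyThresholds", "UnitTypology", function(x) x@thresholds)

setMethod("show", "UnitTypology", function(object) {
  cnt <- typeCounts(object)
  cat(sprintf(
    "UnitTypology: %d units (theta_v=%.3f, theta_a=%.3f bits)\n",
    nrow(object@typology), object@thresholds[["visual"]],
    object@thresholds[["auditory"]]))
  print(cnt)
})
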