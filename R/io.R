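# Delimited-text exports of the analysis products.

#' Write an information table as delimited text
#'
#' Long format with one row per (unit, digit): columns `unit`, `digit`,
#' `bits`, `condition`.
#'
#' @param info an [InfoTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeInfoTable <- function(info, path) {
  stopifnot(is(info, "InfoTable"))
  m <- infoValues(info)
  long <- data.frame(
    unit = rep(rownames(m), times = ncol(m)),
    digit = rep(colnames(m), each = nrow(m)),
    bits = as.vector(m),
    condition = infoCondition(info))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a unit typology as delimited text
#'
#' One row per unit: columns `unit`, `type`, `visualDigits`,
#' `auditoryDigits` (digit sets as comma-separated strings), plus the
#' thresholds echoed in a header comment line.
#'
#' @param typology a [UnitTypology-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTypology <- function(typology, path) {
  stopifnot(is(typology, "UnitTypology"))
  tt <- typologyTable(typology)
  th <- typologyThresholds(typology)
  df <- data.frame(
    unit = tt$unit, type = as.character(tt$type),
    visualDigits = vapply(tt$visualDigits, paste, "", collapse = ","),
    auditoryDigits = vapply(tt$auditoryDigits, paste, "", collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# theta_visual=%.6f theta_auditory=%.6f",
                     th[["visual"]], th[["auditory"]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a modality pool as delimited text with a metadata sidecar
#'
#' The samples go to `<prefix>.tsv` (one row per sample, pixels as
#' columns, label and source id first); the generation metadata to
#' `<prefix>.meta.dcf`.
#'
#' @param pool a [ModalityPool-class].
#' @param prefix output path prefix.
#' @return the data file path, invisibly.
#' @export
writePool <- function(pool, prefix) {
  stopifnot(is(pool, "ModalityPool"))
  dataPath <- paste0(prefix, ".tsv")
  df <- data.frame(label = pool@labels, source = pool@sourceId,
                   pool@samples)
  utils::write.table(df, dataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(modality = pool@modality,
                     rows = pool@gridShape[1L], cols = pool@gridShape[2L],
                     nClasses = pool@nClasses, seed = pool@seed)
  write.dcf(meta, paste0(prefix, ".meta.dcf"))
  invisible(dataPath)
}
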