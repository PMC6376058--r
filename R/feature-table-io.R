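#' Read and write the long feature table as CSV
#'
#' The on-disk format is delimited text with a fixed column order: the four
#' key columns (`patient_id`, `side`, `sequence`, `reading`) followed by
#' the 85 feature columns in schema order. Values round-trip losslessly at
#' full double precision, including `NaN`/`NA` flags for degenerate ROIs.
#'
#' @param table a feature table tibble (keys + 85 features).
#' @param path file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(table, path) {
  .check_feature_table(table)
  table <- table[, c(.key_cols(), feature_schema()$feature)]
  # format doubles at 17 significant digits so the binary values (and the
  # NaN/NA missing flags) survive the text round trip exactly
  out <- table
  for (nm in feature_schema()$feature) {
    v <- sprintf("%.17g", out[[nm]])
    v[is.na(out[[nm]]) & !is.nan(out[[nm]])] <- "NA"
    out[[nm]] <- v
  }
  readr::write_csv(out, path, na = "NA", quote = "needed")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base R's strtod is correctly rounded, so the 17-digit decimal text
  # maps back onto the original binary doubles exactly
  out <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(patient_id = "character",
                                        side = "character",
                                        sequence = "character",
                                        reading = "character"))
  out <- tibble::as_tibble(out)
  for (nm in setdiff(names(out), .key_cols())) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  .check_feature_table(out)
  out
}
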