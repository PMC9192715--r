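#' Write per-study, per-stratum GWAS summary statistics
#'
#' Tab-delimited with header SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N,
#' INFO plus LOG10P (so extreme p-values survive scientific-notation
#' underflow). Paths ending in `.gz` are gzip-compressed.
#'
#' @param stats data.frame as produced by [run_stratified_gwas()].
#' @param path output file; `.gz` suffix triggers compression.
#' @return the path, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  cols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N",
            "INFO", "LOG10P")
  missing <- setdiff(setdiff(cols, "LOG10P"), names(stats))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  if (!"LOG10P" %in% names(stats)) stats$LOG10P <- -log10(stats$P)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(stats[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics file written by [write_sumstats()]
#'
#' @param path input file (plain or gzip TSV).
#' @return data.frame with the standard columns.
#' @export
read_sumstats <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"LOG10P" %in% names(df)) df$LOG10P <- -log10(df$P)
  df
}
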