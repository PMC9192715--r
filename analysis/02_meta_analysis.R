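#!/usr/bin/env Rscript
# Step 2: per-stratum fixed-effect IVW meta-analysis of the per-study
# summary statistics with double genomic control (study level, then meta
# level) and the post-meta presence/MAC filters. Writes one meta TSV per
# stratum under results/.

suppressPackageStartupMessages(library(stratgwas))

in_dir <- "results/sumstats"
for (stratum in c("DM", "noDM")) {
  files <- Sys.glob(file.path(in_dir, sprintf("study*_%s.tsv.gz", stratum)))
  stopifnot(length(files) >= 1)
  studies <- lapply(files, read_sumstats)
  res <- meta_stratum(studies, n_studies_total = length(studies))
  cat(sprintf("%5s: %d studies, lambdas study = %s, lambda meta = %.3f\n",
              stratum, length(studies),
              paste(round(res$lambda_study, 3), collapse = "/"),
              res$lambda_meta))
  cat(sprintf("       %d variants after filters (dropped: %s)\n",
              nrow(res$meta),
              paste(names(attr(res$meta, "n_removed")),
                    attr(res$meta, "n_removed"), collapse = ", ",
                    sep = "=")))
  out <- file.path("results", sprintf("meta_%s.tsv", stratum))
  write.table(res$meta, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  ->", out, "\n")
}
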