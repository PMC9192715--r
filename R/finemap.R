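#' Approximate Bayes factor (Wakefield normal approximation)
#'
#' For a variant with estimate beta and standard error se, and a N(0, W^2)
#' prior on the true effect, the log approximate Bayes factor against the
#' point null is
#' \deqn{\log ABF = \tfrac12 \log\frac{se^2}{se^2 + W^2} +
#'   \frac{z^2 W^2}{2 (se^2 + W^2)}, \quad z = beta / se.}
#' W defaults to 0.05 on the log-eGFR scale. All downstream credible-set
#' properties are prior-agnostic.
#'
#' @param beta,se marginal (or conditioned) estimates.
#' @param W prior standard deviation of the effect (>= 0).
#' @return natural-log ABF (vector).
#' @export
abf_wakefield <- function(beta, se, W = 0.05) {
  stopifnot(all(se > 0), W >= 0)
  z <- beta / se
  v <- se^2
  0.5 * log(v / (v + W^2)) + z^2 * W^2 / (2 * (v + W^2))
}

#' 99% credible set from per-variant log-ABFs
#'
#' Normalizes ABFs within a signal into posterior probabilities of
#' association (single causal variant, flat prior), sorts by descending
#' PPA, and takes the minimal prefix whose cumulative PPA reaches `level`.
#'
#' @param log_abf per-variant natural-log ABFs for one signal.
#' @param ids variant identifiers.
#' @param level credible level (default 0.99).
#' @return data.frame sorted by descending PPA with SNP, LOG_ABF, PPA,
#'   CUM_PPA, IN_CS; attribute `level`.
#' @export
credible_set <- function(log_abf, ids, level = 0.99) {
  stopifnot(length(log_abf) == length(ids), length(log_abf) >= 1,
            all(is.finite(log_abf)))
  m <- max(log_abf)
  ppa <- exp(log_abf - m)
  ppa <- ppa / sum(ppa)
  ord <- order(ppa, decreasing = TRUE)
  out <- data.frame(SNP = as.character(ids)[ord], LOG_ABF = log_abf[ord],
                    PPA = ppa[ord], stringsAsFactors = FALSE)
  out$CUM_PPA <- cumsum(out$PPA)
  # minimal prefix reaching the level (tiny tolerance guards an exact sum
  # like 0.6 + 0.3 + 0.09 against float rounding)
  k <- which(out$CUM_PPA >= level - 1e-9)[1]
  out$IN_CS <- seq_len(nrow(out)) <= k
  attr(out, "level") <- level
  out
}

#' Rule-based gene prioritization at identified loci
#'
#' Applies the prioritization rules to user-supplied annotation tables: a
#' gene is flagged when a 99% credible set variant with PPA >= `ppa_min`
#' (i) is annotated to the gene with CADD PHRED >= `cadd_min`
#' (protein-deleterious), or (ii) is a kidney eQTL/sQTL for the gene at
#' FDR < `fdr_max`; independently, (iii) a gene on the monogene list whose
#' interval overlaps the locus is flagged as a kidney-disease monogene.
#' Annotation rows referencing variants absent from the credible sets are
#' ignored with a warning.
#'
#' @param credible data.frame of credible-set variants with columns SNP,
#'   PPA, IN_CS and LOCUS (locus id per variant).
#' @param cadd data.frame VARIANT, GENE, CADD (may be NULL).
#' @param qtl data.frame VARIANT, GENE, TISSUE, FDR, TYPE ("eQTL"/"sQTL";
#'   may be NULL).
#' @param monogenes character vector of kidney-disease monogenes (may be
#'   NULL).
#' @param gene_intervals data.frame GENE, CHR, START, END (required when
#'   `monogenes` is given).
#' @param loci data.frame with LOCUS, CHR, START, END (required when
#'   `monogenes` is given).
#' @param ppa_min PPA floor for variant-level evidence (default 0.05).
#' @param cadd_min CADD PHRED threshold (default 15).
#' @param fdr_max QTL FDR threshold, strict (default 0.05).
#' @return data.frame with one row per (gene, locus): GENE, LOCUS, logical
#'   evidence columns PROTEIN_DELETERIOUS, KIDNEY_EQTL, KIDNEY_SQTL,
#'   MONOGENE, and VARIANTS (comma-separated supporting variant ids).
#' @export
prioritize_genes <- function(credible, cadd = NULL, qtl = NULL,
                             monogenes = NULL, gene_intervals = NULL,
                             loci = NULL, ppa_min = 0.05, cadd_min = 15,
                             fdr_max = 0.05) {
  stopifnot(all(c("SNP", "PPA", "IN_CS", "LOCUS") %in% names(credible)))
  cs <- credible[credible$IN_CS & credible$PPA >= ppa_min, , drop = FALSE]
  ev <- list()
  add <- function(gene, locus, flag, variants) {
    ev[[length(ev) + 1]] <<- data.frame(
      GENE = gene, LOCUS = locus, FLAG = flag,
      VARIANTS = paste(variants, collapse = ","), stringsAsFactors = FALSE)
  }
  check_known <- function(tab, label) {
    unknown <- setdiff(tab$VARIANT, credible$SNP)
    if (length(unknown)) {
      warning(label, " rows reference variants outside the credible sets: ",
              paste(unique(unknown), collapse = ", "))
    }
  }

  if (!is.null(cadd) && nrow(cadd)) {
    check_known(cadd, "CADD")
    hit <- merge(cs, cadd, by.x = "SNP", by.y = "VARIANT")
    hit <- hit[hit$CADD >= cadd_min, , drop = FALSE]
    for (g in unique(paste(hit$GENE, hit$LOCUS))) {
      rows <- hit[paste(hit$GENE, hit$LOCUS) == g, ]
      add(rows$GENE[1], rows$LOCUS[1], "PROTEIN_DELETERIOUS", rows$SNP)
    }
  }
  if (!is.null(qtl) && nrow(qtl)) {
    check_known(qtl, "QTL")
    hit <- merge(cs, qtl, by.x = "SNP", by.y = "VARIANT")
    hit <- hit[hit$FDR < fdr_max, , drop = FALSE]
    for (type in c("eQTL", "sQTL")) {
      sub <- hit[hit$TYPE == type, , drop = FALSE]
      for (g in unique(paste(sub$GENE, sub$LOCUS))) {
        rows <- sub[paste(sub$GENE, sub$LOCUS) == g, ]
        add(rows$GENE[1], rows$LOCUS[1],
            if (type == "eQTL") "KIDNEY_EQTL" else "KIDNEY_SQTL", rows$SNP)
      }
    }
  }
  if (!is.null(monogenes) && length(monogenes)) {
    stopifnot(!is.null(gene_intervals), !is.null(loci))
    gi <- gene_intervals[gene_intervals$GENE %in% monogenes, , drop = FALSE]
    for (i in seq_len(nrow(gi))) {
      ov <- loci$CHR == gi$CHR[i] & loci$START <= gi$END[i] &
        loci$END >= gi$START[i]
      for (l in loci$LOCUS[ov]) add(gi$GENE[i], l, "MONOGENE", character(0))
    }
  }

  flags <- c("PROTEIN_DELETERIOUS", "KIDNEY_EQTL", "KIDNEY_SQTL", "MONOGENE")
  if (!length(ev)) {
    out <- data.frame(GENE = character(), LOCUS = character(),
                      stringsAsFactors = FALSE)
    for (f in flags) out[[f]] <- logical()
    out$VARIANTS <- character()
    return(out)
  }
  long <- do.call(rbind, ev)
  keys <- unique(long[, c("GENE", "LOCUS")])
  out <- keys
  for (f in flags) out[[f]] <- FALSE
  out$VARIANTS <- ""
  for (i in seq_len(nrow(out))) {
    rows <- long[long$GENE == out$GENE[i] & long$LOCUS == out$LOCUS[i], ]
    for (f in intersect(rows$FLAG, flags)) out[[f]][i] <- TRUE
    vv <- unique(unlist(strsplit(rows$VARIANTS, ",")))
    out$VARIANTS[i] <- paste(vv[nzchar(vv)], collapse = ",")
  }
  rownames(out) <- NULL
  out
}
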