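#' Define non-overlapping loci by iterative clumping
#'
#' Implements the iterative region definition used for genome-wide
#' significant variants: the most significant remaining variant is selected
#' genome-wide (locus lead); its locus is the smallest interval on that
#' chromosome such that no genome-wide significant variant lies within
#' `merge` bp outside its borders (variants within `merge` bp of the current
#' borders are absorbed until a fixed point); the locus region is then the
#' outermost significant members padded by `flank` bp on each side. Member
#' variants are removed and the procedure repeats until no significant
#' variant remains, which guarantees pairwise non-overlapping loci for
#' separations greater than `merge`. Lead ties are broken by larger |Z|
#' (when a `Z_DIFF` column is present), then smaller (chr, pos).
#'
#' @param results data.frame with SNP, CHR, POS and a -log10 p column.
#' @param p_threshold genome-wide significance threshold (strict; default
#'   5e-8).
#' @param flank padding added beyond the outermost significant member
#'   (default 250 kb).
#' @param merge absorption distance between significant variants and locus
#'   borders (inclusive; default 500 kb).
#' @param log10p_col name of the -log10 p column used for significance and
#'   lead selection.
#' @return data.frame with one row per locus: CHR, START, END, LEAD,
#'   P_LEAD (as -log10), N_SIG, KNOWN (NA until [annotate_known()]), and a
#'   list column MEMBERS of member variant ids.
#' @export
define_loci <- function(results, p_threshold = 5e-8, flank = 250000,
                        merge = 500000, log10p_col = "LOG10P") {
  stopifnot(all(c("SNP", "CHR", "POS", log10p_col) %in% names(results)))
  sig <- results[p_below(results[[log10p_col]], p_threshold),
                 c("SNP", "CHR", "POS", log10p_col,
                   intersect("Z_DIFF", names(results)))]
  loci <- list()
  while (nrow(sig) > 0) {
    ord <- order(-sig[[log10p_col]],
                 if ("Z_DIFF" %in% names(sig)) -abs(sig$Z_DIFF) else sig$POS,
                 sig$CHR, sig$POS)
    lead <- sig[ord[1], ]
    same_chr <- sig[sig$CHR == lead$CHR, ]
    lo <- lead$POS
    hi <- lead$POS
    repeat {
      inside <- same_chr$POS >= lo - merge & same_chr$POS <= hi + merge
      new_lo <- min(same_chr$POS[inside])
      new_hi <- max(same_chr$POS[inside])
      if (new_lo == lo && new_hi == hi) break
      lo <- new_lo
      hi <- new_hi
    }
    members <- same_chr$SNP[same_chr$POS >= lo & same_chr$POS <= hi]
    loci[[length(loci) + 1]] <- data.frame(
      CHR = lead$CHR, START = lo - flank, END = hi + flank,
      LEAD = lead$SNP, P_LEAD = lead[[log10p_col]],
      N_SIG = length(members), KNOWN = NA,
      stringsAsFactors = FALSE
    )
    loci[[length(loci)]]$MEMBERS <- I(list(members))
    sig <- sig[!(sig$SNP %in% members), , drop = FALSE]
  }
  if (length(loci) == 0) {
    out <- data.frame(CHR = integer(), START = numeric(), END = numeric(),
                      LEAD = character(), P_LEAD = numeric(),
                      N_SIG = integer(), KNOWN = logical(),
                      stringsAsFactors = FALSE)
    out$MEMBERS <- I(list())
    return(out)
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$CHR, out$START), ]
  rownames(out) <- NULL
  out
}

#' Flag loci overlapping known intervals
#'
#' A locus is known when it overlaps (>= 1 bp, closed intervals) any
#' interval in `known_intervals`; otherwise it is novel.
#'
#' @param loci data.frame from [define_loci()].
#' @param known_intervals data.frame with CHR, START, END (1-based closed).
#' @return `loci` with the KNOWN column filled.
#' @export
annotate_known <- function(loci, known_intervals) {
  stopifnot(all(c("CHR", "START", "END") %in% names(known_intervals)))
  if (nrow(known_intervals) > 0 &&
      any(known_intervals$END < known_intervals$START)) {
    stop("malformed known interval (end < start)", call. = FALSE)
  }
  loci$KNOWN <- vapply(seq_len(nrow(loci)), function(i) {
    any(known_intervals$CHR == loci$CHR[i] &
        known_intervals$START <= loci$END[i] &
        known_intervals$END >= loci$START[i])
  }, logical(1))
  loci
}

#' Write loci as a BED-like TSV
#'
#' Columns CHR, START, END, LEAD, P_LEAD, N_SIG, KNOWN, SIGNALS with
#' 1-based closed coordinates; `bed = TRUE` converts to 0-based half-open.
#'
#' @param loci data.frame from [define_loci()] (optionally with a SIGNALS
#'   column).
#' @param path output file.
#' @param bed convert coordinates to BED convention.
#' @return the path, invisibly.
#' @export
write_loci <- function(loci, path, bed = FALSE) {
  out <- loci[, c("CHR", "START", "END", "LEAD", "P_LEAD", "N_SIG", "KNOWN")]
  out$SIGNALS <- if ("SIGNALS" %in% names(loci)) {
    vapply(loci$SIGNALS, paste, character(1), collapse = ",")
  } else loci$LEAD
  if (bed) out$START <- out$START - 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
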