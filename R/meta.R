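#' Harmonize effect alleles across studies
#'
#' Fixes, per variant, a canonical effect allele (the lexicographically
#' smaller of the two alleles); records reported on the other allele have
#' their beta negated and EAF replaced by 1-EAF. Strand-ambiguous A/T and
#' C/G variants are flagged (column `AMBIGUOUS`), not dropped: in synthetic
#' data strand is known, and for file input the flag lets the caller decide.
#' Records whose allele pair disagrees with the consensus pair for the
#' variant (most frequent pair across studies, first-seen on ties) are
#' dropped and listed in the `dropped` element.
#'
#' @param studies list of summary-statistics data.frames (one per study).
#' @return list with `studies` (aligned data.frames, same order) and
#'   `dropped` (data.frame SNP, STUDY, REASON).
#' @export
harmonize_alleles <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1)
  pair_key <- function(ea, oa) {
    paste(pmin(ea, oa), pmax(ea, oa), sep = "/")
  }
  # consensus allele pair per variant
  all_pairs <- do.call(rbind, lapply(studies, function(d) {
    data.frame(SNP = d$SNP, KEY = pair_key(d$EA, d$OA), stringsAsFactors = FALSE)
  }))
  consensus <- vapply(split(all_pairs$KEY, all_pairs$SNP), function(k) {
    names(sort(table(factor(k, levels = unique(k))), decreasing = TRUE))[1]
  }, character(1))

  dropped <- list()
  aligned <- lapply(seq_along(studies), function(s) {
    d <- studies[[s]]
    key <- pair_key(d$EA, d$OA)
    ok <- key == consensus[d$SNP]
    if (any(!ok)) {
      dropped[[length(dropped) + 1]] <<- data.frame(
        SNP = d$SNP[!ok], STUDY = s, REASON = "allele pair mismatch",
        stringsAsFactors = FALSE)
      d <- d[ok, , drop = FALSE]
    }
    flip <- d$EA > d$OA
    if (any(flip)) {
      tmp <- d$EA[flip]
      d$EA[flip] <- d$OA[flip]
      d$OA[flip] <- tmp
      d$BETA[flip] <- -d$BETA[flip]
      d$EAF[flip] <- 1 - d$EAF[flip]
    }
    d$AMBIGUOUS <- (d$EA == "A" & d$OA == "T") | (d$EA == "T" & d$OA == "A") |
                   (d$EA == "C" & d$OA == "G") | (d$EA == "G" & d$OA == "C")
    rownames(d) <- NULL
    d
  })
  list(
    studies = aligned,
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(SNP = character(), STUDY = integer(),
                              REASON = character(), stringsAsFactors = FALSE)
  )
}

#' Study-level variant QC
#'
#' Excludes variants with imputation Info < `info_min` (default 0.6) or
#' minor allele frequency < `maf_min` (default 0.1%). Boundary values are
#' retained (strict-inequality exclusion).
#'
#' @param stats summary-statistics data.frame.
#' @param info_min minimum imputation quality retained.
#' @param maf_min minimum MAF retained.
#' @return filtered data.frame; attribute `n_removed` holds the counts.
#' @export
qc_filter <- function(stats, info_min = 0.6, maf_min = 0.001) {
  if (nrow(stats) == 0) return(stats)
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  low_info <- stats$INFO < info_min
  low_maf <- maf < maf_min
  keep <- !low_info & !low_maf
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- c(info = sum(low_info), maf = sum(low_maf & !low_info))
  out
}

#' Fixed-effect inverse-variance weighted meta-analysis
#'
#' Combines harmonized per-study records into one stratum-level record per
#' variant: beta = sum(w_s beta_s)/sum(w_s) with w_s = 1/se_s^2,
#' se = 1/sqrt(sum w_s). Sample size and cumulative minor allele count
#' (MAC = sum over studies of 2 n_s min(eaf_s, 1-eaf_s)) are accumulated,
#' and Cochran's Q and I^2 = max(0, (Q - df)/Q) measure between-study
#' heterogeneity.
#'
#' @param studies list of harmonized summary-statistics data.frames.
#' @return meta-analysis data.frame with columns SNP, CHR, POS, EA, OA, EAF
#'   (sample-size weighted), BETA, SE, P, LOG10P, N, NSTUDIES, MAC, Q, I2.
#' @export
ivw_meta <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1)
  stacked <- do.call(rbind, lapply(studies, function(d) {
    d[, c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "N")]
  }))
  if (any(stacked$SE <= 0)) stop("non-positive standard error", call. = FALSE)

  f <- factor(stacked$SNP, levels = unique(stacked$SNP))
  w <- 1 / stacked$SE^2
  sw <- rowsum(w, f)[, 1]
  swb <- rowsum(w * stacked$BETA, f)[, 1]
  beta <- swb / sw
  se <- 1 / sqrt(sw)
  n <- rowsum(stacked$N, f)[, 1]
  k <- as.integer(table(f))
  mac <- rowsum(2 * stacked$N * pmin(stacked$EAF, 1 - stacked$EAF), f)[, 1]
  eaf <- rowsum(stacked$N * stacked$EAF, f)[, 1] / n
  q <- rowsum(w * stacked$BETA^2, f)[, 1] - sw * beta^2
  q <- pmax(q, 0)
  i2 <- ifelse(k > 1 & q > 0, pmax(0, (q - (k - 1)) / q), 0)
  pv <- p_two_sided(beta / se)

  first <- !duplicated(stacked$SNP)
  meta <- data.frame(
    SNP = levels(f),
    CHR = stacked$CHR[first], POS = stacked$POS[first],
    EA = stacked$EA[first], OA = stacked$OA[first],
    EAF = eaf, BETA = beta, SE = se, P = pv$p, LOG10P = pv$log10p,
    N = n, NSTUDIES = k, MAC = mac, Q = q, I2 = i2,
    stringsAsFactors = FALSE, row.names = NULL
  )
  meta
}

#' Genomic-control correction
#'
#' Estimates the inflation factor lambda = median((beta/se)^2) / 0.455
#' (internally qchisq(0.5, 1) = 0.4549364) over the analysis unit. If
#' lambda > 1, standard errors are multiplied by sqrt(lambda) and p-values
#' recomputed; deflation (lambda <= 1) is reported but not applied. Double
#' GC in the two-stage pipeline is obtained by calling this at study level
#' and again on the meta-analysis results.
#'
#' @param stats summary-statistics or meta-analysis data.frame.
#' @return list with `lambda` and `stats` (corrected records, with a
#'   LAMBDA column recording the factor applied).
#' @export
gc_correct <- function(stats) {
  if (nrow(stats) < 100) {
    warning("fewer than 100 records: lambda estimate is unstable")
  }
  chisq <- (stats$BETA / stats$SE)^2
  lambda <- stats::median(chisq) / stats::qchisq(0.5, 1)
  out <- stats
  if (is.finite(lambda) && lambda > 1) {
    out$SE <- out$SE * sqrt(lambda)
    pv <- p_two_sided(out$BETA / out$SE)
    out$P <- pv$p
    out$LOG10P <- pv$log10p
  }
  out$LAMBDA <- lambda
  list(lambda = lambda, stats = out)
}

#' Post-meta-analysis variant filters
#'
#' Keeps variants present in more than `presence_frac` of the contributing
#' studies (e.g. with 72 studies, presence in <= 36 excludes) and with
#' cumulative minor allele count of at least `mac_min`.
#'
#' @param meta meta-analysis data.frame with NSTUDIES and MAC columns.
#' @param n_studies_total number of studies contributing to the analysis.
#' @param presence_frac presence fraction; NSTUDIES must exceed
#'   `presence_frac * n_studies_total`.
#' @param mac_min minimum cumulative MAC retained (MAC < mac_min excluded).
#' @return filtered data.frame; attribute `n_removed` holds the counts.
#' @export
meta_filters <- function(meta, n_studies_total, presence_frac = 0.5,
                         mac_min = 400) {
  low_presence <- meta$NSTUDIES <= presence_frac * n_studies_total
  low_mac <- meta$MAC < mac_min
  out <- meta[!low_presence & !low_mac, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- c(presence = sum(low_presence),
                              mac = sum(low_mac & !low_presence))
  out
}

#' Stage-level stratified meta-analysis pipeline
#'
#' Convenience wrapper applying the stage-1 recipe to one stratum:
#' per-study QC and genomic control, allele harmonization, IVW
#' meta-analysis, a second genomic control on the meta result, and the
#' post-meta presence/MAC filters.
#'
#' @param studies list of per-study summary-statistics data.frames for one
#'   stratum.
#' @param n_studies_total total number of studies in the analysis plan
#'   (defaults to `length(studies)`).
#' @param gc character vector naming where to apply genomic control:
#'   any of "study", "meta".
#' @param ... passed to [meta_filters()].
#' @return list with `meta` (filtered meta data.frame), `lambda_study`
#'   (per-study lambdas), `lambda_meta`, and `dropped` from harmonization.
#' @export
meta_stratum <- function(studies, n_studies_total = length(studies),
                         gc = c("study", "meta"), ...) {
  studies <- lapply(studies, qc_filter)
  lambda_study <- rep(NA_real_, length(studies))
  if ("study" %in% gc) {
    for (s in seq_along(studies)) {
      g <- gc_correct(studies[[s]])
      studies[[s]] <- g$stats
      lambda_study[s] <- g$lambda
    }
  }
  h <- harmonize_alleles(studies)
  meta <- ivw_meta(h$studies)
  lambda_meta <- NA_real_
  if ("meta" %in% gc) {
    g <- gc_correct(meta)
    meta <- g$stats
    lambda_meta <- g$lambda
  }
  meta <- meta_filters(meta, n_studies_total = n_studies_total, ...)
  list(meta = meta, lambda_study = lambda_study, lambda_meta = lambda_meta,
       dropped = h$dropped)
}
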