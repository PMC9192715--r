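#' Bonferroni-corrected follow-up threshold
#'
#' @param k number of variants followed.
#' @param alpha family-wise level (default 0.05).
#' @return alpha / k.
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  stopifnot(k >= 1)
  alpha / k
}

#' Accumulate per-stratum sample sizes across stages
#'
#' Stage meta-analyses contribute disjoint individuals, so combined-stage
#' stratum sizes are plain sums over stages.
#'
#' @param ... named numeric vectors, one per stage, each with elements
#'   `n_dm` and `n_nodm`.
#' @return named vector with combined `n_dm` and `n_nodm`.
#' @export
combine_stage_samples <- function(...) {
  stages <- list(...)
  stopifnot(length(stages) >= 1)
  out <- c(n_dm = 0, n_nodm = 0)
  for (s in stages) {
    stopifnot(all(c("n_dm", "n_nodm") %in% names(s)))
    out <- out + c(n_dm = unname(s["n_dm"]), n_nodm = unname(s["n_nodm"]))
  }
  out
}

# p < threshold on the -log10 scale (strict), robust to underflowed p
p_below <- function(log10p, threshold) {
  log10p > -log10(threshold)
}

#' Run an identification design over stratified test results
#'
#' Orchestrates the two designs and the identification approaches over
#' variant-level stratified results (from [stratified_results()]):
#' \itemize{
#' \item difference approach: P_Diff < 5e-8 (discovery or combined stage);
#'   discovery+replication follows discovered variants into stage 2 at a
#'   one-sided P_Diff < 0.05/k with the direction fixed by the stage-1
#'   difference sign.
#' \item overall+difference approach: candidates are the k variants with
#'   genome-wide significant overall association; the difference is
#'   assessed at P_Diff < 0.05/k in the same data. In the
#'   discovery+replication design, discovered variants are additionally
#'   replicated at one-sided P_Diff < 0.05/k' in stage 2.
#' \item joint / stratified approaches: P_Joint (or P_DM / P_noDM) < 5e-8
#'   for discovery or combined-stage identification; replication at
#'   P < 0.05/k on the same statistic.
#' }
#' All thresholds are strict inequalities evaluated on the -log10 scale.
#'
#' @param stage1 stratified results for stage 1 (or the combined-stage
#'   meta-analysis when `design = "combined"`).
#' @param stage2 stratified results for stage 2 (required for
#'   `design = "discovery+replication"`).
#' @param approach one of "difference", "overall+difference", "joint",
#'   "stratified-DM", "stratified-noDM".
#' @param design "discovery+replication" or "combined".
#' @param gw genome-wide significance threshold (default 5e-8).
#' @param alpha family-wise level for Bonferroni follow-up (default 0.05).
#' @return an object of class `design_outcome`: list with `approach`,
#'   `design`, `k`, `thresholds`, and `decisions` (data.frame SNP, STATUS in
#'   discovered/replicated/identified/failed/non-assessable).
#' @export
run_design <- function(stage1, stage2 = NULL,
                       approach = c("difference", "overall+difference",
                                    "joint", "stratified-DM",
                                    "stratified-noDM"),
                       design = c("discovery+replication", "combined"),
                       gw = 5e-8, alpha = 0.05) {
  approach <- match.arg(approach)
  design <- match.arg(design)
  pcol <- switch(approach,
    "difference" = "LOG10P_DIFF",
    "overall+difference" = "LOG10P_DIFF",
    "joint" = "LOG10P_JOINT",
    "stratified-DM" = "LOG10P_DM",
    "stratified-noDM" = "LOG10P_NODM"
  )

  if (approach == "overall+difference") {
    cand <- p_below(stage1$LOG10P_OVR, gw)
    k <- sum(cand)
    thr <- if (k > 0) bonferroni_threshold(k, alpha) else NA_real_
    hit <- cand & p_below(stage1[[pcol]], thr)
  } else {
    cand <- rep(TRUE, nrow(stage1))
    k <- NA_integer_
    thr <- gw
    hit <- p_below(stage1[[pcol]], gw)
  }

  decisions <- data.frame(SNP = stage1$SNP,
                          STATUS = ifelse(hit, "discovered", "failed"),
                          stringsAsFactors = FALSE)

  if (design == "combined") {
    decisions$STATUS[hit] <- "identified"
    thresholds <- c(genomewide = gw, bonferroni = if (approach ==
      "overall+difference") thr else NA_real_)
    k_out <- if (approach == "overall+difference") k else sum(hit)
  } else {
    if (is.null(stage2)) stop("stage2 results required for discovery+replication",
                              call. = FALSE)
    followed <- decisions$SNP[hit]
    k2 <- length(followed)
    thr2 <- if (k2 > 0) bonferroni_threshold(k2, alpha) else NA_real_
    for (snp in followed) {
      i2 <- match(snp, stage2$SNP)
      i1 <- match(snp, stage1$SNP)
      if (is.na(i2)) {
        decisions$STATUS[i1] <- "non-assessable"
        next
      }
      rep_ok <- if (approach %in% c("difference", "overall+difference")) {
        sgn <- sign(stage1$Z_DIFF[i1])
        p1 <- p_one_sided(stage2$Z_DIFF[i2], sgn)
        p_below(p1$log10p, thr2)
      } else {
        p_below(stage2[[pcol]][i2], thr2)
      }
      decisions$STATUS[i1] <- if (rep_ok) "replicated" else "failed"
    }
    thresholds <- c(genomewide = gw, bonferroni = thr2)
    k_out <- k2
  }

  out <- list(approach = approach, design = design, k = k_out,
              thresholds = thresholds, decisions = decisions)
  class(out) <- "design_outcome"
  out
}

#' @export
print.design_outcome <- function(x, ...) {
  cat("design_outcome:", x$approach, "/", x$design, "\n")
  cat("  k =", x$k, "| thresholds:",
      paste(names(x$thresholds), signif(x$thresholds, 3), sep = "=",
            collapse = ", "), "\n")
  print(table(x$decisions$STATUS))
  invisible(x)
}
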