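#' Genome-wide cross-stratum effect correlation (r_diab analogue)
#'
#' Spearman rank correlation between the DM and noDM effect estimates across
#' all QC-passing variants. A shared polygenic background makes this
#' positive even though the two strata are disjoint samples; it enters the
#' denominator of the difference test. The estimate is clamped to
#' [-0.99, 0.99] before use so the denominator stays positive.
#'
#' @param beta_dm,beta_nodm aligned numeric vectors of per-variant effects.
#' @return the clamped Spearman correlation.
#' @export
estimate_r_diab <- function(beta_dm, beta_nodm) {
  stopifnot(length(beta_dm) == length(beta_nodm))
  if (length(beta_dm) < 10) stop("need at least 10 variants", call. = FALSE)
  if (stats::sd(beta_dm) == 0 || stats::sd(beta_nodm) == 0) {
    stop("correlation undefined for a constant effect vector", call. = FALSE)
  }
  r <- stats::cor(beta_dm, beta_nodm, method = "spearman")
  max(-0.99, min(0.99, r))
}

#' Cross-stratum difference test
#'
#' Tests whether a variant's effect differs between the DM and noDM strata:
#' \deqn{Z_{diff} = (\hat\beta_{DM} - \hat\beta_{noDM}) /
#'   \sqrt{se_{DM}^2 + se_{noDM}^2 - 2 r\, se_{DM} se_{noDM}}}
#' where r is the genome-wide cross-stratum effect correlation
#' ([estimate_r_diab()]). With r = 0 this is the standard two-sample z-test.
#' The statistic is equivalent to a SNP-by-DM-status interaction test.
#'
#' @param beta_dm,se_dm,beta_nodm,se_nodm stratum estimates (vectors).
#' @param r cross-stratum effect correlation, |r| < 1.
#' @param sign_ref optional reference direction (+1/-1, e.g. the stage-1
#'   difference sign) for a one-sided replication p-value.
#' @return data.frame with Z_DIFF, P_DIFF, LOG10P_DIFF and, when `sign_ref`
#'   is given, P_DIFF_1S, LOG10P_DIFF_1S.
#' @export
difference_test <- function(beta_dm, se_dm, beta_nodm, se_nodm, r = 0,
                            sign_ref = NULL) {
  stopifnot(all(se_dm > 0), all(se_nodm > 0), abs(r) < 1)
  if (r == 0) {
    denom2 <- se_dm^2 + se_nodm^2
  } else {
    denom2 <- se_dm^2 + se_nodm^2 - 2 * r * se_dm * se_nodm
  }
  if (any(denom2 <= 0)) {
    stop("non-positive variance of the stratum difference (|r| too close to 1)",
         call. = FALSE)
  }
  z <- (beta_dm - beta_nodm) / sqrt(denom2)
  pv <- p_two_sided(z)
  out <- data.frame(Z_DIFF = z, P_DIFF = pv$p, LOG10P_DIFF = pv$log10p)
  if (!is.null(sign_ref)) {
    p1 <- p_one_sided(z, sign_ref)
    out$P_DIFF_1S <- p1$p
    out$LOG10P_DIFF_1S <- p1$log10p
  }
  out
}

#' Two-degree-of-freedom joint test
#'
#' Combines the two stratum z-statistics into
#' C = (beta_DM/se_DM)^2 + (beta_noDM/se_noDM)^2, referred to a chi-square
#' distribution with 2 df (survival function exp(-C/2)). Sensitive to
#' association in either or both strata.
#'
#' @param beta_dm,se_dm,beta_nodm,se_nodm stratum estimates (vectors).
#' @return data.frame with C_JOINT, P_JOINT, LOG10P_JOINT.
#' @export
joint_test <- function(beta_dm, se_dm, beta_nodm, se_nodm) {
  stopifnot(all(se_dm > 0), all(se_nodm > 0))
  c_joint <- (beta_dm / se_dm)^2 + (beta_nodm / se_nodm)^2
  pv <- p_chisq(c_joint, df = 2)
  data.frame(C_JOINT = c_joint, P_JOINT = pv$p, LOG10P_JOINT = pv$log10p)
}

#' Overall (stratum-combined) association test
#'
#' Reconstructs the all-individuals association by inverse-variance
#' weighting of the two stratum estimates, treating them as independent
#' (the strata are disjoint individuals).
#'
#' @param beta_dm,se_dm,beta_nodm,se_nodm stratum estimates (vectors).
#' @return data.frame with BETA_OVR, SE_OVR, P_OVR, LOG10P_OVR.
#' @export
overall_test <- function(beta_dm, se_dm, beta_nodm, se_nodm) {
  stopifnot(all(se_dm > 0), all(se_nodm > 0))
  w1 <- 1 / se_dm^2
  w2 <- 1 / se_nodm^2
  beta <- (w1 * beta_dm + w2 * beta_nodm) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  pv <- p_two_sided(beta / se)
  data.frame(BETA_OVR = beta, SE_OVR = se, P_OVR = pv$p, LOG10P_OVR = pv$log10p)
}

#' Pair stratum meta-analyses into stratified test results
#'
#' Merges the DM and noDM meta-analysis tables by variant (inner join),
#' estimates r_diab (unless supplied), and computes the difference, joint
#' and overall statistics for every variant.
#'
#' @param meta_dm,meta_nodm per-stratum meta-analysis data.frames.
#' @param r_diab optional fixed cross-stratum correlation; estimated from
#'   all merged variants when NULL.
#' @return data.frame with SNP, CHR, POS, EA, OA, BETA_DM, SE_DM, P_DM,
#'   LOG10P_DM, the noDM analogues, Z_DIFF/P_DIFF, C_JOINT/P_JOINT,
#'   BETA_OVR/SE_OVR/P_OVR and their LOG10P companions; attribute `r_diab`.
#' @export
stratified_results <- function(meta_dm, meta_nodm, r_diab = NULL) {
  dm <- meta_dm[, c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P",
                    "LOG10P", "N")]
  nd <- meta_nodm[, c("SNP", "BETA", "SE", "P", "LOG10P", "N")]
  names(dm) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF_DM", "BETA_DM", "SE_DM",
                 "P_DM", "LOG10P_DM", "N_DM")
  names(nd) <- c("SNP", "BETA_NODM", "SE_NODM", "P_NODM", "LOG10P_NODM",
                 "N_NODM")
  res <- merge(dm, nd, by = "SNP", sort = FALSE)
  if (is.null(r_diab)) r_diab <- estimate_r_diab(res$BETA_DM, res$BETA_NODM)
  res <- cbind(
    res,
    difference_test(res$BETA_DM, res$SE_DM, res$BETA_NODM, res$SE_NODM, r_diab),
    joint_test(res$BETA_DM, res$SE_DM, res$BETA_NODM, res$SE_NODM),
    overall_test(res$BETA_DM, res$SE_DM, res$BETA_NODM, res$SE_NODM)
  )
  res <- res[order(res$CHR, res$POS), ]
  rownames(res) <- NULL
  attr(res, "r_diab") <- r_diab
  res
}

#' Classify the DM/noDM specificity of an identified variant
#'
#' Codifies the narrative reading used for identified difference loci:
#' with an established (or suggestive) difference, a variant is "DM-only"
#' when it passes the identifying significance threshold in DM while being
#' null in noDM (p > 0.05), symmetrically "noDM-only"; when both strata are
#' at least nominally significant the larger |beta| decides
#' "stronger-in-DM" / "stronger-in-noDM"; without a significant difference
#' the effect is "shared".
#'
#' @param beta_dm,p_dm,beta_nodm,p_nodm stratum estimates and p-values.
#' @param diff_significant logical: is the cross-stratum difference
#'   established (or suggestive) for this variant?
#' @param id_threshold identifying significance threshold (default 5e-8).
#' @return character vector of labels.
#' @export
classify_specificity <- function(beta_dm, p_dm, beta_nodm, p_nodm,
                                 diff_significant, id_threshold = 5e-8) {
  n <- length(beta_dm)
  lab <- rep("shared", n)
  dm_only <- diff_significant & p_dm <= id_threshold & p_nodm > 0.05
  nodm_only <- diff_significant & p_nodm <= id_threshold & p_dm > 0.05
  rest <- diff_significant & !dm_only & !nodm_only
  lab[rest] <- ifelse(abs(beta_dm[rest]) >= abs(beta_nodm[rest]),
                      "stronger-in-DM", "stronger-in-noDM")
  lab[dm_only] <- "DM-only"
  lab[nodm_only] <- "noDM-only"
  lab
}
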