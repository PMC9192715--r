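#' Approximate conditional analysis from summary statistics
#'
#' Reconstructs, for each target variant in a locus, the multiple-regression
#' (joint) estimate conditional on a set of conditioning variants, using
#' only marginal summary statistics plus an LD reference — the standard
#' summary-statistics conditional formulation. The reconstruction, written
#' out for variant set S = {target} U conditioning set:
#' \itemize{
#' \item X'X over S is rebuilt as sqrt(D_j D_k) r_jk, where r_jk is the
#'   reference LD correlation and D_j the centered genotype sum of squares:
#'   taken directly from the reference panel (`scale = "sample"`, exact when
#'   the reference is the analysis cohort) or as 2 n_j eaf_j (1 - eaf_j)
#'   under HWE (`scale = "hwe"`).
#' \item X'y is recovered from each marginal fit: X'y_j = D_j beta_j.
#' \item the phenotypic sum of squares y'y is implied by each marginal
#'   regression, y'y_j = D_j (beta_j^2 + (n-2) se_j^2); the median across
#'   the locus is used.
#' \item joint estimates solve X'X b = X'y; the residual variance is
#'   (y'y - b' X'y)/(n - |S| - 1) and conditional p-values use the t
#'   distribution with those df, matching an individual-level OLS fit.
#' }
#' Targets whose LD R-squared with the conditioning set is >= `collinear`
#' are marked not estimable (ESTIMABLE = FALSE, estimates NA).
#'
#' @param records marginal meta-analysis records for the locus (one
#'   stratum): data.frame with SNP, BETA, SE, N, EAF.
#' @param ldref an [ld_reference()] containing all involved variants.
#' @param condition_on character vector of conditioning variant ids.
#' @param scale "sample" (reference moments) or "hwe" (2 n p (1-p)).
#' @param collinear collinearity guard on the target-vs-conditioning-set
#'   R-squared (default 0.9).
#' @return data.frame with SNP, BETA_COND, SE_COND, P_COND, LOG10P_COND,
#'   ESTIMABLE for every record not in the conditioning set.
#' @export
conditional_analysis <- function(records, ldref, condition_on,
                                 scale = c("sample", "hwe"),
                                 collinear = 0.9) {
  scale <- match.arg(scale)
  stopifnot(inherits(ldref, "ld_reference"),
            all(c("SNP", "BETA", "SE", "N", "EAF") %in% names(records)))
  if (!all(condition_on %in% records$SNP)) {
    stop("conditioning variants must be present in the locus records",
         call. = FALSE)
  }
  if (!all(records$SNP %in% ldref$ids)) {
    stop("locus variants missing from the LD reference: ",
         paste(setdiff(records$SNP, ldref$ids), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(records$SNP, ldref$ids)
  R <- ld_submatrix(ldref, idx)
  n <- stats::median(records$N)
  D <- switch(scale,
    sample = ldref$ss[idx] * (n / ldref$n),
    hwe = 2 * records$N * records$EAF * (1 - records$EAF)
  )
  if (any(D <= 0)) stop("monomorphic variant in locus", call. = FALSE)
  sxy <- D * records$BETA
  yy <- stats::median(D * (records$BETA^2 + (records$N - 2) * records$SE^2))

  ci <- match(condition_on, records$SNP)
  Rcc <- R[ci, ci, drop = FALSE]
  if (rcond(Rcc) < 1e-12) {
    stop("singular LD submatrix among conditioning variants: ",
         paste(condition_on, collapse = ", "), call. = FALSE)
  }
  Rcc_inv <- solve(Rcc)

  targets <- setdiff(seq_len(nrow(records)), ci)
  out <- data.frame(SNP = records$SNP[targets],
                    BETA_COND = NA_real_, SE_COND = NA_real_,
                    P_COND = NA_real_, LOG10P_COND = NA_real_,
                    ESTIMABLE = TRUE, stringsAsFactors = FALSE)
  sqD <- sqrt(D)
  for (k in seq_along(targets)) {
    t <- targets[k]
    r_tc <- R[t, ci]
    r2_set <- drop(r_tc %*% Rcc_inv %*% r_tc)
    if (r2_set >= collinear) {
      out$ESTIMABLE[k] <- FALSE
      next
    }
    S <- c(t, ci)
    XtX <- R[S, S] * outer(sqD[S], sqD[S])
    b <- solve(XtX, sxy[S])
    p_model <- length(S)
    dfres <- n - p_model - 1
    sigma2 <- max(yy - sum(b * sxy[S]), 0) / dfres
    v <- sigma2 * solve(XtX)[1, 1]
    out$BETA_COND[k] <- b[1]
    out$SE_COND[k] <- sqrt(v)
    pv <- p_two_sided_t(b[1] / sqrt(v), dfres)
    out$P_COND[k] <- pv$p
    out$LOG10P_COND[k] <- pv$log10p
  }
  attr(out, "condition_on") <- condition_on
  out
}

#' Stepwise search for independent secondary signals in a locus
#'
#' Starting from the locus lead variant, repeatedly conditions the locus on
#' the current signal set (separately in the DM and noDM strata) and
#' declares a new independent signal when any conditioned test remains
#' genome-wide significant, up to `max_signals` signals. The conditioned
#' test matches the test that identified the locus: stratified
#' (P_DM_cond or P_noDM_cond), difference, or joint, the latter two
#' recomputed from the paired conditioned stratum estimates.
#'
#' @param records_dm,records_nodm locus records per stratum (SNP, BETA, SE,
#'   N, EAF), variant-aligned.
#' @param ldref an [ld_reference()].
#' @param lead lead variant id.
#' @param test identifying test: "stratified", "difference" or "joint".
#' @param r_diab cross-stratum effect correlation for the difference test.
#' @param gw genome-wide threshold for conditioned significance.
#' @param max_signals cap on the number of signals (default 5).
#' @param scale passed to [conditional_analysis()].
#' @return character vector of signal lead variants (first element is
#'   `lead`).
#' @export
find_secondary_signals <- function(records_dm, records_nodm, ldref, lead,
                                   test = c("stratified", "difference",
                                            "joint"),
                                   r_diab = 0, gw = 5e-8, max_signals = 5,
                                   scale = c("sample", "hwe")) {
  test <- match.arg(test)
  scale <- match.arg(scale)
  stopifnot(identical(records_dm$SNP, records_nodm$SNP), lead %in% records_dm$SNP)
  signals <- lead
  while (length(signals) < max_signals) {
    cd <- conditional_analysis(records_dm, ldref, signals, scale = scale)
    cn <- conditional_analysis(records_nodm, ldref, signals, scale = scale)
    ok <- cd$ESTIMABLE & cn$ESTIMABLE & is.finite(cd$SE_COND) &
      is.finite(cn$SE_COND) & cd$SE_COND > 0 & cn$SE_COND > 0
    if (!any(ok)) break
    log10p <- rep(-Inf, nrow(cd))
    if (test == "stratified") {
      log10p[ok] <- pmax(cd$LOG10P_COND[ok], cn$LOG10P_COND[ok])
    } else if (test == "difference") {
      dt <- difference_test(cd$BETA_COND[ok], cd$SE_COND[ok],
                            cn$BETA_COND[ok], cn$SE_COND[ok], r_diab)
      log10p[ok] <- dt$LOG10P_DIFF
    } else {
      jt <- joint_test(cd$BETA_COND[ok], cd$SE_COND[ok],
                       cn$BETA_COND[ok], cn$SE_COND[ok])
      log10p[ok] <- jt$LOG10P_JOINT
    }
    best <- which.max(log10p)
    if (!p_below(log10p[best], gw)) break
    signals <- c(signals, cd$SNP[best])
  }
  signals
}
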