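#' Build weighting schemes for the genetic risk score
#'
#' From a stage-1 effect table (overall, DM-specific and noDM-specific
#' per-variant effects plus a flag for variants with identified
#' DM/noDM-difference) builds the four weighting schemes evaluated in the
#' GRS analyses: weights by overall effects, by DM-specific effects, by
#' noDM-specific effects, and a hybrid using stratum-specific effects at
#' flagged variants and overall effects otherwise. Weights are magnitudes
#' aligned to the eGFR-lowering allele, re-derived per scheme: if the
#' scheme's beta for the reported effect allele is negative that allele is
#' the lowering allele and the weight is |beta|; otherwise the other allele
#' is lowering.
#'
#' @param tab data.frame with VARIANT, EA, OA, BETA_OVERALL, BETA_DM,
#'   BETA_NODM, DIFF_FLAG (logical).
#' @param source_cohort optional label of the cohort(s) the weights were
#'   estimated in; propagated so evaluation can enforce stage separation.
#' @return named list of schemes `overall`, `dm`, `nodm` (each a weights
#'   data.frame VARIANT, EA_LOWERING, W) and `hybrid` (list with `dm` and
#'   `nodm` weights data.frames, one per evaluation stratum).
#' @export
weight_schemes <- function(tab, source_cohort = NULL) {
  need <- c("VARIANT", "EA", "OA", "BETA_OVERALL", "BETA_DM", "BETA_NODM",
            "DIFF_FLAG")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$DIFF_FLAG & (is.na(tab$BETA_DM) | is.na(tab$BETA_NODM)))) {
    stop("variant flagged for difference but missing stratum-specific effect",
         call. = FALSE)
  }
  align <- function(beta) {
    lowering <- ifelse(beta < 0, tab$EA, tab$OA)
    w <- data.frame(VARIANT = tab$VARIANT, EA_LOWERING = lowering,
                    W = abs(beta), stringsAsFactors = FALSE)
    attr(w, "source_cohort") <- source_cohort
    w
  }
  hybrid_beta <- function(stratum_beta) {
    ifelse(tab$DIFF_FLAG, stratum_beta, tab$BETA_OVERALL)
  }
  list(
    overall = align(tab$BETA_OVERALL),
    dm = align(tab$BETA_DM),
    nodm = align(tab$BETA_NODM),
    hybrid = list(dm = align(hybrid_beta(tab$BETA_DM)),
                  nodm = align(hybrid_beta(tab$BETA_NODM)))
  )
}

#' Per-individual weighted genetic risk score
#'
#' score_i = sum_v w_v d_iv after aligning dosages to the eGFR-lowering
#' allele (d -> 2 - d where the panel's effect allele is not the lowering
#' allele). Weight-file variants absent from the panel are excluded; the
#' covered fraction is attached as attribute `coverage`. When both the
#' panel's `cohort` and the weights' `source_cohort` are known and equal,
#' evaluation is refused unless `allow_in_sample = TRUE` (the GRS must be
#' evaluated in data independent of the weight-estimating stage).
#'
#' @param dosage individuals x variants matrix, columns named by variant.
#' @param panel_variants data.frame with SNP and EA giving the dosage-coded
#'   allele per panel variant.
#' @param weights weights data.frame (VARIANT, EA_LOWERING, W >= 0).
#' @param cohort optional label of the evaluation cohort.
#' @param allow_in_sample override the stage-separation refusal.
#' @return numeric score vector with attribute `coverage`.
#' @export
build_grs <- function(dosage, panel_variants, weights, cohort = NULL,
                      allow_in_sample = FALSE) {
  stopifnot(all(c("VARIANT", "EA_LOWERING", "W") %in% names(weights)),
            all(weights$W >= 0))
  src <- attr(weights, "source_cohort")
  if (!is.null(src) && !is.null(cohort) && identical(src, cohort) &&
      !allow_in_sample) {
    stop("refusing to evaluate a GRS on the cohort that estimated its ",
         "weights (set allow_in_sample = TRUE to override)", call. = FALSE)
  }
  idx <- match(weights$VARIANT, panel_variants$SNP)
  present <- !is.na(idx)
  if (!all(present)) {
    message(sum(!present), " weight variants missing from panel; coverage ",
            round(mean(present), 3))
  }
  w <- weights[present, , drop = FALSE]
  cols <- idx[present]
  d <- dosage[, cols, drop = FALSE]
  flip <- panel_variants$EA[cols] != w$EA_LOWERING
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  score <- drop(d %*% w$W)
  attr(score, "coverage") <- mean(present)
  score
}

#' GRS association with eGFR within a stratum
#'
#' OLS of eGFR (original scale, ml/min/1.73 m^2, not log) on the
#' standardized GRS plus covariates, restricted to the stratum mask. The
#' GRS is divided by `sd_ref` (default: SD over the full evaluation sample,
#' so per-SD effects are comparable across strata). Incremental R-squared
#' is R2(full) - R2(covariates only).
#'
#' @param score GRS vector (all individuals).
#' @param egfr eGFR vector in ml/min/1.73 m^2.
#' @param covariates data.frame of covariates (may have zero columns).
#' @param mask logical stratum indicator.
#' @param sd_ref standardizing SD (default sd of `score` over all
#'   individuals).
#' @return one-row data.frame: BETA_SD, SE, P, LOG10P, R2_INCR, N.
#' @export
grs_association <- function(score, egfr, covariates, mask,
                            sd_ref = stats::sd(score)) {
  stopifnot(length(score) == length(egfr), length(mask) == length(score))
  n <- sum(mask)
  if (n <= ncol(covariates) + 3) stop("stratum too small", call. = FALSE)
  if (!is.finite(sd_ref) || sd_ref <= 0 ||
      stats::sd(score[mask]) == 0) {
    stop("GRS has zero variance: association undefined", call. = FALSE)
  }
  dat <- data.frame(egfr = egfr[mask], grs_sd = score[mask] / sd_ref)
  cov <- covariates[mask, , drop = FALSE]
  for (j in seq_len(ncol(cov))) {
    v <- cov[[j]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    dat[[names(cov)[j]]] <- v
  }
  full <- stats::lm(egfr ~ ., data = dat)
  base <- stats::lm(egfr ~ ., data = dat[, setdiff(names(dat), "grs_sd"),
                                         drop = FALSE])
  sm <- summary(full)
  co <- sm$coefficients["grs_sd", ]
  pv <- p_two_sided_t(co["t value"], full$df.residual)
  data.frame(BETA_SD = unname(co["Estimate"]), SE = unname(co["Std. Error"]),
             P = pv$p, LOG10P = pv$log10p,
             R2_INCR = sm$r.squared - summary(base)$r.squared, N = n)
}

#' Cross-stratum difference in the GRS effect
#'
#' The DM and noDM strata are disjoint individuals, so the two GRS effect
#' estimates are independent: z = (bDM - bnoDM)/sqrt(seDM^2 + senoDM^2),
#' two-sided p.
#'
#' @param report_dm,report_nodm one-row data.frames from
#'   [grs_association()].
#' @return data.frame with Z, P, LOG10P.
#' @export
grs_difference <- function(report_dm, report_nodm) {
  z <- (report_dm$BETA_SD - report_nodm$BETA_SD) /
    sqrt(report_dm$SE^2 + report_nodm$SE^2)
  pv <- p_two_sided(z)
  data.frame(Z = z, P = pv$p, LOG10P = pv$log10p)
}
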