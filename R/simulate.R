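#' Configuration for a simulated multi-study stratified cohort
#'
#' Describes the study conditions emulated by the generator: several studies
#' of equal size, biallelic variants in LD blocks, a diabetes (DM) stratum of
#' realistic prevalence, a shared polygenic background on log-eGFR that
#' induces a positive cross-stratum effect correlation, and optional planted
#' variant effects that may differ between the DM and noDM strata.
#'
#' @param n_studies number of studies.
#' @param n_per_study individuals per study.
#' @param n_variants number of biallelic variants.
#' @param maf_range range of minor allele frequencies, within (0, 0.5].
#' @param ld_block_size variants per LD block.
#' @param ld_rho adjacent-variant latent correlation within a block, in [0,1).
#' @param dm_prevalence probability of DM, in (0,1).
#' @param effect_table data.frame with columns `variant` (index),
#'   `beta_dm`, `beta_nodm`: planted per-allele effects on log-eGFR.
#' @param polygenic_h2_shared fraction of phenotypic variance (relative to
#'   residual + polygenic) explained by a polygenic background shared between
#'   strata, in [0,1).
#' @param residual_sd_logegfr residual SD of log-eGFR.
#' @param dm_genotype_dependent if TRUE, DM probability depends on the first
#'   variant's dosage (robustness switch; default FALSE, strata independent
#'   of genotype).
#' @param seed integer seed; the full panel is deterministic given the config.
#' @param variant_seed seed for the variant metadata (ids, positions, alleles,
#'   population MAFs, Info); defaults to `seed`. Supplying the same
#'   `variant_seed` with a different `seed` simulates an independent cohort
#'   genotyped on the same variants — e.g. a stage-2 replication study.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 3,
                       n_per_study = 5000,
                       n_variants = 2000,
                       maf_range = c(0.01, 0.5),
                       ld_block_size = 20,
                       ld_rho = 0.4,
                       dm_prevalence = 0.12,
                       effect_table = NULL,
                       polygenic_h2_shared = 0.15,
                       residual_sd_logegfr = 0.25,
                       dm_genotype_dependent = FALSE,
                       seed = 1L,
                       variant_seed = NULL) {
  stopifnot(
    n_studies >= 1, n_per_study >= 10, n_variants >= 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
    dm_prevalence > 0, dm_prevalence < 1,
    polygenic_h2_shared >= 0, polygenic_h2_shared < 1,
    residual_sd_logegfr > 0
  )
  if (!is.null(effect_table)) {
    stopifnot(is.data.frame(effect_table),
              all(c("variant", "beta_dm", "beta_nodm") %in% names(effect_table)))
    if (any(effect_table$variant < 1 | effect_table$variant > n_variants)) {
      stop("effect_table variant indices out of range", call. = FALSE)
    }
  }
  cfg <- list(
    n_studies = as.integer(n_studies), n_per_study = as.integer(n_per_study),
    n_variants = as.integer(n_variants), maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    dm_prevalence = dm_prevalence, effect_table = effect_table,
    polygenic_h2_shared = polygenic_h2_shared,
    residual_sd_logegfr = residual_sd_logegfr,
    dm_genotype_dependent = isTRUE(dm_genotype_dependent),
    seed = as.integer(seed),
    variant_seed = as.integer(if (is.null(variant_seed)) seed else variant_seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_studies, "studies x", x$n_per_study, "individuals,",
      x$n_variants, "variants\n")
  cat("  DM prevalence", x$dm_prevalence,
      "| shared polygenic h2", x$polygenic_h2_shared,
      "| residual SD(log eGFR)", x$residual_sd_logegfr, "\n")
  cat("  planted effects:", if (is.null(x$effect_table)) 0 else nrow(x$effect_table), "\n")
  invisible(x)
}

# Variant metadata is drawn once per config so all studies share the same
# variants, alleles and population MAFs. Positions are laid out on up to 22
# chromosomes at 25 kb spacing.
variant_frame <- function(config) {
  withr_seed(config$variant_seed, {
    m <- config$n_variants
    n_chr <- min(22L, m)
    per_chr <- ceiling(m / n_chr)
    chr <- ((seq_len(m) - 1L) %/% per_chr) + 1L
    idx_in_chr <- stats::ave(seq_len(m), chr, FUN = seq_along)
    pos <- 1000000L + (idx_in_chr - 1L) * 25000L
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    alleles <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    info <- stats::rbeta(m, 18, 2)  # imputation quality; exercises Info < 0.6 QC
    data.frame(
      SNP = sprintf("rs%06d", seq_len(m)), CHR = chr, POS = pos,
      EA = alleles[, 1], OA = alleles[, 2], MAF = maf, INFO = info,
      stringsAsFactors = FALSE
    )
  })
}

# run expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# dosages via a block-diagonal Gaussian copula: latent AR(1) normals within
# each LD block, thresholded through binomial(2, maf) quantiles so each
# variant has the right marginal frequency while adjacent variants in a
# block are correlated.
simulate_dosages <- function(n, variants, ld_block_size, ld_rho) {
  m <- nrow(variants)
  z <- matrix(0, n, m)
  for (j in seq_len(m)) {
    new_block <- ((j - 1L) %% ld_block_size == 0L) ||
      (j > 1L && variants$CHR[j] != variants$CHR[j - 1L])
    e <- stats::rnorm(n)
    z[, j] <- if (new_block || ld_rho == 0) e
              else ld_rho * z[, j - 1L] + sqrt(1 - ld_rho^2) * e
  }
  u <- stats::pnorm(z)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) dos[, j] <- stats::qbinom(u[, j], 2L, variants$MAF[j])
  dos
}

#' Simulate one study's cohort panel
#'
#' Generates genotype dosages, DM status, age/sex covariates and a
#' log-eGFR phenotype. The phenotype is specified directly on the analysed
#' scale (log eGFR): intercept + planted stratum-specific variant effects +
#' shared polygenic background + Gaussian noise; serum creatinine is then
#' obtained by inverting the CKD-EPI equation at that target eGFR, and the
#' stored phenotype is `winsorize_log_egfr(ckdepi_egfr(creatinine, ...))`,
#' i.e. exactly the convention applied to real cohorts.
#'
#' @param config a [sim_config()] object.
#' @param study study index in `1:config$n_studies`.
#' @return an object of class `cohort_panel`: list with `dosage`
#'   (individuals x variants integer matrix), `variants` (metadata
#'   data.frame with per-study EAF), `pheno` (creatinine, age, sex, dm,
#'   log_egfr), `study`, and the generating `config`.
#' @export
simulate_panel <- function(config, study = 1L) {
  stopifnot(inherits(config, "sim_config"), study >= 1, study <= config$n_studies)
  variants <- variant_frame(config)
  seed_s <- (config$seed + 77003L * as.integer(study)) %% .Machine$integer.max
  withr_seed(seed_s, {
    n <- config$n_per_study
    dos <- simulate_dosages(n, variants, config$ld_block_size, config$ld_rho)

    # shared polygenic background: per-variant effects common to both strata,
    # scaled so the background variance is h2/(1-h2) of the residual variance
    g_shared <- numeric(n)
    bg_beta <- rep(0, nrow(variants))
    if (config$polygenic_h2_shared > 0) {
      target_var <- config$polygenic_h2_shared / (1 - config$polygenic_h2_shared) *
        config$residual_sd_logegfr^2
      exp_var <- sum(2 * variants$MAF * (1 - variants$MAF))
      bg_beta <- stats::rnorm(nrow(variants), 0, sqrt(target_var / exp_var))
      g_shared <- drop(dos %*% bg_beta)
    }

    if (config$dm_genotype_dependent) {
      # logit shift by first variant's dosage, centered to keep prevalence
      lo <- stats::qlogis(config$dm_prevalence) + 0.3 * (dos[, 1] - 2 * variants$MAF[1])
      dm <- stats::rbinom(n, 1L, stats::plogis(lo))
    } else {
      dm <- stats::rbinom(n, 1L, config$dm_prevalence)
    }

    planted <- numeric(n)
    if (!is.null(config$effect_table)) {
      for (k in seq_len(nrow(config$effect_table))) {
        v <- config$effect_table$variant[k]
        b <- ifelse(dm == 1L, config$effect_table$beta_dm[k],
                    config$effect_table$beta_nodm[k])
        planted <- planted + b * dos[, v]
      }
    }

    age <- sample(30:79, n, replace = TRUE)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    mu <- log(90) - 0.004 * (age - 55)  # mild age trend beyond the CKD-EPI age term
    y_target <- mu + planted + g_shared + stats::rnorm(n, 0, config$residual_sd_logegfr)
    egfr_target <- exp(y_target)
    scr <- ckdepi_invert(egfr_target, age, sex)
    log_egfr <- winsorize_log_egfr(ckdepi_egfr(scr, age, sex))

    variants$EAF <- colMeans(dos) / 2
    panel <- list(
      dosage = dos,
      variants = variants,
      pheno = data.frame(creatinine = scr, age = age, sex = sex,
                         dm = dm, log_egfr = log_egfr,
                         stringsAsFactors = FALSE),
      study = as.integer(study),
      config = config,
      background_beta = bg_beta
    )
    class(panel) <- "cohort_panel"
    panel
  })
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("cohort_panel: study", x$study, "-", nrow(x$dosage), "individuals,",
      ncol(x$dosage), "variants,", sum(x$pheno$dm), "with DM\n")
  invisible(x)
}

#' Per-stratum single-variant GWAS on log eGFR
#'
#' Runs, within the requested stratum, one linear regression of log eGFR per
#' variant under an additive genotype model, adjusted for the given
#' covariates. Covariates are projected out of phenotype and genotypes
#' (Frisch-Waugh), so estimates are exactly those of the full OLS fit.
#' Monomorphic variants in the stratum are excluded and listed in the
#' `monomorphic` attribute.
#'
#' @param panel a [simulate_panel()] result.
#' @param stratum "DM" or "noDM".
#' @param covariates character vector of columns of `panel$pheno` to adjust
#'   for (default age and sex).
#' @return data.frame with columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P,
#'   LOG10P, N, INFO (one row per polymorphic variant).
#' @export
run_stratified_gwas <- function(panel, stratum = c("DM", "noDM"),
                                covariates = c("age", "sex")) {
  stopifnot(inherits(panel, "cohort_panel"))
  stratum <- match.arg(stratum)
  mask <- if (stratum == "DM") panel$pheno$dm == 1L else panel$pheno$dm == 0L
  n <- sum(mask)
  if (n < length(covariates) + 3) {
    stop("stratum too small for the requested covariate adjustment", call. = FALSE)
  }
  y <- panel$pheno$log_egfr[mask]
  X <- panel$dosage[mask, , drop = FALSE]

  covmat <- cbind(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    v <- panel$pheno[[cv]][mask]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    covmat <- cbind(covmat, v)
  }
  qrc <- qr(covmat)
  y_r <- qr.resid(qrc, y)
  X_r <- qr.resid(qrc, X)

  sxx <- colSums(X_r^2)
  mono <- sxx < 1e-12
  sxy <- colSums(X_r * y_r)
  syy <- sum(y_r^2)
  beta <- sxy / sxx
  df <- n - ncol(covmat) - 1L
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  pv <- p_two_sided_t(tval, df)

  out <- data.frame(
    SNP = panel$variants$SNP, CHR = panel$variants$CHR, POS = panel$variants$POS,
    EA = panel$variants$EA, OA = panel$variants$OA,
    EAF = colMeans(X) / 2,
    BETA = beta, SE = se, P = pv$p, LOG10P = pv$log10p,
    N = n, INFO = panel$variants$INFO,
    stringsAsFactors = FALSE
  )
  keep <- !mono & is.finite(out$SE)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "monomorphic") <- out$SNP[!keep]
  attr(res, "stratum") <- stratum
  res
}
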