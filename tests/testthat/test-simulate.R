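test_that("panel generation is deterministic given the config seed", {
  cfg <- sim_config(n_studies = 2, n_per_study = 300, n_variants = 40, seed = 11)
  p1 <- simulate_panel(cfg, study = 1)
  p2 <- simulate_panel(cfg, study = 1)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$pheno, p2$pheno)
  # different studies share variants but not genotypes
  q <- simulate_panel(cfg, study = 2)
  expect_identical(p1$variants$SNP, q$variants$SNP)
  expect_false(identical(p1$dosage, q$dosage))
})

test_that("variant_seed pins the genome across independently seeded cohorts", {
  c1 <- sim_config(n_studies = 1, n_per_study = 100, n_variants = 25, seed = 1)
  c2 <- sim_config(n_studies = 1, n_per_study = 100, n_variants = 25,
                   seed = 999, variant_seed = 1)
  p1 <- simulate_panel(c1)
  p2 <- simulate_panel(c2)
  cols <- c("SNP", "CHR", "POS", "EA", "OA", "MAF", "INFO")
  expect_identical(p1$variants[, cols], p2$variants[, cols])
  expect_false(identical(p1$dosage, p2$dosage))
})

test_that("panel invariants hold: EAF, phenotype bounds, DM prevalence", {
  cfg <- sim_config(n_studies = 1, n_per_study = 4000, n_variants = 60,
                    dm_prevalence = 0.12, seed = 5)
  p <- simulate_panel(cfg)
  expect_equal(p$variants$EAF, colMeans(p$dosage) / 2)
  expect_true(all(p$pheno$log_egfr >= log(15) & p$pheno$log_egfr <= log(200)))
  prev <- mean(p$pheno$dm)
  expect_lt(abs(prev - 0.12), 4 * sqrt(0.12 * 0.88 / 4000))
})

test_that("null panel has equal stratum phenotype means", {
  cfg <- sim_config(n_studies = 1, n_per_study = 6000, n_variants = 30,
                    polygenic_h2_shared = 0, seed = 7)
  p <- simulate_panel(cfg)
  a <- p$pheno$log_egfr[p$pheno$dm == 1]
  b <- p$pheno$log_egfr[p$pheno$dm == 0]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("stratified GWAS recovers a planted DM-specific effect", {
  eff <- data.frame(variant = 3, beta_dm = -0.02, beta_nodm = 0)
  cfg <- sim_config(n_studies = 1, n_per_study = 20000, n_variants = 10,
                    dm_prevalence = 0.5, effect_table = eff,
                    polygenic_h2_shared = 0, ld_rho = 0, seed = 9)
  p <- simulate_panel(cfg)
  gdm <- run_stratified_gwas(p, "DM")
  gnd <- run_stratified_gwas(p, "noDM")
  i <- match(p$variants$SNP[3], gdm$SNP)
  expect_lt(abs(gdm$BETA[i] - (-0.02)), 2 * gdm$SE[i])
  j <- match(p$variants$SNP[3], gnd$SNP)
  expect_lt(abs(gnd$BETA[j]), 3 * gnd$SE[j])
})

test_that("stratified GWAS matches an independent least-squares fit", {
  cfg <- sim_config(n_studies = 1, n_per_study = 200, n_variants = 10,
                    seed = 13)
  p <- simulate_panel(cfg)
  g <- run_stratified_gwas(p, "noDM", covariates = c("age", "sex"))
  mask <- p$pheno$dm == 0
  sexnum <- as.numeric(factor(p$pheno$sex[mask])) - 1
  for (j in seq_len(nrow(g))) {
    v <- match(g$SNP[j], p$variants$SNP)
    fit <- lm(p$pheno$log_egfr[mask] ~ p$dosage[mask, v] +
                p$pheno$age[mask] + sexnum)
    co <- summary(fit)$coefficients[2, ]
    expect_equal(g$BETA[j], unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(g$SE[j], unname(co["Std. Error"]), tolerance = 1e-10)
  }
})

test_that("stratified GWAS is invariant to individual order and drops monomorphic variants", {
  cfg <- sim_config(n_studies = 1, n_per_study = 400, n_variants = 20, seed = 21)
  p <- simulate_panel(cfg)
  g1 <- run_stratified_gwas(p, "noDM")
  perm <- sample(nrow(p$dosage))
  p2 <- p
  p2$dosage <- p$dosage[perm, ]
  p2$pheno <- p$pheno[perm, ]
  g2 <- run_stratified_gwas(p2, "noDM")
  expect_equal(g1$BETA, g2$BETA, tolerance = 1e-10)
  expect_equal(g1$SE, g2$SE, tolerance = 1e-10)

  # force a monomorphic variant in the stratum
  p3 <- p
  p3$dosage[, 4] <- 0L
  g3 <- run_stratified_gwas(p3, "noDM")
  expect_false(p3$variants$SNP[4] %in% g3$SNP)
  expect_true(p3$variants$SNP[4] %in% attr(g3, "monomorphic"))
})

test_that("perfect linear dosage-phenotype fit returns the exact slope", {
  cfg <- sim_config(n_studies = 1, n_per_study = 10, n_variants = 2, seed = 2)
  p <- simulate_panel(cfg)
  p$dosage <- cbind(c(0L, 1L, 1L, 2L), c(1L, 0L, 2L, 1L))
  p$pheno <- data.frame(creatinine = 1, age = 50, sex = "female",
                        dm = 0L, log_egfr = c(0, 0.5, 0.5, 1.0))
  p$variants <- p$variants[1:2, ]
  g <- run_stratified_gwas(p, "noDM", covariates = character(0))
  expect_equal(g$BETA[1], 0.5, tolerance = 1e-12)
  expect_equal(g$SE[1], 0, tolerance = 1e-12)
})

test_that("null GWAS p-values are uniform", {
  cfg <- sim_config(n_studies = 1, n_per_study = 400, n_variants = 5000,
                    polygenic_h2_shared = 0, ld_rho = 0,
                    maf_range = c(0.05, 0.5), seed = 31)
  p <- simulate_panel(cfg)
  g <- run_stratified_gwas(p, "noDM")
  ks <- suppressWarnings(ks.test(g$P, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shared polygenic background induces a positive cross-stratum effect correlation", {
  cfg <- sim_config(n_studies = 1, n_per_study = 4000, n_variants = 600,
                    polygenic_h2_shared = 0.5, ld_rho = 0,
                    residual_sd_logegfr = 0.15, maf_range = c(0.1, 0.5),
                    seed = 41)
  p <- simulate_panel(cfg)
  gdm <- run_stratified_gwas(p, "DM")
  gnd <- run_stratified_gwas(p, "noDM")
  common <- intersect(gdm$SNP, gnd$SNP)
  r <- cor.test(gdm$BETA[match(common, gdm$SNP)],
                gnd$BETA[match(common, gnd$SNP)], method = "spearman",
                exact = FALSE, alternative = "greater")
  expect_lt(r$p.value, 0.05)
})

test_that("summary statistics round-trip through the gzip TSV dialect", {
  cfg <- sim_config(n_studies = 1, n_per_study = 300, n_variants = 15, seed = 3)
  p <- simulate_panel(cfg)
  g <- run_stratified_gwas(p, "noDM")
  path <- file.path(tempdir(), "study1_noDM.tsv.gz")
  write_sumstats(g, path)
  back <- read_sumstats(path)
  expect_equal(back$BETA, g$BETA, tolerance = 1e-12)
  expect_equal(back$LOG10P, g$LOG10P, tolerance = 1e-10)
  expect_identical(back$SNP, g$SNP)
  unlink(path)
})
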