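toy_weight_table <- function(n = 10, flags = rep(FALSE, n), seed = 55) {
  set.seed(seed)
  data.frame(VARIANT = paste0("v", seq_len(n)),
             EA = rep("A", n), OA = rep("G", n),
             BETA_OVERALL = rnorm(n, -0.01, 0.01),
             BETA_DM = rnorm(n, -0.015, 0.01),
             BETA_NODM = rnorm(n, -0.008, 0.008),
             DIFF_FLAG = flags, stringsAsFactors = FALSE)
}

toy_panel <- function(n = 500, m = 10, seed = 66) {
  set.seed(seed)
  dosage <- sapply(seq_len(m), function(j) rbinom(n, 2, runif(1, 0.1, 0.5)))
  colnames(dosage) <- paste0("v", seq_len(m))
  list(dosage = dosage,
       variants = data.frame(SNP = colnames(dosage), EA = "A",
                             stringsAsFactors = FALSE))
}

test_that("weighting schemes align weights to the lowering allele", {
  tab <- toy_weight_table()
  ws <- weight_schemes(tab)
  expect_named(ws, c("overall", "dm", "nodm", "hybrid"))
  expect_true(all(ws$overall$W >= 0))
  neg <- tab$BETA_OVERALL < 0
  expect_equal(ws$overall$EA_LOWERING[neg], tab$EA[neg])
  expect_equal(ws$overall$EA_LOWERING[!neg], tab$OA[!neg])
  expect_equal(ws$overall$W, abs(tab$BETA_OVERALL))
  # flagged variant without stratum effect is a config error
  bad <- tab
  bad$DIFF_FLAG[1] <- TRUE
  bad$BETA_DM[1] <- NA
  expect_error(weight_schemes(bad), "flagged")
})

test_that("hybrid weights interpolate between overall and stratum-specific", {
  # no flags: hybrid identical to overall in both strata
  ws0 <- weight_schemes(toy_weight_table())
  expect_equal(ws0$hybrid$dm, ws0$overall, ignore_attr = TRUE)
  expect_equal(ws0$hybrid$nodm, ws0$overall, ignore_attr = TRUE)
  # all flagged: hybrid identical to the stratum-specific schemes
  ws1 <- weight_schemes(toy_weight_table(flags = rep(TRUE, 10)))
  expect_equal(ws1$hybrid$dm, ws1$dm, ignore_attr = TRUE)
  expect_equal(ws1$hybrid$nodm, ws1$nodm, ignore_attr = TRUE)
  # 3 of 10 flagged: hybrid differs from overall at exactly those weights
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  tab <- toy_weight_table(flags = flags)
  ws <- weight_schemes(tab)
  differs <- ws$hybrid$dm$W != ws$overall$W |
    ws$hybrid$dm$EA_LOWERING != ws$overall$EA_LOWERING
  expect_equal(differs, flags)
})

test_that("GRS equals the brute-force per-individual weighted sum", {
  panel <- toy_panel()
  tab <- toy_weight_table()
  w <- weight_schemes(tab)$overall
  score <- build_grs(panel$dosage, panel$variants, w)
  naive <- numeric(nrow(panel$dosage))
  for (i in seq_len(nrow(panel$dosage))) {
    for (j in seq_len(nrow(w))) {
      d <- panel$dosage[i, w$VARIANT[j]]
      if (panel$variants$EA[match(w$VARIANT[j], panel$variants$SNP)] !=
          w$EA_LOWERING[j]) d <- 2 - d
      naive[i] <- naive[i] + w$W[j] * d
    }
  }
  expect_equal(unname(score), naive, tolerance = 1e-12, ignore_attr = TRUE)

  # single variant, weight 1: score equals the aligned dosage
  w1 <- data.frame(VARIANT = "v1", EA_LOWERING = "A", W = 1)
  expect_equal(unname(build_grs(panel$dosage, panel$variants, w1)),
               unname(panel$dosage[, "v1"]), ignore_attr = TRUE)

  # missing variants are excluded with a coverage message
  w_miss <- rbind(w1, data.frame(VARIANT = "vZZ", EA_LOWERING = "A", W = 1))
  expect_message(s2 <- build_grs(panel$dosage, panel$variants, w_miss),
                 "coverage")
  expect_equal(attr(s2, "coverage"), 0.5)
})

test_that("zero weights give a degenerate score whose association errors", {
  panel <- toy_panel()
  w0 <- data.frame(VARIANT = paste0("v", 1:10), EA_LOWERING = "A", W = 0)
  score <- build_grs(panel$dosage, panel$variants, w0)
  expect_true(all(score == 0))
  egfr <- rnorm(500, 90, 12)
  expect_error(grs_association(score, egfr, data.frame(age = rnorm(500)),
                               rep(TRUE, 500)), "variance")
})

test_that("noiseless construction recovers the exact per-SD effect", {
  panel <- toy_panel(n = 400)
  w <- weight_schemes(toy_weight_table())$overall
  score <- build_grs(panel$dosage, panel$variants, w)
  set.seed(9)
  age <- runif(400, 30, 80)
  egfr <- -2 * score / sd(score) + 0.5 * age
  # zero-residual fit: lm warns about the perfect fit, which is the point
  rep <- suppressWarnings(
    grs_association(score, egfr, data.frame(age = age), rep(TRUE, 400)))
  expect_equal(rep$BETA_SD, -2, tolerance = 1e-9)
  expect_equal(rep$R2_INCR, 1 - summary(lm(egfr ~ age))$r.squared,
               tolerance = 1e-9)
})

test_that("GRS association matches an independent least-squares fit", {
  panel <- toy_panel(n = 50, seed = 91)
  w <- weight_schemes(toy_weight_table())$overall
  score <- build_grs(panel$dosage, panel$variants, w)
  set.seed(10)
  age <- runif(50, 30, 80)
  sex <- sample(0:1, 50, replace = TRUE)
  egfr <- 100 - 1.5 * score / sd(score) - 0.3 * age + 2 * sex + rnorm(50, 0, 8)
  rep <- grs_association(score, egfr, data.frame(age = age, sex = sex),
                         rep(TRUE, 50))
  fit <- summary(lm(egfr ~ I(score / sd(score)) + age + sex))$coefficients
  expect_equal(rep$BETA_SD, fit[2, 1], tolerance = 1e-10)
  expect_equal(rep$SE, fit[2, 2], tolerance = 1e-10)

  # null GRS: effect within sampling bounds, incremental R2 near zero
  set.seed(11)
  egfr_null <- 100 - 0.3 * age + rnorm(50, 0, 8)
  rep0 <- grs_association(score, egfr_null, data.frame(age = age),
                          rep(TRUE, 50))
  expect_lt(abs(rep0$BETA_SD), 3 * rep0$SE)
})

test_that("incremental R2 is invariant to affine covariate transformations", {
  panel <- toy_panel(n = 300, seed = 92)
  w <- weight_schemes(toy_weight_table())$overall
  score <- build_grs(panel$dosage, panel$variants, w)
  set.seed(12)
  age <- runif(300, 30, 80)
  egfr <- 95 - score - 0.4 * age + rnorm(300, 0, 10)
  r1 <- grs_association(score, egfr, data.frame(age = age), rep(TRUE, 300))
  r2 <- grs_association(score, egfr, data.frame(age = 10 * age - 200),
                        rep(TRUE, 300))
  expect_equal(r1$R2_INCR, r2$R2_INCR, tolerance = 1e-10)
})

test_that("the GRS difference test matches direct evaluation", {
  d <- grs_difference(data.frame(BETA_SD = -1.02, SE = 0.244),
                      data.frame(BETA_SD = -0.68, SE = 0.074))
  expect_equal(d$Z, -0.34 / sqrt(0.244^2 + 0.074^2), tolerance = 1e-12)
  expect_equal(round(d$Z, 3), -1.333)
  expect_equal(d$P, 0.1824, tolerance = 1e-3)
  # identical effects: p = 1
  same <- grs_difference(data.frame(BETA_SD = -1, SE = 0.2),
                         data.frame(BETA_SD = -1, SE = 0.1))
  expect_equal(same$P, 1)
  # one enormous se: p tends to 1
  lim <- grs_difference(data.frame(BETA_SD = -5, SE = 1e8),
                        data.frame(BETA_SD = -1, SE = 0.1))
  expect_gt(lim$P, 0.99)
})

test_that("evaluation refuses the weight-estimating cohort unless overridden", {
  panel <- toy_panel()
  w <- weight_schemes(toy_weight_table(), source_cohort = "stage1")$overall
  expect_error(build_grs(panel$dosage, panel$variants, w, cohort = "stage1"),
               "refusing")
  s <- build_grs(panel$dosage, panel$variants, w, cohort = "stage1",
                 allow_in_sample = TRUE)
  expect_length(s, 500)
  # independent cohort evaluates freely
  expect_silent(build_grs(panel$dosage, panel$variants, w, cohort = "stage2"))
})

test_that("stronger planted DM effects yield larger absolute DM GRS effects", {
  eff <- data.frame(variant = 1:4, beta_dm = c(-0.06, -0.05, -0.06, -0.05),
                    beta_nodm = c(-0.015, -0.01, -0.015, -0.01))
  hits <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_studies = 1, n_per_study = 2500, n_variants = 4,
                      dm_prevalence = 0.35, effect_table = eff,
                      polygenic_h2_shared = 0, ld_rho = 0,
                      maf_range = c(0.2, 0.5), seed = 1000 + r)
    p <- simulate_panel(cfg)
    X <- p$dosage
    colnames(X) <- p$variants$SNP
    w <- data.frame(VARIANT = p$variants$SNP, EA_LOWERING = p$variants$EA,
                    W = c(0.04, 0.03, 0.04, 0.03))
    score <- build_grs(X, data.frame(SNP = p$variants$SNP,
                                     EA = p$variants$EA), w)
    egfr <- exp(p$pheno$log_egfr)
    cov <- data.frame(age = p$pheno$age, sex = p$pheno$sex)
    rdm <- grs_association(score, egfr, cov, p$pheno$dm == 1)
    rnd <- grs_association(score, egfr, cov, p$pheno$dm == 0)
    if (rdm$BETA_SD < 0 && abs(rdm$BETA_SD) > abs(rnd$BETA_SD)) hits <- hits + 1
  }
  # sign test: DM effect more often the stronger (and negative) one
  expect_gt(hits / reps, 0.7)
})
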