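#!/usr/bin/env Rscript
# Step 6: genetic risk score evaluation. Weights come from the stage-1
# interaction scan (overall, DM-specific, noDM-specific, hybrid schemes);
# the GRS is evaluated in an independently simulated stage-2 cohort,
# separately in DM and noDM individuals, on untransformed eGFR, with the
# cross-stratum difference test. Writes results/grs_report.tsv.

suppressPackageStartupMessages(library(stratgwas))

res <- read.delim("results/interaction.tsv")
planted <- readLines("results/sumstats/planted_variants.txt")

# stage-1 weight table over the planted + a few top overall variants
cand <- unique(c(planted,
                 res$SNP[order(-res$LOG10P_OVR)][1:10]))
tab <- res[res$SNP %in% cand,
           c("SNP", "EA", "OA", "BETA_OVR", "BETA_DM", "BETA_NODM")]
names(tab) <- c("VARIANT", "EA", "OA", "BETA_OVERALL", "BETA_DM",
                "BETA_NODM")
diff_hits <- run_design(res, approach = "difference",
                        design = "combined")$decisions
tab$DIFF_FLAG <- tab$VARIANT %in%
  diff_hits$SNP[diff_hits$STATUS == "identified"]
cat(sprintf("weight table: %d variants, %d flagged for DM/noDM-difference\n",
            nrow(tab), sum(tab$DIFF_FLAG)))
ws <- weight_schemes(tab, source_cohort = "stage1")

# independent stage-2 cohort with the same genetic architecture
effects <- data.frame(variant = c(50, 250, 445),
                      beta_dm = c(-0.04, -0.07, 0),
                      beta_nodm = c(-0.04, 0, -0.035))
cfg2 <- sim_config(n_studies = 1, n_per_study = 12000, n_variants = 600,
                   ld_block_size = 20, ld_rho = 0.4, dm_prevalence = 0.12,
                   effect_table = effects, polygenic_h2_shared = 0.15,
                   maf_range = c(0.05, 0.5), seed = 30261102,
                   variant_seed = 20260901)  # same genome as stage 1
panel2 <- simulate_panel(cfg2)
X <- panel2$dosage
colnames(X) <- panel2$variants$SNP
pv <- data.frame(SNP = panel2$variants$SNP, EA = panel2$variants$EA)
egfr <- exp(panel2$pheno$log_egfr)
cov <- data.frame(age = panel2$pheno$age, sex = panel2$pheno$sex)
dm <- panel2$pheno$dm == 1

rows <- list()
for (scheme in c("overall", "dm", "nodm", "hybrid")) {
  w_dm <- if (scheme == "hybrid") ws$hybrid$dm else ws[[scheme]]
  w_nd <- if (scheme == "hybrid") ws$hybrid$nodm else ws[[scheme]]
  s_dm <- build_grs(X, pv, w_dm, cohort = "stage2")
  s_nd <- build_grs(X, pv, w_nd, cohort = "stage2")
  rep_dm <- grs_association(s_dm, egfr, cov, dm)
  rep_nd <- grs_association(s_nd, egfr, cov, !dm)
  d <- grs_difference(rep_dm, rep_nd)
  rows[[scheme]] <- data.frame(
    SCHEME = scheme,
    BETA_SD_DM = rep_dm$BETA_SD, SE_DM = rep_dm$SE, P_DM = rep_dm$P,
    R2_DM = rep_dm$R2_INCR,
    BETA_SD_NODM = rep_nd$BETA_SD, SE_NODM = rep_nd$SE, P_NODM = rep_nd$P,
    R2_NODM = rep_nd$R2_INCR, P_DIFF = d$P)
  cat(sprintf(
    "%-8s beta/sd: DM %+ .3f (R2 %.4f), noDM %+ .3f (R2 %.4f), P_diff %.3g\n",
    scheme, rep_dm$BETA_SD, rep_dm$R2_INCR, rep_nd$BETA_SD, rep_nd$R2_INCR,
    d$P))
}
report <- do.call(rbind, rows)
write.table(report, "results/grs_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("-> results/grs_report.tsv\n")
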