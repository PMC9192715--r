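Package: stratgwas
Title: Diabetes-Stratified GWAS Meta-Analysis and Interaction Testing for Kidney Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association scans of kidney function
    (log eGFR via the CKD-EPI creatinine equation) stratified by diabetes
    status. Implements per-study stratified linear-regression GWAS on
    simulated multi-study cohorts, fixed-effect inverse-variance weighted
    meta-analysis with double genomic-control correction and post-meta
    variant filters, the cross-stratum difference test with a genome-wide
    effect-correlation term, the two-degree-of-freedom joint test,
    discovery+replication and combined-stage identification designs,
    iterative locus clumping with known-locus annotation, approximate
    conditional analysis from summary statistics against an LD reference,
    Wakefield approximate Bayes factor credible sets with rule-based gene
    prioritization, and stratified genetic risk score evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
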