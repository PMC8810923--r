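#!/usr/bin/env Rscript
# Demo: index-event-bias correction of a case-only breast cancer
# mortality GWAS using breast cancer susceptibility as the conditioning
# trait.
#
# Requires external downloads (not shipped, not used by the test suite):
#   * Breast cancer risk and mortality summary statistics (BCAC oncoarray):
#     http://bcac.ccge.medschl.cam.ac.uk/bcacdata/oncoarray/oncoarray-and-combined-summary-result
# plus an LD report for pruning (R^2 0.1, 250-SNP windows, European panel).
#
risk_path <- "bc_risk_sumstats.tsv"
mort_path <- "bc_mortality_sumstats.tsv"
ld_path <- NULL

suppressPackageStartupMessages(library(slopehunt))

risk <- read_sumstats(risk_path)
mort <- read_sumstats(mort_path)
h <- harmonise(risk, mort)
if (!is.null(ld_path)) {
  h <- ld_prune(h, read_ld_report(ld_path), r2_threshold = 0.1,
                window_snps = 250, seed = 1)
}

# Expected qualitative outcome (published analysis of these data): a
# negative correction factor (around -0.24, 95% CI excluding 0), a sign
# change for the FGFR2 lead variant and a strengthened Tox3 association.
fit <- hunt_slope(h, selection_config(lambda = 0.001),
                  em_config(seed = 1, bootstrap_B = 10000))
print(fit)
stopifnot(fit$b1 < 0, fit$ci_b1[2] < 0)

dho <- dho_estimate(h)
print(dho)

report <- compare_report(h, fit, dho)
write_sumstats(report, "bc_mortality_adjusted.tsv")
write_fit_json(fit, "bc_mortality_fit.json")
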