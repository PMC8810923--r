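# Shared fixture builders. Everything is generated in code; files go to
# tempdir and are cleaned up by testthat.

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small canonical summary-statistics data frame
canonical_sumstats <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    EA = c("A", "T", "C"), OA = c("G", "C", "A"),
    EAF = c(0.2, 0.4, 0.3),
    BETA = c(0.10, -0.05, 0.02),
    SE = c(0.01, 0.02, 0.01),
    P = c(1e-8, 0.01, 0.05),
    N = c(10000L, 10000L, 10000L),
    stringsAsFactors = FALSE
  )
}

# harmonised-format table straight from vectors
make_harmonised <- function(beta_I, se_I, beta_P, se_P,
                            snp_id = sprintf("rs%d", seq_along(beta_I)),
                            p_I = NULL) {
  h <- data.frame(
    snp_id = snp_id,
    effect_allele = "A", other_allele = "G",
    beta_I = beta_I, se_I = se_I,
    p_I = if (is.null(p_I)) wald_pvalue(beta_I, se_I) else p_I,
    beta_P = beta_P, se_P = se_P,
    p_P = wald_pvalue(beta_P, se_P),
    stringsAsFactors = FALSE
  )
  class(h) <- c("sh_harmonised", "data.frame")
  h
}

# published lead-locus tables shipped with the package
fi_bmi_loci <- function() {
  read.delim(system.file("extdata", "fi_bmi_published_loci.tsv",
                         package = "slopehunt"), stringsAsFactors = FALSE)
}
bc_loci <- function() {
  read.delim(system.file("extdata", "bcmort_published_loci.tsv",
                         package = "slopehunt"), stringsAsFactors = FALSE)
}

loci_to_harmonised <- function(loci) {
  make_harmonised(beta_I = loci$beta_I, se_I = loci$se_I,
                  beta_P = loci$beta_P, se_P = loci$se_P,
                  snp_id = loci$snp_id)
}
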