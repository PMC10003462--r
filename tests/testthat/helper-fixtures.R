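# Fixture builders: everything is generated in code at test time.

# A genotype_dataset realizing the published per-SNP genotype counts
# exactly: within each phenotype group, each SNP's column is filled with the
# required numbers of NN/NR/RR calls (padded with missing calls when a
# group's counts fall short of the group size, as for the one SNP genotyped
# in 142 of 143 cases). Per-SNP marginals are all that association
# statistics see, so the arrangement across samples is immaterial.
table1_dataset <- function() {
  fx <- make_table1_fixtures()
  n_case <- 143L; n_ctrl <- 119L
  fill <- function(nn, nr, rr, n) {
    calls <- c(rep("AA", nn), rep("AG", nr), rep("GG", rr))
    c(calls, rep(NA_character_, n - length(calls)))
  }
  calls <- matrix(NA_character_, n_case + n_ctrl, nrow(fx))
  for (j in seq_len(nrow(fx))) {
    calls[, j] <- c(
      fill(fx$case_NN[j], fx$case_NR[j], fx$case_RR[j], n_case),
      fill(fx$control_NN[j], fx$control_NR[j], fx$control_RR[j], n_ctrl))
  }
  snps <- data.frame(snp_id = fx$snp_id, chromosome = "1",
                     position = seq_len(nrow(fx)),
                     allele_a = "A", allele_b = "G",
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  genotype_dataset(snps, sprintf("s%03d", seq_len(n_case + n_ctrl)),
                   c(rep(1L, n_case), rep(0L, n_ctrl)), calls)
}

# small hand-built dataset used across the genotype-data tests
toy_dataset <- function() {
  snps <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chromosome = "1",
    position = c(100L, 200L, 300L),
    allele_a = c("A", "C", "A"), allele_b = c("G", "T", "C"),
    risk_allele = c("G", "T", "C"), stringsAsFactors = FALSE)
  calls <- rbind(c("AG", "CC", "AC"),
                 c("GG", "CT", NA),
                 c("AA", "TT", "CC"),
                 c("AG", NA,  "AA"))
  genotype_dataset(snps, paste0("s", 1:4), c(1L, 1L, 0L, 0L), calls)
}

# simulation spec for the causal-recovery experiments: 5 causal SNPs
# (allelic OR 3.0, control risk-allele frequency 0.3) among 92, the rest
# null with frequencies drawn once from a fixed seed
recovery_spec <- function(n_cases = 500L, n_controls = 500L) {
  raf <- local({
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(9090)
    v <- runif(92, 0.1, 0.9)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    v
  })
  raf[1:5] <- 0.3
  or <- rep(1, 92); or[1:5] <- 3.0
  sim_spec(n_snps = 92L, n_cases = n_cases, n_controls = n_controls,
           control_raf = raf, causal_or = or, missing_rate = 0)
}

# reduced search budget shared by the stochastic GA experiments
reduced_ga_config <- function(k = 10L) {
  ga_config(subset_size = k, population_size = 10L, cycles = 10L,
            epochs = 50L)
}

# run QC -> risk alleles -> association -> LD -> complete additive matrix
prepare_pipeline <- function(dataset, split = NULL) {
  ds <- if (is.null(split)) assign_risk_alleles(dataset) else
    assign_risk_alleles(dataset, sample_ids = c(split$train_ids, split$val_ids))
  res <- snp_association(ds)
  ld <- pairwise_r2(ds)
  mat <- impute_missing(encode_additive(ds), ld)
  list(dataset = ds, results = res, ld = ld, matrix = mat)
}
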