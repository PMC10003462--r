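test_that("PLINK text parsing maps calls, missing codes and phenotypes", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0\t100"), map)
  writeLines(c("f1\ts1\t0\t0\t0\t2\tA\tG",
               "f2\ts2\t0\t0\t0\t1\t0\t0"), ped)
  ds <- read_plink_text(ped, map)
  expect_equal(ds$calls[1, 1], "AG")
  expect_true(is.na(ds$calls[2, 1]))
  expect_equal(ds$phenotypes, c(1L, 0L))

  # malformed width errors name the line
  writeLines(c("f1\ts1\t0\t0\t0\t2\tA\tG",
               "f2\ts2\t0\t0\t1"), ped)
  expect_error(read_plink_text(ped, map), "line 2")

  # phenotype codes outside the convention are rejected
  writeLines(c("f1\ts1\t0\t0\t0\t7\tA\tG"), ped)
  expect_error(read_plink_text(ped, map), "phenotype")
})

test_that("PLINK and TSV writers round-trip generated datasets exactly", {
  spec <- default_sim_spec()
  sim <- simulate_genotypes(spec, seed = 11)
  ds <- sim$dataset

  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_plink_text(ds, ped, map)
  back <- read_plink_text(ped, map)
  expect_identical(back$calls, ds$calls)
  expect_identical(back$phenotypes, ds$phenotypes)
  expect_identical(back$sample_ids, ds$sample_ids)
  expect_identical(back$snps$snp_id, ds$snps$snp_id)

  tsv <- tempfile(fileext = ".tsv")
  write_genotype_tsv(ds, tsv)
  back2 <- read_genotype_tsv(tsv)
  expect_identical(back2$calls, ds$calls)
  expect_identical(back2$phenotypes, ds$phenotypes)

  # cross-format equality: both readers see the same dataset
  expect_identical(back$calls, back2$calls)
})

test_that("TSV reader decodes het/hom/missing and rejects duplicates", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype\trsX",
               "s1\t1\tAG", "s2\t0\tGG", "s3\t0\tNA"), tsv)
  ds <- read_genotype_tsv(tsv)
  expect_equal(unname(ds$calls[, 1]), c("AG", "GG", NA))

  writeLines(c("sample_id\tphenotype\trsX\trsX",
               "s1\t1\tAG\tAG"), tsv)
  expect_error(read_genotype_tsv(tsv), "duplicate")
})

test_that("additive encoding counts risk alleles and decodes back", {
  ds <- toy_dataset()
  mat <- encode_additive(ds)
  # rs1: risk G -> AG=1, GG=2, AA=0, AG=1
  expect_equal(unname(mat$values[, "rs1"]), c(1L, 2L, 0L, 1L))
  # missing stays missing
  expect_true(is.na(mat$values[2, "rs3"]))
  # decode(encode(x)) recovers the unordered pair everywhere
  expect_identical(decode_additive(mat, ds$snps), ds$calls)
  # unset risk allele is a configuration error
  ds2 <- ds; ds2$snps$risk_allele[2] <- NA
  expect_error(encode_additive(ds2), "risk_allele")
})

test_that("encoded column sums equal the direct risk-allele tally", {
  sim <- simulate_genotypes(default_sim_spec(), seed = 5)
  ds <- assign_risk_alleles(sim$dataset)
  mat <- encode_additive(ds)
  for (j in seq_len(ncol(mat$values))) {
    risk <- ds$snps$risk_allele[j]
    cells <- ds$calls[, j]
    tally <- sum((substr(cells, 1, 1) == risk) +
                 (substr(cells, 2, 2) == risk), na.rm = TRUE)
    expect_equal(sum(mat$values[, j], na.rm = TRUE), tally)
  }
})

test_that("imputation follows conditional then unconditional modes", {
  make_mat <- function(values) {
    structure(list(values = values,
                   snp_ids = colnames(values),
                   sample_ids = rownames(values),
                   phenotypes = rep(0L, nrow(values))),
              class = "genotype_matrix")
  }
  make_ld <- function(ids, r2) structure(list(snp_ids = ids, r2 = r2),
                                         class = "ld_matrix")

  # no informative partner: unconditional mode (all other samples are 2)
  v <- cbind(a = c(NA, 2L, 2L, 2L), b = c(0L, 1L, 2L, 0L))
  rownames(v) <- paste0("s", 1:4)
  ld <- make_ld(c("a", "b"),
                matrix(c(1, 0.1, 0.1, 1), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  out <- impute_missing(make_mat(v), ld)
  expect_equal(out$values[1, "a"], 2L)

  # perfect-LD partner: conditional mode within the partner stratum
  v2 <- cbind(a = c(NA, 0L, 0L, 2L, 2L), b = c(0L, 0L, 0L, 2L, 2L))
  rownames(v2) <- paste0("s", 1:5)
  ld2 <- make_ld(c("a", "b"),
                 matrix(c(1, 1, 1, 1), 2, 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
  out2 <- impute_missing(make_mat(v2), ld2)
  expect_equal(out2$values[1, "a"], 0L)

  # a SNP missing everywhere has no mode
  v3 <- cbind(a = c(NA_integer_, NA_integer_), b = c(0L, 1L))
  rownames(v3) <- paste0("s", 1:2)
  expect_error(impute_missing(make_mat(v3), ld), "missing in every sample")
})

test_that("imputation never alters observed entries and fills all gaps", {
  sim <- simulate_genotypes(default_sim_spec(missing_rate = 0.05), seed = 21)
  prep_ds <- assign_risk_alleles(sim$dataset)
  mat <- encode_additive(prep_ds)
  ld <- pairwise_r2(prep_ds)
  out <- impute_missing(mat, ld)
  expect_false(anyNA(out$values))
  obs <- !is.na(mat$values)
  expect_identical(out$values[obs], mat$values[obs])
})

test_that("LD-conditional imputation beats the unconditional mode on masked data", {
  # complete data with strong LD, mask 5%, compare recovery accuracy
  spec <- default_sim_spec(missing_rate = 0)
  sim <- simulate_genotypes(spec, seed = 31)
  ds <- assign_risk_alleles(sim$dataset)
  mat <- encode_additive(ds)
  ld <- pairwise_r2(ds)
  truth <- mat$values
  set.seed(77)
  mask <- matrix(runif(length(truth)) < 0.05, nrow(truth), ncol(truth))
  masked <- mat; masked$values[mask] <- NA_integer_

  cond <- impute_missing(masked, ld)
  # unconditional-mode reference: demand an unattainable partner r2
  uncond <- impute_missing(masked, ld, min_r2 = 1.5)
  acc_cond <- mean(cond$values[mask] == truth[mask])
  acc_uncond <- mean(uncond$values[mask] == truth[mask])
  expect_gte(acc_cond, acc_uncond)
})

test_that("dataset construction enforces its invariants", {
  snps <- data.frame(snp_id = "rs1", chromosome = "1", position = 1L,
                     allele_a = "A", allele_b = "A", stringsAsFactors = FALSE)
  expect_error(genotype_dataset(snps, "s1", 1L, matrix("AA", 1, 1)),
               "allele_a must differ")
  snps$allele_b <- "G"
  expect_error(genotype_dataset(snps, c("s1", "s1"), c(1L, 0L),
                                matrix("AA", 2, 1)), "duplicate sample")
  expect_error(genotype_dataset(snps, "s1", 2L, matrix("AA", 1, 1)),
               "phenotypes")
  expect_error(genotype_dataset(snps, "s1", 1L, matrix("AT", 1, 1)),
               "outside its alleles")
})
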