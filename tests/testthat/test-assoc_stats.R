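test_that("HWE exact test matches the published control-group values", {
  fx <- make_table1_fixtures()
  for (i in seq_len(nrow(fx))) {
    p <- hwe_exact_test(fx$control_NN[i], fx$control_NR[i], fx$control_RR[i])
    expect_equal(round(p, 2), fx$hwe_p[i],
                 info = paste("control HWE for", fx$snp_id[i]))
  }
})

test_that("HWE exact test handles degenerate and invalid inputs", {
  expect_equal(hwe_exact_test(0, 0, 25), 1.0)   # monomorphic
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("HWE exact test agrees with full enumeration on all small tables", {
  for (n in c(3, 7, 12, 20, 30)) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                   oracle_hwe_p(n_AA, n_Aa, n_aa), tolerance = 1e-10,
                   info = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
})

test_that("allelic association reproduces the published table rows", {
  fx <- make_table1_fixtures()
  for (i in seq_len(nrow(fx))) {
    r <- allelic_association(
      as.numeric(fx[i, c("case_NN", "case_NR", "case_RR")]),
      as.numeric(fx[i, c("control_NN", "control_NR", "control_RR")]),
      snp_id = fx$snp_id[i])
    expect_equal(round(r$odds_ratio, 2), fx$odds_ratio[i], info = fx$snp_id[i])
    expect_equal(round(100 * r$raf_case, 1), fx$raf_case_pct[i], info = fx$snp_id[i])
    expect_equal(round(100 * r$raf_control, 1), fx$raf_control_pct[i], info = fx$snp_id[i])
    # CI bounds to within one unit in the last printed digit
    expect_lte(abs(round(r$ci_low, 2) - fx$ci_low[i]), 0.0100001)
    expect_lte(abs(round(r$ci_high, 2) - fx$ci_high[i]), 0.0100001)
    # Woolf CI brackets the OR
    expect_lte(r$ci_low, r$odds_ratio)
    expect_gte(r$ci_high, r$odds_ratio)
  }
})

test_that("allelic association is symmetric and exact under enumeration", {
  # identical groups: OR 1, p 1
  same <- allelic_association(c(10, 20, 10), c(10, 20, 10))
  expect_equal(same$odds_ratio, 1.0)
  expect_equal(same$fisher_p, 1.0)

  # Fisher p equals the enumeration oracle over every allele table
  # realizable from genotype counts with up to 40 total alleles
  for (n1 in 1:10) for (n0 in 1:(20 - n1)) {
    for (a in seq(0, 2 * n1, by = 3)) for (c_ in seq(0, 2 * n0, by = 3)) {
      nr1 <- a %% 2; rr1 <- (a - nr1) / 2; nn1 <- n1 - nr1 - rr1
      nr0 <- c_ %% 2; rr0 <- (c_ - nr0) / 2; nn0 <- n0 - nr0 - rr0
      r <- allelic_association(c(nn1, nr1, rr1), c(nn0, nr0, rr0))
      expect_equal(r$fisher_p,
                   oracle_fisher_p(a, 2 * n1 - a, c_, 2 * n0 - c_),
                   tolerance = 1e-9,
                   info = sprintf("a=%d b=%d c=%d d=%d", a, 2 * n1 - a,
                                  c_, 2 * n0 - c_))
    }
  }
})

test_that("zero allele cells get the Haldane-Anscombe correction and a flag", {
  r <- allelic_association(c(119, 22, 2), c(109, 10, 0))
  expect_false(r$haldane_corrected)   # no zero cell here (alleles, not genotypes)
  r0 <- allelic_association(c(0, 0, 10), c(5, 5, 0))
  expect_true(r0$haldane_corrected)
  expect_true(is.finite(r0$odds_ratio) && r0$odds_ratio > 0)
  expect_true(is.finite(r0$ci_high))
})

test_that("CI width shrinks with total count at fixed proportions", {
  widths <- vapply(c(1, 2, 4, 8), function(f) {
    r <- allelic_association(f * c(10, 20, 10), f * c(20, 15, 5))
    log(r$ci_high) - log(r$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("risk alleles point at the case-enriched allele, ties to allele_b", {
  ds <- table1_dataset()
  ds <- assign_risk_alleles(ds)
  # every published row is enriched for the coded risk allele (G here)
  expect_true(all(ds$snps$risk_allele == "G"))
  res <- snp_association(ds)
  expect_true(all(res$odds_ratio >= 1))

  # exact tie goes to allele_b
  snps <- data.frame(snp_id = "rsT", chromosome = "1", position = 1L,
                     allele_a = "A", allele_b = "G",
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  calls <- matrix(c("AG", "AG"), 2, 1)
  tie <- assign_risk_alleles(genotype_dataset(snps, c("s1", "s2"),
                                              c(1L, 0L), calls))
  expect_equal(tie$snps$risk_allele, "G")

  # on simulated data all recomputed ORs are >= 1 after assignment
  sim <- simulate_genotypes(default_sim_spec(), seed = 8)
  res2 <- snp_association(assign_risk_alleles(sim$dataset))
  expect_true(all(res2$odds_ratio >= 1 | res2$haldane_corrected))
})

test_that("QC removes SNPs by call rate, MAF and HWE with reasons", {
  n <- 60L
  snps <- data.frame(snp_id = paste0("rs", 1:4), chromosome = "1",
                     position = 1:4, allele_a = "A", allele_b = "G",
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  good <- rep(c("AA", "AG", "AG", "GG"), n / 4)  # HWE at MAF 0.5 everywhere
  lowcall <- good; lowcall[1:6] <- NA            # 10% missing
  mono <- rep("AA", n)                           # MAF 0
  hwe_bad <- rep(c("AA", "GG"), n / 2)           # no hets at MAF 0.5
  calls <- cbind(good, lowcall, mono, hwe_bad)
  ds <- genotype_dataset(snps, paste0("s", 1:n),
                         rep(c(1L, 0L), each = n / 2), calls)
  qc <- apply_qc(ds)
  expect_equal(qc$dataset$snps$snp_id, "rs1")
  expect_equal(qc$report$reason[qc$report$id == "rs2"], "call_rate")
  expect_equal(qc$report$reason[qc$report$id == "rs3"], "maf")
  expect_equal(qc$report$reason[qc$report$id == "rs4"], "hwe")
})

test_that("QC exclusions match an independent tally on simulated data", {
  sim <- simulate_genotypes(default_sim_spec(missing_rate = 0.03), seed = 13)
  ds <- sim$dataset
  qc <- apply_qc(ds, min_call_rate = 0.97, min_maf = 0.05, min_hwe_p = 0.05)
  # direct recomputation of the exclusion set
  controls <- ds$phenotypes == 0L
  excluded <- character(0)
  for (j in seq_len(ncol(ds$calls))) {
    cells <- ds$calls[, j]
    cr <- mean(!is.na(cells))
    nb <- sum((substr(cells, 1, 1) == "G") + (substr(cells, 2, 2) == "G"),
              na.rm = TRUE)
    fb <- nb / (2 * sum(!is.na(cells)))
    maf <- min(fb, 1 - fb)
    g <- cells[controls & !is.na(cells)]
    cnt <- c(sum(g == "AA"), sum(g == "AG"), sum(g == "GG"))
    hp <- oracle_hwe_p(cnt[1], cnt[2], cnt[3])
    if (cr < 0.97 || maf < 0.05 || hp < 0.05)
      excluded <- c(excluded, ds$snps$snp_id[j])
  }
  expect_setequal(qc$report$id[qc$report$kind == "snp"], excluded)
  expect_setequal(qc$dataset$snps$snp_id,
                  setdiff(ds$snps$snp_id, excluded))
})

test_that("EM r2 recovers constructed LD and vanishes for independent SNPs", {
  # a SNP paired with itself has r2 = 1
  snps <- data.frame(snp_id = c("x", "y"), chromosome = "1", position = 1:2,
                     allele_a = "A", allele_b = "G",
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  set.seed(1)
  g <- sample(c("AA", "AG", "GG"), 100, TRUE, prob = c(.25, .5, .25))
  ds <- genotype_dataset(snps, paste0("s", 1:100), rep(0L, 100), cbind(g, g))
  ld <- pairwise_r2(ds, group = "controls")
  expect_equal(ld$r2["x", "y"], 1, tolerance = 1e-6)

  # independent SNPs at MAF 0.5, n = 10,000 controls: r2 below 0.01
  set.seed(42)
  n <- 10000
  lut <- c("AA", "AG", "GG")
  two <- cbind(lut[rbinom(n, 2, 0.5) + 1], lut[rbinom(n, 2, 0.5) + 1])
  ds2 <- genotype_dataset(snps, paste0("s", 1:n), rep(0L, n), two)
  expect_lt(pairwise_r2(ds2)$r2["x", "y"], 0.01)

  # constructed-truth: haplotypes with known D collapsed to genotypes
  set.seed(7)
  pA <- 0.6; pB <- 0.4; D <- 0.15
  hfreq <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
             (1 - pA) * (1 - pB) + D)
  r2_true <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  n <- 4000
  h1 <- hap[sample(1:4, n, TRUE, prob = hfreq), ]
  h2 <- hap[sample(1:4, n, TRUE, prob = hfreq), ]
  gmat <- cbind(lut[h1[, 1] + h2[, 1] + 1], lut[h1[, 2] + h2[, 2] + 1])
  ds3 <- genotype_dataset(snps, paste0("s", 1:n), rep(0L, n), gmat)
  expect_equal(pairwise_r2(ds3)$r2["x", "y"], r2_true, tolerance = 0.02)
})

test_that("monomorphic SNPs get r2 = 0 with a flag", {
  snps <- data.frame(snp_id = c("x", "y"), chromosome = "1", position = 1:2,
                     allele_a = "A", allele_b = "G",
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  calls <- cbind(rep("AA", 20), rep(c("AA", "AG", "GG", "AG"), 5))
  ds <- genotype_dataset(snps, paste0("s", 1:20), rep(0L, 20), calls)
  ld <- pairwise_r2(ds)
  expect_equal(ld$r2["x", "y"], 0)
  expect_true(attr(ld, "monomorphic")["x", "y"])
})

test_that("LD pruning keeps the lower-p member above the threshold only", {
  res <- data.frame(snp_id = c("a", "b", "c", "d"),
                    fisher_p = c(1e-4, 5e-4, 1e-3, 0.02),
                    stringsAsFactors = FALSE)
  ids <- res$snp_id
  r2 <- matrix(0, 4, 4, dimnames = list(ids, ids)); diag(r2) <- 1
  ld <- structure(list(snp_ids = ids, r2 = r2), class = "ld_matrix")

  # r2 exactly at the threshold is kept (strict inequality excludes)
  ld$r2["a", "b"] <- ld$r2["b", "a"] <- 0.80
  expect_setequal(ld_prune(res, ld), ids)

  # r2 = 0.98 drops the higher-p member
  ld$r2["c", "d"] <- ld$r2["d", "c"] <- 0.98
  expect_setequal(ld_prune(res, ld), c("a", "b", "c"))

  # no LD at all keeps everything
  ld$r2[] <- 0; diag(ld$r2) <- 1
  expect_setequal(ld_prune(res, ld), ids)

  # post hoc: kept set never contains a pair above the threshold
  set.seed(3)
  big_ids <- paste0("s", 1:30)
  m <- matrix(runif(900), 30, 30, dimnames = list(big_ids, big_ids))
  m <- (m + t(m)) / 2; diag(m) <- 1
  big_ld <- structure(list(snp_ids = big_ids, r2 = m), class = "ld_matrix")
  big_res <- data.frame(snp_id = big_ids, fisher_p = runif(30),
                        stringsAsFactors = FALSE)
  kept <- ld_prune(big_res, big_ld, r2_max = 0.6)
  sub <- big_ld$r2[kept, kept]; diag(sub) <- 0
  expect_lte(max(sub), 0.6)
})

test_that("p-threshold subsets are nested, ordered and warn when empty", {
  sim <- simulate_genotypes(default_sim_spec(), seed = 2)
  prep <- prepare_pipeline(sim$dataset)
  subsets <- select_snp_subsets(prep$results, prep$ld)
  expect_named(subsets, c("p001", "p005", "p01", "all"))
  expect_true(all(subsets$p001$snp_ids %in% subsets$p005$snp_ids))
  expect_true(all(subsets$p005$snp_ids %in% subsets$p01$snp_ids))
  expect_true(all(subsets$p01$snp_ids %in% subsets$all$snp_ids))
  p_of <- setNames(prep$results$fisher_p, prep$results$snp_id)
  expect_true(all(p_of[subsets$p005$snp_ids] < 0.05))
  expect_false(is.unsorted(p_of[subsets$p01$snp_ids]))
  # the all subset is never pruned or thresholded
  expect_setequal(subsets$all$snp_ids, prep$results$snp_id)

  # engineered p-values reproduce the study's 3/10/16/92 subset sizes
  m <- 92L
  ids <- sprintf("e%02d", seq_len(m))
  p <- c(runif(3, 1e-5, 9e-3), runif(7, 0.011, 0.049),
         runif(6, 0.051, 0.099), runif(m - 16, 0.11, 1))
  eng <- data.frame(snp_id = ids, fisher_p = p, stringsAsFactors = FALSE)
  r2e <- diag(m); dimnames(r2e) <- list(ids, ids)
  lde <- structure(list(snp_ids = ids, r2 = r2e), class = "ld_matrix")
  sizes <- vapply(select_snp_subsets(eng, lde), function(s)
    length(s$snp_ids), 1L)
  expect_equal(unname(sizes), c(3L, 10L, 16L, 92L))

  res_null <- data.frame(snp_id = c("a", "b"), fisher_p = c(0.5, 0.9),
                         stringsAsFactors = FALSE)
  r2 <- diag(2); dimnames(r2) <- list(c("a", "b"), c("a", "b"))
  ld <- structure(list(snp_ids = c("a", "b"), r2 = r2), class = "ld_matrix")
  expect_warning(s <- select_snp_subsets(res_null, ld, thresholds = 0.01),
                 "empty")
  expect_length(s[[1]]$snp_ids, 0)
})

test_that("the multiple-testing bound reproduces the published threshold", {
  expect_equal(bonferroni_threshold(0.05, 92), 5.4e-4)
})
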