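#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one SNP's genotype counts, conditioning on the
#' observed minor-allele count: the p-value is the sum of the probabilities
#' of every attainable heterozygote count whose conditional probability does
#' not exceed that of the observed count (the Wigginton exact test used by
#' standard association toolkits). Returns 1 when only one genotype
#' configuration is attainable (e.g. a monomorphic SNP).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the labelling is symmetric).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_a <- n_Aa + 2 * min(n_AA, n_aa)     # minor allele count
  # heterozygote count must have the parity of the minor allele count
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  if (length(hets) <= 1) return(1.0)
  # log P(n_Aa = h | n, n_a) up to a constant:
  #   n! / (nAA! nAa! naa!) * 2^h, with nAA, naa determined by h
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - h - aa
    h * log(2) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1)
  }, numeric(1))
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- match(n_Aa, hets)
  min(1.0, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Allelic association test for one SNP
#'
#' Builds the 2x2 allele-count table (risk vs non-risk allele by case vs
#' control status) from genotype counts ordered NN/NR/RR (non-risk
#' homozygote, heterozygote, risk homozygote), then computes:
#' two-sided Fisher's exact p (sum of all tables with point probability at
#' most the observed table's), the sample cross-product odds ratio
#' OR = (a d)/(b c) with a = case risk alleles, b = case non-risk,
#' c = control risk, d = control non-risk, the Woolf log-normal 95%
#' confidence interval exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)),
#' and the risk-allele frequency per group. When any allele cell is zero the
#' Haldane-Anscombe 0.5 correction is applied to all four cells for the OR
#' and CI (never for the Fisher p) and the result is flagged.
#'
#' @param case_counts,control_counts integer vectors `c(NN, NR, RR)`.
#' @param snp_id optional id carried into the result.
#' @return A one-row data.frame with columns `snp_id`, `raf_case`,
#'   `raf_control`, `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`,
#'   `haldane_corrected`, plus the six genotype counts.
#' @export
allelic_association <- function(case_counts, control_counts, snp_id = NA_character_) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3)
  if (sum(case_counts) == 0 || sum(control_counts) == 0)
    stop("both groups must be non-empty")
  a <- case_counts[2] + 2 * case_counts[3]        # case risk alleles
  b <- 2 * case_counts[1] + case_counts[2]        # case non-risk alleles
  c_ <- control_counts[2] + 2 * control_counts[3] # control risk alleles
  d <- 2 * control_counts[1] + control_counts[2]  # control non-risk alleles
  tab <- matrix(c(a, c_, b, d), 2, 2)
  fisher_p <- fisher.test(tab)$p.value
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a2 <- a + 0.5; b2 <- b + 0.5; c2 <- c_ + 0.5; d2 <- d + 0.5
  } else {
    a2 <- a; b2 <- b; c2 <- c_; d2 <- d
  }
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.frame(
    snp_id = snp_id,
    case_NN = case_counts[1], case_NR = case_counts[2], case_RR = case_counts[3],
    control_NN = control_counts[1], control_NR = control_counts[2],
    control_RR = control_counts[3],
    raf_case = a / (a + b), raf_control = c_ / (c_ + d),
    odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    fisher_p = fisher_p,
    haldane_corrected = corrected,
    stringsAsFactors = FALSE)
}

#' Assign per-SNP risk alleles from case/control frequencies
#'
#' The risk allele of each SNP is the allele whose frequency is higher in
#' cases than in controls, so the resulting allelic odds ratio is >= 1
#' (computed on the samples used for assignment). Exact ties break toward
#' `allele_b`.
#'
#' @param dataset a [genotype_dataset()] with phenotypes.
#' @param sample_ids optional subset of samples to use for the frequency
#'   comparison (e.g. a training split to avoid information leaking into
#'   held-out data); default all samples.
#' @return The dataset with the `risk_allele` column filled.
#' @export
assign_risk_alleles <- function(dataset, sample_ids = NULL) {
  ds <- if (is.null(sample_ids)) dataset else subset_dataset(dataset, samples = sample_ids)
  case <- ds$phenotypes == 1L
  for (j in seq_len(nrow(dataset$snps))) {
    b <- dataset$snps$allele_b[j]
    fb_case <- allele_b_freq(ds$calls[case, j], b)
    fb_ctrl <- allele_b_freq(ds$calls[!case, j], b)
    delta_b <- fb_case - fb_ctrl
    dataset$snps$risk_allele[j] <-
      if (is.na(delta_b) || delta_b >= 0) b else dataset$snps$allele_a[j]
  }
  dataset
}

allele_b_freq <- function(cells, b) {
  cells <- cells[!is.na(cells)]
  if (length(cells) == 0) return(NA_real_)
  nb <- sum(substr(cells, 1, 1) == b) + sum(substr(cells, 2, 2) == b)
  nb / (2 * length(cells))
}

# genotype counts (NN, NR, RR) for one SNP column given its risk allele
risk_genotype_counts <- function(cells, risk) {
  cells <- cells[!is.na(cells)]
  n_risk <- (substr(cells, 1, 1) == risk) + (substr(cells, 2, 2) == risk)
  c(sum(n_risk == 0), sum(n_risk == 1), sum(n_risk == 2))
}

#' Per-SNP association scan
#'
#' Runs [allelic_association()] on every SNP of a dataset (assigning risk
#' alleles first if unset) and attaches the control-group Hardy-Weinberg
#' exact p-value.
#'
#' @param dataset a [genotype_dataset()].
#' @param hwe_group `"controls_only"` (default; matches reporting HWE in the
#'   control data) or `"all"`.
#' @return A data.frame, one row per SNP, with the [allelic_association()]
#'   columns plus `risk_allele` and `hwe_p`.
#' @export
snp_association <- function(dataset, hwe_group = c("controls_only", "all")) {
  hwe_group <- match.arg(hwe_group)
  if (any(is.na(dataset$snps$risk_allele)))
    dataset <- assign_risk_alleles(dataset)
  case <- dataset$phenotypes == 1L
  hwe_rows <- if (hwe_group == "controls_only") !case else rep(TRUE, length(case))
  out <- vector("list", nrow(dataset$snps))
  for (j in seq_len(nrow(dataset$snps))) {
    risk <- dataset$snps$risk_allele[j]
    cc <- risk_genotype_counts(dataset$calls[case, j], risk)
    kc <- risk_genotype_counts(dataset$calls[!case, j], risk)
    res <- allelic_association(cc, kc, snp_id = dataset$snps$snp_id[j])
    hw <- risk_genotype_counts(dataset$calls[hwe_rows, j], risk)
    res$hwe_p <- hwe_exact_test(hw[1], hw[2], hw[3])
    res$risk_allele <- risk
    out[[j]] <- res
  }
  do.call(rbind, out)
}

#' SNP and sample quality control
#'
#' Applies the conventional pre-association filters, SNPs first and then
#' samples: a SNP is dropped when its call rate is below `min_call_rate`,
#' its minor allele frequency is below `min_maf`, or its exact
#' Hardy-Weinberg p (on the configured group) is below `min_hwe_p`; then any
#' sample whose call rate over the retained SNPs is below `min_call_rate` is
#' dropped.
#'
#' @param dataset a [genotype_dataset()].
#' @param min_call_rate minimum fraction of non-missing calls per SNP and
#'   per sample (default 0.95).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param min_hwe_p minimum exact HWE p-value (default 0.01).
#' @param hwe_group group on which HWE is tested: `"controls_only"`
#'   (default) or `"all"`.
#' @return list with `dataset` (the filtered [genotype_dataset()]) and
#'   `report`, a data.frame of exclusions with columns `id`, `kind`
#'   (`"snp"`/`"sample"`), `reason` (`"call_rate"`, `"maf"`, `"hwe"`),
#'   `value` and `threshold`.
#' @export
apply_qc <- function(dataset, min_call_rate = 0.95, min_maf = 0.01,
                     min_hwe_p = 0.01,
                     hwe_group = c("controls_only", "all")) {
  hwe_group <- match.arg(hwe_group)
  stopifnot(min_call_rate > 0, min_call_rate < 1,
            min_maf > 0, min_maf < 1, min_hwe_p > 0, min_hwe_p < 1)
  calls <- dataset$calls
  case <- dataset$phenotypes == 1L
  hwe_rows <- if (hwe_group == "controls_only") !case else rep(TRUE, length(case))
  report <- list()
  keep_snp <- rep(TRUE, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    id <- dataset$snps$snp_id[j]
    cr <- mean(!is.na(calls[, j]))
    if (cr < min_call_rate) {
      keep_snp[j] <- FALSE
      report[[length(report) + 1]] <- data.frame(
        id = id, kind = "snp", reason = "call_rate", value = cr,
        threshold = min_call_rate, stringsAsFactors = FALSE)
      next
    }
    fb <- allele_b_freq(calls[, j], dataset$snps$allele_b[j])
    maf <- min(fb, 1 - fb)
    if (is.na(maf) || maf < min_maf) {
      keep_snp[j] <- FALSE
      report[[length(report) + 1]] <- data.frame(
        id = id, kind = "snp", reason = "maf", value = maf,
        threshold = min_maf, stringsAsFactors = FALSE)
      next
    }
    g <- risk_genotype_counts(calls[hwe_rows, j], dataset$snps$allele_b[j])
    hp <- hwe_exact_test(g[1], g[2], g[3])
    if (hp < min_hwe_p) {
      keep_snp[j] <- FALSE
      report[[length(report) + 1]] <- data.frame(
        id = id, kind = "snp", reason = "hwe", value = hp,
        threshold = min_hwe_p, stringsAsFactors = FALSE)
    }
  }
  if (!any(keep_snp)) stop("all SNPs excluded by QC")
  kept <- subset_dataset(dataset, snps = which(keep_snp))
  keep_sample <- rep(TRUE, length(kept$sample_ids))
  for (i in seq_along(kept$sample_ids)) {
    cr <- mean(!is.na(kept$calls[i, ]))
    if (cr < min_call_rate) {
      keep_sample[i] <- FALSE
      report[[length(report) + 1]] <- data.frame(
        id = kept$sample_ids[i], kind = "sample", reason = "call_rate",
        value = cr, threshold = min_call_rate, stringsAsFactors = FALSE)
    }
  }
  kept <- subset_dataset(kept, samples = which(keep_sample))
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(id = character(), kind = character(), reason = character(),
               value = numeric(), threshold = numeric(), stringsAsFactors = FALSE)
  list(dataset = kept, report = report)
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' For every SNP pair, two-locus haplotype frequencies are estimated from
#' unphased genotypes by EM (only the double heterozygote is ambiguous;
#' iteration stops when the largest haplotype-frequency change is below
#' `tol` or after `max_iter` iterations), and r2 = D^2 / (pA pa pB pb) where
#' D is the haplotype-frequency departure from linkage equilibrium. By
#' default only control samples are used, the standard practice for
#' characterizing background LD. Pairs involving a monomorphic SNP get
#' r2 = 0 and are flagged in the `monomorphic` attribute.
#'
#' @param dataset a [genotype_dataset()].
#' @param group `"controls"` (default), `"cases"` or `"all"`.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return An `ld_matrix`: list with `snp_ids` and symmetric matrix `r2`
#'   (unit diagonal for polymorphic SNPs).
#' @export
pairwise_r2 <- function(dataset, group = c("controls", "cases", "all"),
                        tol = 1e-8, max_iter = 1000) {
  group <- match.arg(group)
  rows <- switch(group,
                 controls = dataset$phenotypes == 0L,
                 cases = dataset$phenotypes == 1L,
                 all = rep(TRUE, length(dataset$phenotypes)))
  m <- ncol(dataset$calls)
  # dosage of allele_b per SNP
  dose <- matrix(NA_integer_, sum(rows), m)
  for (j in seq_len(m)) {
    cell <- dataset$calls[rows, j]
    ok <- !is.na(cell)
    b <- dataset$snps$allele_b[j]
    dose[ok, j] <- as.integer((substr(cell[ok], 1, 1) == b) +
                              (substr(cell[ok], 2, 2) == b))
  }
  poly <- apply(dose, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1
  })
  r2 <- matrix(0, m, m, dimnames = list(dataset$snps$snp_id, dataset$snps$snp_id))
  diag(r2)[poly] <- 1
  mono_flag <- matrix(FALSE, m, m, dimnames = dimnames(r2))
  if (m >= 2) {
    for (j in 1:(m - 1)) {
      for (k in (j + 1):m) {
        if (!poly[j] || !poly[k]) {
          mono_flag[j, k] <- mono_flag[k, j] <- TRUE
          next
        }
        v <- em_r2(dose[, j], dose[, k], tol = tol, max_iter = max_iter)
        r2[j, k] <- r2[k, j] <- v
      }
    }
  }
  structure(list(snp_ids = dataset$snps$snp_id, r2 = r2),
            monomorphic = mono_flag, class = "ld_matrix")
}

# EM estimate of r^2 between two dosage vectors (0/1/2, NA allowed)
em_r2 <- function(gx, gy, tol = 1e-8, max_iter = 1000) {
  ok <- !is.na(gx) & !is.na(gy)
  gx <- gx[ok]; gy <- gy[ok]
  n <- length(gx)
  if (n == 0) return(0)
  # 3x3 genotype table
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[gx[i] + 1, gy[i] + 1] <- tab[gx[i] + 1, gy[i] + 1] + 1
  pA <- mean(gx) / 2  # freq of allele coded 1 at locus X
  pB <- mean(gy) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(0)
  # haplotypes: h11 (x=1,y=1), h10, h01, h00
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ndh <- tab[2, 2]  # double heterozygotes: ambiguous phase
  # unambiguous haplotype counts contributed by the other 8 cells
  base <- c(
    2 * tab[3, 3] + tab[3, 2] + tab[2, 3],   # h11
    2 * tab[3, 1] + tab[3, 2] + tab[2, 1],   # h10
    2 * tab[1, 3] + tab[1, 2] + tab[2, 3],   # h01
    2 * tab[1, 1] + tab[1, 2] + tab[2, 1])   # h00
  total <- 2 * n
  for (it in seq_len(max_iter)) {
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / total
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  D <- h[1] - (h[1] + h[2]) * (h[1] + h[3])
  denom <- (h[1] + h[2]) * (h[3] + h[4]) * (h[1] + h[3]) * (h[2] + h[4])
  if (denom <= 0) return(0)
  min(1, D^2 / denom)
}

#' Greedy LD pruning by association significance
#'
#' Visits SNPs in order of ascending Fisher p (ties by ascending id) and
#' keeps a SNP iff its r2 with every SNP already kept is at most `r2_max`.
#' Only pairs strictly above the threshold are excluded.
#'
#' @param results association data.frame from [snp_association()] (needs
#'   `snp_id` and `fisher_p`).
#' @param ld an `ld_matrix` covering all SNPs in `results`.
#' @param r2_max maximum tolerated pairwise r2 (default 0.8).
#' @return Character vector of kept SNP ids, in visiting order.
#' @export
ld_prune <- function(results, ld, r2_max = 0.8) {
  ord <- order(results$fisher_p, results$snp_id)
  ids <- results$snp_id[ord]
  r2 <- ld$r2[ids, ids, drop = FALSE]
  kept <- character(0)
  for (id in ids) {
    if (length(kept) == 0 || all(r2[id, kept] <= r2_max)) kept <- c(kept, id)
  }
  kept
}

#' Significance-threshold SNP subsets
#'
#' Builds the nested analysis subsets: for each p threshold, the LD-pruned
#' SNPs with Fisher p strictly below it (ordered by ascending p), plus an
#' `"all"` subset containing every SNP with neither thresholding nor
#' pruning.
#'
#' @param results association data.frame from [snp_association()].
#' @param ld an `ld_matrix`.
#' @param thresholds numeric p-value cutoffs (default 0.01, 0.05, 0.1).
#' @param r2_max pruning threshold passed to [ld_prune()].
#' @return Named list of `snp_subset` objects (`label`, `p_threshold`,
#'   `snp_ids`), names `p001`/`p005`/`p01`/.../`all`.
#' @export
select_snp_subsets <- function(results, ld, thresholds = c(0.01, 0.05, 0.1),
                               r2_max = 0.8) {
  pruned <- ld_prune(results, ld, r2_max = r2_max)
  p_of <- setNames(results$fisher_p, results$snp_id)
  subsets <- list()
  for (th in sort(thresholds)) {
    ids <- pruned[p_of[pruned] < th]
    label <- paste0("p", sub("^0\\.", "0", format(th, scientific = FALSE)))
    label <- gsub("\\.", "", label)
    if (length(ids) == 0)
      warning("no SNP passes p < ", th, "; emitting empty subset")
    subsets[[label]] <- structure(
      list(label = label, p_threshold = th, snp_ids = ids),
      class = "snp_subset")
  }
  all_ids <- results$snp_id[order(results$fisher_p, results$snp_id)]
  subsets[["all"]] <- structure(
    list(label = "all", p_threshold = NA_real_, snp_ids = all_ids),
    class = "snp_subset")
  subsets
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests.
#' @param signif_digits significant digits for the reported bound (default 2,
#'   the precision at which such bounds are conventionally quoted).
#' @return The corrected threshold alpha / n_tests, rounded to
#'   `signif_digits` significant digits.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests, signif_digits = 2) {
  signif(alpha / n_tests, signif_digits)
}

#' Write an association table as TSV
#'
#' @param results data.frame from [snp_association()].
#' @param path output path.
#' @export
write_association_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
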