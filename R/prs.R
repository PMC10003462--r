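#' Polygenic risk score weights from association results
#'
#' Per-SNP weight = natural log of the allelic odds ratio, re-estimated on a
#' designated set of samples (by default a training split, so no information
#' from held-out samples leaks into the weights). SNPs monomorphic in the
#' weighting samples get weight 0 with a warning; zero allele cells get the
#' Haldane-Anscombe correction inside [allelic_association()].
#'
#' @param dataset a [genotype_dataset()] with risk alleles assigned.
#' @param sample_ids samples on which to estimate the odds ratios (default
#'   all samples; pass the training ids to guard against leakage).
#' @param snp_ids SNPs to weight (default all in the dataset).
#' @return A `prs_weights` data.frame with columns `snp_id`, `risk_allele`,
#'   `log_or`.
#' @export
compute_weights <- function(dataset, sample_ids = NULL, snp_ids = NULL) {
  if (any(is.na(dataset$snps$risk_allele)))
    stop("risk alleles must be assigned before weighting")
  ds <- subset_dataset(dataset, samples = sample_ids, snps = snp_ids)
  case <- ds$phenotypes == 1L
  out <- data.frame(snp_id = ds$snps$snp_id,
                    risk_allele = ds$snps$risk_allele,
                    log_or = NA_real_, stringsAsFactors = FALSE)
  mono <- character(0)
  for (j in seq_len(nrow(ds$snps))) {
    risk <- ds$snps$risk_allele[j]
    cc <- risk_genotype_counts(ds$calls[case, j], risk)
    kc <- risk_genotype_counts(ds$calls[!case, j], risk)
    a <- cc[2] + 2 * cc[3]; b <- 2 * cc[1] + cc[2]
    cr <- kc[2] + 2 * kc[3]; dr <- 2 * kc[1] + kc[2]
    if ((a + cr == 0) || (b + dr == 0)) {   # monomorphic in these samples
      out$log_or[j] <- 0
      mono <- c(mono, ds$snps$snp_id[j])
      next
    }
    res <- allelic_association(cc, kc, snp_id = ds$snps$snp_id[j])
    out$log_or[j] <- log(res$odds_ratio)
  }
  if (length(mono) > 0)
    warning("monomorphic in weighting samples, weight set to 0: ",
            paste(mono, collapse = ", "))
  class(out) <- c("prs_weights", class(out))
  out
}

#' Compute polygenic risk scores
#'
#' The score of sample j is the weighted risk-allele sum
#' \eqn{\sum_i \log(OR_i) \, x_{ij}} where \eqn{x_{ij}} is the additive
#' genotype (0/1/2). The genotype matrix must be complete; impute first.
#'
#' @param matrix a `genotype_matrix` with no missing entries.
#' @param weights a `prs_weights` data.frame from [compute_weights()].
#' @return data.frame with `sample_id` and `prs`.
#' @export
compute_prs <- function(matrix, weights) {
  absent <- setdiff(weights$snp_id, matrix$snp_ids)
  if (length(absent) > 0)
    stop("weights refer to SNPs absent from the matrix: ",
         paste(absent, collapse = ", "))
  cols <- match(weights$snp_id, matrix$snp_ids)
  X <- matrix$values[, cols, drop = FALSE]
  if (anyNA(X))
    stop("genotype matrix contains missing values; run impute_missing() first")
  data.frame(sample_id = matrix$sample_ids,
             prs = as.numeric(X %*% weights$log_or),
             stringsAsFactors = FALSE)
}

#' Logistic calibration of the polygenic risk score
#'
#' Fits the one-feature logistic regression of case status on PRS, giving a
#' calibrated case probability that is monotone in the score whenever the
#' fitted slope is positive.
#'
#' @param train_scores numeric PRS values for the training samples.
#' @param train_labels binary 0/1 labels.
#' @return A `prs_classifier` with a `fit` (the glm) usable via `predict()`.
#' @export
fit_prs_classifier <- function(train_scores, train_labels) {
  train_labels <- as.integer(train_labels)
  if (length(unique(train_labels)) < 2)
    stop("both classes must be present in the training labels")
  fit <- suppressWarnings(
    glm(train_labels ~ train_scores, family = binomial()))
  structure(list(fit = fit), class = "prs_classifier")
}

#' @param object a `prs_classifier`.
#' @param scores numeric PRS values to score.
#' @param ... unused.
#' @return Case probabilities in \[0, 1\].
#' @rdname fit_prs_classifier
#' @export
predict.prs_classifier <- function(object, scores, ...) {
  as.numeric(predict(object$fit,
                     newdata = data.frame(train_scores = scores),
                     type = "response"))
}

#' Write PRS weights / scores as TSV
#'
#' @param x a `prs_weights` or score data.frame.
#' @param path output path.
#' @export
write_prs_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
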