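#' Construct a case-control genotype dataset
#'
#' The central data container: biallelic genotype calls for a set of samples
#' with a binary phenotype (1 = case, 0 = control) and per-SNP metadata.
#' Calls are stored as unordered allele pairs in a character matrix
#' (samples x SNPs), each cell the two allele letters in alphabetical order
#' (e.g. `"AG"`), with `NA` for a missing call.
#'
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b` and optionally `risk_allele` (NA until assigned).
#' @param sample_ids character vector of unique sample identifiers.
#' @param phenotypes integer vector, one per sample, 1 = case, 0 = control.
#' @param calls character matrix `length(sample_ids)` x `nrow(snps)` of
#'   two-letter sorted allele pairs or `NA`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(snps, sample_ids, phenotypes, calls) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  needed <- c("snp_id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols) > 0)
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"risk_allele" %in% names(snps)) snps$risk_allele <- NA_character_
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in SNP table")
  if (any(snps$allele_a == snps$allele_b))
    stop("allele_a must differ from allele_b for every SNP")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != length(sample_ids))
    stop("phenotype must be defined for every sample")
  if (!all(phenotypes %in% c(0L, 1L)))
    stop("phenotypes must be 0 (control) or 1 (case)")
  calls <- as.matrix(calls)
  if (nrow(calls) != length(sample_ids) || ncol(calls) != nrow(snps))
    stop("calls must be |samples| x |snps|")
  dimnames(calls) <- list(sample_ids, snps$snp_id)
  ok <- validate_calls(calls, snps)
  if (!is.null(ok)) stop(ok)
  structure(
    list(snps = snps, sample_ids = as.character(sample_ids),
         phenotypes = phenotypes, calls = calls),
    class = "genotype_dataset")
}

validate_calls <- function(calls, snps) {
  for (j in seq_len(ncol(calls))) {
    col <- calls[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0) next
    legal <- sorted_pairs(snps$allele_a[j], snps$allele_b[j])
    bad <- setdiff(unique(col), legal)
    if (length(bad) > 0)
      return(paste0("SNP ", snps$snp_id[j], " has calls outside its alleles: ",
                    paste(bad, collapse = ", ")))
  }
  NULL
}

# the three legal unordered pairs for a biallelic SNP, canonically sorted
sorted_pairs <- function(a, b) {
  al <- sort(c(a, b))
  c(paste0(al[1], al[1]), paste0(al[1], al[2]), paste0(al[2], al[2]))
}

# canonical cell from two allele characters ("0" = missing in PLINK)
canonical_call <- function(a1, a2) {
  out <- rep(NA_character_, length(a1))
  ok <- a1 != "0" & a2 != "0" & !is.na(a1) & !is.na(a2)
  lo <- pmin(a1[ok], a2[ok])
  hi <- pmax(a1[ok], a2[ok])
  out[ok] <- paste0(lo, hi)
  out
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls), %d SNPs\n",
              length(x$sample_ids), sum(x$phenotypes == 1L),
              sum(x$phenotypes == 0L), nrow(x$snps)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the standard PLINK pedigree text pair. The `.map` file supplies SNP
#' ids and coordinates (chromosome, id, genetic distance, base-pair position);
#' the `.ped` file supplies one row per sample: FID, IID, father, mother, sex,
#' phenotype, then two allele columns per SNP. Allele code `"0"` means a
#' missing call. Phenotypes follow the PLINK convention 1 = control,
#' 2 = case unless `pheno01 = TRUE`, in which case 0/1 codes are accepted
#' directly.
#'
#' Alleles for each SNP are inferred from the observed calls; monomorphic
#' SNPs are given a placeholder second allele so the biallelic invariant
#' holds.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @param pheno01 logical; accept 0/1 phenotype codes instead of 1/2.
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, pheno01 = FALSE) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(vapply(map_fields, length, 1L) != 4L)
  if (length(bad) > 0)
    stop("malformed .map line ", bad[1], ": expected 4 fields")
  map <- do.call(rbind, map_fields)
  snp_ids <- map[, 2]
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in .map")
  n_snp <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_snp
  widths <- vapply(ped_fields, length, 1L)
  if (any(widths != expected))
    stop("malformed .ped line ", which(widths != expected)[1],
         ": expected ", expected, " fields, found ", widths[widths != expected][1])
  ped <- do.call(rbind, ped_fields)
  sample_ids <- ped[, 2]
  if (anyDuplicated(sample_ids)) sample_ids <- paste(ped[, 1], ped[, 2], sep = "_")

  ph_raw <- ped[, 6]
  if (pheno01) {
    if (!all(ph_raw %in% c("0", "1")))
      stop("phenotype codes must be 0/1 when pheno01 = TRUE; found: ",
           paste(setdiff(unique(ph_raw), c("0", "1")), collapse = ", "))
    phenotypes <- as.integer(ph_raw)
  } else {
    if (!all(ph_raw %in% c("1", "2")))
      stop("phenotype codes must be 1 (control) / 2 (case); found: ",
           paste(setdiff(unique(ph_raw), c("1", "2")), collapse = ", "))
    phenotypes <- as.integer(ph_raw) - 1L
  }

  n_sample <- nrow(ped)
  calls <- matrix(NA_character_, n_sample, n_snp)
  snps <- data.frame(
    snp_id = snp_ids, chromosome = map[, 1],
    position = as.integer(map[, 4]),
    allele_a = NA_character_, allele_b = NA_character_,
    risk_allele = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(n_snp)) {
    a1 <- ped[, 6L + 2L * j - 1L]
    a2 <- ped[, 6L + 2L * j]
    calls[, j] <- canonical_call(a1, a2)
    obs <- sort(unique(c(a1, a2)))
    obs <- setdiff(obs, "0")
    if (length(obs) > 2)
      stop("SNP ", snp_ids[j], " has more than two alleles: ",
           paste(obs, collapse = ", "))
    if (length(obs) == 0) obs <- c("A", "B")           # fully missing column
    if (length(obs) == 1) obs <- c(obs, placeholder_allele(obs))
    snps$allele_a[j] <- obs[1]
    snps$allele_b[j] <- obs[2]
  }
  genotype_dataset(snps, sample_ids, phenotypes, calls)
}

placeholder_allele <- function(seen) setdiff(c("A", "C", "G", "T", "B"), seen)[1]

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]; round-trips calls, order and phenotypes
#' exactly. Missing calls are written as `"0 0"`.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @param pheno01 write 0/1 phenotype codes instead of PLINK 1/2.
#' @export
write_plink_text <- function(dataset, ped_path, map_path, pheno01 = FALSE) {
  snps <- dataset$snps
  map <- paste(snps$chromosome, snps$snp_id, 0, snps$position, sep = "\t")
  writeLines(map, map_path)

  ph <- if (pheno01) dataset$phenotypes else dataset$phenotypes + 1L
  n <- length(dataset$sample_ids)
  rows <- character(n)
  allele_cols <- matrix("0", n, 2L * nrow(snps))
  for (j in seq_len(nrow(snps))) {
    cell <- dataset$calls[, j]
    ok <- !is.na(cell)
    allele_cols[ok, 2L * j - 1L] <- substr(cell[ok], 1, 1)
    allele_cols[ok, 2L * j] <- substr(cell[ok], 2, 2)
  }
  for (i in seq_len(n)) {
    rows[i] <- paste(c(dataset$sample_ids[i], dataset$sample_ids[i],
                       "0", "0", "0", ph[i], allele_cols[i, ]), collapse = "\t")
  }
  writeLines(rows, ped_path)
  invisible(dataset)
}

#' Read a TSV genotype matrix
#'
#' A simple wide dialect: columns `sample_id`, `phenotype`, then one column
#' per SNP named by its id, each cell a two-letter allele pair (e.g. `"AG"`)
#' or `"NA"` for missing. Phenotypes are 0/1.
#'
#' @param path path to the TSV file.
#' @return A [genotype_dataset()]. Chromosome/position metadata is not
#'   carried by this dialect and is filled with placeholders.
#' @export
read_genotype_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate column names in genotype TSV: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(tab)))
    stop("genotype TSV needs 'sample_id' and 'phenotype' columns")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in genotype TSV")
  snp_ids <- setdiff(names(tab), c("sample_id", "phenotype"))
  calls <- as.matrix(tab[, snp_ids, drop = FALSE])
  calls[calls == "NA" | calls == ""] <- NA_character_
  # canonicalize the pair ordering
  calls[] <- ifelse(is.na(calls), NA_character_,
                    canonical_call(substr(calls, 1, 1), substr(calls, 2, 2)))
  snps <- data.frame(snp_id = snp_ids, chromosome = "0",
                     position = seq_along(snp_ids),
                     allele_a = NA_character_, allele_b = NA_character_,
                     risk_allele = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(snp_ids)) {
    obs <- sort(unique(unlist(strsplit(calls[!is.na(calls[, j]), j], ""))))
    if (length(obs) > 2)
      stop("SNP ", snp_ids[j], " has more than two alleles")
    if (length(obs) == 0) obs <- c("A", "B")
    if (length(obs) == 1) obs <- c(obs, placeholder_allele(obs))
    snps$allele_a[j] <- obs[1]
    snps$allele_b[j] <- obs[2]
  }
  genotype_dataset(snps, tab$sample_id, as.integer(tab$phenotype), calls)
}

#' Write a TSV genotype matrix
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @export
write_genotype_tsv <- function(dataset, path) {
  cells <- dataset$calls
  cells[is.na(cells)] <- "NA"
  tab <- data.frame(sample_id = dataset$sample_ids,
                    phenotype = dataset$phenotypes,
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Additive (risk-allele count) encoding
#'
#' Maps every call to the number of risk alleles it carries: 0, 1 or 2.
#' Missing calls stay missing (`NA`). Requires [assign_risk_alleles()] (or a
#' manually set `risk_allele` column) first.
#'
#' @param dataset a [genotype_dataset()] with `risk_allele` set for every SNP.
#' @return A `genotype_matrix`: list with integer matrix `values`
#'   (samples x SNPs, entries 0/1/2/NA), `snp_ids`, `sample_ids`,
#'   `phenotypes`.
#' @export
encode_additive <- function(dataset) {
  risk <- dataset$snps$risk_allele
  if (any(is.na(risk)))
    stop("risk_allele unset for: ",
         paste(head(dataset$snps$snp_id[is.na(risk)], 5), collapse = ", "),
         " - run assign_risk_alleles() first")
  values <- matrix(NA_integer_, nrow(dataset$calls), ncol(dataset$calls),
                   dimnames = dimnames(dataset$calls))
  for (j in seq_along(risk)) {
    cell <- dataset$calls[, j]
    ok <- !is.na(cell)
    n_risk <- (substr(cell[ok], 1, 1) == risk[j]) +
              (substr(cell[ok], 2, 2) == risk[j])
    values[ok, j] <- as.integer(n_risk)
  }
  structure(list(values = values, snp_ids = dataset$snps$snp_id,
                 sample_ids = dataset$sample_ids,
                 phenotypes = dataset$phenotypes),
            class = "genotype_matrix")
}

#' Decode an additive matrix back to allele-pair calls
#'
#' Inverse of [encode_additive()] given the SNP metadata: 2 maps to the
#' risk-allele homozygote, 1 to the heterozygote, 0 to the non-risk
#' homozygote.
#'
#' @param matrix a `genotype_matrix` from [encode_additive()].
#' @param snps the SNP metadata table of the originating dataset.
#' @return Character matrix of canonical calls with `NA` for missing.
#' @export
decode_additive <- function(matrix, snps) {
  stopifnot(identical(matrix$snp_ids, snps$snp_id))
  out <- base::matrix(NA_character_, nrow(matrix$values), ncol(matrix$values),
                      dimnames = dimnames(matrix$values))
  for (j in seq_along(matrix$snp_ids)) {
    r <- snps$risk_allele[j]
    nr <- ifelse(snps$allele_a[j] == r, snps$allele_b[j], snps$allele_a[j])
    lut <- c(canonical_call(nr, nr), canonical_call(nr, r), canonical_call(r, r))
    v <- matrix$values[, j]
    ok <- !is.na(v)
    out[ok, j] <- lut[v[ok] + 1L]
  }
  out
}

#' LD-guided imputation of missing genotypes
#'
#' Fills each missing additive genotype deterministically using the linkage
#' structure: for SNP s in sample i, find s's highest-r2 partner SNP with
#' r2 >= `min_r2`; among samples whose partner genotype equals sample i's,
#' take the modal genotype of s (conditional mode). If no partner qualifies,
#' the partner call is itself missing, or the stratum is empty, fall back to
#' the overall modal genotype of s. Ties always break toward the smaller
#' genotype value.
#'
#' @param matrix a `genotype_matrix` (possibly with `NA` entries).
#' @param ld an `ld_matrix` from [pairwise_r2()] covering the same SNPs.
#' @param min_r2 minimum squared correlation for a partner SNP to be used
#'   for conditioning (default 0.3, below which LD carries little
#'   information about the missing call).
#' @return The same `genotype_matrix` with no missing values; non-missing
#'   entries are never altered.
#' @export
impute_missing <- function(matrix, ld, min_r2 = 0.3) {
  values <- matrix$values
  if (!all(matrix$snp_ids %in% ld$snp_ids))
    stop("LD matrix does not cover all SNPs in the genotype matrix")
  r2 <- ld$r2[matrix$snp_ids, matrix$snp_ids, drop = FALSE]
  diag(r2) <- 0
  for (j in seq_len(ncol(values))) {
    miss <- which(is.na(values[, j]))
    if (length(miss) == 0) next
    col_obs <- values[, j]
    if (all(is.na(col_obs)))
      stop("SNP ", matrix$snp_ids[j],
           " is missing in every sample; no mode defined")
    overall <- modal_genotype(col_obs)
    partners <- order(-r2[, j], seq_len(ncol(values)))  # ties -> smaller index
    best <- partners[1]
    use_partner <- r2[best, j] >= min_r2
    for (i in miss) {
      filled <- NA_integer_
      if (use_partner && !is.na(values[i, best])) {
        stratum <- which(values[, best] == values[i, best] & !is.na(col_obs))
        if (length(stratum) > 0)
          filled <- modal_genotype(col_obs[stratum])
      }
      if (is.na(filled)) filled <- overall
      values[i, j] <- filled
    }
  }
  matrix$values <- values
  matrix
}

# mode of 0/1/2 values ignoring NA, ties toward the smaller value
modal_genotype <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_integer_)
  counts <- tabulate(v + 1L, nbins = 3L)
  as.integer(which.max(counts) - 1L)
}

#' Restrict a genotype dataset to a subset of samples and/or SNPs
#'
#' @param dataset a [genotype_dataset()].
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return A [genotype_dataset()].
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(dataset$sample_ids)
        else if (is.character(samples)) match(samples, dataset$sample_ids)
        else samples
  vj <- if (is.null(snps)) seq_len(nrow(dataset$snps))
        else if (is.character(snps)) match(snps, dataset$snps$snp_id)
        else snps
  if (anyNA(si)) stop("unknown sample ids")
  if (anyNA(vj)) stop("unknown SNP ids")
  genotype_dataset(dataset$snps[vj, , drop = FALSE],
                   dataset$sample_ids[si],
                   dataset$phenotypes[si],
                   dataset$calls[si, vj, drop = FALSE])
}
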