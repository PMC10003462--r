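# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: hypergeometric masses from log-factorials instead
# of fisher.test / the package's tests, AUC by explicit pair enumeration,
# binomial coefficients by Pascal's triangle.

# two-sided Fisher p on a 2x2 table by full enumeration:
# sum of P(table) over all tables with the observed margins whose point
# probability is <= the observed one
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(xs))
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact HWE p by enumerating every heterozygote count compatible with the
# allele counts (independent of the package's log-space shortcut: this one
# computes each multinomial mass directly and normalizes at the end)
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * min(n_AA, n_aa)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  if (length(hets) <= 1) return(1.0)
  mass <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - h - aa
    exp(lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
          h * log(2) +
          lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  mass <- mass / sum(mass)
  obs <- mass[match(n_Aa, hets)]
  min(1, sum(mass[mass <= obs * (1 + 1e-9)]))
}

# AUC by explicit enumeration of all case-control pairs, ties half credit
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) for (y in controls)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(cases) * length(controls))
}

# exact binomial coefficient by Pascal's triangle (exact in doubles < 2^53)
oracle_choose <- function(n, k) {
  row <- 1
  for (i in seq_len(n)) row <- c(1, head(row, -1) + row[-1], 1)[seq_len(i + 1)]
  row[k + 1]
}

# Brier score
brier <- function(prob, labels) mean((prob - labels)^2)
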