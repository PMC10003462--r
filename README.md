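# gannet

Case–control disease risk classification from candidate-gene SNP panels with
a **g**enetic-**a**lgorithm-optimized **n**eural **net**work ensemble, plus
the full statistical scaffolding a SNP association study needs: quality
control, exact tests, linkage-disequilibrium (LD) pruning, polygenic risk
scores, conventional machine-learning baselines and a repeated-run
evaluation harness. A synthetic genotype simulator with known causal
structure makes every stage testable end to end.

The package is written for statistical geneticists working with modest
candidate-gene panels (tens of SNPs, hundreds of subjects) — the regime in
which feature selection, not network capacity, decides predictive power.

## The method

Given biallelic genotypes for *n* subjects (binary phenotype, 1 = case) and
*m* SNPs encoded additively (x<sub>ij</sub> ∈ {0, 1, 2} risk-allele
copies):

1. **Association scaffolding.** Per SNP: exact Hardy–Weinberg test
   (Wigginton-style, control group), two-sided Fisher's exact test on the
   2×2 allele table, sample odds ratio OR = ad/bc with Woolf 95% CI
   exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d)), risk-allele frequencies.
   Pairwise r² by EM haplotype-frequency estimation in controls; greedy
   pruning drops a SNP whose r² with a better-ranked SNP exceeds 0.8.
   Significance-threshold subsets at p < 0.01, 0.05, 0.1 and "all".
2. **PRS.** PRS<sub>j</sub> = Σ<sub>i</sub> log(OR<sub>i</sub>)
   x<sub>ij</sub>, weights estimated on training samples only, calibrated by
   one-feature logistic regression.
3. **GANNE.** A genetic algorithm searches fixed-size SNP subsets
   (k ∈ {3, 10, 16}; chromosomes are exact k-subsets, all operators
   conserve size). Fitness of a subset = training loss + validation loss of
   a small feed-forward network (two ReLU hidden layers of width
   8/16/32/64 for 3/10/16/92 inputs, sigmoid head, Adam at 5×10⁻³ with
   10⁻⁵ per-update decay, 100 epochs, best-validation-loss checkpoint
   restored). One population is seeded with the top-k association SNPs.
   Five independent GA runs plus the association subset give six SNP sets;
   one network per set; the ensemble prediction is the unweighted mean of
   the six case probabilities. For k = 10 over 92 SNPs the search space is
   C(92,10) = 7,210,666,060,598 subsets.
4. **Evaluation.** Accuracy, support-weighted F1 and rank-statistic AUC;
   a 100-iteration harness reports means and empirical 2.5/97.5-percentile
   intervals.

## Worked example

```r
library(gannet)

spec  <- default_sim_spec()                 # study-like panel: 92 SNPs, 143/119
sim   <- simulate_genotypes(spec, seed = 1)
sim$dataset
#> genotype_dataset: 262 samples (143 cases / 119 controls), 92 SNPs
#> missing calls: 1.97%

split <- make_split(sim$dataset, seed = 1)  # 180 train / 20 val / 62 test
ds    <- assign_risk_alleles(sim$dataset)
res   <- snp_association(ds)
head(res[order(res$fisher_p),
         c("snp_id", "odds_ratio", "ci_low", "ci_high", "fisher_p", "hwe_p")], 3)
#>    snp_id odds_ratio ci_low ci_high fisher_p hwe_p
#> 5  snp005       2.19   1.53    3.14 1.69e-05 0.553
#> 6  snp006       2.46   1.55    3.90 8.38e-05 0.214
#> 1  snp001       1.99   1.39    2.85 1.93e-04 1.000

ld      <- pairwise_r2(ds)                  # EM r2 in controls
subsets <- select_snp_subsets(res, ld)      # p001 / p005 / p01 / all
sapply(subsets, function(s) length(s$snp_ids))
#> p001 p005  p01  all
#>    7   10   13   92

mat <- impute_missing(encode_additive(ds), ld)
cfg <- ga_config(subset_size = 10, population_size = 10, cycles = 10, epochs = 50)
ens <- run_gannet(mat, split, ld_prune(res, ld), cfg, seed = 1)
pred <- ensemble_predict(ens, mat)
compute_metrics(pred$probability[split$test], mat$phenotypes[split$test])
#> test accuracy 0.629, weighted F1 0.639, AUC 0.711
```

The six ensemble members used 38 distinct SNPs here — the GA explores well
beyond the ten top-ranked markers. Association statistics on this simulated
panel recover the generator's planted odds ratios (e.g. snp001 was planted
at OR 1.91, control RAF 0.513 and is estimated at OR 1.99).

A command-line wrapper with `simulate`, `assoc`, `prs`, `run` and
`evaluate` subcommands lives at `inst/cli/gannet.R`:

```sh
Rscript inst/cli/gannet.R simulate --seed 1 --out sim/
Rscript inst/cli/gannet.R assoc --tsv sim/genotypes.tsv --out assoc/
Rscript inst/cli/gannet.R run --tsv sim/genotypes.tsv --k 10 --seed 7 --out run/
```

Every subcommand writes a `manifest.json` (arguments, seed, package
version, input checksums); identical configuration and seed reproduce every
output byte for byte.

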