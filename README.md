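# heterogen

Additive and dominance genomic dissection of heterosis in crossbred
populations.

## The problem

Crossbreeding a fast-growing commercial sire line with a local dam breed
produces F1 offspring that routinely outperform the mean of their parents —
heterosis. Because heterosis is driven by non-additive gene action, an
analysis that only models additive effects misses the part of the genetic
architecture that makes crossbreeding work. `heterogen` is a pipeline for
quantitative geneticists working with F1 populations (the motivating design
is a pig cross: 6 sires × 24 dams → 171 offspring genotyped on a medium
density SNP array) who want to

1. adjust raw growth records (age, ultrasonic backfat) to a common 100 kg
   body-weight endpoint,
2. quantify heterosis as mid-parent heterosis (MPH),
3. partition genetic variance into additive and dominance components with
   genomic relationship matrices,
4. use the resulting partial genetic values (PGVs) as derived phenotypes, and
5. map loci with additive- and dominance-coded mixed-model GWAS combined
   across engines.

## The model

Phenotypes follow the two-kernel mixed model

    y = Xb + u_a + u_d + e,
    u_a ~ N(0, G_a σ²_a),  u_d ~ N(0, G_d σ²_d),  e ~ N(0, I σ²_e)

with the additive genomic relationship matrix (VanRaden method 1)

    G_a = Z Z' / Σ_j 2 p_j (1 − p_j),      Z_ij = m_ij − 2 p_j,

where `m_ij ∈ {0,1,2}` counts copies of the counted allele, and the dominance
relationship built from the heterozygosity coding

    G_d = W W' / Σ_j [2 p_j (1 − p_j)]²,   W_ij = h_ij − 2 p_j (1 − p_j),

with `h_ij = 1` for heterozygotes. The model is fitted by
average-information REML (`fit_reml()`, the fast default) or by a Gibbs
sampler over the kernel eigenspaces (`fit_gibbs()`, the Bayesian
counterpart). Derived summaries are the heritabilities
`h²_a = σ²_a / (σ²_a + σ²_d + σ²_e)`, `h²_d` likewise, and the dominance
share of total genetic variance `σ²_d / (σ²_a + σ²_d)`. The BLUP effect
vectors are the partial genetic values `y_a = u_a`, `y_d = u_d` (one record
per animal), which feed the scans as derived phenotypes.

Association scans are EMMAX-style: variance components are profiled once on
the null model (P3D), then each SNP column of the chosen coding (additive `Z`
or dominance `W`) is tested by generalized least squares with a Wald test.
A stepwise multi-locus engine promotes significant SNPs to cofactors and
selects the model by extended BIC. Scans are combined by an ensemble rule:
a SNP is reported when at least `min_support` engines call it below the
Bonferroni tier (genome-wide significant `0.05/N`, suggestive `1/N`).

## Worked example

```r
library(heterogen)

# a seeded F1 cross: two diverged parental pools, 6 sires x 24 dams -> 171 F1
cross <- simulate_f1_cross(n_snps = 2000, seed = 42)
f1 <- cross$phenotypes$value[cross$phenotypes$role == "f1"]
mph <- mid_parent_heterosis(f1, cross$parental_means["p1"],
                            cross$parental_means["p2"],
                            group = cross$pedigree$sire[cross$pedigree$role == "f1"])
mph
#> mid-parent heterosis over 6 group(s)
#>   group  n f1_mean  p1  p2 midparent mph_of_group_mean mean_of_individual_mph
#>  sire01 29     237 224 230       227              4.49                   4.49
#>  sire02 29     234 224 230       227              3.18                   3.18
#>  sire03 29     243 224 230       227              6.81                   6.81
#>  sire04 28     240 224 230       227              5.55                   5.55
#>  sire05 28     236 224 230       227              4.06                   4.06
#>  sire06 28     241 224 230       227              6.30                   6.30

# variance decomposition on the F1s
g <- cross$genotypes[cross$pedigree$role == "f1", ]
qc <- qc_filter(impute_missing(g), phase = "post")
d <- build_designs(qc$genotypes)
Ga <- additive_grm(d); Gd <- dominance_grm(d)
fit <- fit_reml(f1, Ga, Gd)
heritability_summary(fit$vc)
#>   sigma2_a sigma2_d  sigma2_e      h2_a       h2_d dominance_share
#> 1 45.06998 4.579215 0.2323322 0.9035405 0.09180182      0.09223141

# PGVs as derived phenotypes for the scans
pgv <- partial_genetic_values(fit)
scan_a <- scan_single_locus(pgv$ya, d, Ga, "additive")
scan_m <- scan_multi_locus(pgv$ya, d, Ga, "additive")
th <- bonferroni_thresholds(nrow(scan_a))
ensemble_combine(list(mlm = scan_a, mlmm = scan_m), th, min_support = 2)
#>        snp chr     pos n_support  engines       best_p       tier
#> 1 snp00668   6 1110000         2 mlm,mlmm 0.0002467808 suggestive
#> 2 snp01985  18  960000         2 mlm,mlmm 0.0002903138 suggestive
manhattan_plot(scan_a, th)
```

(The high `h2_a` here reflects the simulated cross's strong polygenic trait
with little residual noise; it is the example's architecture, not a claim
about real data.)

Every positive group-level MPH says the sire family's F1 mean exceeds the
mid-parent value by that percentage; the `heritability_summary()` row gives
the additive/dominance split of the trait; the ensemble table lists SNPs
supported by at least two engines, ready for `annotate_nearest_gene()`.

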