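---
title: "Methods: partitioning additive and dominance variance and mapping both in F1 crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning additive and dominance variance and mapping both in F1 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`heterogen` analyses heterosis in F1 populations in five stages: record
adjustment, heterosis quantification, variance decomposition, derived
phenotypes, and association scans. This vignette states the models, the
defaults and why, the numerical choices, and what the bundled simulations do
and do not show.

## Record adjustment and mid-parent heterosis

Growth records taken near (not at) a 100 kg endpoint are adjusted linearly:

* age: `100AGE = AGE + (100 − wt)(AGE − A)/wt`, with sex-specific intercepts
  `A_sire = 50.775` and `A_sow = 46.415` days;
* backfat: `100BF = BF + (100 − wt)·BF/(wt − B)`, with `B_sire = −7.277` and
  `B_sow = −9.440` kg.

Both are the identity at `wt = 100`; records above 100 kg adjust downward.
The constants are the conventional sire/sow correction coefficients for this
endpoint and are overridable via `adjustment_constants()`. The backfat
denominator `wt − B` is guarded (must be positive).

Mid-parent heterosis is `MPH = (F1 − MP)/MP × 100` with `MP = (P1 + P2)/2`.
Parental values are *inputs*: how purebred reference means were obtained is a
study-design question the package does not guess at; the simulator generates
them. Per sire family, two group summaries are reported and labelled
distinctly — the MPH of the group-mean F1 value and the mean of individual
MPH values — because they differ whenever mid-parent values vary within a
group. For lower-is-better traits (age at 100 kg; arguably backfat) the index
is reported signed as defined; `negate = TRUE` flips it for reporting
convenience only.

## Genotype handling

Genotypes travel as an `n × m` matrix of counted-allele dosages (0/1/2, `NA`
missing) with a SNP map. PLINK bed/bim/fam and VCF (GT field, biallelic
records; multiallelic records skipped with a warning) decode to identical
objects when A1 = ALT. QC is two-phase, mirroring array practice: before
imputation, non-autosomal SNPs (labels outside "1"–"18", the pig autosomes)
and SNPs with call rate strictly below 0.95 are dropped; the MAF filter
(strictly below 0.01, folded `min(p, 1−p)`) runs *after* imputation.
Imputation is single-marker — per-SNP mode (ties to the smaller code) or a
seeded draw from observed genotype frequencies. Haplotype-based imputation is
deliberately out of scope, so marker-retention counts from pipelines that
phase and impute with a haplotype model will differ slightly from this
package's counts.

Design codings are centered, not variance-scaled: `Z = m − 2p` (additive) and
`W = h − 2p(1−p)` (dominance, `h` the heterozygote indicator). The kinship
denominators carry the scale — column-scaling as well would double-normalize.
Allele frequencies come from the analysis sample after imputation.

A consequence worth stating: the `0/1/0` dominance coding is *not* orthogonal
to the additive coding locus by locus — `cov(Z, W) = H(1 − 2p)` with
`H = 2p(1−p)` — and the off-diagonals of the two relationship matrices
inherit a small positive correlation (`≈ 0.16` for a U(0.05, 0.5) MAF
spectrum) that does not vanish with panel size. Exact orthogonality would
require the natural-and-orthogonal parameterization; this package keeps the
field's heterozygosity coding because it is what the dominance-GRM
construction it implements is defined with. Tests therefore check these
correlations against their coding-implied closed forms, not against zero.

## Relationship matrices

`G_a = ZZ'/Σ 2p(1−p)` (VanRaden method 1; expected diagonal 1 under HWE) and
`G_d = WW'/Σ [2p(1−p)]²`. The expected `G_d` diagonal is
`Σ H(1−H) / Σ H²` — about 1.47 for a uniform MAF spectrum, *not* 1; the
denominator follows the published construction rather than a
diagonal-normalizing choice. Stored matrices are exactly these formulas; a
`1e−6` diagonal ridge is added only inside solvers. F1 individuals from
diverged pools show visibly elevated `G_d` diagonals (excess
heterozygosity) — a useful sanity check on real crossbred data. GCTA binary
and TSV output are supported.

## Variance decomposition

The two-kernel model `y = Xb + u_a + u_d + e` is fitted two ways.

**AI-REML** (`fit_reml`, default): average-information updates with
step-halving, an active-set treatment of components pinned at the floor
(`1e−8 · var(y)`; hitting it is messaged), and EM fallback steps when the AI
system is singular. Convergence requires a stable restricted likelihood and
either a small projected gradient or a stationary parameter vector;
non-convergence is an error carrying the likelihood trace. Standard errors
come from the inverse AI matrix; BLUPs are
`u_a = σ̂²_a G_a V̂⁻¹(y − Xb̂)` and likewise for `u_d`. Traces use
`tr(V⁻¹G) = Σ (V⁻¹ ∘ G)`, keeping each iteration at one Cholesky plus
matrix–vector work, which is what makes the 50-replicate recovery study at
n = 2000 affordable.

**Gibbs** (`fit_gibbs`): the Bayesian counterpart, mirroring the
semi-parametric (RKHS-type) route. Effects are parameterized in the kernel
eigenspaces, making every conditional update diagonal and conjugate;
variance components get scaled-inverse-χ² priors with `df0 = 5` and prior
scale `var(y)/3` (an equal three-way split — the original analysis's prior
hyperparameters are unstated, so these defaults are this package's choice
and are exposed). Chains are seeded and bit-reproducible. Defaults: 12,000
iterations, 2,000 burn-in, thinning 5.

Heritability conventions: `fit_reml` reports plug-in ratios of the point
estimates. `fit_gibbs` reports *both* the ratio of posterior means and the
posterior mean of per-iteration ratios, labelled distinctly — published
tables built from per-iteration MCMC summaries report the latter, and the
two can differ noticeably (a published additive heritability of 0.3322
alongside components whose plug-in ratio is 0.277 is consistent with the
per-iteration convention, not with plug-in arithmetic).

With one record per animal the incidence matrices are identity, so the
partial genetic values are the BLUP vectors themselves: `y_a = u_a`,
`y_d = u_d`. They are the response vectors handed to the scans.

## Association scans

**Single-locus engine** (`scan_single_locus`): EMMAX-style P3D. The variance
ratio `δ = σ²_e/σ²_g` is profiled by REML on the null model in the GRM's
eigenbasis (`optimize` on `log δ ∈ [−12, 12]`), then every marker column is
tested by GLS with a Wald test (`z` against the standard normal; per-marker
residual variance with the usual df correction). The variance-structure GRM
matches the tested coding (dominance GRM for dominance scans) by convention,
switchable for sensitivity analysis. `p3d = FALSE` re-profiles per marker and
is the exact reference, kept for testing. Markers collinear with the fixed
effects yield `NA` p-values with a warning; plots draw every tested SNP.

Measured null calibration (n = 500, m = 2000, 60 replicates): fraction of
p < 0.05 is 0.0498. The residual ~0.002 deflation of a t-referenced variant
traces to the null REML absorbing noise along top GRM eigendirections
(proximal contamination); leave-one-chromosome-out kinship would remove it
but is out of scope here, as it is in the engines this one mirrors.

**Multi-locus engine** (`scan_multi_locus`): forward stepwise in the spirit
of MLMM. Each step promotes the most significant SNP to a cofactor and
re-profiles `δ`; the loop stops when the null pseudo-heritability drops below
0.01 or `max_cofactors` (10) is reached. Among visited models, the one
minimizing the extended BIC — ML deviance in the rotated model (including the
`Σ log w` term, without which models at different variance ratios are not
comparable) plus `k(log n + 2γ log m)` — is selected. `γ = 1`: with
`γ = 0.5` roughly 40% of null panels (n = 500, m = 2000) admit one spurious
cofactor, while `γ = 1` keeps nulls clean and still recovers two 15%-variance
QTNs reliably. Reported p-values come from the selected model; each cofactor
is tested against the others.

**Thresholds and ensemble**: Bonferroni only — genome-wide significant
`0.05/N` and suggestive `1/N` (ratio exactly 20). The ensemble rule reports a
SNP when at least `min_support = 2` engines call it below the chosen tier.
The published integration strategy this mirrors is specified in a reference
we do not re-implement; "two engines at the suggestive tier" is this
package's explicit stand-in, config-exposed. In the replication study,
single-engine detections are counted at the significant tier and the
ensemble at the suggestive tier with double support — the stated rationale
for a suggestive tier is exactly "don't miss true hints", and requiring two
independent engines is what keeps that looser tier honest.

**Annotation**: nearest gene per SNP from a GFF3 (via `rtracklayer`), with
genomic-coordinate sign convention (+ gene at higher coordinates, − lower,
0 inside), ties to the smaller start coordinate (messaged), and gene strand
carried along but not used for the sign — whether published distance signs
are strand-aware is not stated, so the package records both pieces.

## The simulator, and what the tests do and do not show

`simulate_genotypes` draws per-SNP MAF from U(0.05, 0.5), assigns the
counted allele to the minor or major allele with equal probability (as on a
real array; this also makes coding-correlation averages meaningful), and
samples Binomial(2, p) genotypes — HWE, no population structure. Optional
AR(1) latent-Gaussian thresholding induces local LD; the default is
LD-free. `simulate_phenotype` plants 20 QTNs with N(0, 1) effects on the
additive (0/1/2) or dominance (0/1/0) coding and rescales
mean-and-slope-orthogonalized residuals so realized heritability equals the
0.5 target *exactly* — power comparisons then never confound heritability
sampling noise. In dominance mode all genetic variance is dominance
variance, so the 0.5 is broad-sense. QTNs stay in the tested panel (exact
match detection needs them); a window rule is available.

`simulate_f1_cross` defaults to the motivating mating design (6 sires, 24
dams, 171 F1). Pool allele frequencies diverge from a common ancestor by a
Balding–Nichols draw (Fst-like parameter 0.2); gametes are drawn per locus
from parental dosages (no linkage). The trait places additive effect 1 and
heterozygote effect `dominance_degree` at 100 loci; the default is complete
dominance (`d = 1`) — the classical directional-dominance architecture of
heterosis — which makes expected F1 heterosis `Σ d (p1 − p2)²` strictly
positive under divergence, comfortably above the noise of six-sire parental
means. Coding-contrast experiments plant the heterozygote-advantage QTN at
frequency 0.5, where the additive and dominance codings are exactly
orthogonal; at any other frequency a dominance QTN leaks additive signal
(`cov = H(1 − 2p)`), so "the additive scan stays calibrated at the locus" is
a frequency-0.5 statement.

Because the simulator is HWE, LD-free (by default), structure-free and
single-record, passing tests demonstrate correctness of the estimators and
engines under their own assumptions — not robustness to LD between QTNs and
markers, half-sib family structure in the scan response, genotyping error,
or selection, all of which real crossbred data contain.

## Problem sizes and reproducibility

The bundled studies run at: variance-component recovery, 50 replicates of
n = 2000 × m = 5000 (the acceptance script uses 20); null calibration, 20
replicates of n = 500 × m = 2000; coding contrast, 50 replicates; reduced
replication study, 20 additive + 20 dominance replicates at n = 171,
m = 5000, 20 QTNs, h² = 0.5 (script: 10 + 10); heterosis, 100 seeded crosses
(script: 50). These sizes were chosen so the full suite completes on a
laptop-class single core in well under half an hour while leaving each
check's statistical resolution intact. Every stochastic element is seeded;
generators restore the caller's RNG state.

## Interfaces

The package's functions are the interface; the shell-level verbs a
command-line wrapper would expose (qc, grm, varcomp, gwas, simulate) map
one-to-one onto exported functions, and the acceptance script shows the
composition. Readers/writers cover PLINK, VCF, GCTA GRM, TSV phenotype/PGV
tables, and GFF3.

## Known limitations

* Single-marker imputation only; no phasing, strand checks, or liftover.
* No epistatic kernels, maternal effects, repeated records, or GxE.
* The ensemble is defined over this package's two engines; it does not
  re-implement the five published engines it abstracts.
* Nearest-gene annotation is coordinate-based; regulatory context is out of
  scope.
* P3D scans inherit the usual mild proximal-contamination deflation (no
  LOCO).
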