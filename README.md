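# wfmr — within-family Mendelian randomization

Mendelian randomization (MR) treats genetic variants as instrumental
variables for an exposure, but in samples of *unrelated* individuals the
estimates can be confounded by dynastic effects (parents' phenotypes
shaping their children's outcomes), assortative mating and population
stratification — all of which open a path from a person's genotype to
their outcome that bypasses the exposure. Contrasts **within families**
close these paths: sibling genotype differences are randomized by
meiosis, and an offspring's genotype is randomized given both parental
genotypes.

`wfmr` is for statistical geneticists and epidemiologists who want to

* run within-family genetic association and MR analyses on pedigree-aware
  tabular data (sample table, dosage matrix, phenotypes, GWAS weights), and
* study, by simulation, when unrelated-sample MR breaks and how much the
  family designs cost in power.

## What is implemented

**Per-SNP association estimators** (`assoc_scan` and single-SNP
functions), all with CR1 family-clustered sandwich errors:

| method | model |
|---|---|
| `unrelated` | OLS of phenotype on dosage, one sibling per family |
| `sib_diff` | within-pair difference regression through the origin |
| `family_fe` | within transformation (family fixed effects) |
| `trio` | offspring dosage adjusted for mother's and father's |

For sibling pairs, `sib_diff` and `family_fe` coincide exactly. The
within-family model for exposure *x* and outcome *y* of sibling *i* in
family *k* is

x_ki = γ_j g_kij + f_k + v_ki,  y_ki = Γ_j g_kij + f_k + u_ki,

with the family effect f_k absorbed by demeaning; the per-SNP pairs
(γ̂_j, Γ̂_j) feed any summary-data MR estimator.

**Instrumental variables**: allele harmonization
(`harmonize_weights`), weighted polygenic scores (`build_prs`), and 2SLS
with optional family fixed effects and cluster-robust first-stage F
(`tsls`).

**Summary-data MR**: Wald ratio, random-effects IVW, MR-Egger, weighted
median and weighted mode (seeded bootstrap SEs), Cochran's Q, a z-test
for the difference between two independent MR estimates (`mr_pdiff`),
and SUR-based shrinkage of total to within-family associations
(`shrinkage_sur`).

**Simulation study**: a forward-in-time simulator of
mother–father–sibling families under dynastic effects, assortative
mating and two-deme stratification (`simulate_cohort`), exact
identity-by-descent bookkeeping (`sibling_ibd`), and grid drivers
(`run_cell`, `run_grid`, `split_sample_mr`) that compute false discovery
rate, power and bias for the unrelated, sibling-FE and trio designs.
All path parameters are variance shares: the true causal slope under
`b_xy` is `sqrt(b_xy)`.

## Worked example

Simulate 5,000 sibling-pair families with **no causal effect**
(`b_xy = 0`) but a dynastic path (`b_ux = 0.1`) and modest individual
confounding, then compare designs:

```r
library(wfmr)
cfg <- sim_config(n_families = 5000, n_snps = 90, v_gx = 0.1,
                  b_xy = 0, b_ux = 0.1, c_x = 0.1, c_y = 0.1, seed = 1)
coh <- simulate_cohort(cfg)

sibling_ibd(coh)
#> Sibling IBD over 5000 pairs: mean 0.5002, SD 0.0372

un <- assoc_scan(coh, c("x", "y"), "unrelated")
fe <- assoc_scan(coh, c("x", "y"), "family_fe")
mr_ivw(summary_stats(un$x, un$y))
#> MR estimate (ivw): beta = 0.216 (SE 0.04155, 95% CI 0.1345 to 0.2974), p = 2.01e-07, SNPs = 90
#>   heterogeneity Q = 86.53 (df 89), p = 0.554
mr_ivw(summary_stats(fe$x, fe$y))
#> MR estimate (ivw): beta = 0.0641 (SE 0.0584, 95% CI -0.05036 to 0.1786), p = 0.272, SNPs = 90
#>   heterogeneity Q = 95.11 (df 89), p = 0.309
split_sample_mr(coh, method = "family_fe", seed = 2)
#> MR estimate (meta): beta = 0.006984 (SE 0.04943, 95% CI -0.08989 to 0.1039), p = 0.888, SNPs = 90
```

The true causal effect is zero. The unrelated-sample IVW estimate is
strongly "significant" (beta 0.22, p = 2e-07) — pure dynastic
confounding. The sibling fixed-effects estimate is compatible with zero,
and the split-sample within-family estimate (SNP-exposure and
SNP-outcome associations from disjoint family halves, meta-analysed both
ways) is essentially zero: the family design removes the bias at the
price of a larger standard error. Sibling genome sharing averages 50%
with SD 0.037, the theoretical value for 90 independent loci.

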