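---
title: "Within-family Mendelian randomization: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family Mendelian randomization: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. Its independence assumption — nothing causes
both the instrument and the outcome — fails in samples of unrelated
individuals when *dynastic effects* (parental genotype expressed in the
parental phenotype and transmitted environmentally to the child),
*assortative mating*, or *population stratification* open a path from the
offspring's genotype to the offspring's outcome that does not run through
the offspring's exposure. Contrasts *within* families close these paths:
sibling genotype differences arise from random meiotic segregation, and an
offspring genotype conditional on both parental genotypes is randomized by
transmission. `wfmr` implements the estimators that exploit this
(sibling differences, family fixed effects, trio parental adjustment,
family-FE two-stage least squares, and summary-data MR built on
within-family association statistics) together with a forward-in-time
family simulator used to study their false discovery rate, power and bias.

## Structural model

For individual $i$ in family $k$, with genotype dosages $g_{k,i,j}$ at
loci $j = 1, \dots, L$, an individual-level confounder $C_{k,i}$ and a
family-level component $f_k$:

$$x_{k,i} = \sum_j \gamma_j\, g_{k,i,j} + \gamma_C C_{k,i} + f_k + v_{k,i},$$
$$y_{k,i} = \beta_1 x_{k,i} + \beta_C C_{k,i} + f_k + u_{k,i}.$$

$\beta_1$ is the causal effect of interest. In the simulator the
family-level component of the offspring outcome is the *dynastic path*:
the standardized sum of the two parents' exposures. Because parental
exposure is partly genetic and parents transmit their alleles, $g$ and
$f_k$ are correlated, which biases estimates from unrelated samples.

### Variance-share parameterization

Every path parameter is a **variance share** on standardized variables:
a path with share $s$ enters with structural slope $\sqrt{s}$ applied to
its standardized source. So `v_gx = 0.1` means the $L$ SNPs jointly
explain 10% of exposure variance (each SNP carries an equal share
$v_{gx}/L$, giving the per-allele effect
$\gamma_j = \sqrt{(v_{gx}/L) / 2p_jq_j}$), `b_xy = 0.01` means the
exposure explains 1% of outcome variance with true slope
$\sqrt{0.01} = 0.1$, and `b_ux` is the share of offspring-outcome
variance explained by the combined parental exposure. This is the only
parameterization under which the study grids ("effect size 0.05" giving
power above 0.9 at 10,000 families) and the stated percentages of
variance explained are simultaneously coherent, and it is what the
package uses throughout: the estimand of every causal estimator on
simulated data is $\sqrt{b_{xy}}$.

### Residual scaling

Each phenotype is built as systematic component plus normal residual.
The residual variance is set to one minus the *realized sample variance*
of the systematic component, rather than a closed-form population value.
The two agree up to $O(n^{-1/2})$, but the sample form keeps the unit
theoretical variance exact under every option combination — assortative
mating (which inflates the variance of the parental exposure sum),
deme mean offsets, and the confounder-routed dynastic path — without
deriving each covariance term separately. Path slopes are unaffected, so
estimands do not change. Degenerate settings where the systematic
variance reaches 1 are rejected with an error naming the phenotype.

## The simulator

`simulate_cohort(sim_config(...))` builds families of two unrelated
parents and (by default) two full siblings:

1. Parent genotypes at `n_snps` independently segregating biallelic loci
   under Hardy-Weinberg equilibrium at `allele_freq` (default 0.5;
   configurable per locus). Independence across loci reflects the fact
   that ~90 recombination events separate human siblings, so 90 loci are
   effectively unlinked; linked loci and recombination maps are out of
   scope.
2. Parental confounders and exposures; spouse pairing. Under
   `assort_rho` $> 0$, spouses are rank-matched on exposure plus noise
   with standard deviation $\sqrt{1/\rho - 1}$, which produces a realized
   spousal exposure correlation of approximately $\rho$ (checked by the
   test suite at $\rho = 0.4$ within $\pm 0.05$). The default is random
   mating, and assortment is applied for a single generation — no
   multi-generation compounding.
3. Mendelian transmission: each parent passes one of its two allele
   copies with probability 1/2, independently across loci and offspring
   (`transmit()`). The indicator of which copy was transmitted is stored,
   so identity-by-descent sharing between siblings is computed exactly
   from the simulation record rather than inferred. Per-pair mean IBD
   over $L$ loci has mean $1/2$ and SD $\sqrt{0.125/L}$ (0.0373 at
   $L = 90$), which `sibling_ibd()` reproduces.
4. Phenotypes as above. The dynastic path defaults to a direct effect of
   the standardized parental exposure sum on the offspring outcome
   (`dynastic_path = "outcome"`); the alternative routing
   (`"confounder"`) loads it on the offspring confounder instead, which
   then feeds both offspring exposure and outcome through `c_x`, `c_y`.
   Both mechanisms are described in the field; the direct routing is the
   default because it matches the structural equations above, and the
   switch exists because the two imply different biased-path strengths
   for the same `b_ux`.
5. Optional two-deme stratification: deme B (proportion `prop`) gets an
   allele-frequency offset and a mean-centred outcome offset, with
   mating within deme.
6. Optional directional pleiotropy `pleio_y`: direct SNP effects on the
   outcome, all trait-increasing, jointly explaining the given share —
   the default generator has none, and the option exists to exercise the
   pleiotropy-robust estimators (MR-Egger, weighted median/mode).

What the generator deliberately does **not** emulate: linkage
disequilibrium, allele-frequency spectra and imputation noise of real
arrays, missingness, binary phenotypes (analyses of real binary outcomes
are linear probability models), age/cohort structure, sibling
interaction effects, and multi-generation assortment. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to everything real biobank data can do.

## Estimators

* **Unrelated OLS** (`assoc_unrelated`): per-SNP OLS with
  heteroskedasticity-robust (HC1) or family-clustered errors; the study
  design draws one sibling per family (the first by stable ID order) so
  designs are compared at equal family counts.
* **Sibling difference** (`sib_diff_assoc`): phenotype difference on
  dosage difference, through the origin (the difference model has no
  intercept; an intercept is available for diagnostics only). Every
  within-family pair enters as a pseudo-independent pair with errors
  clustered on family.
* **Family fixed effects** (`family_fe_assoc`): the within
  transformation (demeaning by family) followed by OLS; identical to
  per-family indicator variables, and identical to the sibling
  difference estimator when every family has exactly two siblings — an
  algebraic identity the tests assert to machine precision. An option
  adjusts for the family-mean dosage instead, exposing the
  between-family coefficient.
* **Trio adjustment** (`trio_assoc`): offspring phenotype on offspring,
  mother and father dosages; the offspring coefficient is conditionally
  randomized by transmission, and the parental coefficients measure the
  dynastic association. One offspring per family is analysed by default
  (both with family clustering on request).
* **2SLS** (`tsls`): polygenic-score instrumental variables with
  optional family fixed effects (all variables within-transformed before
  both stages); residuals from the actual exposure; cluster-robust
  first-stage F reported; no weak-instrument correction is applied.
* **Summary-data MR** (`mr_ivw`, `mr_egger`, `mr_weighted_median`,
  `mr_weighted_mode`, `cochran_q`, `mr_pdiff`): standard two-sample
  machinery over per-SNP association pairs from any of the designs.
* **SUR shrinkage** (`shrinkage_sur`): the total and within-family
  associations of each SNP estimated jointly on the same siblings, with
  their cross-equation covariance from a stacked estimating-equation
  sandwich clustered by family; percent shrinkage
  $100\,(\text{total} - \text{within})/\text{total}$ with a delta-method
  SE, pooled across SNPs by fixed-effect inverse variance. A classical
  FGLS system fit would be an alternative reading of "seemingly
  unrelated regression"; the stacked sandwich was chosen because it is
  assumption-light (no homoskedasticity across equations) and directly
  testable against a family-resampling bootstrap, with which it agrees
  within 15% in the suite.

### Inference conventions

Cluster-robust covariances use the CR1 finite-sample factor
$\frac{G}{G-1}\cdot\frac{N-1}{N-K}$ (the convention of the
xtreg/ivreg2/plm family of econometric tools), with $t$ reference on
$G-1$ degrees of freedom for individual-level estimators and normal
reference for per-SNP summary exports. With one observation per cluster
CR1 reduces exactly to HC1. The Wald-ratio SE is first order
(`se_y/|beta_x|`), i.e. the NOME convention; a second-order option adds
the exposure-side term. IVW uses multiplicative random effects — the SE
is inflated by $\max(1, \sqrt{Q/(L-1)})$ — and MR-Egger bounds its
residual scale below by 1, with $t_{L-2}$ inference. The weighted median
interpolates the inverse-variance-weighted cumulative distribution at
50%; the weighted mode is the kernel-density mode of the ratios with
bandwidth `bandwidth` (default 1) times the MAD scale; both take seeded
parametric-bootstrap SEs (default 1,000 replicates). Noiseless inputs
(zero SEs) are handled as the corresponding infinite-weight limits.

## The simulation study

`run_cell` simulates one configuration repeatedly and applies up to
three designs per iteration: `unrelated_ivw` (one sibling per family,
per-SNP OLS of exposure and outcome, IVW pooling), `sibling_fe` (within-
family per-SNP associations, IVW), and `trio` (parental-adjusted per-SNP
associations, IVW). The rejection proportion at $p < 0.05$ is the false
discovery rate under $b_{xy} = 0$ and power otherwise; bias is the mean
estimate minus $\sqrt{b_{xy}}$. `run_grid` crosses sample sizes, causal
effects, dynastic strengths and confounding, with per-cell seeds derived
from the base seed so any cell is independently reproducible; iterations
whose design is inestimable are excluded and counted. One IVW test per
iteration per design is the unit of the FDR bookkeeping.

Two readings of the dynastic grid exist in the source material
(0/0.01/0.02 versus 0/0.1/0.2); the package adopts 0/0.1/0.2, the grid
under which the headline false-discovery result (FDR above 0.75 for the
unrelated design at `b_ux = 0.1`) is produced. Similarly the
SNP-exposure share is taken as `v_gx = 0.1`.

### What the study shows, and a caveat

With 90 SNPs explaining 10% of exposure variance, 20,000 families and
`b_ux = 0.1`, the unrelated-sample IVW design rejects a true null in
essentially every iteration, while the within-family designs stay near
the nominal 5% and retain power above 0.9 for a 5%-variance causal
effect at 10,000 families. Two caveats on calibration. First, the
same-sample construction (SNP-exposure and SNP-outcome associations
estimated on the same individuals) leaves a small weak-instrument bias
in the within-family IVW estimates whenever exposure and outcome share
individual-level residual correlation — e.g. under `c_x = c_y = 0.1`
the sibling-FE null estimates centre near +0.02 rather than 0 at 10,000
families, attenuating as samples grow. This is inherent to the design,
is the reason the split-sample workflow (`split_sample_mr`) exists, and
can nudge the sibling-FE false discovery rate slightly above nominal in
small samples. Second, within-family bias at small $n$ is of
weak-instrument type and shrinks with sample size, which the grid
reproduces.

## Numerical and degenerate-input policy

Constant dosages, designs without within-family variance, collinear
parental genotypes, single clusters, zero SNP-exposure associations and
empty split halves are rejected with explicit errors rather than
returning numbers; the grid driver records such iterations and excludes
them from proportions. Ties in the weighted-mode kernel are broken by
the density grid maximum; weighted-median interpolation handles boundary
masses by returning the extreme ratio. All estimator defaults (CR1,
NOME, bandwidth 1, 1,000 bootstrap replicates, multiplicative random
effects) are stated above and in the function documentation.

## Problem sizes used by the test suite

The packaged checks run the study at the sizes the conclusions need:
false-discovery calibration of the within-family designs at 10,000
families with 500 iterations; the unrelated-design FDR at 20,000
families with 100 iterations; power at 10,000 families with 100
iterations; parameter recovery at 20,000 families with 100 iterations
per effect size (with `b_ux = 0.1` and no individual confounder, the
sub-grid in which the recovery claim is exact); and IBD dispersion at
10,000 sibling pairs. Unit tests use smaller cohorts (hundreds to a few
thousand families) with tolerances matched to their Monte Carlo error.

## Limitations

Within-family designs protect against family-level confounding, not
against horizontal pleiotropy (use the Egger/median/mode sensitivity
estimators), sibling interaction effects, or measurement error in the
exposure. The simulator's clean architecture (equal per-SNP effects,
allele frequency 0.5, no LD) makes the power results optimistic relative
to real genotype panels with the same aggregate $R^2$. Binary outcomes
are treated as linear probability models. The SUR shrinkage of real
phenotypes depends on cohort-specific familial effects and cannot be
benchmarked against simulated data beyond direction-of-effect checks.
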