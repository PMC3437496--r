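---
title: "Methods: the rfigwas feed-efficiency analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the rfigwas feed-efficiency analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rfigwas` implements a two-stage quantitative-genetic analysis of feed
efficiency in a paternal half-sib beef cattle design: breeding values are
first estimated with a genomic-relationship animal model, and the breeding
values are then scanned for SNP associations, condensed by forward selection
into QTL-tagging panels, and audited for the additive variance they actually
capture. This vignette is the package's account of the models, the defaults,
the numerical choices, and what the synthetic-data tests do and do not show.

## The traits and RFI

Average daily feed intake (AFI, kg/day), average daily gain (ADG, kg/day) and
mid-test weight (kg) are the observed traits. Metabolic mid-weight is
`MMW = mid_weight^0.75`. Residual feed intake is defined phenotypically:
within each feeding group, AFI is regressed by ordinary least squares on an
intercept, ADG and MMW, and RFI is the residual

```
RFI_i = AFI_i - (b0_g + b1_g ADG_i + b2_g MMW_i),    g = feeding group of i.
```

Negative RFI marks animals that eat less than predicted from their growth and
maintenance. Because RFI is an OLS residual, within every group it sums to
zero and is exactly uncorrelated with ADG and MMW; the test suite asserts
these identities to 1e-10. The regression is fitted per feeding group rather
than pooled with group dummies, matching the within-group definition of the
trait; groups need at least 3 animals and non-collinear regressors, otherwise
`derive_rfi()` stops with the offending group named.

## Genotype QC

`filter_snps()` keeps SNPs with MAF >= 0.05 and call rate >= 0.95 (both
inclusive); `filter_animals()` drops animals with missingness strictly above
5%. These boundary conventions (">=" for SNP filters, ">" for animals) are
deliberate and tested. SNPs mapped to unassigned contigs ("ChrUn") are kept
and treated as one pseudo-chromosome throughout, including spacing summaries
and forward selection. Missing calls are imputed per locus -- by default the
most frequent call (`mode`), with `expected_dosage` (real-valued `2p`) and
Hardy-Weinberg `sample` as alternatives. A haplotype-based imputer would be
overkill here: at the ~0.6% missingness the pipeline is designed around,
downstream statistics are insensitive to the imputation rule, which the
choice of a per-locus default makes explicit. Imputation never alters
observed calls.

## Relationship matrices

Two genomic constructions are available behind one interface:

* `vanraden_grm()`: allele-frequency-centred cross-product scaled by
  `2*sum(p(1-p))` -- the standard GBLUP matrix, exactly specified when the
  markers themselves carry the genetic variance.
* `calibrate_grm()`: mean identity-by-state allele sharing
  (`1 - |g_i - g_j|/2`, averaged over loci) affinely mapped to the pedigree
  numerator relationship matrix `A`. The map is the classical *inverse*
  calibration, `slope = var(A)/cov(S, A)` over the calibration pairs:
  regressing `A` on the noisy sharing statistic directly would attenuate all
  relationships (errors-in-variables), and with the inverse fit the calibrated
  half-sib mean lands on 0.25 and regressing the calibrated matrix back on
  `A` returns slope 1 within 0.02. Off-diagonals and diagonals are calibrated
  separately; when the pedigree diagonal is constant (no inbreeding
  variation) the diagonal slope is unidentifiable and the off-diagonal slope
  is reused with the intercept matching the mean pedigree diagonal.
  Calibration pairs default to all off-diagonal genotyped pairs, which in a
  sire-only pedigree mixes half-sib (A = 0.25) and unrelated (A = 0) classes;
  sire-offspring pairs are unavailable because only the steers are genotyped.

Both matrices are conditioned to positive semi-definiteness by eigenvalue
clipping (negative eigenvalues raised to 1e-6); the REML engine never inverts
the matrix, so exact zeros are harmless.

A known limitation: at scaled-down marker counts the IBS-sharing statistic
maps within-family realized-relationship deviations with a slightly
different local slope than the between-class contrast used for calibration,
so heritability estimated with the calibrated matrix is attenuated relative
to the VanRaden construction. The parameter-recovery and winner's-curse
suites therefore use `vanraden_grm()`; the calibrated matrix remains the
pipeline default because it is the construction the analysis design calls
for.

## The animal model and EM-REML

`fit_animal_model()` fits `y = Xb + u + e` with `Var(u) = G sigma2_a` and
`Var(e) = I sigma2_e`; `X` carries pen, year and season as additive factors
with the first level of each dropped (a deterministic identifiability
constraint). Season does not interact with year. The engine rotates the model
into the eigenbasis of `G` (or of `ZGZ'` when animals have repeated records),
where the covariance is diagonal; the O(n^3) eigendecomposition is paid once
and can be shared across models via `grm_eigen()`, and each EM iteration is
then O(n p^2).

The variance-component updates are Henderson's EM-REML equations, evaluated
without inverting `G`. Plain EM converges linearly with rate equal to the
fraction of missing information, which approaches 1 at low heritability --
iterates creep so slowly that any stopping rule phrased in significant
figures would freeze short of the optimum. The engine therefore wraps the EM
map in SQUAREM acceleration: each cycle composes two EM evaluations with a
safeguarded extrapolation that shares the EM fixed point, followed by one
stabilizing EM step. Convergence is declared when the heritability agrees to
`convergence_sigfigs` (default 3) significant figures across the last three
cycles. The accelerated engine agrees with a direct maximization of the profile
restricted likelihood (an independent oracle kept in the test suite) within
the tolerance asserted there.

A heritability trajectory that approaches the optimum from above and below is
characteristic of the accelerated iteration but not guaranteed -- monotone
approaches exist. The fit records whether the final value was bracketed
(`bracketed` flag in `glance()`) rather than requiring it, because demanding
bracketing would make convergence unattainable for monotone trajectories.
Variance components are floored at 1e-8 with a warning (boundary estimates),
and non-convergence at `max_iterations` is an error carrying the trajectory.

EBV accuracy uses the standard BLUP reliability on the correlation scale,
`sqrt(1 - PEV_i / (sigma2_a G_ii))`, with PEV clamped into its theoretical
range.

## Weighted association scan and permutation threshold

The scan regresses EBVs, weighted by the Cholesky factor of the diagonal
accuracy matrix (elementwise `sqrt(accuracy)`), on each SNP's additive dosage
-- both sides are premultiplied by the weights, so the intercept column is
the weight vector itself. The per-SNP statistic is
`F = SSreg / (SSE / (n - 2))`; equal weights reproduce the unweighted F
exactly, and F is invariant to affine rescaling of the EBVs. Dosages enter
uncentred (centring cannot change F). SNPs with zero weighted dosage variance
are flagged and skipped. Nominal p-values from F(1, n-2) are attached for
reporting only; all significance decisions use the permutation threshold.

`permutation_threshold()` shuffles (EBV, weight) pairs across animals while
the genotype rows stay fixed, preserving both the weighting structure and the
genome-wide LD, and records the maximum F over all SNPs per permutation; the
threshold is the empirical `1 - alpha` quantile of that max-F sample, using
the "higher" order-statistic convention (smallest order statistic with at
least `1 - alpha` coverage -- conservative and deterministic). Whether the
original analysis permuted raw or weighted EBVs is not knowable; both
pairings are exposed (`permute = "weighted_pairs"` default, `"raw_ebv"`
alternative). With `alpha = 0.05` and 1000 permutations the threshold is the
950th order statistic; the family-wise error rate of the whole procedure is
then about 51/1001 ~ 0.051, and the acceptance suite verifies a [0.03, 0.07]
empirical band over 500 global-null replicates. That calibration experiment
uses generator genotypes with iid null EBVs and random accuracies: the
permutation guarantee is conditional on the genotypes and presumes
exchangeable (EBV, weight) pairs, which is exactly the machinery under test.
EBVs from a GRM model are in reality family-correlated -- a property of the
two-stage design itself, shared with the original analysis, not of the
thresholding machinery.

## Forward selection and the final model

Candidates are the SNPs whose single-SNP F reaches the genome-wide threshold.
Selection runs independently within each chromosome (ChrUn as one
pseudo-chromosome): at each step the candidate with the largest partial F --
an extra-sum-of-squares test given the SNPs already selected, with residual
df `n - q - 2` after `q` selections -- is added if it still reaches the same
genome-wide threshold, and selection stops otherwise. Ties break by F
descending, then position, then SNP id. Candidates collinear with the current
model are flagged and skipped. Because selection is chromosome-local, the
processing order of chromosomes cannot change the union panel, and the
greedy path matches an exhaustive oracle on every small-candidate fixture in
the test suite.

`final_model_r2()` reports the multiple-regression R-squared of the weighted
EBVs on all selected SNPs jointly -- the "anova" estimate of EBV variance
explained. The final model keeps every forward-selected SNP; no backward
pruning, and no training/validation split (the design this package emulates
deliberately used all animals).

## The GBLUP variance contrast

`gblup_variance_explained()` fits two REML models sharing one GRM
eigendecomposition: mean-only (total additive variance) and mean plus panel
dosages as fixed covariates (residual additive variance), reporting
`(sigma2_a_null - sigma2_a_snp) / sigma2_a_null`, floored at zero with a
warning. The dependent variable is the weighted EBV, matching the scan stage,
so the "fixed mean" column is the weight vector; pen/year/season are already
absorbed in the EBVs and are deliberately not refitted. Because the GRM
absorbs family resemblance, this estimate resists the winner's curse that
inflates the fixed-effects R-squared on panels chosen for in-sample
significance: on synthetic study-scale replicates the R-squared exceeds the
GBLUP proportion essentially always, reproducing the qualitative pattern that
motivates reporting both numbers.

## QTL regions and concordance

Each selected SNP defines a 1-Mb window (position +/- 0.5 Mb, closed
interval, clipped at zero). Cross-trait concordance counts overlapping
region *pairs* on the same chromosome -- the pair counter is symmetric in its
arguments for any input, equals the list length when two identical disjoint
lists are compared, and treats windows whose endpoints touch as overlapping
(closed intervals). An anchor-based counter (selected SNP of one trait
falling inside the other trait's window) is exposed as an alternative.
External concordance declares a selected SNP validated when a published QTL
position on the same (normalized) chromosome lies within 500 kb inclusive;
the largest distance among the bundled validation pairs is ~471 kb, so the
inclusive boundary is a declared convention rather than a tested one.
Windows export to BED as 0-based half-open intervals; the conversion
round-trips and is tested.

## The synthetic population generator

`simulate_population()` emulates the information structure of a ~700-steer
paternal half-sib feeding trial:

* 100 sires, 698 genotyped offspring, one unrelated non-genotyped dam per
  offspring (maternal pedigree unavailable by design);
* base-population allele frequencies from Beta(1.0, 0.8) truncated to
  [0.05, 0.5], whose mean of 0.280 matches a dense bovine assay after MAF
  filtering;
* SNPs placed uniformly on equal-length chromosomes; offspring genotypes by
  Mendelian sampling of parental gametes with Haldane recombination at
  1 cM/Mb, so within-chromosome LD arises from haplotype transmission (no
  coalescent-exact background LD);
* additive architecture split between a sparse pleiotropic QTL layer (one
  shared locus set, correlated per-trait effects; `qtl_var_frac`, default
  0.3) and a genome-wide polygenic layer of small correlated effects at
  every SNP. Making the polygenic layer genomic (rather than an abstract
  pedigree-transmitted term) is what lets marker-derived relationship
  matrices recover the configured heritabilities; sharing QTL loci across
  traits is what produces cross-trait QTL-region concordance;
* default heritabilities 0.14 (AFI), 0.09 (ADG) and an advisory RFI target of
  0.14 -- RFI itself is never simulated, it is derived downstream, so its
  heritability is emergent; genetic correlation AFI-ADG 0.55 by default
  (mid-weight correlations are fixed internal constants of 0.45/0.55 with
  h2 = 0.35, ordinary literature magnitudes); environmental correlations
  0.25-0.35. Phenotypic scales: AFI 9.5 +/- 1.0 kg/day, ADG 1.6 +/- 0.2
  kg/day, mid-weight 450 +/- 35 kg;
* pen (8), year (4) and season (2) effects drawn per level at 0.2-0.3
  phenotypic SD and assigned at random (estimable with high probability);
  pens nest in 2 feeding groups;
* missing calls injected completely at random at 0.58% by default; the whole
  population is bit-identical under a fixed seed.

All steers are male but the X chromosome (the 30th by default) is simulated
as autosomal diploid -- hemizygous dosage coding is out of scope, and QC can
exclude X if desired. No genotyping-error model and no selection of animals
on prior performance are simulated; if such selection skewed QTL allele
frequencies in a real population, detection power would differ from what the
synthetic tests show. Passing tests on this generator demonstrate the
statistical machinery under the stated architecture, not robustness to
ascertainment, genotyping artefacts, or population structure beyond paternal
half-sib families.

## Problem sizes used by the tests

The acceptance suite runs: heritability recovery over 50 replicates each at
n = 2000 / h2 = 0.4 and n = 698 / h2 = 0.14 (1000 SNPs, 20 chromosomes,
VanRaden GRM); permutation calibration over 500 global-null replicates of
1000 permutations each (n = 500, 2000 SNPs, genotypes redrawn every 10
replicates -- the permutation guarantee is conditional on genotypes, so this
only reduces Monte Carlo cost); the winner's-curse contrast over 50
full-pipeline replicates at n = 698, 2000 SNPs, 500 permutations; 100
small-candidate forward-selection oracle fixtures; and 1000 weighted-F
invariance fixtures. `scripts/acceptance.R` runs the end-to-end pipeline at
n = 698, 5000 SNPs, 1000 permutations. These sizes are the package's own
simulation choices: large enough for the Monte Carlo tolerances stated in
the tests, small enough to re-run routinely. The permutation default in
`pipeline_config()` remains 10000, the study-scale setting; scaled-down
counts must always be set explicitly.

## Worked example

```{r example}
library(rfigwas)

cfg <- pipeline_config(
  sim = sim_config(n_offspring = 698, n_snps = 5000, n_chromosomes = 30,
                   seed = 1),
  n_perm = 1000, seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")

res$summary              # candidate/selected counts, %EBV and %GBLUP variance
glance(res$models$rfi)   # variance components and convergence diagnostics
autoplot(res$scans$rfi)  # Manhattan plot with the permutation threshold
```
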