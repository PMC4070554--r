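---
title: "Multiple-line cross QTL mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-line cross QTL mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcqtl)
```

mlcqtl implements joint QTL linkage mapping for several biparental doubled
haploid (DH) families analysed together, the design used for dissecting a
dynamic trait (biomass at successive developmental stages) in a multi-family
triticale population. This vignette is the package's own account of the
statistics it implements, the choices made where the method leaves room, and
what the synthetic-data generator does and does not emulate.

## The disconnected multiple-line cross model

For $N$ DH lines from $P$ families, the phenotype vector of entry means
(BLUEs) is modelled as

$$ Y = J\,M + X_q B_q + \sum_c X_c B_c + \varepsilon $$

where $J$ is the $N \times P$ family-indicator matrix, $M$ the family means,
$X_q$ the $N \times P$ matrix of expected allele counts at the tested locus
(the entry of line $i$ is nonzero only in its family's column), $B_q$ the
family-specific allele-substitution effects, and the $X_c B_c$ terms are
analogous blocks for cofactor markers. "Disconnected" means every family has
its own mean and its own QTL effect; no allele identity is assumed across
families, which is appropriate when the parent pairs are unrelated.

Because every column of $J$, $X_q$ and $X_c$ lives inside exactly one
family, the design is family-block-diagonal and ordinary least squares
decomposes into independent per-family regressions whose residual sums of
squares add. The scan engine exploits this: each family keeps a QR basis of
its base model and all candidate positions are tested against it at once by
Frisch–Waugh partialling. This is an implementation device only -- the
fitted model is identical to the joint OLS fit, which the test suite checks
against an explicit normal-equations solver.

### Test statistic

The presence of a QTL is tested with a Gaussian likelihood-ratio statistic,
$\mathrm{LR} = N \ln(\mathrm{RSS}_0/\mathrm{RSS}_1)$, reported on the LOD
scale, $\mathrm{LOD} = (N/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. The
profile-likelihood form (with the error variance maximised out) is used
because only the RSS ratio matters; LOD is therefore invariant under
location–scale changes of the phenotype. Families in which the tested
counts do not segregate are dropped from the tested block -- their column is
collinear with the family mean and would make the model singular -- with the
degrees of freedom reduced accordingly.

### Expected allele counts

Scan positions between markers use the expected count (0–2) of the
parent-A allele given the nearest non-missing flanking markers, under the
Haldane map function $r = \tfrac12(1 - e^{-2d/100})$ (no crossover
interference). For DH lines the chromosome is a single doubled gamete, so
the crossover process is Markov and flanking markers carry all the
information of the chromosome; conditioning on the nearest informative
flanks is exact, not an approximation, which the tests verify against
exhaustive enumeration of gamete classes. A line with no genotyped marker
on a group receives the uninformative value 1. We chose the
nearest-informative-flank rule over a full hidden-Markov smoother because
it is exact under the no-interference model, deterministic, and transparent;
it would differ from a multipoint smoother only if genotyping error were
modelled, which is out of scope.

### Cofactor selection

Cofactors are chosen by forward selection of markers, each entering as its
family-specific block, starting from the family-means model and minimising
the Schwarz Bayesian criterion $\mathrm{SBC} = N\ln(\mathrm{RSS}/N) +
k\ln N$ with $k$ counting all fitted parameters (selection stops when no
marker improves the criterion, or at `max_cofactors`, default 10). During
the scan, cofactors within 10 cM of the tested position are excluded,
composite-interval-mapping style. Selection is deterministic given the
input.

### Permutation thresholds

Genome-wide LOD thresholds are the empirical $(1-\alpha)$ quantile (type-7
interpolation) of max-LOD over permutations of the phenotype *within each
family* -- permuting across families would destroy the family-mean structure
and inflate the null. Cofactors are re-selected inside every permutation
replicate: the threshold must account for the selection step's opportunism,
otherwise it is too low. This choice is configurable
(`reselect_cofactors = FALSE` reuses fixed cofactors) but re-selection is
the honest default. The package default is 200 permutations at
$\alpha = 0.10$, which places desk-scale thresholds in the low-5 LOD range;
2000 permutations (publication grade) are supported and only cost linearly
more.

### QTL declaration and support intervals

Local LOD maxima above the threshold become QTL. The method itself gives no
rule for two peaks on one chromosome, so the package uses: peaks are
distinct only if more than 20 cM apart (twice the overlap window) *and*
separated by a valley at least 1.0 LOD below both; otherwise they merge
into the higher peak. Support intervals are the contiguous region around
the peak within 1.0 LOD of the peak value.

### Explained genotypic variance

The proportion of genotypic variance explained by a QTL set is
$p_G = 100\,R^2_{adj}/h^2$, where $R^2_{adj}$ comes from the simultaneous
model with family means plus all QTL blocks and $h^2$ is the entry-mean
heritability -- dividing by $h^2$ converts "explained phenotypic" into
"explained genotypic" variance. Single-QTL contributions are drop-one
partials (the loss in $p_G$ when that QTL is removed), floored at zero.
Drop-one partials of correlated predictors need not sum exactly to the
combined value; small overshoots are possible because the adjusted $R^2$
of a drop-one model can be slightly negative.

### Overlap across stages

QTL from different stages are declared overlapping when they sit on the
same linkage group with peaks at most 10 cM apart (boundary inclusive).
Overlap is closed transitively into clusters and each cluster is labelled
by its set of stages -- the Venn classification. The same 10 cM window also
bins the cross-validation detection frequencies.

## Cross-validation

Fivefold cross-validation stratifies folds within family, so every fold
holds about a fifth of each family. Per run, the estimation set (4/5 of
lines) gets full cofactor selection and a scan at the *fixed full-data
threshold* -- recomputing a permutation threshold inside every fold would
multiply the cost by the fold count while the quantity being validated is
the full-data analysis. Test-set validation predicts each left-out line
from the estimation-set family means and QTL effects;
$p_{G\text{-}TS} = 100\,r^2(\hat y, y_{TS})/h^2$, set to zero when the
correlation is negative. The relative bias
$100\,(p_{G\text{-}ES} - p_{G\text{-}TS})/p_{G\text{-}ES}$ measures how
much the estimation set overstates the explained variance. Twenty
replicate partitions (100 runs) are the default; the acceptance script uses
ten to stay within its time budget.

The bias observed on the default emulation is positive but smaller than
what the real study reported, and that is expected: the generator plants a
handful of well-detectable QTL, so the estimation-set model is close to the
truth and overfits little. The published bias of 30–39% reflects a trait
with many sub-threshold QTL where selection capitalises on noise. The
direction and the mechanism are reproduced; the magnitude is a property of
the unknown real architecture, not of the estimator.

## Two-dimensional epistasis scan

The scan model is extended by a block for the second locus and an
interaction block whose within-family columns are products of
within-family *centred* counts (centring keeps the product term nearly
orthogonal to the main effects). The interaction block is tested with an F
test -- equivalent to the likelihood ratio under Gaussian OLS and
numerically stabler near saturated fits. All grid pairs on different
groups are tested, plus same-group pairs at least 20 cM apart (closer
pairs make the product column collinear with the main effects).
Significance uses a region-based Bonferroni threshold: with two regions
per chromosome, $\alpha / \binom{2G}{2}$ for $G$ linkage groups
($\approx 5.8\times10^{-5}$ at $G = 21$; a 22-group map gives the familiar
$5.3\times10^{-5}$). Significant pairs are clustered (both loci within
10 cM) and each cluster is reported at its best pair, re-tested exactly.

Two properties of this procedure deserve honesty. First, the region-based
correction treats a whole half-chromosome as one test; on a dense grid the
effective number of tests is larger, so a handful of borderline false
positives above the nominal rate are expected on null data at marker
densities of a few cM. Second, the F test assumes Gaussian residuals
*within families*. A strong unmodelled additive QTL -- exactly the
situation of a family segregating for a major dwarfing locus -- leaves a
bimodal within-family residual whose extreme tails the F distribution
understates by orders of magnitude. The pipeline therefore passes the
stage's selected cofactors into the epistasis model (excluded within 10 cM
of either tested locus), which absorbs main-effect QTL and restores
calibration; the bare two-locus model remains the function-level default
for transparency, and both behaviours are available.

## The synthetic-data generator

No dataset accompanies the method, so the generator *is* the study design:

* Four DH families of 131, 120, 200 and 196 lines (647 in total), each an
  F1 gamete doubled, simulated marker by marker with Haldane
  recombination, no interference, no selection, allele frequency one half.
* A 21-linkage-group map (`1A..7A`, `1B..7B`, `1R..7R`), 120 cM per group,
  markers every 5 cM. The real consensus map's density is not stated in a
  reusable form, so density is a configurable default chosen to keep no
  interval wider than typical marker spacing while desk-scale scans stay
  fast.
* Ten additive QTL with family-specific effects (some zero:
  non-segregating) and three epistatic pairs. Temporal dynamics come from
  per-stage scale factors on each effect, not from an explicit correlation
  matrix: stages correlate because they share QTL, and stage-specific QTL
  exist because some profiles fall to near zero -- the same mechanism the
  method is designed to detect. The major locus on 5R acts almost only in
  family EAW78 with a weak–strong–moderate profile across BM1–BM3, giving
  that family a unimodal, then clearly bimodal, then attenuated trait
  distribution (the behaviour of a dominant dwarfing locus such as
  *Ddw1*). Two of the epistatic pairs are strongest at BM1 and one (6A
  with 5B) peaks at BM2, so detectable interactions decline with
  development.
* Phenotypes add genotype-by-environment deviations and plot errors around
  the true genetic values for a balanced trial of four environments (two
  locations by two years) with two replicates. Variances are solved from
  the targeted entry-mean heritability
  $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(Er))$
  and the targeted $\sigma^2_G{:}\sigma^2_{GE}$ ratio, with $\sigma^2_G$
  taken as the realised variance of the simulated genetic values. Stage
  targets are $h^2 = 0.81, 0.91, 0.86$ and ratios $3{:}1, 7{:}1, 5{:}1$
  for BM1, BM2, BM3.

What the generator does *not* emulate: the partially replicated lattice
layout with checks (a balanced design stands in; the variance-component
solver is the expected-mean-squares solution, which under balance coincides
with REML for the full random model), spatial field trends, genotyping
error, segregation distortion, DArT dominance scoring (irrelevant for
fully homozygous DH lines), and a polygenic background of many
sub-threshold QTL. The last point matters for interpretation: passing
tests show the estimators recover *planted* architectures; they cannot
show how much of a real trait's variance such a scan would capture.

## Numerical choices

* Non-segregation of a family block is declared when the residualised
  count column's sum of squares falls below $10^{-7} n_f$; such blocks are
  dropped with their degrees of freedom.
* A saturated fit ($\mathrm{RSS}_1 = 0$) caps the LOD with a warning
  instead of returning infinity.
* Quantiles use type-7 interpolation; the overlap and frequency windows
  are inclusive at the boundary; grid positions always include the marker
  positions themselves so observed genotypes are reproduced exactly.
* Negative method-of-moments variance components are truncated at zero;
  with a single replicate the error and interaction variances are
  confounded and the pooled term is reported as $\sigma^2_{GE}$ with a
  warning.
* All randomised operations take explicit seeds; derived seeds stay inside
  the 32-bit integer range. Identical seeds reproduce populations,
  phenotypes, folds and thresholds bit for bit.

## Problem sizes

The test suite and the acceptance script run the emulation at its native
size (647 lines, 21 groups) with a 5 cM scan grid, 200 permutations per
threshold, ten cross-validation replicate partitions (50 runs) per stage,
and the 5 cM two-dimensional scan; these sizes were chosen so that the
whole analysis of one stage completes in well under a minute on one core
while keeping every statistical property at the study's own scale. The
1 cM grid and 2000 permutations remain available through the same
arguments.

## Known limitations

* Parent phenotypes enter the midparent contrast as known constants; their
  standard errors (small for replicated checks) are ignored, making the
  contrast slightly anti-conservative.
* $p_{G}$ inherits the sampling error of $\hat h^2$; with $h^2$ near one
  this is negligible, at low heritability the ratio is unstable.
* The disconnected model estimates one effect per family per locus; it
  cannot borrow strength across families sharing an allele, so its power
  in small families is limited -- a connected model is out of scope.
* The region-based epistasis correction is approximate on dense grids, as
  discussed above.
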