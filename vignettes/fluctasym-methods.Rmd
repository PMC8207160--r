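---
title: "Fluctuating asymmetry from replicated bilateral landmarks: models and methods"
author: "fluctasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuating asymmetry from replicated bilateral landmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctasym)
```

## The scientific problem

Fluctuating asymmetry (FA) — small, random deviations from perfect
bilateral symmetry — is the phenotypic signature of developmental
instability, and is widely used as an indicator of environmental or
genetic stress in wild populations. Detecting it is delicate: the
asymmetry signal in a structure such as a rodent hemimandible is of the
same order as the error made when photographing and digitizing the
specimen. The standard solution is a hierarchical replicate design
(specimen x side x photograph x digitizing) analyzed with a Procrustes
ANOVA, so that the individual-by-side interaction (the FA signal) can be
tested against measurement-error strata.

`fluctasym` implements that analysis end to end for *matching symmetry*
(paired separate structures, e.g. left and right hemimandibles), together
with the covariate analyses such studies pair it with: microsatellite
heterozygosity and inbreeding as genetic predictors, and buffer-based
habitat amount as a landscape predictor, linked to FA with correlations
and likelihood-ratio tests.

## Matching-symmetry Procrustes alignment

One side is mirrored (x negated; the axis is arbitrary since rotation is
removed next) and all configurations of both sides enter a single
generalized Procrustes analysis: center, scale to unit centroid size,
rotate onto the running consensus, recompute the consensus, iterate.
Internally configurations are complex k-vectors; the least-squares
rotation of `z` onto `w` is multiplication by `exp(i * Arg(sum(conj(z) w)))`.
Complex arithmetic permits only proper rotations (determinant +1), which
is essential here: an improper rotation could silently absorb exactly the
asymmetry being measured.

Numerical choices: convergence is declared when the consensus root mean
square change drops below `tol = 1e-8` (cap `max_iter = 100`; hitting the
cap flags `converged = FALSE` rather than failing). All-coincident
configurations are rejected by name. Centroid sizes are recorded before
rescaling, in input units. Projection to tangent space is omitted: at the
small shape variation typical of mandible data the difference is far
below the tolerances used anywhere in the package.

## The nested ANOVA

Per Procrustes coordinate the model is

    y = individual + side + individual:side + image(individual, side) + digitizing

with the individual effect random, side fixed (its main effect is
directional asymmetry, DA), the interaction carrying FA, and two nested
error strata: image (photographic positioning) within specimen x side,
and digitizing within image. Sums of squares are sequential (Type I) over
this hierarchy, summed over all 2k coordinates; degrees of freedom are
the structural df of the observed design times the shape-space dimension
2k - 4 (a 2-D configuration loses two translations, one rotation and one
scale). For centroid size the same decomposition is used with multiplier
1. F ratios follow the mixed-model chain: individual and side against the
interaction; the interaction against the image stratum; the image stratum
against the digitizing residual. p-values come from the F distribution.

Unbalanced data (missing replicates or specimens) are handled by fitting
the observed design: projections are group means plus one
Frisch–Waugh-style step for the side contrast, so the decomposition is
exact sequential least squares whatever the replicate counts. The
structural df then reflect the observed design rather than a nominal
balanced formula — museum datasets are rarely complete, and forcing
balanced df would misstate the tests.

FA is declared present when the interaction is significant (p < .05) and
its F exceeds 10 times the F of the error stratum — the conventional
requirement that the asymmetry signal stand an order of magnitude clear
of measurement noise. Both criteria are reported separately.

## Individual FA indices

**Shape.** Each specimen's asymmetry vector is the difference of its
replicate-averaged left and (reflected) right Procrustes configurations.
The mean asymmetry across specimens — the DA — is subtracted, and each
centered deviation is standardized by the sample covariance of the
deviations: `score = sqrt(d' S^+ d)`. Shape space is rank-deficient, so
`S` is inverted by eigendecomposition keeping eigenvalues above `1e-10`
times the largest (the cutoff only needs to separate genuine variation
from numerical zeros; where exactly it falls is immaterial at sensible
sample sizes). A caveat worth knowing: when the number of specimens is at
or below the retained rank plus one, all Mahalanobis scores are equal by
construction — the score is informative only with more specimens than
shape dimensions.

**Size.** The signed index is the replicate-mean left centroid size minus
the right (positive when the left side is larger); comparisons among
samples use the absolute value, treating departures from symmetry the
same in either direction.

## Population genetics

Observed heterozygosity is reported per individual (heterozygous loci /
typed loci) and per population (mean over loci of the heterozygote
proportion among typed individuals). The inbreeding coefficient is the
Weir–Cockerham (1984) small-sample f, with variance components pooled
over alleles and loci for the multilocus value; Nei's `1 - Ho/He` is
reported alongside. Exact Hardy–Weinberg tests condition on allele counts
(Levene's distribution), fully enumerating genotype arrays when at most
`1e6` arrays exist and otherwise shuffling the allele vector Monte-Carlo
style; the p-value is the probability mass of arrays no more probable
than the observed one. Genotypic linkage disequilibrium uses a G
statistic on the genotype x genotype table with a permutation null and
the add-one correction `p = (1 + hits) / (n_perm + 1)`.

One property to be aware of: with multi-allelic loci and modest samples
the genotype tables are sparse and the permutation distribution of G is
strongly discrete, so the p-values are conservative (their mean exceeds
0.5 under independence). This is correct exact-test behavior; the test is
never anticonservative, and the package's tests check exactly that.
Missing genotypes are handled by pairwise deletion per locus.

## Landscape: scale of effect and habitat amount

The buffer radii follow the home-range chain: linear dimension
`LD = sqrt(HR)`, maximum dispersal distance `MDD = 40 * LD`, and a
scale-of-effect band from 30% to 50% of MDD. All derived values are
computed from the unrounded LD — rounding first visibly corrupts the last
digit for small home ranges. Habitat amount at a site is the percentage
of habitat cells among raster cells whose *center* lies within the buffer
radius; the cell-center rule is exactly testable and matches common
landscape tools, at the price of small discretization error for coarse
cells (area-weighting partial cells is out of scope). Cells off the
raster are excluded from numerator and denominator, and a coverage
attribute warns when more than 1% of the buffer lies off-raster.

## Associations and multiplicity

Population-level mean FA and individual FA scores are related to habitat
amount, heterozygosity, inbreeding, sex and body size through Pearson
correlations, one-way ANOVA / Kruskal–Wallis group comparisons (both
always computed; a Shapiro–Wilk gate at alpha = .05 labels which is
recommended), and likelihood-ratio tests of `y ~ x` against `y ~ 1` using
the normal-theory statistic `chi2 = n log(RSS0 / RSS1)` (equivalently
`-n log(1 - r^2)` for one numeric predictor), referred to chi-squared
with the number of added parameters. All models are bivariate — with
8-15 individuals per site, richer models are not estimable honestly.
This LRT is known to be liberal at very small n; the package's tests
measure the small-sample type-I rate rather than assuming the nominal
level. Bonferroni control divides the family alpha .05 by the family
size; the pipeline defaults use family sizes 5 (individual level) and 4
(population level), the sizes of the study design this package emulates,
giving per-test alphas .01 and .0125. Individual-level tests treat
specimens as independent; no mixed-effects correction is attempted.

## The synthetic-data generator

The generator exists so every stage is testable without external data.
Its defaults emulate the Atlantic-forest water-rat study design: 8 sites
with habitat cover 18.9-100%, 8-15 specimens per site, 10 landmarks x 2
sides x 2 photographs x 3 digitizings, and 7 microsatellite loci with 5
equifrequent alleles.

Landmark data follow a hierarchical Gaussian model on a fixed
mandible-like mean shape of unit centroid size: a per-individual shape
effect (SD 0.02 per coordinate), an asymmetry draw
`a_i ~ N(da, sigma_fa^2)` applied as `+a_i/2` to the left side and
`-a_i/2` to the right before mirroring — so the signed left-right
difference has mean `da` (DA magnitude 0.003) and variance `sigma_fa^2`
exactly, which makes the ANOVA expectation algebra closed-form:
`E[MS_int] - E[MS_err1] = (m d / 2) sigma_fa^2` for m images and d
digitizings. Image effects (SD 5e-4) are shared by the digitizings of one
photograph; digitizing noise (SD 2e-3) is independent per record. These
error magnitudes put the FA signal roughly an order of magnitude above
measurement noise, as in datasets where FA is detectable at all.
Individual body size is log-normal (5% CV) around a nominal 20 mm
centroid size.

Habitat rasters are Gaussian white noise smoothed at a length-scale of
1.5 cells (~45 m at Landsat-like 30 m cells) and thresholded at the
quantile giving the requested habitat fraction. The fragment grain is
deliberately finer than the 264 m buffer so that the habitat percentage
measured in the buffer tracks the configured global proportion; at
coarser grains a single patch can dominate the buffer and decouple the
measured covariate from the intended one.

The habitat-FA link is a user-configurable scenario, not an estimate: no
study of this design can identify the true mapping from habitat amount to
developmental noise. The default rule is linear,
`sigma_fa = 0.008 + 0.008 (1 - h)` — a twofold SD span over the habitat
range — and `fa_slope = 0` gives the null scenario used for
type-I-error measurement. Genotypes use the classical inbreeding mixture
(autozygous with probability F, else two independent draws), giving
`E[Ho] = (1 - F)(1 - sum p^2)` per locus; the default F is 0.05. One
master seed expands into fixed-offset per-site streams, so sites are
reproducible independently.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: spatially structured gene flow or drift,
allometry, non-Gaussian digitizing blunders, correlated landmark errors,
antisymmetry, and observer effects beyond the two modeled strata.

## Problem sizes used by the tests

The test suite and the acceptance script run everything at desk scale,
chosen so the checks are sharp but quick: variance-component recovery at
200 individuals; interaction-test calibration over 200 simulated null
datasets (10 individuals, k = 5); Weir–Cockerham recovery over 100
simulated populations of 500 individuals at 7 loci; LD calibration over
150 independent locus pairs at 199 permutations; and the end-to-end power
study over 100 seeds of the full 8-site scenario (with the morphometric
and landscape stages only, the association being the quantity under
test), plus 100 null-scenario seeds for the measured type-I rate.

## Known limitations

Only 2-D landmarks and matching symmetry are supported (no
object-symmetry decomposition of a single midline structure). The
Procrustes ANOVA assumes isotropic, landmark-independent error; the
Mahalanobis score relaxes this for scoring but the omnibus tests do not.
The exact HWE enumeration is feasible only for small allele counts —
beyond that the Monte-Carlo path is used automatically. Habitat
percentages use planar coordinates; no geodesy is attempted, which is
harmless at buffer scales of a few kilometers.
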