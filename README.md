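# fluctasym

Fluctuating asymmetry (FA) — small random deviations from bilateral
symmetry — is used as an indicator of developmental instability in wild
populations under environmental or genetic stress. `fluctasym` implements
the complete analysis for studies that quantify FA in paired structures
(e.g. left and right hemimandibles of museum specimens) and relate it to
habitat availability and genetic variation:

* **Morphometrics** — TPS input of replicated 2-D landmark
  configurations, matching-symmetry generalized Procrustes alignment
  (proper rotations only), Procrustes ANOVA and centroid-size ANOVA with
  nested measurement-error strata (`individual + side +
  individual:side + image + digitizing`), the FA detection rule
  (interaction significant *and* F > 10x the error F), and per-individual
  indices: the Mahalanobis shape-FA score `sqrt(d' S^+ d)` on
  DA-centered asymmetry vectors, and the signed/absolute centroid-size
  difference.
* **Population genetics** — observed heterozygosity per individual and
  population, Weir–Cockerham (1984) f with multilocus pooling, exact
  Hardy–Weinberg tests (full enumeration of Levene's conditional
  distribution, Monte-Carlo fallback), and genotypic
  linkage-disequilibrium permutation tests.
* **Landscape** — scale-of-effect radii from home range
  (`LD = sqrt(HR)`, `MDD = 40 LD`, band 30–50% of MDD) and percentage
  habitat within circular buffers on binary rasters (cell-center rule).
* **Associations** — Pearson correlations, ANOVA/Kruskal–Wallis group
  comparisons, likelihood-ratio tests of bivariate linear models against
  the intercept-only null (`chi2 = n log(RSS0/RSS1)`), and Bonferroni
  control.
* **Synthetic data** — a generator reproducing the full specimen x side x
  image x digitizing hierarchy with known variance components, genotypes
  with known inbreeding F, and spatially autocorrelated habitat rasters,
  so the whole pipeline is testable at desk scale.

## Worked example

Scale-of-effect radii from a 2200 m² home range:

```r
library(fluctasym)
scale_effect(2200)
#>   home_range_m2 linear_distance      mdd scale_min scale_max
#> 1          2200        46.90416 1876.166  562.8499  938.0832
```

The linear dimension of the home range is ~46.9 m, the allometric maximum
dispersal distance 40x that (~1876 m), and habitat amount is expected to
act at radii between ~563 and ~938 m.

Population-level association between habitat cover (264 m buffer) and
mean mandible shape FA, using the bundled reference site table:

```r
s <- site_reference()
pearson_assoc(s$habitat_264m, s$shape_fa_mean)
#> $r
#> [1] -0.8760851
#> $p
#> [1] 0.004325634
#> $n
#> [1] 8
```

A strong negative correlation: sites with more forest habitat harbor
populations with lower mean shape FA.

The full pipeline on the built-in synthetic scenario (8 sites, habitat
19–100%, FA variance decreasing in habitat):

```r
out <- run_pipeline(study_config(seed = 1))
out
#> <pipeline_result>
#>   FA detected: shape TRUE, size TRUE
#>   population habitat/shape-FA r = -0.963 (p = 0.0001)
#>   14 association tests, 4 significant

print(out$anova_shape, digits = 3)
#> Nested shape (Procrustes) ANOVA (df multiplier 16)
#>           effect     SS    df       MS     F        p     denominator
#>       individual 6.7685  1376 4.92e-03 12.69 0.00e+00 individual:side
#>             side 0.0250    16 1.56e-03  4.04 1.37e-07 individual:side
#>  individual:side 0.5332  1376 3.88e-04 83.82 0.00e+00          error1
#>           error1 0.0129  2784 4.62e-06  1.17 5.60e-08        residual
#>         residual 0.0440 11136 3.95e-06    NA       NA            <NA>
```

The individual-by-side interaction (the FA signal) is highly significant
and its F is far more than 10x the error-stratum F, so FA is declared
present; the significant side effect is directional asymmetry, which is
removed before FA scoring. `out$scores` holds the per-individual indices,
`out$population_table` the per-site summary (mean FA, habitat %, Ho,
F_is), and `out$assoc` the Bonferroni-controlled LRT battery — in this
run the habitat LRT is significant at the population level
(alpha = .0125) while the genetic factors are not, matching the effect
built into the scenario.

A YAML-driven command line front-end is included:

```sh
Rscript inst/scripts/fluctasym-pipeline.R --seed 1 --out-dir results_demo
```

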