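# islephylo

Temporal community phylogenetics for island floras: how much do local
extinctions and exotic-plant introductions reshape the evolutionary
diversity of an island's flora, and do they make islands phylogenetically
more alike?

The package is built for the classic two-period island design. A regional
species pool with status flags (native/exotic, extinct) and per-island
occurrences defines two assemblages per island: the **pre-European** flora
(all natives, including species extinct today) and the **current** flora
(surviving natives plus naturalized exotics). Every assemblage is scored
against one age-calibrated regional phylogeny, and the two periods are
compared.

## What it computes

**Phylogenetic alpha diversity** of an assemblage *S* on a chronogram:

- Faith's PD: the summed branch length of the minimal subtree connecting
  *S* and the root (root-inclusive, so PD is defined for a single species);
- MPD: the mean patristic distance over all unordered pairs in *S*
  ("deep" structure — orders, families);
- MNTD: the mean distance from each member of *S* to its nearest co-member
  ("terminal" structure — recent extinctions and introductions).

**Standardized effect sizes** under a tip-label randomization null:
`SES = (observed − mean_null) / sd_null` over `n_rand` shuffles of the
phylogeny's tip labels with assemblage membership fixed (999 by default).
`SES < −1.96` is phylogenetic clustering, `SES > 1.96` overdispersion; the
Webb-convention indices NRI = −SES(MPD) and NTI = −SES(MNTD) are reported
alongside.

**Phylogenetic beta diversity** as `1 − PhyloSor`, where
`PhyloSor = 2·BL_shared / (PD_a + PD_b)` is the fraction of branch length
shared by two assemblages' spanning subtrees — 0 means phylogenetic
homogenization, 1 complete turnover. Computed between periods within each
island (temporal) and between islands within each period (spatial), with a
matrix-preserving tip-shuffle SES and one-tailed Mantel tests against
great-circle distance.

**Comparative statistics**: per-island percent changes with two-tailed
one-sample t tests against 0, paired t tests of SES between periods, and a
pooled mean ± 1.96 SE check across islands.

Supporting machinery: a BLADJ-style age calibrator (dated nodes fixed,
undated nodes spaced evenly between them), Newick I/O with graft/prune
editing for megatree workflows, and a seeded generator of synthetic island
systems (Yule chronogram + occurrence matrix with clade-biased extinction
and introduction) so the entire pipeline is testable end to end.

## Worked example

Published per-island richness counts for the six southeastern Pacific
islands ship with the package; the contrast layer runs directly on them:

```r
library(islephylo)

rc <- richness_contrasts(pacific_richness())
rc$complete
#> <change_summary>
#> # A tibble: 6 x 4
#>   island            before after change_pct
#>   <chr>              <dbl> <dbl>      <dbl>
#> 1 San Felix              9    15       66.7
#> 2 San Ambrosio          19    25       31.6
#> 3 Easter                40   366      815
#> 4 Robinson Crusoe      100   575      475
#> 5 Santa Clara           12    53      342.
#> 6 Alejandro Selkirk     71   217      206.
#> mean change 322.6% +/- 119.7 (SE), t(5) = 2.69, p = 0.043
```

Richness roughly quadrupled on average (+323%), driven entirely by exotic
introductions; the per-island changes span +32% to +815%. The same layer
applied to the published alpha-diversity table shows that MNTD collapsed
(−37% ± 6, t(5) = −6.1, p = 0.002: introductions pack the tree's tips with
close relatives) while MPD barely moved (−2.5% ± 1.4, t(5) = −1.76,
p = 0.14: the deep structure is intact):

```r
alpha_contrasts(pacific_alpha())
```

A fully synthetic system under the same richness envelope exercises every
stage, here the temporal beta-diversity layer:

```r
sys <- simulate_system(sim_config(), seed = 1)
tb  <- temporal_beta(sys$tree, sys$flora)
one_sample_t(tb$beta)
#> # A tibble: 1 x 7
#>       n  mean     se     t    df       p degenerate
#>   <int> <dbl>  <dbl> <dbl> <int>   <dbl> <lgl>
#> 1     6 0.339 0.0829  4.09     5 0.00942 FALSE
```

Each island's current flora shares about two-thirds of its branch length
with its pre-European flora (mean 1 − PhyloSor = 0.34, significantly above
0). The full pipeline — alpha, SES, beta, Mantel, contrasts, CSV export —
is one call:

```r
report <- run_analysis(sys$tree, sys$flora, n_rand = 999, seed = 1)
write_report(report, "results/run1")
plot_ses_summary(report$ses)
```

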