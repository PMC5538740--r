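---
title: "Methods: temporal phylogenetic diversity of island floras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal phylogenetic diversity of island floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islephylo)
```

# The design

`islephylo` implements the two-period island comparison: a regional
angiosperm pool is split, per island, into a **pre-European** assemblage
(every native recorded on the island, including species extinct today) and
a **current** assemblage (surviving natives plus naturalized exotics).
Both are scored against a single age-calibrated regional phylogeny, and
differences between the periods — in phylogenetic alpha diversity, its
standardized effect sizes, and phylogenetic beta diversity — quantify what
extinctions and introductions did to the evolutionary structure of the
flora.

Two modelling commitments follow from the data this design uses:

* **Extinction is a species-level flag.** Occurrence tables of this kind
  record a species' status once, not per island. A species flagged extinct
  is therefore removed from the current flora of every island it occupied.
  Per-island extinction would require recolonization records the design
  does not include.
* **One tree for both periods.** Temporal and spatial comparisons use the
  full regional chronogram; only assemblage membership changes between
  periods. Pruning a tree to an assemblage preserves all pairwise tip
  distances (a tested invariant), so scoring assemblages in place on the
  regional tree is exact, not an approximation.

# Alpha diversity and its null model

For an assemblage $S$ on a chronogram with branch lengths in millions of
years:

* **Faith's PD** is the summed branch length of the minimal subtree
  connecting $S$ *and the root*. The root-inclusive convention is a
  deliberate choice: it makes PD well-defined for single-species
  assemblages (their PD is the root path), agrees with the dominant
  implementation default, and gives PhyloSor (below) a consistent
  denominator.
* **MPD** is the mean patristic distance over all unordered pairs of $S$;
  it responds to deep (order/family-level) structure.
* **MNTD** is the mean distance of each member to its nearest co-member;
  it responds to terminal structure, which is where recent extinctions and
  introductions act.

MPD and MNTD require at least two taxa and are reported as `NA` (flagged)
below that; an empty assemblage is an error for PD.

**Standardized effect sizes.** Observed values are compared with a
tip-label randomization null: shuffle all tip labels of the phylogeny,
keep assemblage membership fixed, recompute, repeat `n_rand` times
(default 999), and report
$\mathrm{SES} = (\mathrm{obs} - \bar{x}_{null})/s_{null}$. Shuffling the
tree rather than the community matrix preserves the occurrence structure
of the data (richness per island, shared species between islands).

Internally the null exploits an exact equivalence: relabelling all tips
uniformly at random and scoring a fixed assemblage is distributionally
identical to scoring a uniformly random tip subset of the same size on the
original tree (the assemblage's preimage under a uniform permutation is a
uniform subset). The exported `tip_shuffle()` gives the literal
formulation; the engines use the subset form, and a test compares the two
routes' null moments. For beta-diversity SES the two assemblages share one
permutation, which preserves their sizes *and* overlap.

**Sign convention.** Clustering means the observed metric falls below the
null mean, i.e. negative raw SES. Classification is `clustered` below
−1.96, `overdispersed` above +1.96, `indistinct` between. Because much of
the literature reports the sign-flipped Webb indices (NRI = −SES(MPD),
NTI = −SES(MNTD), clustering positive), the `webb` column carries the flip
so either convention can be read directly. A pooled check across islands
(`pooled_ses_ci()`) reports mean ± 1.96 SE of the per-island SES values.

**Degenerate nulls.** When every relabelling yields the same value — the
full tip set, or a star tree with equal branch lengths — the null standard
deviation is 0. Such results are returned with `ses = NA` and
`degenerate = TRUE` rather than raising an error, because they arise
legitimately in small systems. The numerical threshold is
$s_{null} < 10^{-12}$.

# Beta diversity

PhyloSor similarity is
$\mathrm{PhyloSor}(a, b) = 2 BL_{shared} / (PD_a + PD_b)$, where
$BL_{shared}$ is the branch length lying in both root-inclusive spanning
subtrees; phylogenetic beta diversity is $1 - \mathrm{PhyloSor}$, 0 for
identical assemblages (homogenization) and 1 for complete turnover.
Root-inclusiveness matters here: with the regional tree rooted at a
zero-length crown edge, assemblages from disjoint basal clades share no
measured branch length and attain dissimilarity exactly 1. If the root
edge had positive length it would be shared by construction and the bound
would shrink accordingly — the package treats the stored `root.edge` as
real branch length throughout.

Temporal beta compares each island's two periods; spatial beta compares
island pairs within a period. Raw values are summarised with a two-tailed
one-sample t test against 0, and SES values (tip-shuffle null, overlap
preserved) are reported as a separate layer; the package does not merge
the two into a single significance statement.

The Mantel test correlates the off-diagonal entries of the beta matrix
with great-circle distance (haversine, Earth radius 6371 km), with a
permutation p-value from jointly permuting rows and columns of the second
matrix: $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$. The default
is one-tailed for positive association because distance decay is a
directional hypothesis; `alternative = "two.sided"` is available. Matrices
with zero off-diagonal variance return a flagged result.

# Age calibration (BLADJ)

`bladj()` turns a topology plus a node-age table into a chronogram: named
nodes take their tabulated ages (millions of years), tips are fixed at 0,
and every undated node is placed by even interpolation. For a chain of $u$
undated nodes between a dated ancestor of age $a$ and its nearest dated
descendant (or tip) of age $b$, the $j$-th node from the ancestor gets age
$a - j(a-b)/(u+1)$. Branch lengths are parent age minus child age, so the
output is ultrametric by construction (tested to $10^{-9}$), and the
procedure is idempotent because input branch lengths are ignored.

Two ambiguities required decisions:

* **Multiple dated descendants.** An undated node can see different dated
  descendants along different paths. The constraint is taken from the path
  with the fewest intervening undated nodes, ties broken toward the oldest
  constraint.
* **Conflicting branches.** With dated descendants of very different ages
  on different branches, the minimal-path value can fall outside the
  interval allowed by the node's parent and its oldest dated descendant
  (ages must strictly decrease rootward-to-tipward). When that happens the
  node is re-anchored: evenly spaced between its parent's assigned age and
  its oldest dated descendant. On consistent chain-like tables the
  re-anchor never fires; it exists to guarantee monotone, nonnegative
  branch lengths on adversarial topologies. Equal ages in the table are
  honoured as explicit zero-length branches.

Preconditions enforced with named errors: the root must be dated; a dated
descendant older than a dated ancestor is an inversion; tips may appear in
the table only with age 0.

# Tree handling

Newick I/O, pruning, and grafting wrap the `ape` toolkit with the
bookkeeping this analysis needs. `prune_to()` keeps the path from the
original root to the retained set as the result's `root.edge`, so
root-inclusive PD is invariant under pruning (tested). `graft()` attaches
a subtree (or single tip) as a new child of a named interior node —
the megatree workflow where missing species hang under their family.
Malformed Newick is rejected with the character offset of the offending
parenthesis or quote; duplicate tip labels are an error everywhere.
Underscores in labels are treated literally. One caveat worth knowing:
`ape`'s reader misorders node labels on *nested singleton* nodes (chains
like `(((t)n2)n1)root;`), so calibration chains in the package's own tests
are built programmatically, and internal traversals use the package's own
edge ordering, which handles singleton nodes correctly.

Species present in the occurrence data but absent from the tree are an
error by default: silently dropping them would corrupt SES, whose null
draws come from the tree. An explicit `skip_missing = TRUE` drops them
with a message and reports `n_matched` next to `n_species`.

# The synthetic generator

`simulate_system()` produces a system with the statistical structure the
analysis assumes: a Yule (pure-birth) chronogram conditioned on the pool
size and rescaled to a fixed crown age; natives assigned to islands by
per-island occupancy probabilities (each native kept on at least one
island); extinction applied per island up to a target fraction of its
natives (as a species-level flag, so shared species propagate); and a
fixed number of exotic introductions per island. With `clade_bias > 0`,
extinction and introduction draws are weighted by `exp(clade_bias)` for
members of one randomly chosen clade holding roughly 10% of the tips —
the mechanism behind "invasions come from a few widespread clades".

Defaults are the published envelope of the southeastern Pacific system the
package ships fixtures for: 6 islands, 205 natives, 756 exotics, expected
native richness 9–100 per island, introductions 6–477, extinction
fractions 0–0.35, crown age 140 My (a round figure for the angiosperm
crown). The birth rate (0.1/My) only shapes relative node depths before
rescaling. What the generator does *not* emulate: real spatial dispersal
kernels, environmental filtering, per-island extinction dynamics, trait
evolution, and the hand-curated topology of a real megatree. Passing tests
therefore demonstrate correctness of the machinery and calibration of the
null models — not that any particular empirical system must show a given
effect size.

A Yule process observed for time $t$ has $e^{\lambda t}$ expected lineages;
that expectation applies to the *unconditioned* process. Because the
generator conditions on the tip count and rescales depth, the package
asserts the properties the conditioned generator actually guarantees:
exact tip count, binary topology, ultrametricity to $10^{-9}$, exact crown
age, and seeded reproducibility.

# Problem sizes and tolerances in the tests

The test suite runs in about a minute on one core with these choices,
stated here as the package's own calibration of cost against power:

* exhaustive oracle agreement (explicit path/edge enumeration) on all
  assemblages of 7–8-tip trees and all subset pairs of a 5-tip tree,
  tolerance $10^{-10}$;
* SES null calibration: 500 uniform-random assemblages of 16 tips on a
  64-tip tree, `n_rand = 99`, requiring $|\bar{x}| < 0.15$ and
  $s \in [0.8, 1.2]$;
* construction validity: one 8-tip clade of a 64-tip balanced tree gives
  SES(MPD) $< -1.96$ in at least 95% of 20 seeded runs; disjoint clades
  give beta 1; identical assemblages give 0;
* Mantel type-I error over 500 independent 6-island replicates with 199
  permutations, required within $[0.02, 0.08]$ at $\alpha = 0.05$;
* extinction-fraction recovery within three binomial standard errors plus
  rounding; clade-biased vs unbiased introductions separated by a t test
  at $p < 0.05$ over 25 seeded replicates each.

Floating-point equality is asserted at $10^{-10}$–$10^{-12}$ for exact
quantities; ultrametricity at $10^{-9}$ (accumulated interpolation
arithmetic); printed-value reproduction at the precision the source tables
print (integers for percent changes, one or two decimals for t
statistics).

# Known limitations

* Absolute alpha-diversity levels depend on the calibration table and the
  degree of polytomy resolution of the input megatree; the package
  reproduces contrast statistics from published per-island tables but
  cannot reconstruct a hand-curated topology (the grafting mechanics are
  provided; the curation itself is data).
* Only presence/absence is supported — no abundance-weighted MPD/MNTD or
  PhyloSor variants.
* The tip-label null is the only null model, by design; community-matrix
  shuffles (independent swap and kin) are out of scope.
* The native-only contrast of a published table is computed against the
  pre-European complete flora when no native-scope pre-European rows
  exist, which is exact only when analyses use one shared tree; published
  analyses that scored natives on a separate native-only tree will differ.
* `ape`'s Newick reader mislabels nested singleton chains (see above);
  calibration chains should be built programmatically or written without
  singleton nesting.
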