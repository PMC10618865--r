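---
title: "Methods: age-range correlation, sympatry classification and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-range correlation, sympatry classification and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympatree)
```

## The question and the data model

Comparative biogeography infers the geographic mode of speciation from the
joint distribution of three observables over sister species pairs: the age
of the node subtending the pair (from a time-calibrated phylogeny, in Ma),
the degree of range overlap, and the evenness of range sizes. The logic: if
speciation is predominantly allopatric and ranges move independently
afterwards, overlap should be absent in young pairs and accumulate with
age; predominantly sympatric speciation puts high overlap in the youngest
pairs; peripatric speciation (budding of a small peripheral isolate) leaves
young pairs with strongly asymmetric range sizes.

`sympatree` operates on three inputs: a rooted ultrametric chronogram
(Newick), per-species ranges (polygons or presence/probability grids on
WGS84 lon/lat), and a species trait table. Sister pairs are defined
strictly as cherries — two tips whose common ancestor is shared with no
other sampled tip. Because unsampled species can break true sisterhood, a
`direct` flag records which pairs are believed reciprocally monophyletic;
this is user metadata (via the `complete_genera` argument), not something
the tree itself can certify.

## Range indices on the sphere

Ranges are discretized on a shared lon/lat grid. The area of a cell in
latitude band $[\phi_1,\phi_2]$ with width $\Delta\lambda$ is
$R^2\,\Delta\lambda\,(\sin\phi_2-\sin\phi_1)$ with $R = 6371$ km, so areas
are exact on the sphere and summing a global grid returns $4\pi R^2$.
Planar areas were rejected because ranges spanning tens of degrees of
latitude are badly distorted in any single projection.

For a pair with range areas $A_a, A_b$ and intersection area $A_{ab}$:

$$O = \frac{A_{ab}}{\min(A_a, A_b)} \in [0,1], \qquad
  S = \frac{\min(A_a, A_b)}{A_a + A_b} \in (0, 0.5].$$

"Area occupied by the pair" is read as the intersection area — the only
reading for which $O$ has the stated endpoints (0 = disjoint, 1 = nested or
identical). Classification is allopatric iff $O <$ threshold; the default
threshold 0.05 tolerates small occurrence errors, and the boundary value is
sympatric (the rule is $\ge$).

Tunable parameters and defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| grid resolution | 0.5 | degrees | matches typical half-degree Aquamaps cells |
| probability cutoff | 0.5 | — | occurrence-probability grids carry no canonical cutoff; 0.5 is the midpoint and configurable |
| overlap threshold | 0.05 | — | absorbs digitization error in expert range maps |
| rasterization rule | center | — | cell present iff its center is inside the polygon; an `any` rule (4×4 sub-lattice) is available for conservative coverage |

Polygons crossing the antimeridian are handled by normalizing longitudes to
[−180, 180), unwrapping rings whose consecutive vertices jump more than
180°, and testing each cell center at longitude offsets {−360, 0, +360}.
Holes are honoured by the even-odd rule. Degenerate inputs fail loudly: a
polygon covering no cell, an empty presence matrix, or probabilities
outside [0, 1] are errors, because a species without a usable range must be
excluded from the analysis (and is, with a logged count) rather than
carried as a zero-area range.

## Sister-pair analyses

`build_pair_table()` joins pairs, rasters and traits into one record per
pair. Trait contrasts are absolute differences — sign is meaningless for an
unordered pair. A pair missing range data is retained in the table with
`excluded_reason = "no_range"` and excluded from every statistic; a pair
missing one trait only loses that trait's contrast. Habitat combinations
are stratified binarily (both reef, both non-reef, or mixed), matching the
same-versus-different-habitat comparison the analysis is designed for.

Age-range correlation is ordinary least squares of $O$ (or $S$) on node
age. Both $r$ and $r^2$ are always reported because published regression
tables are not always explicit about which scale they print. Group
comparisons use Welch's unequal-variance $t$ with Welch–Satterthwaite
fractional degrees of freedom. Class summaries (counts, proportions,
medians of node age and symmetry) are computed over all range-usable pairs
by default; because a depth-missing pair changes medians only if it is also
dropped from the symmetry pool, `summarize_pairs(drop_depth_missing =
TRUE)` exposes the second variant and the pipeline writes both.

## Phylogenetic signal

**Blomberg's K.** With $V$ the Brownian covariance implied by the tree,
$\hat a$ the phylogenetically weighted mean, $MSE_0$ the raw mean squared
deviation and $MSE$ the GLS mean squared error,

$$K = \frac{MSE_0/MSE}
  {\left(\mathrm{tr}\,V - n/\mathbf 1^{\mathsf T} V^{-1}\mathbf 1\right)/(n-1)}.$$

K is location- and scale-invariant in the trait. Significance comes from
tip permutations of the trait, using the variance of standardized
independent contrasts as the test statistic, one-tailed toward *low*
contrast variance (signal means relatives resemble each other, hence
smaller contrasts than permuted data). All permutation p-values in the
package include the observed value in numerator and denominator,
$p = (1 + \#\{\text{as extreme}\})/(1 + n_{perm})$, so $p > 0$ always.

**Fritz's D.** For a binary trait, nodal values are estimated by the
unweighted average-of-children recursion and $d$ is the sum over internal
nodes of sister-clade differences. $d_{obs}$ is scaled between the mean
$d$ under tip-state permutation (random; D = 1) and under Brownian motion
thresholded at the observed prevalence (D = 0). Two simulation-tail
probabilities are reported: $p(D>0)$ from the Brownian distribution and
$p(D<1)$ from the random distribution. The default 1000 replicates per
reference model keep the Monte-Carlo error on D well below the biological
signal of interest.

**PGLS with OU errors.** The error correlation is
$V_{ij} = \exp(-\alpha\,d_{ij})$ in patristic distance $d_{ij}$. $\alpha$
is estimated by maximizing the restricted likelihood over 50 log-spaced
values spanning $[10^{-4}, 10^{2}]/h$ ($h$ = tree height) followed by
derivative-free refinement between the best grid point's neighbours —
bounded, reproducible, and immune to gradient pathologies near the OLS
limit ($\alpha \to \infty$, where $V \to I$). If refinement ever fails to
beat the grid, the grid optimum is kept, so the reported likelihood never
falls below the profile.

**Mantel tests.** The statistic is $R^2$ of the regression between the
vectorized upper triangles of two pairwise matrices, residualized on a
third matrix for the partial test; significance comes from simultaneous
row/column permutations of the response matrix. "Phylogenetically informed
permutation" has no single published mechanics, so the package makes the
choice explicit: the default is the plain permutation scheme, and an
optional `phylo-weighted` mode draws permuted labels with probability
decaying exponentially in patristic distance (mean distance as the scale),
concentrating exchanges among close relatives. Results are labelled with
the mode used; the two schemes can give different p-values and should not
be mixed silently.

## The synthetic-data generator

`make_scenario()` produces the full data triplet with known truth. The
defaults were fixed once to describe the kind of clade the analysis
targets: 123 extant species (a mid-sized percomorph radiation), birth 0.08
and death 0.02 events/Ma giving crown ages of a few tens of Ma, ranges on
a 1° grid over latitudes −60..60 (where marine fish diversity lives), an
allopatry-dominant mode mix (0.5 allopatric / 0.25 sympatric / 0.25
peripatric) reflecting the prevailing view of marine speciation, peripheral
fraction 0.1, drift of 2 boundary cells/Ma, and an ancestral seed range
covering 10% of the grid.

Range evolution is a cell-level boundary process, not polygon morphing:
at speciation the parental range is copied (sympatric), bisected along its
longer axis at the area-median line (allopatric — deterministic given the
seed, both halves non-empty), or split into a peripheral block of the
target fraction at a randomly chosen end versus the remainder (peripatric).
Between events a Poisson(drift × branch length) number of single-cell
frontier additions/removals is applied, never emptying a range. Keeping
the simulator exact on the analysis grid makes the truth computable: with
drift 0, allopatric cherries have exactly $O = 0$, sympatric cherries
exactly $O = 1, S = 0.5$, and peripatric cherries $S \le$ the peripheral
fraction *provided the parent range holds at least `1/fraction` cells* —
when repeated splitting exhausts a range below 2 cells the node falls back
to sympatric inheritance and is recorded as such in the truth table
(`n_cells` records the parent size at every node, making exhaustion
auditable).

The tree simulator runs forward from the two root lineages and fixes the
present at the moment the $(n{+}1)$-th extant lineage would appear,
pruning extinct lineages; under pure birth the expected root age is
$\sum_{k=2}^{n} 1/(\lambda k)$, which the test suite checks by Monte
Carlo. Continuous traits are geometric Brownian motion around
field-typical maxima (60 cm body length, 100 m depth); binary traits
(reef association, piscivory) follow a symmetric two-state Markov chain at
0.05 transitions/Ma. All simulators accept a seed and leave the caller's
RNG stream untouched, so they compose inside the user's own replicate
loops.

What the generator does *not* emulate: real oceanographic barriers,
dispersal kernels, niche models, range-size heritability, or correlated
trait-range evolution. Passing calibration tests on synthetic data
therefore demonstrates the statistics behave as designed under their own
assumptions — not that any empirical clade satisfies those assumptions.

## Numerical choices and test scale

- Ultrametricity is checked to a relative tolerance of 1e-6 and violations
  warn rather than fail — empirical chronograms carry rounding error.
- Polytomies yield no sister pair (membership is ambiguous) and warn.
- Equal-area constructions in tests use cells from the same latitude bands,
  where spherical cell areas are identical by symmetry.
- The test suite calibrates Blomberg's K on 500 Brownian traits over
  64-tip pure-birth trees (mean K within [0.9, 1.1]; null permutation
  p uniform by Kolmogorov–Smirnov), Fritz's D on 200 replicates each of
  shuffled and perfectly clade-split states on a 32-tip balanced tree, and
  the Mantel test's type-I error on 500 null replicates of 15-species
  matrices with 999 permutations. Mode recovery uses an 80-tip scaffold
  with exactly 40 cherries. These sizes give binomial/Monte-Carlo standard
  errors comfortably inside the asserted bounds while keeping the whole
  suite under a minute of compute.

## Known limitations

- The overlap of *extant* ranges is an imperfect witness of the geography
  of speciation: post-speciation range movement erodes the signal, which
  is exactly what the drift parameter of the simulator demonstrates
  (classification accuracy against the true mode decays monotonically with
  drift).
- The directness of sister pairs cannot be inferred from a sampled tree;
  the `direct` flag is metadata.
- Rasterization at coarse resolution biases the overlap of narrowly
  abutting ranges; the convergence test shows the error of the center rule
  falls below 0.01 by 0.1° for rectangular ranges, but users with very
  small ranges should refine the grid.
- Mantel tests have low power, and the partial/permutation variants are
  sensitive to the permutation scheme; the package exposes the scheme
  precisely so that this sensitivity is visible rather than hidden.
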