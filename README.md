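# sympatree

Tools for asking *where* speciation happened from two ingredients every
molecular phylogeneticist eventually has in hand: a time-calibrated phylogeny
and range maps for its species. The package implements the comparative
age-range-correlation workflow used to distinguish sympatric, allopatric
(vicariant) and peripatric modes of speciation in marine clades, together
with the phylogenetic-signal statistics that usually accompany it, and a
synthetic-data generator so the whole pipeline can be exercised and
calibrated without any external range databases.

## What it computes

For every **sister species pair** (a cherry of the chronogram — two tips
sharing an ancestor unique to them), with ranges discretized on a shared
longitude/latitude grid with spherical (area-true) cell areas:

- **Range overlap** `O = A(R_a ∩ R_b) / min(A(R_a), A(R_b))`, from 0 (no
  overlap) to 1 (complete overlap or nestedness). Pairs are classified
  **allopatric** when `O < 0.05` and **sympatric** when `O ≥ 0.05`; the
  threshold absorbs small errors in occurrence data and is configurable.
- **Range symmetry** `S = min(A_a, A_b) / (A_a + A_b)`, in (0, 0.5]; values
  near 0.5 mean equal-sized ranges, small values are the signature of
  peripatric budding.
- **Age-range correlation**: OLS regression of `O` (or `S`) on the pair's
  node age. Under allopatric speciation with independent range movement,
  overlap should grow with age; under sympatric speciation young pairs
  already overlap.
- **Trait contrasts** (absolute differences in maximum body length and
  maximum water-column depth) compared between sympatry classes and habitat
  strata with Welch's *t*-tests.
- **Phylogenetic signal**: Blomberg's *K* for continuous traits (K = 1 is
  the Brownian expectation), Fritz's *D* for binary traits (0 ≈ Brownian
  clumping, 1 ≈ random), PGLS regression with an Ornstein–Uhlenbeck error
  model `V_ij = exp(−α d_ij)`, and (partial) Mantel tests of pairwise
  overlap/symmetry matrices against patristic distances, with optional
  phylogenetically weighted permutations.

The simulator (`sim_config()` / `make_scenario()`) grows a birth–death
chronogram, evolves ranges along it under sympatric / vicariant / peripatric
splitting with post-speciation boundary drift, and evolves continuous
(Brownian) and binary (two-state Markov) traits, recording the true mode at
every node so classification accuracy is measurable.

## Worked example

```r
library(sympatree)

cfg   <- sim_config(n_tips = 40, seed = 7)      # allopatry-dominant defaults
sc    <- make_scenario(cfg)                     # tree + ranges + traits
pairs <- sister_pairs(sc$tree)
tab   <- build_pair_table(pairs, sc$rasters, sc$traits)

summarize_pairs(tab)
#> # A tibble: 2 × 5
#>   classification     n proportion median_node_age median_symmetry
#>   <chr>          <int>      <dbl>           <dbl>           <dbl>
#> 1 allopatric        10      0.769           1.66            0.491
#> 2 sympatric          3      0.231           0.695           0.486

arc_regression(tab, "node_age", "overlap")
#> <arc_regression> overlap ~ node_age: slope = 0.03104, r = 0.1539, r^2 = 0.0237, p = 0.6156, n = 13

welch_t(tab$contrast_depth[tab$classification == "sympatric"],
        tab$contrast_depth[tab$classification == "allopatric"])
#> <welch_result> t = 0.5480, df = 10.9940, p = 0.5946 (n = 3, 10)

blomberg_k(sc$tree, setNames(log(sc$traits$max_length_cm), sc$traits$species),
           n_perm = 999, seed = 7)
#> <signal_result> K = 0.8443 (n = 40, 999 permutations/simulations)
#>   p = 0.001
```

Reading the output: 13 of the 19 cherries carried usable ranges after this
drifty scenario; most pairs are allopatric (their ranges were bisected at
speciation and drift has not yet rejoined them), node age does not predict
overlap at this sample size (p = 0.62), depth contrasts do not differ
between classes, and the Brownian body-length trait shows strong
phylogenetic signal (permutation p = 0.001) with K slightly below 1.

`run_pipeline()` wraps these stages over files on disk (Newick tree, grid
CSVs or GeoJSON polygons, trait CSV) and writes `pair_table.csv`,
`summaries.csv`, `tests.csv`, `regressions.csv`, `signal.csv`, a richness
grid and a JSON manifest with every exclusion count. A thin command-line
wrapper is provided:

```sh
Rscript scripts/pipeline.R simulate --out scenario --seed 3 --n-tips 40
Rscript scripts/pipeline.R run --tree scenario/tree.nwk --ranges scenario/grids \
    --traits scenario/traits.csv --out results --seed 4 --n-perm 1000
```

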