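# dagmap

Consensus genetic linkage maps via directed acyclic graphs.

`dagmap` integrates linkage maps from multiple mapping populations of one
species into a single consensus map. Each input map is a sequence of
*bins* — groups of co-segregating markers — with centimorgan (cM)
positions. The package:

1. **Merges** the maps into a consensus directed graph whose vertices are
   marker bins and whose edges are map intervals (edge length = interval
   distance, edge weight = the product of the marker counts the two
   vertices contribute). Markers placed at the same position are connected
   by zero-length edges that carry no ordering information.
2. **Detects marker-order conflicts** between maps as strongly connected
   components of the graph, and reports them for manual curation (Graphviz
   DOT output). A conflict-free graph is a DAG.
3. **Simplifies** the DAG to its minimal ordinally equivalent form:
   transitive edge reduction followed by coalescing of vertices with
   identical neighbourhoods. This is the "what do the maps jointly say
   about marker order" view of the data.
4. **Linearizes** the DAG into a consensus map by minimizing the weighted
   deviation between consensus bin positions and the input map intervals,
   subject to every marker-order constraint:
   `min Σ q_k |c_k'x − d_k|^α  s.t.  Ax ≥ 0`, with α = 2 a quadratic
   program (solved with `quadprog`) and α = 1 a linear program (solved
   with a sparse ADMM iteration plus active-set polishing).
5. **Evaluates** accuracy with a doubled-haploid simulation framework:
   Poisson crossovers without interference, Haldane's mapping function,
   and LOD-weighted least-squares map estimation.

## Worked example: the barley 5HS telomere

The package bundles the published linkage maps of the barley 5HS telomere
region from four populations — Steptoe × Morex (SM), Oregon Wolfe Barley
(OWB), Morex × Barke (MB), and Haruna Nijo × OHU602 (HO) — a region
interesting because it contains the grain hardness locus
(*hinb*/*hina*/*gsp* genes) and very little recombination.

```r
library(dagmap)
maps <- barley_5HS_maps()
G <- merge_linkage_maps(maps, verbose = TRUE)
#> merged SM       -> 3 vertices, 2 directed edges, 79 zero pairs
#> merged OWB      -> 9 vertices, 10 directed edges, 94 zero pairs
#> merged MB       -> 15 vertices, 29 directed edges, 100 zero pairs
#> merged HO       -> 15 vertices, 29 directed edges, 100 zero pairs
G
#> Consensus graph (group 5H): 22 markers, 15 vertices, 29 directed edges,
#> 100 zero-length pairs; maps: SM, OWB, MB, HO
```

The merge succeeds with no ordering conflicts (`assert_acyclic(G)`
returns a topological order instead of raising a `dagmap_conflict`
error). The minimal ordinal graph shows all the order information the
four maps jointly contain; restricted to the nine hardness-locus markers
it contains exactly three ordered pairs, all contributed by the OWB map:

```r
O <- ordinal_graph(G)
pairs <- ordinal_order_pairs(O)
hm <- unname(hardness_markers())
pairs[pairs$from %in% hm & pairs$to %in% hm, ]
#>      from     to
#> 46 3_0984 3_0979
#> 47 3_0984 3_0977
#> 50 3_0984 3_0975
```

Linearizing with the least-squares (QP) objective and rescaling to the
mean input map length:

```r
cm <- linearize_maps(maps, method = "QP")
attr(cm, "solution")
#> QP solution: 15 bins, length 7.915 cM, objective 23.2485
cm
#> Consensus map (QP): 22 markers in 15 bins, 4.312 cM (scale factor 0.5449)
round(sort(marker_positions(cm)), 2)
#> 3_0163 1_0745 2_0894 2_0553 3_0984 3_0543 2_0226 3_0976 3_0978 3_0980 3_0001
#>   0.00   1.17   1.17   1.17   1.19   1.25   1.29   1.29   1.29   1.29   1.34
#> 3_0979 3_0975 3_1023 3_0983 3_0977 3_1022 3_0591 2_0206 2_1202 1_1381 2_1221
#>   1.34   1.35   1.35   1.41   1.42   1.42   1.45   1.85   2.32   2.38   4.31
map_error(cm, maps)   # mean |consensus - map| deviation per marker pair
#> [1] 0.3737263
```

`method = "LP"` gives the weighted least-absolute-deviation map on the
same constraint set; both satisfy every bin order printed in the input
maps.

## Command line

A thin `Rscript` front end is installed under `exec/`:

```sh
dagmap check map1.csv map2.csv --conflict-dot conflicts.dot
dagmap consensus map1.csv map2.csv -o consensus.csv --method qp --report report.txt
dagmap simulate -o study.csv --g 1,2,8 --reps 20 --seed 1
```

Map files are headered CSV/TSV with columns `marker`, `group`,
`position_cM`. Exit codes: 0 success, 2 ordering conflicts (with a DOT
rendering of each strongly connected component), 1 other errors.

## Simulation study

`run_consensus_study()` reproduces the accuracy study: for each number of
crosses `g`, it simulates `g` doubled-haploid populations (1000 markers
on 100 cM, 200 individuals, 30% of markers segregating per cross),
estimates linkage maps by LOD-weighted least squares within windows of 4
adjacent bins, builds LP and QP consensus maps, and scores marker counts,
map compression, and cM accuracy against the simulated truth:

```r
study <- run_consensus_study(g_values = c(1, 2, 8), reps = 20, seed = 1)
study_cell(study, g = 8, method = "QP", metric = "rmse")
```

See the methods vignette (`vignettes/consensus-maps.Rmd`) for the model,
the algorithms, the numerical choices, and known limitations.

## Tests and reproduction

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "dagmap", load_package = "installed")'
```

The suite covers the graph algorithms against independent oracles
(brute-force precedence closures, `igraph` connectivity), the solvers
against analytic optima, KKT conditions and exhaustive breakpoint
search, and the simulation endpoints.

`scripts/acceptance.R` recomputes the headline statistics of the
simulation study (consensus marker counts, LP/QP map compression, RMS
accuracy, and the QP−LP accuracy contrast) from scratch and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
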