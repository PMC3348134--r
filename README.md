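# netdiv

Population-based structural complexity scoring for undirected networks.

## The problem

Classical graph complexity descriptors — Wiener index, graph energy,
orbit-entropy measures, offdiagonal complexity, and their relatives —
assign one number to one network.  But a network drawn from a generating
model is a random object, so the descriptor is a random variable: 100
Erdős–Rényi draws at fixed `(n, p)` give 100 different values of every one
of these measures.  And because a random-graph model emits *any* labeled
graph with positive probability

```
w = p^e (1 - p)^(C(n,2) - e),
```

the complexity value of a single network cannot be attributed unambiguously
to the model that generated it.  Scoring an independent sample of `S`
networks shrinks this misattribution factor to `w^S` and lets a sample mean
do what a single draw cannot.

`netdiv` implements the **network diversity score (NDS)** built on this
idea, for anyone comparing network populations — generative models, graph
ensembles inferred per patient or per condition, or subnetwork samples of
one large interactome.  Each network gets an **individual diversity score**

```
ids(G) = v_lambda / (alpha_module * r_motif * v_module)
```

composed of four structural variables: the Walktrap module density
`alpha_module = M/n`, the motif rate `r_motif = n_motif(3)/n_motif(4)`
(connected induced subgraphs of sizes 3 and 4), the module-size
variability `v_module = var(m)/mean(m)`, and the same variability
functional on the Laplacian spectrum, `v_lambda`.  The NDS of a sample is
the mean of the individual scores with the CLT standard error
`sd(ids)/sqrt(S)`.

The package also ships the sixteen classical single-network measures the
score is benchmarked against (`measure_registry()`), seeded generators for
ordered / random / complex network populations, random-walk subnetwork
sampling for scoring a single large network, and an evaluation harness
(parameter sweeps, histograms, densities, interval-threshold separation
scoring).  Graph plumbing is `igraph` end to end: edge-list / GML /
GraphML I/O, BFS distances, Walktrap, exact motif and automorphism
machinery.

## A worked example

Generate a balanced labeled benchmark (all three classes calibrated to
n = 100 and roughly 200 edges, so size and density separate nothing) and
fit the score to a sample of ten networks per class:

```r
library(netdiv)

pop <- benchmark_population(
  benchmark_spec(counts = c(ordered = 15, random = 15, complex = 15)),
  seed = 42)
pop
#> Labeled population: 45 networks (complex = 15, ordered = 15, random = 15)
#> median edges per class: complex: 197, ordered: 200, random: 202

cls <- split(pop$networks, pop$labels)
nds(cls$random[1:10])
#> Network diversity score (sample of S = 10 network(s))
#>   estimate: 14.22  (log10: 1.153)
#>   std. error: 1.489
nds(cls$ordered[1:10])
#> Network diversity score (sample of S = 10 network(s))
#>   estimate: 30.29  (log10: 1.481)
#>   std. error: 0.1337
nds(cls$complex[1:10])
#> Network diversity score (sample of S = 10 network(s))
#>   estimate: 97  (log10: 1.987)
#>   std. error: 37.78
```

The three estimates land in three disjoint regions — random lowest,
ordered in the middle (and nearly deterministic), complex highest — which
is exactly the interval structure the score is designed to produce; with
`S = 10` the interval classifier in `evaluate_separation()` reaches ≥ 95%
three-class accuracy, while the best of the sixteen single-network
measures stays near 83% on the same benchmark.

The per-network breakdown is always auditable:

```r
nds_score(gen_small_world(100, 4, 0.1, seed = 7))
#> Individual diversity score
#>   ids = 28.69   (log10: 1.458)
#>   components: alpha_module = 0.11, r_motif = 0.3252, v_module = 1.169, v_lambda = 1.2
#>   network: n = 100, e = 200, M = 11 modules
```

Classical measures dispatch by label, with the giant-component convention
one flag away:

```r
compute_measure(gen_erdos_renyi(100, 0.04, seed = 1), "wiener", giant = TRUE)
```

A thin command-line wrapper with `measure`, `nds`, `generate` and
`subsample` subcommands is installed as `exec/netdiv`.

## The methods vignette

`vignettes/network-diversity-score.Rmd` documents the score's definition
and assumptions, the composition choice, the generator calibration, the
numerical conventions of the sixteen measures, and known limitations.
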