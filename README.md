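# cohesionScreen

Downstream analysis of TAP-MS (tandem affinity purification mass
spectrometry) interactor screens, for researchers who have a raw bait
pull-down identification list and want to get from it to (a) a
high-confidence candidate interactor set, (b) the candidates' network in
a reference interactome, (c) a defensible statement that this network is
more cohesive than chance, and (d) a scored RNAi knockdown screen of the
candidates.

## What it computes

**Candidate filtering.** A protein is retained iff it appears in ≥
*r* distinct bait replicates (default 2), never appears in a negative
control purification, and is on no contaminant blocklist (heat-shock,
organellar, ...). Every input protein gets an audit entry naming the
first rule that removed it.

**Network assembly with parsimony expansion.** The induced subgraph of a
reference interactome on the candidate (seed) set, extended by every
node with ≥ 2 interactions with seed nodes — evaluated in a single pass
against the original seeds, so the expansion never cascades.

**PIE (physical interaction enrichment).** For a node set *S* with
induced edge count *e(S)*, draw *N* random node sets matched to *S* in
size and degree multiset (exact per-degree matching, with binned
fallback for unique hub degrees) and form the null distribution of
induced edge counts *e(S₁), ..., e(S_N)*. Then

    PIE(S) = e(S) / mean(e(Sᵢ)),
    p = (1 + #{e(Sᵢ) ≥ e(S)}) / (1 + N).

PIE = 1 is chance-level cohesiveness *given the degrees*; the add-one
empirical p has floor 1/(N+1) (so "p < 0.0001" at N = 10,000). Degree
matching is what prevents a set of well-studied hubs from looking
cohesive for free.

**RNAi screen scoring.** Five phenotype categories per knockdown
(normal / extra turn / wandering / overshoot / other), collapsed to
normal-vs-defective and tested against the control with two-sided
Fisher's exact tests; tiers at p < 0.05 (\*) and p < 0.0005 (\*\*\*\*).
Counts can be reconstructed from printed integer percentages
(round-half-up with deterministic residual repair).

**Synthetic data.** Uniform and exact-degree-sequence reference graphs,
planted cohesive modules via degree-preserving double-edge swaps (the
degree multiset is provably untouched, keeping the PIE null honest),
simulated TAP-MS replicate/control runs, and multinomial phenotype
screens.

## Worked example

A distal-tip-cell migration RNAi screen table (printed percentages plus
animals scored) ships with the package:

```r
library(cohesionScreen)

tab  <- readPhenotypeTable(system.file("extdata", "dtc_screen_percent.tsv",
                                       package = "cohesionScreen"))
ctrl <- tab[tab$treatment == "control", ]
ss   <- screenSummary(tab[tab$treatment != "control", ], ctrl,
                      interactorIds = tab$treatment[tab$role == "interactor"])
ss
#> ScreenSummary: 11 scored treatments, 9 significant interactors
#>   plus 2 significant non-interactor treatments
head(screenResults(ss)[, c("treatment", "percent_normal", "p_two_sided", "tier")], 4)
#>   treatment percent_normal  p_two_sided      tier
#> 1   W03H9.4           25.4 1.721454e-33 four_star
#> 2   C07A9.2           47.9 1.364703e-18 four_star
#> 3   EEED8.5           25.0 3.643024e-32 four_star
#> 4  F49D11.1           50.0 6.564797e-18 four_star
```

All 9 candidate-interactor knockdowns are significantly depleted of
normal gonad arms versus the empty-vector control; the two significant
"other" treatments are the bait knockdown itself (row 1, four-star) and
one network-expansion node. PIE on a synthetic interactome with a
planted cohesive module:

```r
pl  <- makePlantedReference(seed = 1)   # 2,000 nodes / 2,800 edges, 27-node module
res <- pieAnalysis(pl$network, pl$members, nRand = 10000, seed = 2)
res
#> PieResult: observed=53 edges, null mean=1.00 (sd 0.98), PIE=52.757,
#>   p=9.999e-05 [10000 draws, exact matching]
```

The planted module induces 53 edges where degree-matched random sets
average one; the empirical p sits at the 10,000-draw floor.
`runPipeline()` chains filtering → network → PIE → screen from a single
YAML/list config and writes TSV intermediates plus a JSON report; see
`?runPipeline`.

## Scope notes

Reproducing a *published* candidate list or PIE score requires that
study's contaminant blocklists and reference interactome snapshot;
with different inputs the pipeline reproduces the procedure, not the
numbers. See the methods vignette
(`vignettes/cohesion-screen-methods.Rmd`) for the model, conventions
(count reconstruction, matching granularity, tie handling) and known
limitations.
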