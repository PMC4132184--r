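---
title: "Methods: interactome cohesiveness testing and RNAi screen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactome cohesiveness testing and RNAi screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesionScreen)
```

## The analysis problem

A tandem affinity purification mass spectrometry (TAP-MS) experiment
pulls down a tagged bait protein together with whatever co-purifies with
it. The raw identification list mixes genuine complex members with
irreproducible identifications and ubiquitous contaminants. Downstream of
the mass spectrometer, four questions remain:

1. Which identifications are high-confidence candidate interactors?
2. How do the candidates relate to each other in the known interactome,
   and which first-order neighbours plausibly belong to the same module?
3. Is the resulting network more densely self-connected than a random
   gene set of the same size *and the same degree profile* — i.e. is the
   cohesiveness real, or an artefact of having pulled down hubs?
4. When the candidates are knocked down one by one, which knockdowns
   reproduce the bait's loss-of-function phenotype?

`cohesionScreen` implements these four stages plus generators that
produce synthetic inputs with the statistical structure the stages
assume, so the whole pipeline is testable without any database download.

## Candidate filtering

`filterCandidates()` retains a protein if and only if it (i) appears in
at least `minReplicates` distinct bait replicates (default 2, the
standard two-biological-replicate design), (ii) never appears in a
negative-control purification, and (iii) is in no user-supplied
contaminant blocklist (typical lists: heat-shock proteins induced by a
heat-shock-driven bait construct, and organellar — e.g. mitochondrial —
proteins). The audit trail records the first failing rule in the fixed
order replicate → control → blocklist.

Two conventions are worth making explicit because published filter
descriptions usually leave them open. First, "found in the negative
control" is read as *any* appearance, not a ratio test — the strictest
reading, and the one that needs no abundance model. Second,
unique-peptide counts are carried through for reporting but are never a
filter criterion. Blocklists are explicit input files rather than
built-in annotation lookups: contaminant categories are not enumerable
in general, so reproducing any particular published candidate list
requires the user to supply the same lists its authors used. This is a
documented limitation, not an oversight.

## Network assembly and parsimony expansion

`buildSeedGraph()` takes the induced subgraph of a reference interactome
on the candidate (seed) set. `expandParsimony()` then admits every
non-seed node with at least `minLinks` (default 2) interactions *with
seed nodes*, in a single pass: qualification is always measured against
the original seed set, never against previously added nodes, so adding a
node can never qualify another. The induced subgraph on seeds plus added
nodes does include added–added edges; they simply never count toward the
threshold. This matches the usual statement of the rule — neighbours
"connected to two or more" of the candidate interactors — and keeps the
expansion order-independent and idempotent. Published edge tallies for
such expansions are ambiguous about whether they count only edges
touching added nodes or all newly induced edges, so the node-role export
reports both tallies.

Seeds missing from the reference are dropped with a warning rather than
an error, because reference snapshots differ in identifier coverage; the
dropped ids are recorded on the result object.

## PIE: cohesiveness against a degree-matched null

The observed statistic is the number of reference edges induced by the
query node set. The null distribution is that count over `nRand`
(default 10,000) random node sets of the same size whose degree multiset
in the *full* reference matches the query's. Degree matching is the
crux: protein interaction networks are heavy-tailed, and an
unconstrained random set comparison would declare any collection of
well-studied hubs "cohesive". Two summaries are returned:

* the **PIE score** `observed / mean(null)` — 1 means chance-level
  cohesiveness given the degrees; and
* the **empirical p-value** `(1 + #{null >= observed}) / (1 + nRand)`,
  the add-one estimator. It can never be 0; with 10,000 draws its floor
  is 1/10,001, which is what a reported "P < 0.0001" corresponds to.
  Ties count as extreme (conservative).

Degenerate cases are defined rather than left to chance: on a complete
reference every degree-matched set induces the same count, so the score
is exactly 1 and p exactly 1; a query inducing zero edges has score 0;
and if the null mean is zero the score is flagged undefined (`NA`) while
the p-value remains valid.

### Matching granularity

Exact per-degree matching is the default. It requires every degree
represented in the query to have at least two candidate nodes in the
reference; when a degree class is thinner than that (unique hub
degrees), the sampler falls back to binned matching with a warning,
using bins 0, 1, 2, 3–4, 5–8, 9–16, 17+ — geometric above 2, because
degree distributions are roughly scale-free and proportional degree
error matters more than absolute. Published PIE-style analyses rarely
state their granularity; both policies are available and the one
actually used is recorded in the result object.

Sampling is without replacement within a draw (a node set, not a
multiset) and draws are independent. Under exact matching each
degree class contributes a uniform without-replacement sample, so no
rejection is ever needed and feasibility is checked up front; the
structural error message names the deficient degree bin.

## RNAi screen scoring

Phenotype screens report, per knockdown, counts (or percentages) of
animals in five outcome categories — here the gonad-arm categories
normal, extra turn, wandering, overshoot, other. Testing collapses these
to normal versus defective, exactly as screen figure legends state
("% of normal gonad arms"), and compares each treatment to the control
with a two-sided Fisher's exact test (the sum-of-no-more-probable-tables
convention, via `stats::fisher.test`). Tiers follow the common
figure-legend thresholds: p < 0.0005 (four stars) and p < 0.05 (one
star). No multiple-testing correction is applied to the tiers, matching
per-comparison reporting practice in such screens; a Benjamini–Hochberg
column is emitted alongside for modern use.

### Count reconstruction from printed percentages

Published tables print integer percentages plus the number of animals
`n`. `countsFromPercent()` reconstructs integer counts as
round-half-up(p/100 · n) and repairs any residual against `n` by
adjusting the categories with the largest fractional parts first (ties
broken in column order). The repair rule is this package's convention —
the true per-animal counts behind a printed table are not recoverable in
general — and the shipped screen table was checked to reconstruct with
zero residual on every row and to reproduce its printed percentages
exactly on the way back. For very small `n` (a few animals) the
percent→count→percent round trip is inherently lossy; at screen-typical
`n` (about 100) it is exact.

Knockdowns that arrest before the phenotype can be scored are
represented as unscored rows (`NA` totals); they are excluded from
testing and never counted as hits.

## Synthetic data: what it emulates, and what it does not

`makeReference()` produces either a uniform random simple graph
(`igraph::sample_gnm`) or an exact realization of a degree sequence via
configuration-model stub pairing with rejection of self-loops and
multi-edges (Erdős–Gallai feasibility is checked first). The default
desk scale — 2,000 nodes, 2,800 edges — preserves the edge-to-node
sparsity of a genome-scale metazoan interactome (roughly 1.4 catalogued
interactions per protein-coding gene), so null induced-edge counts are
in a comparable regime at about a hundredth of the node count.

`plantCohesiveModule()` makes a chosen member set cohesive by repeated
double-edge swaps `(a,x),(b,y) → (a,b),(x,y)` with `a,b` members and
`x,y` outsiders, each moving one edge inside the module, until the
induced count reaches `multiplier ×` its initial value or no legal swap
remains. Swaps — not edge additions — are essential: adding edges would
raise member degrees and contaminate the very degree-matched null the
test relies on. The degree multiset is preserved exactly, which the test
suite asserts per seed. The target can be unreachable when the members'
combined degree budget runs out; the generator then stops at the
feasible maximum, and a test verifies by independent scan that no legal
swap was left behind.

Module members are selected by `selectModuleMembers()` as a snowball
(breadth-like) sample from a degree-biased start. This is a deliberate
design choice: real functional modules — protein complexes such as a
spliceosome core — are connected, hub-enriched subgraphs of the
interactome, not uniform random gene sets. In a 2,000-node/2,800-edge
graph a uniform random 27-node set induces about half an edge in
expectation, which no degree-preserving densification can turn into a
testable signal; a snowball module starts with a connected skeleton, and
the multiplier then controls how much denser than its skeleton it
becomes. Consequently the planted-module recovery test exercises
detection of a realistically structured module, and says nothing about
power against diffuse, disconnected enrichment — a documented limit of
the emulation. Other features of real data the generators do not
emulate: evidence heterogeneity (all synthetic edges are one class),
abundance-dependent MS detection (detection is Bernoulli per protein),
and inter-animal correlation in phenotype scoring (counts are
multinomial).

`makeTapmsTables()` emulates the replicate/control design: true
interactors appear in each bait replicate with probability `pTrue`
(default 0.9) and never in the control; background proteins appear in
any run independently with probability `pBg` (default 0.05). Under the
default two-replicate design the expected truth recovery of the filter
is `pTrue²` = 0.81, which the suite checks against simulation.
`makeScreen()` draws multinomial outcome counts; its defaults are the
regime of a distal-tip-cell migration screen — a 20-treatment screen
with 9 true hits, about 100 gonad arms scored per treatment, a control
at 99% normal, and hits with a severe overshoot-dominated defect
spectrum (25/13/11/46/5%).

## Numerical and testing choices

Problem sizes used by the test suite and the acceptance script were
chosen to keep the whole analysis on a laptop-class single core:
exhaustive-enumeration cross-checks of the PIE null run on 12-node
references (where *all* degree-matched sets can be enumerated);
planted-module recovery uses 100 generator seeds at desk scale with
10,000 permutation draws each; screen calibration uses 200 simulated
screens of 20 treatments; the Fisher implementation is checked against a
full hypergeometric enumeration on every 2×2 table with total up to 40.
Monte-Carlo agreement is always asserted within three Monte-Carlo
standard errors rather than at fixed constants.

Reproducibility: every stochastic function takes an integer `seed`;
`runPipeline()` derives per-stage seeds from one master seed by fixed
offsets, so any stage can be reproduced in isolation and a rerun is
byte-identical. Randomness uses R's global RNG (Mersenne–Twister);
results are bit-reproducible for a given R version.

## Known limitations

* Reproducing any published candidate list requires the original
  blocklists and reference interactome snapshot; with other inputs the
  pipeline reproduces the procedure, not the numbers. Quantities that
  depend on a specific curated interactome (a particular expansion's
  node/edge count, a particular PIE score) are therefore
  database-dependent and are covered here by synthetic analogues.
* The PIE null conditions on degree only; it does not preserve higher-
  order structure (clustering, community sizes). This is the standard
  formulation, and the right null for the hub-bias question, but a set
  embedded in one large community can still score above 1.
* Analytical nulls (e.g. Chung–Lu expected edge counts) are deliberately
  out of scope; the permutation formulation is the method.
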