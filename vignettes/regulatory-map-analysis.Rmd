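---
title: "Analysing curated transcriptional regulatory maps with regnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing curated transcriptional regulatory maps with regnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnet)
```

## The data model

A curated regulatory map is a directed graph whose edges are individually
evidenced TF → target regulations, signed as activation or repression.
`reg_network()` holds it as two tibbles — genes (`id`, `symbol`, `is_tf`,
`family`) and edges (`regulator`, `target`, `mode`, evidence and assay set
columns) — because every downstream analysis consumes or produces tables.
Duplicate curation records for the same ordered pair are merged: evidence
is unioned and conflicting modes promote to `dual` (an `unknown` record
yields to an informative one). We treat regulations as unique ordered
pairs rather than as a multigraph because the analyses below count pairs,
not records. TFs are recognised from the regulator role unless an explicit
TF list accompanies the data; curated maps usually ship one, and it
matters because a TF that only ever appears as a target would otherwise be
misclassified.

Companion containers follow the same pattern: `process_annotation()` for
gene → biological-process (BP) term sets plus a term → high-level class
map (development / stress_response / other), `binding_matrix()` for 4×W
position probability matrices with optional counts (counts convert via
`(c + pseudocount)/(total + 4·pseudocount)`), and `presence_matrix()` for
family × species presence profiles with clade labels and a divergence-order
rank per species.

## Map quality

The quality score is the proportion of regulations whose two endpoints
share at least one BP term. Two choices deserve justification:

* *Sharing means sharing an annotated term at the granularity supplied.*
  Ontology ancestor propagation is deliberately out of scope; callers
  control granularity through the annotation file (a slim works well).
* *Pairs with an unannotated endpoint leave the denominator.* Absent
  annotation is missing data, not evidence that the two genes act in
  different processes. Counting such pairs as failures would punish maps
  that include less-studied genes.

Against a comparison network summarised as `(k, n)` co-annotated/eligible
pairs, the score is tested with a one-tailed exact binomial test using the
comparison proportion as the fixed null — the simplest model that treats
the comparison network as a reference rather than a second sample.

Reference-pathway recall (`pathway_recall()`) matches edges
direction-sensitively but mode-insensitively, because published pathway
summaries encode signs inconsistently.

## Subnetwork topology and subsampling

`classify_genes()` calls a gene developmental if it has at least one
development-class term and no stress-class term ("unambiguous"), and
symmetrically for stress; genes with both kinds are `both` and excluded
from either subnetwork. `extract_subnetwork()` induces on the gene set.

`topology_summary()` reports four quantities with these conventions:

* targets per TF and regulators per target are means over nodes with
  non-zero out-/in-degree — they are "per active node" averages, which
  keeps them comparable when subsampling shrinks the active sets;
* characteristic path length is the mean directed shortest-path length
  over ordered pairs with a finite path, self-pairs excluded; unreachable
  pairs are dropped rather than imputed (the igraph convention);
* the clustering coefficient is the global transitivity (3 × closed
  triplets / connected triplets) of the undirected simple projection. A
  local-average or directed variant would also have been defensible; the
  global undirected form is the documented choice and is what the
  subsampling analysis perturbs.

`subsample_robustness()` keeps `round(f·|E|)` edges uniformly at random
(nodes retained), recomputes the four metrics, and reports per-fraction
means and standard deviations. Defaults — fractions 0.5–0.9 and 1,000
replicates — suit curated-map scale, and everything is deterministic
given the seed.

## Motif census and enrichment

There are exactly 13 weakly connected 3-node digraph classes. Each class
is identified by a canonical 6-bit code: the off-diagonal entries of the
3×3 adjacency in row-major order, minimised over the six node
permutations; class ids 1–13 follow ascending canonical code. Display
names are attached where a standard name exists (fan-out, fan-in, cascade,
feed-forward loop, three-node cycle, fully mutual). Published motif
figures typically number subgraphs by the Mfinder dictionary; only the
feed-forward loop can be pinned to that numbering from structure alone, so
`motif_id_map()` ships the remaining entries as explicit `NA` placeholders
and every function that needs "novel" or "ancient" motif classes takes the
class-id sets as arguments.

The census (`triad_census()`, compiled) enumerates connected triples by
expanding the neighbourhoods of adjacent node pairs rather than scanning
all C(n,3) triples, counts every connected triple exactly once, ignores
self-loops for typing, and ignores modes (the analysis is unsigned). The
null model (`randomize_network()`, compiled) is the standard
degree-preserving double edge switch: `swaps_per_edge × |E|` attempted
swaps, rejecting self-loops and duplicates, preserving every node's in-
and out-degree exactly (asserted on every call). Defaults — 100 swaps per
edge, 1,000 null networks — are the conventional Mfinder-style regime.

Enrichment uses `z = (obs − mean)/sd` with the conventions `z = 0` when
`sd = 0 ∧ obs = mean` and `z = ∞` when `sd = 0 ∧ obs > mean`, and the
plus-one–corrected empirical p `(1 + #{null ≥ obs})/(1 + n_random)`, which
cannot return 0. A motif must satisfy `p ≤ 0.01`, `z ≥ 2` and `obs ≥ 4`.

## Communities

`mcl()` implements Markov clustering directly: symmetrize, add unit
self-loops, column-normalize, then alternate expansion (matrix power,
default 2) and inflation (entrywise power, default 2.0, then
renormalize), pruning entries below 1e-5, until the largest entry change
falls below 1e-6 or 200 iterations. Clusters are the connected components
of the limit matrix's non-zero pattern; the procedure is deterministic and
invariant to edge order. `label_communities()` labels communities of ≥ 5
members with their most frequent specific term among annotated members
(ties break lexicographically for determinism) and calls the community
"corresponding to a specific process" when that term covers ≥ 50 % of
annotated members — the coverage threshold is an exposed parameter because
the original call was a manual judgement.

## Statistics

All five tests used by the analyses are implemented exactly at desk scale,
with the one-tailed direction always stated by the caller:

* exact binomial tail sums;
* one-tailed Fisher's exact test as the hypergeometric tail on the (1,1)
  cell with fixed margins (and `hypergeom_enrichment()` as the matching
  upper tail, used by `go_enrichment()` with optional Benjamini–Hochberg
  adjustment);
* Wilcoxon rank-sum: the exact Mann–Whitney null for pooled n ≤ 20 without
  ties; an exact permutation distribution conditional on the observed
  values for pooled n ≤ 12 with ties; otherwise the normal approximation
  with tie and continuity corrections. The `method` field records the path;
* Spearman's ρ on average ranks, with an exact permutation p for n ≤ 8
  without ties and the t approximation otherwise.

Tests return a small `reg_test` record with a `tidy()` method; no multiple
testing correction happens inside the tests themselves.

## Family dating and wiring preference

Dating is Dollo-style: a family emerged in the earliest-diverging lineage
containing any member. Presence in any green alga makes a family
*ancient*; absence from algae with an earliest occurrence no later than
`novel_max_rank` makes it *novel* (emerged around terrestrialization);
later first occurrences are *recent_other* and sit out of the
ancient/novel contrasts. The default `novel_max_rank` is the rank of the
most basal land plant in the profile — a family that appears only in a
single late-diverging flowering plant is recent, not novel.

The wiring battery scores each classified TF on three aspects — fraction
of targets that are TFs, membership count in the designated novel motif
classes, and in the ancient classes — dichotomizes each score at its mean
("more than average" vs not, with values equal to the mean on the lower
side), and runs one-tailed Fisher tests on the 2×2 epoch-by-side tables.
The mean rather than the median is used because the dichotomy is defined
as "fewer/more than the average value". Aspects whose scores are all
identical are reported as `NA` with a warning instead of failing the whole
battery. The member-level process test excludes `both`-annotated TFs for
symmetry with the unambiguous-subnetwork rule; the family-level test
compares per-family developmental fractions by rank-sum.

Binding specificity is information content in bits under a uniform
background, log base 2, no small-sample correction (none is standard for
this use); multiple matrices for one TF average. The IC–wiring link is the
Spearman correlation between per-TF IC and the per-TF fraction of targets
that are TFs, over TFs with a matrix and at least one target; it is
computed per TF, unbinned.

## Kinetics

Circuits of up to three regulatory nodes (plus an optional external
signal) follow Hill kinetics with multiplicative (AND) input integration:

$$\frac{dx_i}{dt} = b_i + \beta_i \prod_{j \in \mathrm{act}(i)}
\frac{x_j^n}{K^n + x_j^n} \prod_{j \in \mathrm{rep}(i)}
\frac{K^n}{K^n + x_j^n} - \alpha_i x_i,$$

with a node lacking inputs reducing to `b − αx`. K and n are shared per
model by default, and every parameter is exposed; the default set (β = 4,
α = 1, K = 1, n = 2, b = 0.01) places the mutual-repression toggle switch
in its textbook bistable regime, which is the benchmark all stability
machinery is validated against. Integration is adaptive Runge–Kutta 4(5)
(deSolve's `ode45`), and a run is steady when max |dx/dt| < 1e-6 at the
horizon.

`find_stable_states()` integrates from a regular grid (default 6 points
per axis up to x_max = 5) and merges terminal states within a Euclidean
tolerance of 0.05. One numerical subtlety: symmetric grid starts can ride
a separatrix straight into a saddle point, which then looks steady. Each
candidate state is therefore verified by perturbing it slightly in both
directions along an alternating-sign vector and checking that the flow
returns; saddles fail and are discarded. `pulse_transition()` applies a
constant input — extra production on a regulatory node, or a level on the
external signal node — for a fixed duration, relaxes, and reports whether
the system settled into a different attractor. Zero-amplitude pulses never
switch; sufficiently strong and long pulses flip the toggle; too-short
pulses do not.

## Synthetic data: what it emulates and what it does not

The generators exist so that every analysis can be exercised against
inputs with known, planted truth:

* `gen_network()` — TFs are the only sources; Erdős–Rényi or power-law
  out-degree models. The `gen_atrm_like()` preset uses 388 TFs, 47
  families and 400 non-TF targets with ~1,400 power-law-fan-out
  regulations — the scale of the curated *Arabidopsis* map; the edge count
  is an order-of-magnitude artifact choice, not a published figure.
* `gen_annotations()` — one base term per gene from a pool of `n_terms`
  (background co-annotation ≈ 1/n_terms) plus, with probability
  `(q − q0)/(1 − q0)` per edge, a fresh term private to that edge. Private
  terms cannot leak sharing into other pairs, so the edge co-annotation
  rate is exactly q in expectation — earlier designs that copied existing
  terms across edges inflated the realized rate through hub accumulation.
* `gen_pwms()` — Dirichlet-distributed columns whose concentration is
  bisected on the closed-form expected column IC,
  `2 + (ψ(a+1) − ψ(4a+1))/ln 2` bits, so mean IC lands on target; the
  boundaries (0 and 2 bits per column) are constructed exactly.
* `gen_presence()` — ancient families occur in ≥1 alga, novel families
  start at the most basal land plant, recent families only in the
  latest-diverging species; planted epochs are recovered exactly by
  `date_families()`.
* `gen_ic_wired_network()` — P(target is a TF) = logistic(slope · (IC −
  mean IC)) plants the IC–wiring correlation.

What passing tests on these inputs shows is that the machinery measures
what it claims to measure when the signal is present by construction. It
does not show that real curated maps contain such signals, and the
generators deliberately omit several features of real data: curation
ascertainment bias (well-studied pathways are overrepresented), correlated
evidence across edges, ontology term hierarchy, sequence-level PWM
realism, and gene-family size structure.

## Problem sizes and numerical choices

The shipped tests run the subsampling analysis at 100 replicates on the
preset-scale network, motif enrichment with 200 null networks, and the
planted-motif detection study over 100 seeds — sizes chosen so the whole
suite completes in a couple of minutes while keeping every stochastic
assertion comfortably away from its threshold; the package defaults (1,000
replicates, 1,000 nulls) are the full-scale regime. Ties in rank-based
tests break as documented above; MCL pruning/convergence tolerances and
the stable-state merge tolerance are stated in their function signatures.

## Known limitations

* Triad analysis is unsigned and three-node only; signed/colored motif
  typing and four-node patterns are out of scope.
* The MCL inflation that best matches any particular dataset's community
  granularity must be chosen by the user; cluster counts are sensitive
  to it.
* Kinetic models are deterministic ODEs with shared K and n per model by
  default; stochastic dynamics and parameter fitting are out of scope.
* The mapping from internal triad classes to any published motif numbering
  beyond the feed-forward loop must be supplied by the user.
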