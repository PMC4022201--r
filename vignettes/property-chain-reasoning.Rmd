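---
title: "Property-chain reasoning over linked biological knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-chain reasoning over linked biological knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainreasoner)
library(dplyr)
```

## The problem

Biological knowledge is scattered across databases of herbs, diseases, drugs,
targets, proteins and genes. Integrated as RDF triples, these sources form a
linked knowledge graph in which interesting associations are *implicit*:
there is no direct herb-to-gene edge, but there is a path

```
Herb --treatment--> Disease --possibleDrug--> Drug --hasTarget--> Target
     --hasAccession--> Protein --classifiedWith--> EntrezID --symbol--> Gene
```

An OWL property-chain axiom states that the composition of these six object
properties entails a new property from Herb to Gene. Materializing that
entailment over a large instance graph is a chain of relational joins, and
`chainreasoner` implements it three ways on a deterministic local
map/shuffle/reduce engine, each verified against a brute-force path oracle.

## The formal model

A *reasoning rule chain* is an ordered list of class-level rules
(`Herb, treatment, Disease`), each contributing one primitive property. The
*property chain set* (PCS) is the ordered list of OWL property chains (OPCs)
still to be composed; the zero-based position of an OPC is its *PID*. An
instance triple inherits the PID of the OPC matching its predicate, or `-1`
when its predicate is in no chain — those triples are ignored. Two OPCs
compose with an associative concatenation operator; we serialize the
composition by joining component names with `"|"`, which is reversible
because primitive property names may not contain that character. A predicate
that occurs at several PCS positions (legal for chains like `p, q, p`)
receives one PID per position and the triple participates at each; this is a
conservative extension of the model, which assumes unique predicates, and
keeps the reasoners equivalent to the oracle.

The answer to a chain over graph `G` is the set of `(source, sink)` endpoint
pairs connected by at least one instance path whose edge labels spell the
chain, labelled with the fully composed OPC. Results are *sets*: two
converging intermediate paths yield one association.

## Three join schedules

**Naive.** Each pass joins only PID-0 triples (keyed on their object) with
PID-1 triples (keyed on their subject); derived triples take the merged
first-two OPC, PID >= 2 triples pass through unreduced, and the PCS merges
its first two entries. A length-`N` chain takes exactly `N - 1` passes
whatever the graph contains. Unjoined PID-0/1 triples are discarded at
reduce time: they are dead-end path fragments, and the PCS update would
render them PID `-1` next pass anyway.

**Parity rule.** The join key of a PID-`k` triple is `(k - 1, subject)` when
`k` is odd and `(k, object)` when `k` is even, so *every* adjacent position
pair joins in the same pass, the PCS halves (adjacent pairs merge; an
unpaired final OPC is carried over), and a length-`N` chain finishes in
`ceiling(log2 N)` passes. The unpaired-last-OPC passthrough is required for
odd-length PCSs to be correct: without it the lone tail OPC's triples would
be lost between passes. We recompute PIDs from the current PCS each pass
instead of mutating stored counters; predicates absent from the updated PCS
drop out automatically, which reproduces the "every later PID decreases"
bookkeeping with no mutable state.

**Multichain.** Several chains run through the same iterated jobs. Keys
carry the chain id, so reducers of different chains never mix, and a triple
whose predicate lies on a chain intersection (e.g. `treatment` shared by the
herb-to-gene and herb-to-ingredient chains) fans out to one keyed record per
matching chain. A chain that completes before the longest one parks its
result triples and contributes nothing to later passes — anything else would
corrupt the shorter chain's results. The shared pass count is
`ceiling(log2)` of the longest chain length. Chain definitions arrive as a
YAML config (id, source class, sink class, ordered properties); the
herb-to-ingredient chain defaults to
`{treatment, possibleDrug, hasIngredient}` in the shipped fixtures.

## The engine

`run_job()` emulates the distributed contract in one process: the map
function turns the input table into keyed records plus direct emissions
(`NA` key), records are grouped by exact key equality, keys are visited in
sorted order, and the reduce function fires once per key. Both output
channels are sorted by all columns, so the result is invariant under any
permutation of the input — determinism stands in for parallelism. Join keys
are `<chain> SOH <pid> SOH <resource>` (SOH = `\u0001`) with a control-character separator:
resource labels may themselves contain underscores, so a printable separator
could make distinct keys collide.

## The worked example

```{r worked}
fixture_g0()
res <- efficient_reason(fixture_g0(), herb_gene_chain())
res
res$trace
```

The first pass derives four composed triples (the two herb-to-drug pairs
plus drug-to-protein and protein-to-gene); the second pass carries the lone
`classifiedWith|symbol` triple through while joining the rest; the third
yields the two herb-to-gene associations. The naive schedule reaches the
same answer in five passes:

```{r naive}
glance(naive_reason(fixture_g0(), herb_gene_chain()))
```

## The synthetic generator

`generate_network()` builds layered graphs shaped like the herb-to-gene
backbone: `layer_sizes` entities per class, forward edges with a fixed
per-source out-degree (sampled without replacement, so many-to-one
convergence occurs and exercises deduplication; an `injective` switch gives
disjoint linear paths with closed-form ground-truth counts), and distractor
triples under reserved predicates (`crossRef`, `annotation`) pointing at
fresh `Aux_` nodes, which can never extend a chain path. Ground truth is
computed layer by layer during generation and is cross-checked against the
oracle in the tests. `distractor_fraction` is the share of the final graph
made of distractors. Defaults are seven layers of 20 entities, out-degree
2 and a 0.2 distractor fraction — a scale at which chain joins fan out and
converge visibly while any single run stays well under a second.
`scale_dataset()` replicates a dataset disjointly (fresh entity names,
rules unchanged): association counts scale exactly with the factor while
iteration counts, which depend only on chain length, do not.

What the generator does *not* emulate: real biological degree distributions
(hubs, scale-free tails), literal-valued annotations, inter-layer shortcuts
or noisy/contradictory assertions. Passing tests therefore demonstrate the
algorithms' set-level correctness and complexity laws, not robustness to the
statistical quirks of any particular curated source.

## Verification strategy

Every reasoner is checked against `brute_force_associations()`, a sequential
nested-loop join along the flattened primitive property sequence — the
direct realization of the solution-set definition, deliberately quadratic
per hop and independent of the engine. The oracle itself is checked against
a boolean adjacency-matrix product in the test suite, and oracle output is
invariant under re-bracketing of the chain because it flattens compositions
first. The oracle-equivalence tests sweep 200 seeded layered graphs with varying
layer counts, sizes, out-degrees and distractor fractions and require exact
set equality from all three reasoners; graph sizes there (2-6 entities per
layer, 3-7 layers) are chosen so the whole sweep stays fast while still
producing convergent, cyclic-free multi-path topologies.

## Numerical and degenerate-input choices

* Graphs have set semantics; duplicates collapse on construction and after
  every pass.
* A length-1 chain runs zero jobs: the associations are simply the triples
  bearing that predicate.
* An empty graph (or a chain with no instances) runs its full schedule of
  passes — iteration counts are structural, not data-dependent — and
  returns an empty association set.
* Literal objects (quoted strings) are carried through the triple model but
  never extend a path: joins match objects to *subjects*, and literals do
  not occur as subjects in well-formed RDF.
* Bare labels serialize to N-Triples as IRIs under a fixed `urn:bkg:`
  namespace and are stripped back on read, so in-memory comparisons use the
  readable label form.
* Precision demands `TP + FP >= 1`; speedup/sizeup demand strictly positive
  times. The speedup baseline is a *designated* configuration rather than
  literally one machine, matching how scalability is reported when a single
  node cannot hold the input.

## Limitations

Only property chains are modelled: no OWL-DL class expressions, inverse or
symmetric properties, subsumption, blank-node semantics or named graphs.
The engine is single-process — it reproduces the distributed algorithms'
semantics and iteration counts, not their wall-clock behaviour — and the
full-scale association catalogues reported for integrated multi-database
networks require those external sources, which this package does not ship.
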