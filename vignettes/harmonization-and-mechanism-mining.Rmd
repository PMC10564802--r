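---
title: "Identifier harmonization and network mechanism mining with proteoHarm"
author: "proteoHarm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifier harmonization and network mechanism mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoHarm)
```

# The problem

Published proteomics result lists are identifier chaos. One study reports
MaxQuant protein groups (several UniProt accessions per row, separated by
";", possibly decorated with `REV__` decoy and `CON__` contaminant flags);
another reports one representative accession per row (Proteome Discoverer
style); a third reports only gene symbols, in a different organism, under a
different database release. Intersecting such lists as published
systematically understates the agreement between studies: the same gene
hides behind an accession here, a synonym there, and a rodent-cased symbol
elsewhere. proteoHarm makes the lists comparable by mapping them step by
step into one namespace (one identifier type, canonical symbols, one
organism) and logging every identifier lost or gained, so the cost of each
step is auditable rather than silent.

# Data model

A study is a `StudyTable`: ordered rows, each carrying a protein-ID group
and/or a gene-name group, stable integer row ids, and all other input
columns preserved byte-identically. Two invariants are maintained by every
operation and asserted by the test suite:

* **Conservation.** Per row, the previous identifiers equal the kept plus
  the removed ones as multisets (`n_previous = n_kept + n_removed`), and
  added identifiers are disjoint from the previous ones.
* **Stability.** Surviving rows keep their row ids; extra columns are
  never touched.

Every identifier-changing function returns an overview log (per-row
previous/kept/removed/added) and a detail log (one record per affected
identifier with exactly one reason drawn from a closed vocabulary:
`wrong_organism`, `unreviewed`, `obsolete`, `contaminant`, `decoy`,
`no_gene_name`, `not_in_namespace`, `no_ortholog`).

All annotation knowledge (protein records, gene namespaces, ortholog
pairs) flows through an `AnnotationProvider` loaded from three flat TSV
snapshots. The original services behind these tables (UniProt, Ensembl,
HGNC, MyGene.info) are queried live by comparable web tools; we freeze
snapshots instead, trading freshness for reproducibility: the same inputs
give the same outputs on any machine, offline, forever. A live provider
could implement the identical lookup contract, but is deliberately outside
the default test surface.

# The harmonization steps

## Filtering of protein IDs

Three selectable modes: *organism-based* (drop members annotated to a
different organism than the study's), *reviewed-based* (drop members
without reviewed status), *decoy-based* (drop `REV__` decoys and `CON__`
contaminants). Checks run in a fixed precedence — decoy, contaminant,
obsolete/unknown, organism, reviewed — and the first failing check is the
single logged reason. The precedence is a design choice (downstream
reason-frequency plots need one reason per identifier); placing the flag
checks first means a contaminant that would also fail the organism check
is logged as a contaminant, which matches how such entries enter the data
in the first place. Accessions unknown to the snapshot are treated like
obsolete ones (a retired accession and an absent one are indistinguishable
in a snapshot) but carry `not found` metadata. The obsolete/unknown check
belongs to the record-based modes; decoy-only filtering never consults the
provider. Rows whose whole group is removed are dropped by default
(`keepEmpty = FALSE`), mirroring how one-accession-per-row tables lose
whole rows.

## Re-mapping to gene names

Five modes, all per protein group: `uniprot` (all annotated names listed
in HGNC), `uniprot_primary` (primary names only), `uniprot_one` (the
single most frequent primary name in the group), `fasta` (names from
`GN=` tokens in user-supplied UniProt-dialect FASTA headers), `all`
(FASTA first, UniProt primary names fill gaps). Ties in `uniprot_one` are
broken by group order, then lexicographically; frequency is counted over
primary names (counting synonyms would let heavily aliased genes outvote
the canonical annotation). Existing gene cells are overwritten by default
so all names stem from one snapshot version; `skipFilled = TRUE` preserves
them. Accessions yielding no name are logged `no_gene_name`; overwritten
old names are logged `not_in_namespace` with `superseded by remapping`
metadata, keeping the conservation invariant intact.

## Reduction of gene names

Synonym-laden cells are collapsed to one namespace: `ensembl` keeps names
with an Ensembl gene id and rewrites each to the Ensembl-listed symbol
(rewrites are logged as removal plus addition, with the replacement named
in the metadata); `hgnc` (human only), `mygeneinfo` and `enrichment` keep
names carrying the respective membership flag. Because Ensembl-listed
symbols are their own fixed points in the snapshot, Ensembl reduction is
idempotent — a property test, not an accident. Which annotation sources
count as "functional annotation" for the `enrichment` ground is delegated
to the snapshot's boolean column: the provider is the contract.

## Ortholog mapping

Symbols are translated between the supported organisms (human, rat,
mouse, rabbit — NCBI taxon ids accepted as aliases) in two steps: symbol
to Ensembl gene id, then ortholog pairs to the target organism.
One-to-many orthology keeps all partners (";"-joined); many-to-one
collisions deduplicate within a cell. A row survives if at least one
member has a partner — gene-level loss and row-level loss are therefore
different numbers, and both are visible in the logs. No transitive mapping
through a third organism is attempted, and the pair table is agnostic to
homology subtype (one2one vs one2many).

## Intersection analysis

Harmonized studies are flattened to gene sets (a gene present in several
rows of one study counts once) and rated by the number of studies they
occur in; the default threshold of two studies reflects the usual
meta-analysis reading of "shared". Matching is exact-string and
case-sensitive on purpose: pre-harmonization rodent and human spellings
*should* fail to intersect, and the curated fixture asserts exactly that
gap (and its closure after harmonization) as a strict inequality rather
than a fixed percentage, which would depend on fixture proportions.

# Network mechanism mining

Multi-study candidates become seeds on an undirected PPI graph with
drug-target edges attached (drug nodes never take part in PPI edges;
edge weights default to 1).

**Seed connectivity** is reported in both defensible readings — components
of the seed-induced subgraph, and seeds grouped by full-network
components — because "the seeds span a connected subnetwork" is ambiguous
between them; reporting both avoids a silent choice.

**Connector search** uses the shortest-path attachment heuristic
(Takahashi–Matsuyama): start at a seed, repeatedly attach the nearest
unconnected seed along a weighted shortest path, take the MST of the
collected nodes, prune non-seed leaves. On small instances the tree
weight is provably within twice the exhaustive Steiner optimum; the test
suite checks this on 200 sampled connected graphs with up to 9 nodes and
4 seeds against full enumeration. The multi-tree variant runs the
heuristic `nTrees` times (default 10), multiplying the weights of used
edges by `1 + delta` (delta = 0.05) after each iteration to diversify
routes, and returns the union; connectors are ranked by tree
participation, then degree, then name. An optional hub penalty
`hp` in [0, 1] inflates the weight of edge (u, v) by
`1 + hp * (deg(u) + deg(v)) / (2 * maxdeg)` to discourage routing through
promiscuous hubs. The only stochastic element is the per-iteration choice
of starting seed, controlled by an explicit RNG seed (default 42);
everything else is deterministic, with name-ordered tie-breaks.

**TrustRank** solves `s = (1 - d) p + d W^T s` with `p` uniform over the
seeds and `W` the column-normalized weighted adjacency of the combined
protein+drug graph (damping 0.85, L1 tolerance 1e-8, at most 1000
iterations). Mass arriving at isolated nodes is redistributed to the seed
distribution, the standard personalized-PageRank treatment, so scores sum
to one. The implementation is checked against the hand-solved two-state
stationary solution, against symmetry on fully seeded regular graphs, and
against an independent personalized-PageRank routine.

**Centralities** (degree, closeness, harmonic, betweenness) use standard
unnormalized definitions on the protein graph, validated against an
all-pairs brute-force oracle on random 12-node graphs; on disconnected
graphs closeness sums distances to reachable nodes only and harmonic
centrality counts unreachable pairs as zero contribution.

**Drug ranking**: candidates are drugs with at least one target in the
mechanism (seeds plus connectors). Under `trustrank` the drug node's own
propagated score is used; under a centrality method a drug scores the sum
of its mechanism targets' centralities. Ties break by target count, then
drug id. Non-approved drugs are excluded by default and included on
request.

# What the synthetic fixtures emulate — and what they do not

The random generator (`fixtureSpec()`, `generateProviderTables()`,
`sampleStudyTable()`, `generateNetworkFixture()`) emulates the *shapes*
that matter to the algorithms: MaxQuant-like group sizes (uniform 1–4),
a few percent each of obsolete, unreviewed, flagged and wrong-organism
members, ~6% of records without gene names, ~8% of genes without Ensembl
ids, ~10% of Ensembl symbols differing from the common symbol, ~93%
ortholog coverage into human, and a network whose two seed cliques are
joined only through one planted bridge. These proportions are fixed once
as defaults of the generator and give every removal reason and every code
path a realistic frequency; all outputs are byte-deterministic under a
seed, and a ground-truth manifest accompanies each snapshot.

Two planted properties are deliberate idealizations: the bridge is the
*only* inter-clique route (so connector recovery has an exact ground
truth), and the snapshot is perfectly self-consistent (every protein's
gene exists in the gene table). Real annotation is messier — isoform
accessions, retired-and-merged entries, many-to-many orthology tangles,
PPI networks with thousands of alternative paths — so passing tests
demonstrate correctness of the mechanics under controlled conditions, not
recall on any particular public database release. The curated four-study
fixture is hand-built, not sampled, so that the scenario's named
identifier behaviors hold verbatim at ~10–14 rows per study.

# Numerical and degenerate-input choices

* Empty ID cells parse to empty groups, never errors; `keepEmpty`
  decides their fate downstream.
* Duplicate identifiers within one group are preserved in the table
  (operations never *introduce* duplicates) but logged once per row in
  the detail log.
* Unparseable FASTA headers yield no accession and are skipped;
  duplicate accessions in a FASTA keep the first header.
* Tie-breaks everywhere are deterministic (group order, then
  lexicographic; participation, then degree, then name), so identical
  inputs give identical outputs including log order.
* The pipeline validates the whole stage plan against each study's
  column types before executing anything, so a misconfigured run fails
  fast instead of half-writing outputs.

# Problem sizes in the test suite

The suite runs at desk scale, chosen to finish in well under a minute
while still exercising every property: 1000 randomized rows for log
conservation, 500 rows for the ortholog row-survival oracle, 200 sampled
instances for the 2x Steiner bound, 50 random 12-node graphs for the
centrality oracles, and 100 seeded runs for planted-connector recovery
(the bridge construction makes recovery deterministic; the 95% acceptance
bar leaves room for future fixture variants with alternative routes).

# Known limitations

* Exact-string lookups only: no isoform (`P12345-2`) resolution, no
  fuzzy symbol matching, no alias-graph walking beyond the snapshot's
  synonym lists.
* No statistical significance for intersections or mined modules; the
  package ranks and reports, it does not test hypotheses.
* The dense-matrix TrustRank implementation targets networks up to a few
  thousand nodes; genome-scale interactomes would warrant a sparse
  backend.
* Snapshots age: results are reproducible per snapshot, not stable
  across database releases — that trade-off is the point of the provider
  design.
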