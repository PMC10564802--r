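# proteoHarm

Harmonization of multi-study protein and gene identifier lists, with
loss/gain logging, meta-study intersection analysis, and network-based
mechanism mining.

## The problem

Proteomics meta-analyses stumble at the identifier level before any
biology happens. One study publishes MaxQuant protein groups (several
UniProt accessions per row, `REV__` decoys and `CON__` contaminants
included), another single Proteome-Discoverer accessions, a third bare
gene symbols of a different organism. Intersected as published, such
lists barely overlap — not because the biology disagrees, but because the
same gene hides behind an accession here, a synonym there, and a
rodent-cased symbol elsewhere.

proteoHarm converts heterogeneous study lists into one shared namespace
and makes every conversion auditable:

1. **Filter protein IDs** — remove wrong-organism, unreviewed, obsolete,
   contaminant and decoy members of each protein group (modes
   selectable; fixed reason precedence decoy → contaminant → obsolete →
   organism → reviewed).
2. **Re-map to gene names** — five modes: all HGNC-listed names, primary
   names, the most frequent single name per group, FASTA-header `GN=`
   names, or FASTA-with-UniProt-gap-filling.
3. **Reduce gene names** — collapse synonyms onto one canonical
   namespace (Ensembl symbol rewrite, or HGNC / MyGene.info /
   functional-annotation membership).
4. **Map orthologs** — translate symbols between human, rat, mouse and
   rabbit through Ensembl gene ids (two-step: symbol → Ensembl id →
   ortholog pair); a row survives if at least one member has a partner.
5. **Intersect studies** — rate genes by the number of studies they
   occur in (gene × study membership matrix, UpSet-style combination
   counts).
6. **Mine mechanisms** — on a PPI network with drug-target edges:
   multi-Steiner-tree connector search (shortest-path attachment
   heuristic, iteration-wise edge reweighting by 1 + δ, δ = 0.05),
   TrustRank propagation `s = (1 − d)·p + d·Wᵀs` (d = 0.85, p uniform
   over seeds, W column-normalized adjacency), harmonic / closeness /
   degree / betweenness centralities, and drug ranking over the mined
   mechanism.

Every identifier-changing step returns an **overview log** (per row:
previous, kept, removed, added IDs and counts, with
`n_previous = n_kept + n_removed` guaranteed) and a **detail log** (per
affected identifier: exactly one reason plus metadata). All annotation
knowledge comes from a local three-table snapshot
(`proteins.tsv`, `genes.tsv`, `orthologs.tsv`) behind a provider
contract — no web services, fully reproducible offline.

## Worked example

The package ships a curated four-study micro-fixture (two human
protein-group studies, one rat single-ID study, one mouse gene-only
study) with a matching annotation snapshot:

```r
library(proteoHarm)
fx  <- generateUseCaseFixture()
res <- harmonizeUseCase(fx)   # filter -> remap -> reduce -> orthologs -> intersect
res$after
#> IntersectionResult: 12 gene(s) in >= 2 of 4 studies
#>        gene count                                           studies
#> 1     POSTN     4 study1_human;study2_human;study3_rat;study4_mouse
#> 2    COL1A1     3            study1_human;study2_human;study4_mouse
#> 3       DCN     2                         study2_human;study4_mouse
#> ...
res$log                       # the rat study's pipeline log
#> HarmonizationLog: 46 overview records, 8 detail records
#>   per step (kept / removed / added identifiers):
#>     filter       12 / 2 / 0
#>     remap        0 / 0 / 10
#>     reduce       8 / 2 / 2
#>     orthologs    8 / 2 / 8
```

Reading the numbers: filtering the rat study removes exactly its two
human accessions (`B4DQ80`, `B7Z722`) while keeping the rat entry
`Q63610`; re-mapping attaches ten primary gene names; Ensembl reduction
rewrites `Ppia → Ppial4d` and `Serpina3n → RGD1565462`; ortholog mapping
brings the surviving rat symbols into the human namespace. Before
harmonization 10 genes are shared by ≥ 2 studies and `POSTN` by only the
two human ones; afterwards 12 genes are shared and `POSTN` is found in
all four — the harmonization gain the pipeline exists for.

The network stage runs the same way on any edge lists:

```r
nf  <- generateNetworkFixture(fixtureSpec(seed = 1))
sol <- mustConnect(nf$network, nTrees = 10, rngSeed = 42)
connectors(sol)               # the planted bridge, participation 10/10
rankDrugs(nf$network, union(seeds(nf$network), connectors(sol)$node),
          method = "trustrank", topK = 20)
```

A thin CLI over the same functions lives at
`inst/scripts/proteoharm.R` (subcommands `run`, `filter`, `remap`,
`reduce`, `orthologs`, `intersect`, `fixtures`, `connect`, `drugs`;
exit codes 0/2/3), and `runPipeline()` executes a whole JSON-configured
run with per-stage logs and a checksummed manifest.

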