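## Shared fixtures (memoized per test run) and independent oracles.

.fixtureCache <- new.env(parent = emptyenv())

ucFixture <- function() {
    if (is.null(.fixtureCache$uc))
        .fixtureCache$uc <- generateUseCaseFixture()
    .fixtureCache$uc
}

randomWorld <- function(seed = 11L) {
    key <- paste0("world", seed)
    if (is.null(.fixtureCache[[key]])) {
        dir <- file.path(tempdir(), paste0("provider_seed", seed))
        .fixtureCache[[key]] <-
            generateProviderTables(fixtureSpec(seed = seed), dir)
    }
    .fixtureCache[[key]]
}

netFixture <- function(seed = 3L) {
    key <- paste0("net", seed)
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- generateNetworkFixture(
            fixtureSpec(seed = seed))
    .fixtureCache[[key]]
}

## ---- independent oracles -------------------------------------------------

## Exhaustive Steiner optimum: enumerate all subsets of non-terminals,
## keep those whose induced subgraph connects the terminals, and take the
## lightest spanning tree.  Only for tiny graphs.
bruteSteinerOptimum <- function(g, terminals) {
    vs <- igraph::V(g)$name
    others <- setdiff(vs, terminals)
    best <- Inf
    for (mask in 0:(2^length(others) - 1L)) {
        extra <- others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0]
        sub <- igraph::induced_subgraph(g, c(terminals, extra))
        if (!igraph::is_connected(sub)) next
        tw <- sum(igraph::E(igraph::mst(
            sub, weights = igraph::E(sub)$weight))$weight)
        ## MST of the induced node set upper-bounds its Steiner tree; the
        ## minimum over all node sets is the exact Steiner optimum.
        best <- min(best, tw)
    }
    best
}

## Random connected small weighted graph for the Steiner property test.
randomSteinerInstance <- function() {
    n <- sample(4:9, 1L)
    repeat {
        g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.7))
        if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- paste0("v", seq_len(n))
    igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
    k <- sample(2:min(4L, n), 1L)
    list(graph = g, seeds = sample(igraph::V(g)$name, k))
}

## All-pairs brute-force centralities on a small unweighted graph:
## Floyd-Warshall distances plus shortest-path counts.
bruteCentralities <- function(g) {
    n <- igraph::vcount(g)
    vs <- igraph::V(g)$name
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    d <- matrix(Inf, n, n, dimnames = list(vs, vs))
    sigma <- matrix(0, n, n, dimnames = list(vs, vs))
    diag(d) <- 0
    diag(sigma) <- 1
    d[A] <- 1
    sigma[A] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
        nd <- d[i, k] + d[k, j]
        if (nd < d[i, j]) {
            d[i, j] <- nd
            sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (nd == d[i, j] && is.finite(nd) && k != i && k != j) {
            sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
    }
    degree <- rowSums(A)
    closeness <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        di <- di[is.finite(di)]
        if (!length(di) || sum(di) == 0) 0 else 1 / sum(di)
    }, numeric(1))
    harmonic <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        sum(1 / di[is.finite(di) & di > 0])
    }, numeric(1))
    betweenness <- numeric(n)
    for (v in seq_len(n)) {
        tot <- 0
        for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
            if (s == v || t == v || !is.finite(d[s, t])) next
            if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0)
                tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
        betweenness[v] <- tot
    }
    list(degree = stats::setNames(degree, vs),
         closeness = stats::setNames(closeness, vs),
         harmonic = stats::setNames(harmonic, vs),
         betweenness = stats::setNames(betweenness, vs))
}

## Direct row-survival oracle for ortholog mapping: scans the provider's
## raw tables without going through lookupOrthologs.
rowSurvivesOracle <- function(cell, genesDf, orthDf, src, tgt) {
    any(vapply(cell, function(s) {
        i <- which(genesDf$symbol == s & genesDf$organism == src)
        if (!length(i)) return(FALSE)
        eid <- genesDf$ensembl_id[i[1]]
        if (!nzchar(eid)) return(FALSE)
        any(orthDf$source_ensembl_id == eid &
            orthDf$source_organism == src &
            orthDf$target_organism == tgt)
    }, logical(1)))
}

## Tiny provider built in code for focused remapping tests.
miniProvider <- function(proteins, genes = NULL, orthologs = NULL) {
    emptyGenes <- data.frame(symbol = character(), organism = character(),
        ensembl_id = character(), ensembl_symbol = character(),
        in_hgnc = logical(), in_mygene = logical(),
        has_annotation = logical(), stringsAsFactors = FALSE)
    emptyOrth <- data.frame(source_ensembl_id = character(),
        source_organism = character(), target_organism = character(),
        target_ensembl_id = character(), target_symbol = character(),
        stringsAsFactors = FALSE)
    new("AnnotationProvider", proteins = proteins,
        genes = if (is.null(genes)) emptyGenes else genes,
        orthologs = if (is.null(orthologs)) emptyOrth else orthologs)
}

protRow <- function(acc, org = "human", reviewed = TRUE,
                    obsolete = FALSE, primary = "", synonyms = "") {
    data.frame(accession = acc, organism = org, reviewed = reviewed,
               obsolete = obsolete, primary_gene_name = primary,
               synonyms = synonyms, stringsAsFactors = FALSE)
}

geneRow <- function(sym, org = "human", eid = "", esym = "",
                    hgnc = TRUE, mygene = TRUE, annot = TRUE) {
    data.frame(symbol = sym, organism = org, ensembl_id = eid,
               ensembl_symbol = esym, in_hgnc = hgnc, in_mygene = mygene,
               has_annotation = annot, stringsAsFactors = FALSE)
}

## Conservation checks shared by several suites.
expectLogInvariants <- function(res) {
    ov <- res$overview
    expect_true(all(ov$n_previous == ov$n_kept + ov$n_removed))
    for (i in seq_len(nrow(ov))) {
        prev <- sort(strsplit(ov$previous_ids[i], ";")[[1]])
        keptrem <- sort(c(strsplit(ov$kept_ids[i], ";")[[1]],
                          strsplit(ov$removed_ids[i], ";")[[1]]))
        expect_identical(prev, keptrem)
        added <- strsplit(ov$added_ids[i], ";")[[1]]
        expect_length(intersect(added, prev), 0L)
    }
    ## every removed identifier has at least one detail record
    removedAll <- unlist(strsplit(ov$removed_ids[ov$n_removed > 0], ";"))
    expect_true(all(removedAll %in% res$detail$identifier))
    expect_true(all(res$detail$reason %in%
        c("wrong_organism", "unreviewed", "obsolete", "contaminant",
          "decoy", "no_gene_name", "not_in_namespace", "no_ortholog")))
}
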