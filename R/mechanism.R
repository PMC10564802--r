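## mechanism_mining: seed mapping, multi-Steiner connector search,
## TrustRank/centrality scoring and drug ranking on a PPI network with
## attached drug nodes.  igraph backs all graph primitives; the Steiner
## attachment heuristic, the multi-tree diversification and the TrustRank
## propagation are implemented here.

#' Construct a MechanismNetwork
#'
#' @param ppiEdges data.frame with columns \code{node_a}, \code{node_b}
#'   and optional \code{weight} (default 1), or an undirected igraph.
#'   Self-loops and duplicate edges are removed (keeping the smallest
#'   weight).
#' @param drugTargets optional data.frame with columns \code{drug},
#'   \code{protein} and optional \code{approved} (0/1 or logical, default
#'   approved).  Target edges pointing outside the PPI vertex set are
#'   dropped with a warning.
#' @param seeds character vector of seed symbols; members absent from the
#'   network are kept in the unmapped-seeds slot, never silently dropped.
#' @return a \linkS4class{MechanismNetwork}.
#' @export
mechanismNetwork <- function(ppiEdges, drugTargets = NULL,
                             seeds = character()) {
    if (igraph::is_igraph(ppiEdges)) {
        g <- ppiEdges
        if (igraph::is_directed(g))
            g <- igraph::as_undirected(g, mode = "collapse")
    } else {
        stopifnot(all(c("node_a", "node_b") %in% names(ppiEdges)))
        w <- if ("weight" %in% names(ppiEdges))
            as.numeric(ppiEdges$weight) else rep(1, nrow(ppiEdges))
        g <- igraph::graph_from_data_frame(
            data.frame(from = as.character(ppiEdges$node_a),
                       to = as.character(ppiEdges$node_b),
                       weight = w, stringsAsFactors = FALSE),
            directed = FALSE)
    }
    if (is.null(igraph::V(g)$name))
        igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (is.null(igraph::E(g)$weight))
        igraph::E(g)$weight <- 1
    if (any(igraph::E(g)$weight < 0))
        stop("edge weights must be nonnegative", call. = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(weight = "min"))
    if (is.null(drugTargets)) {
        dt <- data.frame(drug = character(), protein = character(),
                         approved = logical(), stringsAsFactors = FALSE)
    } else {
        stopifnot(all(c("drug", "protein") %in% names(drugTargets)))
        appr <- if ("approved" %in% names(drugTargets))
            drugTargets$approved %in% c(TRUE, "1", "TRUE", 1)
        else rep(TRUE, nrow(drugTargets))
        dt <- data.frame(drug = as.character(drugTargets$drug),
                         protein = as.character(drugTargets$protein),
                         approved = appr, stringsAsFactors = FALSE)
        known <- dt$protein %in% igraph::V(g)$name
        if (any(!known)) {
            warning(sum(!known), " drug-target edge(s) point outside the ",
                    "PPI network and were dropped")
            dt <- dt[known, , drop = FALSE]
        }
        dt <- dt[!duplicated(dt[c("drug", "protein")]), , drop = FALSE]
        rownames(dt) <- NULL
    }
    seeds <- unique(as.character(seeds))
    mapped <- seeds[seeds %in% igraph::V(g)$name]
    new("MechanismNetwork", ppi = g, drugTargets = dt, seeds = mapped,
        unmappedSeeds = setdiff(seeds, mapped))
}

#' Read a MechanismNetwork from TSV edge lists
#'
#' @param ppiPath TSV with header columns \code{node_a}, \code{node_b}
#'   and optional \code{weight}.
#' @param drugPath optional TSV with header columns \code{drug},
#'   \code{protein} and optional \code{approved} (0/1).
#' @param seedPath optional newline-delimited seed file.
#' @return a \linkS4class{MechanismNetwork}.
#' @export
readMechanismNetwork <- function(ppiPath, drugPath = NULL,
                                 seedPath = NULL) {
    ppi <- utils::read.table(ppiPath, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             stringsAsFactors = FALSE)
    drugs <- if (!is.null(drugPath))
        utils::read.table(drugPath, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE) else NULL
    seeds <- if (!is.null(seedPath)) {
        s <- readLines(seedPath)
        trimws(s[nzchar(trimws(s))])
    } else character()
    mechanismNetwork(ppi, drugs, seeds)
}

#' @rdname MechanismNetwork-class
#' @export
setMethod("seeds", "MechanismNetwork", function(x) x@seeds)

#' @rdname MechanismNetwork-class
#' @export
setMethod("ppiGraph", "MechanismNetwork", function(x) x@ppi)

#' @rdname MechanismNetwork-class
#' @export
setMethod("drugTargets", "MechanismNetwork", function(x) x@drugTargets)

setMethod("show", "MechanismNetwork", function(object) {
    g <- object@ppi
    cat("MechanismNetwork:", igraph::vcount(g), "proteins,",
        igraph::ecount(g), "PPI edges,",
        length(unique(object@drugTargets$drug)), "drugs,",
        length(object@seeds), "mapped seed(s)")
    if (length(object@unmappedSeeds))
        cat(" (", length(object@unmappedSeeds), " unmapped)", sep = "")
    cat("\n")
})

#' Map seed symbols onto the network and report their connectivity
#'
#' Reports which requested seeds exist in the PPI network and how connected
#' they are, in two readings: the connected components of the seed-induced
#' subgraph (seeds adjacent to each other directly), and the grouping of
#' seeds by the components of the full network (seeds connectable through
#' non-seed proteins).  Both are reported because "spanning a connected
#' subnetwork" is ambiguous between them.
#'
#' @param network a \linkS4class{MechanismNetwork}.
#' @param seedSymbols character vector of requested seeds; defaults to the
#'   network's stored seeds.
#' @return list with \code{mapped}, \code{unmapped},
#'   \code{inducedComponentSizes} (decreasing), \code{largestInduced},
#'   \code{linkedComponentSizes} (seed counts per full-network component,
#'   decreasing) and \code{largestLinked}.
#' @export
mapSeeds <- function(network, seedSymbols = seeds(network)) {
    stopifnot(is(network, "MechanismNetwork"))
    g <- network@ppi
    seedSymbols <- unique(as.character(seedSymbols))
    mapped <- seedSymbols[seedSymbols %in% igraph::V(g)$name]
    unmapped <- setdiff(seedSymbols, mapped)
    if (length(mapped)) {
        sub <- igraph::induced_subgraph(g, mapped)
        indSizes <- sort(igraph::components(sub)$csize, decreasing = TRUE)
        comp <- igraph::components(g)$membership[mapped]
        linkSizes <- sort(as.integer(table(comp)), decreasing = TRUE)
    } else {
        indSizes <- linkSizes <- integer()
    }
    indSizes <- as.integer(indSizes)
    list(mapped = mapped, unmapped = unmapped,
         inducedComponentSizes = indSizes,
         largestInduced = if (length(indSizes)) indSizes[1L] else 0L,
         linkedComponentSizes = linkSizes,
         largestLinked = if (length(linkSizes)) linkSizes[1L] else 0L)
}

## Takahashi-Matsuyama attachment heuristic on one component.
## Returns list(nodes, edges (2-col matrix), weight).
.steinerOneComponent <- function(g, seeds, weights, start) {
    vs <- igraph::V(g)$name
    treeNodes <- start
    remaining <- setdiff(seeds, start)
    while (length(remaining)) {
        d <- igraph::distances(g, v = remaining, to = treeNodes,
                               weights = weights)
        ## nearest unconnected seed; deterministic tie-break by name order
        ij <- which(d == min(d), arr.ind = TRUE)
        ord <- order(remaining[ij[, 1L]], treeNodes[ij[, 2L]])
        pick <- ij[ord[1L], , drop = TRUE]
        from <- remaining[pick[1L]]
        to <- treeNodes[pick[2L]]
        sp <- igraph::shortest_paths(g, from = from, to = to,
                                     weights = weights, output = "vpath")
        pathNodes <- names(sp$vpath[[1L]])
        treeNodes <- union(treeNodes, pathNodes)
        remaining <- setdiff(remaining, from)
    }
    ## MST of the induced subgraph, then prune non-seed leaves
    sub <- igraph::induced_subgraph(g, treeNodes)
    subW <- igraph::E(sub)$weight
    tree <- igraph::mst(sub, weights = subW)
    repeat {
        deg <- igraph::degree(tree)
        drop <- names(deg)[deg <= 1L & !names(deg) %in% seeds]
        if (!length(drop)) break
        tree <- igraph::delete_vertices(tree, drop)
    }
    em <- igraph::as_edgelist(tree)
    list(nodes = igraph::V(tree)$name, edges = em,
         weight = sum(igraph::E(tree)$weight))
}

#' Approximate Steiner tree over the seed set
#'
#' Shortest-path attachment heuristic: starting from one seed, repeatedly
#' joins the nearest not-yet-connected seed along a weighted shortest path,
#' then prunes non-seed leaves from the minimum spanning tree of the
#' collected nodes.  On metric instances the tree weight is within a factor
#' 2 of the optimal Steiner tree.  Seeds spread over several components
#' yield one tree per component, with a warning.
#'
#' @param network a \linkS4class{MechanismNetwork} (or an undirected
#'   igraph).
#' @param seedSet seed vertices to connect; defaults to the network seeds.
#' @param weights edge weights (distances); defaults to the graph's
#'   \code{weight} attribute.
#' @param start starting seed (defaults to the alphabetically first);
#'   varied by [mustConnect()] between iterations.
#' @return list with \code{nodes}, \code{edges} (two-column matrix),
#'   \code{weight} (total tree weight) and \code{connectors}
#'   (\code{nodes} minus seeds).
#' @export
steinerApprox <- function(network, seedSet = NULL, weights = NULL,
                          start = NULL) {
    g <- if (is(network, "MechanismNetwork")) network@ppi else network
    if (is.null(seedSet))
        seedSet <- if (is(network, "MechanismNetwork")) network@seeds
                   else stop("seedSet required", call. = FALSE)
    seedSet <- unique(as.character(seedSet))
    if (!length(seedSet))
        stop("no seeds to connect", call. = FALSE)
    if (!all(seedSet %in% igraph::V(g)$name))
        stop("seed(s) not in network: ",
             paste(setdiff(seedSet, igraph::V(g)$name), collapse = ", "),
             call. = FALSE)
    if (is.null(weights)) weights <- igraph::E(g)$weight
    memb <- igraph::components(g)$membership[seedSet]
    comps <- split(seedSet, memb)
    if (length(comps) > 1L)
        warning("seeds lie in ", length(comps), " components; returning ",
                "one tree per component")
    trees <- lapply(comps, function(cs) {
        st <- if (!is.null(start) && start %in% cs) start else sort(cs)[1L]
        .steinerOneComponent(g, cs, weights, st)
    })
    nodes <- unique(unlist(lapply(trees, `[[`, "nodes")))
    edges <- do.call(rbind, lapply(trees, `[[`, "edges"))
    list(nodes = nodes, edges = edges,
         weight = sum(vapply(trees, `[[`, numeric(1), "weight")),
         connectors = setdiff(nodes, seedSet))
}

#' Multi-Steiner-tree connector search
#'
#' Runs the attachment heuristic \code{nTrees} times; after each
#' iteration the weights of the used edges are multiplied by
#' \code{1 + delta} so that later iterations explore alternative routes.
#' The union of the trees is returned; non-seed nodes are the connector
#' candidates, ranked by how many trees they participate in (then by
#' network degree, then name).  A hub penalty can discourage routing
#' through high-degree proteins by inflating the weight of an edge
#' (u, v) to \code{w * (1 + hubPenalty * (deg(u) + deg(v)) / (2 *
#' maxdeg))}.
#'
#' @param network a \linkS4class{MechanismNetwork}.
#' @param seedSet seeds to connect (default: network seeds).
#' @param nTrees number of diversified iterations (>= 1; default 10).
#' @param hubPenalty hub-avoidance strength in [0, 1] (default 0).
#' @param delta edge-reweighting factor between iterations (default 0.05).
#' @param rngSeed integer seed controlling the per-iteration choice of the
#'   starting seed (default 42).
#' @return a \linkS4class{SteinerSolution}.
#' @export
mustConnect <- function(network, seedSet = seeds(network), nTrees = 10L,
                        hubPenalty = 0, delta = 0.05, rngSeed = 42L) {
    stopifnot(is(network, "MechanismNetwork"))
    nTrees <- as.integer(nTrees)
    if (is.na(nTrees) || nTrees < 1L)
        stop("nTrees must be a positive integer", call. = FALSE)
    if (hubPenalty < 0 || hubPenalty > 1)
        stop("hubPenalty must lie in [0, 1]", call. = FALSE)
    g <- network@ppi
    seedSet <- unique(as.character(seedSet))
    w <- igraph::E(g)$weight
    if (hubPenalty > 0) {
        deg <- igraph::degree(g)
        ends <- igraph::ends(g, igraph::E(g), names = TRUE)
        w <- w * (1 + hubPenalty *
                  (deg[ends[, 1L]] + deg[ends[, 2L]]) /
                  (2 * max(deg)))
        w <- as.numeric(w)
    }
    trees <- vector("list", nTrees)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(rngSeed))
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old,
                                  envir = globalenv())
    })
    for (t in seq_len(nTrees)) {
        start <- sample(sort(seedSet), 1L)
        tr <- suppressWarnings(
            steinerApprox(network, seedSet, weights = w, start = start))
        trees[[t]] <- tr
        if (nrow(tr$edges)) {
            eids <- igraph::get_edge_ids(g, t(tr$edges))
            w[eids] <- w[eids] * (1 + delta)
        }
    }
    nodes <- unique(unlist(lapply(trees, `[[`, "nodes")))
    conn <- setdiff(nodes, seedSet)
    part <- vapply(conn, function(v)
        sum(vapply(trees, function(tr) v %in% tr$nodes, logical(1))),
        integer(1))
    deg <- igraph::degree(g)[conn]
    df <- data.frame(node = conn, participation = as.integer(part),
                     degree = as.integer(deg), stringsAsFactors = FALSE)
    df <- df[order(-df$participation, -df$degree, df$node), , drop = FALSE]
    rownames(df) <- NULL
    new("SteinerSolution",
        trees = lapply(trees, `[[`, "edges"),
        nodes = nodes, connectors = df, seeds = seedSet)
}

#' @rdname SteinerSolution-class
#' @export
setMethod("connectors", "SteinerSolution",
          function(x) x@connectors)

setMethod("show", "SteinerSolution", function(object) {
    cat("SteinerSolution:", length(object@trees), "tree(s),",
        length(object@nodes), "nodes,", nrow(object@connectors),
        "connector(s) for", length(object@seeds), "seed(s)\n")
    if (nrow(object@connectors))
        print(utils::head(object@connectors, 10L))
})

## combined protein+drug graph (drug-target edges weight 1)
.combinedGraph <- function(network) {
    g <- network@ppi
    dt <- network@drugTargets
    if (nrow(dt)) {
        g <- igraph::add_vertices(g, length(unique(dt$drug)),
                                  name = unique(dt$drug))
        ends <- rbind(dt$drug, dt$protein)
        g <- igraph::add_edges(g, as.vector(ends), weight = 1)
    }
    g
}

#' TrustRank propagation from a seed set
#'
#' Damped score propagation over the combined protein--drug graph:
#' \deqn{s = (1 - d) p + d W^T s}
#' with \eqn{p} uniform over the seeds and \eqn{W} the column-normalized
#' (weighted) adjacency matrix.  Iteration stops when the L1 change drops
#' below \code{tol}; scores sum to ~1 over the nodes reachable from the
#' seeds.
#'
#' @param network a \linkS4class{MechanismNetwork}.
#' @param seedSet trusted nodes (nonempty; default: network seeds).
#' @param damping damping factor d (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return named numeric vector of scores over all protein and drug nodes.
#' @export
trustrank <- function(network, seedSet = seeds(network), damping = 0.85,
                      tol = 1e-8, maxIter = 1000L) {
    stopifnot(is(network, "MechanismNetwork"))
    seedSet <- unique(as.character(seedSet))
    if (!length(seedSet))
        stop("TrustRank requires a nonempty seed set", call. = FALSE)
    g <- .combinedGraph(network)
    vs <- igraph::V(g)$name
    if (!all(seedSet %in% vs))
        stop("seed(s) not in network: ",
             paste(setdiff(seedSet, vs), collapse = ", "), call. = FALSE)
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    colsum <- colSums(A)
    dangling <- colsum == 0
    nz <- !dangling
    A[, nz] <- sweep(A[, nz, drop = FALSE], 2L, colsum[nz], "/")
    A[, dangling] <- 0
    p <- numeric(length(vs))
    names(p) <- vs
    p[seedSet] <- 1 / length(seedSet)
    s <- p
    for (it in seq_len(maxIter)) {
        ## mass arriving at isolated (dangling) nodes flows back to the
        ## seed distribution, as in standard personalized PageRank
        s2 <- (1 - damping) * p +
            damping * (drop(A %*% s) + sum(s[dangling]) * p)
        if (sum(abs(s2 - s)) < tol) {
            s <- s2
            break
        }
        s <- s2
    }
    names(s) <- vs
    s
}

#' Node centralities on the protein interaction graph
#'
#' Standard unnormalized definitions on the undirected PPI graph; edge
#' weights are treated as distances for the path-based measures.  On
#' disconnected graphs, closeness sums distances to reachable nodes only
#' and harmonic centrality sums 1/d with 1/Inf = 0.
#'
#' @param network a \linkS4class{MechanismNetwork}.
#' @param measure one of \code{"degree"}, \code{"closeness"},
#'   \code{"harmonic"}, \code{"betweenness"}.
#' @return named numeric vector over protein nodes.
#' @export
centralities <- function(network, measure = c("degree", "closeness",
                                              "harmonic", "betweenness")) {
    stopifnot(is(network, "MechanismNetwork"))
    measure <- match.arg(measure)
    g <- network@ppi
    w <- igraph::E(g)$weight
    out <- switch(measure,
        degree = igraph::degree(g),
        closeness = {
            x <- igraph::closeness(g, weights = w, normalized = FALSE)
            x[is.nan(x) | is.na(x)] <- 0
            x
        },
        harmonic = igraph::harmonic_centrality(g, weights = w,
                                               normalized = FALSE),
        betweenness = igraph::betweenness(g, weights = w,
                                          normalized = FALSE))
    out[igraph::V(g)$name]
}

#' Rank drugs targeting a mined mechanism
#'
#' Candidate drugs are those with at least one target among the mechanism
#' nodes (typically seeds plus connectors).  Under \code{method =
#' "trustrank"} drugs are scored directly by TrustRank over the combined
#' protein--drug graph seeded on the mechanism; under a centrality method a
#' drug scores the sum of the centralities of its mechanism targets.  Ties
#' are broken by the number of mechanism targets, then by drug id.
#'
#' @param network a \linkS4class{MechanismNetwork}.
#' @param mechanismNodes protein nodes forming the mechanism.
#' @param method \code{"trustrank"} (default) or one of the centrality
#'   measures of [centralities()].
#' @param topK truncate the ranking (default all).
#' @param includeNonApproved also rank drugs not flagged approved
#'   (default FALSE).
#' @return data.frame with columns drug, score, n_targets, targets
#'   (";"-joined mechanism targets), approved; best drug first.
#' @export
rankDrugs <- function(network, mechanismNodes,
                      method = c("trustrank", "harmonic", "closeness",
                                 "degree", "betweenness"),
                      topK = Inf, includeNonApproved = FALSE) {
    stopifnot(is(network, "MechanismNetwork"))
    method <- match.arg(method)
    mech <- unique(as.character(mechanismNodes))
    empty <- data.frame(drug = character(), score = numeric(),
                        n_targets = integer(), targets = character(),
                        approved = logical(), stringsAsFactors = FALSE)
    if (!length(mech))
        return(empty)
    if (!all(mech %in% igraph::V(network@ppi)$name))
        stop("mechanism node(s) not in network: ",
             paste(setdiff(mech, igraph::V(network@ppi)$name),
                   collapse = ", "), call. = FALSE)
    dt <- network@drugTargets
    dt <- dt[dt$protein %in% mech, , drop = FALSE]
    if (!includeNonApproved) {
        approvedDrug <- tapply(dt$approved, dt$drug, all)
        dt <- dt[dt$drug %in% names(approvedDrug)[approvedDrug], ,
                 drop = FALSE]
    }
    if (!nrow(dt))
        return(empty)
    drugs <- sort(unique(dt$drug))
    targets <- lapply(drugs, function(d) sort(unique(dt$protein[dt$drug == d])))
    score <- if (method == "trustrank") {
        s <- trustrank(network, seedSet = mech)
        unname(s[drugs])
    } else {
        cen <- centralities(network, method)
        vapply(targets, function(tg) sum(cen[tg]), numeric(1))
    }
    full <- network@drugTargets
    appr <- vapply(drugs, function(d) all(full$approved[full$drug == d]),
                   logical(1))
    df <- data.frame(drug = drugs, score = score,
                     n_targets = lengths(targets),
                     targets = vapply(targets, paste, character(1),
                                      collapse = ";"),
                     approved = appr, stringsAsFactors = FALSE)
    df <- df[order(-df$score, -df$n_targets, df$drug), , drop = FALSE]
    if (is.finite(topK))
        df <- utils::head(df, as.integer(topK))
    rownames(df) <- NULL
    df
}
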