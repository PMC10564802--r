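pathNet <- function() {
    mechanismNetwork(data.frame(node_a = c("A", "B"),
                                node_b = c("B", "C"),
                                stringsAsFactors = FALSE))
}

test_that("seed mapping reports induced and linked connectivity", {
    net <- mechanismNetwork(data.frame(
        node_a = c("A", "B", "C", "D"), node_b = c("B", "C", "A", "E"),
        stringsAsFactors = FALSE))
    ms <- mapSeeds(net, c("A", "B", "C"))
    expect_identical(ms$largestInduced, 3L)
    ms2 <- mapSeeds(net, c("A", "B", "D", "E"))
    expect_identical(ms2$largestInduced, 2L)
    ms3 <- mapSeeds(net, c("A", "MISSING"))
    expect_identical(ms3$unmapped, "MISSING")
    ## seeds connectable only through a non-seed: induced < linked
    ms4 <- mapSeeds(pathNet(), c("A", "C"))
    expect_identical(ms4$largestInduced, 1L)
    expect_identical(ms4$largestLinked, 2L)
    ## random graphs: induced sizes equal brute component labeling
    set.seed(12)
    for (rep in 1:10) {
        g <- igraph::sample_gnp(10, 0.3)
        igraph::V(g)$name <- paste0("n", 1:10)
        igraph::E(g)$weight <- 1
        rn <- mechanismNetwork(g)
        sd <- sample(igraph::V(g)$name, 4)
        ms <- mapSeeds(rn, sd)
        sub <- igraph::induced_subgraph(g, sd)
        expect_identical(ms$inducedComponentSizes,
                         sort(as.integer(igraph::components(sub)$csize),
                              decreasing = TRUE))
    }
})

test_that("attachment heuristic finds the unique small Steiner trees", {
    tr <- steinerApprox(pathNet(), c("A", "C"))
    expect_setequal(tr$nodes, c("A", "B", "C"))
    expect_identical(tr$connectors, "B")
    expect_identical(tr$weight, 2)
    ## star: hub is the single connector of the leaf seeds
    star <- mechanismNetwork(data.frame(
        node_a = "H", node_b = c("L1", "L2", "L3", "L4"),
        stringsAsFactors = FALSE))
    tr2 <- steinerApprox(star, c("L1", "L2", "L3"))
    expect_identical(tr2$connectors, "H")
    ## seeds across components: one tree per component, with a warning
    two <- mechanismNetwork(data.frame(node_a = c("A", "X"),
                                       node_b = c("B", "Y"),
                                       stringsAsFactors = FALSE))
    expect_warning(tr3 <- steinerApprox(two, c("A", "B", "X", "Y")),
                   "components")
    expect_setequal(tr3$nodes, c("A", "B", "X", "Y"))
})

test_that("heuristic stays within twice the exhaustive optimum", {
    set.seed(1234)
    worst <- 0
    for (rep in 1:60) {
        inst <- randomSteinerInstance()
        net <- mechanismNetwork(inst$graph)
        tr <- steinerApprox(net, inst$seeds)
        opt <- bruteSteinerOptimum(inst$graph, inst$seeds)
        expect_lte(tr$weight, 2 * opt + 1e-9)
        worst <- max(worst, tr$weight / max(opt, 1e-12))
    }
    expect_lte(worst, 2)
})

test_that("multi-tree search unions diversified trees and ranks connectors", {
    nf <- netFixture()
    sol <- mustConnect(nf$network, nTrees = 5, rngSeed = 11)
    expect_s4_class(sol, "SteinerSolution")
    expect_true(nf$connector %in% connectors(sol)$node)
    expect_length(intersect(connectors(sol)$node, nf$seeds), 0L)
    expect_true(all(nf$seeds %in% sol@nodes))
    ## participation is bounded by the number of trees and sorted
    cp <- connectors(sol)$participation
    expect_true(all(cp >= 1 & cp <= 5))
    expect_true(all(diff(cp) <= 0))
    ## nTrees = 1 reduces to the single-tree heuristic (same node set)
    one <- mustConnect(nf$network, nTrees = 1, rngSeed = 11)
    expect_identical(length(one@trees), 1L)
    expect_error(mustConnect(nf$network, nTrees = 0), "positive")
    ## already-connected seeds need no connectors
    tri <- mechanismNetwork(data.frame(node_a = c("A", "B", "C"),
                                       node_b = c("B", "C", "A"),
                                       stringsAsFactors = FALSE))
    expect_identical(nrow(connectors(mustConnect(tri, c("A", "B", "C"),
                                                 nTrees = 2))), 0L)
})

test_that("trustrank matches closed forms and igraph's propagation", {
    ## single self-seeded node keeps all mass
    single <- mechanismNetwork(
        igraph::make_empty_graph(directed = FALSE) +
            igraph::vertices("A"))
    expect_equal(unname(trustrank(single, "A")["A"]), 1.0)
    ## two-node closed form: sA=(1-d)/(1-d^2), sB=d(1-d)/(1-d^2)
    two <- mechanismNetwork(data.frame(node_a = "A", node_b = "B",
                                       stringsAsFactors = FALSE))
    s <- trustrank(two, "A", damping = 0.85, tol = 1e-12)
    d <- 0.85
    expect_equal(unname(s["A"]), (1 - d) / (1 - d^2), tolerance = 1e-8)
    expect_equal(unname(s["B"]), d * (1 - d) / (1 - d^2),
                 tolerance = 1e-8)
    ## fully seeded regular graph: uniform by symmetry
    ring <- mechanismNetwork(igraph::make_ring(6))
    rs <- trustrank(initialize(ring, seeds = igraph::V(ring@ppi)$name))
    expect_equal(unname(rs), rep(1 / 6, 6), tolerance = 1e-8)
    ## independent route: personalized PageRank from igraph
    nf <- netFixture()
    seedsv <- seeds(nf$network)
    mine <- trustrank(nf$network, seedsv, tol = 1e-12)
    g <- proteoHarm:::.combinedGraph(nf$network)
    p <- as.numeric(igraph::V(g)$name %in% seedsv)
    pr <- igraph::page_rank(g, personalized = p / sum(p), damping = 0.85,
                            weights = igraph::E(g)$weight)$vector
    expect_equal(unname(mine[igraph::V(g)$name]), unname(pr),
                 tolerance = 1e-6)
    ## mass conservation on a connected seeded component
    expect_equal(sum(mine), 1, tolerance = 1e-6)
    expect_error(trustrank(nf$network, character()), "seed")
})

test_that("centralities equal all-pairs brute force on random graphs", {
    expect_identical(unname(centralities(pathNet(), "betweenness")["B"]),
                     1)
    expect_identical(unname(centralities(pathNet(), "degree")["B"]), 2)
    k4 <- mechanismNetwork(igraph::make_full_graph(4))
    expect_true(all(centralities(k4, "betweenness") == 0))
    set.seed(77)
    for (rep in 1:12) {
        g <- igraph::sample_gnp(12, stats::runif(1, 0.2, 0.5))
        igraph::V(g)$name <- paste0("n", 1:12)
        net <- mechanismNetwork(g)
        oracle <- bruteCentralities(net@ppi)
        for (m in c("degree", "closeness", "harmonic", "betweenness"))
            expect_equal(centralities(net, m), oracle[[m]],
                         tolerance = 1e-10)
    }
})

test_that("drug ranking scores, filters and truncates deterministically", {
    ## symmetric 4-cycle: all centralities equal, so target count decides
    ppi <- data.frame(node_a = c("M1", "M2", "M3", "M4"),
                      node_b = c("M2", "M3", "M4", "M1"),
                      stringsAsFactors = FALSE)
    drugs <- data.frame(drug = c("D1", "D1", "D2", "D3"),
                        protein = c("M1", "M2", "M1", "M3"),
                        approved = c("1", "1", "1", "0"),
                        stringsAsFactors = FALSE)
    net <- mechanismNetwork(ppi, drugs)
    rk <- rankDrugs(net, c("M1", "M2", "M3", "M4"), method = "degree")
    expect_identical(rk$drug[1], "D1")      # two targets beat one
    expect_identical(rk$score[1], 4)        # degree 2 + degree 2
    expect_false("D3" %in% rk$drug)         # not approved
    rkAll <- rankDrugs(net, c("M1", "M2", "M3", "M4"), method = "degree",
                       includeNonApproved = TRUE)
    expect_true("D3" %in% rkAll$drug)
    expect_identical(nrow(rankDrugs(net, c("M1", "M2"), method = "degree",
                                    topK = 1)), 1L)
    ## empty mechanism or no drug edges give empty rankings
    expect_identical(nrow(rankDrugs(net, character())), 0L)
    bare <- mechanismNetwork(ppi)
    expect_identical(nrow(rankDrugs(bare, "M1")), 0L)
    ## positive score implies at least one mechanism target
    expect_true(all(rk$n_targets[rk$score > 0] >= 1))
    ## deterministic under the trustrank method too
    nf <- netFixture()
    mech <- union(seeds(nf$network),
                  connectors(mustConnect(nf$network, nTrees = 3,
                                         rngSeed = 1))$node)
    r1 <- rankDrugs(nf$network, mech, method = "trustrank")
    r2 <- rankDrugs(nf$network, mech, method = "trustrank")
    expect_identical(r1, r2)
    expect_true(all(r1$score > 0))
})
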