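test_that("path statistics match hand enumeration on small graphs", {
    # directed path 1 -> 2 -> 3
    g <- connectivityGraph(1:3, data.frame(from = c(1, 2), to = c(2, 3)))
    sp <- shortestPaths(g)
    expect_identical(sp$d["1", "3"], 2)
    expect_identical(sp$sigma["1", "3"], 1)
    expect_identical(sp$d["3", "1"], Inf)
    expect_identical(diag(sp$d), setNames(rep(0, 3), as.character(1:3)))
    m <- nodeMetrics(g, sp)
    expect_identical(m$betweenness, c(0, 1, 0))
    expect_identical(m$eccentricity, c(2, 1, 0))
    # diamond 1->2, 1->3, 2->4, 3->4: two shortest 1->4 paths
    gd <- connectivityGraph(1:4, data.frame(from = c(1, 1, 2, 3),
                                            to = c(2, 3, 4, 4)))
    spd <- shortestPaths(gd)
    expect_identical(spd$sigma["1", "4"], 2)
    md <- nodeMetrics(gd, spd)
    expect_identical(md$betweenness, c(0, 0.5, 0.5, 0))
})

test_that("closeness follows the reachable-set convention", {
    # isolated node: closeness is exactly 0
    g <- connectivityGraph(1:3, data.frame(from = 1, to = 2))
    m <- nodeMetrics(g)
    expect_identical(m$closeness[m$cell_id == 3], 0)
    # a driver hub h -> a, b, c reaches its whole set at distance 1:
    # closeness exactly 1
    gh <- connectivityGraph(1:4, data.frame(from = c(1, 1, 1),
                                            to = c(2, 3, 4)))
    mh <- nodeMetrics(gh)
    expect_identical(mh$closeness[1], 1)
    expect_identical(mh$closeness[-1], rep(0, 3))
})

test_that("metrics agree with the exhaustive-path oracle on random digraphs", {
    set.seed(31)
    for (rep in 1:40) {
        A <- randomAdjacency(sample(3:6, 1), runif(1, 0.15, 0.5))
        expectMetricsMatchOracle(A)
    }
})

test_that("metrics agree with igraph on larger random digraphs", {
    set.seed(37)
    for (rep in 1:12) {
        n <- sample(8:25, 1)
        A <- randomAdjacency(n, 0.12)
        m <- nodeMetrics(graphFromAdjacency(A))
        ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
        expect_equal(m$betweenness,
                     unname(igraph::betweenness(ig, directed = TRUE)),
                     tolerance = 1e-9)
        cl <- suppressWarnings(igraph::closeness(ig, mode = "out",
                                                 normalized = TRUE))
        cl[is.nan(cl)] <- 0
        expect_equal(m$closeness, unname(cl), tolerance = 1e-9)
        expect_equal(m$eccentricity,
                     unname(igraph::eccentricity(ig, mode = "out")),
                     tolerance = 1e-9)
    }
})

test_that("degree sums, transposition and 1-hop graphs behave as theory says", {
    set.seed(41)
    for (rep in 1:10) {
        A <- randomAdjacency(sample(4:12, 1), 0.25)
        g <- graphFromAdjacency(A)
        m <- nodeMetrics(g)
        expect_identical(sum(m$k_in), nEdges(g))
        expect_identical(sum(m$k_out), nEdges(g))
        mT <- nodeMetrics(graphFromAdjacency(t(A)))
        expect_identical(m$k_in, mT$k_out)
        expect_identical(m$k_out, mT$k_in)
        expect_equal(sort(m$betweenness), sort(mT$betweenness))
    }
    # complete digraph: every shortest path is one hop, betweenness all 0
    K <- 1 - diag(5)
    mK <- nodeMetrics(graphFromAdjacency(K))
    expect_identical(mK$betweenness, rep(0, 5))
    expect_identical(mK$eccentricity, rep(1, 5))
})

test_that("network summary reports density both ways plus radius/diameter", {
    g <- connectivityGraph(1:4, data.frame(from = c(1, 2), to = c(2, 3)))
    s <- networkSummary(g)
    expect_equal(s$density, 2 / 4)        # edges-per-node convention
    expect_equal(s$density_std, 2 / 12)   # |E| / (N (N-1))
    expect_identical(s$radius, 1)
    expect_identical(s$diameter, 2)
    s0 <- networkSummary(connectivityGraph(1:5))
    expect_equal(s0$density, 0)
    expect_true(is.na(s0$diameter))
    expect_error(networkSummary(connectivityGraph(integer())), "empty")
})

test_that("hub classification tags integrators, pacemakers and bottlenecks", {
    # hub with in-degree 6
    gIn <- connectivityGraph(1:7, data.frame(from = 2:7, to = rep(1, 6)))
    tin <- classifyHubs(nodeMetrics(gIn))
    expect_match(tin$tags[1], "integrator_hub")
    expect_false(any(grepl("integrator", tin$tags[-1])))
    # out-degree-6 hub with top closeness: distributor and pacemaker
    gOut <- connectivityGraph(1:7, data.frame(from = rep(1, 6), to = 2:7))
    tout <- classifyHubs(nodeMetrics(gOut))
    expect_match(tout$tags[1], "distributor_hub")
    expect_match(tout$tags[1], "pacemaker")
    # a pure relay on a long chain is a bottleneck but not a connector
    gc <- connectivityGraph(1:5, data.frame(from = 1:4, to = 2:5))
    tc <- classifyHubs(nodeMetrics(gc))
    expect_match(tc$tags[3], "bottleneck")
    expect_false(grepl("connector", tc$tags[3]))
    # edgeless graph: nothing is tagged
    t0 <- classifyHubs(nodeMetrics(connectivityGraph(1:6)))
    expect_identical(unique(t0$tags), "")
})
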