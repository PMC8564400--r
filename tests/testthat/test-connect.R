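specC <- LatticeSpec(55, 70, rows = 5, cols = 5)

# minimal annotation builder: cells given as list(dend = ..., axon = ...)
makeAnn <- function(cells, spec = specC) {
    ids <- seq_along(cells)
    soma <- vapply(cells, function(c) c$dend[1], numeric(1))
    ctr <- hexCenter(spec, soma)
    dend <- lapply(cells, function(c) as.integer(c$dend))
    axon <- lapply(cells, function(c) as.integer(c$axon))
    names(dend) <- names(axon) <- as.character(ids)
    circuitAnnotation(
        somata = data.frame(cell_id = ids, x_um = ctr[, 1], y_um = ctr[, 2]),
        dendrites = dend, axons = axon, lattice = spec)
}

test_that("contact rule hand fixtures build the expected edges", {
    # A's axon reaches pattern 7 where B holds dendrites: A -> B only
    ann <- makeAnn(list(list(dend = 1, axon = c(1, 7)),
                        list(dend = 7, axon = 13)))
    e <- edgeTable(buildGraph(ann))
    expect_identical(nrow(e), 1L)
    expect_identical(c(e$from, e$to), c(1L, 2L))
    # a cell whose axon overlaps its own dendrites gains no self-edge
    annSelf <- makeAnn(list(list(dend = c(1, 2), axon = c(1, 2, 3))))
    expect_identical(nrow(edgeTable(buildGraph(annSelf))), 0L)
    expect_identical(nrow(edgeTable(buildGraph(annSelf,
                                               keepSelfLoops = TRUE))), 1L)
    # chain: A->B via p, B->C via q, nothing else
    annChain <- makeAnn(list(list(dend = 1, axon = c(1, 7)),
                             list(dend = 7, axon = c(7, 13)),
                             list(dend = 13, axon = 13)))
    # cell 3's axon sits in its own RPA only; cell 2 gets 3's contact too?
    e <- edgeTable(buildGraph(annChain))
    expect_identical(paste(e$from, e$to), c("1 2", "2 3"))
    # multiple shared patterns collapse into one edge with evidence
    annMulti <- makeAnn(list(list(dend = 1, axon = c(1, 7, 8)),
                             list(dend = c(7, 8), axon = c(7, 8))))
    g <- buildGraph(annMulti)
    e <- edgeTable(g)
    expect_identical(e$n_contacts[e$from == 1], 2L)
    expect_identical(sort(g@evidence[[which(e$from == 1)]]), c(7L, 8L))
})

test_that("graph construction agrees with a brute-force pair scan", {
    set.seed(17)
    for (rep in 1:15) {
        ann <- randomAnnotation(specC, sample(5:50, 1))
        e <- edgeTable(buildGraph(ann))
        bf <- bruteForceEdges(ann)
        expect_identical(e$from, bf$from)
        expect_identical(e$to, bf$to)
    }
})

test_that("adding axon patterns never removes edges; transposition swaps them", {
    set.seed(23)
    for (rep in 1:8) {
        ann <- randomAnnotation(specC, 20)
        e0 <- edgeTable(buildGraph(ann))
        # grow one cell's axon territory
        ann2 <- ann
        k <- sample(cellIds(ann), 1)
        ann2@axons[[as.character(k)]] <-
            sort(unique(c(ann2@axons[[as.character(k)]],
                          sample.int(25, 2))))
        e1 <- edgeTable(buildGraph(ann2))
        expect_true(all(paste(e0$from, e0$to) %in% paste(e1$from, e1$to)))
        # swapping all axon/dendrite sets transposes the graph
        annT <- ann
        tmp <- annT@axons
        annT@axons <- annT@dendrites
        annT@dendrites <- tmp
        eT <- edgeTable(buildGraph(annT))
        expect_identical(sort(paste(eT$to, eT$from)),
                         sort(paste(e0$from, e0$to)))
    }
})

test_that("with no synapse loss the reconstruction equals the simulator truth", {
    spec <- LatticeSpec(55, 70, rows = 12, cols = 12)
    sim <- simulateCircuit(spec, SimulationParams(
        nCells = 120, seed = 13, pSynapseGivenContact = 1))
    g <- buildGraph(sim$annotation)
    expect_identical(edgeTable(g), edgeTable(sim$truth))
    expect_identical(nodeIds(g), nodeIds(sim$truth))
})

test_that("components split into size-ordered segments plus isolated nodes", {
    g0 <- connectivityGraph(1:6)
    c0 <- graphComponents(g0)
    expect_length(c0$segments, 0)
    expect_identical(c0$isolated, 1:6)
    g1 <- connectivityGraph(1:5, data.frame(from = c(1, 3), to = c(2, 4)))
    c1 <- graphComponents(g1)
    expect_identical(c1$segments, list(c(1L, 2L), c(3L, 4L)))
    expect_identical(c1$isolated, 5L)
    # ordering: larger segments first, ties by smallest member
    g2 <- connectivityGraph(1:7, data.frame(from = c(5, 6, 1),
                                            to = c(6, 7, 2)))
    c2 <- graphComponents(g2)
    expect_identical(c2$segments[[1]], c(5L, 6L, 7L))
    expect_identical(c2$segments[[2]], c(1L, 2L))
})

test_that("malformed annotations are rejected", {
    expect_error(circuitAnnotation(
        somata = data.frame(cell_id = c(1, 1), x_um = 0, y_um = 0),
        dendrites = list(`1` = 1L), axons = list(`1` = 1L),
        lattice = specC), "unique")
    expect_error(makeAnn(list(list(dend = integer(), axon = 1))))
})
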