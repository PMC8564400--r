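spec10 <- LatticeSpec(55, 70, rows = 10, cols = 10)

test_that("simulation is fully reproducible from its seed", {
    p <- SimulationParams(nCells = 60, seed = 99)
    a <- simulateCircuit(spec10, p)
    b <- simulateCircuit(spec10, p)
    expect_identical(a, b)
    c <- simulateCircuit(spec10, SimulationParams(nCells = 60, seed = 100))
    expect_false(identical(somaTable(a$annotation), somaTable(c$annotation)))
    # the caller's RNG stream is untouched
    set.seed(5); before <- rnorm(3)
    set.seed(5); invisible(simulateCircuit(spec10, p)); after <- rnorm(3)
    expect_identical(before, after)
})

test_that("generator recovers its configured occupancy statistics", {
    spec <- LatticeSpec(55, 70, rows = 40, cols = 40)
    n <- 1500L
    sim <- simulateCircuit(spec, SimulationParams(nCells = n, seed = 21))
    st <- somaTable(sim$annotation)
    insideFrac <- mean(!is.na(st$soma_pattern))
    expect_lt(abs(insideFrac - 0.643), 3 * sqrt(0.643 * 0.357 / n))
    sm <- occupancySummary(spec, sim$annotation)
    rpa12 <- sum(sm$rpa_count_hist[1:2]) / n
    expect_lt(abs(rpa12 - 0.762), 3 * sqrt(0.762 * 0.238 / n))
    cov <- lengths(axonPatterns(sim$annotation))
    expect_lt(abs(mean(cov) - 6.7), 3 * stats::sd(cov) / sqrt(n))
    # soma_pattern column is consistent with the geometry
    expect_identical(st$soma_pattern,
                     pointToPattern(spec, st$x_um, st$y_um))
    # histograms account for every cell
    expect_identical(sum(sm$rpa_count_hist), n)
    expect_identical(sum(sm$axon_coverage_hist), n)
})

test_that("every truth edge is backed by an axon-dendrite co-occupancy", {
    sim <- simulateCircuit(spec10, SimulationParams(nCells = 80, seed = 3))
    e <- edgeTable(sim$truth)
    dend <- dendritePatterns(sim$annotation)
    axon <- axonPatterns(sim$annotation)
    for (k in seq_len(nrow(e))) {
        expect_gt(length(intersect(axon[[as.character(e$from[k])]],
                                   dend[[as.character(e$to[k])]])), 0)
    }
    # sub-unity synapse probability only removes edges
    simAll <- simulateCircuit(spec10, SimulationParams(
        nCells = 80, seed = 3, pSynapseGivenContact = 1))
    eAll <- edgeTable(simAll$truth)
    expect_true(all(paste(e$from, e$to) %in% paste(eAll$from, eAll$to)))
})

test_that("occupancy summary matches hand-computed fixtures", {
    spec <- LatticeSpec(55, 70, rows = 2, cols = 5)  # 10 patterns
    ctr <- hexCenter(spec, 3)
    ann <- circuitAnnotation(
        somata = data.frame(cell_id = 1L, x_um = ctr[1], y_um = ctr[2]),
        dendrites = list(`1` = 3L), axons = list(`1` = 3L), lattice = spec)
    sm <- occupancySummary(spec, ann)
    expect_equal(sm$frac_patterns_with_soma, 0.1)
    expect_equal(sm$frac_patterns_with_dendrite, 0.1)
    expect_equal(sm$frac_patterns_with_axon, 0.1)
    expect_true(is.na(sm$mean_dist_3_nearest_um))  # < 4 cells

    # three collinear cells 100 um apart plus one far away
    spec2 <- LatticeSpec(55, 0, rows = 20, cols = 20, origin = c(0, 0))
    xs <- c(0, 100, 200, 1000)
    pats <- pointToPattern(spec2, xs, rep(0, 4))
    ann2 <- circuitAnnotation(
        somata = data.frame(cell_id = 1:4, x_um = xs, y_um = 0),
        dendrites = as.list(setNames(pats, 1:4)),
        axons = as.list(setNames(pats, 1:4)), lattice = spec2)
    d3 <- occupancySummary(spec2, ann2)$dist_3_nearest_um
    expect_equal(d3, c(mean(c(100, 200, 1000)),   # cell 1
                       mean(c(100, 100, 900)),    # cell 2
                       mean(c(100, 200, 800)),    # cell 3
                       mean(c(800, 900, 1000))))  # cell 4
})

test_that("overcrowded lattices fail placement with a clear error", {
    tiny <- LatticeSpec(55, 70, rows = 1, cols = 1)
    expect_error(
        simulateCircuit(tiny, SimulationParams(nCells = 500, seed = 1,
                                               minSomaSep = 40)),
        "placement")
})

test_that("rendered rasters are consistent with the lattice geometry", {
    spec <- LatticeSpec(55, 70, rows = 4, cols = 4)
    r <- renderImage(spec, pxPerUm = 0.25)
    expect_identical(length(dim(r$img)), 3L)
    # pattern channel equals the rasterized point-to-pattern interior mask
    tr <- r$transform
    H <- dim(r$img)[1]; W <- dim(r$img)[2]
    px <- expand.grid(row = seq_len(H), col = seq_len(W))
    mask <- !is.na(pointToPattern(spec,
        tr$xMin + (px$col - 0.5) / tr$pxPerUm,
        tr$yMax - (px$row - 0.5) / tr$pxPerUm))
    expect_identical(as.vector(r$img[, , 1] == 1), mask)
    # pattern-only render has a single channel; with an annotation the cell
    # channels light up
    sim <- simulateCircuit(spec, SimulationParams(nCells = 8, seed = 4))
    rc <- renderImage(spec, sim$annotation, pxPerUm = 0.25)
    expect_identical(dim(rc$img)[3], 4L)
    expect_gt(sum(rc$img[, , 2] + rc$img[, , 3] + rc$img[, , 4]), 0)
    # determinism of the noise stream
    n1 <- renderImage(spec, pxPerUm = 0.25, noiseSd = 0.1, seed = 8)
    n2 <- renderImage(spec, pxPerUm = 0.25, noiseSd = 0.1, seed = 8)
    expect_identical(n1$img, n2$img)
})

test_that("rasters survive a TIFF/PNG round trip", {
    spec <- LatticeSpec(55, 70, rows = 3, cols = 3)
    sim <- simulateCircuit(spec, SimulationParams(nCells = 5, seed = 6))
    r <- renderImage(spec, sim$annotation, pxPerUm = 0.2)
    tf <- tempfile(fileext = ".tiff")
    writeRaster(r, tf, "tiff")
    back <- readRaster(tf)
    expect_identical(dim(back), dim(r$img))
    expect_lt(max(abs(back - pmin(1, pmax(0, r$img)))), 1 / 255)
    pf <- tempfile(fileext = ".png")
    paths <- writeRaster(r, pf, "png")
    expect_length(paths, dim(r$img)[3])
    expect_true(all(file.exists(paths)))
})
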