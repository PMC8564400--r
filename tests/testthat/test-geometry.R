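test_that("closed-form distances reproduce the printed pattern dimensions", {
    spec <- LatticeSpec(edge_um = 55, gap_um = 70)
    d <- deriveDistances(spec)
    expect_equal(d$apothem, sqrt(3) / 2 * 55)
    expect_equal(d$spacing, sqrt(3) * 55 + 70)
    # exact closed forms, and their values at the 0.1 um precision the
    # pattern dimensions are printed at (truncation)
    expect_equal(d$l1, sqrt(3) / 2 * 55 + 70)
    expect_equal(d$l2, 3 * sqrt(3) / 2 * 55 + 70)
    expect_identical(trunc(d$l1 * 10) / 10, 117.6)
    expect_identical(trunc(d$l2 * 10) / 10, 212.8)
    expect_equal(d$r1, d$spacing + 55)
    expect_equal(d$r2, sqrt(3) * d$spacing + 55)
    expect_error(LatticeSpec(-1, 10), "edgeLength")
    expect_error(LatticeSpec(55, -5), "gap")
})

test_that("l2 - l1 equals two apothems (sqrt(3) L) for any lattice", {
    set.seed(101)
    for (i in 1:25) {
        L <- runif(1, 1, 200)
        D <- runif(1, 0, 150)
        d <- deriveDistances(LatticeSpec(L, D))
        expect_equal(d$l2 - d$l1, sqrt(3) * L, tolerance = 1e-12)
    }
})

test_that("hex centers and point lookup are mutually consistent", {
    spec <- LatticeSpec(55, 70, rows = 8, cols = 9,
                        origin = c(120, -40), rotation = 13)
    pt <- patternTable(spec)
    # round trip on every centre
    expect_identical(pointToPattern(spec, pt$center_x_um, pt$center_y_um),
                     pt$pattern_id)
    # origin index maps to the origin point
    expect_equal(unname(hexCenter(spec, 1)[1, ]), c(120, -40))
    # adjacent centres are exactly one spacing apart
    nb <- neighborShell(spec, 40, 1)
    c0 <- hexCenter(spec, 40)
    for (j in nb)
        expect_equal(sqrt(sum((hexCenter(spec, j) - c0)^2)),
                     sqrt(3) * 55 + 70, tolerance = 1e-9)
    expect_error(hexCenter(spec, NA), "OUTSIDE")
    expect_error(hexCenter(spec, 8 * 9 + 1), "out of bounds")
})

test_that("gap points are OUTSIDE and boundaries belong to patterns", {
    spec <- LatticeSpec(55, 70, rows = 5, cols = 5)
    c1 <- hexCenter(spec, 13)
    nb <- neighborShell(spec, 13, 1)
    for (j in nb) {
        mid <- (c1 + hexCenter(spec, j)) / 2
        expect_true(is.na(pointToPattern(spec, mid[1], mid[2])))
    }
    # a point exactly on a flat edge is inside (boundary-inclusive)
    apo <- deriveDistances(spec)$apothem
    onEdge <- c1 + c(0, apo)
    expect_identical(pointToPattern(spec, onEdge[1], onEdge[2]), 13L)
    # beyond the array, OUTSIDE
    expect_true(is.na(pointToPattern(spec, 1e5, 1e5)))
})

test_that("uniform points fall inside patterns at the closed-form area ratio", {
    spec <- LatticeSpec(55, 70, rows = 12, cols = 12)
    s <- sqrt(3) * 55 + 70
    # sample an interior window spanning whole lattice periods so the
    # expected coverage is exactly hexArea / unitCellArea = 3 L^2 / s^2
    x0 <- sqrt(3) / 2 * s * 2; y0 <- s * 2
    set.seed(7)
    n <- 10000
    x <- runif(n, x0, x0 + sqrt(3) * s * 3)  # 3 full x-periods
    y <- runif(n, y0, y0 + s * 4)            # 4 full y-periods
    frac <- mean(!is.na(pointToPattern(spec, x, y)))
    p <- 3 * 55^2 / s^2
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("neighbor shells have honeycomb coordination numbers", {
    spec <- LatticeSpec(55, 70, rows = 7, cols = 7)
    interior <- axialToId(spec, 3, 2)  # row 3+1, col 4: well inside
    expect_length(neighborShell(spec, interior, 1), 6)
    expect_length(neighborShell(spec, interior, 2), 18)
    expect_lt(length(neighborShell(spec, 1, 1)), 6)      # corner
    # symmetry: j in shell1(i) <=> i in shell1(j)
    set.seed(11)
    for (i in sample(spec@rows * spec@cols, 10)) {
        for (j in neighborShell(spec, i, 1))
            expect_true(i %in% neighborShell(spec, j, 1))
    }
    # r1 covers the first ring entirely; r2 covers the second-nearest
    # distance class (the 6 ring-2 hexagons at sqrt(3) * spacing)
    d <- deriveDistances(spec)
    c0 <- hexCenter(spec, interior)
    ring1 <- neighborShell(spec, interior, 1)
    for (j in ring1) {
        dist <- sqrt(sum((hexCenter(spec, j) - c0)^2))
        expect_lte(dist + 55, d$r1 + 1e-9)
    }
    ring2 <- setdiff(neighborShell(spec, interior, 2), ring1)
    dists <- vapply(ring2, function(j)
        sqrt(sum((hexCenter(spec, j) - c0)^2)), numeric(1))
    second <- abs(dists - sqrt(3) * d$spacing) < 1e-6
    expect_identical(sum(second), 6L)
    expect_true(all(dists[second] + 55 <= d$r2 + 1e-9))
})
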