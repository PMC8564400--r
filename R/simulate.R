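## Synthetic micropatterned circuits. The generator places somata, draws each
## cell's receptive pattern areas (RPAs; patterns occupied by its dendrites)
## near the soma, grows the axon territory as a random walk on the lattice
## adjacency, and applies the contact rule to produce a ground-truth directed
## graph. All randomness flows from one seed through named substreams so each
## stage is independently reproducible.

## run code under a given seed without disturbing the caller's RNG state
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## default axon-coverage law: 1 + negative binomial, truncated to 1..25.
## size and mu solved once so the truncated law has mean 6.700 and
## P(coverage < 10) = 0.808, the reported culture statistics.
.defaultAxonCoverageDist <- function() {
    p <- stats::dnbinom(0:24, size = 4.980, mu = 5.704)
    p / sum(p)
}

## default RPA-count law over 1..5 patterns; P{1 or 2} = 0.762 as reported
.defaultRpaCountDist <- function() c(0.462, 0.300, 0.140, 0.068, 0.030)

#' Construct simulation parameters
#'
#' Defaults are the mature-culture statistics described in
#' \linkS4class{SimulationParams}.
#'
#' @param nCells number of neurons. The default matches the scale of a
#'   representative reconstruction (about 106 traceable cells over a
#'   ~400-pattern array, i.e. ~0.27 cells per pattern, which reproduces the
#'   reported 15.7\% soma occupancy of patterns given that 64.3\% of somata
#'   lie inside patterns); see \code{\link{nCellsForDensity}} to derive a
#'   count from a seeding density instead.
#' @param pSomaInside probability a soma lands inside a pattern
#'   (default 0.643).
#' @param rpaCountDist probability vector over RPA counts 1, 2, ...;
#'   the default puts 0.762 of its mass on counts 1-2.
#' @param axonCoverageDist probability vector over axon coverage 1..25;
#'   the default (shifted truncated negative binomial) has mean 6.7 with
#'   80.8\% of mass below 10.
#' @param pSynapseGivenContact probability an axon-dendrite co-occupancy
#'   forms a synapse (default 0.9).
#' @param nColors fluorophore channels (default 3).
#' @param minSomaSep minimum soma separation in micrometres (default 15, a
#'   soma diameter).
#' @param seed integer seed.
#' @return a \linkS4class{SimulationParams}.
#' @export
SimulationParams <- function(nCells = 106L,
                             pSomaInside = 0.643,
                             rpaCountDist = .defaultRpaCountDist(),
                             axonCoverageDist = .defaultAxonCoverageDist(),
                             pSynapseGivenContact = 0.9,
                             nColors = 3L,
                             minSomaSep = 15,
                             seed = 1L) {
    new("SimulationParams", nCells = as.integer(nCells),
        pSomaInside = pSomaInside,
        rpaCountDist = rpaCountDist / sum(rpaCountDist),
        axonCoverageDist = axonCoverageDist / sum(axonCoverageDist),
        pSynapseGivenContact = pSynapseGivenContact,
        nColors = as.integer(nColors), minSomaSep = as.numeric(minSomaSep),
        seed = as.integer(seed))
}

#' Cell count for a target seeding density
#'
#' Cultures in the emulated experiments were seeded at 39.5-78.9 cells per
#' square millimetre; this converts such a density into a cell count for the
#' area spanned by the lattice (centres bounding box plus one spacing of
#' margin).
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param density_per_mm2 seeding density in cells/mm^2.
#' @return integer cell count.
#' @export
nCellsForDensity <- function(spec, density_per_mm2) {
    s <- .spacing(spec)
    w <- sqrt(3) / 2 * s * (spec@cols - 1) + s
    h <- s * (spec@rows - 1) + s
    as.integer(round(density_per_mm2 * (w * h) / 1e6))
}

## lattice adjacency list over serial ids (shell-1 neighbours)
.adjacencyList <- function(spec) {
    np <- spec@rows * spec@cols
    ax <- idToAxial(spec, seq_len(np))
    offs <- .ringOffsets(1L)
    nb <- matrix(NA_integer_, np, nrow(offs))
    for (k in seq_len(nrow(offs)))
        nb[, k] <- axialToId(spec, ax$q + offs[k, 1], ax$r + offs[k, 2])
    lapply(seq_len(np), function(i) nb[i, !is.na(nb[i, ])])
}

## uniform point inside a flat-top hexagon (base frame, centred at ctr)
.runifHex <- function(L, ctr) {
    repeat {
        dx <- stats::runif(1, -L, L)
        dy <- stats::runif(1, -sqrt(3) / 2 * L, sqrt(3) / 2 * L)
        if (.inHex(dx, dy, L)) return(c(ctr[1] + dx, ctr[2] + dy))
    }
}

#' Simulate a synthetic micropatterned circuit
#'
#' Somata are placed inside a uniformly chosen pattern with probability
#' \code{pSomaInside}, otherwise uniformly in the repulsive gap. Dendrite
#' patterns (RPAs) are drawn locally: the soma's own pattern first, then
#' shell-1 neighbours; a cell whose soma sits in the gap draws from all
#' patterns whose centre lies within l1 of the soma. The axon territory is a
#' random walk on the lattice adjacency from the soma pattern, stopped when
#' the number of distinct visited patterns reaches a draw from
#' \code{axonCoverageDist}. The ground-truth graph applies the contact rule
#' (axon of i and dendrites of j share a pattern) and keeps each contact as a
#' synaptic edge with probability \code{pSynapseGivenContact}.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param params a \linkS4class{SimulationParams}.
#' @return list with elements \code{annotation}
#'   (\linkS4class{CircuitAnnotation}) and \code{truth}
#'   (\linkS4class{ConnectivityGraph}).
#' @examples
#' spec <- LatticeSpec(55, 70, rows = 10, cols = 10)
#' sim <- simulateCircuit(spec, SimulationParams(nCells = 60, seed = 7))
#' sim$annotation
#' sim$truth
#' @export
simulateCircuit <- function(spec, params = SimulationParams()) {
    stopifnot(is(spec, "LatticeSpec"), is(params, "SimulationParams"))
    validObject(spec); validObject(params)
    sub <- .withSeed(params@seed, sample.int(2^31 - 2, 5L))
    n <- params@nCells
    np <- spec@rows * spec@cols
    L <- spec@edgeLength
    s <- .spacing(spec)
    centers <- .axialToBaseXY(spec, idToAxial(spec, seq_len(np))$q,
                              idToAxial(spec, seq_len(np))$r)

    ## --- soma placement (base frame) ---
    place <- .withSeed(sub[1], {
        inside <- stats::runif(n) < params@pSomaInside
        xs <- numeric(n); ys <- numeric(n); pat <- rep(NA_integer_, n)
        bb <- c(range(centers[, 1]) + c(-s / 2, s / 2),
                range(centers[, 2]) + c(-s / 2, s / 2))
        for (i in seq_len(n)) {
            placed <- FALSE
            for (try in seq_len(200L)) {
                if (inside[i]) {
                    p <- sample.int(np, 1L)
                    pt <- .runifHex(L, centers[p, ])
                } else {
                    repeat {
                        pt <- c(stats::runif(1, bb[1], bb[2]),
                                stats::runif(1, bb[3], bb[4]))
                        p <- .pointToPatternBase(spec, rbind(pt))
                        if (is.na(p)) break
                    }
                    p <- NA_integer_
                }
                if (i == 1L || all((xs[seq_len(i - 1L)] - pt[1])^2 +
                                   (ys[seq_len(i - 1L)] - pt[2])^2 >=
                                   params@minSomaSep^2)) {
                    xs[i] <- pt[1]; ys[i] <- pt[2]; pat[i] <- p
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("soma placement failed: density too high for ",
                     "minSomaSep = ", params@minSomaSep, " um")
        }
        list(x = xs, y = ys, pat = pat)
    })

    ## nearest pattern for gap somata (walk start / RPA fallback)
    nearestPat <- vapply(seq_len(n), function(i) {
        if (!is.na(place$pat[i])) return(place$pat[i])
        which.min((centers[, 1] - place$x[i])^2 +
                  (centers[, 2] - place$y[i])^2)
    }, integer(1))

    ## --- dendrite patterns (RPAs) ---
    l1 <- deriveDistances(spec)$l1
    dendrites <- .withSeed(sub[2], {
        kk <- sample.int(length(params@rpaCountDist), n, replace = TRUE,
                         prob = params@rpaCountDist)
        ## candidate pools are local-first (soma pattern, then shell 1, then
        ## outward by distance) but never truncate the drawn RPA count, so
        ## the configured count law is recovered exactly in expectation
        lapply(seq_len(n), function(i) {
            d2 <- (centers[, 1] - place$x[i])^2 +
                  (centers[, 2] - place$y[i])^2
            if (!is.na(place$pat[i])) {
                ring1 <- neighborShell(spec, place$pat[i], 1L)
                far <- setdiff(order(d2), c(place$pat[i], ring1))
                pool <- c(ring1[sample.int(length(ring1))], far)
                sort(c(place$pat[i], pool[seq_len(kk[i] - 1L)]))
            } else {
                near <- which(d2 <= l1^2)
                far <- setdiff(order(d2), near)
                pool <- c(near[sample.int(length(near))], far)
                sort(pool[seq_len(kk[i])])
            }
        })
    })

    ## --- axon territories: random walks on the lattice adjacency ---
    adj <- .adjacencyList(spec)
    paths <- .withSeed(sub[3], {
        mm <- sample.int(length(params@axonCoverageDist), n, replace = TRUE,
                         prob = params@axonCoverageDist)
        lapply(seq_len(n), function(i) {
            cur <- nearestPat[i]
            path <- cur
            seen <- cur
            cap <- 40L * mm[i] + 400L
            while (length(seen) < mm[i] && length(path) < cap) {
                nb <- adj[[cur]]
                cur <- nb[sample.int(length(nb), 1L)]
                path <- c(path, cur)
                if (!(cur %in% seen)) seen <- c(seen, cur)
            }
            path
        })
    })
    axons <- lapply(paths, function(p) sort(unique(p)))

    ## --- stochastic multicolor labels ---
    colors <- .withSeed(sub[4], {
        m <- matrix(0, n, params@nColors)
        for (i in seq_len(n)) {
            for (try in seq_len(50L)) {
                w <- stats::rexp(params@nColors)
                w <- w / sum(w)
                if (max(w) > 0.3) break
            }
            m[i, ] <- w
        }
        m
    })

    ids <- seq_len(n)
    names(dendrites) <- names(axons) <- names(paths) <- as.character(ids)
    annotation <- new("CircuitAnnotation",
        somata = data.frame(cell_id = ids, x_um = place$x, y_um = place$y,
                            soma_pattern = place$pat),
        dendrites = dendrites, axons = axons, axonPaths = paths,
        colors = colors, lattice = spec)

    ## --- ground-truth graph from the contact rule ---
    truth <- .withSeed(sub[5], {
        full <- buildGraph(annotation)
        e <- edgeTable(full)
        keep <- if (params@pSynapseGivenContact >= 1) rep(TRUE, nrow(e))
                else stats::runif(nrow(e)) < params@pSynapseGivenContact
        connectivityGraph(nodes = nodeIds(full), edges = e[keep, , drop = FALSE],
                          evidence = full@evidence[keep])
    })

    list(annotation = annotation, truth = truth)
}

#' Occupancy and spacing summary of an annotated circuit
#'
#' The statistics reported for cultured circuits: the fraction of patterns
#' occupied by at least one cell body, dendrite, or axon; the histogram of
#' per-cell RPA counts; the histogram of per-cell axon coverage; and the mean
#' over cells of the average Euclidean distance from each soma to its three
#' nearest neighbouring somata.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param annotation a \linkS4class{CircuitAnnotation}.
#' @return list with \code{frac_patterns_with_soma},
#'   \code{frac_patterns_with_dendrite}, \code{frac_patterns_with_axon},
#'   \code{rpa_count_hist}, \code{axon_coverage_hist},
#'   \code{dist_3_nearest_um} (per cell) and \code{mean_dist_3_nearest_um}
#'   (\code{NA} with fewer than 4 cells).
#' @export
occupancySummary <- function(spec, annotation) {
    stopifnot(is(spec, "LatticeSpec"), is(annotation, "CircuitAnnotation"))
    np <- spec@rows * spec@cols
    s <- somaTable(annotation)
    n <- nrow(s)
    occ <- function(ids) length(unique(ids)) / np
    rpa <- lengths(annotation@dendrites[as.character(s$cell_id)])
    cov <- lengths(annotation@axons[as.character(s$cell_id)])
    if (n >= 4L) {
        d3 <- vapply(seq_len(n), function(i) {
            d <- sqrt((s$x_um - s$x_um[i])^2 + (s$y_um - s$y_um[i])^2)
            mean(sort(d[-i])[1:3])
        }, numeric(1))
    } else d3 <- rep(NA_real_, n)
    list(
        frac_patterns_with_soma = occ(s$soma_pattern[!is.na(s$soma_pattern)]),
        frac_patterns_with_dendrite =
            occ(unlist(annotation@dendrites, use.names = FALSE)),
        frac_patterns_with_axon =
            occ(unlist(annotation@axons, use.names = FALSE)),
        rpa_count_hist = tabulate(rpa, nbins = max(rpa, 1L)),
        axon_coverage_hist = tabulate(cov, nbins = max(cov, 1L)),
        dist_3_nearest_um = d3,
        mean_dist_3_nearest_um = if (n >= 4L) mean(d3) else NA_real_
    )
}
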