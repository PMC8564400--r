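# Independent oracles and fixture builders used across the suite.

# adjacency matrix of a ConnectivityGraph (node order = nodeIds order)
adjacencyOf <- function(graph) {
    ids <- nodeIds(graph)
    A <- matrix(0L, length(ids), length(ids))
    e <- edgeTable(graph)
    if (nrow(e)) A[cbind(match(e$from, ids), match(e$to, ids))] <- 1L
    A
}

graphFromAdjacency <- function(A, ids = seq_len(nrow(A))) {
    ed <- which(A == 1, arr.ind = TRUE)
    connectivityGraph(ids, data.frame(from = ids[ed[, 1]],
                                      to = ids[ed[, 2]]))
}

randomAdjacency <- function(n, p) {
    A <- matrix(stats::rbinom(n * n, 1L, p), n, n)
    diag(A) <- 0L
    A
}

# exhaustive simple-path enumeration: distances, shortest-path counts,
# betweenness, closeness and eccentricity from first principles
oraclePathMetrics <- function(A) {
    n <- nrow(A)
    d <- matrix(Inf, n, n); diag(d) <- 0
    sigma <- matrix(0, n, n); diag(sigma) <- 1
    btw <- numeric(n)
    for (s in seq_len(n)) {
        res <- list()
        walk <- function(path) {
            v <- path[length(path)]
            for (w in which(A[v, ] == 1)) {
                if (w %in% path) next
                res[[length(res) + 1L]] <<- c(path, w)
                walk(c(path, w))
            }
        }
        walk(s)
        if (!length(res)) next
        ends <- vapply(res, function(p) p[length(p)], integer(1))
        for (t in seq_len(n)) {
            if (t == s) next
            sel <- res[ends == t]
            if (!length(sel)) next
            ls <- lengths(sel) - 1L
            dm <- min(ls)
            d[s, t] <- dm
            sp <- sel[ls == dm]
            sigma[s, t] <- length(sp)
            for (p in sp) {
                mid <- p[-c(1, length(p))]
                btw[mid] <- btw[mid] + 1 / length(sp)
            }
        }
    }
    ecc <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]; r <- is.finite(di)
        if (any(r)) max(di[r]) else 0
    }, numeric(1))
    clo <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]; r <- is.finite(di)
        if (any(r)) sum(r) / sum(di[r]) else 0
    }, numeric(1))
    list(d = d, sigma = sigma, betweenness = btw, closeness = clo,
         eccentricity = ecc)
}

expectMetricsMatchOracle <- function(A) {
    m <- nodeMetrics(graphFromAdjacency(A))
    o <- oraclePathMetrics(A)
    expect_equal(m$betweenness, o$betweenness, tolerance = 1e-10)
    expect_equal(m$closeness, o$closeness, tolerance = 1e-10)
    expect_equal(m$eccentricity, o$eccentricity, tolerance = 1e-10)
}

# enumerate all n-node digraphs by their off-diagonal bit patterns
allDigraphs <- function(n) {
    off <- which(diag(n) == 0)
    m <- length(off)
    lapply(0:(2^m - 1), function(code) {
        A <- matrix(0L, n, n)
        A[off] <- as.integer(intToBits(code))[seq_len(m)]
        A
    })
}

# permutation-search triad isomorphism, independent of canonical codes
perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
triadIso <- function(A, B) {
    for (k in seq_len(nrow(perms3))) {
        p <- perms3[k, ]
        if (all(A[p, p] == B)) return(TRUE)
    }
    FALSE
}

# count triads of `graph` isomorphic to representative `rep` by brute force
naiveTriadCount <- function(A, rep) {
    n <- nrow(A)
    if (n < 3) return(0L)
    cnt <- 0L
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
        if (triadIso(A[tri, tri], rep)) cnt <- cnt + 1L
    }
    cnt
}

# random annotation on a small lattice (direct set sampling, no simulator)
randomAnnotation <- function(spec, nCells) {
    np <- spec@rows * spec@cols
    ids <- seq_len(nCells)
    somaPat <- sample.int(np, nCells, replace = TRUE)
    ctr <- hexCenter(spec, somaPat)
    dend <- lapply(ids, function(i)
        sort(unique(c(somaPat[i], sample.int(np, sample(0:3, 1))))))
    axon <- lapply(ids, function(i) sort(sample.int(np, sample(1:6, 1))))
    names(dend) <- names(axon) <- as.character(ids)
    circuitAnnotation(
        somata = data.frame(cell_id = ids, x_um = ctr[, 1], y_um = ctr[, 2],
                            soma_pattern = somaPat),
        dendrites = dend, axons = axon, lattice = spec)
}

# quadratic-time reference for the contact rule
bruteForceEdges <- function(annotation) {
    ids <- cellIds(annotation)
    key <- as.character(ids)
    out <- data.frame(from = integer(), to = integer())
    for (i in key) for (j in key) {
        if (i == j) next
        if (length(intersect(axonPatterns(annotation)[[i]],
                             dendritePatterns(annotation)[[j]])))
            out <- rbind(out, data.frame(from = as.integer(i),
                                         to = as.integer(j)))
    }
    out[order(out$from, out$to), , drop = FALSE]
}
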