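#' Construct a connectivity graph from node and edge tables
#'
#' @param nodes integer vector of cell ids (isolated nodes allowed).
#' @param edges data.frame with columns \code{from}, \code{to} and optionally
#'   \code{n_contacts}.
#' @param evidence optional list of contact-pattern ids, parallel to the edge
#'   rows.
#' @return a \linkS4class{ConnectivityGraph}, edges sorted by (from, to).
#' @export
connectivityGraph <- function(nodes, edges = data.frame(from = integer(),
                                                        to = integer()),
                              evidence = list()) {
    nodes <- as.integer(nodes)
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    if (is.null(edges$n_contacts))
        edges$n_contacts <- rep(1L, nrow(edges))
    o <- order(edges$from, edges$to)
    edges <- edges[o, c("from", "to", "n_contacts"), drop = FALSE]
    rownames(edges) <- NULL
    if (length(evidence)) evidence <- evidence[o]
    new("ConnectivityGraph", nodes = sort(nodes), edges = edges,
        evidence = evidence)
}

#' Construct a circuit annotation from cell component tables
#'
#' @param somata data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um} and optionally \code{soma_pattern} (computed from the
#'   position when absent).
#' @param dendrites,axons named lists (by cell id as character) of integer
#'   pattern-id vectors.
#' @param lattice the \linkS4class{LatticeSpec} the ids refer to.
#' @param axonPaths optional ordered walk paths (for rendering).
#' @param colors optional per-cell color matrix.
#' @return a \linkS4class{CircuitAnnotation}.
#' @export
circuitAnnotation <- function(somata, dendrites, axons, lattice,
                              axonPaths = list(),
                              colors = matrix(numeric(), 0, 0)) {
    if (is.null(somata$soma_pattern))
        somata$soma_pattern <- pointToPattern(lattice, somata$x_um,
                                              somata$y_um)
    somata$cell_id <- as.integer(somata$cell_id)
    key <- as.character(somata$cell_id)
    dendrites <- lapply(dendrites, function(x) sort(as.integer(x)))
    axons <- lapply(axons, function(x) sort(as.integer(x)))
    new("CircuitAnnotation", somata = somata, dendrites = dendrites[key],
        axons = axons[key], axonPaths = axonPaths, colors = colors,
        lattice = lattice)
}

#' Reconstruct the directed connectome from pattern co-occupancy
#'
#' The contact rule of the micropattern platform: cell i is presynaptic to
#' cell j (edge i -> j) whenever i's axon and j's dendrites occupy at least
#' one common pattern. All synapses form inside patterns, so shared pattern
#' occupancy is the complete connectivity evidence. Autapses (a cell's own
#' axon meeting its own dendrites) are excluded by default; multiple shared
#' patterns collapse into one unweighted edge with the contact count and
#' pattern ids kept as evidence. Cells with no contacts remain as isolated
#' nodes.
#'
#' @param annotation a \linkS4class{CircuitAnnotation}.
#' @param keepSelfLoops retain autaptic edges (default \code{FALSE}).
#' @return a \linkS4class{ConnectivityGraph}.
#' @examples
#' spec <- LatticeSpec(55, 70, rows = 4, cols = 4)
#' sim <- simulateCircuit(spec, SimulationParams(nCells = 12, seed = 2))
#' buildGraph(sim$annotation)
#' @export
buildGraph <- function(annotation, keepSelfLoops = FALSE) {
    stopifnot(is(annotation, "CircuitAnnotation"))
    validObject(annotation)
    ids <- cellIds(annotation)
    key <- as.character(ids)
    dend <- annotation@dendrites[key]
    axon <- annotation@axons[key]

    ## inverted index: pattern id -> indices of cells with a dendrite there
    dendIdx <- split(rep(seq_along(ids), lengths(dend)),
                     unlist(dend, use.names = FALSE))

    from <- integer(); to <- integer(); nc <- integer()
    evidence <- list()
    for (i in seq_along(ids)) {
        hits <- unlist(dendIdx[as.character(axon[[i]])], use.names = FALSE)
        if (!length(hits)) next
        for (j in unique(hits)) {
            if (j == i && !keepSelfLoops) next
            ev <- intersect(axon[[i]], dend[[j]])
            from <- c(from, ids[i]); to <- c(to, ids[j])
            nc <- c(nc, length(ev))
            evidence[[length(evidence) + 1L]] <- ev
        }
    }
    connectivityGraph(nodes = ids,
                      edges = data.frame(from = from, to = to,
                                         n_contacts = nc),
                      evidence = evidence)
}

#' Decompose a graph into network segments and isolated nodes
#'
#' Segments are the weakly connected components of size two or more (edge
#' direction ignored), ordered by decreasing size with ties broken by the
#' smallest member id; the remaining nodes are isolated.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @return list with \code{segments} (list of sorted integer id vectors) and
#'   \code{isolated} (sorted integer ids).
#' @export
graphComponents <- function(graph) {
    stopifnot(is(graph, "ConnectivityGraph"))
    ids <- nodeIds(graph)
    comp <- seq_along(ids)
    names(comp) <- as.character(ids)
    e <- edgeTable(graph)
    ## union-find over the undirected skeleton
    find <- function(i) {
        while (comp[i] != i) {
            comp[i] <<- comp[comp[i]]
            i <- comp[i]
        }
        i
    }
    if (nrow(e)) {
        ia <- match(e$from, ids); ib <- match(e$to, ids)
        for (k in seq_len(nrow(e))) {
            ra <- find(ia[k]); rb <- find(ib[k])
            if (ra != rb) comp[ra] <- rb
        }
    }
    root <- vapply(seq_along(ids), find, integer(1))
    groups <- split(ids, root)
    sizes <- lengths(groups)
    segs <- groups[sizes >= 2L]
    if (length(segs)) {
        segs <- lapply(segs, sort)
        o <- order(-lengths(segs), vapply(segs, min, integer(1)))
        segs <- unname(segs[o])
    } else segs <- list()
    list(segments = segs,
         isolated = sort(unlist(groups[sizes == 1L], use.names = FALSE)))
}

#' Extract the induced subgraph on a node subset
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @param nodes ids of the nodes to keep.
#' @return a \linkS4class{ConnectivityGraph} on \code{nodes}.
#' @export
inducedSubgraph <- function(graph, nodes) {
    stopifnot(all(nodes %in% nodeIds(graph)))
    e <- edgeTable(graph)
    keep <- e$from %in% nodes & e$to %in% nodes
    connectivityGraph(nodes = nodes, edges = e[keep, , drop = FALSE],
                      evidence = if (length(graph@evidence))
                          graph@evidence[keep] else list())
}
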