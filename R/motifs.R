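## Three-node motif census. A labeled triad is encoded as a 6-bit integer
## over the ordered pairs (1,2),(1,3),(2,1),(2,3),(3,1),(3,2) with weights
## 1,2,4,8,16,32; the canonical code of a triad is the minimum code over the
## six node permutations. Brute force over all 64 labeled triads yields 16
## isomorphism classes, of which 13 are weakly connected - the motif
## alphabet. Class ids order the connected classes by ascending edge count
## then canonical code, and are then remapped so the feedforward triangle is
## class 5 and the 3-cycle (feedback) class 6, the two conventional anchors.

.motifCache <- new.env(parent = emptyenv())

.permutations3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                        c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

.codeToAdj <- function(code) {
    bits <- as.integer(intToBits(code))[1:6]
    A <- matrix(0L, 3, 3)
    A[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] <- bits
    A
}

.adjToCode <- function(A) {
    sum(A[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] *
        c(1L, 2L, 4L, 8L, 16L, 32L))
}

.canonicalCode <- function(A) {
    min(apply(.permutations3, 1, function(p) .adjToCode(A[p, p])))
}

.triadTables <- function() {
    if (!is.null(.motifCache$tables)) return(.motifCache$tables)
    canon <- integer(64)
    connected <- logical(64)
    nedges <- integer(64)
    for (code in 0:63) {
        A <- .codeToAdj(code)
        canon[code + 1L] <- .canonicalCode(A)
        nedges[code + 1L] <- sum(A)
        ## weak connectivity via undirected reachability
        R <- ((A + t(A)) > 0) | diag(3) > 0
        R <- (R %*% R %*% R) > 0
        connected[code + 1L] <- all(R[1, ])
    }
    reps <- sort(unique(canon))
    classes <- data.frame(canonical_code = reps,
                          n_edges = nedges[reps + 1L],
                          connected = connected[reps + 1L])
    cc <- classes[classes$connected, ]
    cc <- cc[order(cc$n_edges, cc$canonical_code), ]
    ## anchor the two conventional classes: feedforward triangle at 5,
    ## feedback cycle at 6; remaining classes keep their relative order
    ffl <- .canonicalCode(matrix(c(0, 1, 1, 0, 0, 1, 0, 0, 0), 3, 3,
                                 byrow = TRUE))
    cyc <- .canonicalCode(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3,
                                 byrow = TRUE))
    ord <- cc$canonical_code
    rest <- ord[!ord %in% c(ffl, cyc)]
    ord <- append(rest, c(ffl, cyc), after = 4L)
    cc <- cc[match(ord, cc$canonical_code), ]
    cc$class_id <- seq_len(nrow(cc))
    rownames(cc) <- NULL

    ## lookup: labeled 6-bit code -> class id (NA for disconnected)
    lut <- rep(NA_integer_, 64)
    m <- match(canon, cc$canonical_code)
    lut[!is.na(m)] <- cc$class_id[m[!is.na(m)]]
    .motifCache$tables <- list(
        classes = cc[, c("class_id", "canonical_code", "n_edges")],
        all_classes = classes, lut = lut)
    .motifCache$tables
}

#' The 13 connected three-node motif classes
#'
#' Brute-force enumeration of all 64 labeled three-node digraphs (each
#' unordered node pair in one of four states: none, forward, backward,
#' reciprocal), grouped into isomorphism classes under the six node
#' permutations. Sixteen classes exist; the 13 whose underlying undirected
#' graph is connected form the motif alphabet. Class 5 is the feedforward
#' triangle (A->B, B->C, A->C) and class 6 the feedback cycle (A->B->C->A).
#'
#' @return data.frame with columns \code{class_id} (1-13),
#'   \code{canonical_code} (minimal 6-bit adjacency signature) and
#'   \code{n_edges}; the full 16-class table is attached as attribute
#'   \code{"all_classes"}.
#' @examples
#' triadClasses()
#' @export
triadClasses <- function() {
    t <- .triadTables()
    out <- t$classes
    attr(out, "all_classes") <- t$all_classes
    out
}

#' Classify a single triad
#'
#' @param A a 3 x 3 0/1 adjacency matrix with zero diagonal
#'   (\code{A[i, j] = 1} for edge i -> j).
#' @return the motif class id (1-13), or \code{NA} when the triad's
#'   underlying undirected graph is disconnected.
#' @examples
#' classifyTriad(matrix(c(0, 1, 1, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE))
#' @export
classifyTriad <- function(A) {
    A <- (A != 0) * 1L
    if (!identical(dim(A), c(3L, 3L)))
        stop("A must be a 3 x 3 adjacency matrix")
    if (any(diag(A) != 0))
        stop("invalid subgraph: nonzero diagonal (self-loops)")
    .triadTables()$lut[.adjToCode(A) + 1L]
}

#' Triad census of a connectome
#'
#' Classifies every induced three-node subgraph of the directed graph into
#' the 13 connected motif classes. Induced means all edges among the triplet
#' count. Complexity is O(N^3) over the C(N, 3) triplets, appropriate for the
#' tens-of-nodes networks this platform produces.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @return list with \code{counts} (integer vector, names 1-13),
#'   \code{frequencies} (counts normalized by connected-triad total, all zero
#'   when none), \code{n_disconnected} and \code{n_triads} (= C(N, 3)).
#' @examples
#' g <- connectivityGraph(1:4, data.frame(from = c(1, 1, 2, 3),
#'                                        to   = c(2, 3, 3, 4)))
#' motifProfile(g)$counts
#' @export
motifProfile <- function(graph) {
    stopifnot(is(graph, "ConnectivityGraph"))
    lut <- .triadTables()$lut
    A <- .adjMatrix(graph) * 1L
    n <- nrow(A)
    counts <- integer(13)
    names(counts) <- as.character(1:13)
    if (n < 3) {
        return(list(counts = counts, frequencies = counts * 0,
                    n_disconnected = 0L, n_triads = 0L))
    }
    tri <- utils::combn(n, 3L)
    i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
    code <- A[cbind(i, j)] + 2L * A[cbind(i, k)] + 4L * A[cbind(j, i)] +
        8L * A[cbind(j, k)] + 16L * A[cbind(k, i)] + 32L * A[cbind(k, j)]
    cls <- lut[code + 1L]
    tab <- tabulate(cls[!is.na(cls)], nbins = 13L)
    counts[] <- tab
    total <- sum(tab)
    list(counts = counts,
         frequencies = if (total) counts / total else counts * 0,
         n_disconnected = ncol(tri) - total,
         n_triads = ncol(tri))
}
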