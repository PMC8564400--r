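## Shortest-path machinery for unweighted directed graphs: breadth-first
## search from every source with shortest-path counting (sigma) accumulated
## along BFS layers. Betweenness uses the pair-decomposition
##   sigma_st(n) = sigma_sn * sigma_nt  when d(s,n) + d(n,t) = d(s,t)
## which follows from counting shortest s->t paths through n.

## dense adjacency in node order; nodes indexed 1..N internally
.adjMatrix <- function(graph) {
    ids <- nodeIds(graph)
    n <- length(ids)
    A <- matrix(FALSE, n, n)
    e <- edgeTable(graph)
    if (nrow(e))
        A[cbind(match(e$from, ids), match(e$to, ids))] <- TRUE
    A
}

#' Shortest directed path lengths and path counts
#'
#' Breadth-first search from every node of the unweighted directed graph.
#' \code{d[s, t]} is the hop count of the shortest directed path s -> t
#' (\code{Inf} when t is unreachable, 0 on the diagonal); \code{sigma[s, t]}
#' is the number of distinct shortest s -> t paths (0 when unreachable).
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @return list with matrices \code{d} and \code{sigma}, dimnames = node ids.
#' @export
shortestPaths <- function(graph) {
    stopifnot(is(graph, "ConnectivityGraph"))
    A <- .adjMatrix(graph)
    n <- nrow(A)
    out <- lapply(seq_len(n), function(i) which(A[i, ]))
    d <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        d[s, s] <- 0
        sigma[s, s] <- 1
        frontier <- s
        depth <- 0
        while (length(frontier)) {
            depth <- depth + 1
            nxt <- integer()
            for (v in frontier) {
                for (w in out[[v]]) {
                    if (is.infinite(d[s, w])) {
                        d[s, w] <- depth
                        nxt <- c(nxt, w)
                    }
                    if (d[s, w] == depth)
                        sigma[s, w] <- sigma[s, w] + sigma[s, v]
                }
            }
            frontier <- unique(nxt)
        }
    }
    ids <- as.character(nodeIds(graph))
    dimnames(d) <- dimnames(sigma) <- list(ids, ids)
    list(d = d, sigma = sigma)
}

#' Per-node degree, eccentricity and centrality metrics
#'
#' For each node n of the directed, unweighted connectome:
#' \describe{
#'   \item{k_in, k_out}{number of edges into / out of n.}
#'   \item{eccentricity}{max over reachable m of d(n, m); 0 for a node that
#'     reaches no other node.}
#'   \item{closeness}{R(n) / sum of d(n, m) over the R(n) nodes reachable
#'     from n; 0 for an isolated node (or any node reaching nothing). A node
#'     whose whole reachable set sits at distance 1 scores exactly 1.}
#'   \item{betweenness}{sum over ordered pairs s != n != t with at least one
#'     shortest path of sigma_st(n) / sigma_st, directed, endpoint-excluding
#'     and unnormalized.}
#' }
#' Summing over unreachable pairs is excluded throughout: the graphs this
#' package targets are fragmented, and a strict all-pairs denominator would
#' zero the closeness of every node that does not reach the whole network.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @param stats optional precomputed \code{\link{shortestPaths}} result.
#' @return data.frame with columns \code{cell_id}, \code{k_in}, \code{k_out},
#'   \code{eccentricity}, \code{closeness}, \code{betweenness}.
#' @examples
#' g <- connectivityGraph(1:3, data.frame(from = c(1, 2), to = c(2, 3)))
#' nodeMetrics(g)  # node 2 carries the single 1->3 shortest path
#' @export
nodeMetrics <- function(graph, stats = shortestPaths(graph)) {
    ids <- nodeIds(graph)
    n <- length(ids)
    e <- edgeTable(graph)
    kin <- kout <- integer(n)
    if (nrow(e)) {
        kin <- tabulate(match(e$to, ids), nbins = n)
        kout <- tabulate(match(e$from, ids), nbins = n)
    }
    d <- stats$d; sigma <- stats$sigma
    ecc <- clo <- btw <- numeric(n)
    for (i in seq_len(n)) {
        di <- d[i, -i]
        reach <- is.finite(di)
        ecc[i] <- if (any(reach)) max(di[reach]) else 0
        clo[i] <- if (any(reach)) sum(reach) / sum(di[reach]) else 0
    }
    if (n >= 3) {
        for (i in seq_len(n)) {
            ## shortest s->t paths through i: d(s,i) + d(i,t) == d(s,t)
            ds <- d[-i, i, drop = FALSE]
            dt <- d[i, -i, drop = FALSE]
            dst <- d[-i, -i, drop = FALSE]
            on <- outer(ds[, 1], dt[1, ], `+`) == dst & is.finite(dst)
            diag(on) <- FALSE  # s == t
            if (!any(on)) next
            num <- outer(sigma[-i, i], sigma[i, -i])
            btw[i] <- sum((num / sigma[-i, -i])[on])
        }
    }
    data.frame(cell_id = ids, k_in = kin, k_out = kout, eccentricity = ecc,
               closeness = clo, betweenness = btw)
}

#' Whole-network summary statistics
#'
#' \code{density} follows the edges-per-node convention |E| / N; the standard
#' directed density |E| / (N (N - 1)) is reported alongside as
#' \code{density_std}. Radius and diameter are the minimum and maximum
#' eccentricity over nodes with finite positive eccentricity (\code{NA} when
#' no node reaches another).
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @param metrics optional precomputed \code{\link{nodeMetrics}}.
#' @return list with \code{n_nodes}, \code{n_edges}, \code{density},
#'   \code{density_std}, \code{radius}, \code{diameter}.
#' @export
networkSummary <- function(graph, metrics = nodeMetrics(graph)) {
    n <- nNodes(graph)
    if (n == 0L) stop("summary undefined for an empty graph")
    m <- nEdges(graph)
    pos <- metrics$eccentricity[metrics$eccentricity > 0]
    list(n_nodes = n, n_edges = m,
         density = m / n,
         density_std = if (n > 1) m / (n * (n - 1)) else 0,
         radius = if (length(pos)) min(pos) else NA_real_,
         diameter = if (length(pos)) max(pos) else NA_real_)
}

#' Classify hub roles of nodes
#'
#' Tags follow the hub taxonomy used for micropatterned cultures:
#' \describe{
#'   \item{integrator_hub}{k_in >= \code{degHi} (integrates input from many
#'     neighbours).}
#'   \item{distributor_hub}{k_out >= \code{degHi}.}
#'   \item{pacemaker}{a distributor hub whose closeness centrality is at or
#'     above the \code{closenessQ} quantile - it can drive many neighbours
#'     while having short access to the rest of the network (driver cell).}
#'   \item{bottleneck}{positive betweenness at or above the
#'     \code{betweennessQ} quantile - the node carries many shortest paths.}
#'   \item{connector}{a bottleneck with k_out >= \code{degHi} - 1, linking
#'     network modules.}
#' }
#' Degree cut-offs of 4-5 and per-network quantiles reflect that hub
#' thresholds vary between networks; all are configurable.
#'
#' @param metrics a \code{\link{nodeMetrics}} data.frame.
#' @param degHi absolute in/out-degree threshold (default 5).
#' @param closenessQ,betweennessQ quantile levels (default 0.9).
#' @return \code{metrics} with an added character column \code{tags}
#'   (semicolon-separated, empty when untagged).
#' @export
classifyHubs <- function(metrics, degHi = 5L, closenessQ = 0.9,
                         betweennessQ = 0.9) {
    cq <- stats::quantile(metrics$closeness, closenessQ, names = FALSE)
    bq <- stats::quantile(metrics$betweenness, betweennessQ, names = FALSE)
    integ <- metrics$k_in >= degHi
    distr <- metrics$k_out >= degHi
    pace <- distr & metrics$closeness >= cq
    bott <- metrics$betweenness >= bq & metrics$betweenness > 0
    conn <- bott & metrics$k_out >= degHi - 1L
    tags <- vapply(seq_len(nrow(metrics)), function(i) {
        paste(c("integrator_hub", "distributor_hub", "pacemaker",
                "bottleneck", "connector")[
                  c(integ[i], distr[i], pace[i], bott[i], conn[i])],
              collapse = ";")
    }, character(1))
    metrics$tags <- tags
    metrics
}
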