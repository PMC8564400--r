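## File contracts. The occupancy table is the interface shared between
## manually segmented microscopy data and the simulator: one row per
## (cell, component, pattern) with component in {soma, dendrite, axon},
## pattern_id -1 for OUTSIDE, and soma coordinates on soma rows.

#' Read an occupancy annotation table
#'
#' Expected CSV header: \code{cell_id, component, pattern_id, x_um, y_um}.
#' Exactly one \code{soma} row per cell (carrying the soma position;
#' \code{pattern_id = -1} when the soma lies in the repulsive gap) plus one
#' row per dendrite-occupied and axon-occupied pattern. Malformed content is
#' rejected with the offending line number.
#'
#' @param path CSV file path.
#' @param spec the \linkS4class{LatticeSpec} the pattern ids refer to.
#' @return a \linkS4class{CircuitAnnotation}.
#' @export
readOccupancyTable <- function(path, spec) {
    stopifnot(is(spec, "LatticeSpec"))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "component", "pattern_id", "x_um", "y_um")
    if (!all(need %in% names(df)))
        stop("occupancy table ", path, " is missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", "))
    line <- seq_len(nrow(df)) + 1L  # header is line 1
    bad <- !df$component %in% c("soma", "dendrite", "axon")
    if (any(bad))
        stop("unknown component ", dQuote(df$component[which(bad)[1]]),
             " at line ", line[which(bad)[1]])
    idnum <- suppressWarnings(as.integer(df$cell_id))
    if (any(is.na(idnum)))
        stop("non-integer cell_id at line ", line[which(is.na(idnum))[1]])
    df$cell_id <- idnum
    pat <- suppressWarnings(as.integer(df$pattern_id))
    if (any(is.na(pat)))
        stop("non-integer pattern_id at line ", line[which(is.na(pat))[1]])
    np <- spec@rows * spec@cols
    oob <- pat != -1L & (pat < 1L | pat > np)
    if (any(oob))
        stop("pattern_id out of bounds at line ", line[which(oob)[1]])
    soma <- df[df$component == "soma", ]
    if (anyDuplicated(soma$cell_id))
        stop("duplicate soma row for cell_id ",
             soma$cell_id[anyDuplicated(soma$cell_id)])
    known <- soma$cell_id
    other <- df[df$component != "soma", ]
    orphan <- !other$cell_id %in% known
    if (any(orphan))
        stop(other$component[which(orphan)[1]], " row for unknown cell_id ",
             other$cell_id[which(orphan)[1]], " at line ",
             line[df$component != "soma"][which(orphan)[1]])
    gapOut <- other$pattern_id == -1L
    if (any(gapOut))
        stop("dendrite/axon rows must name a pattern (line ",
             line[df$component != "soma"][which(gapOut)[1]], ")")
    key <- as.character(known)
    pick <- function(comp)
        lapply(key, function(k) {
            sort(unique(as.integer(
                other$pattern_id[other$component == comp &
                                 other$cell_id == as.integer(k)]))) })
    dend <- pick("dendrite"); axon <- pick("axon")
    names(dend) <- names(axon) <- key
    empty <- !lengths(dend) | !lengths(axon)
    if (any(empty))
        stop("cell ", key[which(empty)[1]],
             " has no dendrite or no axon patterns")
    new("CircuitAnnotation",
        somata = data.frame(cell_id = known, x_um = soma$x_um,
                            y_um = soma$y_um,
                            soma_pattern = ifelse(soma$pattern_id == -1L,
                                                  NA_integer_,
                                                  soma$pattern_id)),
        dendrites = dend, axons = axon, axonPaths = list(),
        colors = matrix(numeric(), nrow = 0, ncol = 0), lattice = spec)
}

#' Write an occupancy annotation table
#'
#' @param annotation a \linkS4class{CircuitAnnotation}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeOccupancyTable <- function(annotation, path) {
    st <- somaTable(annotation)
    key <- as.character(st$cell_id)
    rows <- list(data.frame(
        cell_id = st$cell_id, component = "soma",
        pattern_id = ifelse(is.na(st$soma_pattern), -1L, st$soma_pattern),
        x_um = st$x_um, y_um = st$y_um))
    for (comp in c("dendrite", "axon")) {
        sets <- if (comp == "dendrite") annotation@dendrites[key]
                else annotation@axons[key]
        rows[[comp]] <- data.frame(
            cell_id = rep(st$cell_id, lengths(sets)),
            component = comp,
            pattern_id = unlist(sets, use.names = FALSE),
            x_um = NA_real_, y_um = NA_real_)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$cell_id, match(out$component,
                                        c("soma", "dendrite", "axon")),
                     out$pattern_id), ]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

.xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a connectivity graph
#'
#' \code{csv}: the Cytoscape-importable edge table
#' (\code{source_id, target_id, n_contact_patterns}). \code{sif}: one
#' \code{pre syn post} line per edge (isolated nodes as bare node lines).
#' \code{graphml}: nodes carry all metric columns as attributes. Output is
#' byte-stable for fixed inputs.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @param path output file path.
#' @param format one of \code{"csv"}, \code{"sif"}, \code{"graphml"}.
#' @param metrics optional \code{\link{nodeMetrics}} data.frame whose columns
#'   become GraphML node attributes.
#' @return invisibly, \code{path}.
#' @export
exportGraph <- function(graph, path, format = c("csv", "sif", "graphml"),
                        metrics = NULL) {
    format <- match.arg(format)
    e <- edgeTable(graph)
    if (format == "csv") {
        out <- data.frame(source_id = e$from, target_id = e$to,
                          n_contact_patterns = e$n_contacts)
        utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    } else if (format == "sif") {
        lines <- character()
        if (nrow(e)) lines <- sprintf("%d syn %d", e$from, e$to)
        linked <- unique(c(e$from, e$to))
        lone <- setdiff(nodeIds(graph), linked)
        writeLines(c(lines, sprintf("%d", lone)), path)
    } else {
        ids <- nodeIds(graph)
        con <- file(path, "w")
        on.exit(close(con))
        w <- function(...) writeLines(sprintf(...), con)
        w("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
        w("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
        attrCols <- character()
        if (!is.null(metrics)) {
            attrCols <- setdiff(names(metrics), "cell_id")
            for (i in seq_along(attrCols)) {
                type <- if (is.numeric(metrics[[attrCols[i]]])) "double"
                        else "string"
                w("  <key id=\"d%d\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
                  i, attrCols[i], type)
            }
        }
        w("  <graph id=\"G\" edgedefault=\"directed\">")
        for (n in ids) {
            if (length(attrCols)) {
                w("    <node id=\"n%d\">", n)
                row <- match(n, metrics$cell_id)
                for (i in seq_along(attrCols)) {
                    v <- metrics[[attrCols[i]]][row]
                    w("      <data key=\"d%d\">%s</data>", i,
                      .xmlEscape(format(v, scientific = FALSE)))
                }
                w("    </node>")
            } else w("    <node id=\"n%d\"/>", n)
        }
        if (nrow(e)) for (k in seq_len(nrow(e)))
            w("    <edge source=\"n%d\" target=\"n%d\"/>", e$from[k], e$to[k])
        w("  </graph>")
        w("</graphml>")
    }
    invisible(path)
}

#' Write the motif census as a CSV
#'
#' @param profile a \code{\link{motifProfile}} result.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeMotifProfile <- function(profile, path) {
    utils::write.csv(data.frame(class_id = 1:13,
                                count = as.integer(profile$counts),
                                frequency = as.numeric(profile$frequencies)),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
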