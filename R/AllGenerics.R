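#' @rdname ConnectivityGraph-class
#' @param object,x a package object
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname ConnectivityGraph-class
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname ConnectivityGraph-class
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname ConnectivityGraph-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname CircuitAnnotation-class
#' @export
setGeneric("somaTable", function(object) standardGeneric("somaTable"))

#' @rdname CircuitAnnotation-class
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname CircuitAnnotation-class
#' @export
setGeneric("dendritePatterns", function(object) standardGeneric("dendritePatterns"))

#' @rdname CircuitAnnotation-class
#' @export
setGeneric("axonPatterns", function(object) standardGeneric("axonPatterns"))

#' @rdname CircuitAnnotation-class
#' @export
setGeneric("latticeSpec", function(object) standardGeneric("latticeSpec"))

setMethod("nodeIds", "ConnectivityGraph", function(object) object@nodes)
setMethod("nNodes", "ConnectivityGraph", function(object) length(object@nodes))
setMethod("nEdges", "ConnectivityGraph", function(object) nrow(object@edges))
setMethod("edgeTable", "ConnectivityGraph", function(object) object@edges)

setMethod("somaTable", "CircuitAnnotation", function(object) object@somata)
setMethod("cellIds", "CircuitAnnotation", function(object) object@somata$cell_id)
setMethod("dendritePatterns", "CircuitAnnotation", function(object) object@dendrites)
setMethod("axonPatterns", "CircuitAnnotation", function(object) object@axons)
setMethod("latticeSpec", "CircuitAnnotation", function(object) object@lattice)

setMethod("show", "LatticeSpec", function(object) {
    d <- deriveDistances(object)
    cat(sprintf(paste0(
        "LatticeSpec: %d x %d flat-top honeycomb\n",
        "  L = %g um, D = %g um, spacing = %.2f um\n",
        "  l1 = %.2f um, l2 = %.2f um, r1 = %.2f um, r2 = %.2f um\n",
        "  origin = (%g, %g) um, rotation = %g deg\n"),
        object@rows, object@cols, object@edgeLength, object@gap, d$spacing,
        d$l1, d$l2, d$r1, d$r2, object@origin[1], object@origin[2],
        object@rotation))
    invisible(NULL)
})

setMethod("show", "SimulationParams", function(object) {
    cat(sprintf(paste0(
        "SimulationParams: %d cells, seed %d\n",
        "  P(soma inside pattern) = %.3f\n",
        "  RPA count: P{1,2} = %.3f; axon coverage mean = %.2f patterns\n",
        "  P(synapse | contact) = %.2f, %d color channels\n"),
        object@nCells, object@seed, object@pSomaInside,
        sum(object@rpaCountDist[1:min(2, length(object@rpaCountDist))]),
        sum(seq_along(object@axonCoverageDist) * object@axonCoverageDist),
        object@pSynapseGivenContact, object@nColors))
    invisible(NULL)
})

setMethod("show", "CircuitAnnotation", function(object) {
    n <- nrow(object@somata)
    inside <- sum(!is.na(object@somata$soma_pattern))
    cat(sprintf(paste0(
        "CircuitAnnotation: %d cells on a %d x %d lattice\n",
        "  somata inside patterns: %d (%.1f%%)\n",
        "  RPAs/cell: median %s; axon coverage/cell: median %s patterns\n"),
        n, object@lattice@rows, object@lattice@cols, inside,
        if (n) 100 * inside / n else 0,
        if (n) stats::median(lengths(object@dendrites)) else "NA",
        if (n) stats::median(lengths(object@axons)) else "NA"))
    invisible(NULL)
})

setMethod("show", "ConnectivityGraph", function(object) {
    cat(sprintf("ConnectivityGraph: %d nodes, %d directed edges\n",
                nNodes(object), nEdges(object)))
    invisible(NULL)
})

setMethod("show", "RegistrationResult", function(object) {
    cat(sprintf(paste0(
        "RegistrationResult: %d detected pattern centers\n",
        "  rotation = %.3f deg, scale = %g px/um\n",
        "  score range = [%.3f, %.3f]\n"),
        nrow(object@centers), object@rotation, object@pxPerUm,
        if (nrow(object@centers)) min(object@centers$score) else NA,
        if (nrow(object@centers)) max(object@centers$score) else NA))
    invisible(NULL)
})
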