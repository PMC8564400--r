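#' @import methods
NULL

#' Honeycomb micropattern lattice geometry
#'
#' An S4 class describing a rectangular array of flat-top hexagonal
#' cell-permissive patterns. Hexagons of edge length \code{edgeLength} (the
#' symbol L, in micrometres) are separated by a gap \code{gap} (D, in
#' micrometres) measured as the perpendicular distance between the facing flat
#' edges of adjacent hexagons. Neighbouring hexagons are adjacent across flat
#' edges, so the centre-to-centre spacing is \code{sqrt(3) * L + D}.
#'
#' Patterns are indexed two ways: by axial coordinates \code{(q, r)} on the
#' hexagonal lattice, and by a 1-based serial \code{pattern_id} enumerated
#' row-major over the \code{rows} x \code{cols} array (see
#' \code{\link{patternTable}}). Positions off every pattern (the repulsive gap)
#' are the OUTSIDE sentinel, represented as \code{NA}.
#'
#' @slot edgeLength hexagon edge length L in micrometres (> 0).
#' @slot gap inter-hexagon gap D in micrometres (>= 0).
#' @slot origin numeric(2), micrometre position of the centre of pattern
#'   \code{(q = 0, r = 0)}.
#' @slot rotation lattice rotation in degrees, counter-clockwise about
#'   \code{origin}.
#' @slot rows,cols array extent (positive integers).
#'
#' @seealso \code{\link{LatticeSpec}}, \code{\link{deriveDistances}},
#'   \code{\link{hexCenter}}, \code{\link{pointToPattern}}
#' @name LatticeSpec-class
#' @rdname LatticeSpec-class
#' @exportClass LatticeSpec
setClass("LatticeSpec",
    slots = c(
        edgeLength = "numeric",
        gap        = "numeric",
        origin     = "numeric",
        rotation   = "numeric",
        rows       = "integer",
        cols       = "integer"
    )
)

setValidity("LatticeSpec", function(object) {
    msg <- character()
    if (length(object@edgeLength) != 1 || !is.finite(object@edgeLength) ||
        object@edgeLength <= 0)
        msg <- c(msg, "edgeLength (L) must be a single positive number")
    if (length(object@gap) != 1 || !is.finite(object@gap) || object@gap < 0)
        msg <- c(msg, "gap (D) must be a single non-negative number")
    if (length(object@origin) != 2 || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be a finite numeric of length 2")
    if (length(object@rotation) != 1 || !is.finite(object@rotation))
        msg <- c(msg, "rotation must be a single finite number")
    if (length(object@rows) != 1 || is.na(object@rows) || object@rows < 1)
        msg <- c(msg, "rows must be a positive integer")
    if (length(object@cols) != 1 || is.na(object@cols) || object@cols < 1)
        msg <- c(msg, "cols must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' Simulation parameters for synthetic micropatterned circuits
#'
#' Defaults reproduce the occupancy statistics of mature (DIV 21) hippocampal
#' cultures on L = 55 um / D = 70 um honeycomb patterns: 64.3% of somata land
#' inside a pattern; 76.2% of neurons hold one or two receptive pattern areas
#' (RPAs, the patterns occupied by a cell's dendrites); axons cover on average
#' 6.7 patterns, ranging 1-25 with 80.8% of cells below 10; and over 90% of
#' axon-dendrite co-occupancies form a synapse.
#'
#' @slot nCells number of neurons to place.
#' @slot pSomaInside probability a soma lies inside a pattern (else in the
#'   repulsive gap).
#' @slot rpaCountDist probability vector over RPA counts 1, 2, ... .
#' @slot axonCoverageDist probability vector over axon pattern coverage
#'   1..25.
#' @slot pSynapseGivenContact probability that an axon-dendrite co-occupancy
#'   becomes a synaptic edge in the ground-truth graph.
#' @slot nColors number of fluorophore channels for stochastic multicolor
#'   labeling.
#' @slot minSomaSep minimum centre-to-centre soma separation in micrometres.
#' @slot seed integer seed governing all randomness (named substreams are
#'   derived from it).
#'
#' @seealso \code{\link{SimulationParams}}, \code{\link{simulateCircuit}}
#' @name SimulationParams-class
#' @rdname SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
    slots = c(
        nCells               = "integer",
        pSomaInside          = "numeric",
        rpaCountDist         = "numeric",
        axonCoverageDist     = "numeric",
        pSynapseGivenContact = "numeric",
        nColors              = "integer",
        minSomaSep           = "numeric",
        seed                 = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character()
    okProb <- function(p) length(p) == 1 && is.finite(p) && p >= 0 && p <= 1
    if (length(object@nCells) != 1 || is.na(object@nCells) ||
        object@nCells < 1)
        msg <- c(msg, "nCells must be a positive integer")
    if (!okProb(object@pSomaInside))
        msg <- c(msg, "pSomaInside must be a probability in [0, 1]")
    if (!okProb(object@pSynapseGivenContact))
        msg <- c(msg, "pSynapseGivenContact must be a probability in [0, 1]")
    for (nm in c("rpaCountDist", "axonCoverageDist")) {
        p <- slot(object, nm)
        if (!length(p) || any(!is.finite(p)) || any(p < 0) ||
            abs(sum(p) - 1) > 1e-8)
            msg <- c(msg, sprintf("%s must be a normalized probability vector",
                                  nm))
    }
    if (length(object@nColors) != 1 || is.na(object@nColors) ||
        object@nColors < 1)
        msg <- c(msg, "nColors must be a positive integer")
    if (length(object@minSomaSep) != 1 || !is.finite(object@minSomaSep) ||
        object@minSomaSep < 0)
        msg <- c(msg, "minSomaSep must be non-negative")
    if (length(object@seed) != 1 || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Per-cell pattern occupancy of a micropatterned circuit
#'
#' The file-level contract shared between real (manually segmented) and
#' simulated data: each neuron has a soma position, the set of patterns its
#' dendrites occupy (its receptive pattern areas, RPAs), and the set of
#' patterns its axon occupies. Pattern membership is stored by serial
#' \code{pattern_id} (see \code{\link{patternTable}}); a soma in the repulsive
#' gap has \code{soma_pattern = NA} (OUTSIDE).
#'
#' @slot somata data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{soma_pattern} (integer pattern id or \code{NA}).
#' @slot dendrites named list (by cell id) of integer pattern-id vectors;
#'   non-empty for every cell.
#' @slot axons named list (by cell id) of integer pattern-id vectors;
#'   non-empty for every cell.
#' @slot axonPaths named list of the ordered pattern-id walks that generated
#'   each axon territory (simulated data only; may be empty). Used for
#'   rendering axon traces.
#' @slot colors numeric matrix, one row per cell, one column per fluorophore
#'   channel (may have zero rows for unlabeled data).
#' @slot lattice the \linkS4class{LatticeSpec} the pattern ids refer to.
#'
#' @seealso \code{\link{readOccupancyTable}}, \code{\link{simulateCircuit}},
#'   \code{\link{buildGraph}}
#' @name CircuitAnnotation-class
#' @rdname CircuitAnnotation-class
#' @exportClass CircuitAnnotation
setClass("CircuitAnnotation",
    slots = c(
        somata    = "data.frame",
        dendrites = "list",
        axons     = "list",
        axonPaths = "list",
        colors    = "matrix",
        lattice   = "LatticeSpec"
    )
)

setValidity("CircuitAnnotation", function(object) {
    msg <- character()
    s <- object@somata
    need <- c("cell_id", "x_um", "y_um", "soma_pattern")
    if (!all(need %in% names(s)))
        return(paste("somata must have columns", paste(need, collapse = ", ")))
    ids <- s$cell_id
    if (anyDuplicated(ids))
        msg <- c(msg, "cell_id values must be unique")
    key <- as.character(ids)
    if (!setequal(names(object@dendrites), key) ||
        !setequal(names(object@axons), key))
        msg <- c(msg, "dendrites and axons must be named by every cell_id")
    else {
        if (any(!lengths(object@dendrites[key])))
            msg <- c(msg, "every cell must occupy at least one dendrite pattern")
        if (any(!lengths(object@axons[key])))
            msg <- c(msg, "every cell must occupy at least one axon pattern")
        np <- object@lattice@rows * object@lattice@cols
        pat <- c(unlist(object@dendrites, use.names = FALSE),
                 unlist(object@axons, use.names = FALSE))
        if (length(pat) && (any(is.na(pat)) || any(pat < 1) || any(pat > np)))
            msg <- c(msg, "dendrite/axon pattern ids must be in-bounds")
    }
    if (nrow(object@colors) && nrow(object@colors) != nrow(s))
        msg <- c(msg, "colors must have one row per cell (or zero rows)")
    if (length(msg)) msg else TRUE
})

#' Directed connectome of a micropatterned circuit
#'
#' A simple directed graph over cell ids: an edge (pre -> post) means the
#' presynaptic cell's axon and the postsynaptic cell's dendrites co-occupy at
#' least one pattern. \code{\link{buildGraph}} excludes self-loops (autapses)
#' unless explicitly retained; multiple shared patterns fold into one edge,
#' with the shared pattern ids retained as edge evidence.
#'
#' @slot nodes integer vector of cell ids (isolated cells included).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{n_contacts}.
#' @slot evidence list, parallel to the rows of \code{edges}, of the pattern
#'   ids where the contact occurred (may be empty for graphs built without
#'   evidence).
#'
#' @seealso \code{\link{buildGraph}}, \code{\link{connectivityGraph}},
#'   \code{\link{nodeMetrics}}, \code{\link{motifProfile}}
#' @name ConnectivityGraph-class
#' @rdname ConnectivityGraph-class
#' @exportClass ConnectivityGraph
setClass("ConnectivityGraph",
    slots = c(
        nodes    = "integer",
        edges    = "data.frame",
        evidence = "list"
    )
)

setValidity("ConnectivityGraph", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node ids must be unique")
    e <- object@edges
    if (!all(c("from", "to") %in% names(e)))
        return("edges must have columns from, to")
    if (nrow(e)) {
        if (anyDuplicated(paste(e$from, e$to)))
            msg <- c(msg, "duplicate edges are not allowed")
        if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
            msg <- c(msg, "edge endpoints must be graph nodes")
    }
    if (length(object@evidence) && length(object@evidence) != nrow(e))
        msg <- c(msg, "evidence must be parallel to the edge table")
    if (length(msg)) msg else TRUE
})

#' Result of registering a pattern array in a raster image
#'
#' @slot rotation estimated lattice rotation in degrees, folded into
#'   [-30, 30) by the 60-degree symmetry of the honeycomb.
#' @slot centers data.frame of accepted template-matching peaks, sorted by
#'   descending correlation score: columns \code{row_px}, \code{col_px}
#'   (sub-pixel, 1-based), \code{score} in [-1, 1], axial indices \code{q},
#'   \code{r}, serial \code{pattern_id}, and \code{resid_px} (distance to the
#'   fitted lattice position).
#' @slot pxPerUm pixels per micrometre of the analysed image.
#' @slot originPx numeric(2): (row, col) pixel position of the fitted lattice
#'   origin, i.e. the centre of pattern (q = 0, r = 0). Together with
#'   \code{pxPerUm} this is the px-to-um transform (um +y axis is -row).
#'
#' @seealso \code{\link{detectPatterns}}, \code{\link{estimateRotation}}
#' @name RegistrationResult-class
#' @rdname RegistrationResult-class
#' @exportClass RegistrationResult
setClass("RegistrationResult",
    slots = c(
        rotation = "numeric",
        centers  = "data.frame",
        pxPerUm  = "numeric",
        originPx = "numeric"
    )
)

setValidity("RegistrationResult", function(object) {
    msg <- character()
    cen <- object@centers
    if (nrow(cen)) {
        if (any(cen$score > 1 + 1e-6) || any(cen$score < -1 - 1e-6))
            msg <- c(msg, "correlation scores must lie in [-1, 1]")
        if (is.unsorted(rev(cen$score)) && is.unsorted(-cen$score))
            msg <- c(msg, "centers must be sorted by descending score")
    }
    if (length(msg)) msg else TRUE
})
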