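## Flat-top honeycomb lattice: hexagons of edge L, adjacent across flat edges,
## separated by a perpendicular edge-to-edge gap D. Centre-to-centre spacing of
## adjacent hexagons is s = sqrt(3)*L + D. Axial coordinates (q, r) map to base
## (unrotated, origin-at-zero) Cartesian micrometres as
##   x = (sqrt(3)/2) * s * q,   y = s * (q/2 + r)
## so that all six shell-1 neighbours sit exactly s away.

#' Construct a honeycomb lattice specification
#'
#' @param edge_um hexagon edge length L in micrometres.
#' @param gap_um gap D between facing flat edges of adjacent hexagons, in
#'   micrometres.
#' @param rows,cols array extent.
#' @param origin micrometre position of the centre of pattern (q = 0, r = 0).
#' @param rotation lattice rotation in degrees (counter-clockwise).
#' @return a \linkS4class{LatticeSpec}.
#' @examples
#' spec <- LatticeSpec(edge_um = 55, gap_um = 70, rows = 10, cols = 10)
#' deriveDistances(spec)
#' @export
LatticeSpec <- function(edge_um, gap_um, rows = 10L, cols = 10L,
                        origin = c(0, 0), rotation = 0) {
    new("LatticeSpec", edgeLength = as.numeric(edge_um),
        gap = as.numeric(gap_um), origin = as.numeric(origin),
        rotation = as.numeric(rotation), rows = as.integer(rows),
        cols = as.integer(cols))
}

.spacing <- function(spec) sqrt(3) * spec@edgeLength + spec@gap

#' Closed-form distances of the honeycomb geometry
#'
#' All characteristic distances of the pattern array, in micrometres:
#' \describe{
#'   \item{apothem}{hexagon centre to flat edge, (sqrt(3)/2) L.}
#'   \item{spacing}{centre-to-centre distance of edge-adjacent hexagons,
#'     sqrt(3) L + D.}
#'   \item{l1}{centre of a hexagon to the closest edge of a nearest
#'     neighbouring hexagon, (sqrt(3)/2) L + D.}
#'   \item{l2}{centre of a hexagon to the farthest edge of a nearest
#'     neighbouring hexagon, (3 sqrt(3)/2) L + D.}
#'   \item{r1}{radius of a circle covering the full first ring of neighbours,
#'     spacing + L.}
#'   \item{r2}{radius of a circle covering the second ring as well,
#'     sqrt(3) spacing + L.}
#' }
#' For L = 55 and D = 70 the landmark distances are l1 = 117.6 um and
#' l2 = 212.89 um (117.6/212.8 at the 0.1 um truncation used in printed
#' pattern dimensions); for any L, l2 - l1 = sqrt(3) L, two apothems.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @return named list with the six distances.
#' @export
deriveDistances <- function(spec) {
    stopifnot(is(spec, "LatticeSpec"))
    validObject(spec)
    L <- spec@edgeLength
    s <- .spacing(spec)
    list(
        apothem = sqrt(3) / 2 * L,
        spacing = s,
        l1 = sqrt(3) / 2 * L + spec@gap,
        l2 = 3 * sqrt(3) / 2 * L + spec@gap,
        r1 = s + L,
        r2 = sqrt(3) * s + L
    )
}

## serial id <-> axial. Enumeration is row-major over the rows x cols array;
## column col holds axial q = col - 1, row holds r = row - 1 - q %/% 2 so the
## array is visually rectangular despite the half-spacing stagger of odd
## columns.
.axialToRowCol <- function(spec, q, r) {
    list(row = r + q %/% 2L + 1L, col = q + 1L)
}

.inBounds <- function(spec, q, r) {
    rc <- .axialToRowCol(spec, q, r)
    !is.na(q) & !is.na(r) &
        rc$col >= 1L & rc$col <= spec@cols &
        rc$row >= 1L & rc$row <= spec@rows
}

#' Convert between axial coordinates and serial pattern ids
#'
#' Pattern ids are 1-based and enumerate the rows x cols array row-major;
#' out-of-bounds axial coordinates (and NA) map to \code{NA}.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param q,r integer axial coordinates (vectorized).
#' @param id integer serial pattern ids (vectorized).
#' @return \code{axialToId}: integer ids; \code{idToAxial}: data.frame with
#'   columns \code{q}, \code{r}.
#' @export
axialToId <- function(spec, q, r) {
    q <- as.integer(q); r <- as.integer(r)
    rc <- .axialToRowCol(spec, q, r)
    ok <- .inBounds(spec, q, r)
    ifelse(ok, (rc$row - 1L) * spec@cols + rc$col, NA_integer_)
}

#' @rdname axialToId
#' @export
idToAxial <- function(spec, id) {
    id <- as.integer(id)
    bad <- !is.na(id) & (id < 1L | id > spec@rows * spec@cols)
    if (any(bad))
        stop("pattern id out of bounds: ", paste(id[bad], collapse = ", "))
    col <- (id - 1L) %% spec@cols + 1L
    row <- (id - 1L) %/% spec@cols + 1L
    q <- col - 1L
    data.frame(q = q, r = row - 1L - q %/% 2L)
}

## base-frame centres (no rotation/origin)
.axialToBaseXY <- function(spec, q, r) {
    s <- .spacing(spec)
    cbind(x = sqrt(3) / 2 * s * q, y = s * (q / 2 + r))
}

.applyFrame <- function(spec, xy) {
    th <- spec@rotation * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(xy %*% t(R), 2, spec@origin, `+`)
}

.removeFrame <- function(spec, x, y) {
    th <- spec@rotation * pi / 180
    x0 <- x - spec@origin[1]
    y0 <- y - spec@origin[2]
    cbind(x = cos(th) * x0 + sin(th) * y0,
          y = -sin(th) * x0 + cos(th) * y0)
}

#' Cartesian centre of a pattern
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param id serial pattern id(s); \code{NA} (the OUTSIDE sentinel) is an
#'   error.
#' @return numeric matrix with columns \code{x}, \code{y} (micrometres).
#' @export
hexCenter <- function(spec, id) {
    if (any(is.na(id)))
        stop("OUTSIDE (NA) has no pattern centre")
    ax <- idToAxial(spec, id)
    xy <- .applyFrame(spec, .axialToBaseXY(spec, ax$q, ax$r))
    colnames(xy) <- c("x", "y")
    xy
}

#' Table of all patterns in the array
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @return data.frame with columns \code{pattern_id}, \code{q}, \code{r},
#'   \code{center_x_um}, \code{center_y_um}.
#' @export
patternTable <- function(spec) {
    id <- seq_len(spec@rows * spec@cols)
    ax <- idToAxial(spec, id)
    xy <- hexCenter(spec, id)
    data.frame(pattern_id = id, q = ax$q, r = ax$r,
               center_x_um = xy[, "x"], center_y_um = xy[, "y"])
}

## point-in-flat-top-hexagon (centred, edge L), boundary-inclusive
.inHex <- function(dx, dy, L, eps = 1e-9) {
    tol <- eps * max(L, 1)
    abs(dy) <= sqrt(3) / 2 * L + tol &
        sqrt(3) * abs(dx) + abs(dy) <= sqrt(3) * L + tol
}

## nearest axial cell by cube rounding (vectorized)
.cubeRound <- function(qf, rf) {
    xf <- qf; zf <- rf; yf <- -xf - zf
    x <- round(xf); y <- round(yf); z <- round(zf)
    dx <- abs(x - xf); dy <- abs(y - yf); dz <- abs(z - zf)
    fixX <- dx > dy & dx > dz
    fixZ <- !fixX & dz > dy
    x[fixX] <- -y[fixX] - z[fixX]
    z[fixZ] <- -x[fixZ] - y[fixZ]
    list(q = as.integer(x), r = as.integer(z))
}

#' Map micrometre points to the pattern containing them
#'
#' Returns the serial id of the hexagon whose interior (boundary inclusive)
#' contains each point, or \code{NA} (OUTSIDE) for points in the repulsive
#' gap or off the array. Points exactly on a shared boundary are assigned to
#' the containing hexagon with the lowest serial id.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param x,y point coordinates in micrometres (vectorized).
#' @return integer vector of pattern ids with \code{NA} for OUTSIDE.
#' @export
pointToPattern <- function(spec, x, y) {
    stopifnot(length(x) == length(y))
    if (!length(x)) return(integer())
    b <- .removeFrame(spec, x, y)
    .pointToPatternBase(spec, b)
}

## base-frame (unrotated, origin-at-zero) core of pointToPattern
.pointToPatternBase <- function(spec, b) {
    s <- .spacing(spec)
    qf <- b[, 1] / (sqrt(3) / 2 * s)
    rf <- b[, 2] / s - qf / 2
    cc <- .cubeRound(qf, rf)
    best <- rep(NA_integer_, nrow(b))
    offs <- rbind(c(0L, 0L), .ringOffsets(1L))
    for (k in seq_len(nrow(offs))) {
        q <- cc$q + offs[k, 1]; r <- cc$r + offs[k, 2]
        ctr <- .axialToBaseXY(spec, q, r)
        hit <- .inHex(b[, 1] - ctr[, 1], b[, 2] - ctr[, 2], spec@edgeLength) &
            .inBounds(spec, q, r)
        if (any(hit)) {
            id <- axialToId(spec, q[hit], r[hit])
            cur <- best[hit]
            best[hit] <- ifelse(is.na(cur), id, pmin(cur, id))
        }
    }
    best
}

## axial offsets at exact hex distance k
.ringOffsets <- function(k) {
    dq <- rep(-k:k, each = 2L * k + 1L)
    dr <- rep(-k:k, times = 2L * k + 1L)
    d <- (abs(dq) + abs(dr) + abs(dq + dr)) / 2L
    cbind(dq, dr)[d == k, , drop = FALSE]
}

#' Neighbouring patterns of a pattern
#'
#' Shell 1 is the up-to-6 hexagons adjacent across flat edges (all inside the
#' circle of radius r1 about the centre); shell 2 additionally includes the
#' next ring of up-to-12 hexagons (radius r2), 18 for an interior pattern.
#' Array-boundary patterns return fewer.
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param id a single serial pattern id.
#' @param shell 1 or 2.
#' @return integer vector of neighbouring pattern ids (sorted).
#' @export
neighborShell <- function(spec, id, shell = 1L) {
    stopifnot(length(id) == 1L, !is.na(id), shell %in% c(1L, 2L))
    ax <- idToAxial(spec, id)
    offs <- .ringOffsets(1L)
    if (shell == 2L) offs <- rbind(offs, .ringOffsets(2L))
    ids <- axialToId(spec, ax$q + offs[, 1], ax$r + offs[, 2])
    sort(ids[!is.na(ids)])
}
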