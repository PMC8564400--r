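## Raster rendering of a lattice + annotation: channel 1 is the pattern mask
## (filled hexagons), channels 2..(1+nColors) carry each cell's color
## intensities painted over its soma disc, dendrite patterns and a thin axon
## trace along the pattern-walk polyline. Pixel convention: (row, col),
## row 1 at top; micrometre y points up, so y_um = yMax - (row - 0.5)/ppu and
## x_um = xMin + (col - 0.5)/ppu.

.pxGrid <- function(nrow, ncol, transform) {
    col <- rep(seq_len(ncol), each = nrow)
    row <- rep(seq_len(nrow), times = ncol)
    list(x = transform$xMin + (col - 0.5) / transform$pxPerUm,
         y = transform$yMax - (row - 0.5) / transform$pxPerUm)
}

## distance from points to segment ab (vectorized over points)
.segDist <- function(px, py, ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Render a circuit annotation to a multi-channel raster
#'
#' @param spec a \linkS4class{LatticeSpec}.
#' @param annotation a \linkS4class{CircuitAnnotation}, or \code{NULL} for a
#'   pattern-only image.
#' @param pxPerUm raster scale in pixels per micrometre (> 0).
#' @param noiseSd standard deviation of additive Gaussian noise (image units;
#'   pattern foreground is 1).
#' @param rotation degrees by which the rendered frame is rotated
#'   (counter-clockwise in micrometre space) about the canvas centre.
#' @param marginUm canvas margin beyond the hexagon bounding box (default
#'   l1).
#' @param somaRadiusUm,axonWidthUm drawn sizes of soma discs and axon traces.
#' @param seed seed for the noise stream.
#' @return list with \code{img} (array height x width x channels, channel 1
#'   the pattern mask), \code{transform} (\code{pxPerUm}, \code{xMin},
#'   \code{yMax}: the px-to-um mapping before rotation) and \code{rotation}.
#' @examples
#' spec <- LatticeSpec(55, 70, rows = 4, cols = 4)
#' r <- renderImage(spec, pxPerUm = 0.2)
#' dim(r$img)
#' @export
renderImage <- function(spec, annotation = NULL, pxPerUm = 0.5, noiseSd = 0,
                        rotation = 0, marginUm = NULL, somaRadiusUm = 7.5,
                        axonWidthUm = 2, seed = 1L) {
    stopifnot(is(spec, "LatticeSpec"), pxPerUm > 0)
    d <- deriveDistances(spec)
    if (is.null(marginUm)) marginUm <- d$l1
    ctr <- hexCenter(spec, seq_len(spec@rows * spec@cols))
    ext <- spec@edgeLength + marginUm
    xMin <- min(ctr[, 1]) - ext; xMax <- max(ctr[, 1]) + ext
    yMin <- min(ctr[, 2]) - ext; yMax <- max(ctr[, 2]) + ext
    W <- ceiling((xMax - xMin) * pxPerUm)
    H <- ceiling((yMax - yMin) * pxPerUm)
    transform <- list(pxPerUm = pxPerUm, xMin = xMin, yMax = yMax)
    g <- .pxGrid(H, W, transform)
    pid <- pointToPattern(spec, g$x, g$y)
    pidM <- matrix(pid, H, W)
    nC <- if (is.null(annotation)) 0L else ncol(annotation@colors)
    img <- array(0, dim = c(H, W, 1L + nC))
    img[, , 1] <- (!is.na(pidM)) * 1

    if (!is.null(annotation) && nrow(somaTable(annotation))) {
        st <- somaTable(annotation)
        key <- as.character(st$cell_id)
        gx <- matrix(g$x, H, W); gy <- matrix(g$y, H, W)
        for (i in seq_len(nrow(st))) {
            w <- annotation@colors[i, ]
            ## dendrite patterns (RPAs)
            dmask <- pidM %in% annotation@dendrites[[key[i]]]
            ## soma disc, local bounding box
            rows <- pmax(1, floor((yMax - st$y_um[i] - somaRadiusUm) * pxPerUm)):
                    pmin(H, ceiling((yMax - st$y_um[i] + somaRadiusUm) * pxPerUm))
            cols <- pmax(1, floor((st$x_um[i] - xMin - somaRadiusUm) * pxPerUm)):
                    pmin(W, ceiling((st$x_um[i] - xMin + somaRadiusUm) * pxPerUm))
            soma <- outer((yMax - (rows - 0.5) / pxPerUm - st$y_um[i])^2,
                          (xMin + (cols - 0.5) / pxPerUm - st$x_um[i])^2,
                          `+`) <= somaRadiusUm^2
            ## axon trace along the walk polyline
            path <- annotation@axonPaths[[key[i]]]
            amask <- matrix(FALSE, H, W)
            if (!is.null(path) && length(path)) {
                pts <- rbind(c(st$x_um[i], st$y_um[i]),
                             hexCenter(spec, path))
                for (sgm in seq_len(nrow(pts) - 1L)) {
                    ax <- pts[sgm, 1]; ay <- pts[sgm, 2]
                    bx <- pts[sgm + 1L, 1]; by <- pts[sgm + 1L, 2]
                    pad <- axonWidthUm
                    r0 <- pmax(1, floor((yMax - max(ay, by) - pad) * pxPerUm))
                    r1 <- pmin(H, ceiling((yMax - min(ay, by) + pad) * pxPerUm))
                    c0 <- pmax(1, floor((min(ax, bx) - xMin - pad) * pxPerUm))
                    c1 <- pmin(W, ceiling((max(ax, bx) - xMin + pad) * pxPerUm))
                    if (r1 < r0 || c1 < c0) next
                    rr <- r0:r1; cc <- c0:c1
                    py <- yMax - (rr - 0.5) / pxPerUm
                    px <- xMin + (cc - 0.5) / pxPerUm
                    dd <- .segDist(rep(px, each = length(py)),
                                   rep(py, times = length(px)),
                                   ax, ay, bx, by)
                    hit <- matrix(dd <= axonWidthUm / 2,
                                  length(rr), length(cc))
                    amask[rr, cc] <- amask[rr, cc] | hit
                }
            }
            for (ch in seq_len(nC)) {
                if (w[ch] <= 0) next
                lay <- img[, , 1L + ch]
                lay[dmask] <- pmax(lay[dmask], 0.8 * w[ch])
                lay[amask] <- pmax(lay[amask], 0.9 * w[ch])
                sub <- lay[rows, cols, drop = FALSE]
                sub[soma] <- pmax(sub[soma], w[ch])
                lay[rows, cols] <- sub
                img[, , 1L + ch] <- lay
            }
        }
    }

    if (rotation != 0) img <- .rotateRaster(img, rotation)
    if (noiseSd > 0)
        img <- img + .withSeed(seed, array(stats::rnorm(length(img),
                                                        sd = noiseSd),
                                           dim = dim(img)))
    list(img = img, transform = transform, rotation = rotation)
}

#' Rotate a raster counter-clockwise about its centre
#'
#' Nearest-neighbour resampling on the same canvas (zeros outside); the
#' rotation sense matches \code{\link{renderImage}}'s \code{rotation}
#' argument, so \code{rotateRaster(x, -estimateRotation(x))} straightens a
#' rotated pattern image.
#'
#' @param img 2D matrix or 3D array.
#' @param degrees rotation angle (counter-clockwise in micrometre space).
#' @return rotated array of the same dimensions.
#' @export
rotateRaster <- function(img, degrees) {
    if (length(dim(img)) == 2L)
        return(.rotateRaster(array(img, dim = c(dim(img), 1L)),
                             degrees)[, , 1])
    .rotateRaster(img, degrees)
}

## rotate a raster array counter-clockwise (in um space, y up) about its
## centre; nearest-neighbour resampling, zeros outside
.rotateRaster <- function(img, degrees) {
    d <- dim(img)
    H <- d[1]; W <- d[2]
    th <- degrees * pi / 180
    rc <- (H + 1) / 2; cc <- (W + 1) / 2
    row <- matrix(seq_len(H), H, W)
    col <- matrix(rep(seq_len(W), each = H), H, W)
    ## um-space ccw rotation = cw in (row, col) because row is -y
    dy <- -(row - rc); dx <- col - cc
    sx <- cos(-th) * dx - sin(-th) * dy
    sy <- sin(-th) * dx + cos(-th) * dy
    srow <- round(rc - sy); scol <- round(cc + sx)
    ok <- srow >= 1 & srow <= H & scol >= 1 & scol <= W
    idx <- cbind(srow[ok], scol[ok])
    out <- array(0, dim = d)
    for (ch in seq_len(d[3])) {
        lay <- matrix(0, H, W)
        src <- img[, , ch]
        lay[cbind(row[ok], col[ok])] <- src[idx]
        out[, , ch] <- lay
    }
    out
}

#' Write a rendered raster to disk
#'
#' Multi-channel images are written either as a multi-page TIFF (one page per
#' channel) or as per-channel PNG files with a channel suffix. Intensities
#' are clamped to [0, 1].
#'
#' @param render a \code{\link{renderImage}} result (or a plain array).
#' @param path output file path (extension selects nothing; see
#'   \code{format}).
#' @param format \code{"tiff"} or \code{"png"}.
#' @return invisibly, the written file path(s).
#' @export
writeRaster <- function(render, path, format = c("tiff", "png")) {
    format <- match.arg(format)
    img <- if (is.list(render)) render$img else render
    if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
    img <- pmin(pmax(img, 0), 1)  # img first so dim attributes survive
    chans <- lapply(seq_len(dim(img)[3]), function(ch) img[, , ch])
    if (format == "tiff") {
        tiff::writeTIFF(chans, path)
        invisible(path)
    } else {
        paths <- sprintf("%s_ch%d.png", sub("\\.png$", "", path),
                         seq_along(chans))
        for (i in seq_along(chans)) png::writePNG(chans[[i]], paths[i])
        invisible(paths)
    }
}

#' Read a single- or multi-channel raster image
#'
#' @param path a TIFF or PNG file.
#' @return numeric array height x width x channels.
#' @export
readRaster <- function(path) {
    img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        pages <- tiff::readTIFF(path, all = TRUE)
        if (is.list(pages))
            array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
        else pages
    } else png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
    img
}
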