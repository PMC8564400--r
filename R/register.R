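## Lattice registration from a raster pattern image, in two stages mirroring
## the platform's image pipeline: (1) rotation from the angular position of
## the first-order peaks of the 2D power spectrum (a periodic hexagonal array
## concentrates power in six peaks 60 degrees apart); (2) pattern centres by
## zero-normalized cross-correlation against a synthesized single-hexagon
## template, peak picking with non-maximum suppression, sub-pixel quadratic
## refinement, and a least-squares fit of the detected centres to the lattice
## model for indexing.

## sub-pixel 1D parabola vertex through (-1, a), (0, b), (1, c)
.parabolaVertex <- function(a, b, c) {
    den <- a - 2 * b + c
    if (!is.finite(den) || den >= 0) return(0)
    off <- 0.5 * (a - c) / den
    max(-0.5, min(0.5, off))
}

#' Estimate the lattice rotation of a pattern image
#'
#' Computes the 2D power spectrum of the (windowed, mean-removed) image,
#' locates the strongest non-DC peaks, refines their positions to sub-bin
#' accuracy, and returns the circular mean of their angles folded into
#' [-30, 30) degrees by the 60-degree symmetry of the honeycomb. Angles are
#' measured counter-clockwise in micrometre space (y up); an unrotated
#' flat-top lattice reports 0.
#'
#' @param img 2D numeric matrix (a single-channel pattern image containing at
#'   least a 3 x 3 block of patterns).
#' @param padFactor zero-padding factor of the FFT (frequency-domain
#'   oversampling; default 3).
#' @param minPeakRatio minimum ratio of peak power to the median non-DC
#'   power; below it the image is declared aperiodic.
#' @return rotation angle in degrees, in [-30, 30).
#' @export
estimateRotation <- function(img, padFactor = 3, minPeakRatio = 200) {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    stopifnot(is.matrix(img))
    if (!all(is.finite(img)) || stats::sd(img) == 0)
        stop("no periodic lattice structure detected (flat image)")
    H <- nrow(img); W <- ncol(img)
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    win <- outer(hann(H), hann(W))
    x <- (img - mean(img)) * win
    PH <- 2^ceiling(log2(H * padFactor))
    PW <- 2^ceiling(log2(W * padFactor))
    z <- matrix(0, PH, PW)
    z[seq_len(H), seq_len(W)] <- x
    P <- Mod(stats::fft(z))^2
    ## frequency coordinates (cycles/px), DC at [1, 1]
    fr <- ((seq_len(PH) - 1 + PH %/% 2) %% PH - PH %/% 2) / PH
    fc <- ((seq_len(PW) - 1 + PW %/% 2) %% PW - PW %/% 2) / PW
    fr2 <- matrix(fr^2, PH, PW); fc2 <- matrix(fc^2, PH, PW, byrow = TRUE)
    freq <- sqrt(fr2 + fc2)
    ## exclude the windowed-DC lobe
    fmin <- 4 / min(H, W)
    cand <- which(freq > fmin)
    kmax <- cand[which.max(P[cand])]
    med <- stats::median(P[cand])
    if (P[kmax] < minPeakRatio * max(med, .Machine$double.eps))
        stop("no periodic lattice structure detected")
    f0 <- freq[kmax]
    ## all strong peaks on the fundamental ring
    ring <- which(freq > 0.8 * f0 & freq < 1.2 * f0 & P > 0.2 * P[kmax])
    ## greedy clustering of ring bins into peaks
    o <- ring[order(-P[ring])]
    rows <- (o - 1) %% PH + 1
    cols <- (o - 1) %/% PH + 1
    py <- fr[rows]; px <- fc[cols]
    keep <- logical(0); ky <- numeric(0); kx <- numeric(0); kidx <- integer(0)
    for (i in seq_along(o)) {
        if (length(kx) &&
            any((px[i] - kx)^2 + (py[i] - ky)^2 < (0.3 * f0)^2)) next
        kx <- c(kx, px[i]); ky <- c(ky, py[i]); kidx <- c(kidx, i)
        if (length(kx) >= 6) break
    }
    ## sub-bin refinement and angle of each peak (um frame: y up = -row)
    ang <- vapply(kidx, function(i) {
        r <- rows[i]; c <- cols[i]
        rr <- (r + c(-1, 0, 1) - 1) %% PH + 1
        cc <- (c + c(-1, 0, 1) - 1) %% PW + 1
        dr <- .parabolaVertex(P[rr[1], c], P[r, c], P[rr[3], c])
        dc <- .parabolaVertex(P[r, cc[1]], P[r, c], P[r, cc[3]])
        fy <- fr[r] + dr / PH
        fx <- fc[c] + dc / PW
        atan2(-fy, fx) * 180 / pi
    }, numeric(1))
    ## circular mean on the 60-degree period
    z6 <- mean(exp(1i * ang * 6 * pi / 180))
    theta <- Arg(z6) * 180 / pi / 6
    ((theta + 30) %% 60) - 30
}

## FFT-based 'valid' cross-correlation of image with kernel
.xcorrValid <- function(img, ker) {
    H <- nrow(img); W <- ncol(img)
    h <- nrow(ker); w <- ncol(ker)
    PH <- 2^ceiling(log2(H + h)); PW <- 2^ceiling(log2(W + w))
    A <- matrix(0, PH, PW); A[seq_len(H), seq_len(W)] <- img
    B <- matrix(0, PH, PW); B[seq_len(h), seq_len(w)] <- ker[h:1, w:1]
    full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
        (PH * PW)
    full[h:H, w:W, drop = FALSE]
}

## local sums of img over an h x w sliding window ('valid' positions)
.localSum <- function(img, h, w) {
    cs <- apply(img, 2, cumsum)
    cs <- t(apply(cs, 1, cumsum))
    I <- matrix(0, nrow(img) + 1, ncol(img) + 1)
    I[-1, -1] <- cs
    H <- nrow(img); W <- ncol(img)
    r <- seq_len(H - h + 1); c <- seq_len(W - w + 1)
    I[r + h, c + w, drop = FALSE] - I[r, c + w, drop = FALSE] -
        I[r + h, c, drop = FALSE] + I[r, c, drop = FALSE]
}

## synthesized flat-top hexagon template at the image scale
.hexTemplate <- function(spec, pxPerUm) {
    L <- spec@edgeLength
    hw <- ceiling(L * pxPerUm) + 1L
    hh <- ceiling(sqrt(3) / 2 * L * pxPerUm) + 1L
    cols <- (-hw):hw; rows <- (-hh):hh
    dx <- matrix(cols / pxPerUm, length(rows), length(cols), byrow = TRUE)
    dy <- matrix(-rows / pxPerUm, length(rows), length(cols))
    (.inHex(dx, dy, L)) * 1
}

#' Detect pattern centres by template matching and index them
#'
#' Zero-normalized cross-correlation (scores in [-1, 1]) of the
#' rotation-corrected pattern image against a hexagon template synthesized
#' from the lattice spec; local maxima above \code{scoreMin}, separated by at
#' least \code{minSepFactor} times the lattice spacing, are accepted as
#' centres, refined to sub-pixel accuracy, and fitted to the lattice model
#' (least squares over the origin offset) to obtain axial indices.
#'
#' @param img 2D matrix (or array whose first channel is the pattern image),
#'   already rotation-corrected.
#' @param spec a \linkS4class{LatticeSpec} giving L and D.
#' @param pxPerUm image scale.
#' @param scoreMin correlation acceptance threshold (default 0.5).
#' @param minSepFactor minimum peak separation as a fraction of the lattice
#'   spacing (default 0.8).
#' @return a \linkS4class{RegistrationResult}.
#' @export
detectPatterns <- function(img, spec, pxPerUm, scoreMin = 0.5,
                           minSepFactor = 0.8) {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    stopifnot(is.matrix(img), is(spec, "LatticeSpec"), pxPerUm > 0)
    tpl <- .hexTemplate(spec, pxPerUm)
    h <- nrow(tpl); w <- ncol(tpl)
    if (nrow(img) < h || ncol(img) < w)
        stop("image smaller than one pattern template")
    t0 <- tpl - mean(tpl)
    normT <- sqrt(sum(t0^2))
    num <- .xcorrValid(img, t0)
    S1 <- .localSum(img, h, w)
    S2 <- .localSum(img^2, h, w)
    varI <- pmax(S2 - S1^2 / (h * w), 0)
    den <- sqrt(varI) * normT
    score <- ifelse(den > 1e-9, num / den, 0)

    ## peak picking: strict local maxima above threshold
    sepPx <- minSepFactor * .spacing(spec) * pxPerUm
    Hs <- nrow(score); Ws <- ncol(score)
    isMax <- score >= scoreMin
    if (Hs >= 3 && Ws >= 3) {
        core <- score[2:(Hs - 1), 2:(Ws - 1)]
        nb <- array(NA_real_, dim = c(Hs - 2, Ws - 2, 8))
        k <- 0
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            k <- k + 1
            nb[, , k] <- score[2:(Hs - 1) + dr, 2:(Ws - 1) + dc]
        }
        loc <- core >= apply(nb, c(1, 2), max)
        inner <- matrix(FALSE, Hs, Ws)
        inner[2:(Hs - 1), 2:(Ws - 1)] <- loc
        isMax <- isMax & inner
    }
    peaks <- which(isMax, arr.ind = TRUE)
    if (nrow(peaks)) {
        sc <- score[peaks]
        o <- order(-sc)
        peaks <- peaks[o, , drop = FALSE]; sc <- sc[o]
        keep <- rep(TRUE, nrow(peaks))
        for (i in seq_len(nrow(peaks))) {
            if (!keep[i]) next
            if (i < nrow(peaks)) {
                j <- (i + 1):nrow(peaks)
                close <- (peaks[j, 1] - peaks[i, 1])^2 +
                         (peaks[j, 2] - peaks[i, 2])^2 < sepPx^2
                keep[j][close] <- FALSE
            }
        }
        peaks <- peaks[keep, , drop = FALSE]; sc <- sc[keep]
    } else sc <- numeric()
    if (nrow(peaks) < 4L)
        stop("insufficient detections: fewer than 4 pattern centres above ",
             "score ", scoreMin)

    ## sub-pixel refinement on the score surface, then shift from the
    ## 'valid' correlation frame to image-centre coordinates
    sub <- t(vapply(seq_len(nrow(peaks)), function(i) {
        r <- peaks[i, 1]; c <- peaks[i, 2]
        dr <- if (r > 1 && r < Hs)
            .parabolaVertex(score[r - 1, c], score[r, c], score[r + 1, c])
            else 0
        dc <- if (c > 1 && c < Ws)
            .parabolaVertex(score[r, c - 1], score[r, c], score[r, c + 1])
            else 0
        c(r + dr + (h - 1) / 2, c + dc + (w - 1) / 2)
    }, numeric(2)))

    ## lattice fit: centres (um, y up) = origin + q * vq + r * vr
    s <- .spacing(spec)
    cx <- sub[, 2] / pxPerUm
    cy <- -sub[, 1] / pxPerUm
    B <- cbind(c(sqrt(3) / 2 * s, s / 2), c(0, s))
    Binv <- solve(B)
    anchor <- c(cx[1], cy[1])
    uv <- round(Binv %*% rbind(cx - anchor[1], cy - anchor[2]))
    for (it in 1:2) {
        fit <- B %*% uv
        origin <- c(mean(cx - fit[1, ]), mean(cy - fit[2, ]))
        uv <- round(Binv %*% rbind(cx - origin[1], cy - origin[2]))
    }
    fit <- B %*% uv
    resid <- sqrt((cx - origin[1] - fit[1, ])^2 +
                  (cy - origin[2] - fit[2, ])^2) * pxPerUm
    ## normalize indices to the array enumeration (min col/row at 0)
    q <- as.integer(uv[1, ]); r <- as.integer(uv[2, ])
    dq <- -min(q)
    q2 <- q + dq
    row0 <- r + q2 %/% 2L
    r2 <- r - min(row0)
    origin <- origin + B %*% c(-dq, min(row0))
    pid <- axialToId(spec, q2, r2)

    centers <- data.frame(row_px = sub[, 1], col_px = sub[, 2], score = sc,
                          q = q2, r = r2, pattern_id = pid,
                          resid_px = resid)
    centers <- centers[order(-centers$score), ]
    rownames(centers) <- NULL
    new("RegistrationResult", rotation = 0, centers = centers,
        pxPerUm = pxPerUm, originPx = c(-origin[2] * pxPerUm,
                                        origin[1] * pxPerUm))
}
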