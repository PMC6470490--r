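## Fixture builders and independent oracles used across the suite.

uniformImage <- function(h, w, rgb) {
    if (length(rgb) == 1L) rgb <- rep(rgb, 3L)
    RGBImage(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

randomImage <- function(h, w, maxVal = 255) {
    RGBImage(array(sample.int(maxVal + 1L, h * w * 3, replace = TRUE) - 1L,
                   dim = c(h, w, 3)))
}

## Solid color disk (given HSV) on black background.
diskImage <- function(h, w, cx, cy, r, hue, sat, val) {
    x <- matrix(rep(seq_len(w), each = h), h, w)
    y <- matrix(rep(seq_len(h), w), h, w)
    inside <- (x - cx)^2 + (y - cy)^2 <= r^2
    rgb <- grDevices::col2rgb(grDevices::hsv(hue / 360, sat / 255,
                                             val / 255))
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
        m <- matrix(0, h, w); m[inside] <- rgb[ch, 1]
        px[, , ch] <- m
    }
    list(img = RGBImage(px), mask = inside, area = sum(inside))
}

rectMask <- function(h, w, rows, cols) {
    m <- matrix(FALSE, h, w)
    m[rows, cols] <- TRUE
    m
}

toyDetection <- function(mask) {
    new("Detection", blobMask = mask, area = sum(mask),
        bbox = pepperFNF:::tightBBox(mask))
}

## Independent per-pixel compositing oracle: plain loops, no vectorized
## shortcuts shared with the implementation.
naiveComposite <- function(flash, noflash, satLevel = 255) {
    f <- pixelArray(flash); n <- pixelArray(noflash)
    out <- array(0, dim = dim(f))
    for (i in seq_len(dim(f)[1])) for (j in seq_len(dim(f)[2])) {
        if (any(f[i, j, ] >= satLevel)) {
            out[i, j, ] <- f[i, j, ]
        } else {
            for (ch in 1:3) out[i, j, ch] <- max(f[i, j, ch] - n[i, j, ch], 0)
        }
    }
    RGBImage(out)
}

## Independent connected-components oracle: breadth-first flood fill.
floodFillLabels <- function(mask, connectivity = 8) {
    H <- nrow(mask); W <- ncol(mask)
    lab <- matrix(0L, H, W)
    nbr <- if (connectivity == 8)
        cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    nextLab <- 0L
    for (j in seq_len(W)) for (i in seq_len(H)) {
        if (!mask[i, j] || lab[i, j] > 0L) next
        nextLab <- nextLab + 1L
        queue <- matrix(c(i, j), 1, 2)
        lab[i, j] <- nextLab
        while (nrow(queue) > 0L) {
            cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
            for (k in seq_len(nrow(nbr))) {
                yy <- cur[1] + nbr[k, 1]; xx <- cur[2] + nbr[k, 2]
                if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
                    mask[yy, xx] && lab[yy, xx] == 0L) {
                    lab[yy, xx] <- nextLab
                    queue <- rbind(queue, c(yy, xx))
                }
            }
        }
    }
    lab
}

toyTruth <- function(mask, maturity = "mature") {
    GroundTruthObject(mask, maturity)
}

## Toy labeled scene: one solid ripe-colored square on black.
toyScene <- function(h = 80, w = 80, rows = 21:50, cols = 21:50,
                     id = "toy") {
    px <- array(0, dim = c(h, w, 3))
    rgb <- grDevices::col2rgb(grDevices::hsv(35 / 360, 200 / 255,
                                             230 / 255))
    for (ch in 1:3) {
        m <- matrix(0, h, w); m[rows, cols] <- rgb[ch, 1]
        px[, , ch] <- m
    }
    mask <- rectMask(h, w, rows, cols)
    truth <- new("SceneTruth",
                 labelMask = matrix(as.integer(mask), h, w),
                 objects = list(toyTruth(mask, "mature")))
    new("SceneData", flash = RGBImage(px),
        noflash = RGBImage(array(0, dim = c(h, w, 3))),
        truth = truth, id = id)
}
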