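#' @include AllClasses.R AllGenerics.R imaging.R
NULL

#' HSV band thresholding
#'
#' A pixel passes iff its hue lies in [hueMin, hueMax] and its saturation
#' in [satMin, satMax], both bounds inclusive. Value is deliberately left
#' unconstrained: on an FNF composite, distance alone darkens out-of-range
#' objects.
#'
#' @param hsv an [HSVImage-class].
#' @param params a [DetectorParams-class].
#' @return logical H x W matrix.
#' @export
thresholdMask <- function(hsv, params = DetectorParams()) {
    hsv@hue >= params@hueMin & hsv@hue <= params@hueMax &
        hsv@saturation >= params@satMin & hsv@saturation <= params@satMax
}

#' Morphological cleanup of a thresholded mask
#'
#' Morphological closing with a square structuring element of side
#' `morphCloseSize`, followed by filling of fully enclosed holes. Closing
#' bridges small gaps (which is why adjacent fruit can merge into one
#' blob); hole filling removes speckle holes left by specular highlights.
#'
#' @param mask logical H x W matrix.
#' @param params a [DetectorParams-class].
#' @return logical matrix of the same dimensions.
#' @export
cleanMask <- function(mask, params = DetectorParams()) {
    m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
    brush <- EBImage::makeBrush(as.integer(params@morphCloseSize),
                                shape = "box")
    m <- EBImage::closing(m, brush)
    m <- EBImage::fillHull(m)
    m > 0.5
}

#' Connected-component extraction
#'
#' Labels the connected components of a binary mask under the configured
#' connectivity (4 or 8) and returns one unfiltered [Detection-class] per
#' component, in raster-scan order (top to bottom, left to right) of each
#' component's first pixel. The adjacency graph is assembled from pixel
#' neighbor offsets and its components found with \pkg{igraph}.
#'
#' @param mask logical H x W matrix.
#' @param params a [DetectorParams-class].
#' @return list of [Detection-class].
#' @export
extractBlobs <- function(mask, params = DetectorParams()) {
    H <- nrow(mask); W <- ncol(mask)
    idx <- which(mask)
    if (length(idx) == 0L) return(list())
    rank <- integer(H * W)
    rank[idx] <- seq_along(idx)

    edgePairs <- function(a, b) {       # linear-index pairs, both TRUE
        keep <- mask[a] & mask[b]
        rbind(rank[a[keep]], rank[b[keep]])
    }
    lin <- matrix(seq_len(H * W), H, W)
    edges <- cbind(
        if (W > 1) edgePairs(lin[, -W], lin[, -1]),              # right
        if (H > 1) edgePairs(lin[-H, ], lin[-1, ]))              # down
    if (params@connectivity == 8 && H > 1 && W > 1) {
        edges <- cbind(edges,
            edgePairs(lin[-H, -W], lin[-1, -1]),                 # down-right
            edgePairs(lin[-1, -W], lin[-H, -1]))                 # up-right
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges) && length(edges))
        g <- igraph::add_edges(g, as.vector(edges))
    memb <- igraph::components(g)$membership

    ## order components by raster-scan position of their first pixel
    col0 <- (idx - 1L) %/% H
    row0 <- (idx - 1L) %% H
    scanPos <- row0 * W + col0
    firstPos <- tapply(scanPos, memb, min)
    ord <- order(firstPos)
    lapply(seq_along(ord), function(k) {
        sel <- idx[memb == as.integer(names(firstPos)[ord[k]])]
        bm <- matrix(FALSE, H, W)
        bm[sel] <- TRUE
        new("Detection", blobMask = bm, area = length(sel),
            bbox = tightBBox(bm))
    })
}

#' Minimum-size blob filter
#'
#' Retains blobs whose pixel area is at least the configured minimum,
#' scaled linearly with the image's pixel count relative to the reference
#' resolution (400 px at 320 x 240 by default, hence 1600 px at 640 x 480).
#'
#' @param blobs list of [Detection-class] from one image.
#' @param imageWidth,imageHeight dimensions of that image.
#' @param params a [DetectorParams-class].
#' @return the retained blobs, order preserved.
#' @export
filterBlobs <- function(blobs, imageWidth, imageHeight,
                        params = DetectorParams()) {
    minArea <- params@minAreaRef * (imageWidth * imageHeight) /
        (params@refWidth * params@refHeight)
    blobs[vapply(blobs, function(b) b@area >= minArea, logical(1))]
}

#' Color-blob fruit detection
#'
#' The full detection pipeline on a single image (typically an FNF
#' composite, or a flash frame for comparison): RGB to HSV conversion,
#' hue/saturation band thresholding, morphological cleanup,
#' connected-component extraction, and minimum-size filtering. Each
#' surviving blob carries its pixel mask, area and bounding-box window.
#'
#' @param img an [RGBImage-class].
#' @param params a [DetectorParams-class].
#' @return list of [Detection-class].
#' @examples
#' px <- array(0, dim = c(60, 60, 3))
#' px[20:45, 20:45, 1] <- 230; px[20:45, 20:45, 2] <- 180
#' detectPeppers(RGBImage(px))
#' @export
setMethod("detectPeppers", "RGBImage", function(img,
                                                params = DetectorParams()) {
    mask <- cleanMask(thresholdMask(rgbToHSV(img), params), params)
    blobs <- extractBlobs(mask, params)
    filterBlobs(blobs, imgWidth(img), imgHeight(img), params)
})

#' Threshold calibration from a few labeled images
#'
#' Recovers hue/saturation detection bands from at most a handful of
#' labeled images, preserving the method's fast-adaptation property
#' (re-calibration for a new greenhouse or cultivar from ~3 images). The
#' hue band is set to the 1st and 99th percentiles of hue over all
#' fruit-mask pixels, widened outward by one whole degree; the saturation
#' floor to the 1st percentile of saturation; the saturation ceiling stays
#' at 255. All other parameters keep their defaults.
#'
#' @param images list of [RGBImage-class] (typically <= 3).
#' @param fruitMasks list of logical masks marking fruit pixels, parallel
#'   to `images`.
#' @return a [DetectorParams-class].
#' @export
calibrateThresholds <- function(images, fruitMasks) {
    if (length(images) == 0L || length(images) != length(fruitMasks))
        stop("need equally many images and fruit masks, at least one each")
    hs <- mapply(function(img, m) {
        hsv <- rgbToHSV(img)
        list(h = hsv@hue[m], s = hsv@saturation[m])
    }, images, fruitMasks, SIMPLIFY = FALSE)
    h <- unlist(lapply(hs, `[[`, "h"))
    s <- unlist(lapply(hs, `[[`, "s"))
    if (length(h) == 0L)
        stop("fruit masks are empty: no pixels to calibrate from")
    q <- stats::quantile(h, c(0.01, 0.99), names = FALSE)
    ## snap to whole degrees before widening (guards the floor/ceiling
    ## against floating-point residue from the colorspace conversion)
    eps <- 1e-6
    DetectorParams(hueMin = floor(q[1] + eps) - 1,
                   hueMax = ceiling(q[2] - eps) + 1,
                   satMin = max(0, floor(stats::quantile(s, 0.01,
                                                         names = FALSE) +
                                         eps)),
                   satMax = 255)
}
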