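#' @include AllClasses.R AllGenerics.R
NULL

#' Mean brightness of an image
#'
#' Arithmetic mean intensity over all pixels and all three channels, the
#' quantity used to tell flash frames from no-flash frames in an
#' alternating acquisition stream.
#'
#' @param img an [RGBImage-class].
#' @return scalar in [0, 255].
#' @examples
#' img <- RGBImage(array(37, dim = c(4, 4, 3)))
#' meanBrightness(img)  # 37
#' @export
setMethod("meanBrightness", "RGBImage", function(img) {
    mean(img@pixels)
})

#' Classify two consecutive frames as a flash/no-flash pair
#'
#' Compares the mean brightness of the two frames. If the difference
#' strictly exceeds `brightnessDeltaThreshold` the brighter frame is
#' designated the flash frame and a validated [FNFPair-class] is returned;
#' otherwise the frames do not form a pair and NULL is returned. A delta
#' exactly equal to the threshold is rejected.
#'
#' @param a,b two [RGBImage-class] frames of identical dimensions.
#' @param params an [FNFParams-class].
#' @return an [FNFPair-class] or NULL.
#' @export
classifyPair <- function(a, b, params = FNFParams()) {
    if (!identical(dim(a@pixels), dim(b@pixels)))
        stop("frames must have identical dimensions")
    delta <- meanBrightness(a) - meanBrightness(b)
    if (abs(delta) <= params@brightnessDeltaThreshold)
        return(NULL)
    if (delta > 0)
        new("FNFPair", flash = a, noflash = b)
    else
        new("FNFPair", flash = b, noflash = a)
}

#' Scan a frame stream for flash/no-flash pairs
#'
#' Slides over consecutive frames of an acquisition stream whose flash
#' alternation may be disturbed by dropped frames or variable frame rate.
#' Whenever two consecutive frames form a valid pair an [FNFPair-class] is
#' emitted and the scan advances past both frames; otherwise it advances
#' by one. Within a stream the illumination rig fires on the first frame
#' of each pair, so a pair is accepted only when the brighter (flash)
#' frame comes first; a dark-to-bright transition spans two different
#' pairs and is never treated as one. Emitted pairs are non-overlapping
#' and in stream order; frames participating in no valid pair (dropped
#' frames, repeated exposures) are skipped.
#'
#' @param frames list of [RGBImage-class] frames (>= 2).
#' @param params an [FNFParams-class].
#' @return list of [FNFPair-class] objects, each carrying the 1-based
#'   `frameIndices` (flash frame first) of its source frames.
#' @export
scanStream <- function(frames, params = FNFParams()) {
    if (length(frames) < 2L)
        stop("a stream must contain at least 2 frames")
    pairs <- list()
    i <- 1L
    while (i < length(frames)) {
        p <- classifyPair(frames[[i]], frames[[i + 1L]], params)
        flashFirst <- !is.null(p) &&
            meanBrightness(frames[[i]]) > meanBrightness(frames[[i + 1L]])
        if (flashFirst) {
            p@frameIndices <- c(i, i + 1L)
            pairs[[length(pairs) + 1L]] <- p
            i <- i + 2L
        } else {
            i <- i + 1L
        }
    }
    pairs
}

#' Build an FNFPair from two frames known to be flash and no-flash
#'
#' Unlike [classifyPair()] the roles are given, not inferred; the pair is
#' still validated for matching dimensions. Useful for datasets stored as
#' pre-paired images rather than raw streams.
#'
#' @param flash,noflash [RGBImage-class] frames.
#' @return an [FNFPair-class].
#' @export
fnfPair <- function(flash, noflash) {
    new("FNFPair", flash = flash, noflash = noflash)
}

#' Flash/no-flash compositing
#'
#' Subtracts the no-flash (ambient-only) frame from the flash frame per
#' pixel, leaving the scene as if lit by the artificial source alone.
#' Negative differences are clamped to 0. Pixels overexposed in the flash
#' frame (any channel at or above `saturationLevel`) carry no reliable
#' subtraction information and are excluded: the flash value is passed
#' through unchanged for all three channels of such a pixel.
#'
#' @param pair an [FNFPair-class].
#' @param params an [FNFParams-class].
#' @return the pair with its `composite` slot filled; retrieve the image
#'   with [compositeImage()].
#' @export
setMethod("composeFNF", "FNFPair", function(pair, params = FNFParams()) {
    f <- pair@flash@pixels
    n <- pair@noflash@pixels
    diff <- pmax(f - n, 0)
    sat <- f[, , 1] >= params@saturationLevel |
           f[, , 2] >= params@saturationLevel |
           f[, , 3] >= params@saturationLevel
    if (any(sat)) {
        satA <- array(sat, dim = dim(f))
        diff[satA] <- f[satA]
    }
    pair@composite <- RGBImage(diff)
    pair
})

#' @describeIn composeFNF Convenience wrapper taking the two frames
#'   directly and returning the composite [RGBImage-class].
#' @param flash,noflash [RGBImage-class] frames.
#' @export
fnfComposite <- function(flash, noflash, params = FNFParams()) {
    compositeImage(composeFNF(fnfPair(flash, noflash), params))
}

#' RGB to HSV conversion
#'
#' Standard colorspace conversion with hue in degrees [0, 360) and
#' saturation and value rescaled to [0, 255], the ranges the detector's
#' thresholds are expressed in.
#'
#' @param img an [RGBImage-class].
#' @return an [HSVImage-class].
#' @export
setMethod("rgbToHSV", "RGBImage", function(img) {
    d <- dim(img@pixels)
    rgb <- rbind(as.vector(img@pixels[, , 1]),
                 as.vector(img@pixels[, , 2]),
                 as.vector(img@pixels[, , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
    new("HSVImage",
        hue = matrix((hsv[1, ] * 360) %% 360, d[1], d[2]),
        saturation = matrix(hsv[2, ] * 255, d[1], d[2]),
        value = matrix(hsv[3, ] * 255, d[1], d[2]))
})
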