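#' @include AllClasses.R
NULL

#' @rdname meanBrightness
#' @export
setGeneric("meanBrightness", function(img) standardGeneric("meanBrightness"))

#' @rdname composeFNF
#' @export
setGeneric("composeFNF", function(pair, params = FNFParams())
    standardGeneric("composeFNF"))

#' @rdname rgbToHSV
#' @export
setGeneric("rgbToHSV", function(img) standardGeneric("rgbToHSV"))

#' @rdname detectPeppers
#' @export
setGeneric("detectPeppers", function(img, params = DetectorParams())
    standardGeneric("detectPeppers"))

#' @rdname renderScene
#' @export
setGeneric("renderScene", function(spec) standardGeneric("renderScene"))

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Pixel array of an image
#' @param x an [RGBImage-class].
#' @return the H x W x 3 intensity array.
#' @export
pixelArray <- function(x) x@pixels

#' @rdname pixelArray
#' @export
imgHeight <- function(x) dim(x@pixels)[1]

#' @rdname pixelArray
#' @export
imgWidth <- function(x) dim(x@pixels)[2]

#' HSV channel accessors
#' @param x an [HSVImage-class].
#' @return the requested channel matrix.
#' @export
hueChannel <- function(x) x@hue

#' @rdname hueChannel
#' @export
satChannel <- function(x) x@saturation

#' @rdname hueChannel
#' @export
valChannel <- function(x) x@value

#' FNFPair accessors
#' @param x an [FNFPair-class].
#' @return the requested component.
#' @export
flashImage <- function(x) x@flash

#' @rdname flashImage
#' @export
noflashImage <- function(x) x@noflash

#' @rdname flashImage
#' @export
frameIndices <- function(x) x@frameIndices

#' Composite image of a pair or scene, if already computed
#' @param x an [FNFPair-class] or [SceneData-class].
#' @return an [RGBImage-class] or NULL.
#' @export
compositeImage <- function(x) x@composite

#' Detection accessors
#' @param x a [Detection-class] or [GroundTruthObject-class].
#' @return the requested component.
#' @export
blobMask <- function(x) if (is(x, "Detection")) x@blobMask else x@mask

#' @rdname blobMask
#' @export
blobArea <- function(x) if (is(x, "Detection")) x@area else sum(x@mask)

#' @rdname blobMask
#' @export
boundingBox <- function(x) x@bbox

#' @rdname blobMask
#' @export
maturityOf <- function(x) x@maturity

#' Evaluation accessors
#' @param x an [EvalResult-class] or [EvalCounts-class].
#' @return the requested component.
#' @export
evalCounts <- function(x) if (is(x, "EvalResult")) x@counts else x

#' @rdname evalCounts
#' @export
precisionOf <- function(x) x@precision

#' @rdname evalCounts
#' @export
recallOf <- function(x) x@recall

#' @rdname evalCounts
#' @export
countsVector <- function(x) {
    x <- evalCounts(x)
    c(nTP = x@nTP, nFP = x@nFP, nFN = x@nFN, nFP1 = x@nFP1, nFP2 = x@nFP2,
      nDC = x@nDC)
}

#' Scene accessors
#' @param x a [SceneData-class].
#' @return the requested component.
#' @export
sceneTruth <- function(x) x@truth

#' @rdname sceneTruth
#' @export
sceneId <- function(x) x@id

#' @rdname sceneTruth
#' @export
truthObjects <- function(x) {
    if (is(x, "SceneData")) x <- x@truth
    x@objects
}

#' @rdname sceneTruth
#' @export
labelMask <- function(x) {
    if (is(x, "SceneData")) x <- x@truth
    x@labelMask
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "RGBImage", function(object) {
    cat(sprintf("RGBImage %d x %d, mean brightness %.1f\n",
                imgHeight(object), imgWidth(object),
                mean(object@pixels)))
})

setMethod("show", "HSVImage", function(object) {
    cat(sprintf("HSVImage %d x %d\n", nrow(object@hue), ncol(object@hue)))
})

setMethod("show", "FNFPair", function(object) {
    cat(sprintf(
        "FNFPair %d x %d (frames %s, %s), brightness delta %.1f, %s\n",
        imgHeight(object@flash), imgWidth(object@flash),
        object@frameIndices[1], object@frameIndices[2],
        meanBrightness(object@flash) - meanBrightness(object@noflash),
        if (is.null(object@composite)) "composite pending"
        else "composite ready"))
})

setMethod("show", "Detection", function(object) {
    cat(sprintf("Detection: area %d px, bbox [%s)\n", as.integer(object@area),
                paste(object@bbox, collapse = ", ")))
})

setMethod("show", "EvalCounts", function(object) {
    v <- countsVector(object)
    cat("EvalCounts:", paste(names(v), v, sep = "=", collapse = " "), "\n")
})

setMethod("show", "EvalResult", function(object) {
    cat(sprintf("EvalResult [%s, %s]: precision %s, recall %s\n",
                object@scheme, object@clusterMode,
                formatFraction(object@precision),
                formatFraction(object@recall)))
    show(object@counts)
})

setMethod("show", "SceneSpec", function(object) {
    cat(sprintf(
        "SceneSpec %d x %d: %d peppers, %d occluders, ambient %.2f, flash %.3f\n",
        object@width, object@height, length(object@peppers),
        length(object@occluders), object@ambientIntensity,
        object@flashIntensity))
})

setMethod("show", "SceneData", function(object) {
    cat(sprintf("SceneData '%s' %d x %d: %s, %s\n", object@id,
                imgHeight(object@flash), imgWidth(object@flash),
                if (is.null(object@composite)) "no composite"
                else "composite ready",
                if (is.null(object@truth)) "unlabeled"
                else sprintf("%d labeled objects",
                             length(object@truth@objects))))
})

formatFraction <- function(x) if (is.na(x)) "undefined" else sprintf("%.3f", x)
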