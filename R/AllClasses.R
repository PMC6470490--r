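#' @import methods
NULL

## ---------------------------------------------------------------------------
## Raster containers
## ---------------------------------------------------------------------------

#' RGBImage: 8-bit RGB raster
#'
#' A height x width x 3 array of integer intensities in [0, 255], channel
#' order red, green, blue. Row index is the image y coordinate (top to
#' bottom), column index the x coordinate.
#'
#' @slot pixels numeric array, dim c(height, width, 3), values in [0, 255].
#' @export
setClass("RGBImage", representation(pixels = "array"))

setValidity("RGBImage", function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
        return("'pixels' must be an H x W x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
        return("image must have height >= 1 and width >= 1")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
        return("channel values must lie in [0, 255]")
    TRUE
})

#' @describeIn RGBImage Constructor; rounds and validates the pixel array.
#' @param pixels H x W x 3 array (or H x W matrix, replicated over channels)
#'   of intensities in [0, 255].
#' @export
RGBImage <- function(pixels) {
    if (is.matrix(pixels))
        pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
    storage.mode(pixels) <- "double"
    new("RGBImage", pixels = round(pixels))
}

#' HSVImage: hue/saturation/value raster
#'
#' Per-pixel hue in degrees [0, 360), saturation and value in [0, 255].
#' A saturation of 0 implies hue 0 by convention.
#'
#' @slot hue numeric matrix, degrees in [0, 360).
#' @slot saturation numeric matrix in [0, 255].
#' @slot value numeric matrix in [0, 255].
#' @export
setClass("HSVImage", representation(hue = "matrix", saturation = "matrix",
                                    value = "matrix"))

setValidity("HSVImage", function(object) {
    d <- dim(object@hue)
    if (!identical(d, dim(object@saturation)) ||
        !identical(d, dim(object@value)))
        return("hue, saturation and value must share dimensions")
    if (min(object@hue) < 0 || max(object@hue) >= 360)
        return("hue must lie in [0, 360)")
    if (min(object@saturation) < 0 || max(object@saturation) > 255 ||
        min(object@value) < 0 || max(object@value) > 255)
        return("saturation and value must lie in [0, 255]")
    TRUE
})

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Flash/no-flash pairing and compositing parameters
#'
#' @slot brightnessDeltaThreshold minimum difference in mean image brightness
#'   (intensity units in [0, 255]) for two consecutive frames to form a valid
#'   flash/no-flash pair. The field-calibrated value is rig-specific; the
#'   default of 10 is conservative for any flash that visibly lifts exposure.
#' @slot saturationLevel channel value at or above which a flash pixel is
#'   considered overexposed ("saturated") and excluded from subtraction.
#' @export
setClass("FNFParams",
         representation(brightnessDeltaThreshold = "numeric",
                        saturationLevel = "numeric"),
         prototype(brightnessDeltaThreshold = 10, saturationLevel = 255))

setValidity("FNFParams", function(object) {
    if (length(object@brightnessDeltaThreshold) != 1L ||
        object@brightnessDeltaThreshold <= 0)
        return("brightnessDeltaThreshold must be a positive scalar")
    if (length(object@saturationLevel) != 1L ||
        object@saturationLevel <= 0 || object@saturationLevel > 255)
        return("saturationLevel must lie in (0, 255]")
    TRUE
})

#' @describeIn FNFParams Constructor with defaults.
#' @param brightnessDeltaThreshold see slot documentation.
#' @param saturationLevel see slot documentation.
#' @export
FNFParams <- function(brightnessDeltaThreshold = 10, saturationLevel = 255) {
    new("FNFParams", brightnessDeltaThreshold = brightnessDeltaThreshold,
        saturationLevel = saturationLevel)
}

#' Color-blob detector parameters
#'
#' Defaults are the calibrated yellow-pepper operating point: hue 20-50
#' degrees, saturation 90-255, minimum blob size 400 px at the 320 x 240
#' reference resolution. The minimum size scales linearly with pixel count
#' for other resolutions.
#'
#' @slot hueMin,hueMax hue band in degrees.
#' @slot satMin,satMax saturation band in [0, 255].
#' @slot minAreaRef minimum blob area in pixels at the reference resolution.
#' @slot refWidth,refHeight reference resolution for \code{minAreaRef}.
#' @slot morphCloseSize side of the square structuring element used for
#'   morphological closing.
#' @slot connectivity pixel connectivity for blob labeling, 4 or 8.
#' @export
setClass("DetectorParams",
         representation(hueMin = "numeric", hueMax = "numeric",
                        satMin = "numeric", satMax = "numeric",
                        minAreaRef = "numeric",
                        refWidth = "numeric", refHeight = "numeric",
                        morphCloseSize = "numeric", connectivity = "numeric"),
         prototype(hueMin = 20, hueMax = 50, satMin = 90, satMax = 255,
                   minAreaRef = 400, refWidth = 320, refHeight = 240,
                   morphCloseSize = 5, connectivity = 8))

setValidity("DetectorParams", function(object) {
    if (object@hueMin >= object@hueMax)
        return("hueMin must be < hueMax")
    if (object@satMin > object@satMax)
        return("satMin must be <= satMax")
    if (object@minAreaRef < 1)
        return("minAreaRef must be >= 1")
    if (!object@connectivity %in% c(4, 8))
        return("connectivity must be 4 or 8")
    if (object@morphCloseSize < 1)
        return("morphCloseSize must be >= 1")
    TRUE
})

#' @describeIn DetectorParams Constructor with the calibrated defaults.
#' @param hueMin,hueMax,satMin,satMax,minAreaRef,refWidth,refHeight
#'   see slot documentation.
#' @param morphCloseSize,connectivity see slot documentation.
#' @export
DetectorParams <- function(hueMin = 20, hueMax = 50, satMin = 90,
                           satMax = 255, minAreaRef = 400, refWidth = 320,
                           refHeight = 240, morphCloseSize = 5,
                           connectivity = 8) {
    new("DetectorParams", hueMin = hueMin, hueMax = hueMax, satMin = satMin,
        satMax = satMax, minAreaRef = minAreaRef, refWidth = refWidth,
        refHeight = refHeight, morphCloseSize = morphCloseSize,
        connectivity = connectivity)
}

#' Evaluation parameters
#'
#' @slot iouThreshold minimum bounding-box overlap ratio
#'   (intersection-over-union) for a detection to match a labeled fruit.
#' @slot containmentThreshold minimum fraction of a labeled fruit's pixels
#'   that must lie inside a single detection blob for the fruit to count as
#'   covered under cluster-credit scoring.
#' @export
setClass("EvalParams",
         representation(iouThreshold = "numeric",
                        containmentThreshold = "numeric"),
         prototype(iouThreshold = 0.5, containmentThreshold = 0.5))

setValidity("EvalParams", function(object) {
    if (object@iouThreshold <= 0 || object@iouThreshold > 1 ||
        object@containmentThreshold <= 0 || object@containmentThreshold > 1)
        return("thresholds must lie in (0, 1]")
    TRUE
})

#' @describeIn EvalParams Constructor.
#' @param iouThreshold,containmentThreshold see slot documentation.
#' @export
EvalParams <- function(iouThreshold = 0.5, containmentThreshold = 0.5) {
    new("EvalParams", iouThreshold = iouThreshold,
        containmentThreshold = containmentThreshold)
}

## ---------------------------------------------------------------------------
## Pairing, detections, ground truth
## ---------------------------------------------------------------------------

#' A validated flash/no-flash image pair
#'
#' Construct with [fnfPair()] or obtain from [scanStream()]. The composite
#' slot is filled lazily by [composeFNF()].
#'
#' @slot flash,noflash the two frames, identical dimensions.
#' @slot composite the FNF composite ([RGBImage]) once computed, else NULL.
#' @slot frameIndices integer positions (1-based) of the two frames in the
#'   source stream, flash first; c(NA, NA) for pairs built outside a stream.
#' @export
setClass("FNFPair",
         representation(flash = "RGBImage", noflash = "RGBImage",
                        composite = "ANY", frameIndices = "integer"),
         prototype(composite = NULL, frameIndices = c(NA_integer_,
                                                      NA_integer_)))

setValidity("FNFPair", function(object) {
    if (!identical(dim(object@flash@pixels), dim(object@noflash@pixels)))
        return("flash and noflash must have identical dimensions")
    TRUE
})

#' A segmented candidate-fruit blob
#'
#' @slot blobMask logical H x W matrix, TRUE on the blob's pixels.
#' @slot area number of TRUE pixels.
#' @slot bbox integer (x0, y0, x1, y1), 0-based half-open pixel coordinates,
#'   tight around the blob.
#' @export
setClass("Detection",
         representation(blobMask = "matrix", area = "numeric",
                        bbox = "numeric"))

setValidity("Detection", function(object) {
    if (object@area != sum(object@blobMask))
        return("area must equal the number of TRUE pixels in blobMask")
    if (length(object@bbox) != 4L)
        return("bbox must be (x0, y0, x1, y1)")
    tight <- tightBBox(object@blobMask)
    if (!isTRUE(all.equal(as.numeric(object@bbox), tight)))
        return("bbox must tightly enclose blobMask")
    TRUE
})

#' Maturity classes recognized by the evaluation protocol
#' @export
maturityClasses <- function() c("mature", "partially_mature", "immature",
                                "distant")

#' A labeled fruit region with maturity class
#'
#' @slot mask logical H x W matrix of the fruit's visible pixels (non-empty).
#' @slot bbox tight (x0, y0, x1, y1), 0-based half-open.
#' @slot maturity one of [maturityClasses()].
#' @export
setClass("GroundTruthObject",
         representation(mask = "matrix", bbox = "numeric",
                        maturity = "character"))

setValidity("GroundTruthObject", function(object) {
    if (!any(object@mask))
        return("ground-truth mask must be non-empty")
    if (!object@maturity %in% maturityClasses())
        return(sprintf("unknown maturity class '%s'", object@maturity))
    tight <- tightBBox(object@mask)
    if (!isTRUE(all.equal(as.numeric(object@bbox), tight)))
        return("bbox must tightly enclose mask")
    TRUE
})

#' @describeIn GroundTruthObject Constructor; the bbox is derived from the
#'   mask.
#' @param mask logical matrix of the fruit's pixels.
#' @param maturity maturity class string.
#' @export
GroundTruthObject <- function(mask, maturity) {
    new("GroundTruthObject", mask = mask, bbox = tightBBox(mask),
        maturity = maturity)
}

## ---------------------------------------------------------------------------
## Evaluation results
## ---------------------------------------------------------------------------

#' Detection/ground-truth agreement counts
#'
#' Houses the true-positive, false-positive and false-negative tallies
#' together with the finer false-positive taxonomy: nFP2 (partially mature
#' fruit detected as mature, strict scheme only), nFP1 (immature fruit
#' detected as mature) and nDC (distant out-of-range fruit detected;
#' ignored by both precision and recall).
#'
#' @slot nTP,nFP,nFN,nFP1,nFP2,nDC non-negative integer counts.
#' @export
setClass("EvalCounts",
         representation(nTP = "numeric", nFP = "numeric", nFN = "numeric",
                        nFP1 = "numeric", nFP2 = "numeric", nDC = "numeric"),
         prototype(nTP = 0, nFP = 0, nFN = 0, nFP1 = 0, nFP2 = 0, nDC = 0))

setValidity("EvalCounts", function(object) {
    v <- c(object@nTP, object@nFP, object@nFN, object@nFP1, object@nFP2,
           object@nDC)
    if (any(v < 0)) return("all counts must be non-negative")
    TRUE
})

#' @describeIn EvalCounts Constructor.
#' @param nTP,nFP,nFN,nFP1,nFP2,nDC counts.
#' @export
EvalCounts <- function(nTP = 0, nFP = 0, nFN = 0, nFP1 = 0, nFP2 = 0,
                       nDC = 0) {
    new("EvalCounts", nTP = unname(as.numeric(nTP)),
        nFP = unname(as.numeric(nFP)), nFN = unname(as.numeric(nFN)),
        nFP1 = unname(as.numeric(nFP1)), nFP2 = unname(as.numeric(nFP2)),
        nDC = unname(as.numeric(nDC)))
}

#' An evaluation outcome: counts plus derived precision and recall
#'
#' Precision and recall are `NA_real_` when their denominator is zero
#' (the explicit "undefined" marker).
#'
#' @slot counts an [EvalCounts].
#' @slot precision,recall fractions in [0, 1] or NA.
#' @slot scheme "strict" or "flexible".
#' @slot clusterMode "per_object" or "cluster_credit".
#' @export
setClass("EvalResult",
         representation(counts = "EvalCounts", precision = "numeric",
                        recall = "numeric", scheme = "character",
                        clusterMode = "character"))

setValidity("EvalResult", function(object) {
    if (!object@scheme %in% c("strict", "flexible"))
        return("scheme must be 'strict' or 'flexible'")
    if (!object@clusterMode %in% c("per_object", "cluster_credit"))
        return("clusterMode must be 'per_object' or 'cluster_credit'")
    TRUE
})

## ---------------------------------------------------------------------------
## Scene simulation
## ---------------------------------------------------------------------------

#' Generative description of one synthetic fruit
#'
#' @slot center (x, y) pixel coordinates of the ellipse center.
#' @slot semiAxes (a, b) ellipse semi-axes in pixels (>= 3).
#' @slot rotation major-axis rotation in degrees.
#' @slot depth distance from the camera in meters (> 0).
#' @slot maturity one of [maturityClasses()] except "distant" (the distant
#'   class is assigned from depth at render time).
#' @slot maturityLevel for partially mature fruit, the fraction of the
#'   surface carrying the mature hue.
#' @slot baseHue,baseSat,baseVal reflectance color (degrees, [0,255], [0,255]).
#' @export
setClass("PepperSpec",
         representation(center = "numeric", semiAxes = "numeric",
                        rotation = "numeric", depth = "numeric",
                        maturity = "character", maturityLevel = "numeric",
                        baseHue = "numeric", baseSat = "numeric",
                        baseVal = "numeric"),
         prototype(rotation = 0, maturityLevel = 1, baseSat = 210,
                   baseVal = 230))

setValidity("PepperSpec", function(object) {
    if (any(object@semiAxes < 3)) return("semiAxes must be >= 3 px")
    if (object@depth <= 0) return("depth must be > 0")
    TRUE
})

#' Generative description of a synthetic greenhouse scene
#'
#' The lighting model: the no-flash frame sees the scene under ambient
#' light only (intensity x directional gradient x per-channel tint); the
#' flash frame adds an artificial-light term that falls off with the
#' inverse square of object depth. Both frames receive independent
#' additive Gaussian sensor noise and are clipped to [0, 255], so strong
#' ambient light produces genuinely saturated pixels.
#'
#' @slot width,height raster size in pixels.
#' @slot peppers list of [PepperSpec-class].
#' @slot occluders list of leaf-shaped green elliptical patches (lists with
#'   center, semiAxes, rotation, depth, hue, sat, val).
#' @slot ambientIntensity ambient exposure (>= 0) against a quarter-scale
#'   reference: intensity 1 lights a perfect reflector to 25% of full
#'   scale, so 0.2 is dusk, 2 is strong daylight at a short exposure, and
#'   around 4 the frame blows out.
#' @slot ambientTint per-channel (R, G, B) ambient multipliers.
#' @slot ambientGradient c(angle_degrees, strength): linear directional
#'   shading across the frame simulating low sun; strength 0 disables it.
#' @slot objectShading strength in [0, 1] of the directional ambient
#'   shading across each curved object (sun-lit side versus shadow side of
#'   a fruit); 0 disables it. Affects ambient light only, so the
#'   flash-minus-ambient composite is invariant to it.
#' @slot flashIntensity flash power; an object at depth d receives a flash
#'   term of flashIntensity / d^2 times its reflectance. The default of
#'   0.029 fully exposes a target at 0.17 m, the nearest working distance,
#'   so flash light alone never overexposes fruit in range.
#' @slot noiseSigma additive Gaussian sensor noise, intensity units.
#' @slot distantCutoff depth in meters beyond which fruit is labeled
#'   "distant" (out of harvesting range).
#' @slot backgroundDepth,backgroundColor canvas depth (m) and RGB
#'   reflectance.
#' @slot rngSeed integer seed making the render deterministic.
#' @export
setClass("SceneSpec",
         representation(width = "numeric", height = "numeric",
                        peppers = "list", occluders = "list",
                        ambientIntensity = "numeric", ambientTint = "numeric",
                        ambientGradient = "numeric",
                        objectShading = "numeric",
                        flashIntensity = "numeric", noiseSigma = "numeric",
                        distantCutoff = "numeric",
                        backgroundDepth = "numeric",
                        backgroundColor = "numeric", rngSeed = "numeric"),
         prototype(width = 320, height = 240, peppers = list(),
                   occluders = list(), ambientIntensity = 1,
                   ambientTint = c(1, 1, 1), ambientGradient = c(0, 0),
                   objectShading = 0,
                   flashIntensity = 0.018, noiseSigma = 0.5,
                   distantCutoff = 0.6, backgroundDepth = 2.5,
                   backgroundColor = c(48, 52, 38), rngSeed = 1))

setValidity("SceneSpec", function(object) {
    if (object@width < 1 || object@height < 1)
        return("width and height must be >= 1")
    if (object@ambientIntensity < 0 || object@flashIntensity < 0 ||
        object@noiseSigma < 0)
        return("ambientIntensity, flashIntensity and noiseSigma must be >= 0")
    if (length(object@ambientTint) != 3L)
        return("ambientTint must have one multiplier per channel")
    if (object@objectShading < 0 || object@objectShading > 1)
        return("objectShading must lie in [0, 1]")
    ok <- vapply(object@peppers, is, logical(1), class2 = "PepperSpec")
    if (length(ok) && !all(ok))
        return("peppers must be a list of PepperSpec")
    TRUE
})

#' Ground truth for a rendered scene
#'
#' @slot labelMask integer H x W matrix of class codes (0 background,
#'   1 mature, 2 partially_mature, 3 immature, 4 distant).
#' @slot objects list of [GroundTruthObject-class], one per visible fruit.
#' @slot spec the [SceneSpec-class] that produced the scene (or NULL for
#'   scenes loaded from disk).
#' @export
setClass("SceneTruth",
         representation(labelMask = "matrix", objects = "list",
                        spec = "ANY"),
         prototype(spec = NULL))

#' One scene: flash and no-flash frames plus optional composite and truth
#'
#' @slot flash,noflash the paired frames.
#' @slot composite the FNF composite if already computed, else NULL.
#' @slot truth a [SceneTruth-class] or NULL for unlabeled scenes.
#' @slot id scene identifier string.
#' @export
setClass("SceneData",
         representation(flash = "RGBImage", noflash = "RGBImage",
                        composite = "ANY", truth = "ANY", id = "character"),
         prototype(composite = NULL, truth = NULL, id = NA_character_))
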