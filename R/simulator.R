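#' @include AllClasses.R AllGenerics.R imaging.R
NULL

#' Constructor for a synthetic fruit description
#'
#' @param center,semiAxes,rotation,depth,maturity,maturityLevel geometry
#'   and class, see [PepperSpec-class].
#' @param baseHue,baseSat,baseVal reflectance color; `baseHue` defaults to
#'   a ripe-yellow hue for mature fruit and a foliage-green hue for
#'   immature fruit.
#' @return a [PepperSpec-class].
#' @export
PepperSpec <- function(center, semiAxes, rotation = 0, depth = 0.2,
                       maturity = "mature", maturityLevel = 1,
                       baseHue = if (maturity == "immature") 100 else 35,
                       baseSat = 210, baseVal = 230) {
    new("PepperSpec", center = center, semiAxes = semiAxes,
        rotation = rotation, depth = depth, maturity = maturity,
        maturityLevel = maturityLevel, baseHue = baseHue, baseSat = baseSat,
        baseVal = baseVal)
}

#' Constructor for a synthetic scene description
#'
#' @param peppers list of [PepperSpec-class].
#' @param occluders list of leaf patches (see [leafSpec()]).
#' @param width,height,ambientIntensity,ambientTint,ambientGradient
#'   see [SceneSpec-class].
#' @param objectShading see [SceneSpec-class].
#' @param flashIntensity,noiseSigma,distantCutoff,rngSeed
#'   see [SceneSpec-class].
#' @param backgroundDepth,backgroundColor canvas depth and reflectance.
#' @return a [SceneSpec-class].
#' @export
SceneSpec <- function(peppers = list(), occluders = list(), width = 320,
                      height = 240, ambientIntensity = 1,
                      ambientTint = c(1, 1, 1), ambientGradient = c(0, 0),
                      objectShading = 0, flashIntensity = 0.018,
                      noiseSigma = 0.5, distantCutoff = 0.6,
                      backgroundDepth = 2.5,
                      backgroundColor = c(48, 52, 38), rngSeed = 1) {
    new("SceneSpec", width = width, height = height, peppers = peppers,
        occluders = occluders, ambientIntensity = ambientIntensity,
        ambientTint = ambientTint, ambientGradient = ambientGradient,
        objectShading = objectShading, flashIntensity = flashIntensity,
        noiseSigma = noiseSigma, distantCutoff = distantCutoff,
        backgroundDepth = backgroundDepth,
        backgroundColor = backgroundColor, rngSeed = rngSeed)
}

#' Leaf-shaped occluder description
#'
#' A green elliptical patch placed in front of the fruit plane to create
#' occlusion, the main source of missed fruit in real canopies.
#'
#' @param center,semiAxes,rotation,depth geometry; depth should be smaller
#'   than the occluded fruit's depth.
#' @param hue,sat,val reflectance color (foliage green by default).
#' @return a list usable in the `occluders` slot of [SceneSpec-class].
#' @export
leafSpec <- function(center, semiAxes, rotation = 0, depth = 0.15,
                     hue = 110, sat = 160, val = 120) {
    list(center = center, semiAxes = semiAxes, rotation = rotation,
         depth = depth, hue = hue, sat = sat, val = val)
}

## Logical mask of an axis-rotated ellipse over an H x W raster, plus the
## normalized radial and along-axis coordinates used for shading and the
## partial-maturity hue gradient.
ellipseField <- function(H, W, center, semiAxes, rotation) {
    x <- matrix(rep(seq_len(W), each = H), H, W) - center[1]
    y <- matrix(rep(seq_len(H), W), H, W) - center[2]
    th <- rotation * pi / 180
    u <- (x * cos(th) + y * sin(th)) / semiAxes[1]
    v <- (-x * sin(th) + y * cos(th)) / semiAxes[2]
    r2 <- u^2 + v^2
    list(mask = r2 <= 1, r2 = r2, axis = (u + 1) / 2, u = u, v = v)
}

hsv255ToRGB <- function(h, s, v) {
    grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 359.999) / 360,
                                      pmin(pmax(s, 0), 255) / 255,
                                      pmin(pmax(v, 0), 255) / 255))
}

#' Render a synthetic flash/no-flash scene with ground truth
#'
#' Per pixel, the reflectance color comes from the topmost
#' (smallest-depth) object, with a radial shading factor mimicking the
#' fruit's curvature. The no-flash frame is the reflectance under ambient
#' light alone (intensity x directional gradient x per-channel tint); the
#' flash frame adds `flashIntensity / depth^2` times the reflectance, so
#' flash light falls off with the inverse square of distance and nearby
#' fruit is exposed while the background stays dark. Independent Gaussian
#' sensor noise is added to each frame before clipping to [0, 255] and
#' rounding, so strong ambient light yields genuinely saturated pixels.
#' Fruit beyond `distantCutoff` is labeled "distant". The render is
#' deterministic given `rngSeed`.
#'
#' @param spec a [SceneSpec-class].
#' @return a [SceneData-class] carrying the flash frame, the no-flash
#'   frame and a [SceneTruth-class] (label mask + per-object ground truth).
#' @export
setMethod("renderScene", "SceneSpec", function(spec) {
    validObject(spec)
    H <- spec@height; W <- spec@width
    depth <- matrix(spec@backgroundDepth, H, W)
    refl <- lapply(spec@backgroundColor, function(cc) matrix(cc, H, W))
    objectId <- matrix(0L, H, W)
    ambShade <- matrix(1, H, W)     # directional ambient shading per object
    specAmb <- matrix(0, H, W)      # glossy reflection of the ambient light
    specFlash <- matrix(0, H, W)    # glossy reflection of the flash

    classCode <- c(mature = 1L, partially_mature = 2L, immature = 3L,
                   distant = 4L)
    immatureHue <- 100

    paintEllipse <- function(fld, objDepth, h, s, v, id) {
        vis <- fld$mask & (objDepth < depth)
        if (!any(vis)) return(invisible(NULL))
        shade <- 1 - 0.25 * fld$r2[vis]
        rgb <- hsv255ToRGB(h[vis], s[vis], v[vis] * shade)
        for (ch in 1:3) {
            m <- refl[[ch]]; m[vis] <- rgb[ch, ]; refl[[ch]] <<- m
        }
        depth[vis] <<- objDepth
        objectId[vis] <<- id
        ## ambient reaches the sun-facing end of the object fully and the
        ## far end attenuated: the within-object illumination gradient the
        ## flash-minus-ambient composite is designed to remove
        ambShade[vis] <<- 1 - spec@objectShading * fld$axis[vis]
        vis
    }

    withSeed(spec@rngSeed, {
        objs <- c(lapply(seq_along(spec@peppers), function(i)
                      list(kind = "pepper", i = i,
                           depth = spec@peppers[[i]]@depth)),
                  lapply(spec@occluders, function(o)
                      list(kind = "leaf", o = o, depth = o$depth)))
        ord <- order(-vapply(objs, `[[`, numeric(1), "depth"))   # far first
        for (ob in objs[ord]) {
            if (ob$kind == "pepper") {
                p <- spec@peppers[[ob$i]]
                fld <- ellipseField(H, W, p@center, p@semiAxes, p@rotation)
                hue <- matrix(p@baseHue, H, W)
                if (p@maturity == "partially_mature") {
                    ## hue switches from mature to immature along the
                    ## fruit axis; the mature fraction is maturityLevel
                    t0 <- p@maturityLevel
                    band <- 0.08
                    wgt <- pmin(pmax((t0 - fld$axis) / band + 0.5, 0), 1)
                    hue <- immatureHue + (p@baseHue - immatureHue) * wgt
                }
                vis <- paintEllipse(fld, p@depth, hue,
                                    matrix(p@baseSat, H, W),
                                    matrix(p@baseVal, H, W), ob$i)
                if (!is.null(vis) && any(vis)) {
                    ## waxy pepper skin reflects its illuminants
                    ## specularly: the ambient light leaves an
                    ## illuminant-colored lobe at a random spot on the lit
                    ## surface (removed exactly by FNF compositing, being
                    ## linear in ambient); the camera-mounted flash leaves
                    ## a centered lobe that survives in the composite
                    hc <- stats::runif(2, -0.5, 0.5)
                    amp <- stats::runif(1, 0.2, 0.6)
                    d2 <- (fld$u - hc[1])^2 + (fld$v - hc[2])^2
                    specAmb[vis] <- amp * exp(-d2[vis] / (2 * 0.35^2))
                    specFlash[vis] <- 0.3 * exp(-fld$r2[vis] / (2 * 0.25^2))
                }
            } else {
                o <- ob$o
                fld <- ellipseField(H, W, o$center, o$semiAxes, o$rotation)
                paintEllipse(fld, o$depth, matrix(o$hue, H, W),
                             matrix(o$sat, H, W), matrix(o$val, H, W), 0L)
            }
        }

        ## directional ambient gradient, mean ~1 across the frame
        ga <- spec@ambientGradient[1] * pi / 180
        gs <- spec@ambientGradient[2]
        if (gs > 0) {
            x <- matrix(rep(seq_len(W), each = H), H, W) / W
            y <- matrix(rep(seq_len(H), W), H, W) / H
            proj <- (x * cos(ga) + y * sin(ga) + 1) / 2
            grad <- 1 - gs / 2 + gs * proj
        } else grad <- matrix(1, H, W)

        flashFactor <- spec@flashIntensity / depth^2
        ## ambientIntensity is expressed against a quarter-scale reference
        ## exposure: intensity 1 lights a perfect reflector to 25% of full
        ## scale, so the dim-to-strong daylight span is roughly 0.2-2 and
        ## only intensities near 4 blow out the whole frame
        ambientRef <- 0.25
        mkFrame <- function(withFlash) {
            px <- array(0, dim = c(H, W, 3))
            for (ch in 1:3) {
                sig <- spec@ambientIntensity * ambientRef *
                    spec@ambientTint[ch] *
                    (grad * ambShade * refl[[ch]] + 255 * specAmb)
                if (withFlash)
                    sig <- sig + flashFactor * (refl[[ch]] + 255 * specFlash)
                if (spec@noiseSigma > 0)
                    sig <- sig + matrix(stats::rnorm(H * W, 0,
                                                     spec@noiseSigma), H, W)
                px[, , ch] <- clamp255(sig)
            }
            RGBImage(px)
        }
        noflash <- mkFrame(FALSE)
        flash <- mkFrame(TRUE)

        label <- matrix(0L, H, W)
        objects <- list()
        for (i in seq_along(spec@peppers)) {
            p <- spec@peppers[[i]]
            vis <- objectId == i
            if (!any(vis)) next     # fully occluded fruit carries no label
            cls <- if (p@depth > spec@distantCutoff) "distant" else
                p@maturity
            label[vis] <- classCode[[cls]]
            objects[[length(objects) + 1L]] <- GroundTruthObject(vis, cls)
        }
        truth <- new("SceneTruth", labelMask = label, objects = objects,
                     spec = spec)
        new("SceneData", flash = flash, noflash = noflash, truth = truth)
    })
})

#' Default random-scene configuration
#'
#' Ranges emulating the acquisition conditions of a greenhouse
#' sweet-pepper database: 320 x 240 frames, one to four fruit per scene at
#' working distances of 0.17-0.26 m, occasional adjacent fruit forming
#' clusters, leaf occluders, out-of-range background fruit, ambient light
#' varying in intensity, color cast and direction between scenes, and a
#' flash tuned to fully expose fruit at 0.2 m.
#'
#' @param ... overrides for any listed element.
#' @return named list of generation ranges.
#' @export
sceneConfig <- function(...) {
    cfg <- list(
        width = 320, height = 240,
        nPeppersRange = c(1L, 4L),
        maturityProbs = c(mature = 0.55, partially_mature = 0.20,
                          immature = 0.15, distant = 0.10),
        clusterProbability = 0.3,
        baseSizeRange = c(18, 30),          # semi-major axis at 0.22 m, px
        aspectRange = c(0.8, 1.1),
        nearDepthRange = c(0.17, 0.26),
        distantDepthRange = c(0.65, 1.0),
        sizeRefDepth = 0.22,                # apparent size ~ 1/depth
        maturityLevelRange = c(0.5, 0.95),
        occluderCountRange = c(0L, 2L),
        occluderSizeRange = c(8, 16),
        ambientIntensityRange = c(0.2, 2.0),
        tintRange = c(0.4, 1.6),
        gradientStrengthRange = c(0, 0.6),
        objectShadingRange = c(0.4, 0.9),
        flashIntensity = 0.018,
        noiseSigma = 0.5,
        distantCutoff = 0.6)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad,
                                                         collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

## integer draw from an inclusive range; safe for degenerate ranges where
## sample(n:n, 1) would draw from 1:n
sampleRange <- function(range) {
    if (range[1] == range[2]) return(as.integer(range[1]))
    sample(seq.int(range[1], range[2]), 1)
}

#' Draw a random scene description from a configuration
#'
#' All randomness (fruit count, classes, geometry, lighting) flows from
#' `seed`; the returned spec renders deterministically.
#'
#' @param config list from [sceneConfig()].
#' @param seed integer seed.
#' @return a [SceneSpec-class].
#' @export
randomSceneSpec <- function(config = sceneConfig(), seed = 1) {
    withSeed(seed, {
        W <- config$width; H <- config$height
        n <- sampleRange(config$nPeppersRange)
        peppers <- list()
        lastCenter <- NULL
        for (i in seq_len(n)) {
            mat <- sample(names(config$maturityProbs), 1,
                          prob = config$maturityProbs)
            depth <- if (mat == "distant") runif1(config$distantDepthRange)
                     else runif1(config$nearDepthRange)
            a <- runif1(config$baseSizeRange) * config$sizeRefDepth / depth
            b <- a * runif1(config$aspectRange)
            a <- max(a, 3); b <- max(b, 3)
            clustered <- !is.null(lastCenter) && mat != "distant" &&
                stats::runif(1) < config$clusterProbability
            center <- if (clustered)
                lastCenter + stats::runif(2, -1, 1) * c(a, b) * 1.2
            else c(stats::runif(1, 0.15 * W, 0.85 * W),
                   stats::runif(1, 0.15 * H, 0.85 * H))
            if (mat != "distant") lastCenter <- center
            peppers[[i]] <- PepperSpec(
                center = center, semiAxes = c(a, b),
                rotation = stats::runif(1, 0, 180), depth = depth,
                maturity = if (mat == "distant") "mature" else mat,
                maturityLevel = if (mat == "partially_mature")
                    runif1(config$maturityLevelRange) else 1,
                baseHue = if (mat == "immature")
                    stats::rnorm(1, 100, 5) else stats::rnorm(1, 35, 3),
                baseSat = stats::runif(1, 185, 235),
                baseVal = stats::runif(1, 205, 245))
        }
        nOcc <- sampleRange(config$occluderCountRange)
        occluders <- lapply(seq_len(nOcc), function(k) {
            anchor <- peppers[[sample(length(peppers), 1)]]
            leafSpec(center = anchor@center + stats::runif(2, -25, 25),
                     semiAxes = c(runif1(config$occluderSizeRange),
                                  runif1(config$occluderSizeRange) * 0.6),
                     rotation = stats::runif(1, 0, 180),
                     depth = max(0.08,
                                 anchor@depth - stats::runif(1, 0.02, 0.05)),
                     hue = stats::rnorm(1, 110, 8),
                     sat = stats::runif(1, 120, 200),
                     val = stats::runif(1, 80, 160))
        })
        SceneSpec(peppers = peppers, occluders = occluders, width = W,
                  height = H,
                  ambientIntensity = runif1(config$ambientIntensityRange),
                  ## tints carry chromaticity only (mean-normalized);
                  ## overall ambient energy lives in ambientIntensity
                  ambientTint = {
                      tnt <- stats::runif(3, config$tintRange[1],
                                          config$tintRange[2])
                      tnt / mean(tnt)
                  },
                  ambientGradient = c(stats::runif(1, 0, 360),
                                      runif1(config$gradientStrengthRange)),
                  objectShading = runif1(config$objectShadingRange),
                  flashIntensity = config$flashIntensity,
                  noiseSigma = config$noiseSigma,
                  distantCutoff = config$distantCutoff,
                  rngSeed = sample.int(2147483646L, 1))
    })
}

#' Render a batch of random scenes in memory
#'
#' @param config list from [sceneConfig()].
#' @param nScenes number of scenes.
#' @param masterSeed integer; per-scene seeds are derived deterministically
#'   from it.
#' @return list of [SceneData-class] with ids scene_0001, ...
#' @export
simulateScenes <- function(config = sceneConfig(), nScenes = 10,
                           masterSeed = 1) {
    lapply(seq_len(nScenes), function(i) {
        sc <- renderScene(randomSceneSpec(config, deriveSeed(masterSeed, i)))
        sc@id <- sprintf("scene_%04d", i)
        sc
    })
}
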