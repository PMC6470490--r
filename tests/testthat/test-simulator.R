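onePepperSpec <- function(depth = 0.2, maturity = "mature", seed = 9,
                          ...) {
    SceneSpec(peppers = list(PepperSpec(center = c(60, 50),
                                        semiAxes = c(18, 14),
                                        depth = depth,
                                        maturity = maturity)),
              width = 120, height = 100, rngSeed = seed, ...)
}

test_that("no ambient light and no noise renders a black no-flash frame", {
    sc <- renderScene(onePepperSpec(ambientIntensity = 0, noiseSigma = 0))
    expect_equal(max(pixelArray(noflashImage(sc))), 0)
    expect_gt(max(pixelArray(flashImage(sc))), 0)
})

test_that("flash light falls off with the inverse square of depth", {
    base <- onePepperSpec(depth = 1, ambientIntensity = 0, noiseSigma = 0,
                          flashIntensity = 0.5)    # avoid clipping at d=1
    near <- renderScene(base)
    base@peppers[[1]]@depth <- 2
    far <- renderScene(base)
    fn <- pixelArray(flashImage(near)); ff <- pixelArray(flashImage(far))
    lit <- fn[, , 1] > 20 & ff[, , 1] > 0
    ratio <- fn[, , 1][lit] / ff[, , 1][lit]
    expect_equal(median(ratio), 4, tolerance = 0.05)
})

test_that("the flash frame never falls below the ambient frame", {
    for (seed in c(2, 3)) {
        spec <- randomSceneSpec(sceneConfig(noiseSigma = 0), seed)
        sc <- renderScene(spec)
        expect_true(all(pixelArray(flashImage(sc)) >=
                        pixelArray(noflashImage(sc))))
    }
})

test_that("ambient perturbations leave the noiseless composite invariant", {
    ## low ambient + gentle flash: no pixel clips, so subtraction recovers
    ## the flash-only render to integer rounding
    mk <- function(amb, tint, grad, shading) {
        renderScene(onePepperSpec(ambientIntensity = amb,
                                  ambientTint = tint,
                                  ambientGradient = grad,
                                  objectShading = shading,
                                  noiseSigma = 0, flashIntensity = 0.01))
    }
    a <- mk(0.3, c(1.2, 0.9, 0.9), c(45, 0.4), 0.6)
    b <- mk(0.8, c(0.7, 1.1, 1.2), c(200, 0.2), 0.2)
    expect_lt(max(pixelArray(flashImage(a))), 255)   # genuinely unclipped
    expect_lt(max(pixelArray(flashImage(b))), 255)
    ca <- pixelArray(fnfComposite(flashImage(a), noflashImage(a)))
    cb <- pixelArray(fnfComposite(flashImage(b), noflashImage(b)))
    expect_lte(max(abs(ca - cb)), 1)
})

test_that("distant fruit receives flash below the saturation threshold", {
    spec <- onePepperSpec(depth = 0.7, ambientIntensity = 0, noiseSigma = 0)
    sc <- renderScene(spec)
    expect_lt(max(pixelArray(flashImage(sc))), 90)
    expect_equal(maturityOf(truthObjects(sc)[[1]]), "distant")
    expect_equal(sort(unique(as.vector(labelMask(sc)))), c(0L, 4L))
})

test_that("maturity classes drive reflectance hue and label codes", {
    scM <- renderScene(onePepperSpec(ambientIntensity = 0, noiseSigma = 0))
    hsv <- rgbToHSV(flashImage(scM))
    fruit <- labelMask(scM) == 1
    expect_true(any(fruit))
    expect_true(median(hueChannel(hsv)[fruit]) > 20 &&
                median(hueChannel(hsv)[fruit]) < 50)

    scI <- renderScene(onePepperSpec(maturity = "immature",
                                     ambientIntensity = 0, noiseSigma = 0))
    hsvI <- rgbToHSV(flashImage(scI))
    green <- labelMask(scI) == 3
    expect_true(median(hueChannel(hsvI)[green]) > 80)

    ## partial maturity mixes both hue populations over one fruit
    spec <- onePepperSpec(maturity = "partially_mature",
                          ambientIntensity = 0, noiseSigma = 0)
    spec@peppers[[1]]@maturityLevel <- 0.6
    scP <- renderScene(spec)
    hsvP <- rgbToHSV(flashImage(scP))
    hues <- hueChannel(hsvP)[labelMask(scP) == 2]
    expect_true(mean(hues < 60) > 0.3 && mean(hues > 80) > 0.1)
})

test_that("rendering is deterministic and occlusion trims truth masks", {
    spec <- randomSceneSpec(sceneConfig(), 77)
    s1 <- renderScene(spec); s2 <- renderScene(spec)
    expect_identical(pixelArray(flashImage(s1)), pixelArray(flashImage(s2)))
    expect_identical(labelMask(s1), labelMask(s2))

    ## a leaf painted over a fruit removes those pixels from its truth mask
    base <- onePepperSpec(ambientIntensity = 0, noiseSigma = 0)
    occ <- base
    occ@occluders <- list(leafSpec(center = c(60, 50),
                                   semiAxes = c(10, 6), depth = 0.1))
    so <- renderScene(occ); sb <- renderScene(base)
    expect_lt(blobArea(truthObjects(so)[[1]]),
              blobArea(truthObjects(sb)[[1]]))
})

test_that("forced clustering places overlapping fruit pairs", {
    cfg <- sceneConfig(clusterProbability = 1, nPeppersRange = c(2L, 2L),
                       maturityProbs = c(mature = 1, partially_mature = 0,
                                         immature = 0, distant = 0),
                       occluderCountRange = c(0L, 0L))
    for (seed in c(4, 8, 15)) {
        spec <- randomSceneSpec(cfg, seed)
        p1 <- spec@peppers[[1]]; p2 <- spec@peppers[[2]]
        gap <- sqrt(sum((p1@center - p2@center)^2))
        expect_lt(gap, max(p1@semiAxes) + max(p2@semiAxes))
    }
})

test_that("dataset generation is reproducible and self-consistent", {
    d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
    on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
    m1 <- generateDataset(sceneConfig(), 2, 123, d1)
    m2 <- generateDataset(sceneConfig(), 2, 123, d2)
    for (f in c("classmap.json", "manifest.json",
                file.path("scene_0001", c("flash.png", "noflash.png",
                                          "labels.png", "instances.png",
                                          "truth.json")))) {
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6),
                         label = f)
    }
    ## manifest bookkeeping matches the scenes on disk
    scenes <- readDataset(d1)
    expect_length(scenes, 2L)
    nOnDisk <- vapply(scenes, function(s) length(truthObjects(s)),
                      integer(1))
    nManifest <- vapply(m1$scenes, function(s) s$n_objects, integer(1))
    expect_equal(nOnDisk, nManifest)
})
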