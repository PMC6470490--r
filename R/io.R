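#' @include AllClasses.R AllGenerics.R simulator.R
NULL

classMap <- function() {
    c("0" = "background", "1" = "mature", "2" = "partially_mature",
      "3" = "immature", "4" = "distant")
}

#' Read an 8-bit PNG as an RGBImage
#' @param path PNG file path.
#' @return an [RGBImage-class].
#' @export
readRGBImage <- function(path) {
    if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L)
        a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    RGBImage(round(a[, , 1:3, drop = FALSE] * 255))
}

#' Write an RGBImage as an 8-bit PNG
#' @param img an [RGBImage-class].
#' @param path output file path.
#' @export
writeRGBImage <- function(img, path) {
    png::writePNG(img@pixels / 255, path)
    invisible(path)
}

readCodePNG <- function(path) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

writeCodePNG <- function(codes, path) {
    png::writePNG(codes / 255, path)
    invisible(path)
}

#' Write one scene to a directory
#'
#' Layout: flash.png, noflash.png, and for labeled scenes labels.png
#' (8-bit class codes), instances.png (8-bit per-object ids) and
#' truth.json (object table and render parameters). A composite already
#' attached to the scene is written as fnf.png.
#'
#' @param scene a [SceneData-class].
#' @param path target directory (created if needed).
#' @export
writeSceneDir <- function(scene, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    writeRGBImage(scene@flash, file.path(path, "flash.png"))
    writeRGBImage(scene@noflash, file.path(path, "noflash.png"))
    if (!is.null(scene@composite))
        writeRGBImage(scene@composite, file.path(path, "fnf.png"))
    tr <- scene@truth
    if (!is.null(tr)) {
        writeCodePNG(tr@labelMask, file.path(path, "labels.png"))
        inst <- matrix(0L, nrow(tr@labelMask), ncol(tr@labelMask))
        for (i in seq_along(tr@objects)) inst[tr@objects[[i]]@mask] <- i
        writeCodePNG(inst, file.path(path, "instances.png"))
        objs <- lapply(seq_along(tr@objects), function(i) {
            o <- tr@objects[[i]]
            list(id = i, maturity = o@maturity,
                 bbox = as.integer(o@bbox), area = sum(o@mask))
        })
        meta <- list(id = scene@id, objects = objs)
        if (!is.null(tr@spec))
            meta$render <- list(
                ambient_intensity = tr@spec@ambientIntensity,
                ambient_tint = tr@spec@ambientTint,
                flash_intensity = tr@spec@flashIntensity,
                noise_sigma = tr@spec@noiseSigma,
                rng_seed = tr@spec@rngSeed)
        jsonlite::write_json(meta, file.path(path, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}

#' Read one scene directory
#'
#' Expects flash.png and noflash.png; fnf.png, labels.png, instances.png
#' and truth.json are loaded when present. Label codes are validated
#' against classmap.json (searched in the scene directory, then its
#' parent); codes absent from the classmap are an error.
#'
#' @param path scene directory.
#' @param classmap optional named character vector code -> class name,
#'   overriding the classmap.json lookup.
#' @return a [SceneData-class].
#' @export
readSceneDir <- function(path, classmap = NULL) {
    if (!dir.exists(path)) stop(sprintf("scene directory not found: %s",
                                        path))
    for (f in c("flash.png", "noflash.png"))
        if (!file.exists(file.path(path, f)))
            stop(sprintf("scene '%s' is missing %s", path, f))
    flash <- readRGBImage(file.path(path, "flash.png"))
    noflash <- readRGBImage(file.path(path, "noflash.png"))
    if (!identical(dim(flash@pixels), dim(noflash@pixels)))
        stop(sprintf("scene '%s': flash and noflash dimensions differ",
                     path))
    composite <- if (file.exists(file.path(path, "fnf.png")))
        readRGBImage(file.path(path, "fnf.png")) else NULL

    truth <- NULL
    labPath <- file.path(path, "labels.png")
    if (file.exists(labPath)) {
        if (is.null(classmap)) {
            for (cand in c(file.path(path, "classmap.json"),
                           file.path(dirname(path), "classmap.json"))) {
                if (file.exists(cand)) {
                    cm <- jsonlite::read_json(cand)
                    classmap <- vapply(cm, as.character, character(1))
                    break
                }
            }
            if (is.null(classmap)) classmap <- classMap()
        }
        label <- readCodePNG(labPath)
        codes <- unique(as.vector(label))
        unknown <- setdiff(as.character(codes), names(classmap))
        if (length(unknown))
            stop(sprintf("scene '%s': label code(s) %s absent from classmap",
                         path, paste(unknown, collapse = ", ")))
        objects <- list()
        instPath <- file.path(path, "instances.png")
        metaPath <- file.path(path, "truth.json")
        if (file.exists(instPath) && file.exists(metaPath)) {
            inst <- readCodePNG(instPath)
            meta <- jsonlite::read_json(metaPath)
            objects <- lapply(meta$objects, function(o) {
                m <- inst == o$id
                if (!any(m))
                    stop(sprintf("scene '%s': object %d has no pixels",
                                 path, o$id))
                GroundTruthObject(m, o$maturity)
            })
        }
        truth <- new("SceneTruth", labelMask = label, objects = objects)
    }
    new("SceneData", flash = flash, noflash = noflash,
        composite = composite, truth = truth, id = basename(path))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nScenes` scene directories (scene_0001, ...) under `outDir`,
#' each with flash.png, noflash.png, labels.png, instances.png and
#' truth.json, plus classmap.json and manifest.json at the root. Scene
#' parameters are drawn from `config` using per-scene seeds derived
#' deterministically from `masterSeed`, so two runs with the same
#' arguments produce byte-identical output.
#'
#' @param config list from [sceneConfig()].
#' @param nScenes number of scenes (>= 1).
#' @param masterSeed integer master seed.
#' @param outDir output directory.
#' @return (invisibly) the manifest as a list.
#' @export
generateDataset <- function(config = sceneConfig(), nScenes = 10,
                            masterSeed = 1, outDir) {
    if (nScenes < 1L) stop("nScenes must be >= 1")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop(sprintf("cannot create out_dir: %s",
                                          outDir))
    jsonlite::write_json(as.list(classMap()),
                         file.path(outDir, "classmap.json"),
                         auto_unbox = TRUE)
    entries <- vector("list", nScenes)
    for (i in seq_len(nScenes)) {
        seed <- deriveSeed(masterSeed, i)
        scene <- renderScene(randomSceneSpec(config, seed))
        scene@id <- sprintf("scene_%04d", i)
        writeSceneDir(scene, file.path(outDir, scene@id))
        entries[[i]] <- list(id = scene@id, seed = seed,
                             n_objects = length(scene@truth@objects))
    }
    manifest <- list(n_scenes = nScenes, master_seed = masterSeed,
                     scenes = entries)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Read a dataset directory into a list of scenes
#'
#' Scenes are taken from manifest.json when present, otherwise from the
#' scene_* subdirectories in sorted order.
#'
#' @param root dataset root directory.
#' @return list of [SceneData-class].
#' @export
readDataset <- function(root) {
    if (!dir.exists(root)) stop(sprintf("dataset directory not found: %s",
                                        root))
    manPath <- file.path(root, "manifest.json")
    ids <- if (file.exists(manPath)) {
        man <- jsonlite::read_json(manPath)
        vapply(man$scenes, function(s) s$id, character(1))
    } else {
        sort(basename(Filter(dir.exists,
                             list.files(root, pattern = "^scene_",
                                        full.names = TRUE))))
    }
    if (length(ids) == 0L) stop(sprintf("no scenes found under %s", root))
    lapply(ids, function(id) readSceneDir(file.path(root, id)))
}

#' Serialize detections to JSON
#'
#' One record per blob: image id, 0-based half-open bbox and pixel area.
#'
#' @param detsPerScene named list (scene id -> list of [Detection-class]).
#' @param path output JSON file.
#' @export
writeDetectionsJSON <- function(detsPerScene, path) {
    recs <- list()
    for (id in names(detsPerScene))
        for (d in detsPerScene[[id]])
            recs[[length(recs) + 1L]] <- list(
                image_id = id, bbox = as.integer(d@bbox), area = d@area)
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
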