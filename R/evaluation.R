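#' @include AllClasses.R AllGenerics.R detector.R
NULL

#' Bounding-box overlap ratio (intersection over union)
#'
#' Boxes are (x0, y0, x1, y1) in 0-based half-open pixel coordinates.
#' Disjoint boxes have ratio 0; degenerate (zero-area) boxes are an error.
#'
#' @param boxA,boxB numeric length-4 boxes.
#' @return fraction in [0, 1].
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
boxIoU <- function(boxA, boxB) {
    areaOf <- function(b) (b[3] - b[1]) * (b[4] - b[2])
    if (areaOf(boxA) <= 0 || areaOf(boxB) <= 0)
        stop("degenerate (zero-area) bounding box")
    iw <- min(boxA[3], boxB[3]) - max(boxA[1], boxB[1])
    ih <- min(boxA[4], boxB[4]) - max(boxA[2], boxB[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / (areaOf(boxA) + areaOf(boxB) - inter)
}

countableClasses <- function(scheme) {
    if (scheme == "flexible") c("mature", "partially_mature") else "mature"
}

## Classify one matched/covering (detection, truth) event into the
## six-way taxonomy, returning the count-slot name it increments
## ("nTP", "nFP2", "nFP1" or "nDC").
classifyMatch <- function(maturity, scheme) {
    switch(maturity,
           mature = "nTP",
           partially_mature = if (scheme == "flexible") "nTP" else "nFP2",
           immature = "nFP1",
           distant = "nDC")
}

#' Per-object detection/truth matching
#'
#' Candidate (detection, truth) pairs with bounding-box overlap ratio of at
#' least `iouThreshold` are matched greedily in descending overlap order
#' (ties broken by truth index, then detection index); each detection and
#' each truth is used at most once. Matched pairs are classified by the
#' truth's maturity: mature is a true positive; partially mature a true
#' positive under the flexible scheme and an FP2 under strict; immature an
#' FP1; distant a DC (ignored by both measures). Unmatched detections are
#' false positives. Unmatched countable truths (mature, plus partially
#' mature under flexible) are false negatives; immature and distant truths
#' never count as missed.
#'
#' @param dets list of [Detection-class].
#' @param truths list of [GroundTruthObject-class] from the same image.
#' @param scheme "strict" or "flexible".
#' @param params an [EvalParams-class].
#' @return an [EvalCounts-class].
#' @export
matchDetections <- function(dets, truths, scheme = c("strict", "flexible"),
                            params = EvalParams()) {
    scheme <- match.arg(scheme)
    nd <- length(dets); nt <- length(truths)
    cand <- NULL
    if (nd > 0L && nt > 0L) {
        cand <- expand.grid(det = seq_len(nd), truth = seq_len(nt))
        cand$iou <- mapply(function(d, t)
            boxIoU(dets[[d]]@bbox, truths[[t]]@bbox), cand$det, cand$truth)
        cand <- cand[cand$iou >= params@iouThreshold, , drop = FALSE]
        cand <- cand[order(-cand$iou, cand$truth, cand$det), , drop = FALSE]
    }
    detUsed <- logical(nd); truthUsed <- logical(nt)
    counts <- c(nTP = 0, nFP = 0, nFN = 0, nFP1 = 0, nFP2 = 0, nDC = 0)
    if (!is.null(cand)) {
        for (k in seq_len(nrow(cand))) {
            d <- cand$det[k]; t <- cand$truth[k]
            if (detUsed[d] || truthUsed[t]) next
            detUsed[d] <- TRUE; truthUsed[t] <- TRUE
            slot <- classifyMatch(truths[[t]]@maturity, scheme)
            counts[slot] <- counts[slot] + 1
        }
    }
    counts["nFP"] <- sum(!detUsed)
    countable <- vapply(truths, function(t)
        t@maturity %in% countableClasses(scheme), logical(1))
    counts["nFN"] <- sum(!truthUsed & countable)
    EvalCounts(counts["nTP"], counts["nFP"], counts["nFN"], counts["nFP1"],
               counts["nFP2"], counts["nDC"])
}

#' Cluster-credit counting
#'
#' The harvesting-oriented relaxation of per-object matching: when
#' morphological cleanup merges a cluster of fruit into one blob, every
#' fruit lying within the detected region still counts as detected,
#' because visual servoing separates merged detections during the
#' approach. A truth is "covered" when at least `containmentThreshold` of
#' its mask pixels lie inside a single detection's blob mask. Every covered
#' countable truth is a true positive; uncovered countable truths are
#' false negatives. A detection covering no countable truth is classified
#' by the best-covered truth it does cover (partially mature under strict:
#' FP2; immature: FP1; distant: DC), or is a plain false positive if it
#' covers nothing.
#'
#' @inheritParams matchDetections
#' @return an [EvalCounts-class].
#' @export
clusterCreditCounts <- function(dets, truths,
                                scheme = c("strict", "flexible"),
                                params = EvalParams()) {
    scheme <- match.arg(scheme)
    nd <- length(dets); nt <- length(truths)
    if (nd > 0L && any(vapply(dets, function(d) length(d@blobMask) == 0L,
                              logical(1))))
        stop("cluster-credit counting requires detection blob masks")
    cover <- matrix(0, nd, nt)      # fraction of truth t inside det d
    for (d in seq_len(nd)) for (t in seq_len(nt)) {
        tm <- truths[[t]]@mask
        cover[d, t] <- sum(dets[[d]]@blobMask & tm) / sum(tm)
    }
    covered <- if (nd > 0L && nt > 0L)
        apply(cover >= params@containmentThreshold, 2, any) else
        rep(FALSE, nt)
    countable <- vapply(truths, function(t)
        t@maturity %in% countableClasses(scheme), logical(1))
    counts <- c(nTP = sum(covered & countable),
                nFP = 0, nFN = sum(!covered & countable),
                nFP1 = 0, nFP2 = 0, nDC = 0)
    for (d in seq_len(nd)) {
        hits <- which(cover[d, ] >= params@containmentThreshold)
        if (length(hits) == 0L) {
            counts["nFP"] <- counts["nFP"] + 1
        } else if (!any(countable[hits])) {
            best <- hits[which.max(cover[d, hits])]
            slot <- classifyMatch(truths[[best]]@maturity, scheme)
            if (slot != "nTP")  # countable classes excluded above
                counts[slot] <- counts[slot] + 1
        }
    }
    EvalCounts(counts["nTP"], counts["nFP"], counts["nFN"], counts["nFP1"],
               counts["nFP2"], counts["nDC"])
}

#' Precision and recall from agreement counts
#'
#' precision = NTP / (NTP + NFP) and recall = NTP / (NTP + NFN), with the
#' FP1/FP2 sub-categories folded into NFP and the DC category ignored.
#' A zero denominator yields the explicit undefined marker `NA` (never 0
#' or 1).
#'
#' @param counts an [EvalCounts-class].
#' @return named numeric c(precision, recall), NA where undefined.
#' @export
precisionRecall <- function(counts) {
    fp <- counts@nFP + counts@nFP1 + counts@nFP2
    prec <- if (counts@nTP + fp > 0) counts@nTP / (counts@nTP + fp)
            else NA_real_
    rec <- if (counts@nTP + counts@nFN > 0)
        counts@nTP / (counts@nTP + counts@nFN) else NA_real_
    c(precision = prec, recall = rec)
}

combineCounts <- function(a, b) {
    EvalCounts(a@nTP + b@nTP, a@nFP + b@nFP, a@nFN + b@nFN,
               a@nFP1 + b@nFP1, a@nFP2 + b@nFP2, a@nDC + b@nDC)
}

sceneImage <- function(scene, modality, fnfParams) {
    switch(modality,
           fnf = if (!is.null(scene@composite)) scene@composite
                 else fnfComposite(scene@flash, scene@noflash, fnfParams),
           flash = scene@flash,
           noflash = scene@noflash)
}

#' Dataset-level evaluation
#'
#' Runs the detector on every scene of a labeled dataset (on the FNF
#' composite, the flash frame, or the no-flash frame), accumulates
#' agreement counts under the chosen scheme and cluster mode, and returns
#' the aggregate result, a per-scene breakdown, and the six-way category
#' distribution of all detection events.
#'
#' @param scenes list of [SceneData-class], or a dataset directory path
#'   (see [readDataset()]).
#' @param detectorParams a [DetectorParams-class].
#' @param evalParams an [EvalParams-class].
#' @param scheme "strict" or "flexible".
#' @param clusterMode "per_object" or "cluster_credit".
#' @param modality image to detect on: "fnf", "flash" or "noflash".
#' @param fnfParams an [FNFParams-class] used when composing on the fly.
#' @return list with elements `result` ([EvalResult-class]), `perScene`
#'   (data.frame) and `categories` (named vector TP, FP2, FP1, DC, FP, FN).
#' @export
evaluateDataset <- function(scenes, detectorParams = DetectorParams(),
                            evalParams = EvalParams(),
                            scheme = c("strict", "flexible"),
                            clusterMode = c("per_object", "cluster_credit"),
                            modality = c("fnf", "flash", "noflash"),
                            fnfParams = FNFParams()) {
    scheme <- match.arg(scheme)
    clusterMode <- match.arg(clusterMode)
    modality <- match.arg(modality)
    if (is.character(scenes)) scenes <- readDataset(scenes)
    if (length(scenes) == 0L) stop("empty dataset: no scenes to evaluate")
    total <- EvalCounts()
    rows <- vector("list", length(scenes))
    for (i in seq_along(scenes)) {
        sc <- scenes[[i]]
        if (is.null(sc@truth))
            stop(sprintf("scene '%s' has no labels", sc@id))
        dets <- detectPeppers(sceneImage(sc, modality, fnfParams),
                              detectorParams)
        counts <- if (clusterMode == "per_object")
            matchDetections(dets, sc@truth@objects, scheme, evalParams)
        else
            clusterCreditCounts(dets, sc@truth@objects, scheme, evalParams)
        total <- combineCounts(total, counts)
        pr <- precisionRecall(counts)
        rows[[i]] <- data.frame(scene = sc@id, t(countsVector(counts)),
                                precision = pr["precision"],
                                recall = pr["recall"], row.names = NULL)
    }
    pr <- precisionRecall(total)
    result <- new("EvalResult", counts = total,
                  precision = pr[["precision"]], recall = pr[["recall"]],
                  scheme = scheme, clusterMode = clusterMode)
    categories <- c(TP = total@nTP, FP2 = total@nFP2, FP1 = total@nFP1,
                    DC = total@nDC, FP = total@nFP, FN = total@nFN)
    list(result = result, perScene = do.call(rbind, rows),
         categories = categories)
}

#' Hue/saturation statistics of labeled fruit pixels
#'
#' Collects hue and saturation over every pixel of every labeled fruit of
#' the requested maturity class, normalizes hue to [0, 1] by /360 and
#' saturation to [0, 1] by /255, and returns 100-bin histograms over
#' [0, 1] together with population standard deviations on the normalized
#' scale. Comparing these statistics between FNF composites and flash-only
#' frames quantifies the color stability the compositing buys.
#'
#' @param images list of [RGBImage-class].
#' @param truthsPerImage list (parallel to `images`) of lists of
#'   [GroundTruthObject-class].
#' @param classFilter maturity class to collect (default "mature").
#' @return list with `hueHist`, `satHist` (bin counts), `hueStd`, `satStd`
#'   and `nPixels`.
#' @export
labeledPixelStats <- function(images, truthsPerImage,
                              classFilter = "mature") {
    stopifnot(length(images) == length(truthsPerImage))
    hs <- list(h = numeric(0), s = numeric(0))
    for (i in seq_along(images)) {
        sel <- Filter(function(t) t@maturity == classFilter,
                      truthsPerImage[[i]])
        if (length(sel) == 0L) next
        hsv <- rgbToHSV(images[[i]])
        for (t in sel) {
            hs$h <- c(hs$h, hsv@hue[t@mask] / 360)
            hs$s <- c(hs$s, hsv@saturation[t@mask] / 255)
        }
    }
    if (length(hs$h) == 0L)
        stop(sprintf("no labeled pixels of class '%s'", classFilter))
    breaks <- seq(0, 1, length.out = 101L)
    list(hueHist = hist(hs$h, breaks = breaks, plot = FALSE)$counts,
         satHist = hist(hs$s, breaks = breaks, plot = FALSE)$counts,
         hueStd = popSD(hs$h), satStd = popSD(hs$s),
         nPixels = length(hs$h))
}

#' Detector parameter sweep
#'
#' Evaluates the dataset once per row of a parameter grid. Grid columns
#' may be any subset of the [DetectorParams-class] fields (e.g. `satMin`,
#' `hueMin`, `hueMax`, `minAreaRef`); unlisted fields keep the values of
#' `detectorParams`. Rows are evaluated and returned in grid order.
#'
#' @param scenes list of [SceneData-class] or dataset directory.
#' @param grid data.frame of parameter overrides, one sweep point per row.
#' @inheritParams evaluateDataset
#' @return data.frame: the grid columns plus counts, precision and recall.
#' @export
sweepThresholds <- function(scenes, grid,
                            detectorParams = DetectorParams(),
                            evalParams = EvalParams(),
                            scheme = c("strict", "flexible"),
                            clusterMode = c("per_object", "cluster_credit"),
                            modality = c("fnf", "flash", "noflash"),
                            fnfParams = FNFParams()) {
    if (!is.data.frame(grid) || nrow(grid) == 0L)
        stop("grid must be a non-empty data.frame")
    if (is.character(scenes)) scenes <- readDataset(scenes)
    bad <- setdiff(names(grid), slotNames("DetectorParams"))
    if (length(bad))
        stop("unknown DetectorParams fields in grid: ",
             paste(bad, collapse = ", "))
    rows <- lapply(seq_len(nrow(grid)), function(r) {
        p <- detectorParams
        for (nm in names(grid)) slot(p, nm) <- grid[[nm]][r]
        validObject(p)
        ev <- evaluateDataset(scenes, p, evalParams, scheme, clusterMode,
                              modality, fnfParams)
        cbind(grid[r, , drop = FALSE], t(countsVector(ev$result)),
              precision = ev$result@precision, recall = ev$result@recall)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
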