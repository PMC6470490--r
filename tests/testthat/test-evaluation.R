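## Boxes and masks used for matching toys: 20x40 canvas.
H <- 20; W <- 40

detRect <- function(rows, cols) toyDetection(rectMask(H, W, rows, cols))
truthRect <- function(rows, cols, maturity = "mature")
    toyTruth(rectMask(H, W, rows, cols), maturity)

test_that("box overlap ratio follows the intersection-over-union rule", {
    a <- c(0, 0, 10, 10)
    expect_equal(boxIoU(a, a), 1)
    expect_equal(boxIoU(a, c(20, 0, 30, 10)), 0)
    expect_equal(boxIoU(a, c(5, 0, 15, 10)), 1 / 3)
    expect_error(boxIoU(a, c(5, 5, 5, 10)), "degenerate")
})

test_that("per-object matching applies the 50% overlap criterion", {
    truth <- list(truthRect(1:10, 1:10))
    ## overlap 0.6: columns shifted by 2.5 -> use 8/12 ... build iou = 2/3
    detHigh <- detRect(1:10, 3:12)     # inter 80, union 120 -> 2/3
    detLow <- detRect(1:10, 6:15)      # inter 50, union 150 -> 1/3
    c1 <- matchDetections(list(detHigh), truth, "strict")
    expect_equal(unname(countsVector(c1)[c("nTP", "nFP", "nFN")]),
                 c(1, 0, 0))
    c2 <- matchDetections(list(detLow), truth, "strict")
    expect_equal(unname(countsVector(c2)[c("nTP", "nFP", "nFN")]),
                 c(0, 1, 1))
})

test_that("maturity classes map onto the six-way taxonomy", {
    det <- detRect(1:10, 1:10)
    for (case in list(
        list("partially_mature", "strict", c(nTP = 0, nFP2 = 1, nFN = 0)),
        list("partially_mature", "flexible", c(nTP = 1, nFP2 = 0, nFN = 0)),
        list("immature", "strict", c(nFP1 = 1, nFN = 0)),
        list("distant", "strict", c(nDC = 1, nFP = 0, nFN = 0)))) {
        counts <- countsVector(matchDetections(
            list(det), list(truthRect(1:10, 1:10, case[[1]])), case[[2]]))
        for (nm in names(case[[3]]))
            expect_equal(unname(counts[nm]), unname(case[[3]][nm]),
                         label = paste(case[[1]], case[[2]], nm))
    }
    ## unmatched immature/distant truths never count as missed
    counts <- countsVector(matchDetections(
        list(), list(truthRect(1:10, 1:10, "immature"),
                     truthRect(1:10, 21:30, "distant")), "flexible"))
    expect_equal(unname(counts["nFN"]), 0)
})

test_that("greedy matching uses each detection and truth at most once", {
    set.seed(31)
    for (rep in 1:25) {
        nd <- sample(0:4, 1); nt <- sample(0:4, 1)
        dets <- lapply(seq_len(nd), function(i) {
            r0 <- sample(1:10, 1); c0 <- sample(1:30, 1)
            detRect(r0:(r0 + 8), c0:(c0 + 8))
        })
        cls <- sample(maturityClasses(), max(nt, 1), replace = TRUE)
        truths <- lapply(seq_len(nt), function(i) {
            r0 <- sample(1:10, 1); c0 <- sample(1:30, 1)
            truthRect(r0:(r0 + 8), c0:(c0 + 8), cls[i])
        })
        for (scheme in c("strict", "flexible")) {
            v <- countsVector(matchDetections(dets, truths, scheme))
            countable <- sum(cls[seq_len(nt)] %in%
                             pepperFNF:::countableClasses(scheme))
            ## every countable truth is matched once or missed once
            expect_equal(unname(v["nTP"] + v["nFN"]), countable)
            ## every detection lands in exactly one category
            expect_equal(unname(sum(v[c("nTP", "nFP", "nFP1", "nFP2",
                                        "nDC")])), nd)
        }
    }
})

test_that("cluster credit counts every fruit inside a detected region", {
    ## merged cluster: one blob spans two touching mature fruit
    blob <- detRect(5:14, 1:20)
    t1 <- truthRect(5:14, 1:10)
    t2 <- truthRect(5:14, 11:20)
    per <- countsVector(matchDetections(list(blob), list(t1, t2),
                                        "flexible"))
    expect_equal(unname(per[c("nTP", "nFN")]), c(1, 1))
    clu <- countsVector(clusterCreditCounts(list(blob), list(t1, t2),
                                            "flexible"))
    expect_equal(unname(clu[c("nTP", "nFN", "nFP")]), c(2, 0, 0))

    ## a detection covering no fruit is a plain false positive
    lone <- detRect(1:4, 30:39)
    expect_equal(unname(countsVector(clusterCreditCounts(
        list(lone), list(t1), "flexible"))[c("nTP", "nFP", "nFN")]),
        c(0, 1, 1))

    ## 40% containment is below the 0.5 threshold -> fruit not covered
    part <- detRect(5:14, 1:4)     # covers 4 of 10 columns of t1
    expect_equal(unname(countsVector(clusterCreditCounts(
        list(part), list(t1), "flexible"))[c("nTP", "nFN")]), c(0, 1))
})

test_that("cluster credit dominates per-object counting", {
    set.seed(17)
    for (rep in 1:15) {
        nd <- sample(1:3, 1); nt <- sample(1:4, 1)
        dets <- lapply(seq_len(nd), function(i) {
            r0 <- sample(1:8, 1); c0 <- sample(1:28, 1)
            detRect(r0:(r0 + sample(5:10, 1)), c0:(c0 + sample(5:10, 1)))
        })
        truths <- lapply(seq_len(nt), function(i) {
            r0 <- sample(1:10, 1); c0 <- sample(1:30, 1)
            truthRect(r0:(r0 + 7), c0:(c0 + 7),
                      sample(c("mature", "partially_mature"), 1))
        })
        for (scheme in c("strict", "flexible")) {
            per <- countsVector(matchDetections(dets, truths, scheme))
            clu <- countsVector(clusterCreditCounts(dets, truths, scheme))
            expect_gte(unname(clu["nTP"]), unname(per["nTP"]))
            expect_lte(unname(clu["nFN"]), unname(per["nFN"]))
        }
    }
})

test_that("precision and recall implement the counting formulas exactly", {
    pr <- precisionRecall(EvalCounts(nTP = 3, nFP = 1, nFN = 1))
    expect_equal(unname(pr), c(0.75, 0.75))
    pr0 <- precisionRecall(EvalCounts(nTP = 0, nFP = 0, nFN = 2))
    expect_true(is.na(pr0["precision"]))
    expect_equal(unname(pr0["recall"]), 0)
    expect_equal(unname(precisionRecall(EvalCounts(nTP = 5))), c(1, 1))

    ## exhaustive check against the direct formulas, FP1/FP2 folded in
    for (tp in 0:6) for (fp in 0:6) for (fn in 0:6)
        for (fp1 in c(0, 2)) {
            pr <- precisionRecall(EvalCounts(tp, fp, fn, nFP1 = fp1,
                                             nDC = 3))
            denomP <- tp + fp + fp1
            expP <- if (denomP > 0) tp / denomP else NA_real_
            expR <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
            expect_equal(unname(pr), c(expP, expR))
        }
})

test_that("distant fruit never changes precision or recall", {
    det <- detRect(1:10, 1:10)
    base <- precisionRecall(matchDetections(list(det),
                                            list(truthRect(1:10, 1:10)),
                                            "strict"))
    withDC <- precisionRecall(matchDetections(
        list(det, detRect(1:8, 25:35)),
        list(truthRect(1:10, 1:10), truthRect(1:8, 25:35, "distant")),
        "strict"))
    expect_equal(base, withDC)
})

test_that("dataset evaluation aggregates per-scene counts", {
    scenes <- list(toyScene(id = "s1"), toyScene(id = "s2"))
    ev <- evaluateDataset(scenes, scheme = "strict",
                          clusterMode = "per_object")
    expect_equal(unname(countsVector(ev$result)[c("nTP", "nFP", "nFN")]),
                 c(2, 0, 0))
    expect_equal(ev$result@precision, 1)
    expect_equal(ev$result@recall, 1)
    expect_equal(nrow(ev$perScene), 2L)
    expect_equal(unname(ev$categories["TP"]), 2)

    expect_error(evaluateDataset(list()), "empty dataset")
    bad <- toyScene(id = "nolabels"); bad@truth <- NULL
    expect_error(evaluateDataset(list(bad)), "nolabels")
})

test_that("labeled-pixel statistics use normalized population spread", {
    one <- toyScene()
    st <- labeledPixelStats(list(flashImage(one)), list(truthObjects(one)))
    expect_equal(st$hueStd, 0, tolerance = 1e-8)
    expect_equal(sum(st$hueHist), st$nPixels)

    ## two-point distribution at normalized hue 0.2 / 0.4 -> std 0.1
    mkHue <- function(h) {
        rgb <- grDevices::col2rgb(grDevices::hsv(h, 0.8, 0.9))
        px <- array(0, dim = c(10, 10, 3))
        for (ch in 1:3) px[, , ch] <- rgb[ch, 1]
        RGBImage(px)
    }
    truths <- list(list(toyTruth(matrix(TRUE, 10, 10))),
                   list(toyTruth(matrix(TRUE, 10, 10))))
    st2 <- labeledPixelStats(list(mkHue(0.2), mkHue(0.4)), truths)
    expect_equal(st2$hueStd, 0.1, tolerance = 0.01)

    expect_error(labeledPixelStats(list(flashImage(one)),
                                   list(truthObjects(one)), "immature"),
                 "no labeled pixels")
})

test_that("threshold sweeps reproduce single-point evaluation", {
    scenes <- list(toyScene())
    single <- evaluateDataset(scenes)
    tab <- sweepThresholds(scenes, data.frame(satMin = 90))
    expect_equal(tab$precision, single$result@precision)
    expect_equal(tab$nTP, unname(countsVector(single$result)["nTP"]))

    expect_error(sweepThresholds(scenes, data.frame()), "non-empty")
    expect_error(sweepThresholds(scenes, data.frame(bogus = 1)), "bogus")
})

test_that("raising the saturation floor never increases recall", {
    scenes <- simulateScenes(sceneConfig(), 6, 97)
    tab <- sweepThresholds(scenes, data.frame(satMin = c(60, 90, 120, 200)),
                           scheme = "flexible",
                           clusterMode = "cluster_credit")
    expect_true(all(diff(tab$recall) <= 1e-12))
})
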