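test_that("IOU matches the pixel-count oracle and its identities", {
  expect_equal(boxIoU(5, 5, 10, 10, 5, 5, 10, 10), 1)
  expect_equal(boxIoU(0, 0, 4, 4, 100, 0, 4, 4), 0)
  expect_equal(boxIoU(5, 5, 10, 10, 10, 5, 10, 10), 1 / 3)
  expect_equal(pixelIoU(5, 5, 10, 10, 10, 5, 10, 10), 1 / 3)

  set.seed(9)
  for (i in 1:10) {
    # integer-aligned boxes so the pixel grid is exact
    b1 <- c(cx = sample(0:20, 1), cy = sample(0:20, 1),
            w = sample(seq(2, 12, 2), 1), h = sample(seq(2, 12, 2), 1))
    b2 <- c(cx = sample(0:20, 1), cy = sample(0:20, 1),
            w = sample(seq(2, 12, 2), 1), h = sample(seq(2, 12, 2), 1))
    args <- function(u, v) as.list(unname(c(u, v)))
    iou <- do.call(boxIoU, args(b1, b2))
    expect_equal(iou, do.call(pixelIoU, args(b1, b2)))
    # symmetry and translation invariance
    expect_equal(iou, do.call(boxIoU, args(b2, b1)))
    expect_equal(iou, do.call(boxIoU, args(b1 + c(7, -3, 0, 0),
                                           b2 + c(7, -3, 0, 0))))
  }
})

test_that("greedy matching follows confidence order and one-match rule", {
  gt <- data.frame(class = 1, cx = 100, cy = 100, w = 20, h = 20)
  hit <- data.frame(class = 1, cx = 102, cy = 100, w = 20, h = 20, mu = 0.9)
  m <- matchDetections(hit, gt)
  expect_equal(sum(m$labels$tp), 1L)
  expect_equal(m$fn, 0L)

  # double detection: only the higher-confidence one matches
  two <- rbind(hit, transform(hit, cx = 101, mu = 0.8))
  m2 <- matchDetections(two, gt)
  expect_identical(m2$labels$tp, c(TRUE, FALSE))
  expect_equal(m2$fn, 0L)

  # right box, wrong class: FP, and the ground truth stays unmatched
  wrong <- transform(hit, class = 2)
  m3 <- matchDetections(wrong, gt)
  expect_false(any(m3$labels$tp))
  expect_equal(m3$fn, 1L)

  # below the IOU threshold is a miss
  far <- transform(hit, cx = 130)
  m4 <- matchDetections(far, gt)
  expect_false(any(m4$labels$tp))
})

test_that("all-point interpolated AP reproduces hand-computed curves", {
  expect_equal(averagePrecision(TRUE, 1), 1)
  # TP then FP: full recall reached at precision 1
  expect_equal(averagePrecision(c(TRUE, FALSE), 1), 1)
  # FP then TP: recall 1 only reached at precision 1/2
  expect_equal(averagePrecision(c(FALSE, TRUE), 1), 0.5)
  # hand-computed three-detection curve: (TP, FP, TP) with 2 GT
  # recalls 0.5, 0.5, 1; interpolated precisions 1, 2/3, 2/3
  expect_equal(averagePrecision(c(TRUE, FALSE, TRUE), 2), 0.5 * 1 + 0.5 * 2 / 3)
  expect_equal(averagePrecision(c(FALSE, FALSE), 0), 0)
  expect_equal(averagePrecision(logical(), 3), 0)
  # appending a lowest-ranked FP never increases AP
  set.seed(4)
  for (i in 1:10) {
    flags <- runif(8) > 0.4
    ap <- averagePrecision(flags, sum(flags))
    expect_lte(averagePrecision(c(flags, FALSE), sum(flags)), ap + 1e-12)
  }
})

test_that("report aggregates per-class AP, mAP and micro F1 correctly", {
  gt <- data.frame(class = c("a", "a", "b"),
                   cx = c(0, 50, 100), cy = 0, w = 10, h = 10)
  preds <- data.frame(class = c("a", "a", "b", "b"),
                      cx = c(0, 50, 100, 200), cy = 0, w = 10, h = 10,
                      mu = c(0.9, 0.8, 0.9, 0.7))
  rep <- evaluateDetections(preds, gt)
  pc <- perClassMetrics(rep)
  expect_equal(pc$ap[pc$class == "a"], 1.0)
  expect_equal(pc$ap[pc$class == "b"], 1.0)  # the FP ranks after full recall
  expect_equal(meanAveragePrecision(rep), 1.0)
  m <- microMetrics(rep)
  expect_equal(m[["precision"]], 3 / 4)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["f1"]], 2 * (3 / 4) / (3 / 4 + 1))
  # per class TP + FN equals the ground-truth count
  expect_equal(pc$instances, c(2L, 1L))

  # mAP is the plain mean of per-class APs
  predsB <- data.frame(class = c("a", "b", "b"), cx = c(0, 200, 100),
                       cy = 0, w = 10, h = 10, mu = c(0.9, 0.9, 0.7))
  repB <- evaluateDetections(predsB, gt)
  pcB <- perClassMetrics(repB)
  expect_equal(meanAveragePrecision(repB), mean(pcB$ap))
  expect_equal(pcB$ap[pcB$class == "b"], 0.5)

  # AP depends on confidence only through the ordering
  predsC <- preds
  predsC$mu <- predsC$mu^3 / 2
  expect_equal(meanAveragePrecision(evaluateDetections(predsC, gt)),
               meanAveragePrecision(rep))

  # degenerate F1 cases
  none <- evaluateDetections(preds[0, ], gt)
  expect_equal(microMetrics(none)[["f1"]], 0)
})
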