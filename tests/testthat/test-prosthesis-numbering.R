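test_that("bridge boxes split 33:30:33 with the denture in the middle", {
  b <- prosthesisDetections("bridge", cx = 300, cy = 200, w = 96, h = 40,
                            mu = 0.9)
  s <- splitBridge(b)
  expect_equal(s$w, c(33, 30, 33))
  expect_equal(s$cx, c(268.5, 300, 331.5))
  expect_equal(s$section,
               c("bridge_abutment", "bridge_denture", "bridge_abutment"))
  expect_equal(s$cy, rep(200, 3))
  expect_equal(s$mu, rep(0.9, 3))

  # partition property holds for arbitrary widths
  for (w in c(50, 64, 77.3, 120)) {
    b2 <- prosthesisDetections("bridge", cx = 10, cy = 0, w = w, h = 5,
                               mu = 0.5)
    s2 <- splitBridge(b2)
    expect_equal(sum(s2$w), w)
    # contiguous: each section starts where the previous one ends
    expect_equal(s2$cx - s2$w / 2, c(10 - w / 2, 10 - w / 2 + s2$w[1],
                                     10 - w / 2 + s2$w[1] + s2$w[2]))
  }
  expect_error(splitBridge(prosthesisDetections("crown", 1, 1, 2, 2, 0.5)),
               "bridge")
})

test_that("number ranges follow jaw and side of the dentition centre", {
  model <- flatModel(width = 640, occY = 320)  # centre at 320
  none <- toothCandidates()
  box <- function(cx, cy) data.frame(section = "implant", cx = cx, cy = cy,
                                     w = 20, h = 44, mu = 0.8,
                                     stringsAsFactors = FALSE)
  ranges <- list(list(box(200, 260), 1:13),    # maxilla, left of centre
                 list(box(500, 260), 3:16),    # maxilla, right of centre
                 list(box(200, 380), 20:32),   # mandible, left of centre
                 list(box(500, 380), 17:29))   # mandible, right of centre
  for (r in ranges) {
    got <- assignToothNumbers(r[[1]], model, existing = none)
    expect_identical(sort(got$tooth), as.integer(r[[2]]))
    expect_equal(nrow(got), length(r[[2]]))  # one candidate per number
    expect_true(all(got$origin == "prosthesis_detector"))
    expect_true(all(got$cx == r[[1]]$cx))
  }
})

test_that("confidence halves exactly once when the tooth is already detected", {
  model <- flatModel()
  pbox <- data.frame(section = "crown", cx = 200, cy = 260, w = 20, h = 44,
                     mu = 0.8, stringsAsFactors = FALSE)
  # two step-1 candidates overlap the box (IOU 1 and ~0.67): halve once
  hits <- toothCandidates(tooth = c(4, 5), cx = c(200, 204), cy = 260,
                          w = 20, h = 44, mu = 0.9)
  got <- assignToothNumbers(pbox, model, existing = hits)
  expect_true(all(got$mu == 0.4))
  # sub-threshold overlap keeps the full confidence
  far <- toothCandidates(tooth = 4, cx = 240, cy = 260, w = 20, h = 44,
                         mu = 0.9)
  expect_true(all(assignToothNumbers(pbox, model, existing = far)$mu == 0.8))
  # threshold is configurable
  grazing <- toothCandidates(tooth = 4, cx = 210, cy = 260, w = 20, h = 44,
                             mu = 0.9)  # IOU = 1/3
  expect_true(all(assignToothNumbers(pbox, model, existing = grazing,
                                     halveIoU = 0.3)$mu == 0.4))
})

test_that("generated candidates always land in their own jaw", {
  set.seed(21)
  model <- flatModel(occY = 320)
  for (i in 1:20) {
    pb <- data.frame(section = sample(c("inlay", "crown", "implant"), 1),
                     cx = runif(1, 100, 540), cy = runif(1, 150, 470),
                     w = 20, h = 44, mu = runif(1), stringsAsFactors = FALSE)
    got <- assignToothNumbers(pb, model, existing = toothCandidates())
    jaw <- jawOf(pb$cx, pb$cy, model)
    expect_true(all((got$tooth <= 16) == (jaw == "maxilla")))
  }
})
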