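test_that("YOLO-style records parse to absolute pixel candidates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("4 0.5 0.25 0.05 0.1 0.9",
               "0 0.2 0.4 0.03 0.07 0.30"), f)
  frame <- imageFrame(640, 640)
  got <- readCandidates(f, frame, type = "tooth")
  # class id 4 is UTN 5 under 0-based ids; the mu = 0.30 record falls below
  # the default 0.35 inference threshold and is dropped
  expect_equal(nrow(got), 1L)
  expect_equal(got$tooth, 5L)
  expect_equal(got[, c("cx", "cy", "w", "h", "mu")],
               data.frame(cx = 320, cy = 160, w = 32, h = 64, mu = 0.9))

  got2 <- readCandidates(f, frame, type = "tooth", confThreshold = 0)
  expect_equal(nrow(got2), 2L)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_equal(nrow(readCandidates(empty, frame, type = "tooth")), 0L)
})

test_that("malformed records and unknown class ids are rejected by line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1 0.9", "1 0.5 bad 0.1 0.1"), f)
  expect_error(readCandidates(f, imageFrame(640, 640), type = "tooth"),
               "line 2")
  writeLines("32 0.5 0.5 0.1 0.1 0.9", f)
  expect_error(readCandidates(f, imageFrame(640, 640), type = "tooth"),
               "outside 0..31")
  writeLines("0 0.5 0.5 0.1", f)
  expect_error(readCandidates(f, imageFrame(640, 640), type = "tooth"),
               "line 1")
})

test_that("normalized write/read round trip preserves coordinates to 1e-9", {
  set.seed(42)
  frame <- imageFrame(1170, 600)
  cands <- toothCandidates(tooth = sample(1:32, 20, TRUE),
                           cx = runif(20, 50, 1100), cy = runif(20, 50, 550),
                           w = runif(20, 10, 60), h = runif(20, 10, 80),
                           mu = runif(20, 0.4, 1))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCandidates(cands, f, frame, normalized = TRUE)
  back <- readCandidates(f, frame, type = "tooth", confThreshold = 0)
  for (col in c("cx", "cy", "w", "h", "mu")) {
    expect_lt(max(abs(back[[col]] - cands[[col]]) / abs(cands[[col]])), 1e-9)
  }
  expect_identical(back$tooth, cands$tooth)
})

test_that("combination files round trip field-exactly", {
  set.seed(7)
  present <- sort(sample(1:32, 29))
  P <- combination(toothCandidates(
    tooth = present, cx = runif(29, 100, 540), cy = runif(29, 200, 420),
    w = runif(29, 15, 25), h = runif(29, 35, 50), mu = runif(29),
    restoration = sample(c("normal", "crown", "implant"), 29, TRUE)))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCombination(P, f)
  back <- readCombination(f)
  expect_identical(missingTeeth(back), missingTeeth(P))
  expect_equal(selectedTeeth(back), selectedTeeth(P))
})

test_that("candidate table sorts by confidence with area and order ties", {
  frame <- imageFrame(640, 640)
  cands <- toothCandidates(tooth = c(5, 5, 3, 3, 3),
                           cx = c(300, 310, 200, 201, 202), cy = 250,
                           w = c(20, 22, 10, 20, 10), h = c(40, 40, 10, 10, 10),
                           mu = c(0.7, 0.9, 0.5, 0.5, 0.5))
  tab <- buildCandidateTable(cands, frame)
  expect_equal(slotCandidates(tab, 5)$mu, c(0.9, 0.7))
  # equal mu: larger area (20 x 10 = 200) first, then input order
  expect_equal(slotCandidates(tab, 3)$cx, c(201, 200, 202))
  expect_equal(nrow(slotCandidates(tab, 4)), 0L)

  # permutation property: the table holds exactly the input multiset
  pooled <- do.call(rbind, lapply(1:32, slotCandidates, table = tab))
  key <- function(df) sort(paste(df$tooth, df$cx, df$mu))
  expect_identical(key(pooled), key(cands))
})

test_that("scene JSON round trips", {
  sc <- generateScene(sceneSpec(seed = 5))
  f <- withr::local_tempfile(fileext = ".json")
  writeScene(sc, f)
  back <- readScene(f)
  expect_equal(back@toothCandidates, sc@toothCandidates)
  expect_equal(back@prosthesisDetections, sc@prosthesisDetections)
  expect_equal(back@allGT, sc@allGT)
  expect_equal(back@seed, sc@seed)
})
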