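test_that("zero noise with full dentition reproduces the tooth view exactly", {
  sp <- sceneSpec(noise = zeroNoise(), missingProb = 0,
                  prosthesisMix = c(inlay = 0, crown = 0, implant = 0,
                                    bridge = 0), seed = 3)
  sc <- generateScene(sp)
  expect_equal(nrow(sc@toothGT), 32L)
  expect_equal(sc@toothCandidates[, c("tooth", "cx", "cy", "w", "h")],
               sc@toothGT)
  expect_true(all(sc@toothCandidates$mu == 1))
  expect_equal(nrow(sc@prosthesisDetections), 0L)
})

test_that("scenes are pure functions of the seed", {
  sp <- sceneSpec(seed = 99)
  a <- generateScene(sp)
  b <- generateScene(sp)
  for (sl in c("stations", "toothGT", "prosthesisGT", "allGT",
               "toothCandidates", "prosthesisDetections")) {
    expect_identical(slot(a, sl), slot(b, sl))
  }
  # different seeds give different missing patterns essentially always
  pats <- vapply(1:20, function(s) {
    st <- generateScene(sceneSpec(seed = s))@stations
    paste(which(st$status == "missing"), collapse = ",")
  }, character(1))
  expect_gt(length(unique(pats)), 15L)
})

test_that("arch geometry follows the panoramic numbering convention", {
  st <- generateScene(sceneSpec(seed = 12))@stations
  up <- st[st$tooth %in% 1:16, ]
  lo <- st[st$tooth %in% 17:32, ]
  # T1 image-left -> T16 image-right; T17 image-right -> T32 image-left
  expect_true(all(diff(up$cx) > 0))
  expect_true(all(diff(lo$cx) < 0))
  # upper row lies above the lower row at every station
  expect_true(max(up$cy) < min(lo$cy))
  # stations stay inside the central 55% of the width
  expect_true(all(st$cx > 0.225 * 640 & st$cx < 0.775 * 640))
})

test_that("at least five teeth per jaw survive even heavy missingness", {
  for (s in 1:15) {
    st <- generateScene(sceneSpec(missingProb = 0.6, seed = 200 + s))@stations
    present <- st$status != "missing"
    expect_gte(sum(present[1:16]), 5L)
    expect_gte(sum(present[17:32]), 5L)
  }
})

test_that("bridges span abutment-denture-abutment across the views", {
  found <- FALSE
  for (s in 1:80) {
    sc <- generateScene(sceneSpec(noise = zeroNoise(), seed = s))
    st <- sc@stations
    dentures <- which(st$status == "bridge_denture")
    if (!length(dentures)) next
    found <- TRUE
    for (t in dentures) {
      expect_equal(st$status[c(t - 1L, t + 1L)], rep("bridge_abutment", 2))
      # prosthesis view: one bridge box covering all three stations
      br <- sc@prosthesisGT[sc@prosthesisGT$class == "bridge", ]
      covers <- abs(br$cx - st$cx[t]) < 1e-9 &
        br$w / 2 >= (st$cx[t + 1] - st$cx[t - 1]) / 2
      expect_true(any(covers | br$w > st$w[t]))
      # tooth view lacks the denture station, all view contains it
      expect_false(t %in% sc@toothGT$tooth)
      expect_true(t %in% sc@allGT$tooth)
      expect_true(all(c(t - 1L, t + 1L) %in% sc@toothGT$tooth))
    }
    if (s > 40 && found) break
  }
  expect_true(found)
})

test_that("treated teeth miss more often than normal teeth", {
  sp <- sceneSpec(missingProb = 0, seed = 1,
                  prosthesisMix = c(inlay = 0, crown = 0.5, implant = 0,
                                    bridge = 0))
  missNormal <- 0L; nNormal <- 0L; missTreated <- 0L; nTreated <- 0L
  for (s in 1:40) {
    sc <- generateScene(sp, seed = s)
    st <- sc@stations
    det <- sc@toothCandidates
    for (t in 1:32) {
      hit <- any(abs(det$cx - st$cx[t]) < 8 & abs(det$cy - st$cy[t]) < 8)
      if (st$status[t] == "crown") {
        nTreated <- nTreated + 1L
        if (!hit) missTreated <- missTreated + 1L
      } else {
        nNormal <- nNormal + 1L
        if (!hit) missNormal <- missNormal + 1L
      }
    }
  }
  expect_gt(missTreated / nTreated, missNormal / nNormal)
})

test_that("batches record reproducible per-scene seeds", {
  sp <- sceneSpec(seed = 50)
  b <- generateBatch(sp, 3)
  expect_equal(b$manifest$seed, c(50L, 51L, 52L))
  redo <- generateScene(sp, seed = b$manifest$seed[2])
  expect_identical(redo@stations, b$scenes[[2]]@stations)
  expect_identical(redo@toothCandidates, b$scenes[[2]]@toothCandidates)
})
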