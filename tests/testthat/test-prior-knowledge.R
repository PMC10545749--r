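test_that("threshold derivation matches the width-640 arithmetic", {
  p <- derivePriorParams(640, 8, 9)  # adjacent maxillary pair, as printed
  expect_equal(c(p@a, p@b, p@c, p@d, p@e, p@f),
               c(4.4, 8.8, 17.6, 44, 44, 52.8))
  expect_equal(p@range, 35.2)
  # the printed parameterisation forces d = e; the quartile variant ends the
  # plateau at Q3 of the range instead
  q <- derivePriorParams(640, 8, 9, variant = "quartile")
  expect_equal(q@d, 8.8 + 26.4)
  expect_lt(q@d, q@e)

  # mandibular molar pair: e stretches by 1.5 and dependents recompute
  m <- derivePriorParams(640, 18, 19)
  expect_equal(m@e, 66)
  expect_equal(c(m@a, m@b, m@c, m@d, m@f), c(4.4, 8.8, 23.1, 66, 80.3))

  # crowded mandibular centre: b halves and dependents recompute
  cc <- derivePriorParams(640, 24, 25)
  expect_equal(cc@b, 4.4)
  expect_equal(c(cc@a, cc@c, cc@d, cc@e, cc@f), c(2.2, 14.3, 44, 44, 53.9))

  # next-nearest pair: too-close cutoff becomes the unshifted c and the rest
  # shift outward by it
  s <- derivePriorParams(640, 8, 10)
  expect_equal(c(s@a, s@b, s@c, s@d, s@e, s@f),
               c(17.6, 26.4, 35.2, 61.6, 61.6, 70.4))

  expect_error(derivePriorParams(640, 8, 11), "1 or 2")
  expect_error(derivePriorParams(640, 16, 17), "same jaw")
})

test_that("threshold ordering 0 < a <= b <= c <= d <= e <= f always holds", {
  for (width in c(320, 640, 1170)) {
    for (x in 1:32) {
      jaw <- if (x <= 16) 1:16 else 17:32
      for (y in intersect(c(x - 2, x - 1, x + 1, x + 2), jaw)) {
        for (v in c("as_printed", "quartile")) {
          p <- derivePriorParams(width, x, y, variant = v)
          expect_true(validObject(p))
        }
      }
    }
  }
})

test_that("the piecewise score reproduces every branch", {
  p <- derivePriorParams(640, 8, 9)          # a 4.4 b 8.8 c 17.6 d = e 44
  expect_equal(priorDelta(2, p), -4)         # too close
  expect_equal(priorDelta(-25, p), -4)       # reversed order
  expect_equal(priorDelta(c(4.4, 8), p), c(0, 0))
  expect_equal(priorDelta(13.2, p), 0.5)     # ramp midpoint
  expect_equal(priorDelta(c(17.6, 30, 43.9), p), c(1, 1, 1))
  expect_equal(priorDelta(c(44, 50), p), c(0, 0))
  expect_equal(priorDelta(c(52.8, 100), p), c(-4, -4))
  expect_equal(priorDelta(NA, p), 0)         # kappa default
  pk <- derivePriorParams(640, 8, 9, kappa = 0.3)
  expect_equal(priorDelta(NA, pk), 0.3)

  # quartile variant exposes the ramp-down segment
  q <- derivePriorParams(640, 8, 9, variant = "quartile")  # d 35.2 e 44
  expect_equal(priorDelta(39.6, q), 0.5)

  # monotone non-decreasing on [b, c], non-increasing on [d, e]
  up <- priorDelta(seq(q@b, q@c, length.out = 50), q)
  dn <- priorDelta(seq(q@d, q@e - 1e-9, length.out = 50), q)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
})

test_that("directed separation encodes each jaw's numbering direction", {
  # maxilla: higher number sits at larger x; mandible: at smaller x
  expect_equal(directedSeparation(2, 1, 120, 100), 20)
  expect_equal(directedSeparation(1, 2, 100, 120), 20)   # symmetric in pair
  expect_equal(directedSeparation(2, 1, 100, 120), -20)  # reversed
  expect_equal(directedSeparation(18, 17, 100, 120), 20)
  expect_equal(directedSeparation(18, 17, 120, 100), -20)
})

test_that("per-tooth score averages over the jaw-restricted neighbour set", {
  P <- uniformCombination(spacing = 26)
  # jaw ends lose out-of-jaw neighbours: T1 compares with {2, 3} only
  expect_equal(fpTooth(1, P, 640), 1)
  expect_equal(fpTooth(20, P, 640), 1)
  # spacing 26 puts every pair class on the plateau, so all teeth score 1
  for (x in 1:32) expect_equal(fpTooth(x, P, 640), 1)

  # a missing tooth scores kappa and its neighbours average it in
  P2 <- combination(selectedTeeth(P)[-2, ])  # drop T2
  expect_equal(fpTooth(2, P2, 640), 0)
  expect_equal(fpTooth(1, P2, 640), mean(c(0, 1)))       # Omega(1) = {2, 3}
  expect_equal(fpTooth(3, P2, 640), mean(c(1, 0, 1, 1)))
})

test_that("objective composes the positional and confidence terms", {
  P <- uniformCombination(spacing = 26, mu = 1)
  s <- objectiveScore(P, 640, omegaP = 0.8, omegaC = 0.2)
  expect_equal(s$fp, 1)
  expect_equal(s$fc, 1)
  expect_equal(s$objective, 1)

  # all-missing combination: fc = 0 and fp = kappa
  Pempty <- combination(toothCandidates())
  s0 <- objectiveScore(Pempty, 640)
  expect_equal(s0$fc, 0)
  expect_equal(s0$fp, 0)
  sK <- objectiveScore(Pempty, 640, kappa = 0.25)
  expect_equal(sK$fp, 0.25)

  # linear in the weights
  sA <- objectiveScore(P, 640, omegaP = 0.5, omegaC = 0.1)$objective
  sB <- objectiveScore(P, 640, omegaP = 0.3, omegaC = 0.1)$objective
  sAB <- objectiveScore(P, 640, omegaP = 0.8, omegaC = 0.2)$objective
  expect_equal(sA + sB, sAB)

  # mu(phi) = 0: declaring one tooth missing costs 1/32 of fc
  P31 <- combination(selectedTeeth(P)[-5, ])
  expect_equal(objectiveScore(P31, 640)$fc, 31 / 32)

  # planting a too-close candidate strictly decreases fp
  sel <- selectedTeeth(P)
  sel$cx[6] <- sel$cx[5] + 1
  expect_lt(objectiveScore(combination(sel), 640)$fp, 1)
})
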