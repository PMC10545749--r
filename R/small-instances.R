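# Small optimizer benchmark instances: few enough multi-option slots that
# exhaustive enumeration is feasible.

#' Generate a small optimizer benchmark instance
#'
#' Builds a candidate table from a zero-noise synthetic dentition (perfect
#' arch positions, no prostheses), randomizes the confidences, and plants a
#' decoy second candidate in a few slots -- a jittered copy of a
#' neighbouring station's box, the classic double-detection failure mode.
#' With at most `nMulti` multi-option slots of two candidates each (plus the
#' missing option) the exact optimum is computable by [exhaustiveOptimum()]
#' over at most `3^nMulti` combinations, which makes these instances a
#' brute-force oracle for [optimizeCombination()].
#'
#' @param seed integer seed; instances are pure functions of it.
#' @param frame the [ImageFrame-class] (default 640 x 640).
#' @param nMulti number of slots receiving a decoy candidate (<= 6 keeps
#'   enumeration trivial).
#' @param missingProb per-tooth missing probability of the underlying scene.
#' @return a [CandidateTable-class].
#' @export
smallBenchmarkTable <- function(seed, frame = imageFrame(640, 640),
                                nMulti = 6L, missingProb = 0.05) {
  sp <- sceneSpec(frame = frame, missingProb = missingProb,
                  prosthesisMix = c(inlay = 0, crown = 0, implant = 0,
                                    bridge = 0),
                  noise = zeroNoise(), seed = seed)
  scene <- generateScene(sp)
  withr::with_seed(seed + 1L, {
    cands <- scene@toothCandidates
    cands$mu <- stats::runif(nrow(cands), 0.6, 1)
    present <- cands$tooth
    slots <- sample(present, min(nMulti, length(present)))
    decoys <- lapply(slots, function(t) {
      jaw <- .jawNumbers(t)
      nb <- intersect(c(t - 1L, t + 1L), jaw)
      nb <- nb[nb %in% present]
      src <- if (length(nb)) cands[cands$tooth == sample(rep(nb, 2), 1), ]
             else cands[cands$tooth == t, ]
      toothCandidates(tooth = t, cx = src$cx + stats::rnorm(1, 0, 3),
                      cy = src$cy + stats::rnorm(1, 0, 3),
                      w = src$w, h = src$h,
                      mu = stats::runif(1, 0.4, 1))
    })
    buildCandidateTable(rbind(cands, do.call(rbind, decoys)), frame)
  })
}
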