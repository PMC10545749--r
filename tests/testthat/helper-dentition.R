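# Shared fixtures, all built in code.

# A flat occlusal model: occlusion at y = occY, centre at width/2.
flatModel <- function(width = 640, occY = 320) {
  q <- c(0, 0, occY)
  new("OcclusalModel", upper = q - c(0, 0, 45), lower = q + c(0, 0, 45),
      occlusion = q, centerX = width / 2, centerFallbackUsed = FALSE,
      degenerate = FALSE)
}

# A full 32-tooth combination with uniform within-jaw spacing; spacing 26 px
# puts every neighbour pair (including the mandibular molar and centre
# special cases at width 640) on the plateau of the positional prior.
uniformCombination <- function(spacing = 26, mu = 1, width = 640) {
  cxMax <- 100 + (1:16 - 1) * spacing
  cxMan <- 100 + (16 - (17:32 - 17) - 1) * spacing  # T17 rightmost
  combination(toothCandidates(
    tooth = 1:32, cx = c(cxMax, cxMan),
    cy = rep(c(260, 380), each = 16), w = 20, h = 44, mu = mu))
}

# Quick micro-F1 of pipeline results against a scene view.
sceneF1 <- function(results, scenes, view) {
  microMetrics(evaluateScenes(results, scenes, view))[["f1"]]
}

# Pixel-count IOU oracle for integer-aligned boxes (half-open intervals).
pixelIoU <- function(cx1, cy1, w1, h1, cx2, cy2, w2, h2) {
  inBox <- function(px, py, cx, cy, w, h) {
    px >= cx - w / 2 & px < cx + w / 2 & py >= cy - h / 2 & py < cy + h / 2
  }
  xs <- seq(floor(min(cx1 - w1, cx2 - w2)), ceiling(max(cx1 + w1, cx2 + w2)))
  ys <- seq(floor(min(cy1 - h1, cy2 - h2)), ceiling(max(cy1 + h1, cy2 + h2)))
  g <- expand.grid(px = xs, py = ys)
  a <- inBox(g$px, g$py, cx1, cy1, w1, h1)
  b <- inBox(g$px, g$py, cx2, cy2, w2, h2)
  sum(a & b) / sum(a | b)
}
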