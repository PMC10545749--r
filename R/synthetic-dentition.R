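# Seeded synthetic panoramic-layout scenes: ground truth in the three
# annotation views plus detector-style noisy candidates.

.TREATED <- c("inlay", "crown", "bridge_abutment")

# Station geometry: 16 stations per jaw along the central 55% of the width.
# UTN left/right convention of the panoramic view: T1 at image-left of the
# upper arch through T16 at image-right; T17 at image-right of the lower
# arch through T32 at image-left.
.stationGeometry <- function(spec, apexX) {
  width <- frameWidth(spec@frame)
  height <- frameHeight(spec@frame)
  spacing <- width * 0.55 / 16
  left <- width * 0.225
  idx <- c(1:16, 16:1)                     # image position index per tooth
  cx <- left + (idx - 0.5) * spacing
  yOcc <- spec@curvature * (cx - apexX)^2 + spec@occlusalYFrac * height
  cy <- yOcc + ifelse(1:32 <= 16, -spec@jawGap / 2, spec@jawGap / 2)
  data.frame(tooth = 1:32, cx = cx, cy = cy, w = spec@toothWidth,
             h = spec@toothHeight, stringsAsFactors = FALSE)
}

.sampleStatus <- function(spec) {
  present <- stats::runif(32) >= spec@missingProb
  # the scene family mirrors the data-selection rule: at least five teeth
  # retained per jaw
  for (jaw in list(MAXILLA, MANDIBLE)) {
    while (sum(present[jaw]) < 5L) {
      gone <- jaw[!present[jaw]]
      present[gone[floor(stats::runif(1) * length(gone)) + 1L]] <- TRUE
    }
  }
  status <- ifelse(present, "normal", "missing")
  mix <- spec@prosthesisMix
  # bridges: span exactly one missing tooth with two present abutments
  for (t in 1:32) {
    if (status[t] != "missing") next
    jaw <- .jawNumbers(t)
    if (!((t - 1L) %in% jaw && (t + 1L) %in% jaw)) next
    if (status[t - 1L] != "normal" || status[t + 1L] != "normal") next
    if (stats::runif(1) < mix[["bridge"]]) {
      status[t] <- "bridge_denture"
      status[t - 1L] <- "bridge_abutment"
      status[t + 1L] <- "bridge_abutment"
    }
  }
  # implants replace remaining missing teeth
  for (t in which(status == "missing")) {
    if (stats::runif(1) < mix[["implant"]]) status[t] <- "implant"
  }
  # crowns / inlays overlay remaining untouched teeth
  for (t in which(status == "normal")) {
    u <- stats::runif(1)
    if (u < mix[["crown"]]) status[t] <- "crown"
    else if (u < mix[["crown"]] + mix[["inlay"]]) status[t] <- "inlay"
  }
  status
}

.buildGroundTruth <- function(stations) {
  boxCols <- c("tooth", "cx", "cy", "w", "h")
  natural <- stations$status %in% c("normal", .TREATED)
  toothGT <- stations[natural, boxCols]
  allGT <- stations[natural | stations$status %in%
                      c("implant", "bridge_denture"), boxCols]
  rownames(toothGT) <- rownames(allGT) <- NULL

  pros <- list()
  for (t in which(stations$status %in% c("inlay", "crown", "implant"))) {
    pros[[length(pros) + 1L]] <- data.frame(
      class = stations$status[t], cx = stations$cx[t], cy = stations$cy[t],
      w = stations$w[t], h = stations$h[t], stringsAsFactors = FALSE)
  }
  for (t in which(stations$status == "bridge_denture")) {
    span <- stations[c(t - 1L, t, t + 1L), ]
    xmin <- min(span$cx - span$w / 2)
    xmax <- max(span$cx + span$w / 2)
    pros[[length(pros) + 1L]] <- data.frame(
      class = "bridge", cx = (xmin + xmax) / 2, cy = stations$cy[t],
      w = xmax - xmin, h = stations$h[t], stringsAsFactors = FALSE)
  }
  prosthesisGT <- if (length(pros)) do.call(rbind, pros) else
    data.frame(class = character(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric(), stringsAsFactors = FALSE)
  rownames(prosthesisGT) <- NULL
  list(tooth = toothGT, all = allGT, prosthesis = prosthesisGT)
}

.sampleConf <- function(n, shape) {
  if (any(is.na(shape))) rep(1, n) else stats::rbeta(n, shape[1], shape[2])
}

.noisyToothCandidates <- function(stations, noise) {
  rows <- list()
  for (t in which(stations$status %in% c("normal", .TREATED))) {
    st <- stations[t, ]
    pMiss <- if (st$status == "normal") noise@missProbNormal else
      noise@missProbTreated
    if (stats::runif(1) < pMiss) next
    number <- t
    if (stats::runif(1) < noise@shiftProb) {
      jaw <- .jawNumbers(t)
      shift <- if (stats::runif(1) < 0.5) -1L else 1L
      if (!((t + shift) %in% jaw)) shift <- -shift
      number <- t + shift
    }
    # positional jitter scales with tooth width on both axes
    jitter <- function(k = 1) stats::rnorm(1, 0, k * noise@posJitter * st$w)
    sizeF <- function() max(0.2, 1 + stats::rnorm(1, 0, noise@sizeJitter))
    rows[[length(rows) + 1L]] <- toothCandidates(
      tooth = number, cx = st$cx + jitter(), cy = st$cy + jitter(),
      w = st$w * sizeF(), h = st$h * sizeF(),
      mu = .sampleConf(1, noise@confTP))
    if (stats::runif(1) < noise@dupProb) {
      rows[[length(rows) + 1L]] <- toothCandidates(
        tooth = t, cx = st$cx + jitter(2), cy = st$cy + jitter(2),
        w = st$w * sizeF(), h = st$h * sizeF(),
        mu = .sampleConf(1, noise@confFP))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else toothCandidates()
  rownames(out) <- NULL
  out
}

.noisyProsthesisDetections <- function(prosthesisGT, noise, toothWidth) {
  rows <- list()
  for (i in seq_len(nrow(prosthesisGT))) {
    if (stats::runif(1) < noise@missProbNormal) next
    g <- prosthesisGT[i, ]
    jit <- function() stats::rnorm(1, 0, noise@posJitter * toothWidth)
    sizeF <- function() max(0.2, 1 + stats::rnorm(1, 0, noise@sizeJitter))
    rows[[length(rows) + 1L]] <- prosthesisDetections(
      class = g$class, cx = g$cx + jit(), cy = g$cy + jit(),
      w = g$w * sizeF(), h = g$h * sizeF(),
      mu = .sampleConf(1, noise@confTP))
  }
  out <- if (length(rows)) do.call(rbind, rows) else prosthesisDetections()
  rownames(out) <- NULL
  out
}

#' Generate one synthetic dentition scene
#'
#' Places 16 tooth stations per jaw along two quadratic arches inside the
#' central 55% of the image width, samples missing teeth (at least five
#' retained per jaw), prostheses (a bridge consumes one missing tooth plus
#' its two present neighbours as abutments; implants replace missing teeth;
#' crowns and inlays overlay present teeth), builds the three ground-truth
#' annotation views, and corrupts the truth into detector-style candidates
#' according to the [NoiseSpec-class]. The tooth-annotation view omits
#' complete restorations (implants and bridge dentures); the all-annotation
#' view numbers them by station. Scenes are pure functions of the spec and
#' seed.
#'
#' @param spec a [SceneSpec-class].
#' @param seed optional integer overriding `spec@seed`.
#' @return a [DentitionScene-class].
#' @export
generateScene <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  theSeed <- as.integer(seed %||% spec@seed)
  withr::with_seed(theSeed, {
    width <- frameWidth(spec@frame)
    apexX <- width / 2 +
      stats::runif(1, -spec@apexJitterFrac, spec@apexJitterFrac) * width
    stations <- .stationGeometry(spec, apexX)
    stations$status <- .sampleStatus(spec)
    gt <- .buildGroundTruth(stations)
    tc <- .noisyToothCandidates(stations, spec@noise)
    pd <- .noisyProsthesisDetections(gt$prosthesis, spec@noise,
                                     spec@toothWidth)
    new("DentitionScene", frame = spec@frame, seed = theSeed,
        stations = stations, toothGT = gt$tooth, prosthesisGT = gt$prosthesis,
        allGT = gt$all, toothCandidates = tc, prosthesisDetections = pd)
  })
}

#' Generate a batch of scenes with derived seeds
#'
#' Scene `i` is generated with seed `spec@seed + i - 1`, so any scene can be
#' reproduced individually from the manifest.
#'
#' @param spec a [SceneSpec-class].
#' @param n number of scenes (>= 1).
#' @return list with `scenes` (list of [DentitionScene-class]) and
#'   `manifest` (data frame of indices and seeds).
#' @export
generateBatch <- function(spec, n) {
  stopifnot(n >= 1)
  seeds <- spec@seed + seq_len(n) - 1L
  scenes <- lapply(seeds, function(s) generateScene(spec, seed = s))
  list(scenes = scenes,
       manifest = data.frame(index = seq_len(n), seed = seeds))
}
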