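#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageFrame
# ---------------------------------------------------------------------------

#' Image frame dimensions
#'
#' Panoramic radiograph coordinates use the image convention: origin at the
#' upper-left corner, x rightward, y downward, in absolute pixels. Boxes are
#' stored centre-format (`cx`, `cy`, `w`, `h`) with half-open pixel intervals
#' `[cx - w/2, cx + w/2) x [cy - h/2, cy + h/2)` for area computations.
#'
#' @slot width image width in pixels (> 0).
#' @slot height image height in pixels (> 0).
#' @export
setClass("ImageFrame", representation(width = "numeric", height = "numeric"),
         validity = function(object) {
           if (length(object@width) != 1L || length(object@height) != 1L ||
               !is.finite(object@width) || !is.finite(object@height) ||
               object@width <= 0 || object@height <= 0) {
             return("width and height must be single positive finite numbers")
           }
           TRUE
         })

#' @param width,height frame dimensions in pixels.
#' @rdname ImageFrame-class
#' @export
#' @examples
#' imageFrame(640, 640)
imageFrame <- function(width, height) {
  new("ImageFrame", width = as.numeric(width), height = as.numeric(height))
}

#' @param x an `ImageFrame`.
#' @rdname ImageFrame-class
#' @export
frameWidth <- function(x) x@width

#' @rdname ImageFrame-class
#' @export
frameHeight <- function(x) x@height

setMethod("show", "ImageFrame", function(object) {
  cat(sprintf("ImageFrame %g x %g px\n", object@width, object@height))
})

# ---------------------------------------------------------------------------
# Candidate data frames (documented column contracts, validated by helpers)
# ---------------------------------------------------------------------------

.toothCandidateCols <- c("tooth", "cx", "cy", "w", "h", "mu",
                         "restoration", "origin")

.validateToothCandidates <- function(df) {
  if (!is.data.frame(df)) stop("tooth candidates must be a data.frame")
  missing <- setdiff(.toothCandidateCols, names(df))
  if (length(missing)) {
    stop("tooth candidate columns missing: ", paste(missing, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(df$tooth < 1L | df$tooth > 32L | df$tooth != round(df$tooth))) {
      stop("tooth numbers must be integers in 1..32")
    }
    if (any(df$mu < 0 | df$mu > 1)) stop("confidence mu must lie in [0, 1]")
    if (any(df$w <= 0 | df$h <= 0)) stop("box width/height must be positive")
    bad <- setdiff(unique(df$restoration), RESTORATION_LEVELS)
    if (length(bad)) stop("unknown restoration labels: ",
                          paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Construct a tooth-candidate table
#'
#' A tooth candidate is one detector bounding box proposed for one universal
#' tooth number (UTN, 1-32): the box centre and size in pixels, the detector
#' confidence `mu` in `[0, 1]`, a restoration label, and the detector of
#' origin. Candidates are plain data frames with a fixed column contract so
#' that they compose with base R and the IO helpers.
#'
#' @param tooth integer UTN numbers in 1..32.
#' @param cx,cy box centre coordinates, absolute pixels.
#' @param w,h box width and height, absolute pixels (> 0).
#' @param mu detector confidence scores in `[0, 1]`.
#' @param restoration one of `"normal"`, `"inlay"`, `"crown"`, `"implant"`,
#'   `"bridge_abutment"`, `"bridge_denture"`. Step-1 tooth-detector output is
#'   `"normal"`; prosthesis-derived candidates carry their prosthesis class.
#' @param origin `"tooth_detector"` or `"prosthesis_detector"`.
#' @return data.frame with columns
#'   `tooth, cx, cy, w, h, mu, restoration, origin`.
#' @export
#' @examples
#' toothCandidates(tooth = c(5, 5), cx = c(320, 330), cy = 160,
#'                 w = 30, h = 60, mu = c(0.9, 0.4))
toothCandidates <- function(tooth = integer(), cx = numeric(), cy = numeric(),
                            w = numeric(), h = numeric(), mu = numeric(),
                            restoration = "normal",
                            origin = "tooth_detector") {
  df <- data.frame(tooth = as.integer(tooth), cx = as.numeric(cx),
                   cy = as.numeric(cy), w = as.numeric(w), h = as.numeric(h),
                   mu = as.numeric(mu),
                   restoration = if (length(tooth)) as.character(restoration)
                                 else character(),
                   origin = if (length(tooth)) as.character(origin)
                            else character(),
                   stringsAsFactors = FALSE)
  .validateToothCandidates(df)
  df
}

.prosthesisCols <- c("class", "cx", "cy", "w", "h", "mu")

.validateProsthesisDetections <- function(df, classes = PROSTHESIS_CLASSES) {
  if (!is.data.frame(df)) stop("prosthesis detections must be a data.frame")
  missing <- setdiff(.prosthesisCols, names(df))
  if (length(missing)) {
    stop("prosthesis detection columns missing: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df)) {
    bad <- setdiff(unique(df$class), classes)
    if (length(bad)) stop("unknown prosthesis classes: ",
                          paste(bad, collapse = ", "))
    if (any(df$mu < 0 | df$mu > 1)) stop("confidence mu must lie in [0, 1]")
    if (any(df$w <= 0 | df$h <= 0)) stop("box width/height must be positive")
  }
  invisible(df)
}

#' Construct a prosthesis-detection table
#'
#' @param class prosthesis class, one of `"inlay"`, `"crown"`, `"implant"`,
#'   `"bridge"`.
#' @inheritParams toothCandidates
#' @return data.frame with columns `class, cx, cy, w, h, mu`.
#' @export
prosthesisDetections <- function(class = character(), cx = numeric(),
                                 cy = numeric(), w = numeric(), h = numeric(),
                                 mu = numeric()) {
  df <- data.frame(class = as.character(class), cx = as.numeric(cx),
                   cy = as.numeric(cy), w = as.numeric(w), h = as.numeric(h),
                   mu = as.numeric(mu), stringsAsFactors = FALSE)
  .validateProsthesisDetections(df)
  df
}

# ---------------------------------------------------------------------------
# CandidateTable
# ---------------------------------------------------------------------------

#' Per-tooth candidate table
#'
#' Groups tooth candidates by UTN slot 1..32 with each slot's list sorted in
#' non-increasing confidence. The "missing" option (phi) is implicit in every
#' slot and is represented downstream by the absence of a selection.
#'
#' @slot candidates list of 32 tooth-candidate data frames (possibly 0-row),
#'   element `x` holding only candidates with `tooth == x`, sorted by
#'   decreasing `mu` (ties: larger box area first, then input order).
#' @slot frame the [ImageFrame-class] the coordinates refer to.
#' @seealso [buildCandidateTable()]
#' @export
setClass("CandidateTable",
         representation(candidates = "list", frame = "ImageFrame"),
         validity = function(object) {
           if (length(object@candidates) != 32L) {
             return("candidate list must have exactly 32 slots")
           }
           for (x in 1:32) {
             df <- object@candidates[[x]]
             if (!is.data.frame(df)) return("each slot must be a data.frame")
             if (nrow(df)) {
               if (any(df$tooth != x)) {
                 return(sprintf("slot %d holds candidates for another tooth", x))
               }
               if (is.unsorted(rev(df$mu))) {
                 return(sprintf("slot %d not sorted by non-increasing mu", x))
               }
             }
           }
           TRUE
         })

#' Build a candidate table from a flat candidate list
#'
#' Candidates are grouped by tooth number and sorted within each slot by
#' decreasing confidence; confidence ties are broken by larger box area, then
#' by input order. The sort is what makes the optimizer's greedy
#' initialisation (each slot's head candidate) well defined.
#'
#' @param cands tooth-candidate data frame (see [toothCandidates()]).
#' @param frame the [ImageFrame-class] of the source image.
#' @return a [CandidateTable-class].
#' @export
buildCandidateTable <- function(cands, frame) {
  .validateToothCandidates(cands)
  slots <- vector("list", 32L)
  for (x in 1:32) {
    sub <- cands[cands$tooth == x, , drop = FALSE]
    if (nrow(sub)) {
      area <- sub$w * sub$h
      ord <- order(-sub$mu, -area, seq_len(nrow(sub)))
      sub <- sub[ord, , drop = FALSE]
    }
    rownames(sub) <- NULL
    slots[[x]] <- sub
  }
  new("CandidateTable", candidates = slots, frame = frame)
}

#' @param table a `CandidateTable`.
#' @param x tooth number 1..32.
#' @rdname CandidateTable-class
#' @export
slotCandidates <- function(table, x) {
  stopifnot(is(table, "CandidateTable"), x >= 1L, x <= 32L)
  table@candidates[[as.integer(x)]]
}

#' @rdname CandidateTable-class
#' @export
tableFrame <- function(table) table@frame

setMethod("show", "CandidateTable", function(object) {
  n <- vapply(object@candidates, nrow, integer(1))
  cat(sprintf("CandidateTable: %d candidates over %d occupied slots (of 32)\n",
              sum(n), sum(n > 0L)))
  cat(sprintf("  empty slots (phi only): %s\n",
              if (all(n > 0L)) "none" else paste(which(n == 0L), collapse = " ")))
  cat(sprintf("  frame: %g x %g px\n", object@frame@width, object@frame@height))
})

# ---------------------------------------------------------------------------
# Combination
# ---------------------------------------------------------------------------

#' A full 32-slot tooth assignment
#'
#' One choice per universal tooth number: either a selected candidate box or
#' the missing option phi. This is the object the prior-knowledge objective
#' scores and the optimizer searches over.
#'
#' @slot selected tooth-candidate data frame of the non-phi slots, one row per
#'   selected tooth, unique `tooth` values.
#' @slot missing integer vector of slots assigned phi; together with
#'   `selected$tooth` it partitions 1..32.
#' @export
setClass("Combination",
         representation(selected = "data.frame", missing = "integer"),
         validity = function(object) {
           t <- object@selected$tooth
           if (anyDuplicated(t)) return("duplicated tooth slots in selection")
           if (!setequal(c(t, object@missing), 1:32)) {
             return("selected and missing slots must partition 1..32")
           }
           TRUE
         })

#' @param selected data frame of selected candidates (see [toothCandidates()]).
#' @rdname Combination-class
#' @export
combination <- function(selected) {
  .validateToothCandidates(selected)
  selected <- selected[order(selected$tooth), , drop = FALSE]
  rownames(selected) <- NULL
  new("Combination", selected = selected,
      missing = as.integer(setdiff(1:32, selected$tooth)))
}

#' @param P a `Combination`.
#' @rdname Combination-class
#' @export
selectedTeeth <- function(P) P@selected

#' @rdname Combination-class
#' @export
missingTeeth <- function(P) P@missing

setMethod("show", "Combination", function(object) {
  cat(sprintf("Combination: %d teeth selected, %d missing\n",
              nrow(object@selected), length(object@missing)))
  if (length(object@missing)) {
    cat("  missing:", paste(object@missing, collapse = " "), "\n")
  }
  rest <- object@selected$restoration
  if (any(rest != "normal")) {
    tab <- table(rest[rest != "normal"])
    cat("  restorations:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

# ---------------------------------------------------------------------------
# OcclusalModel
# ---------------------------------------------------------------------------

#' Fitted occlusal geometry
#'
#' Quadratics `y = a2 x^2 + a1 x + a0` (image pixel coordinates) fitted by
#' ordinary least squares to the maxillary and mandibular candidate centres;
#' the occlusion line is their coefficient-wise mean, and the dentition centre
#' is the occlusion apex unless it deviates from the image centre by more than
#' the configured fraction of the width.
#'
#' @slot upper,lower,occlusion numeric coefficient vectors `c(a2, a1, a0)`.
#' @slot centerX dentition centre x in pixels.
#' @slot centerFallbackUsed TRUE if the apex deviated and the image-width
#'   centre was substituted.
#' @slot degenerate TRUE for the flat fallback model used when a jaw has too
#'   few points to fit.
#' @seealso [fitOcclusalModel()]
#' @export
setClass("OcclusalModel",
         representation(upper = "numeric", lower = "numeric",
                        occlusion = "numeric", centerX = "numeric",
                        centerFallbackUsed = "logical",
                        degenerate = "logical"))

setMethod("show", "OcclusalModel", function(object) {
  cat("OcclusalModel\n")
  f <- function(q) sprintf("y = %.4g x^2 + %.4g x + %.4g", q[1], q[2], q[3])
  cat("  upper:    ", f(object@upper), "\n")
  cat("  lower:    ", f(object@lower), "\n")
  cat("  occlusion:", f(object@occlusion), "\n")
  cat(sprintf("  dentition centre x = %.2f px%s%s\n", object@centerX,
              if (object@centerFallbackUsed) " (image-centre fallback)" else "",
              if (object@degenerate) " [degenerate flat fit]" else ""))
})

#' @param model an `OcclusalModel`.
#' @rdname OcclusalModel-class
#' @export
dentitionCenter <- function(model) model@centerX

#' Evaluate a fitted curve
#'
#' @param model an [OcclusalModel-class].
#' @param x x coordinates (pixels).
#' @param curve which curve to evaluate.
#' @return y values in pixels.
#' @export
occlusalY <- function(model, x, curve = c("occlusion", "upper", "lower")) {
  curve <- match.arg(curve)
  q <- slot(model, curve)
  q[1] * x^2 + q[2] * x + q[3]
}

# ---------------------------------------------------------------------------
# PriorParams
# ---------------------------------------------------------------------------

#' Distance thresholds of the positional prior
#'
#' The piecewise score for the horizontal distance between two chosen
#' candidates is parameterised by pixel thresholds
#' `0 < a <= b <= c <= d <= e <= f`: below `a` (too close / reversed) the
#' score is -4, `[a, b)` scores 0, `[b, c)` ramps linearly up to the plateau
#' `[c, d)` at 1, `[d, e)` ramps down (empty under the printed parameterisation
#' where `d = e`), `[e, f)` scores 0, and beyond `f` (too far) -4. Comparisons
#' involving a missing tooth score `kappa`.
#'
#' @slot a,b,c,d,e,f pixel distance thresholds.
#' @slot range `e - b`, the span where tooth presence is plausible.
#' @slot kappa score returned when either tooth of the pair is missing.
#' @seealso [derivePriorParams()], [priorDelta()]
#' @export
setClass("PriorParams",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        d = "numeric", e = "numeric", f = "numeric",
                        range = "numeric", kappa = "numeric"),
         validity = function(object) {
           v <- c(object@a, object@b, object@c, object@d, object@e, object@f)
           if (any(!is.finite(v))) return("thresholds must be finite")
           if (object@a <= 0) return("a must be positive")
           if (is.unsorted(v)) return("need a <= b <= c <= d <= e <= f")
           TRUE
         })

setMethod("show", "PriorParams", function(object) {
  cat(sprintf(
    "PriorParams: a=%.3g b=%.3g c=%.3g d=%.3g e=%.3g f=%.3g (range=%.3g, kappa=%g)\n",
    object@a, object@b, object@c, object@d, object@e, object@f,
    object@range, object@kappa))
})

# ---------------------------------------------------------------------------
# Synthetic scene classes
# ---------------------------------------------------------------------------

#' Detector noise specification for the simulator
#'
#' Controls how ground-truth boxes are corrupted into detector-style
#' candidates: positional and size jitter, duplicate detections, adjacent
#' tooth-number confusion, per-tooth miss probabilities (higher for teeth
#' carrying prosthetic treatment, emulating the lower detector accuracy on
#' treated teeth), and Beta-distributed confidence scores.
#'
#' @slot posJitter std-dev of centre jitter as a fraction of tooth width.
#' @slot sizeJitter fractional std-dev of width/height jitter.
#' @slot dupProb probability of an extra duplicate detection per tooth.
#' @slot shiftProb probability the detection's tooth number is confused with
#'   an adjacent number in the same jaw.
#' @slot missProbNormal,missProbTreated per-tooth miss probabilities;
#'   `missProbTreated >= missProbNormal`.
#' @slot confTP,confFP `c(shape1, shape2)` of the Beta confidence distribution
#'   for genuine and spurious detections; `NA` means a degenerate score of 1.
#' @export
setClass("NoiseSpec",
         representation(posJitter = "numeric", sizeJitter = "numeric",
                        dupProb = "numeric", shiftProb = "numeric",
                        missProbNormal = "numeric", missProbTreated = "numeric",
                        confTP = "numeric", confFP = "numeric"),
         validity = function(object) {
           for (nm in c("dupProb", "shiftProb", "missProbNormal",
                        "missProbTreated")) {
             v <- slot(object, nm)
             if (v < 0 || v > 1) return(sprintf("%s must lie in [0, 1]", nm))
           }
           if (object@missProbTreated < object@missProbNormal) {
             return("missProbTreated must be >= missProbNormal")
           }
           TRUE
         })

#' @param posJitter,sizeJitter,dupProb,shiftProb,missProbNormal,missProbTreated,confTP,confFP
#'   see the class slots; defaults are the package's synthetic benchmark
#'   conditions.
#' @rdname NoiseSpec-class
#' @export
noiseSpec <- function(posJitter = 0.10, sizeJitter = 0.05, dupProb = 0.10,
                      shiftProb = 0.05, missProbNormal = 0.02,
                      missProbTreated = 0.15, confTP = c(14, 2),
                      confFP = c(5, 5)) {
  new("NoiseSpec", posJitter = posJitter, sizeJitter = sizeJitter,
      dupProb = dupProb, shiftProb = shiftProb,
      missProbNormal = missProbNormal, missProbTreated = missProbTreated,
      confTP = confTP, confFP = confFP)
}

#' @rdname NoiseSpec-class
#' @export
zeroNoise <- function() {
  noiseSpec(posJitter = 0, sizeJitter = 0, dupProb = 0, shiftProb = 0,
            missProbNormal = 0, missProbTreated = 0,
            confTP = NA_real_, confFP = NA_real_)
}

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(paste0("NoiseSpec: posJitter=%g sizeJitter=%g dupProb=%g ",
                     "shiftProb=%g miss=%g/%g (normal/treated)\n"),
              object@posJitter, object@sizeJitter, object@dupProb,
              object@shiftProb, object@missProbNormal, object@missProbTreated))
})

#' Synthetic scene specification
#'
#' Describes one synthetic panoramic layout: two quadratic dental arches of 16
#' stations each inside the central 55% of the image width, per-tooth missing
#' probability, prosthesis incidence, and the detector noise model.
#'
#' @slot frame the [ImageFrame-class].
#' @slot missingProb per-tooth probability of a missing tooth.
#' @slot prosthesisMix named numeric `c(inlay=, crown=, implant=, bridge=)`:
#'   inlay/crown are per-present-tooth probabilities, implant/bridge are
#'   per-missing-station probabilities (a bridge needs both flanking teeth
#'   present and is only placed over a single missing tooth).
#' @slot noise a [NoiseSpec-class].
#' @slot curvature occlusal quadratic coefficient a2 (pixels^-1); negative
#'   values give the radiograph's upward-turned arch ends.
#' @slot occlusalYFrac occlusion line height at the apex, as fraction of the
#'   image height.
#' @slot jawGap vertical distance in pixels between upper and lower tooth-row
#'   centres.
#' @slot toothWidth,toothHeight ground-truth box size in pixels.
#' @slot apexJitterFrac per-scene uniform jitter of the arch apex x, as a
#'   fraction of width.
#' @slot seed integer RNG seed; scenes are pure functions of the spec.
#' @export
setClass("SceneSpec",
         representation(frame = "ImageFrame", missingProb = "numeric",
                        prosthesisMix = "numeric", noise = "NoiseSpec",
                        curvature = "numeric", occlusalYFrac = "numeric",
                        jawGap = "numeric", toothWidth = "numeric",
                        toothHeight = "numeric", apexJitterFrac = "numeric",
                        seed = "integer"),
         validity = function(object) {
           .assertProb(object@missingProb, "missingProb")
           .assertProb(object@prosthesisMix, "prosthesisMix")
           if (!setequal(names(object@prosthesisMix), PROSTHESIS_CLASSES)) {
             return("prosthesisMix must be named inlay/crown/implant/bridge")
           }
           TRUE
         })

#' @param frame image frame (default 640 x 640, the usual detector input
#'   resolution).
#' @param missingProb,prosthesisMix,noise,curvature,occlusalYFrac,jawGap,toothWidth,toothHeight,apexJitterFrac
#'   see the class slots.
#' @param seed integer RNG seed.
#' @rdname SceneSpec-class
#' @export
sceneSpec <- function(frame = imageFrame(640, 640), missingProb = 0.10,
                      prosthesisMix = c(inlay = 0.016, crown = 0.066,
                                        implant = 0.03, bridge = 0.05),
                      noise = noiseSpec(), curvature = NULL,
                      occlusalYFrac = 0.52, jawGap = 90, toothWidth = 20,
                      toothHeight = 44, apexJitterFrac = 0.02,
                      seed = 1L) {
  if (is.null(curvature)) {
    # arch ends rise ~40 px above the apex over the 55% tooth-bearing span
    half <- 0.275 * frameWidth(frame)
    curvature <- -40 / half^2
  }
  new("SceneSpec", frame = frame, missingProb = missingProb,
      prosthesisMix = prosthesisMix[PROSTHESIS_CLASSES], noise = noise,
      curvature = curvature, occlusalYFrac = occlusalYFrac, jawGap = jawGap,
      toothWidth = toothWidth, toothHeight = toothHeight,
      apexJitterFrac = apexJitterFrac, seed = as.integer(seed))
}

#' A generated synthetic scene
#'
#' Holds the station-level truth, the three ground-truth annotation views
#' (tooth, prosthesis, all), and the noisy detector-style candidates.
#'
#' @slot frame the [ImageFrame-class].
#' @slot seed the seed the scene was generated from.
#' @slot stations data frame with one row per UTN station (tooth, cx, cy, w,
#'   h, status) where status is one of missing/normal/inlay/crown/implant/
#'   bridge_abutment/bridge_denture.
#' @slot toothGT,allGT tooth-annotation and all-annotation views: boxes
#'   labelled with UTN classes. The tooth view omits complete restorations
#'   (implants, bridge dentures); the all view includes them, numbered by
#'   station.
#' @slot prosthesisGT prosthesis-annotation view: boxes labelled with the four
#'   prosthesis classes (a bridge box spans both abutments and the denture).
#' @slot toothCandidates,prosthesisDetections the noisy detector outputs.
#' @export
setClass("DentitionScene",
         representation(frame = "ImageFrame", seed = "integer",
                        stations = "data.frame", toothGT = "data.frame",
                        prosthesisGT = "data.frame", allGT = "data.frame",
                        toothCandidates = "data.frame",
                        prosthesisDetections = "data.frame"))

setMethod("show", "DentitionScene", function(object) {
  st <- object@stations
  cat(sprintf("DentitionScene (seed %d): %d/32 teeth present\n",
              object@seed, sum(st$status != "missing")))
  tab <- table(st$status)
  cat("  stations:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  GT boxes: tooth=%d prosthesis=%d all=%d\n",
              nrow(object@toothGT), nrow(object@prosthesisGT),
              nrow(object@allGT)))
  cat(sprintf("  detections: tooth=%d prosthesis=%d\n",
              nrow(object@toothCandidates),
              nrow(object@prosthesisDetections)))
})

#' @param scene a `DentitionScene`.
#' @param view which annotation view to return.
#' @rdname DentitionScene-class
#' @export
groundTruth <- function(scene, view = c("all", "tooth", "prosthesis")) {
  view <- match.arg(view)
  switch(view, all = scene@allGT, tooth = scene@toothGT,
         prosthesis = scene@prosthesisGT)
}

#' @rdname DentitionScene-class
#' @export
sceneFrame <- function(scene) scene@frame

# ---------------------------------------------------------------------------
# MatchReport
# ---------------------------------------------------------------------------

#' Detection evaluation report
#'
#' @slot perClass data frame with one row per class: instances, TP, FP,
#'   precision, recall, AP.
#' @slot micro named numeric: pooled TP, FP, FN, precision, recall, F1.
#' @slot mAP mean of the per-class average precisions.
#' @seealso [evaluateDetections()]
#' @export
setClass("MatchReport",
         representation(perClass = "data.frame", micro = "numeric",
                        mAP = "numeric"))

setMethod("show", "MatchReport", function(object) {
  cat(sprintf("MatchReport over %d classes\n", nrow(object@perClass)))
  cat(sprintf("  mAP = %.4f\n", object@mAP))
  m <- object@micro
  cat(sprintf("  micro: P = %.4f  R = %.4f  F1 = %.4f  (TP=%d FP=%d FN=%d)\n",
              m["precision"], m["recall"], m["f1"],
              as.integer(m["tp"]), as.integer(m["fp"]), as.integer(m["fn"])))
})

#' @param report a `MatchReport`.
#' @rdname MatchReport-class
#' @export
perClassMetrics <- function(report) report@perClass

#' @rdname MatchReport-class
#' @export
microMetrics <- function(report) report@micro

#' @rdname MatchReport-class
#' @export
meanAveragePrecision <- function(report) report@mAP
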