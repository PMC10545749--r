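# Occlusal curve fitting and jaw assignment.

.fitQuadratic <- function(cx, cy) {
  if (length(unique(cx)) < 3L) {
    stop("occlusal fit needs at least 3 candidates with distinct x per jaw; ",
         "use fallbackOcclusalModel()", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(cx^2, cx, 1), cy)
  co <- fit$coefficients
  if (any(is.na(co))) {
    stop("rank-deficient occlusal fit; use fallbackOcclusalModel()",
         call. = FALSE)
  }
  unname(co)
}

#' Fit the occlusal geometry from tooth candidates
#'
#' The maxillary (T1-T16) and mandibular (T17-T32) candidate box centres are
#' each fitted with a quadratic `y = a2 x^2 + a1 x + a0` by ordinary least
#' squares. The occlusion line is the coefficient-wise (additive) mean of the
#' two curves; the dentition centre is the x of the occlusion apex,
#' `-a1 / (2 a2)`, unless the apex deviates from the image centre by more than
#' `centerDeviationFraction` of the width (or the curve is flat), in which
#' case the image-width centre is used and flagged.
#'
#' Filtered candidates should be excluded before calling: positional
#' filtering precedes curve fitting in the pipeline.
#'
#' @param cands tooth-candidate data frame; needs >= 3 candidates with
#'   distinct `cx` in each jaw.
#' @param frame the [ImageFrame-class].
#' @param centerDeviationFraction apex deviation tolerance (default 0.05).
#' @return an [OcclusalModel-class].
#' @export
fitOcclusalModel <- function(cands, frame, centerDeviationFraction = 0.05) {
  .validateToothCandidates(cands)
  up <- cands[cands$tooth %in% MAXILLA, , drop = FALSE]
  lo <- cands[cands$tooth %in% MANDIBLE, , drop = FALSE]
  upper <- .fitQuadratic(up$cx, up$cy)
  lower <- .fitQuadratic(lo$cx, lo$cy)
  occ <- (upper + lower) / 2
  width <- frameWidth(frame)
  fallback <- FALSE
  if (abs(occ[1]) < 1e-12) {
    apex <- width / 2          # flat occlusion line has no vertex
    fallback <- TRUE
  } else {
    apex <- -occ[2] / (2 * occ[1])
    if (abs(apex - width / 2) > centerDeviationFraction * width) {
      apex <- width / 2
      fallback <- TRUE
    }
  }
  new("OcclusalModel", upper = upper, lower = lower, occlusion = occ,
      centerX = min(max(apex, 0), width), centerFallbackUsed = fallback,
      degenerate = FALSE)
}

#' Flat fallback occlusal model
#'
#' Used when a jaw has too few candidates for a quadratic fit: both curves
#' become horizontal lines at the jaw's mean candidate y (or fixed fractions
#' of the image height when a jaw is empty), and the dentition centre is the
#' image-width centre.
#'
#' @inheritParams fitOcclusalModel
#' @return an [OcclusalModel-class] with `degenerate = TRUE`.
#' @export
fallbackOcclusalModel <- function(cands, frame) {
  .validateToothCandidates(cands)
  h <- frameHeight(frame)
  up <- cands$cy[cands$tooth %in% MAXILLA]
  lo <- cands$cy[cands$tooth %in% MANDIBLE]
  upperY <- if (length(up)) mean(up) else 0.4 * h
  lowerY <- if (length(lo)) mean(lo) else 0.6 * h
  upper <- c(0, 0, upperY)
  lower <- c(0, 0, lowerY)
  new("OcclusalModel", upper = upper, lower = lower,
      occlusion = (upper + lower) / 2, centerX = frameWidth(frame) / 2,
      centerFallbackUsed = TRUE, degenerate = TRUE)
}

#' Assign a box to a jaw
#'
#' A box belongs to the maxilla when its centre lies above the occlusion line
#' (smaller y in image coordinates), otherwise to the mandible; a centre
#' exactly on the line is assigned to the mandible.
#'
#' @param cx,cy box centre coordinates (vectorised).
#' @param model an [OcclusalModel-class].
#' @return character vector, `"maxilla"` or `"mandible"`.
#' @export
jawOf <- function(cx, cy, model) {
  ifelse(cy < occlusalY(model, cx), "maxilla", "mandible")
}
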