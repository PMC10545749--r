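# Converting prosthesis detections into numbered tooth candidates.

#' Segment a bridge detection into abutments and denture
#'
#' A bridge replacing a single missing tooth consists of two supportive
#' (abutment) teeth flanking one artificial (denture) tooth. The detected
#' bridge box is partitioned along x into three contiguous sections with
#' widths in ratio 33:30:33 (normalized to 33/96, 30/96, 33/96 of the parent
#' width so the sections tile the box exactly); all sections share the
#' parent's `cy`, `h` and confidence. The middle section is the denture.
#'
#' @param b one-row prosthesis-detection data frame with `class == "bridge"`.
#' @return three-row data frame with columns `section`
#'   (`"bridge_abutment"`, `"bridge_denture"`, `"bridge_abutment"`),
#'   `cx, cy, w, h, mu`.
#' @export
#' @examples
#' b <- prosthesisDetections("bridge", cx = 300, cy = 200, w = 96, h = 40,
#'                           mu = 0.9)
#' splitBridge(b)  # widths 33, 30, 33; centres 268.5, 300, 331.5
splitBridge <- function(b) {
  .validateProsthesisDetections(b)
  if (nrow(b) != 1L || b$class != "bridge") {
    stop("splitBridge() expects a single bridge detection")
  }
  frac <- c(33, 30, 33) / 96
  w <- b$w * frac
  left <- b$cx - b$w / 2
  centres <- left + cumsum(w) - w / 2
  data.frame(section = c("bridge_abutment", "bridge_denture",
                         "bridge_abutment"),
             cx = centres, cy = b$cy, w = w, h = b$h, mu = b$mu,
             stringsAsFactors = FALSE)
}

# Expand raw prosthesis detections: bridges are split, other classes pass
# through with their class as the section label.
.expandProstheses <- function(pdet) {
  .validateProsthesisDetections(pdet)
  if (!nrow(pdet)) {
    return(data.frame(section = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), mu = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(pdet)), function(i) {
    row <- pdet[i, , drop = FALSE]
    if (row$class == "bridge") {
      splitBridge(row)
    } else {
      data.frame(section = row$class, cx = row$cx, cy = row$cy, w = row$w,
                 h = row$h, mu = row$mu, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Applicable UTN range for a prosthesis-derived box. The left/right split at
# the dentition centre is deliberately overlapping near the midline; the
# optimizer resolves the exact number.
.numberRange <- function(jaw, cx, centerX) {
  if (jaw == "maxilla") {
    if (cx < centerX) 1:13 else 3:16
  } else {
    if (cx < centerX) 20:32 else 17:29
  }
}

#' Assign approximate tooth numbers to prosthesis-derived boxes
#'
#' Each prosthesis-derived box (bridges already split, see [splitBridge()])
#' is assigned to a jaw by comparing its centre with the occlusion line, then
#' fanned out into one tooth candidate per UTN number in its applicable
#' range: maxilla left of the dentition centre 1-13, maxilla right 3-16,
#' mandible left 20-32, mandible right 17-29. All candidates of one box share
#' the box and confidence; the downstream optimizer selects the number. When
#' the box overlaps a step-1 tooth candidate (max IOU >= `halveIoU`), i.e.
#' the tooth was already detected, the confidence of every generated
#' candidate is halved (applied at most once per box).
#'
#' @param pBoxes data frame of prosthesis-derived boxes ([splitBridge()]
#'   output for bridges, pass-through sections for the other classes):
#'   columns `section, cx, cy, w, h, mu` where `section` is a restoration
#'   label (inlay/crown/implant/bridge_abutment/bridge_denture).
#' @param model the fitted [OcclusalModel-class].
#' @param existing step-1 tooth-candidate data frame used for the overlap
#'   test (typically the filtered detector output).
#' @param halveIoU IOU threshold of the "already detected" test
#'   (default 0.5).
#' @param classesEnabled restoration labels allowed to generate candidates.
#' @return tooth-candidate data frame with `origin = "prosthesis_detector"`.
#' @export
assignToothNumbers <- function(pBoxes, model, existing,
                               halveIoU = 0.5,
                               classesEnabled = c("inlay", "crown", "implant",
                                                  "bridge_abutment",
                                                  "bridge_denture")) {
  if (!nrow(pBoxes)) return(toothCandidates())
  pBoxes <- pBoxes[pBoxes$section %in% classesEnabled, , drop = FALSE]
  if (!nrow(pBoxes)) return(toothCandidates())
  out <- vector("list", nrow(pBoxes))
  for (i in seq_len(nrow(pBoxes))) {
    row <- pBoxes[i, , drop = FALSE]
    jaw <- jawOf(row$cx, row$cy, model)
    numbers <- .numberRange(jaw, row$cx, dentitionCenter(model))
    mu <- row$mu
    if (nrow(existing)) {
      ious <- boxIoU(row$cx, row$cy, row$w, row$h,
                     existing$cx, existing$cy, existing$w, existing$h)
      if (max(ious) >= halveIoU) mu <- mu / 2
    }
    cand <- toothCandidates(tooth = numbers, cx = row$cx, cy = row$cy,
                            w = row$w, h = row$h, mu = mu,
                            restoration = row$section,
                            origin = "prosthesis_detector")
    cand$boxId <- paste0("p", i)  # all fan-out copies share one physical box
    out[[i]] <- cand
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
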