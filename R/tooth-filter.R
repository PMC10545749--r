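#' Remove positionally impossible tooth candidates
#'
#' The tooth-bearing oral cavity occupies roughly the central 55% of a
#' panoramic radiograph's width, so candidates numbered for one side of the
#' mouth cannot appear on the far opposite side. Candidates for T10-T24
#' (image-right teeth under the panoramic left/right reversal) are false
#' positives when their box centre lies within the left `leftFraction` of the
#' image width, and candidates for T1-T7 or T26-T32 are false positives when
#' their centre lies beyond the right `rightFraction`. T8, T9 and T25 sit
#' near the midline and are exempt. Comparisons are strict: a centre exactly
#' on a boundary is retained.
#'
#' @param cands tooth-candidate data frame (see [toothCandidates()]).
#' @param frame the [ImageFrame-class].
#' @param leftFraction left cutoff as a fraction of width (default 0.40).
#' @param rightFraction right cutoff as a fraction of width (default 0.60).
#' @param enabled set FALSE to pass candidates through unchanged.
#' @return the retained candidates, in input order.
#' @export
#' @examples
#' f <- imageFrame(640, 640)
#' cands <- toothCandidates(tooth = c(12, 1), cx = c(128, 512), cy = 200,
#'                          w = 20, h = 40, mu = 0.9)
#' filterToothCandidates(cands, f)  # both removed
filterToothCandidates <- function(cands, frame, leftFraction = 0.40,
                                  rightFraction = 0.60, enabled = TRUE) {
  .validateToothCandidates(cands)
  if (!enabled || !nrow(cands)) return(cands)
  w <- frameWidth(frame)
  rightSide <- cands$tooth %in% 10:24
  lateral <- cands$tooth %in% c(1:7, 26:32)
  drop <- (rightSide & cands$cx < leftFraction * w) |
          (lateral & cands$cx > rightFraction * w)
  out <- cands[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
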