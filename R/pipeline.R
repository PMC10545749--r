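# End-to-end orchestration: filter -> fit geometry -> (prosthesis numbering)
# -> optimize.

#' Pipeline configuration defaults
#'
#' Collects every stage's tunables in one list: positional-filter fractions,
#' the dentition-centre deviation tolerance, prosthesis numbering thresholds,
#' prior-model weights and variant, and optimizer settings. Values not
#' overridden keep these defaults.
#'
#' @param ... named overrides of the defaults.
#' @return named list of settings.
#' @export
#' @examples
#' pipelineControl(omegaP = 0.7, maxSweeps = 5)
pipelineControl <- function(...) {
  ctl <- list(
    filterEnabled = TRUE, leftFraction = 0.40, rightFraction = 0.60,
    centerDeviationFraction = 0.05,
    halveIoU = 0.5,
    classesEnabled = c("inlay", "crown", "implant", "bridge_abutment",
                       "bridge_denture"),
    omegaP = 0.8, omegaC = 0.2, kappa = 0, variant = "as_printed",
    mandibleCenterHalving = TRUE, molarEFactor = 1.5,
    maxSweeps = 10L, roundRobinBudget = 5^5, enableRoundRobin = TRUE,
    enableStep7 = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(ctl))
  if (length(bad)) stop("unknown control settings: ",
                        paste(bad, collapse = ", "))
  ctl[names(over)] <- over
  ctl
}

#' Run the tooth-numbering pipeline
#'
#' Executes the full chain on one image's candidates: positional
#' false-positive filtering, occlusal-model fitting (with the flat fallback
#' when a jaw has too few candidates), then -- in `"proposed"` mode --
#' bridge segmentation and prosthesis-to-tooth-number assignment merged into
#' the candidate table, and finally the combinatorial search. In
#' `"earlier"` mode the prosthesis stages are skipped and only step-1 tooth
#' candidates are used.
#'
#' @param x tooth-candidate data frame, or a [DentitionScene-class] (whose
#'   candidates and frame are used).
#' @param ... passed between methods.
#' @param prostheses prosthesis-detection data frame (required in proposed
#'   mode unless `x` is a scene).
#' @param frame the [ImageFrame-class] (unless `x` is a scene).
#' @param mode `"proposed"` (tooth + prosthesis candidates) or `"earlier"`
#'   (tooth candidates only).
#' @param control settings list from [pipelineControl()].
#' @param verbose log per-stage candidate counts.
#' @return list with `combination` (a [Combination-class]), `score`,
#'   `model` (the [OcclusalModel-class]), `table` (the optimized
#'   [CandidateTable-class]) and `counts` (per-stage candidate counts).
#' @export
setGeneric("runPipeline", function(x, ...) standardGeneric("runPipeline"))

#' @rdname runPipeline
#' @export
setMethod("runPipeline", "data.frame",
  function(x, prostheses = NULL, frame, mode = c("proposed", "earlier"),
           control = pipelineControl(), verbose = FALSE) {
    mode <- match.arg(mode)
    .validateToothCandidates(x)
    if (mode == "proposed" && is.null(prostheses)) {
      stop("proposed mode needs prosthesis detections; ",
           "use mode = \"earlier\" for tooth candidates only")
    }
    say <- function(...) if (verbose) message(sprintf(...))
    counts <- c(input = nrow(x))

    kept <- filterToothCandidates(x, frame,
                                  leftFraction = control$leftFraction,
                                  rightFraction = control$rightFraction,
                                  enabled = control$filterEnabled)
    counts["filtered"] <- nrow(kept)
    say("filter: %d -> %d tooth candidates", nrow(x), nrow(kept))

    model <- tryCatch(
      fitOcclusalModel(kept, frame,
                       centerDeviationFraction =
                         control$centerDeviationFraction),
      error = function(e) {
        say("occlusal fit failed (%s); using flat fallback model",
            conditionMessage(e))
        fallbackOcclusalModel(kept, frame)
      })

    merged <- kept
    if (mode == "proposed" && nrow(prostheses)) {
      expanded <- .expandProstheses(prostheses)
      derived <- assignToothNumbers(expanded, model, existing = kept,
                                    halveIoU = control$halveIoU,
                                    classesEnabled = control$classesEnabled)
      counts["prosthesis_derived"] <- nrow(derived)
      say("prosthesis numbering: %d boxes -> %d derived candidates",
          nrow(expanded), nrow(derived))
      kept2 <- kept
      kept2$boxId <- if (nrow(kept2)) paste0("t", seq_len(nrow(kept2)))
                     else character()
      merged <- rbind(kept2, derived)
    } else {
      counts["prosthesis_derived"] <- 0L
    }

    table <- buildCandidateTable(merged, frame)
    res <- optimizeCombination(
      table, omegaP = control$omegaP, omegaC = control$omegaC,
      variant = control$variant, kappa = control$kappa,
      mandibleCenterHalving = control$mandibleCenterHalving,
      molarEFactor = control$molarEFactor, maxSweeps = control$maxSweeps,
      roundRobinBudget = control$roundRobinBudget,
      enableRoundRobin = control$enableRoundRobin,
      enableStep7 = control$enableStep7)
    counts["selected"] <- nrow(selectedTeeth(res$combination))
    say("optimizer: %d teeth selected, score %.4f (%d sweeps)",
        counts["selected"], res$score, res$sweeps)

    list(combination = res$combination, score = res$score, model = model,
         table = table, counts = counts)
  })

#' @rdname runPipeline
#' @export
setMethod("runPipeline", "DentitionScene",
  function(x, mode = c("proposed", "earlier"), control = pipelineControl(),
           verbose = FALSE) {
    mode <- match.arg(mode)
    runPipeline(x@toothCandidates,
                prostheses = if (mode == "proposed") x@prosthesisDetections,
                frame = x@frame, mode = mode, control = control,
                verbose = verbose)
  })

#' Convert a combination to class-labelled detections
#'
#' @param P a [Combination-class].
#' @param dropCompleteRestorations drop implant and bridge-denture slots
#'   before reporting (the "without complete restorations" comparison
#'   against tooth-only annotations).
#' @return data frame `class, cx, cy, w, h, mu` with the UTN number as the
#'   class label, suitable for [evaluateDetections()].
#' @export
combinationDetections <- function(P, dropCompleteRestorations = FALSE) {
  sel <- selectedTeeth(P)
  if (dropCompleteRestorations) {
    sel <- sel[!sel$restoration %in% c("implant", "bridge_denture"), ,
               drop = FALSE]
  }
  data.frame(class = sel$tooth, cx = sel$cx, cy = sel$cy, w = sel$w,
             h = sel$h, mu = sel$mu, stringsAsFactors = FALSE)
}

#' Evaluate pipeline outputs against scene ground truth
#'
#' Scores a list of pipeline results against the chosen annotation view of
#' the corresponding scenes, pooling scenes into one [MatchReport-class].
#'
#' @param results list of [runPipeline()] results (or of
#'   [Combination-class] objects).
#' @param scenes list of [DentitionScene-class], parallel to `results`.
#' @param view ground-truth view to score against.
#' @param dropCompleteRestorations see [combinationDetections()]; typically
#'   paired with `view = "tooth"`.
#' @param iouThreshold matching threshold, default 0.5.
#' @return a [MatchReport-class].
#' @export
evaluateScenes <- function(results, scenes, view = c("all", "tooth"),
                           dropCompleteRestorations = FALSE,
                           iouThreshold = 0.5) {
  view <- match.arg(view)
  if (length(results) != length(scenes)) {
    stop("results and scenes must pair up")
  }
  preds <- lapply(results, function(r) {
    P <- if (is(r, "Combination")) r else r$combination
    combinationDetections(P, dropCompleteRestorations)
  })
  gts <- lapply(scenes, function(s) {
    gt <- groundTruth(s, view)
    data.frame(class = gt$tooth, cx = gt$cx, cy = gt$cy, w = gt$w,
               h = gt$h, stringsAsFactors = FALSE)
  })
  evaluateDetections(preds, gts, iouThreshold)
}
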