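# Readers and writers for YOLO-style detection text and the JSON scene format.

#' Read detector candidates or ground truth from YOLO-style text
#'
#' Each line is `class cx cy w h [conf]`. In the normalized dialect (the YOLO
#' convention) coordinates are fractions of the frame; in the absolute dialect
#' they are pixels. Class ids are 0-based: ids 0..31 map to UTN 1..32 for
#' tooth files, ids 0..3 map to inlay/crown/implant/bridge for prosthesis
#' files. Records whose confidence falls below `confThreshold` are dropped at
#' read time, mirroring the usual detector inference threshold; ground-truth
#' files without a confidence column are read with `mu = 1`.
#'
#' @param path file path.
#' @param frame the [ImageFrame-class] used to convert normalized coordinates.
#' @param type `"tooth"` or `"prosthesis"` (selects the class scheme).
#' @param normalized TRUE (default) for the normalized dialect; files must
#'   declare their dialect, the format itself does not.
#' @param confThreshold drop records with `mu` below this (default 0.35).
#' @return a tooth-candidate or prosthesis-detection data frame.
#' @export
readCandidates <- function(path, frame, type = c("tooth", "prosthesis"),
                           normalized = TRUE, confThreshold = 0.35) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  nmax <- if (type == "tooth") 32L else 4L
  rec <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (!(length(parts) %in% c(5L, 6L))) {
      stop(sprintf("%s: malformed record at line %d (need 5 or 6 fields)",
                   path, i))
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      stop(sprintf("%s: non-numeric field at line %d", path, i))
    }
    cls <- vals[1]
    if (cls != round(cls) || cls < 0 || cls >= nmax) {
      stop(sprintf("%s: class id %g at line %d outside 0..%d",
                   path, cls, i, nmax - 1L))
    }
    rec[[i]] <- c(cls, vals[2:5], if (length(vals) == 6L) vals[6] else 1)
  }
  m <- do.call(rbind, rec)
  if (is.null(m)) m <- matrix(numeric(), ncol = 6)
  keep <- m[, 6] >= confThreshold
  m <- m[keep, , drop = FALSE]
  sx <- if (normalized) frameWidth(frame) else 1
  sy <- if (normalized) frameHeight(frame) else 1
  if (type == "tooth") {
    toothCandidates(tooth = as.integer(m[, 1]) + 1L,
                    cx = m[, 2] * sx, cy = m[, 3] * sy,
                    w = m[, 4] * sx, h = m[, 5] * sy, mu = m[, 6])
  } else {
    prosthesisDetections(class = PROSTHESIS_CLASSES[as.integer(m[, 1]) + 1L],
                         cx = m[, 2] * sx, cy = m[, 3] * sy,
                         w = m[, 4] * sx, h = m[, 5] * sy, mu = m[, 6])
  }
}

#' Write detections or ground truth as YOLO-style text
#'
#' Inverse of [readCandidates()]: writes `class cx cy w h conf` lines with
#' full-precision numbers so that a read/write round trip is exact.
#'
#' @param df tooth-candidate or prosthesis-detection data frame.
#' @param path output path.
#' @param frame the [ImageFrame-class].
#' @param normalized write normalized (default) or absolute coordinates.
#' @param conf include the confidence column.
#' @return invisibly, `path`.
#' @export
writeCandidates <- function(df, path, frame, normalized = TRUE, conf = TRUE) {
  isTooth <- "tooth" %in% names(df)
  cls <- if (isTooth) df$tooth - 1L else match(df$class, PROSTHESIS_CLASSES) - 1L
  sx <- if (normalized) frameWidth(frame) else 1
  sy <- if (normalized) frameHeight(frame) else 1
  conf <- conf && "mu" %in% names(df)
  lines <- paste(cls, .fmtNum(df$cx / sx), .fmtNum(df$cy / sy),
                 .fmtNum(df$w / sx), .fmtNum(df$h / sy),
                 if (conf) .fmtNum(df$mu) else NULL)
  writeLines(lines, path)
  invisible(path)
}

#' Write a tooth chart (combination) to text
#'
#' One record per selected tooth, `tooth cx cy w h mu restoration origin`
#' in absolute pixels, preceded by a comment line listing the teeth declared
#' missing. [readCombination()] restores the object field-exactly.
#'
#' @param P a [Combination-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCombination <- function(P, path) {
  stopifnot(is(P, "Combination"))
  sel <- P@selected
  header <- paste("# missing:", paste(P@missing, collapse = " "))
  lines <- paste(sel$tooth, .fmtNum(sel$cx), .fmtNum(sel$cy), .fmtNum(sel$w),
                 .fmtNum(sel$h), .fmtNum(sel$mu), sel$restoration, sel$origin)
  ok <- tryCatch({
    writeLines(c(header, lines), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write combination to ", path)
  invisible(path)
}

#' @rdname writeCombination
#' @export
readCombination <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) {
    return(new("Combination", selected = toothCandidates(),
               missing = 1:32))
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(lengths(parts) != 8L)
  if (length(bad)) stop(sprintf("%s: malformed record (line %d)", path, bad[1]))
  m <- do.call(rbind, parts)
  combination(toothCandidates(
    tooth = as.integer(m[, 1]), cx = as.numeric(m[, 2]),
    cy = as.numeric(m[, 3]), w = as.numeric(m[, 4]), h = as.numeric(m[, 5]),
    mu = as.numeric(m[, 6]), restoration = m[, 7], origin = m[, 8]))
}

# ---------------------------------------------------------------------------
# JSON scene format
# ---------------------------------------------------------------------------

#' Serialize a synthetic scene to JSON
#'
#' The scene format bundles the frame, the station truth, the three
#' ground-truth views and the detector-style candidates in one JSON object
#' (all coordinates absolute pixels, boxes centre-format).
#'
#' @param scene a [DentitionScene-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeScene <- function(scene, path) {
  obj <- list(
    frame = list(width = frameWidth(scene@frame),
                 height = frameHeight(scene@frame)),
    seed = scene@seed,
    stations = scene@stations,
    tooth_annotation = scene@toothGT,
    prosthesis_annotation = scene@prosthesisGT,
    all_annotation = scene@allGT,
    tooth_candidates = scene@toothCandidates,
    prosthesis_detections = scene@prosthesisDetections)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asdf <- function(x, template) {
    if (is.null(x) || !length(x) || !length(x[[1]])) return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if ("tooth" %in% names(df)) df$tooth <- as.integer(df$tooth)
    df
  }
  emptyT <- toothCandidates()
  emptyP <- prosthesisDetections()
  new("DentitionScene",
      frame = imageFrame(obj$frame$width, obj$frame$height),
      seed = as.integer(obj$seed),
      stations = asdf(obj$stations, data.frame()),
      toothGT = asdf(obj$tooth_annotation, emptyT[0, 1:5]),
      prosthesisGT = asdf(obj$prosthesis_annotation, emptyP),
      allGT = asdf(obj$all_annotation, emptyT[0, 1:5]),
      toothCandidates = asdf(obj$tooth_candidates, emptyT),
      prosthesisDetections = asdf(obj$prosthesis_detections, emptyP))
}
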