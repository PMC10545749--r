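# Internal helpers shared across modules.

RESTORATION_LEVELS <- c("normal", "inlay", "crown", "implant",
                        "bridge_abutment", "bridge_denture")
PROSTHESIS_CLASSES <- c("inlay", "crown", "implant", "bridge")

MAXILLA <- 1:16
MANDIBLE <- 17:32

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse the six-valued restoration labels to the four prosthesis classes
#'
#' Internally bridges are split into abutment and denture sections; reporting
#' against prosthesis-level annotations uses the collapsed four-class view
#' (both bridge sections map back to `"bridge"`).
#'
#' @param restoration character vector of restoration labels.
#' @return character vector with `"bridge_abutment"` and `"bridge_denture"`
#'   replaced by `"bridge"`; `"normal"` is kept as is.
#' @export
#' @examples
#' collapseRestoration(c("crown", "bridge_denture", "normal"))
collapseRestoration <- function(restoration) {
  out <- as.character(restoration)
  out[out %in% c("bridge_abutment", "bridge_denture")] <- "bridge"
  out
}

# Same-jaw tooth numbers for a given tooth.
.jawNumbers <- function(x) if (x <= 16L) MAXILLA else MANDIBLE

# The four-neighbour comparison set of a tooth, truncated at jaw ends.
.omegaOf <- function(x) {
  jaw <- .jawNumbers(x)
  nb <- c(x - 2L, x - 1L, x + 1L, x + 2L)
  nb[nb %in% jaw]
}

# Format numbers for text output without losing precision on round trips.
.fmtNum <- function(x) sprintf("%.17g", x)

.assertProb <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
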