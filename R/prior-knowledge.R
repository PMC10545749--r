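# The prior-knowledge positional model and the combination objective.

# Numeric fast path used by both the exported constructor and the optimizer's
# precomputed pair context. Returns c(a, b, c, d, e, f).
.priorParamsNum <- function(width, x, y, variant = "as_printed",
                            mandibleCenterHalving = TRUE,
                            molarEFactor = 1.5) {
  unit <- width * 0.55 / 16
  b <- unit * 0.4
  e <- unit * 2
  # mandible centre: crowded incisor region, plausible spacings shrink
  if (mandibleCenterHalving && all(c(x, y) %in% 21:28)) b <- b / 2
  # mandibular molars: wide teeth, plausible spacings stretch
  if (any(c(x, y) %in% c(17:19, 30:32))) e <- e * molarEFactor
  rng <- e - b
  a <- b / 2
  cc <- b + rng / 4
  d <- if (variant == "as_printed") cc + rng / 4 * 3 else b + rng / 4 * 3
  f <- e + rng / 4
  if (abs(x - y) == 2L) {
    # next-nearest neighbours: one tooth lies between the pair, so every
    # threshold shifts outward by c while the too-close cutoff becomes the
    # unshifted c itself
    a <- cc
    b <- b + cc; d <- d + cc; e <- e + cc; f <- f + cc
    cc <- cc + cc
  }
  c(a = a, b = b, c = cc, d = d, e = e, f = f)
}

#' Derive the positional-prior distance thresholds for a tooth pair
#'
#' Thresholds are anchored on the tooth-bearing span: the oral cavity covers
#' about 55% of the image width and holds 16 teeth per row, so the nominal
#' station spacing is `width * 0.55 / 16`. The base values are
#' `b = spacing * 0.4`, `e = spacing * 2`, `Range = e - b`, `a = b / 2`,
#' `c = b + Range/4`, `f = e + Range/4`, and the plateau end
#' `d = c + 3 Range/4` (the printed parameterisation, under which `d = e`
#' identically and the ramp-down segment is empty) or
#' `d = b + 3 Range/4` (the quartile reading, plateau from Q1 to Q3 of the
#' Range). Three adjustments apply, in order: if both teeth lie in the
#' crowded mandibular centre (21-28) `b` is halved and the dependent values
#' recomputed; if either tooth is a mandibular molar (17-19, 30-32) `e` is
#' multiplied by `molarEFactor` and the dependents recomputed; and for
#' next-nearest pairs (`|x - y| = 2`) the too-close cutoff `a` becomes the
#' unshifted `c` while `b..f` shift outward by that same `c`.
#'
#' @param width image width in pixels.
#' @param x,y tooth numbers in the same jaw with `|x - y|` 1 or 2.
#' @param variant `"as_printed"` (default) or `"quartile"` plateau end.
#' @param kappa score assigned to comparisons with a missing tooth
#'   (default 0: missing neighbours neither rewarded nor penalized).
#' @param mandibleCenterHalving,molarEFactor jaw-specific adjustments; set
#'   `mandibleCenterHalving = FALSE` or `molarEFactor = 1` to disable.
#' @return a [PriorParams-class].
#' @export
#' @examples
#' derivePriorParams(640, 8, 9)   # b = 8.8, e = 44, plateau [17.6, 44)
derivePriorParams <- function(width, x, y,
                              variant = c("as_printed", "quartile"),
                              kappa = 0, mandibleCenterHalving = TRUE,
                              molarEFactor = 1.5) {
  variant <- match.arg(variant)
  x <- as.integer(x); y <- as.integer(y)
  if (!(abs(x - y) %in% 1:2)) stop("|x - y| must be 1 or 2")
  if ((x <= 16L) != (y <= 16L)) stop("x and y must lie in the same jaw")
  v <- .priorParamsNum(width, x, y, variant, mandibleCenterHalving,
                       molarEFactor)
  new("PriorParams", a = v[["a"]], b = v[["b"]], c = v[["c"]], d = v[["d"]],
      e = v[["e"]], f = v[["f"]], range = v[["e"]] - v[["b"]], kappa = kappa)
}

#' Piecewise positional score for a pair of chosen candidates
#'
#' Scores the direction-corrected horizontal separation `g` between the
#' candidates chosen for two teeth (see [directedSeparation()]): -4 when the
#' pair is reversed or too close (`g < a`), 0 on `[a, b)`, a linear ramp
#' `(g - b) / (c - b)` on `[b, c)`, 1 on the plateau `[c, d)`, a ramp down
#' on `[d, e)` (empty when `d = e`), 0 on `[e, f)`, and -4 beyond `f`. `NA`
#' separations encode comparisons with a missing tooth and score `kappa`.
#'
#' @param g directed separations in pixels (vectorised); negative values
#'   mean the pair sits in reversed order for its jaw; `NA` for
#'   missing-tooth pairs.
#' @param params a [PriorParams-class].
#' @return numeric scores in `{-4} U [0, 1] U {kappa}`.
#' @export
#' @examples
#' p <- derivePriorParams(640, 8, 9)
#' priorDelta(c(2, 13.2, 30, NA), p)  # -4, 0.5, 1, kappa
#' priorDelta(-25, p)                 # reversed pair: -4
priorDelta <- function(g, params) {
  stopifnot(is(params, "PriorParams"))
  out <- numeric(length(g))
  na <- is.na(g)
  out[na] <- params@kappa
  gg <- g[!na]
  a <- params@a; b <- params@b; cc <- params@c
  d <- params@d; e <- params@e; f <- params@f
  v <- ifelse(gg < a, -4,
       ifelse(gg < b, 0,
       ifelse(gg < cc, (gg - b) / (cc - b),
       ifelse(gg < d, 1,
       ifelse(gg < e, 1 - (gg - d) / (e - d),
       ifelse(gg < f, 0, -4))))))
  out[!na] <- v
  out
}

#' Direction-corrected separation of a tooth pair
#'
#' The universal numbering runs left-to-right across the image in the
#' maxilla (T1 image-left through T16 image-right) and right-to-left in the
#' mandible (T17 image-right through T32 image-left), so the expected sign
#' of `cx(x) - cx(y)` depends on the jaw. This helper returns the
#' separation measured in the jaw's expected direction: positive when the
#' higher-numbered tooth lies on its expected side, negative when the pair
#' is reversed. Reversed pairs then fall into the `g < a` penalty branch of
#' [priorDelta()].
#'
#' @param x,y tooth numbers in the same jaw.
#' @param cxX,cxY centre x coordinates of the chosen candidates.
#' @return signed separation in pixels.
#' @export
#' @examples
#' directedSeparation(2, 1, 120, 100)   # maxilla, expected order: +20
#' directedSeparation(18, 17, 120, 100) # mandible, reversed: -20
directedSeparation <- function(x, y, cxX, cxY) {
  s <- sign(x - y) * ifelse(x <= 16, 1, -1)
  (cxX - cxY) * s
}

# ---------------------------------------------------------------------------
# Pair context: everything width-dependent precomputed once per image.
# ---------------------------------------------------------------------------

.priorContext <- function(width, variant = "as_printed", kappa = 0,
                          mandibleCenterHalving = TRUE, molarEFactor = 1.5) {
  px <- integer(); py <- integer(); wpair <- numeric()
  for (x in 1:32) {
    om <- .omegaOf(x)
    px <- c(px, rep.int(x, length(om)))
    py <- c(py, om)
    wpair <- c(wpair, rep.int(1 / length(om), length(om)))
  }
  P <- t(vapply(seq_along(px), function(i) {
    .priorParamsNum(width, px[i], py[i], variant, mandibleCenterHalving,
                    molarEFactor)
  }, numeric(6)))
  sgn <- sign(px - py) * ifelse(px <= 16L, 1, -1)
  list(px = px, py = py, wpair = wpair, kappa = kappa, sgn = sgn,
       a = P[, 1], b = P[, 2], c = P[, 3], d = P[, 4], e = P[, 5], f = P[, 6])
}

# Objective for slot-wise centre-x and confidence vectors (NA = phi).
# The workhorse of the optimizer: one vectorised pass over ~120 pairs.
.objectiveNum <- function(cx, mu, ctx, omegaP, omegaC) {
  g <- (cx[ctx$px] - cx[ctx$py]) * ctx$sgn
  na <- is.na(g)
  v <- numeric(length(g))
  v[na] <- ctx$kappa
  if (!all(na)) {
    gg <- g[!na]
    a <- ctx$a[!na]; b <- ctx$b[!na]; cc <- ctx$c[!na]
    d <- ctx$d[!na]; e <- ctx$e[!na]; f <- ctx$f[!na]
    v[!na] <- ifelse(gg < a, -4,
              ifelse(gg < b, 0,
              ifelse(gg < cc, (gg - b) / (cc - b),
              ifelse(gg < d, 1,
              ifelse(gg < e, 1 - (gg - d) / (e - d),
              ifelse(gg < f, 0, -4))))))
  }
  fp <- sum(v * ctx$wpair) / 32
  fc <- sum(mu[!is.na(mu)]) / 32
  omegaP * fp + omegaC * fc
}

.combinationVectors <- function(P) {
  cx <- rep(NA_real_, 32)
  mu <- rep(NA_real_, 32)
  sel <- P@selected
  cx[sel$tooth] <- sel$cx
  mu[sel$tooth] <- sel$mu
  list(cx = cx, mu = mu)
}

#' Per-tooth positional score
#'
#' Averages [priorDelta()] over the tooth's same-jaw comparison set
#' Omega = \{x-2, x-1, x+1, x+2\} truncated at jaw boundaries (maxilla 1-16,
#' mandible 17-32): T1 compares only with \{2, 3\}, T20 with
#' \{18, 19, 21, 22\}.
#'
#' @param x tooth number 1..32.
#' @param P a [Combination-class].
#' @param width image width in pixels.
#' @inheritParams derivePriorParams
#' @return the mean pair score; `kappa` when tooth `x` is missing.
#' @export
fpTooth <- function(x, P, width, variant = "as_printed", kappa = 0,
                    mandibleCenterHalving = TRUE, molarEFactor = 1.5) {
  stopifnot(x >= 1, x <= 32)
  vec <- .combinationVectors(P)
  om <- .omegaOf(as.integer(x))
  if (!length(om)) return(0)
  scores <- vapply(om, function(y) {
    params <- derivePriorParams(width, x, y, variant, kappa,
                                mandibleCenterHalving, molarEFactor)
    g <- directedSeparation(x, y, vec$cx[x], vec$cx[y])  # NA at phi slots
    priorDelta(g, params)
  }, numeric(1))
  mean(scores)
}

#' Prior-knowledge objective of a combination
#'
#' `f(P) = omegaP * fp(P) + omegaC * fc(P)` where `fp(P)` is the mean of the
#' 32 per-tooth positional scores ([fpTooth()]) and `fc(P)` is the mean
#' confidence over the 32 slots with missing slots contributing 0 (declaring
#' a tooth missing costs confidence mass, counterbalancing the positional
#' penalties a bad candidate would incur).
#'
#' @param P a [Combination-class].
#' @param width image width in pixels.
#' @param omegaP,omegaC weights of the positional and confidence terms
#'   (defaults 0.8 and 0.2).
#' @inheritParams derivePriorParams
#' @return list with elements `objective`, `fp`, `fc`.
#' @export
objectiveScore <- function(P, width, omegaP = 0.8, omegaC = 0.2,
                           variant = "as_printed", kappa = 0,
                           mandibleCenterHalving = TRUE, molarEFactor = 1.5) {
  stopifnot(is(P, "Combination"), omegaP >= 0, omegaC >= 0)
  ctx <- .priorContext(width, variant, kappa, mandibleCenterHalving,
                       molarEFactor)
  vec <- .combinationVectors(P)
  fp <- .objectiveNum(vec$cx, vec$mu, ctx, 1, 0)
  fc <- .objectiveNum(vec$cx, vec$mu, ctx, 0, 1)
  list(objective = omegaP * fp + omegaC * fc, fp = fp, fc = fc)
}
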