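# Heuristic combinatorial search over the candidate table.

# Build the final Combination object from a choice vector (0 = phi).
.choiceToCombination <- function(slots, choice, renumbered = NULL) {
  rows <- vector("list", 32L)
  for (x in 1:32) {
    if (choice[x] > 0L) {
      row <- slots[[x]][choice[x], , drop = FALSE]
      rows[[x]] <- row
    }
  }
  if (!is.null(renumbered)) {
    for (x in names(renumbered)) rows[[as.integer(x)]] <- renumbered[[x]]
  }
  sel <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sel)) sel <- toothCandidates()
  rownames(sel) <- NULL
  combination(sel)
}

#' Select one candidate (or missing) per tooth by maximizing the objective
#'
#' Deterministic coordinate-ascent search over a [CandidateTable-class]:
#'
#' * Step 0: initialize each slot with its highest-confidence candidate
#'   (missing where the slot is empty) and score the combination.
#' * Steps 1-4: sweep teeth 1..32; for each tooth try every option in
#'   \{phi\} plus the slot's candidates, keeping any strict improvement of
#'   the objective.
#' * Step 5: repeat sweeps until a full sweep makes no update, at most
#'   `maxSweeps` times.
#' * Step 6: for every slot still missing despite having candidates, run an
#'   exhaustive joint (round-robin) search over that slot and its four
#'   same-jaw neighbours (Cartesian product of their option sets including
#'   phi), accepting the best strictly improving assignment. If the product
#'   exceeds `roundRobinBudget`, pairwise joint searches are used instead.
#' * Step 7 (optional isolation exception): when a chosen tooth is flanked
#'   by missing slots and exactly one tooth is present on each side of it in
#'   the jaw, the candidate may be renumbered one slot toward the spatially
#'   nearer flanking tooth, if that strictly improves the objective.
#'
#' The incumbent objective never decreases, the search is fully
#' deterministic, and the returned score is always at least the Step-0
#' initialization score.
#'
#' @param table a [CandidateTable-class].
#' @param omegaP,omegaC objective weights (defaults 0.8 / 0.2).
#' @param maxSweeps maximum number of full coordinate-ascent sweeps.
#' @param roundRobinBudget option-combination cap of the Step-6 joint search
#'   (default `5^5`).
#' @param enableRoundRobin,enableStep7 toggles for Steps 6 and 7.
#' @inheritParams derivePriorParams
#' @return list with `combination` (a [Combination-class]), `score`,
#'   `initScore` (Step-0 objective) and `sweeps` (sweeps actually run).
#' @export
optimizeCombination <- function(table, omegaP = 0.8, omegaC = 0.2,
                                variant = "as_printed", kappa = 0,
                                mandibleCenterHalving = TRUE,
                                molarEFactor = 1.5, maxSweeps = 10L,
                                roundRobinBudget = 5^5,
                                enableRoundRobin = TRUE,
                                enableStep7 = TRUE) {
  stopifnot(is(table, "CandidateTable"), maxSweeps >= 1L)
  width <- frameWidth(table@frame)
  ctx <- .priorContext(width, variant, kappa, mandibleCenterHalving,
                       molarEFactor)
  slots <- table@candidates
  N <- vapply(slots, nrow, integer(1))
  slotCx <- lapply(slots, function(df) df$cx)
  slotMu <- lapply(slots, function(df) df$mu)
  # a physical detection may fan out into several slots (prosthesis-derived
  # candidates); shared box ids keep it from being selected twice
  slotId <- lapply(seq_along(slots), function(x) {
    df <- slots[[x]]
    if ("boxId" %in% names(df)) as.character(df$boxId)
    else if (nrow(df)) paste0("s", x, "#", seq_len(nrow(df)))
    else character()
  })
  idOf <- function(x, k) if (k == 0L) NA_character_ else slotId[[x]][k]
  conflicts <- function(x, k, ids) {
    k != 0L && slotId[[x]][k] %in% ids[-x]
  }

  # Step 0: greedy initialization (skipping box-id clashes down the list)
  choice <- integer(32)
  usedId <- rep(NA_character_, 32)
  cx <- rep(NA_real_, 32)
  mu <- rep(NA_real_, 32)
  for (x in 1:32) {
    for (k in seq_len(N[x])) {
      if (!conflicts(x, k, usedId)) {
        choice[x] <- k
        usedId[x] <- idOf(x, k)
        cx[x] <- slotCx[[x]][k]
        mu[x] <- slotMu[[x]][k]
        break
      }
    }
  }
  best <- .objectiveNum(cx, mu, ctx, omegaP, omegaC)
  initScore <- best

  applyChoice <- function(x, k) {
    if (k == 0L) {
      cx[x] <<- NA_real_; mu[x] <<- NA_real_
    } else {
      cx[x] <<- slotCx[[x]][k]; mu[x] <<- slotMu[[x]][k]
    }
    choice[x] <<- k
    usedId[x] <<- idOf(x, k)
  }

  # Steps 1-5: coordinate-ascent sweeps
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    updated <- FALSE
    for (x in 1:32) {
      for (k in 0:N[x]) {
        if (k == choice[x]) next
        if (conflicts(x, k, usedId)) next
        tcx <- cx; tmu <- mu
        if (k == 0L) {
          tcx[x] <- NA_real_; tmu[x] <- NA_real_
        } else {
          tcx[x] <- slotCx[[x]][k]; tmu[x] <- slotMu[[x]][k]
        }
        s <- .objectiveNum(tcx, tmu, ctx, omegaP, omegaC)
        if (s > best) {
          best <- s
          applyChoice(x, k)
          updated <- TRUE
        }
      }
    }
    if (!updated || sweeps >= maxSweeps) break
  }

  # Step 6: round-robin search around remaining missing slots
  if (enableRoundRobin) {
    for (x in which(choice == 0L & N > 0L)) {
      group <- c(x, .omegaOf(x))
      sizes <- N[group] + 1L
      outsideIds <- usedId
      outsideIds[group] <- NA_character_
      if (prod(sizes) <= roundRobinBudget) {
        grid <- expand.grid(lapply(sizes, function(s) 0:(s - 1L)),
                            KEEP.OUT.ATTRS = FALSE)
        for (r in seq_len(nrow(grid))) {
          ks <- vapply(seq_along(group), function(j) grid[[j]][r], integer(1))
          ids <- vapply(seq_along(group), function(j) idOf(group[j], ks[j]),
                        character(1))
          nz <- ids[!is.na(ids)]
          if (anyDuplicated(nz) || any(nz %in% outsideIds)) next
          tcx <- cx; tmu <- mu
          for (j in seq_along(group)) {
            g <- group[j]; k <- ks[j]
            if (k == 0L) {
              tcx[g] <- NA_real_; tmu[g] <- NA_real_
            } else {
              tcx[g] <- slotCx[[g]][k]; tmu[g] <- slotMu[[g]][k]
            }
          }
          s <- .objectiveNum(tcx, tmu, ctx, omegaP, omegaC)
          if (s > best) {
            best <- s
            for (j in seq_along(group)) applyChoice(group[j], ks[j])
          }
        }
      } else {
        for (y in .omegaOf(x)) {
          for (kx in 0:N[x]) {
            for (ky in 0:N[y]) {
              idx <- idOf(x, kx); idy <- idOf(y, ky)
              pairIds <- c(idx, idy)
              pairIds <- pairIds[!is.na(pairIds)]
              other <- usedId
              other[c(x, y)] <- NA_character_
              if (anyDuplicated(pairIds) || any(pairIds %in% other)) next
              tcx <- cx; tmu <- mu
              if (kx == 0L) { tcx[x] <- NA; tmu[x] <- NA }
              else { tcx[x] <- slotCx[[x]][kx]; tmu[x] <- slotMu[[x]][kx] }
              if (ky == 0L) { tcx[y] <- NA; tmu[y] <- NA }
              else { tcx[y] <- slotCx[[y]][ky]; tmu[y] <- slotMu[[y]][ky] }
              s <- .objectiveNum(tcx, tmu, ctx, omegaP, omegaC)
              if (s > best) {
                best <- s
                applyChoice(x, kx)
                applyChoice(y, ky)
              }
            }
          }
        }
      }
    }
  }

  # Step 7: isolation exception (renumber an isolated tooth toward the
  # spatially nearer flanking tooth when that strictly improves the score)
  renumbered <- list()
  if (enableStep7) {
    for (x in 1:32) {
      if (choice[x] == 0L) next
      jaw <- .jawNumbers(x)
      if (!((x - 1L) %in% jaw && (x + 1L) %in% jaw)) next
      if (choice[x - 1L] != 0L || choice[x + 1L] != 0L) next
      leftNon <- jaw[jaw < x & choice[jaw] > 0L]
      rightNon <- jaw[jaw > x & choice[jaw] > 0L]
      if (length(leftNon) != 1L || length(rightNon) != 1L) next
      dl <- abs(cx[x] - cx[leftNon])
      dr <- abs(cx[x] - cx[rightNon])
      target <- if (dl <= dr) x - 1L else x + 1L
      if (choice[target] != 0L) next
      tcx <- cx; tmu <- mu
      tcx[target] <- cx[x]; tmu[target] <- mu[x]
      tcx[x] <- NA_real_; tmu[x] <- NA_real_
      s <- .objectiveNum(tcx, tmu, ctx, omegaP, omegaC)
      if (s > best) {
        best <- s
        row <- slots[[x]][choice[x], , drop = FALSE]
        row$tooth <- target
        renumbered[[as.character(target)]] <- row
        applyChoice(x, 0L)
        cx[target] <- row$cx; mu[target] <- row$mu
      }
    }
  }

  list(combination = .choiceToCombination(slots, choice, renumbered),
       score = best, initScore = initScore, sweeps = sweeps)
}

#' Exact reference optimum by exhaustive enumeration
#'
#' Enumerates the full Cartesian product of option sets (phi plus every
#' candidate) over the `freeSlots` while holding every other non-empty slot
#' fixed at its head candidate, and returns the best objective found. This is
#' a brute-force oracle for small instances -- it shares no search logic with
#' [optimizeCombination()] -- and is intended for validating the heuristic on
#' instances with few multi-candidate slots.
#'
#' @param table a [CandidateTable-class].
#' @param freeSlots slots to enumerate exhaustively; defaults to every slot
#'   with two or more candidates.
#' @inheritParams optimizeCombination
#' @return list with `score` (the exact maximum over the enumerated space)
#'   and `combination`.
#' @export
exhaustiveOptimum <- function(table, freeSlots = NULL, omegaP = 0.8,
                              omegaC = 0.2, variant = "as_printed",
                              kappa = 0, mandibleCenterHalving = TRUE,
                              molarEFactor = 1.5) {
  stopifnot(is(table, "CandidateTable"))
  width <- frameWidth(table@frame)
  ctx <- .priorContext(width, variant, kappa, mandibleCenterHalving,
                       molarEFactor)
  slots <- table@candidates
  N <- vapply(slots, nrow, integer(1))
  if (is.null(freeSlots)) freeSlots <- which(N >= 2L)
  freeSlots <- as.integer(freeSlots)

  base <- ifelse(N > 0L, 1L, 0L)
  cx0 <- rep(NA_real_, 32); mu0 <- rep(NA_real_, 32)
  for (x in which(base > 0L)) {
    cx0[x] <- slots[[x]]$cx[1L]
    mu0[x] <- slots[[x]]$mu[1L]
  }

  if (!length(freeSlots)) {
    return(list(score = .objectiveNum(cx0, mu0, ctx, omegaP, omegaC),
                combination = .choiceToCombination(slots, base)))
  }
  grid <- expand.grid(lapply(freeSlots, function(x) 0:N[x]),
                      KEEP.OUT.ATTRS = FALSE)
  bestScore <- -Inf
  bestChoice <- base
  for (r in seq_len(nrow(grid))) {
    cx <- cx0; mu <- mu0; ch <- base
    for (j in seq_along(freeSlots)) {
      x <- freeSlots[j]; k <- grid[[j]][r]
      ch[x] <- k
      if (k == 0L) {
        cx[x] <- NA_real_; mu[x] <- NA_real_
      } else {
        cx[x] <- slots[[x]]$cx[k]; mu[x] <- slots[[x]]$mu[k]
      }
    }
    s <- .objectiveNum(cx, mu, ctx, omegaP, omegaC)
    if (s > bestScore) {
      bestScore <- s
      bestChoice <- ch
    }
  }
  list(score = bestScore,
       combination = .choiceToCombination(slots, bestChoice))
}
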