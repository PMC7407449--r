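# Two-point linkage mapping: parental/recombinant classification, the
# RF = 100 R/(P+R) statistic with exact CIs, replicate pooling and locus
# placement on the cM map.

#' Infer the lethal-locus state of a tested male
#'
#' A scored F3 male is crossed to lethal/balancer females; if his tested
#' chromosome carries the lethal, the non-balancer progeny class that would
#' combine it with the maternal lethal dies. The call is \code{"l"} when
#' zero such non-balancer adults emerge from an adequately sized cross,
#' \code{"l+"} when any emerge, and \code{"unknown"} when the cross is too
#' small to trust an absence.
#'
#' @param nonBalancerAdults Count of surviving diagnostic non-balancer
#'   adults (vectorized).
#' @param totalScored Total adults scored in the testcross.
#' @param minTotal Minimum \code{totalScored} for a confident \code{"l"}
#'   call.
#' @return Character vector in \code{c("l", "l+", "unknown")}.
#' @examples
#' inferLStatus(0, 40)   # "l"
#' inferLStatus(12, 40)  # "l+"
#' inferLStatus(0, 5)    # "unknown"
#' @export
inferLStatus <- function(nonBalancerAdults, totalScored, minTotal = 20) {
  if (any(nonBalancerAdults < 0) || any(totalScored < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(nonBalancerAdults > totalScored))
    stop("nonBalancerAdults cannot exceed totalScored", call. = FALSE)
  ifelse(nonBalancerAdults > 0, "l+",
         ifelse(totalScored >= minTotal, "l", "unknown"))
}

#' Tally parental and recombinant chromosomes for marker--locus pairs
#'
#' In the repulsion-phase cross the lethal and the visible recessives enter
#' on opposite homologs, so a chromosome is parental for a marker when it is
#' wild type at the marker and carries the lethal, or mutant at the marker
#' and lethal-free; the two exchanged combinations are recombinant. Males
#' whose locus state is \code{"unknown"} are excluded from the tally and
#' reported via the \code{"excluded"} attribute.
#'
#' @param males \code{data.frame} of scored males: one \code{"mut"}/
#'   \code{"wt"} column per marker plus \code{locus_state}
#'   (\code{"l"}/\code{"l+"}/\code{"unknown"}), as produced by
#'   [simulateMappingExperiment()] or [readScoredMales()].
#' @param marker Marker name(s) to tally; default every marker column.
#' @return \code{data.frame} with columns \code{marker, parental,
#'   recombinant}; the number of unknown-state males excluded is attached
#'   as attribute \code{"excluded"}.
#' @export
classifyPair <- function(males, marker = NULL) {
  stopifnot(is.data.frame(males), "locus_state" %in% names(males))
  markerCols <- setdiff(names(males), "locus_state")
  if (is.null(marker)) marker <- markerCols
  missing <- setdiff(marker, markerCols)
  if (length(missing))
    stop(sprintf("marker(s) not in table: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  known <- males$locus_state != "unknown"
  hasL <- males$locus_state == "l"
  rows <- lapply(marker, function(m) {
    mut <- males[[m]] == "mut"
    parental <- sum(known & ((!mut & hasL) | (mut & !hasL)))
    recombinant <- sum(known & ((!mut & !hasL) | (mut & hasL)))
    data.frame(marker = m, parental = parental, recombinant = recombinant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- sum(!known)
  out
}

#' Recombination-frequency estimate with exact confidence interval
#'
#' RF = 100 R / (P + R), the percentage of recombinant chromosomes among
#' classified chromosomes, with a Clopper--Pearson exact binomial interval
#' (chosen because recombinant counts near a tightly linked marker are
#' tiny). RF in percent reads directly as map distance in cM for small
#' values.
#'
#' @param counts \code{data.frame} with columns \code{marker, parental,
#'   recombinant} (e.g. from [classifyPair()], [poolCounts()] or
#'   [readPairCounts()]).
#' @param ciLevel Confidence level, default 0.95.
#' @return \code{data.frame} with columns \code{marker, parental,
#'   recombinant, n, rf, ci_low, ci_high} (percent scale).
#' @examples
#' estimateRF(data.frame(marker = "ru", parental = 62, recombinant = 51))
#' @export
estimateRF <- function(counts, ciLevel = 0.95) {
  stopifnot(is.data.frame(counts),
            all(c("marker", "parental", "recombinant") %in% names(counts)))
  if (any(counts$parental < 0) || any(counts$recombinant < 0))
    stop("counts must be non-negative", call. = FALSE)
  n <- counts$parental + counts$recombinant
  if (any(n == 0))
    stop("RF undefined: parental + recombinant is zero for marker(s) ",
         paste(counts$marker[n == 0], collapse = ", "), call. = FALSE)
  ci <- t(mapply(.clopperPearson, counts$recombinant, n, ciLevel))
  data.frame(marker = counts$marker,
             parental = counts$parental,
             recombinant = counts$recombinant,
             n = n,
             rf = 100 * counts$recombinant / n,
             ci_low = 100 * ci[, "low"],
             ci_high = 100 * ci[, "high"],
             stringsAsFactors = FALSE)
}

#' Pool replicate pair counts
#'
#' Component-wise sum of parental and recombinant counts over replicate
#' rows of the same marker--locus pair; pooling then estimating RF is
#' equivalent to estimating on the concatenated male table.
#'
#' @param counts \code{data.frame} with columns \code{marker, parental,
#'   recombinant} (a \code{replicate} column, if present, is collapsed).
#' @param marker Optional single marker to pool; an error if absent from
#'   \code{counts}.
#' @return \code{data.frame} with one row per marker.
#' @export
poolCounts <- function(counts, marker = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("marker", "parental", "recombinant") %in% names(counts)))
  if (!is.null(marker)) {
    if (!all(marker %in% counts$marker))
      stop(sprintf("marker(s) not present: %s",
                   paste(setdiff(marker, counts$marker), collapse = ", ")),
           call. = FALSE)
    counts <- counts[counts$marker %in% marker, , drop = FALSE]
  }
  out <- aggregate(cbind(parental, recombinant) ~ marker, data = counts, sum)
  out[order(match(out$marker, unique(counts$marker))), , drop = FALSE]
}

#' Place the lethal locus on the cM map
#'
#' \strong{flank_subtraction} (the classical arithmetic): the anchor is the
#' marker with the smallest RF (ties broken toward the larger sample,
#' recorded in the result). The side of the anchor is the one whose implied
#' positions \code{pos(m) - rf(m)} (left) or \code{pos(m) + rf(m)} (right)
#' over the informative markers are most mutually consistent (smallest sum
#' of squared deviations from their mean). The interval bounds are the
#' min and max implied positions over the informative set. By default the
#' informative set is the two smallest-RF markers; when the anchor's RF is
#' exactly 0 its side is ambiguous, so the anchor is excluded and the next
#' two markers are used. RF percent is read directly as cM (identity map
#' function), matching the classical arithmetic; apply a map-function
#' correction to \code{rf} beforehand if desired.
#'
#' \strong{least_squares}: single point estimate minimizing
#' \code{sum((rf - |pos - x|)^2)} over a 0.01 cM grid, with a bootstrap
#' percentile interval over markers.
#'
#' @param estimates \code{data.frame} with columns \code{marker, rf} (and
#'   optionally \code{n}, used for tie-breaks and reported in results).
#' @param map A [MarkerMap-class] giving marker positions.
#' @param method \code{"flank_subtraction"} (default) or
#'   \code{"least_squares"}.
#' @param informative Optional character vector overriding the informative
#'   marker set.
#' @param side Optional \code{"left"}/\code{"right"} override.
#' @param bootstrap Bootstrap replicates for the least-squares interval.
#' @param seed Seed for the bootstrap.
#' @return A [PlacementResult-class].
#' @examples
#' est <- data.frame(marker = c("st", "cu"), rf = c(1.23, 8.29))
#' placeLocus(est, rucucaMap())   # bounds [41.71, 42.77], left of thread
#' @export
placeLocus <- function(estimates, map, method = c("flank_subtraction",
                                                  "least_squares"),
                       informative = NULL, side = NULL, bootstrap = 200,
                       seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(estimates),
            all(c("marker", "rf") %in% names(estimates)),
            is(map, "MarkerMap"))
  pos <- markerPositions(map)
  if (!all(estimates$marker %in% names(pos)))
    stop("estimates include markers absent from the map", call. = FALSE)
  if (nrow(estimates) < 2)
    stop("placement needs at least 2 markers with estimates", call. = FALSE)
  est <- estimates
  est$pos <- pos[est$marker]
  maxBound <- max(pos) + 10
  if (method == "least_squares") {
    if (!is.null(informative)) {
      if (!all(informative %in% est$marker))
        stop("informative markers lack estimates", call. = FALSE)
      est <- est[est$marker %in% informative, , drop = FALSE]
      if (nrow(est) < 2)
        stop("fewer than 2 informative markers", call. = FALSE)
    }
    return(.placeLeastSquares(est, maxBound, bootstrap, seed))
  }

  note <- character(0)
  minRf <- min(est$rf)
  cand <- which(est$rf == minRf)
  if (length(cand) > 1) {
    if ("n" %in% names(est)) {
      cand <- cand[order(-est$n[cand])]
      note <- c(note, sprintf("RF tie broken toward larger n (%s)",
                              est$marker[cand[1]]))
    } else {
      note <- c(note, sprintf("RF tie broken by map order (%s)",
                              est$marker[cand[1]]))
    }
  }
  anchorIdx <- cand[1]
  anchor <- est$marker[anchorIdx]
  if (is.null(informative)) {
    ord <- order(est$rf, -if ("n" %in% names(est)) est$n else rep(0, nrow(est)))
    if (est$rf[anchorIdx] == 0) {
      ord <- setdiff(ord, anchorIdx)
      note <- c(note, "anchor RF is 0 (side ambiguous): anchor excluded from bounds")
    }
    if (length(ord) < 2)
      stop("fewer than 2 informative markers", call. = FALSE)
    informative <- est$marker[ord[seq_len(2)]]
  } else {
    if (!all(informative %in% est$marker))
      stop("informative markers lack estimates", call. = FALSE)
    if (length(informative) < 2)
      stop("fewer than 2 informative markers", call. = FALSE)
  }
  inf <- est[match(informative, est$marker), , drop = FALSE]
  impliedLeft <- inf$pos - inf$rf
  impliedRight <- inf$pos + inf$rf
  if (is.null(side)) {
    ssr <- function(x) sum((x - mean(x))^2)
    side <- if (ssr(impliedLeft) <= ssr(impliedRight)) "left" else "right"
  }
  implied <- if (side == "left") impliedLeft else impliedRight
  low <- max(0, min(implied))
  high <- min(maxBound, max(implied))
  new("PlacementResult", side = side, low = low, high = high,
      method = "flank_subtraction", anchor = anchor,
      informative = informative, point = (low + high) / 2,
      note = if (length(note)) paste(note, collapse = "; ") else "")
}

.placeLeastSquares <- function(est, maxBound, bootstrap, seed) {
  grid <- seq(0, maxBound, by = 0.01)
  # residual matrix: rows = markers, cols = grid points
  resid <- (est$rf - abs(outer(est$pos, grid, "-")))^2
  point <- grid[which.min(colSums(resid))]
  lo <- hi <- point
  if (nrow(est) >= 3 && bootstrap > 0) {
    pts <- .withSeed(seed, vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(nrow(est), replace = TRUE)
      grid[which.min(colSums(resid[idx, , drop = FALSE]))]
    }, numeric(1)))
    qs <- quantile(pts, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  anchor <- est$marker[which.min(est$rf)]
  side <- if (point <= est$pos[match(anchor, est$marker)]) "left" else "right"
  new("PlacementResult", side = side, low = lo, high = hi,
      method = "least_squares", anchor = anchor,
      informative = est$marker, point = point,
      note = if (nrow(est) < 3) "too few markers for a bootstrap interval" else "")
}

setMethod("show", "PlacementResult", function(object) {
  cat(sprintf("PlacementResult (%s): %s of anchor '%s'\n", object@method,
              object@side, object@anchor))
  cat(sprintf("  bounds [%.2f, %.2f] cM; point %.2f cM\n", object@low,
              object@high, object@point))
  cat("  informative markers:", paste(object@informative, collapse = ", "), "\n")
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Placement accessors
#' @param x A [PlacementResult-class].
#' @return \code{placementBounds}: numeric \code{c(low, high)} in cM;
#'   \code{placementSide}: \code{"left"} or \code{"right"}.
#' @export
placementBounds <- function(x) {
  stopifnot(is(x, "PlacementResult"))
  c(low = x@low, high = x@high)
}

#' @describeIn placementBounds Side of the anchor marker.
#' @export
placementSide <- function(x) {
  stopifnot(is(x, "PlacementResult"))
  x@side
}

#' Display an RF value with truncation
#'
#' Published RF tables truncate rather than round (8/113 prints as 7.07,
#' 34/113 as 30.08); this reproduces that display convention.
#'
#' @param rf RF percent in [0, 100] (vectorized).
#' @param decimals Digits kept after the decimal point.
#' @return Character vector.
#' @examples
#' formatRF(100 * 8 / 113)   # "7.07"
#' @export
formatRF <- function(rf, decimals = 2) {
  if (any(rf < 0 | rf > 100)) stop("rf must be in [0, 100]", call. = FALSE)
  f <- 10^decimals
  trunc_ <- floor(rf * f + 1e-9) / f
  sprintf(paste0("%.", decimals, "f"), trunc_)
}

#' Read a scored-male table from TSV
#'
#' One row per male; marker columns hold \code{mut}/\code{wt} and the
#' \code{locus_state} column holds \code{l}, \code{l+} or \code{unknown}.
#' Lines starting with \code{#} are comments.
#'
#' @param file Path to the TSV.
#' @return \code{data.frame} as consumed by [classifyPair()].
#' @export
readScoredMales <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!("locus_state" %in% names(df)))
    stop("scored-male file needs a locus_state column", call. = FALSE)
  bad <- setdiff(unique(df$locus_state), c("l", "l+", "unknown"))
  if (length(bad))
    stop(sprintf("invalid locus_state value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  df
}

#' Read a pair-count table from TSV
#'
#' Columns \code{marker, parental, recombinant} and optionally
#' \code{replicate}.
#'
#' @param file Path to the TSV.
#' @return \code{data.frame}.
#' @export
readPairCounts <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker", "parental", "recombinant")
  if (!all(need %in% names(df)))
    stop(sprintf("pair-count file needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}
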