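# Polytene band parsing, ordering and lattice arithmetic.

.inferArm <- function(division) {
  for (arm in names(.ARM_DIVISIONS)) {
    rng <- .ARM_DIVISIONS[[arm]]
    if (division >= rng[1] && division <= rng[2]) return(arm)
  }
  stop(sprintf("division %d matches no chromosome arm; supply an arm",
               division), call. = FALSE)
}

#' Parse a polytene band string
#'
#' Accepts bare forms like \code{"71F4"} or \code{"72A"} and arm-qualified
#' forms like \code{"3L:71F4"}. When no arm is given it is taken from the
#' \code{arm} argument, or inferred from the division number via the
#' standard division-to-arm assignment (61--80 is 3L, etc.).
#'
#' @param text Band string.
#' @param arm Optional arm label supplying context for bare forms.
#' @return A [CytoBand-class] object.
#' @examples
#' parseCytoband("72A1")            # 3L inferred from division 72
#' parseCytoband("71F4", arm = "3L")
#' @export
parseCytoband <- function(text, arm = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^(?:(X|2L|2R|3L|3R|4)[: ])?([0-9]+)([A-F])([0-9]+)?$", text))[[1]]
  if (length(m) == 0)
    stop(sprintf("malformed band string '%s'", text), call. = FALSE)
  armTok <- m[2]
  division <- as.integer(m[3])
  letter <- m[4]
  subband <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  if (nzchar(armTok)) arm <- armTok
  if (is.null(arm)) arm <- .inferArm(division)
  new("CytoBand", arm = arm, division = division, letter = letter,
      subband = subband)
}

#' Format a polytene band
#'
#' Round-trips with [parseCytoband()]: \code{formatCytoband(parseCytoband(x))}
#' equals \code{x} for any well-formed bare band string.
#'
#' @param band A [CytoBand-class].
#' @param withArm Prefix the arm as \code{"3L:71F4"}?
#' @return Character band string.
#' @export
formatCytoband <- function(band, withArm = FALSE) {
  stopifnot(is(band, "CytoBand"))
  core <- paste0(band@division, band@letter,
                 if (!is.na(band@subband)) band@subband else "")
  if (withArm) paste0(band@arm, ":", core) else core
}

setMethod("show", "CytoBand", function(object) {
  cat("CytoBand ", formatCytoband(object, withArm = TRUE), "\n", sep = "")
})

#' Compare two polytene bands
#'
#' Total order within an arm by (division, letter, sub-band); a missing
#' sub-band sorts before sub-band 1. Bands on different arms are
#' incomparable.
#'
#' @param a,b [CytoBand-class] objects on the same arm.
#' @return -1, 0 or 1 as \code{a} sorts before, with, or after \code{b}.
#' @export
compareCytobands <- function(a, b) {
  stopifnot(is(a, "CytoBand"), is(b, "CytoBand"))
  if (a@arm != b@arm)
    stop(sprintf("bands %s and %s lie on different arms and are incomparable",
                 formatCytoband(a, TRUE), formatCytoband(b, TRUE)),
         call. = FALSE)
  ka <- c(a@division, match(a@letter, LETTERS),
          if (is.na(a@subband)) 0L else a@subband)
  kb <- c(b@division, match(b@letter, LETTERS),
          if (is.na(b@subband)) 0L else b@subband)
  d <- ka - kb
  nz <- which(d != 0)
  if (length(nz) == 0) 0L else as.integer(sign(d[nz[1]]))
}

#' Sort a list of bands on one arm
#'
#' @param bands List of [CytoBand-class] objects, all on one arm.
#' @return The list sorted ascending under band order.
#' @export
sortCytobands <- function(bands) {
  stopifnot(length(bands) >= 1)
  key <- vapply(bands, function(b) {
    (b@division * 7L + match(b@letter, LETTERS)) * 1000 +
      (if (is.na(b@subband)) 0L else b@subband)
  }, numeric(1))
  arms <- vapply(bands, function(b) b@arm, character(1))
  if (length(unique(arms)) > 1)
    stop("cannot sort bands from different arms", call. = FALSE)
  bands[order(key)]
}

#' Parse a band interval string
#'
#' Accepts \code{"71F1-72A1"}, the abbreviated \code{"71F4-F5"} (the second
#' endpoint inherits the division), \code{"71F4..71F5"}, or a single band
#' (degenerate interval).
#'
#' @param text Interval string.
#' @param arm Optional arm context.
#' @return A [CytoInterval-class].
#' @export
parseCytoInterval <- function(text, arm = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "\\.\\.|-")[[1]]
  if (length(parts) == 1) {
    b <- parseCytoband(parts[1], arm = arm)
    return(new("CytoInterval", start = b, end = b))
  }
  if (length(parts) != 2)
    stop(sprintf("malformed band interval '%s'", text), call. = FALSE)
  startBand <- parseCytoband(parts[1], arm = arm)
  endTxt <- parts[2]
  if (grepl("^[A-F][0-9]*$", endTxt))   # "F5" inherits the division
    endTxt <- paste0(startBand@division, endTxt)
  endBand <- parseCytoband(endTxt, arm = startBand@arm)
  new("CytoInterval", start = startBand, end = endBand)
}

#' Format a band interval
#' @param x A [CytoInterval-class].
#' @param withArm Prefix the arm?
#' @return Character such as \code{"71F4-71F5"} (or a single band when
#'   degenerate).
#' @export
formatCytoInterval <- function(x, withArm = FALSE) {
  stopifnot(is(x, "CytoInterval"))
  if (compareCytobands(x@start, x@end) == 0) return(formatCytoband(x@start, withArm))
  paste0(formatCytoband(x@start, withArm), "-", formatCytoband(x@end))
}

setMethod("show", "CytoInterval", function(object) {
  cat("CytoInterval ", object@start@arm, ":",
      formatCytoInterval(object), "\n", sep = "")
})

# ---- band lattice ----------------------------------------------------------
# The discretization substrate for complementation logic: every (division,
# letter, sub-band 1..maxSubband) position on an arm maps to one integer.

.latticeIndex <- function(band, maxSubband, role = c("point", "start", "end")) {
  role <- match.arg(role)
  sub <- band@subband
  if (is.na(sub))
    sub <- switch(role, point = 1L, start = 1L, end = as.integer(maxSubband))
  if (sub > maxSubband)
    stop(sprintf("subband %d of %s exceeds lattice maxSubband %d", sub,
                 formatCytoband(band, TRUE), maxSubband), call. = FALSE)
  divMin <- .ARM_DIVISIONS[[band@arm]][1]
  ((band@division - divMin) * 6L + (match(band@letter, LETTERS) - 1L)) *
    as.integer(maxSubband) + sub
}

.latticeBand <- function(idx, arm, maxSubband) {
  divMin <- .ARM_DIVISIONS[[arm]][1]
  idx0 <- idx - 1L
  sub <- idx0 %% maxSubband + 1L
  rest <- idx0 %/% maxSubband
  letter <- LETTERS[rest %% 6L + 1L]
  division <- as.integer(rest %/% 6L + divMin)
  new("CytoBand", arm = arm, division = division, letter = letter,
      subband = as.integer(sub))
}

.latticeRange <- function(interval, maxSubband) {
  c(.latticeIndex(interval@start, maxSubband, "start"),
    .latticeIndex(interval@end, maxSubband, "end"))
}

#' Does a band interval contain a band?
#'
#' Containment on the band lattice; endpoints without sub-bands span the
#' whole letter.
#'
#' @param interval A [CytoInterval-class].
#' @param band A [CytoBand-class] on the same arm.
#' @param maxSubband Lattice sub-band count per letter.
#' @return Logical.
#' @export
cytoContains <- function(interval, band, maxSubband = 20L) {
  stopifnot(is(interval, "CytoInterval"), is(band, "CytoBand"))
  if (interval@start@arm != band@arm) return(FALSE)
  rng <- .latticeRange(interval, maxSubband)
  idx <- .latticeIndex(band, maxSubband, "point")
  idx >= rng[1] && idx <= rng[2]
}
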