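# S4 classes shared across the mapping stages.

#' CytoBand: a polytene chromosome band
#'
#' A position in Drosophila polytene band nomenclature: chromosome arm,
#' numbered division, letter (A--F) and optional positive sub-band, e.g.
#' \code{3L:71F4}. Within an arm, bands are totally ordered by
#' (division, letter, sub-band); a missing sub-band sorts before sub-band 1.
#'
#' @slot arm Arm label, one of \code{X, 2L, 2R, 3L, 3R, 4}.
#' @slot division Integer division number (the standard map assigns
#'   divisions 1--20 to X, 21--40 to 2L, 41--60 to 2R, 61--80 to 3L,
#'   81--100 to 3R and 101--102 to chromosome 4).
#' @slot letter Band letter, \code{"A"}--\code{"F"}.
#' @slot subband Integer sub-band (>= 1) or \code{NA} when unresolved.
#'
#' @seealso [parseCytoband()], [formatCytoband()], [compareCytobands()]
#' @export
setClass("CytoBand",
  representation(arm = "character", division = "integer",
                 letter = "character", subband = "integer"))

.ARM_DIVISIONS <- list(
  "X"  = c(1L, 20L),
  "2L" = c(21L, 40L),
  "2R" = c(41L, 60L),
  "3L" = c(61L, 80L),
  "3R" = c(81L, 100L),
  "4"  = c(101L, 102L))

setValidity("CytoBand", function(object) {
  msg <- character()
  if (!(object@arm %in% names(.ARM_DIVISIONS)))
    msg <- c(msg, sprintf("unknown arm '%s'", object@arm))
  if (!(object@letter %in% LETTERS[1:6]))
    msg <- c(msg, sprintf("band letter '%s' not in A-F", object@letter))
  if (object@arm %in% names(.ARM_DIVISIONS)) {
    rng <- .ARM_DIVISIONS[[object@arm]]
    if (object@division < rng[1] || object@division > rng[2])
      msg <- c(msg, sprintf("division %d outside arm %s (%d-%d)",
                            object@division, object@arm, rng[1], rng[2]))
  }
  if (!is.na(object@subband) && object@subband < 1L)
    msg <- c(msg, "subband must be >= 1 or NA")
  if (length(msg)) msg else TRUE
})

#' CytoInterval: a contiguous span of polytene bands
#'
#' A deleted or candidate interval, e.g. the extent of a deficiency, given
#' by its first and last band on one arm.
#'
#' @slot start,end [CytoBand-class] endpoints on the same arm with
#'   \code{start <= end} under band order. Endpoints without a sub-band are
#'   interpreted as spanning that letter's whole sub-band range.
#'
#' @seealso [parseCytoInterval()], [solveRegion()]
#' @export
setClass("CytoInterval",
  representation(start = "CytoBand", end = "CytoBand"))

setValidity("CytoInterval", function(object) {
  if (object@start@arm != object@end@arm)
    return("start and end bands lie on different arms")
  if (compareCytobands(object@start, object@end) > 0)
    return("start band sorts after end band")
  TRUE
})

#' GenomicInterval: a 1-based inclusive genomic span
#'
#' Sequence coordinates in the \code{contig:start..end} convention used for
#' PCR amplicons, with both endpoints included, so the length of
#' \code{3L:15826279..15827223} is 945 bp.
#'
#' @slot contig Contig/arm label, e.g. \code{"3L"}.
#' @slot start,end 1-based inclusive coordinates, \code{start <= end}.
#'
#' @seealso [parseGenomicInterval()], [intervalLength()]
#' @export
setClass("GenomicInterval",
  representation(contig = "character", start = "numeric", end = "numeric"))

setValidity("GenomicInterval", function(object) {
  msg <- character()
  if (object@start < 1 || object@end < 1)
    msg <- c(msg, "coordinates are 1-based and must be >= 1")
  if (object@start != round(object@start) || object@end != round(object@end))
    msg <- c(msg, "coordinates must be whole numbers")
  if (object@start > object@end)
    msg <- c(msg, "start must not exceed end")
  if (length(msg)) msg else TRUE
})

#' MarkerMap: ordered visible markers on one chromosome
#'
#' The genetic map the cross is scored against: marker symbols with
#' centiMorgan positions (strictly increasing) and polytene bands.
#'
#' @slot chromosome Chromosome label, e.g. \code{"3"}.
#' @slot markers \code{data.frame} with columns \code{name} (unique symbol),
#'   \code{cm} (non-negative map position), \code{band} (band string) and
#'   \code{recessive} (logical; visible recessive phenotype).
#'
#' @seealso [MarkerMap()], [rucucaMap()], [readMarkerMap()]
#' @export
setClass("MarkerMap",
  representation(chromosome = "character", markers = "data.frame"))

setValidity("MarkerMap", function(object) {
  m <- object@markers
  msg <- character()
  need <- c("name", "cm", "band", "recessive")
  if (!all(need %in% names(m)))
    return(sprintf("markers must have columns %s", paste(need, collapse = ", ")))
  if (nrow(m) < 2) msg <- c(msg, "a map needs at least 2 markers")
  if (anyDuplicated(m$name)) msg <- c(msg, "marker names must be unique")
  if (any(m$cm < 0)) msg <- c(msg, "cM positions must be non-negative")
  if (nrow(m) >= 2 && any(diff(m$cm) <= 0))
    msg <- c(msg, "markers must be sorted by strictly increasing cM")
  if (length(msg)) msg else TRUE
})

#' CrossoverModel: the meiotic crossover process of the simulator
#'
#' Governs how recombinant gametes are generated in female meiosis.
#'
#' @slot kind \code{"haldane"} (independent recombination across marker
#'   intervals, probabilities from the map function), \code{"fixed_count"}
#'   (exactly \code{param} crossovers placed uniformly) or
#'   \code{"gamma_interference"} (stationary gamma renewal process with
#'   shape \code{param}; shape 1 recovers the no-interference case).
#' @slot param Non-negative model parameter (rate multiplier, crossover
#'   count, or gamma shape; see \code{kind}).
#' @slot mapFunction Distance-to-recombination conversion:
#'   \code{"haldane"}, \code{"kosambi"} or \code{"identity"} (RF = cM/100,
#'   capped at 0.5). Used by the \code{"haldane"} kind.
#'
#' @seealso [crossoverModel()], [simulateGametes()]
#' @export
setClass("CrossoverModel",
  representation(kind = "character", param = "numeric",
                 mapFunction = "character"))

setValidity("CrossoverModel", function(object) {
  msg <- character()
  if (!(object@kind %in% c("haldane", "fixed_count", "gamma_interference")))
    msg <- c(msg, sprintf("unknown model kind '%s'", object@kind))
  if (!(object@mapFunction %in% c("haldane", "kosambi", "identity")))
    msg <- c(msg, sprintf("unknown map function '%s'", object@mapFunction))
  if (object@param < 0) msg <- c(msg, "model parameter must be non-negative")
  if (object@kind == "gamma_interference" && object@param <= 0)
    msg <- c(msg, "gamma shape must be positive")
  if (length(msg)) msg else TRUE
})

#' PlacementResult: where the lethal locus sits on the cM map
#'
#' @slot side \code{"left"} or \code{"right"} of the anchor marker.
#' @slot low,high Interval bounds in cM, \code{low <= high}.
#' @slot method \code{"flank_subtraction"} or \code{"least_squares"}.
#' @slot anchor Name of the anchor marker (smallest RF).
#' @slot informative Marker names whose implied positions define the bounds.
#' @slot point Point estimate in cM (least squares; mid-interval otherwise).
#' @slot note Free-text notes, e.g. tie-breaks applied.
#'
#' @seealso [placeLocus()]
#' @export
setClass("PlacementResult",
  representation(side = "character", low = "numeric", high = "numeric",
                 method = "character", anchor = "character",
                 informative = "character", point = "numeric",
                 note = "character"))

setValidity("PlacementResult", function(object) {
  if (object@low > object@high) return("low bound exceeds high bound")
  TRUE
})

#' CandidateRegion: solved complementation interval
#'
#' Result of intersecting failing deficiencies and excluding complementing
#' ones on the band lattice. When the exclusion splits the region, all
#' fragments are kept, ranked by width (widest first); the first fragment is
#' the primary candidate.
#'
#' @slot intervals List of [CytoInterval-class] fragments, widest first.
#' @slot supporting Ids of deficiencies that failed to complement.
#' @slot excluding Ids of complementing deficiencies.
#' @slot arm Arm label.
#' @slot maxSubband Sub-band count per letter used for the lattice.
#'
#' @seealso [solveRegion()], [checkAllelism()]
#' @export
setClass("CandidateRegion",
  representation(intervals = "list", supporting = "character",
                 excluding = "character", arm = "character",
                 maxSubband = "integer"))

setValidity("CandidateRegion", function(object) {
  if (length(object@intervals) < 1) return("region must be non-empty")
  if (!all(vapply(object@intervals, is, logical(1), class2 = "CytoInterval")))
    return("intervals must be CytoInterval objects")
  TRUE
})

setClassUnion("GenomicIntervalOrNULL", c("GenomicInterval", "NULL"))

#' LesionScan: outcome of a tiling-PCR lesion search
#'
#' @slot status \code{"lesion"} (one contiguous candidate),
#'   \code{"multi"} (anomalous amplicons in disjoint clusters) or
#'   \code{"no_lesion"} (every amplicon wild type).
#' @slot span Minimal [GenomicInterval-class] containing all candidate
#'   bases, or \code{NULL} when no lesion.
#' @slot clusters \code{data.frame} with \code{start}, \code{end} of each
#'   disjoint candidate cluster (empty when no lesion).
#' @slot anomalous Ids of the failed or size-shifted amplicons.
#'
#' @seealso [findLesionInterval()]
#' @export
setClass("LesionScan",
  representation(status = "character", span = "GenomicIntervalOrNULL",
                 clusters = "data.frame", anomalous = "character"))
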