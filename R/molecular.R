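# Fine-mapping inference from tiling-PCR panels and densitometry.

#' Locate a lesion from a tiling-PCR amplicon panel
#'
#' An amplicon is anomalous when it failed to amplify or amplified at a
#' size differing from its wild-type coordinates by more than
#' \code{sizeTol} (both regimes occur in practice: outright failure under
#' standard extension, a shifted large product under long-range
#' conditions). The candidate lesion interval is the union of anomalous
#' amplicon intervals minus every base covered by an amplicon that
#' amplified at wild-type size, reported as the minimal interval containing
#' the remaining bases. Disjoint anomalous clusters trigger a multi-lesion
#' warning and are all reported.
#'
#' @param panel \code{data.frame} with columns \code{id, contig, start,
#'   end, outcome, observed_size} (\code{observed_size} may be \code{NA}
#'   for failed amplicons); see [simulateTilingPCR()] and
#'   [readAmpliconPanel()].
#' @param sizeTol Relative size-shift tolerance (default 0.10) beyond
#'   which an amplified product counts as anomalous.
#' @return A [LesionScan-class]; status \code{"no_lesion"} when every
#'   amplicon is wild type.
#' @export
findLesionInterval <- function(panel, sizeTol = 0.10) {
  need <- c("id", "contig", "start", "end", "outcome", "observed_size")
  if (!all(need %in% names(panel)))
    stop(sprintf("amplicon panel needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  contig <- unique(panel$contig)
  if (length(contig) != 1)
    stop("amplicons must tile a single contig", call. = FALSE)
  bad <- setdiff(unique(panel$outcome), c("amplified", "failed"))
  if (length(bad))
    stop(sprintf("invalid outcome value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  wt <- panel$end - panel$start + 1
  amplified <- panel$outcome == "amplified"
  if (any(amplified & (is.na(panel$observed_size) | panel$observed_size <= 0)))
    stop("amplified amplicons need a positive observed_size", call. = FALSE)
  shifted <- amplified & abs(panel$observed_size - wt) / wt > sizeTol
  anomalous <- !amplified | shifted
  if (!any(anomalous))
    return(new("LesionScan", status = "no_lesion", span = NULL,
               clusters = data.frame(start = numeric(0), end = numeric(0)),
               anomalous = character(0)))
  anom <- reduce(IRanges(panel$start[anomalous], panel$end[anomalous]))
  normal <- panel[!anomalous, , drop = FALSE]
  candidate <- if (nrow(normal))
    setdiff(anom, reduce(IRanges(normal$start, normal$end)))
  else anom
  if (length(candidate) == 0) {
    # every anomalous base is also covered by a clean amplicon; fall back
    # to the anomalous union so the signal is not silently discarded
    candidate <- anom
  }
  clusters <- data.frame(start = start(candidate), end = end(candidate))
  status <- if (nrow(clusters) > 1) "multi" else "lesion"
  if (status == "multi")
    warning(sprintf("anomalous amplicons form %d disjoint clusters: %s",
                    nrow(clusters),
                    paste(sprintf("%s:%d..%d", contig, clusters$start,
                                  clusters$end), collapse = ", ")),
            call. = FALSE)
  span <- genomicInterval(contig, min(clusters$start), max(clusters$end))
  new("LesionScan", status = status, span = span, clusters = clusters,
      anomalous = panel$id[anomalous])
}

setMethod("show", "LesionScan", function(object) {
  cat("LesionScan status=", object@status, "\n", sep = "")
  if (!is.null(object@span))
    cat("  candidate span ", formatGenomicInterval(object@span), " (",
        intervalLength(object@span), " bp)\n", sep = "")
  if (nrow(object@clusters) > 1)
    cat("  ", nrow(object@clusters), " disjoint clusters\n", sep = "")
})

#' Lesion-scan accessors
#' @param x A [LesionScan-class].
#' @return \code{lesionSpan}: the candidate [GenomicInterval-class] (or
#'   \code{NULL}); \code{lesionStatus}: the status string.
#' @export
lesionSpan <- function(x) {
  stopifnot(is(x, "LesionScan"))
  x@span
}

#' @describeIn lesionSpan Status string.
#' @export
lesionStatus <- function(x) {
  stopifnot(is(x, "LesionScan"))
  x@status
}

#' Insertion (or deletion) size from amplicon sizes
#'
#' The size difference between the mutant and wild-type product of the same
#' primer pair; negative values indicate a deletion.
#'
#' @param mutantSize,wildtypeSize Product sizes in bp (both positive).
#' @return Size difference in bp (mutant minus wild type).
#' @examples
#' insertionSize(8500, 945)   # ~7.6 kb insertion
#' @export
insertionSize <- function(mutantSize, wildtypeSize) {
  if (any(mutantSize <= 0) || any(wildtypeSize <= 0))
    stop("amplicon sizes must be positive", call. = FALSE)
  mutantSize - wildtypeSize
}

#' Densitometric target/control ratios per genotype
#'
#' Semi-quantitative band intensities: the target amplicon is normalized to
#' an internal-control amplicon within each genotype (lane), cancelling
#' lane-wise scale, and fold changes are reported against a reference
#' genotype.
#'
#' @param samples \code{data.frame} with columns \code{genotype, role,
#'   intensity}; \code{role} is \code{"target"} or \code{"control"}.
#'   Replicate measures per role are averaged.
#' @param reference Reference genotype for fold change (default: first
#'   genotype in the table).
#' @return \code{data.frame} with \code{genotype, target, control, ratio,
#'   fold_change}.
#' @export
relativeAbundance <- function(samples, reference = NULL) {
  stopifnot(all(c("genotype", "role", "intensity") %in% names(samples)))
  if (any(samples$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  bad <- setdiff(unique(samples$role), c("target", "control"))
  if (length(bad))
    stop(sprintf("invalid role(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  genotypes <- unique(samples$genotype)
  rows <- lapply(genotypes, function(g) {
    sg <- samples[samples$genotype == g, , drop = FALSE]
    tgt <- mean(sg$intensity[sg$role == "target"])
    ctl <- mean(sg$intensity[sg$role == "control"])
    if (!is.finite(tgt) || !is.finite(ctl))
      stop(sprintf("genotype %s lacks a target or control measure", g),
           call. = FALSE)
    if (ctl == 0)
      stop(sprintf("zero control intensity for genotype %s: ratio undefined", g),
           call. = FALSE)
    data.frame(genotype = g, target = tgt, control = ctl, ratio = tgt / ctl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(reference)) reference <- genotypes[1]
  if (!(reference %in% genotypes))
    stop(sprintf("reference genotype %s not present", reference), call. = FALSE)
  out$fold_change <- out$ratio / out$ratio[match(reference, out$genotype)]
  out
}

#' Read a tiling amplicon panel from TSV
#'
#' Columns \code{id, contig, start, end, outcome, observed_size}.
#' @param file Path to the TSV.
#' @return \code{data.frame} for [findLesionInterval()].
#' @export
readAmpliconPanel <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "contig", "start", "end", "outcome", "observed_size")
  if (!all(need %in% names(df)))
    stop(sprintf("amplicon panel file needs columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}

#' Read densitometry measures from TSV
#'
#' Columns \code{genotype, role, intensity}.
#' @param file Path to the TSV.
#' @return \code{data.frame} for [relativeAbundance()].
#' @export
readDensitometry <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("genotype", "role", "intensity") %in% names(df)))
    stop("densitometry file needs columns genotype, role, intensity",
         call. = FALSE)
  df
}
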