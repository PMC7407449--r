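# Synthetic-experiment generators: every input the analysis stages consume
# can be produced here with the statistical structure the analysis assumes
# (female meiotic crossovers, repulsion phase, balancer lethality, no male
# recombination, deficiency panels, tiling-PCR panels, stage survival).

#' Construct a crossover model
#'
#' @param kind \code{"haldane"} (default; recombination independent across
#'   marker intervals with probability given by \code{mapFunction}),
#'   \code{"fixed_count"} (exactly \code{param} crossovers uniform on the
#'   map span) or \code{"gamma_interference"} (gamma renewal process with
#'   shape \code{param}; larger shape = stronger positive interference).
#' @param param Model parameter. For \code{"haldane"} this is a rate
#'   multiplier on map distance (default 1; 0 abolishes recombination), for
#'   \code{"fixed_count"} the crossover count, for
#'   \code{"gamma_interference"} the gamma shape.
#' @param mapFunction \code{"haldane"}, \code{"kosambi"} or
#'   \code{"identity"}; converts interval distance d (cM) into a
#'   recombination probability. Identity uses min(d/100, 0.5).
#' @return A [CrossoverModel-class].
#' @export
crossoverModel <- function(kind = c("haldane", "fixed_count",
                                    "gamma_interference"),
                           param = 1, mapFunction = c("haldane", "kosambi",
                                                      "identity")) {
  new("CrossoverModel", kind = match.arg(kind), param = as.numeric(param),
      mapFunction = match.arg(mapFunction))
}

setMethod("show", "CrossoverModel", function(object) {
  cat("CrossoverModel kind=", object@kind, " param=", object@param,
      " mapFunction=", object@mapFunction, "\n", sep = "")
})

# Distance (cM) -> recombination probability.
.mapFun <- function(d, mapFunction) {
  switch(mapFunction,
    identity = pmin(d / 100, 0.5),
    haldane = (1 - exp(-2 * d / 100)) / 2,
    kosambi = tanh(2 * d / 100) / 2)
}

#' Simulate gametes from a repulsion-phase female
#'
#' One parental chromosome carries every recessive marker allele
#' (\code{"mut"}), the homolog is wild type at all markers; crossovers are
#' placed per the model and parental origin alternates along the chromosome.
#' The transmitted gamete records, per locus, which homolog it came from.
#'
#' @param map A [MarkerMap-class].
#' @param model A [CrossoverModel-class].
#' @param n Number of gametes (> 0).
#' @param seed Integer seed (required for reproducibility).
#' @param extraLoci Optional named numeric of additional cM positions (e.g.
#'   the hidden lethal locus) to score alongside the markers.
#' @return \code{data.frame} with one \code{"mut"}/\code{"wt"} column per
#'   locus, in cM order; cM positions attached as attribute
#'   \code{"positions"}.
#' @export
simulateGametes <- function(map, model = crossoverModel(), n, seed,
                            extraLoci = NULL) {
  stopifnot(is(map, "MarkerMap"), is(model, "CrossoverModel"))
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  pos <- markerPositions(map)
  if (!is.null(extraLoci)) {
    stopifnot(!is.null(names(extraLoci)), all(nzchar(names(extraLoci))))
    pos <- c(pos, extraLoci)
  }
  pos <- sort(pos)
  k <- length(pos)
  .withSeed(seed, {
    origin <- rbinom(n, 1L, 0.5)          # 1 = mutant-marked homolog
    alleles <- matrix(0L, nrow = n, ncol = k)
    switches <- .simulateSwitches(model, pos, n)
    alleles[, 1] <- origin
    if (k > 1)
      for (j in 2:k) alleles[, j] <- bitwXor(alleles[, j - 1], switches[, j - 1])
    out <- as.data.frame(ifelse(alleles == 1L, "mut", "wt"),
                         stringsAsFactors = FALSE)
    names(out) <- names(pos)
    attr(out, "positions") <- pos
    out
  })
}

# n x (k-1) matrix of 0/1 recombination indicators per adjacent interval.
.simulateSwitches <- function(model, pos, n) {
  k <- length(pos)
  if (k < 2) return(matrix(0L, n, 0))
  d <- diff(pos)
  if (model@kind == "haldane") {
    r <- .mapFun(model@param * d, model@mapFunction)
    sw <- vapply(r, function(ri) rbinom(n, 1L, ri), integer(n))
    return(matrix(sw, nrow = n))
  }
  span <- pos[k] - pos[1]
  sw <- matrix(0L, n, k - 1)
  if (model@kind == "fixed_count") {
    nx <- as.integer(round(model@param))
    if (nx > 0) {
      for (i in seq_len(n)) {
        x <- runif(nx, pos[1], pos[k])
        cnt <- findInterval(x, pos)
        tab <- tabulate(cnt, nbins = k - 1)
        sw[i, ] <- tab %% 2L
      }
    }
    return(sw)
  }
  # gamma_interference: stationary renewal with mean inter-crossover
  # distance 100 cM (1 crossover per Morgan); burn-in absorbs edge effects.
  shape <- model@param
  rate <- shape / 100
  burn <- 400
  for (i in seq_len(n)) {
    t <- pos[1] - burn
    pts <- numeric(0)
    while (t <= pos[k]) {
      t <- t + rgamma(1, shape = shape, rate = rate)
      if (t >= pos[1] && t <= pos[k]) pts <- c(pts, t)
    }
    if (length(pts)) {
      tab <- tabulate(findInterval(pts, pos), nbins = k - 1)
      sw[i, ] <- tab %% 2L
    }
  }
  sw
}

#' Simulate the full mapping experiment
#'
#' Emulates the three-generation cross: repulsion-phase F2 females carrying
#' the lethal on the wild-marked homolog over the multiply marked
#' chromosome, F3 males each receiving one recombinant maternal chromosome
#' (transmitted without male recombination), and a per-male testcross to
#' lethal/balancer females that determines the lethal-locus state from
#' surviving progeny classes via [inferLStatus()].
#'
#' In the repulsion configuration the hidden lethal rides the marker-free
#' homolog, so a gamete reading \code{"wt"} at the lethal's position carries
#' the lethal allele.
#'
#' @param map A [MarkerMap-class].
#' @param trueLocusCm Hidden locus position (cM); must lie in
#'   [0, max marker cM + 10].
#' @param nMales Number of scored F3 males.
#' @param nTestcrossProgeny Progeny scored per male testcross.
#' @param misclassificationRate Probability a male's determined state is
#'   recorded wrongly (flipped l <-> l+). Default 0: a nonzero default
#'   would silently bias RF upward.
#' @param minTotal Minimum scored testcross progeny for a confident lethal
#'   call (see [inferLStatus()]).
#' @param model A [CrossoverModel-class].
#' @param seed Integer seed.
#' @return \code{data.frame}: one row per male, one \code{"mut"}/\code{"wt"}
#'   column per marker plus \code{locus_state} (\code{"l"}, \code{"l+"} or
#'   \code{"unknown"}).
#' @export
simulateMappingExperiment <- function(map, trueLocusCm, nMales = 113,
                                      nTestcrossProgeny = 50,
                                      misclassificationRate = 0,
                                      minTotal = 20,
                                      model = crossoverModel(), seed) {
  stopifnot(is(map, "MarkerMap"))
  pos <- markerPositions(map)
  if (trueLocusCm < 0 || trueLocusCm > max(pos) + 10)
    stop("trueLocusCm outside [0, max marker cM + 10]", call. = FALSE)
  if (misclassificationRate < 0 || misclassificationRate >= 0.5)
    stop("misclassificationRate must be in [0, 0.5)", call. = FALSE)
  if (nMales <= 0 || nTestcrossProgeny <= 0)
    stop("counts must be positive", call. = FALSE)
  seeds <- .subSeeds(seed, 2)
  gam <- simulateGametes(map, model, nMales, seed = seeds[1],
                         extraLoci = c(".locus" = trueLocusCm))
  carriesL <- gam$.locus == "wt"   # repulsion: lethal on the unmarked homolog
  males <- gam[, setdiff(names(gam), ".locus"), drop = FALSE]
  .withSeed(seeds[2], {
    state <- character(nMales)
    for (i in seq_len(nMales)) {
      # Testcross to lethal/balancer females. Progeny classes (1/4 each):
      # tested-chr/lethal (the diagnostic non-balancer class), tested/balancer,
      # tester-chr/lethal, tester/balancer. Balancer homozygotes never arise
      # (both parents contribute at most one balancer here). The diagnostic
      # class dies when the tested chromosome carries the lethal.
      cls <- rmultinom(1, nTestcrossProgeny, rep(0.25, 4))[, 1]
      diagSurvivors <- if (carriesL[i]) 0L else cls[1]
      totalScored <- diagSurvivors + sum(cls[2:4])
      state[i] <- inferLStatus(diagSurvivors, totalScored, minTotal)
    }
    if (misclassificationRate > 0) {
      known <- state != "unknown"
      flip <- known & (runif(nMales) < misclassificationRate)
      state[flip] <- ifelse(state[flip] == "l", "l+", "l")
    }
    males$locus_state <- state
    attr(males, "true_locus_cm") <- trueLocusCm
    attr(males, "true_carries_l") <- carriesL
    males
  })
}

#' Simulate a deficiency complementation panel
#'
#' Random deleted intervals on the band lattice around a hidden locus band;
#' a deficiency fails to complement exactly when its deleted interval
#' contains the locus band, then the outcome is flipped with probability
#' \code{noiseRate}.
#'
#' @param trueLocusBand Hidden locus band ([CytoBand-class] or string).
#' @param nDeficiencies Panel size.
#' @param divisions Integer range (length 2) of divisions the simulated
#'   breakpoints may fall in; default spans 3 divisions either side of the
#'   locus, clipped to the arm.
#' @param maxSubband Sub-bands per letter on the lattice.
#' @param noiseRate Probability of a flipped outcome, in [0, 0.2].
#' @param seed Integer seed.
#' @return \code{data.frame} with columns \code{id, arm, del_start,
#'   del_end, outcome} as consumed by [solveRegion()].
#' @export
simulateDeficiencyPanel <- function(trueLocusBand, nDeficiencies = 50,
                                    divisions = NULL, maxSubband = 20L,
                                    noiseRate = 0, seed) {
  if (is.character(trueLocusBand)) trueLocusBand <- parseCytoband(trueLocusBand)
  stopifnot(is(trueLocusBand, "CytoBand"))
  if (noiseRate < 0 || noiseRate > 0.2)
    stop("noiseRate must be in [0, 0.2]", call. = FALSE)
  arm <- trueLocusBand@arm
  armRng <- .ARM_DIVISIONS[[arm]]
  if (is.null(divisions))
    divisions <- c(max(armRng[1], trueLocusBand@division - 3L),
                   min(armRng[2], trueLocusBand@division + 3L))
  lo <- .latticeIndex(new("CytoBand", arm = arm,
                          division = as.integer(divisions[1]), letter = "A",
                          subband = 1L), maxSubband)
  hi <- .latticeIndex(new("CytoBand", arm = arm,
                          division = as.integer(divisions[2]), letter = "F",
                          subband = as.integer(maxSubband)), maxSubband)
  trueIdx <- .latticeIndex(trueLocusBand, maxSubband, "point")
  stopifnot(trueIdx >= lo, trueIdx <= hi)
  .withSeed(seed, {
    a <- sample(lo:hi, nDeficiencies, replace = TRUE)
    b <- sample(lo:hi, nDeficiencies, replace = TRUE)
    s <- pmin(a, b); e <- pmax(a, b)
    fails <- s <= trueIdx & e >= trueIdx
    flip <- runif(nDeficiencies) < noiseRate
    fails <- xor(fails, flip)
    data.frame(
      id = sprintf("DfSIM%03d", seq_len(nDeficiencies)),
      arm = arm,
      del_start = vapply(s, function(i) formatCytoband(.latticeBand(i, arm, maxSubband)), character(1)),
      del_end = vapply(e, function(i) formatCytoband(.latticeBand(i, arm, maxSubband)), character(1)),
      outcome = ifelse(fails, "fails", "complements"),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a tiling-PCR amplicon panel
#'
#' Overlapping amplicons tile a gene; the amplicon(s) spanning a hidden
#' insertion report the wild-type size plus the insertion size, or fail
#' outright when that total exceeds the long-range PCR ceiling. The
#' generator is deterministic given its arguments.
#'
#' @param geneInterval [GenomicInterval-class] (or coordinate string) to
#'   tile.
#' @param ampliconLength,overlap Tiling geometry in bp.
#' @param insertionSite Coordinate of the hidden insertion (must lie inside
#'   \code{geneInterval}); use \code{NULL} for a wild-type panel.
#' @param insertionSize Insertion size in bp (0 = wild type).
#' @param maxAmplifiable Largest product the reaction can amplify, bp.
#' @return \code{data.frame} with columns \code{id, contig, start, end,
#'   outcome, observed_size} as consumed by [findLesionInterval()].
#' @export
simulateTilingPCR <- function(geneInterval, ampliconLength = 500,
                              overlap = 50, insertionSite = NULL,
                              insertionSize = 0, maxAmplifiable = 3000) {
  if (is.character(geneInterval)) geneInterval <- parseGenomicInterval(geneInterval)
  stopifnot(is(geneInterval, "GenomicInterval"),
            ampliconLength > overlap, overlap >= 0)
  if (!is.null(insertionSite) &&
      (insertionSite < geneInterval@start || insertionSite > geneInterval@end))
    stop("insertionSite must lie inside geneInterval", call. = FALSE)
  starts <- seq(geneInterval@start, geneInterval@end,
                by = ampliconLength - overlap)
  ends <- pmin(starts + ampliconLength - 1, geneInterval@end)
  wt <- ends - starts + 1
  hit <- if (is.null(insertionSite) || insertionSize == 0) rep(FALSE, length(starts))
         else starts <= insertionSite & ends >= insertionSite
  obs <- ifelse(hit, wt + insertionSize, wt)
  failed <- obs > maxAmplifiable
  data.frame(
    id = sprintf("amp%02d", seq_along(starts)),
    contig = geneInterval@contig,
    start = starts, end = ends,
    outcome = ifelse(failed, "failed", "amplified"),
    observed_size = ifelse(failed, NA_real_, obs),
    stringsAsFactors = FALSE)
}

#' Simulate stage-survival counts
#'
#' Genotype classes drawn multinomially at fertilization, then binomial
#' thinning through successive developmental stages; per-class counts are
#' monotonically non-increasing across stages.
#'
#' @param classProportions Named numeric summing to 1: genotype-class
#'   proportions at fertilization (e.g. the 1:2:1 intercross classes).
#' @param stageSurvival Numeric matrix, classes x stages, of per-stage
#'   survival probabilities in [0, 1] (0 encodes balancer/homozygous
#'   lethality at that stage). Row names must match
#'   \code{names(classProportions)}; column names are the stage labels.
#' @param nEggs Total eggs at fertilization.
#' @param seed Integer seed.
#' @return \code{data.frame}: \code{class}, an \code{eggs} column and one
#'   column per stage, counts non-increasing left to right.
#' @export
simulateStageSurvival <- function(classProportions, stageSurvival, nEggs,
                                  seed) {
  stopifnot(abs(sum(classProportions) - 1) < 1e-8,
            all(stageSurvival >= 0 & stageSurvival <= 1),
            !is.null(names(classProportions)),
            identical(rownames(stageSurvival), names(classProportions)))
  .withSeed(seed, {
    counts <- rmultinom(1, nEggs, classProportions)[, 1]
    out <- data.frame(class = names(classProportions), eggs = counts,
                      stringsAsFactors = FALSE)
    prev <- counts
    for (j in seq_len(ncol(stageSurvival))) {
      cur <- rbinom(length(prev), prev, stageSurvival[, j])
      out[[colnames(stageSurvival)[j]]] <- cur
      prev <- cur
    }
    out
  })
}
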