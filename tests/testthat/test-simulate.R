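map <- rucucaMap()

test_that("crossover-free models give all-parental gametes", {
  g0 <- simulateGametes(map, crossoverModel("haldane", param = 0), 50, seed = 1)
  expect_true(all(apply(g0, 1, function(r) length(unique(r)) == 1)))
  gf <- simulateGametes(map, crossoverModel("fixed_count", param = 0), 50,
                        seed = 2)
  expect_true(all(apply(gf, 1, function(r) length(unique(r)) == 1)))
})

test_that("markers 50+ cM apart recombine freely under the identity map", {
  wide <- MarkerMap(c("a", "b"), c(0, 60), c("61A1", "80A1"))
  g <- simulateGametes(wide, crossoverModel(mapFunction = "identity"), 10000,
                       seed = 33)
  r <- mean(g$a != g$b)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(r - 0.5), 3 * se)
})

test_that("generators are bit-reproducible given a seed", {
  expect_identical(simulateGametes(map, crossoverModel(), 200, seed = 5),
                   simulateGametes(map, crossoverModel(), 200, seed = 5))
  expect_identical(
    simulateMappingExperiment(map, 42.3, nMales = 40, seed = 9),
    simulateMappingExperiment(map, 42.3, nMales = 40, seed = 9))
  expect_identical(simulateDeficiencyPanel("71F4", 20, seed = 4),
                   simulateDeficiencyPanel("71F4", 20, seed = 4))
  surv <- matrix(c(1, 1, 0, 0.9, 0.95, 0), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("hatch", "pupa")))
  expect_identical(
    simulateStageSurvival(c(a = .25, b = .5, c = .25), surv, 1000, seed = 8),
    simulateStageSurvival(c(a = .25, b = .5, c = .25), surv, 1000, seed = 8))
})

test_that("mapping experiment recovers transmitted locus states without noise", {
  males <- simulateMappingExperiment(map, 42.3, nMales = 200,
                                     nTestcrossProgeny = 400,
                                     misclassificationRate = 0, seed = 17)
  truth <- attr(males, "true_carries_l")
  expect_identical(males$locus_state, ifelse(truth, "l", "l+"))
  # partition property: every marker tally uses all known-state males
  counts <- classifyPair(males)
  expect_true(all(counts$parental + counts$recombinant ==
                    sum(males$locus_state != "unknown")))
})

test_that("mapping experiment respects its argument contracts", {
  expect_error(simulateMappingExperiment(map, 200, seed = 1), "outside")
  expect_error(simulateMappingExperiment(map, 42, misclassificationRate = 0.6,
                                         seed = 1), "misclassification")
  expect_error(simulateGametes(map, crossoverModel(), n = 0, seed = 1),
               "positive")
})

test_that("noise-free deficiency panels bracket the truth and tighten with size", {
  trueBand <- parseCytoband("71F4")
  for (s in c(11, 12, 13)) {
    panel <- simulateDeficiencyPanel(trueBand, nDeficiencies = 40,
                                     noiseRate = 0, seed = s)
    expect_true(any(panel$outcome == "fails"))
    region <- solveRegion(panel)
    expect_true(any(vapply(region@intervals, cytoContains, logical(1),
                           band = trueBand)))
    # width never grows as deficiencies accumulate
    first <- which(panel$outcome == "fails")[1]
    widths <- vapply(seq(first, nrow(panel), by = 4), function(k) {
      r <- solveRegion(panel[1:k, , drop = FALSE])
      sum(vapply(r@intervals, function(iv) {
        rng <- flymap:::.latticeRange(iv, 20L)
        rng[2] - rng[1] + 1
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(widths) <= 0))
  }
})

test_that("tiling panels shift or drop exactly the insertion-spanning amplicons", {
  gene <- parseGenomicInterval("3L:15811576..15820204")
  wt <- simulateTilingPCR(gene, insertionSite = NULL, insertionSize = 0)
  expect_true(all(wt$outcome == "amplified"))
  expect_true(all(wt$observed_size == wt$end - wt$start + 1))

  site <- 15815000
  panel <- simulateTilingPCR(gene, insertionSite = site, insertionSize = 7500,
                             maxAmplifiable = 3000)
  spanning <- panel$start <= site & panel$end >= site
  expect_identical(panel$outcome == "failed", spanning)
  expect_error(simulateTilingPCR(gene, insertionSite = 1, insertionSize = 10),
               "inside")
})

test_that("stage survival thins binomially with hard lethal classes", {
  props <- c(hom = 0.25, het = 0.5, bal = 0.25)
  surv <- matrix(c(1, 1, 0, 0.7, 0.95, 0), nrow = 3,
                 dimnames = list(names(props), c("hatch", "pupa")))
  x <- simulateStageSurvival(props, surv, 5000, seed = 21)
  expect_identical(x$hatch[x$class == "bal"], 0L)  # balancer homozygotes die
  counts <- as.matrix(x[, c("eggs", "hatch", "pupa")])
  expect_true(all(counts[, -1] <= counts[, -3]))
  # observed thinning within 3 binomial SE of the specified probabilities
  for (cl in c("hom", "het")) {
    i <- match(cl, x$class)
    for (j in 1:2) {
      nPrev <- counts[i, j]; p <- surv[cl, j]
      obs <- counts[i, j + 1] / nPrev
      expect_lte(abs(obs - p), 3 * sqrt(p * (1 - p) / nPrev))
    }
  }
  noLoss <- simulateStageSurvival(props, matrix(1, 3, 2,
    dimnames = list(names(props), c("s1", "s2"))), 2000, seed = 2)
  expect_true(all(noLoss$s2 == noLoss$eggs))
})
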