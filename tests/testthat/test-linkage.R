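map <- rucucaMap()

test_that("lethal-status inference follows the absence rule", {
  expect_identical(inferLStatus(0, 40, 20), "l")
  expect_identical(inferLStatus(12, 40, 20), "l+")
  expect_identical(inferLStatus(0, 5, 20), "unknown")
  expect_identical(inferLStatus(c(0, 3, 0), c(25, 10, 10)),
                   c("l", "l+", "unknown"))
  expect_error(inferLStatus(-1, 10), "non-negative")
  expect_error(inferLStatus(11, 10), "exceed")
})

test_that("pair classification matches an exhaustive manual tally", {
  males <- handMales()
  counts <- classifyPair(males)
  for (m in c("m1", "m2")) {
    oracle <- bruteTally(males, m)
    row <- counts[counts$marker == m, ]
    expect_identical(c(P = row$parental, R = row$recombinant), oracle)
  }
  expect_identical(attr(counts, "excluded"), 2L)
  # permutation invariance
  shuffled <- males[sample(nrow(males)), ]
  expect_identical(classifyPair(shuffled)[, c("parental", "recombinant")],
                   counts[, c("parental", "recombinant")])
  # intact mutant chromosomes only: no recombinants
  pure <- data.frame(m1 = "wt", locus_state = rep("l", 10),
                     stringsAsFactors = FALSE)
  expect_identical(classifyPair(pure)$recombinant, 0L)
  expect_error(classifyPair(males, "nope"), "not in table")
})

test_that("RF is 100 R/(P+R) with Clopper-Pearson intervals", {
  est <- estimateRF(data.frame(marker = c("ru", "th"),
                               parental = c(62, 110), recombinant = c(51, 3)))
  expect_equal(est$rf, c(100 * 51 / 113, 100 * 3 / 113))
  expect_equal(formatRF(est$rf), c("45.13", "2.65"))

  zero <- estimateRF(data.frame(marker = "m", parental = 50, recombinant = 0))
  expect_equal(zero$rf, 0)
  expect_equal(zero$ci_low, 0)

  expect_error(estimateRF(data.frame(marker = "m", parental = 0,
                                     recombinant = 0)), "undefined")

  # CI endpoints match a bisection search on the binomial CDF and binom.test
  for (case in list(c(3, 113), c(51, 113), c(0, 50), c(8, 113))) {
    x <- case[1]; n <- case[2]
    est1 <- estimateRF(data.frame(marker = "m", parental = n - x,
                                  recombinant = x))
    oracle <- bisectCP(x, n)
    expect_equal(est1$ci_low, 100 * oracle[["low"]], tolerance = 1e-6)
    expect_equal(est1$ci_high, 100 * oracle[["high"]], tolerance = 1e-6)
    bt <- binom.test(x, n)$conf.int
    expect_equal(c(est1$ci_low, est1$ci_high), 100 * as.numeric(bt),
                 tolerance = 1e-8)
  }
})

test_that("RF is invariant under a joint phase flip", {
  males <- simulateMappingExperiment(map, 42.3, nMales = 113,
                                     nTestcrossProgeny = 100, seed = 12)
  rf1 <- estimateRF(classifyPair(males))
  flipped <- males
  for (m in markerNames(map))
    flipped[[m]] <- ifelse(flipped[[m]] == "mut", "wt", "mut")
  flipped$locus_state <- ifelse(flipped$locus_state == "l", "l+", "l")
  rf2 <- estimateRF(classifyPair(flipped))
  expect_equal(rf1$rf, rf2$rf)
})

test_that("replicate pooling sums counts and equals concatenated estimation", {
  reps <- data.frame(marker = "h", parental = c(89, 185, 96),
                     recombinant = c(18, 40, 22), replicate = 1:3)
  pooled <- poolCounts(reps)
  expect_equal(c(pooled$parental, pooled$recombinant), c(370, 80))
  expect_equal(formatRF(estimateRF(pooled)$rf), "17.77")  # truncated display
  expect_equal(estimateRF(pooled)$rf, 100 * 80 / 450)

  single <- poolCounts(reps[1, ])
  expect_equal(c(single$parental, single$recombinant), c(89, 18))
  expect_error(poolCounts(reps, marker = "st"), "not present")

  # pooling two synthetic batches == estimating on the concatenated table
  a <- simulateMappingExperiment(map, 42.3, nMales = 60,
                                 nTestcrossProgeny = 100, seed = 31)
  b <- simulateMappingExperiment(map, 42.3, nMales = 53,
                                 nTestcrossProgeny = 100, seed = 32)
  both <- rbind(a, b)
  pooledCounts <- poolCounts(rbind(classifyPair(a), classifyPair(b)))
  expect_equal(estimateRF(pooledCounts)$rf,
               estimateRF(classifyPair(both))$rf)
})

test_that("flank subtraction reproduces the published interval and handles edge cases", {
  est <- data.frame(marker = c("h", "st", "cu"), rf = c(17.78, 1.23, 8.29),
                    n = c(450, 982, 1204))
  pl <- placeLocus(est, map)
  expect_identical(placementSide(pl), "left")
  expect_identical(pl@anchor, "st")
  expect_identical(sort(pl@informative), c("cu", "st"))
  expect_equal(unname(placementBounds(pl)), c(41.71, 42.77))

  # two markers suffice
  pl2 <- placeLocus(est[est$marker != "h", ], map)
  expect_equal(unname(placementBounds(pl2)), c(41.71, 42.77))

  # zero-RF anchor is excluded from the bounds with a note
  est0 <- data.frame(marker = c("th", "st", "cu"), rf = c(0, 1.23, 8.29),
                     n = c(113, 982, 1204))
  pl0 <- placeLocus(est0, map)
  expect_identical(pl0@anchor, "th")
  expect_false("th" %in% pl0@informative)
  expect_match(pl0@note, "ambiguous")

  # right-side geometry mirrors correctly
  estR <- data.frame(marker = c("ru", "h"), rf = c(20, 2), n = c(100, 100))
  plR <- placeLocus(estR, map)
  expect_identical(placementSide(plR), "right")
  expect_equal(unname(placementBounds(plR)), c(20, 28.5))

  expect_error(placeLocus(est[1, , drop = FALSE], map), "at least 2")
  expect_error(placeLocus(data.frame(marker = "zz", rf = 1), map), "absent")
})

test_that("least-squares placement equals a finer brute-force grid", {
  est <- data.frame(marker = c("th", "st", "cu", "sr"),
                    rf = c(1.1, 1.9, 7.4, 19.2))
  pl <- placeLocus(est, map, method = "least_squares", bootstrap = 50,
                   seed = 99)
  pos <- markerPositions(map)[est$marker]
  grid <- seq(35, 55, by = 0.001)
  obj <- vapply(grid, function(x) sum((est$rf - abs(pos - x))^2), numeric(1))
  expect_lt(abs(pl@point - grid[which.min(obj)]), 0.011)
  expect_true(pl@low <= pl@point && pl@point <= pl@high)
})

test_that("RF display truncates instead of rounding", {
  expect_identical(formatRF(100 * 8 / 113), "7.07")
  expect_identical(formatRF(100 * 34 / 113), "30.08")
  expect_identical(formatRF(45.1327), "45.13")
  expect_identical(formatRF(0), "0.00")
  expect_identical(formatRF(7.0796, 1), "7.0")
  expect_error(formatRF(101), "\\[0, 100\\]")
})
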