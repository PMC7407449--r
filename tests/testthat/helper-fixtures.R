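# Shared fixtures and independent oracles.

extfile <- function(name) {
  path <- system.file("extdata", name, package = "flymap")
  stopifnot(nzchar(path))
  path
}

# A small hand-checkable scored-male table over two markers.
handMales <- function() {
  data.frame(
    m1 = c(rep("wt", 8), rep("mut", 8), rep("wt", 2), rep("mut", 2)),
    m2 = c(rep("wt", 10), rep("mut", 10)),
    locus_state = c(rep("l", 6), rep("l+", 6), rep("l", 4), rep("l+", 2),
                    rep("unknown", 2)),
    stringsAsFactors = FALSE)
}

# Brute-force P/R tally: explicit loop, no vectorized shortcuts, mirroring
# a by-hand count of the repulsion-phase classes.
bruteTally <- function(males, marker) {
  P <- 0L; R <- 0L
  for (i in seq_len(nrow(males))) {
    st <- males$locus_state[i]
    if (st == "unknown") next
    mut <- males[[marker]][i] == "mut"
    if ((!mut && st == "l") || (mut && st == "l+")) P <- P + 1L
    else R <- R + 1L
  }
  c(P = P, R = R)
}

# Clopper-Pearson endpoints by bisection on the binomial CDF, independent
# of qbeta.
bisectCP <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  solve1 <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else
    solve1(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
           0, 1)
  high <- if (x == n) 1 else
    solve1(function(p) -(pbinom(x, n, p) - alpha / 2), 0, 1)
  c(low = low, high = high)
}

# Independent band-lattice oracle: enumerate every (division, letter,
# subband) tuple in a division window and test panel membership tuple by
# tuple.
latticeTuples <- function(divisions, maxSubband) {
  expand.grid(sub = seq_len(maxSubband), letter = 1:6,
              div = divisions[1]:divisions[2])[, c("div", "letter", "sub")]
}

tupleKey <- function(div, letter, sub) (div * 6 + letter) * 100 + sub

bandToTuple <- function(text, role, maxSubband) {
  b <- flymap::parseCytoband(text, arm = "3L")
  sub <- b@subband
  if (is.na(sub)) sub <- if (role == "start") 1L else maxSubband
  c(div = b@division, letter = match(b@letter, LETTERS), sub = sub)
}

# Per-band voting: a tuple survives when inside every failing deletion and
# outside every complementing one.
voteRegion <- function(panel, divisions, maxSubband) {
  tup <- latticeTuples(divisions, maxSubband)
  keys <- tupleKey(tup$div, tup$letter, tup$sub)
  keep <- rep(TRUE, nrow(tup))
  for (i in seq_len(nrow(panel))) {
    s <- bandToTuple(panel$del_start[i], "start", maxSubband)
    e <- bandToTuple(panel$del_end[i], "end", maxSubband)
    inside <- keys >= tupleKey(s["div"], s["letter"], s["sub"]) &
      keys <= tupleKey(e["div"], e["letter"], e["sub"])
    keep <- if (panel$outcome[i] == "fails") keep & inside else keep & !inside
  }
  sort(keys[keep])
}

# Expand a solved CandidateRegion into the same tuple keys.
regionKeys <- function(region, divisions, maxSubband) {
  tup <- latticeTuples(divisions, maxSubband)
  keys <- tupleKey(tup$div, tup$letter, tup$sub)
  keep <- rep(FALSE, nrow(tup))
  for (iv in region@intervals) {
    s <- c(div = iv@start@division, letter = match(iv@start@letter, LETTERS),
           sub = iv@start@subband)
    e <- c(div = iv@end@division, letter = match(iv@end@letter, LETTERS),
           sub = iv@end@subband)
    keep <- keep | (keys >= tupleKey(s["div"], s["letter"], s["sub"]) &
                      keys <= tupleKey(e["div"], e["letter"], e["sub"]))
  }
  sort(keys[keep])
}
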