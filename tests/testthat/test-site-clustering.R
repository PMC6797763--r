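test_that("single-position clusters obey the tag-count threshold", {
  sig <- mkSignal("five_prime", s1 = list(pos = 500, count = 25))
  cs <- clusterTags(sig)
  expect_length(cs, 1)
  expect_equal(BiocGenerics::start(clusterRanges(cs)), 500)
  expect_equal(S4Vectors::mcols(clusterRanges(cs))$total, 25)
  expect_equal(clusterKind(cs), "TSS")
  sigLow <- mkSignal("five_prime", s1 = list(pos = 500, count = 10))
  expect_length(clusterTags(sigLow), 0)
  expect_error(clusterTags(sig, minValue = 0), "minValue")
  expect_error(clusterTags(sig, maxLength = -1), "maxLength")
})

test_that("distant dense positions split into separate clusters", {
  sig <- mkSignal("three_prime",
                  s1 = list(pos = c(100, 101, 500), count = c(30, 30, 30)))
  cs <- clusterTags(sig, maxLength = 200)
  gr <- clusterRanges(cs)
  expect_equal(length(cs), 2)
  expect_equal(BiocGenerics::start(gr), c(100, 500))
  expect_equal(BiocGenerics::end(gr), c(101, 500))
  expect_equal(clusterKind(cs), "TES")
})

test_that("clustering equals the exhaustive segment-enumeration oracle", {
  set.seed(99)
  for (r in 1:40) {
    n <- sample(1:30, 1)
    pos <- sort(sample(1:400, n))
    val <- sample(1:40, n, replace = TRUE)
    minValue <- sample(c(1, 5, 20), 1)
    maxLength <- sample(c(50, 200, 500), 1)
    fold <- sample(c(1, 2, 5), 1)
    sig <- mkSignal("five_prime", s1 = list(pos = pos, count = val))
    cs <- clusterTags(sig, minValue = minValue, maxLength = maxLength,
                      minDensityFold = fold)
    exp <- oracleClusterRuns(pos, val, minValue, maxLength, fold)
    gr <- clusterRanges(cs)
    expect_equal(BiocGenerics::start(gr), pos[exp$i])
    expect_equal(BiocGenerics::end(gr), pos[exp$j])
  }
})

test_that("cross-sample merging unions overlapping clusters only", {
  sig <- mkSignal("five_prime",
                  A = list(pos = 100:149, count = rep(2, 50)),
                  B = list(pos = 140:179, count = rep(3, 40)))
  csA <- clusterTags(sig, sample = "A")
  csB <- clusterTags(sig, sample = "B")
  merged <- mergeAcrossSamples(list(csA, csB), sig)
  expect_length(merged, 1)
  gr <- clusterRanges(merged)
  expect_equal(c(BiocGenerics::start(gr), BiocGenerics::end(gr)), c(100, 179))
  expect_equal(unname(clusterCounts(merged)[1, c("A", "B")]), c(100, 120))
  ## counts conserved
  expect_equal(sum(clusterCounts(merged)), sum(sig@tags$count))
  ## disjoint clusters stay apart
  sig2 <- mkSignal("five_prime",
                   A = list(pos = 100:104, count = rep(10, 5)),
                   B = list(pos = 300:304, count = rep(10, 5)))
  m2 <- mergeAcrossSamples(list(clusterTags(sig2, sample = "A"),
                                clusterTags(sig2, sample = "B")), sig2)
  expect_length(m2, 2)
  expect_error(mergeAcrossSamples(list(csA, clusterTags(
    mkSignal("three_prime", A = list(pos = 1:5, count = rep(10, 5))))),
    sig), "mixed")
})

test_that("chained overlaps collapse to a single cluster", {
  sig <- mkSignal("five_prime",
                  A = list(pos = 100:120, count = rep(5, 21)),
                  B = list(pos = 115:135, count = rep(5, 21)),
                  C = list(pos = 130:150, count = rep(5, 21)))
  parts <- lapply(c("A", "B", "C"), function(s) clusterTags(sig, sample = s))
  merged <- mergeAcrossSamples(parts, sig)
  expect_length(merged, 1)
  expect_equal(BiocGenerics::start(clusterRanges(merged)), 100)
  expect_equal(BiocGenerics::end(clusterRanges(merged)), 150)
})

test_that("reliability filter applies TPM and recurrent-signal rules", {
  mk <- function(maxPerSample) {
    ## one cluster at 100..101; per-sample per-base maxima controlled
    specs <- lapply(seq_along(maxPerSample), function(i)
      list(pos = c(100, 101), count = c(maxPerSample[i], 1)))
    names(specs) <- paste0("s", seq_along(maxPerSample))
    do.call(mkSignal, c(list("five_prime"), specs))
  }
  ## TPM is count/library*1e6; tiny libraries make TPM large, so the TPM
  ## rule passes and the per-base rule decides
  sig3 <- mk(c(12, 12, 12))
  cs <- clusterTags(sig3, minValue = 10)
  expect_length(filterReliable(cs, sig3, tpmMin = 0.5, topSignalMin = 10,
                               minSamples = 3), 1)
  sig2 <- mk(c(12, 12, 2))
  cs2 <- clusterTags(sig2, minValue = 10)
  expect_length(filterReliable(cs2, sig2, tpmMin = 0.5, topSignalMin = 10,
                               minSamples = 3), 0)
  ## TPM rule: huge library with tiny cluster -> TPM below threshold
  sigT <- mkSignal("five_prime",
                   s1 = list(pos = c(100, 101, 5000:5999),
                             count = c(12, 10, rep(60000, 1000))))
  csT <- clusterTags(sigT, minValue = 10, maxLength = 10)
  small <- csT[BiocGenerics::start(clusterRanges(csT)) == 100]
  expect_length(small, 1)
  expect_length(filterReliable(small, sigT, tpmMin = 0.5,
                               topSignalMin = 10, minSamples = 1), 0)
})

test_that("raising reliability thresholds never adds clusters", {
  sig <- mkSignal("five_prime",
                  a = list(pos = 100:110, count = rep(11, 11)),
                  b = list(pos = 100:110, count = rep(5, 11)),
                  c = list(pos = 300:310, count = rep(20, 11)))
  cs <- mergeAcrossSamples(lapply(c("a", "b", "c"), function(s)
    clusterTags(sig, sample = s, minValue = 10)), sig)
  base <- length(filterReliable(cs, sig, 0.5, 10, 1))
  for (tpm in c(0.5, 5)) for (top in c(10, 15)) for (ns in 1:3) {
    expect_lte(length(filterReliable(cs, sig, tpm, top, ns)), base)
  }
})

test_that("summit selection is max-signal with leftmost tie-break", {
  sig <- mkSignal("five_prime", s1 = list(pos = c(100, 101),
                                          count = c(5, 9)))
  cs <- clusterTags(sig, minValue = 5)
  expect_equal(selectSummit(cs, 1, sig), 101)
  sigT <- mkSignal("five_prime", s1 = list(pos = c(100, 101),
                                           count = c(5, 5)))
  csT <- clusterTags(sigT, minValue = 5)
  expect_equal(selectSummit(csT, 1, sigT), 100)
  sig1 <- mkSignal("five_prime", s1 = list(pos = 42, count = 30))
  cs1 <- clusterTags(sig1)
  expect_equal(selectSummit(cs1, 1, sig1), 42)
})

test_that("assembly merging uses a strict distance cutoff", {
  mkTwo <- function(gap) {
    mkSignal("five_prime", s1 = list(pos = c(100, 100 + 1 + gap),
                                     count = c(30, 30)))
  }
  near <- mkTwo(399)
  csNear <- clusterTags(near, maxLength = 5)
  m <- mergeNearbyForAssembly(csNear, near, cutoff = 400)
  expect_length(m, 1)
  ## the merged summit is the highest-signal position (leftmost on ties)
  expect_equal(clusterSummits(m), 100)
  far <- mkTwo(400)
  csFar <- clusterTags(far, maxLength = 5)
  expect_length(mergeNearbyForAssembly(csFar, far, cutoff = 400), 2)
  chain <- mkSignal("five_prime", s1 = list(pos = c(100, 450, 800),
                                            count = c(30, 40, 30)))
  csC <- clusterTags(chain, maxLength = 5)
  mC <- mergeNearbyForAssembly(csC, chain, cutoff = 400)
  expect_length(mC, 1)
  expect_equal(clusterSummits(mC), 450)
})

test_that("summit pruning keeps the stronger of nearby clusters", {
  mkCs <- function(pos1, pos2, tot1, tot2) {
    sig <- mkSignal("five_prime", s1 = list(pos = c(pos1, pos2),
                                            count = c(tot1, tot2)))
    list(cs = clusterTags(sig, maxLength = 1, minValue = 1), sig = sig)
  }
  x <- mkCs(100, 130, 100, 40)
  out <- pruneWithin(x$cs, cutoff = 50)
  expect_length(out, 1)
  expect_equal(clusterSummits(out), 100)
  y <- mkCs(100, 160, 100, 40)
  expect_length(pruneWithin(y$cs, cutoff = 50), 2)
  z <- mkCs(100, 130, 40, 40)     # equal totals: leftmost survives
  outz <- pruneWithin(z$cs, cutoff = 50)
  expect_equal(clusterSummits(outz), 100)
})
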