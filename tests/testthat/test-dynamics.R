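test_that("FPKM arithmetic and scaling", {
  expect_equal(computeFpkm(100, 1000, 1e6), 100)
  expect_equal(computeFpkm(0, 1000, 1e6), 0)
  expect_equal(computeFpkm(100, 1000, 2e6), 50)   # doubling library halves
  expect_error(computeFpkm(10, 0, 1e6), "length")
  expect_error(computeFpkm(10, 100, 0), "library")
})

test_that("tissue specificity hits its entropy closed forms", {
  expect_equal(tissueSpecificity(rep(5, 16)), 0)
  single <- c(rep(0, 15), 7)
  expect_equal(tissueSpecificity(single), 4)        # log2(16)
  two <- c(rep(0, 14), 3, 3)
  expect_equal(tissueSpecificity(two), 3)           # log2(16) - 1
  expect_error(tissueSpecificity(rep(0, 16)), "zero")
  expect_error(tissueSpecificity(c(-1, 2)), "negative")
})

test_that("specificity is bounded and extremal only at the extremes", {
  set.seed(41)
  for (r in 1:100) {
    n <- sample(2:20, 1)
    x <- stats::rgamma(n, 1)
    s <- tissueSpecificity(x)
    expect_gte(s, 0)
    expect_lte(s, log2(n) + 1e-12)
  }
  m <- rbind(a = c(3, 3), b = c(0, 5))
  expect_equal(unname(tissueSpecificity(m)), c(0, 1))
})

test_that("expressed tissues use a strict 20%-of-max rule", {
  row <- c(a = 10, b = 2.1, c = 2.0, d = 0)
  expect_setequal(expressedTissues(row), c("a", "b"))
  expect_setequal(expressedTissues(rep(3, 5)), 1:5)
})

test_that("dominant sites need strictly more than half the signal", {
  expect_equal(dominantSite(c(0.6, 0.4)), 1)
  expect_true(is.na(dominantSite(c(0.5, 0.5))))
  expect_equal(dominantSite(c(s1 = 1)), "s1")
})

test_that("switch scores follow the two-branch formula", {
  i <- c(A = 0.6, B = 0.4)
  j <- c(A = 0.2, B = 0.8)
  expect_equal(switchScore(i, j), 0.4)
  expect_equal(switchScore(i, c(A = 0.9, B = 0.1)), 0)   # same dominant
  expect_equal(switchScore(c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  expect_error(switchScore(i, c(A = 0.5, B = 0.5)), "dominant")
  ## symmetry and range on random usage rows
  set.seed(42)
  for (r in 1:50) {
    u <- c(stats::runif(1, 0.55, 1)); u <- c(u, 1 - u)
    v <- c(stats::runif(1, 0, 0.45)); v <- c(v, 1 - v)
    names(u) <- names(v) <- c("A", "B")
    w1 <- switchScore(u, v); w2 <- switchScore(v, u)
    expect_equal(w1, w2)
    expect_gte(w1, 0); expect_lte(w1, 1)
  }
})

test_that("switch-gene calling recovers exactly the planted gene", {
  truth <- simulateTruth(nGenes = 12, nSwitch = 1, nTissues = 16, seed = 8)
  calls <- callSwitchGenes(truth$tssUsage)
  expect_equal(calls$gene_id[calls$called], truth$planted$switch)
  ## usage 0.9/0.1 flipped gives W = 0.8 for the planted gene
  expect_equal(max(calls$max_w), 0.8)
  ## a W exactly at the threshold is not called (strict inequality);
  ## binary-exact usage values avoid floating-point ambiguity
  u <- matrix(c(0.625, 0.375, 0.3125, 0.6875), 2, 2,
              dimnames = list(c("s1", "s2"), NULL))   # W = 0.3125
  expect_false(callSwitchGenes(list(g = u), wMin = 0.3125)$called)
  expect_true(callSwitchGenes(list(g = u), wMin = 0.31)$called)
})

test_that("weighted 3'UTR length is a usage-weighted mean", {
  expect_equal(weightedUtrLength(c(0.25, 0.75), c(100, 200)), 175)
  expect_equal(weightedUtrLength(1, 150), 150)
  expect_equal(weightedUtrLength(c(0.5, 0.5), c(120, 120)), 120)
  expect_error(weightedUtrLength(c(0.5, 0.5), 100), "length")
  ## permutation invariance and bounds
  set.seed(43)
  for (r in 1:30) {
    n <- sample(2:5, 1)
    u <- stats::rgamma(n, 1); u <- u / sum(u)
    L <- sample(50:500, n)
    lw <- weightedUtrLength(u, L)
    p <- sample(n)
    expect_equal(weightedUtrLength(u[p], L[p]), lw)
    expect_gte(lw, min(L)); expect_lte(lw, max(L))
  }
})

test_that("APA switches need both a length change and expression", {
  u <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  L <- c(100, 287.5)            # deltaLw = 0.8 * 187.5 = 150
  tpmHi <- matrix(c(9, 1, 1, 7), 2, 2)
  expect_true(callApaSwitch(u, L, tpmHi, 1, 2))
  tpmLo <- matrix(c(3, 1, 0.5, 0.5), 2, 2)   # second sample at TPM 1
  expect_false(callApaSwitch(u, L, tpmLo, 1, 2))
  L100 <- c(100, 225)           # deltaLw exactly 100 -> strict, not called
  expect_false(callApaSwitch(u, L100, tpmHi, 1, 2))
})

test_that("planted APA genes are called at 200 nt but not 80 nt shifts", {
  truth <- simulateTruth(nGenes = 10, nApa = 2, apaDelta = c(250, 100),
                         seed = 9)
  res <- logical(2)
  for (k in 1:2) {
    g <- truth$planted$apa[k]
    u <- truth$tesUsage[[g]]
    L <- truth$utr3[[g]]
    tpm <- matrix(10, nrow(u), ncol(u))
    res[k] <- callApaSwitch(u, L, tpm, 1, ncol(u))
  }
  expect_true(res[1])      # deltaLw = 200
  expect_false(res[2])     # deltaLw = 80
})

test_that("dynamics cluster prefilter applies TPM and pruning rules", {
  sig <- mkSignal("five_prime",
                  s1 = list(pos = c(100, 500), count = c(30, 30)),
                  s2 = list(pos = c(100, 500), count = c(30, 2)))
  cs <- mergeAcrossSamples(list(clusterTags(sig, sample = "s1"),
                                clusterTags(sig, sample = "s2",
                                            minValue = 2)), sig)
  out <- dynamicsClusterFilter(cs, tpmMin = 0.5, minTissues = 2,
                               pruneNt = 50)
  expect_lte(length(out), length(cs))
  summits <- clusterSummits(out)
  if (length(summits) > 1)
    expect_true(all(abs(diff(sort(summits))) > 50))
})
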