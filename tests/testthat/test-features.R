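test_that("longest ORF matches hand-checked cases", {
  orf <- findLongestOrf("ATGAAATAG")
  expect_equal(orf$start, 1)
  expect_equal(orf$end, 9)
  expect_equal(orf$aa, 2)
  expect_null(findLongestOrf("CCCCCCTAG"))
  ## a longer ORF downstream wins over a shorter upstream one
  seq2 <- paste0("ATGAAATAG", "T", "ATG", strrep("GCA", 8), "TGA")
  orf2 <- findLongestOrf(seq2)
  expect_equal(orf2$end - orf2$start + 1, 3 + 24 + 3)
  expect_equal(orf2$start, 11)
})

test_that("longest ORF agrees with the brute-force scanner", {
  set.seed(21)
  for (r in 1:200) {
    s <- randomSeq(sample(30:600, 1))
    got <- findLongestOrf(s)
    exp <- oracleLongestOrf(s)
    if (is.null(exp)) expect_null(got)
    else {
      expect_equal(got$end - got$start + 1, exp$len)
      expect_equal(got$start, exp$start)   # 5'-most tie break
    }
  }
})

test_that("microexons are internal exons at or below the threshold", {
  ts <- mkTs(list(
    me51 = mkChain(c(1, 201, 453, 701), c(100, 251, 504, 800)),   # 51 nt
    me52 = mkChain(c(1001, 1201, 1453, 1701), c(1100, 1252, 1504, 1800)),
    term = mkChain(c(2001, 2201), c(2010, 2400))))  # short FIRST exon
  hits <- detectMicroexons(ts, maxLen = 51)
  expect_equal(hits$tx_id, "me51")
  expect_equal(hits$width, 51)
  expect_equal(hits$exon_rank, 2)
  ## a 3 nt internal exon is also a microexon
  ts2 <- mkTs(list(tiny = mkChain(c(1, 201, 301), c(100, 203, 400))))
  expect_equal(detectMicroexons(ts2)$width, 3)
  ## invariance under strand flip
  flip <- mkTs(list(me51 = mkChain(c(1, 201, 453, 701),
                                   c(100, 251, 504, 800), strand = "-")))
  expect_equal(nrow(detectMicroexons(flip)), 1)
})

test_that("site roles split into distal, proximal and coding", {
  ## plus strand gene, CDS starting at genomic 1000
  ch <- mkChain(401, 2000)
  ts <- mkTs(list(t = ch), cds_start = 600L, cds_end = 1500L)
  ## summits at 500, 800 (upstream) and 1200 (inside CDS)
  sig <- mkSignal("five_prime", s1 = list(pos = c(500, 800, 1200),
                                          count = c(30, 30, 30)))
  cs <- clusterTags(sig, maxLength = 5)
  roles <- classifySites(ts, cs)
  expect_equal(roles$role[match(c(500, 800, 1200), roles$summit)],
               c("DT", "PT", "CT"))
  ## exactly one DT whenever a non-CT site exists
  expect_equal(sum(roles$role == "DT"), 1)
  ## single upstream site is DT
  sig1 <- mkSignal("five_prime", s1 = list(pos = 500, count = 30))
  roles1 <- classifySites(ts, clusterTags(sig1))
  expect_equal(roles1$role, "DT")
  expect_error(classifySites(mkTs(list(t = ch)), cs), "CDS")
})

test_that("site roles mirror correctly on the minus strand", {
  ## minus strand: the CDS start codon sits at the genomic RIGHT end
  ch <- mkChain(401, 2000, strand = "-")
  ts <- mkTs(list(t = ch), cds_start = 600L, cds_end = 1500L)
  ## spliced 600 on minus = genomic 2000-600+1 = 1401 (start codon)
  sigM <- mkSignal("five_prime",
                   s1 = list(pos = c(1900, 1600, 1000), count = rep(30, 3),
                             strand = "-"))
  roles <- classifySites(ts, clusterTags(sigM, maxLength = 5))
  expect_equal(roles$role[match(c(1900, 1600, 1000), roles$summit)],
               c("DT", "PT", "CT"))
})

test_that("intronic-terminus coupling events classify as Is or Ic", {
  ## B has an intron [201,400]; A starts inside it
  B <- mkChain(c(1, 401), c(200, 700))
  isA <- mkChain(c(250, 501), c(320, 700))   # first exon inside the intron,
                                             # splices out on its own
  icA <- mkChain(250, 700)                   # runs into B's exon
  ts <- mkTs(list(B = B, isA = isA, icA = icA))
  ev <- detectCouplingEvents(ts)
  expect_true(any(ev$type == "Is" & ev$isoform == "isA" & ev$end == "5p"))
  expect_true(any(ev$type == "Ic" & ev$isoform == "icA" & ev$end == "5p"))
  ## a TSS inside another's exon is no event
  inExon <- mkTs(list(B = B, x = mkChain(c(100, 401), c(200, 700))))
  evX <- detectCouplingEvents(inExon)
  expect_false(any(evX$isoform == "x"))
})

test_that("G-quadruplex scanning enforces tract and loop rules", {
  hit <- scanRg4("GGGGAAGGGGAAGGGGAAGGGG")
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(1, 22))
  expect_equal(nrow(scanRg4("GGGGAGGGGAAGGGGAAGGGG")), 0)   # 1 nt loop
  expect_equal(nrow(scanRg4("GGGAAGGGAAGGGAAGGG")), 0)      # tracts of 3
  set.seed(31)
  for (r in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(40:300, 1),
                      replace = TRUE, prob = c(.2, .15, .5, .15)),
               collapse = "")
    got <- scanRg4(s)
    exp <- oracleRg4(s)
    expect_equal(got[, c("start", "end")], exp,
                 ignore_attr = TRUE)
  }
})

test_that("U-rich element scanning matches its window definition", {
  expect_equal(nrow(scanUrich("UUUUUU")), 1)
  expect_equal(nrow(scanUrich("UAUAUA")), 0)
  expect_equal(nrow(scanUrich("AAAAAAAAAA")), 0)
  set.seed(32)
  for (r in 1:100) {
    s <- paste(sample(c("A", "U", "G", "U"), sample(15:200, 1),
                      replace = TRUE), collapse = "")
    got <- scanUrich(s)
    exp <- oracleUrich(s)
    expect_equal(got[, c("start", "end")], exp[, c("start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("uORF finding requires a contained stop and minimum length", {
  u <- findUorfs("ATGAAATGA")
  expect_equal(nrow(u), 1)
  expect_equal(u$aa, 2)
  expect_equal(nrow(findUorfs("ATGAAAAAA")), 0)   # no stop in the UTR
  two <- findUorfs("ATGAAATGATTTATGCCCTAA")
  expect_equal(nrow(two), 2)
  set.seed(33)
  for (r in 1:100) {
    s <- randomSeq(sample(20:300, 1))
    got <- findUorfs(s)
    exp <- oracleUorfs(s)
    expect_equal(got[, c("start", "end")], exp, ignore_attr = TRUE)
  }
})

test_that("alternative-UTR motif comparison reports gains and losses", {
  a <- "AAATTTTTTTTTTAAA"
  b <- "AAAAAAAACCCCCCCC"
  cmp <- compareUtrMotifs(a, b, scanner = "urich")
  expect_equal(nrow(cmp$gained), 1)
  expect_equal(nrow(cmp$lost), 0)
})
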