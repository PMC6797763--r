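## fixtures for the segment/path machinery: a plus-strand locus
## group [1,1000], TSS summit 50, credible intron [201,400], TES summit 900
mkLocus <- function() {
  group <- mkChain(1, 1000)
  sig5 <- mkSignal("five_prime", s1 = list(pos = 50, count = 30))
  sig3 <- mkSignal("three_prime", s1 = list(pos = 900, count = 30))
  tss <- clusterTags(sig5)
  tes <- clusterTags(sig3)
  jx <- mkJx(201, 400)
  list(group = group, tss = tss, tes = tes, jx = jx)
}

test_that("linkage groups form from windowed signal and read bridging", {
  cov <- mkChain(c(1, 501), c(250, 650))
  g <- findLinkageGroups(GenomicRanges::GRangesList(), cov, window = 100)
  expect_length(g, 2)
  ## adjacent windows merge
  cov2 <- mkChain(c(1, 101), c(90, 180))
  expect_length(findLinkageGroups(GenomicRanges::GRangesList(), cov2,
                                  window = 100), 1)
  ## a read spanning the gap merges the two groups
  bridge <- GenomicRanges::GRangesList(r = mkChain(c(1, 501), c(250, 650)))
  expect_length(findLinkageGroups(bridge, cov, window = 100), 1)
})

test_that("credible junctions require enough reads in enough samples", {
  jx <- mkJx(c(101, 201, 301), c(200, 300, 400),
             counts = matrix(c(5, 2, 0), 3, 1, dimnames = list(NULL, "s1")))
  cred <- callCredibleJunctions(jx, minReads = 3, minSamples = 1)
  expect_equal(cred$donor, 101)
  expect_equal(nrow(callCredibleJunctions(jx, minReads = 1)), 2)
})

test_that("segmentation places element boundaries and labels", {
  fx <- mkLocus()
  seg <- segmentLocus(fx$group, fx$tss, fx$tes, fx$jx)
  expect_equal(seg$start, c(1, 50, 201, 401, 901))
  expect_equal(seg$end, c(49, 200, 400, 900, 1000))
  expect_equal(which(seg$is_tss), 2)
  expect_equal(which(seg$is_tes), 4)
  expect_equal(seg$tss_summit[2], 50)
  expect_equal(seg$tes_summit[4], 900)
  ## no elements -> one unlabelled segment
  seg0 <- segmentLocus(fx$group, NULL, NULL, mkJx(integer(), integer()))
  expect_equal(nrow(seg0), 1)
  expect_false(any(seg0$is_tss | seg0$is_tes))
  ## two junctions sharing a donor contribute set-unique boundaries
  jx2 <- mkJx(c(201, 201), c(400, 600))
  seg2 <- segmentLocus(fx$group, NULL, NULL, jx2)
  expect_equal(seg2$start, c(1, 201, 401, 601))
})

test_that("read projection fills bits, junctions and anchors", {
  fx <- mkLocus()
  seg <- segmentLocus(fx$group, fx$tss, fx$tes, fx$jx)
  ## full-length spliced read: exons [50,200] and [401,900]
  p <- projectRead(mkChain(c(50, 401), c(200, 900)), seg, fx$jx)
  expect_equal(p$bits, c(0L, 1L, 0L, 1L, 0L))
  expect_true(p$five_ok && p$three_ok)
  expect_equal(nrow(p$jx), 1)
  expect_true(p$jx$supported)
  ## unspliced read across everything: no implied junction
  p2 <- projectRead(mkChain(50, 900), seg, fx$jx)
  expect_equal(p2$bits, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(nrow(p2$jx), 0)
  ## a shallow brush over a segment does not set its bit
  p3 <- projectRead(mkChain(c(50, 401), c(240, 900)), seg, fx$jx)
  expect_equal(p3$bits[3], 0L)   # 40/200 of segment 3 covered
  expect_error(projectRead(mkChain(2000, 2100), seg, fx$jx), "no segment")
})

test_that("paths classify into full-length, candidate and conflicted", {
  fx <- mkLocus()
  seg <- segmentLocus(fx$group, fx$tss, fx$tes, fx$jx)
  full <- projectRead(mkChain(c(50, 401), c(200, 900)), seg, fx$jx)
  noTss <- projectRead(mkChain(c(150, 401), c(200, 900)), seg, fx$jx)
  noTss$five_ok <- FALSE          # starts mid-segment without TSS label
  badJx <- projectRead(mkChain(c(50, 395), c(195, 900)), seg, fx$jx)
  cl <- classifyPaths(list(full, noTss, badJx))
  expect_length(cl$isoF, 1)
  expect_length(cl$candidate, 1)
  expect_length(cl$conflicted, 1)
  expect_false(all(cl$conflicted[[1]]$jx$supported))
})

test_that("partial paths complete uniquely against full-length paths", {
  cand <- list(bits = c(0L, 1L, 1L), five_ok = FALSE, three_ok = TRUE)
  isoF <- list(c(1L, 1L, 1L))
  expect_equal(completePartial(cand, isoF, "+"), c(1L, 1L, 1L))
  ## two different completions -> ambiguity -> none
  cand4 <- list(bits = c(0L, 0L, 1L, 1L), five_ok = FALSE, three_ok = TRUE)
  expect_null(completePartial(cand4,
                              list(c(1L, 1L, 1L, 1L), c(0L, 1L, 1L, 1L)),
                              "+"))
  ## no matching isoF
  mism <- list(bits = c(0L, 1L, 0L, 1L), five_ok = FALSE, three_ok = TRUE)
  expect_null(completePartial(mism, list(c(1L, 1L, 1L, 1L)), "+"))
})

test_that("complementary candidates merge when overlaps agree", {
  a <- list(bits = c(1L, 1L, 0L, 0L), five_ok = TRUE, three_ok = FALSE)
  b <- list(bits = c(0L, 1L, 0L, 1L), five_ok = FALSE, three_ok = TRUE)
  m <- mergeComplementary(list(a, b), "+")
  expect_equal(m, list(c(1L, 1L, 0L, 1L)))
  ## conflicting overlap -> no merge
  b2 <- list(bits = c(0L, 0L, 1L, 1L), five_ok = FALSE, three_ok = TRUE)
  expect_length(mergeComplementary(list(a, b2), "+"), 0)
  ## no overlap -> no merge
  a3 <- list(bits = c(1L, 0L, 0L, 0L), five_ok = TRUE, three_ok = FALSE)
  b3 <- list(bits = c(0L, 0L, 0L, 1L), five_ok = FALSE, three_ok = TRUE)
  expect_length(mergeComplementary(list(a3, b3), "+"), 0)
})

test_that("boundary-jitter conflicts are rescued from full-length paths", {
  fx <- mkLocus()
  seg <- segmentLocus(fx$group, fx$tss, fx$tes, fx$jx)
  ## read with a 6 nt jittered donor: bits right, junction unsupported
  jittered <- projectRead(mkChain(c(50, 401), c(194, 900)), seg, fx$jx)
  expect_false(all(jittered$jx$supported))
  isoFbits <- list(c(0L, 1L, 0L, 1L, 0L))
  fixed <- rescueConflict(jittered, isoFbits, seg)
  expect_equal(fixed, c(0L, 1L, 0L, 1L, 0L))
  ## two different local corrections -> none
  fixed2 <- rescueConflict(jittered,
                           list(c(0L, 1L, 0L, 1L, 0L), c(0L, 1L, 1L, 1L, 0L)),
                           seg)
  expect_null(fixed2)
  expect_null(rescueConflict(jittered, list(), seg))
})

test_that("gap filling removes bad junctions and follows coverage", {
  fx <- mkLocus()
  seg <- segmentLocus(fx$group, fx$tss, fx$tes, fx$jx)
  jittered <- projectRead(mkChain(c(50, 401), c(194, 900)), seg, fx$jx)
  ## with the intron uncovered by short reads, the spliced filling wins
  cov <- mkChain(c(50, 401), c(200, 900))
  filled <- fillPartial(jittered, fx$jx, seg, coverage = cov)
  expect_equal(filled, c(0L, 1L, 0L, 1L, 0L))
  ## with the whole region covered, intron retention scores higher
  covAll <- mkChain(50, 900)
  filledAll <- fillPartial(jittered, fx$jx, seg, coverage = covAll)
  expect_equal(filledAll, c(0L, 1L, 1L, 1L, 0L))
  ## no coverage and several consistent fillings -> none
  expect_null(fillPartial(jittered, fx$jx, seg))
})

test_that("duplicate reads collapse to one record", {
  fx <- mkLocus()
  reads <- GenomicRanges::GRangesList(
    r1 = mkChain(c(50, 401), c(200, 900)),
    r2 = mkChain(c(50, 401), c(200, 900)))
  out <- assembleLocus(fx$group, fx$tss, fx$tes, fx$jx, reads)
  expect_length(out, 1)
  expect_equal(txClass(out), "isoF")
  expect_equal(txData(out)$tss_summit, 50L)
  expect_equal(txData(out)$tes_summit, 900L)
})

test_that("a noise-free simulated genome is reconstructed exactly", {
  truth <- simulateTruth(nGenes = 8, maxIsoforms = 6, seed = 42)
  lr <- simulateLongReads(truth, depth = 8, seed = 43)
  tj <- simulateTagsAndJunctions(truth, seed = 44)
  rel5 <- filterReliable(clusterTags(tj$sig5), tj$sig5)
  rel3 <- filterReliable(clusterTags(tj$sig3), tj$sig3)
  asm <- assembleTranscripts(lr$reads, rel5, rel3, tj$junctions,
                             tj$sig5, tj$sig3, coverage = tj$coverage)
  expect_true(all(txClass(asm) == "isoF"))
  expressed <- unique(lr$info$tx_id)
  tk <- vapply(as.list(exonChains(truth$transcripts)[expressed]),
               chainKey, character(1))
  ak <- vapply(as.list(exonChains(asm)), chainKey, character(1))
  expect_setequal(unname(ak), unname(tk))
  ## terminal exon ends sit on the true summits
  expect_false(anyNA(txData(asm)$tss_summit))
  expect_false(anyNA(txData(asm)$tes_summit))
  ## determinism: a rerun gives identical output
  asm2 <- assembleTranscripts(lr$reads, rel5, rel3, tj$junctions,
                              tj$sig5, tj$sig3, coverage = tj$coverage)
  expect_identical(txData(asm), txData(asm2))
  expect_equal(vapply(as.list(exonChains(asm2)), chainKey, character(1)), ak)
})

test_that("truncated reads complete against full-length paths", {
  fx <- mkLocus()
  reads <- GenomicRanges::GRangesList(
    full = mkChain(c(50, 401), c(200, 900)),
    trunc = mkChain(c(150, 401), c(200, 900)))   # 5' truncated
  out <- assembleLocus(fx$group, fx$tss, fx$tes, fx$jx, reads)
  ## the truncated read completes to the same chain and collapses into
  ## the full-length record
  expect_length(out, 1)
  expect_equal(txClass(out), "isoF")
  ## without the full-length read the candidate cannot complete
  out2 <- assembleLocus(fx$group, fx$tss, fx$tes, fx$jx,
                        GenomicRanges::GRangesList(
                          trunc = mkChain(c(150, 401), c(200, 900))))
  expect_length(out2, 0)
})

test_that("every emitted junction is credible", {
  truth <- simulateTruth(nGenes = 10, maxIsoforms = 8, seed = 77)
  lr <- simulateLongReads(truth, depth = 6,
                          err = list(boundary_jitter_rate = 0.15,
                                     truncation_5p_rate = 0.25), seed = 78)
  tj <- simulateTagsAndJunctions(truth, seed = 79)
  rel5 <- filterReliable(clusterTags(tj$sig5), tj$sig5)
  rel3 <- filterReliable(clusterTags(tj$sig3), tj$sig3)
  asm <- assembleTranscripts(lr$reads, rel5, rel3, tj$junctions,
                             tj$sig5, tj$sig3, coverage = tj$coverage)
  cred <- callCredibleJunctions(tj$junctions)
  credKey <- paste(cred$strand, cred$donor, cred$acceptor)
  for (i in seq_along(asm)) {
    g <- exonChains(asm)[[i]]
    intr <- intronsOf(g)
    if (length(intr) == 0) next
    k <- paste(as.character(BiocGenerics::strand(g))[1],
               BiocGenerics::start(intr), BiocGenerics::end(intr))
    expect_true(all(k %in% credKey))
  }
})
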