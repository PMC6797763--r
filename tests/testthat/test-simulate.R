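test_that("truth simulation is deterministic and sized as requested", {
  t1 <- simulateTruth(nGenes = 6, seed = 4)
  t2 <- simulateTruth(nGenes = 6, seed = 4)
  expect_equal(length(unique(geneIds(t1$transcripts))), 6)
  expect_identical(as.data.frame(txData(t1$transcripts)),
                   as.data.frame(txData(t2$transcripts)))
  expect_equal(BiocGenerics::start(exonChains(t1$transcripts)),
               BiocGenerics::start(exonChains(t2$transcripts)))
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  t3 <- simulateTruth(nGenes = 6, seed = 5)
  expect_false(identical(as.character(t1$genome), as.character(t3$genome)))
})

test_that("planted features are registered for recall scoring", {
  truth <- simulateTruth(nGenes = 12, nSwitch = 2, nApa = 1, nMicroexon = 2,
                         nHotspot = 1, nPolycistron = 1,
                         nTissueSpecific = 2, seed = 6)
  expect_length(truth$planted$switch, 2)
  expect_length(truth$planted$apa, 1)
  expect_length(truth$planted$microexon, 2)
  expect_length(truth$planted$hotspot, 1)
  expect_length(truth$planted$polycistron, 1)
  expect_length(truth$planted$tissueSpecific, 2)
  ## microexon genes really contain an internal exon <= 51 nt
  me <- detectMicroexons(truth$transcripts)
  meGenes <- unique(geneIds(truth$transcripts)[
    match(me$tx_id, txIds(truth$transcripts))])
  expect_true(all(truth$planted$microexon %in% meGenes))
  ## hotspot genes carry 8 isoforms
  hs <- truth$planted$hotspot
  expect_equal(sum(geneIds(truth$transcripts) == hs), 8)
  ## single-tissue genes reach the maximal specificity score
  for (g in truth$planted$tissueSpecific)
    expect_equal(tissueSpecificity(truth$geneExpr[g, ]),
                 log2(truth$params$nTissues))
  expect_error(simulateTruth(nGenes = 2, nSwitch = 3), "more planted")
})

test_that("error-free reads reproduce the true exon chains", {
  truth <- simulateTruth(nGenes = 5, seed = 7)
  lr <- simulateLongReads(truth, depth = 5, seed = 8)
  expect_gt(length(lr$reads), 0)
  truthKeys <- vapply(as.list(exonChains(truth$transcripts)), chainKey,
                      character(1))
  names(truthKeys) <- txIds(truth$transcripts)
  for (i in seq_len(min(length(lr$reads), 50))) {
    expect_equal(chainKey(lr$reads[[i]]),
                 unname(truthKeys[lr$info$tx_id[i]]))
  }
  ## same seed, same reads
  lr2 <- simulateLongReads(truth, depth = 5, seed = 8)
  expect_identical(lr$info, lr2$info)
})

test_that("full 5'-truncation leaves no read starting at its true start", {
  truth <- simulateTruth(nGenes = 5, seed = 9)
  lr <- simulateLongReads(truth, depth = 5,
                          err = list(truncation_5p_rate = 1), seed = 10)
  ends5 <- isoforge:::txEnds(truth$transcripts)
  for (i in seq_along(lr$reads)) {
    g <- lr$reads[[i]]
    strand <- as.character(BiocGenerics::strand(g))[1]
    read5 <- if (strand == "-") max(BiocGenerics::end(g))
             else min(BiocGenerics::start(g))
    true5 <- ends5$five[match(lr$info$tx_id[i], ends5$tx_id)]
    expect_false(read5 == true5)
  }
})

test_that("tag signal lands on true sites and splits usage as planted", {
  truth <- simulateTruth(nGenes = 6, nSwitch = 1, seed = 11)
  tj <- simulateTagsAndJunctions(truth, spread = 0, seed = 12)
  ends <- isoforge:::txEnds(truth$transcripts)
  expect_true(all(tj$sig5@tags$pos %in% ends$five))
  expect_true(all(tj$sig3@tags$pos %in% ends$three))
  ## switch gene: usage mass ratio between its two sites ~ 9:1 per tissue
  g <- truth$planted$switch
  u <- truth$tssUsage[[g]]
  expect_equal(dim(u)[1], 2)
  expect_true(all(abs(colSums(u) - 1) < 1e-12))
  expect_setequal(round(as.vector(u), 1), c(0.9, 0.1))
  ## junction counts scale with abundance and are credible for all introns
  cred <- callCredibleJunctions(tj$junctions)
  allIntrons <- unique(unlist(lapply(
    as.list(exonChains(truth$transcripts)), function(ch) {
      i <- intronsOf(ch)
      if (length(i)) paste(BiocGenerics::start(i), BiocGenerics::end(i))
    })))
  expect_true(all(allIntrons %in% paste(cred$donor, cred$acceptor)))
})

test_that("zero depth produces empty tracks", {
  truth <- simulateTruth(nGenes = 3, seed = 13)
  tj <- simulateTagsAndJunctions(truth, tagDepth = 0, jxDepth = 0, seed = 14)
  expect_equal(nrow(tj$sig5@tags), 0)
  expect_equal(nrow(tj$sig3@tags), 0)
})

test_that("expression noise scales as requested", {
  truth <- simulateTruth(nGenes = 8, seed = 15)
  e0 <- simulateExpression(truth, noiseCv = 0, seed = 16)
  expect_equal(e0, truth$geneExpr)
  e1 <- simulateExpression(truth, noiseCv = 0.3, seed = 16)
  expect_false(identical(e1, truth$geneExpr))
  expect_true(all(e1 >= 0))
  expect_error(simulateExpression(truth, noiseCv = -1), "noiseCv")
})

test_that("simulated files round-trip through the readers", {
  truth <- simulateTruth(nGenes = 4, seed = 17)
  lr <- simulateLongReads(truth, depth = 3, seed = 18)
  tj <- simulateTagsAndJunctions(truth, seed = 19)
  dir <- tempfile(); dir.create(dir)
  ## reads as BED12
  bed <- file.path(dir, "reads.bed")
  writeBed12(lr$reads, bed)
  back <- readBed12(bed)
  expect_equal(length(back), length(lr$reads))
  expect_equal(chainKey(back[[1]]), chainKey(lr$reads[[1]]))
  ## tag signal as bedGraph
  man <- writeTagSignal(tj$sig5, dir, prefix = "cage")
  sig <- readTagSignal(man$path, man$sample, man$strand, "five_prime")
  expect_equal(sum(sig@tags$count), sum(tj$sig5@tags$count))
  ## junctions as TSV
  jf <- file.path(dir, "jx.tsv")
  writeJunctionTable(tj$junctions, jf)
  jx <- readJunctionTable(jf)
  expect_equal(nrow(jx), nrow(tj$junctions))
  ## truth annotation as GFF3
  gf <- file.path(dir, "truth.gff3")
  writeTranscripts(truth$transcripts, gf)
  ts <- readTranscripts(gf)
  expect_equal(length(ts), length(truth$transcripts))
  ## genome as FASTA
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(truth$genome, fa)
  genome <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(genome[[1]]), as.character(truth$genome[[1]]))
})
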