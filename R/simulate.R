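## Ground-truth simulator: emits a genome, a true isoform annotation with
## per-tissue abundances and terminal-site usage, and every input the
## pipeline consumes (long reads, 5'/3' tag tracks, junction tables,
## expression matrices), with controllable error processes.

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

## random coding sequence: ATG + (nCodon-1) non-stop codons + stop
.randCds <- function(nCodon) {
  bases <- c("A", "C", "G", "T")
  codons <- character(nCodon - 1L)
  k <- 1L
  while (k <= nCodon - 1L) {
    cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
    if (!(cd %in% .STOPS) && cd != "ATG") { codons[k] <- cd; k <- k + 1L }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(.STOPS, 1L))
}

## overwrite genome sequence so that the spliced sequence of `chain`
## carries `seqStr` starting at spliced position `from`
.writeSplicedSeq <- function(chromSeq, chain, from, seqStr) {
  pieces <- splicedToGenomic(chain, from, from + nchar(seqStr) - 1L)
  strand <- as.character(BiocGenerics::strand(chain))[1L]
  ## pieces come in transcript order; walk them accumulating the payload
  off <- 0L
  for (i in seq_along(pieces)) {
    w <- BiocGenerics::width(pieces)[i]
    sub <- substring(seqStr, off + 1L, off + w)
    if (strand == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    chromSeq <- Biostrings::replaceAt(
      chromSeq, IRanges::IRanges(BiocGenerics::start(pieces)[i],
                                 BiocGenerics::end(pieces)[i]), sub)
    off <- off + w
  }
  chromSeq
}

#' Simulate a ground-truth gene set
#'
#' Lays out non-overlapping genes along one synthetic chromosome,
#' generates isoforms by internal-exon skipping, optionally plants
#' feature genes (promoter-switch, alternative-polyadenylation,
#' microexon, splicing-hotspot, polycistron, tissue-specific), writes
#' coding sequence into the genome, and draws per-tissue isoform
#' abundances. Planted features are registered for recall scoring.
#'
#' Planted structure: switch genes carry two transcription start sites
#' more than 500 nt apart with usage 0.9/0.1 flipped between the two
#' tissue halves; APA genes carry two termination sites on the last exon
#' separated by \code{apaDelta} nt with the same usage flip (a 0.9/0.1
#' flip turns a site separation of d into a weighted-3'UTR change of
#' 0.8 d); hotspot genes hold 8 isoforms diversified over a window of 3
#' internal exons; polycistron genes carry two >= 120-codon ORFs in one
#' transcript; microexon genes contain one internal exon of at most
#' 51 nt.
#'
#' @param nGenes total gene count (default 50).
#' @param maxIsoforms cap on isoforms per gene (default 10).
#' @param nTissues tissue count (default 16).
#' @param nSwitch,nApa,nMicroexon,nHotspot,nPolycistron,nTissueSpecific
#'   planted feature gene counts (defaults 0).
#' @param apaDelta termination-site separations (nt) recycled over the
#'   APA genes (default c(250, 100)).
#' @param exonCount,exonLen,intronLen,gapLen integer ranges (min, max)
#'   for the gene skeletons.
#' @param plantCds write a coding sequence into each non-polycistron
#'   gene (default TRUE).
#' @param seed RNG seed.
#' @return list of class "isoforgeTruth": genome (DNAStringSet),
#'   transcripts (TranscriptSet), abundance (isoform x tissue matrix),
#'   geneExpr (gene x tissue), tssSites/tesSites (per-gene site tables),
#'   tssUsage/tesUsage (per-gene site x tissue usage), utr3 (per-gene
#'   per-site 3'UTR lengths), planted (registry), params.
#' @export
simulateTruth <- function(nGenes = 50, maxIsoforms = 10, nTissues = 16,
                          nSwitch = 0, nApa = 0, nMicroexon = 0,
                          nHotspot = 0, nPolycistron = 0,
                          nTissueSpecific = 0, apaDelta = c(250, 100),
                          exonCount = c(3, 8), exonLen = c(100, 300),
                          intronLen = c(80, 250), gapLen = c(1500, 2500),
                          plantCds = TRUE, seed = 1) {
  set.seed(seed)
  nPlanted <- nSwitch + nApa + nMicroexon + nHotspot + nPolycistron
  if (nPlanted + nTissueSpecific > nGenes)
    stop("more planted genes than genes")
  if (exonLen[1L] < 20 || intronLen[1L] < 20)
    stop("exons and introns must be at least 20 nt")
  if (exonLen[2L] > gapLen[1L])
    stop("infeasible: exons longer than the intergenic gap")
  kind <- rep("plain", nGenes)
  idx <- 1L
  for (k in c(rep("switch", nSwitch), rep("apa", nApa),
              rep("microexon", nMicroexon), rep("hotspot", nHotspot),
              rep("polycistron", nPolycistron))) {
    kind[idx] <- k; idx <- idx + 1L
  }
  tsGenes <- if (nTissueSpecific > 0)
    seq(nPlanted + 1L, nPlanted + nTissueSpecific) else integer(0)
  cursor <- 1000L
  chains <- list(); meta <- list()
  geneInfo <- list()
  for (g in seq_len(nGenes)) {
    gid <- sprintf("g%03d", g)
    strand <- sample(c("+", "-"), 1L)
    kd <- kind[g]
    nEx <- switch(kd,
                  hotspot = max(7L, sample(seq(exonCount[1L], exonCount[2L]), 1L)),
                  polycistron = 3L,
                  sample(seq(exonCount[1L], exonCount[2L]), 1L))
    ew <- sample(seq(exonLen[1L], exonLen[2L]), nEx, replace = TRUE)
    iw <- sample(seq(intronLen[1L], intronLen[2L]), max(nEx - 1L, 0L),
                 replace = TRUE)
    if (kd == "switch") {            # 5'-terminal exon + intron > 500 nt
      if (strand == "-") {
        ew[nEx] <- max(ew[nEx], 260L); iw[nEx - 1L] <- max(iw[nEx - 1L], 300L)
      } else {
        ew[1L] <- max(ew[1L], 260L); iw[1L] <- max(iw[1L], 300L)
      }
    }
    if (kd == "apa") {               # 3'-terminal exon long enough to trim
      dNext <- as.integer(max(apaDelta))
      if (strand == "-") ew[1L] <- max(ew[1L], dNext + 120L)
      else ew[nEx] <- max(ew[nEx], dNext + 120L)
    }
    if (kd == "microexon") {
      internal <- 2:(nEx - 1L)
      me <- internal[sample.int(length(internal), 1L)]
      ew[me] <- sample(10:51, 1L)
    }
    if (kd == "polycistron") ew <- sample(500:700, nEx, replace = TRUE)
    starts <- cursor + cumsum(c(0L, utils::head(ew, -1L) + iw))
    ends <- starts + ew - 1L
    skeleton <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                                       strand = strand)
    ## isoform definitions as exon index sets (plus terminal tweaks)
    iso <- list(full = seq_len(nEx))
    if (kd == "switch") {
      ## the alternative start drops the 5'-terminal exon (strand-aware)
      iso <- if (strand == "-")
        list(tss1 = seq_len(nEx), tss2 = seq_len(nEx - 1L))
      else list(tss1 = seq_len(nEx), tss2 = seq(2L, nEx))
    } else if (kd == "apa") {
      iso <- list(tesLong = seq_len(nEx), tesShort = seq_len(nEx))
    } else if (kd == "hotspot") {
      win <- 3:5
      iso <- lapply(0:7, function(m) {
        drop <- win[as.logical(intToBits(m)[1:3])]
        setdiff(seq_len(nEx), drop)
      })
      names(iso) <- paste0("h", 1:8)
    } else if (kd %in% c("plain", "microexon") && nEx >= 3L) {
      nIso <- sample.int(min(maxIsoforms, 2^(nEx - 2L)), 1L)
      if (kd == "microexon") nIso <- max(nIso, 2L)
      seen <- list(seq_len(nEx))
      internal <- 2:(nEx - 1L)
      while (length(seen) < nIso) {
        drop <- internal[sample.int(length(internal),
                                    sample.int(length(internal), 1L))]
        cand <- setdiff(seq_len(nEx), sort(drop))
        if (kd == "microexon" && length(seen) == 1L)
          cand <- setdiff(seq_len(nEx), me)   # one isoform skips the ME
        if (!any(vapply(seen, identical, logical(1), y = cand)))
          seen[[length(seen) + 1L]] <- cand
      }
      iso <- seen
      names(iso) <- paste0("i", seq_along(iso))
    }
    if (is.null(names(iso)) || any(names(iso) == ""))
      names(iso) <- paste0("i", seq_along(iso))
    apaD <- 0L
    if (kd == "apa") {
      apaD <- as.integer(apaDelta[((sum(kind[seq_len(g)] == "apa") - 1L) %%
                                     length(apaDelta)) + 1L])
    }
    for (k in seq_along(iso)) {
      gch <- skeleton[iso[[k]]]
      if (kd == "apa" && names(iso)[k] == "tesShort") {
        ## shorten the 3'-terminal exon by apaD
        if (strand == "-") {
          BiocGenerics::start(gch)[1L] <- BiocGenerics::start(gch)[1L] + apaD
        } else {
          n <- length(gch)
          BiocGenerics::end(gch)[n] <- BiocGenerics::end(gch)[n] - apaD
        }
      }
      chains[[length(chains) + 1L]] <- gch
      meta[[length(meta) + 1L]] <- data.frame(
        tx_id = paste0(gid, ".", names(iso)[k]), gene_id = gid,
        stringsAsFactors = FALSE)
    }
    geneInfo[[gid]] <- list(kind = kd, strand = strand, skeleton = skeleton,
                            iso = iso, apaDelta = apaD,
                            microexon = if (kd == "microexon") me else NA)
    cursor <- ends[nEx] + sample(seq(gapLen[1L], gapLen[2L]), 1L)
  }
  md <- do.call(rbind, meta)
  grl <- GenomicRanges::GRangesList(chains)
  names(grl) <- md$tx_id
  ts <- TranscriptSet(grl, gene_id = md$gene_id)
  ## genome
  genomeLen <- cursor + 1000L
  genome <- Biostrings::DNAStringSet(.randSeq(genomeLen))
  names(genome) <- "chr1"
  ## abundances: per gene base level, per-isoform usage, tissue pattern
  txPerGene <- split(seq_len(nrow(md)), md$gene_id)
  tissues <- sprintf("t%02d", seq_len(nTissues))
  abund <- matrix(0, nrow(md), nTissues,
                  dimnames = list(md$tx_id, tissues))
  halfA <- seq_len(floor(nTissues / 2))
  halfB <- setdiff(seq_len(nTissues), halfA)
  for (g in seq_len(nGenes)) {
    gid <- sprintf("g%03d", g)
    rows <- txPerGene[[gid]]
    base <- exp(stats::rnorm(1L, log(50), 0.4))
    tissueLevel <- rep(base, nTissues)
    if (g %in% tsGenes) {
      tissueLevel <- rep(0, nTissues)
      tissueLevel[sample.int(nTissues, 1L)] <- base * 5
      geneInfo[[gid]]$kind <- "tissueSpecific"
    }
    kd <- geneInfo[[gid]]$kind
    if (kd %in% c("switch", "apa")) {
      usage <- matrix(0, 2L, nTissues)
      usage[1L, halfA] <- 0.9; usage[2L, halfA] <- 0.1
      usage[1L, halfB] <- 0.1; usage[2L, halfB] <- 0.9
      abund[rows, ] <- usage * rep(tissueLevel, each = 2L)
    } else {
      w <- stats::rgamma(length(rows), shape = 4, rate = 1)
      w <- w / sum(w)
      w <- pmax(w, 0.08)          # every isoform detectably expressed
      w <- w / sum(w)
      abund[rows, ] <- outer(w, tissueLevel)
    }
  }
  ## plant coding sequence
  chrom <- genome[[1L]]
  polyCds <- list()
  for (g in seq_len(nGenes)) {
    gid <- sprintf("g%03d", g)
    info <- geneInfo[[gid]]
    primary <- txPerGene[[gid]][1L]
    if (info$kind == "apa") {
      ## plant on the short isoform so both isoforms share the full ORF
      short <- which(md$gene_id == gid &
                     grepl("tesShort$", md$tx_id))
      primary <- short
    }
    chain <- grl[[primary]]
    sl <- sum(BiocGenerics::width(chain))
    if (info$kind == "polycistron") {
      n1 <- 130L; n2 <- 130L
      gap <- 60L
      utr5 <- 100L
      need <- utr5 + 3L * (n1 + 1L) + gap + 3L * (n2 + 1L)
      if (need + 50L > sl) next
      cds1 <- .randCds(n1 + 1L)
      cds2 <- .randCds(n2 + 1L)
      chrom <- .writeSplicedSeq(chrom, chain, utr5 + 1L, cds1)
      chrom <- .writeSplicedSeq(chrom, chain,
                                utr5 + nchar(cds1) + gap + 1L, cds2)
      polyCds[[gid]] <- data.frame(
        start = c(utr5 + 1L, utr5 + nchar(cds1) + gap + 1L),
        end = c(utr5 + nchar(cds1), utr5 + nchar(cds1) + gap + nchar(cds2)),
        aa = c(n1, n2))
    } else if (plantCds) {
      utr5 <- min(120L, max(30L, sl %/% 6L))
      utr3 <- min(200L, max(30L, sl %/% 5L))
      nCodon <- (sl - utr5 - utr3) %/% 3L
      if (nCodon < 30L) next
      cds <- .randCds(nCodon)
      chrom <- .writeSplicedSeq(chrom, chain, utr5 + 1L, cds)
      geneInfo[[gid]]$cds <- c(utr5 + 1L, utr5 + nchar(cds))
    }
  }
  genome[[1L]] <- chrom
  ## terminal sites and usage
  ends <- txEnds(ts)
  tssSites <- list(); tesSites <- list()
  tssUsage <- list(); tesUsage <- list()
  utr3 <- list()
  for (g in seq_len(nGenes)) {
    gid <- sprintf("g%03d", g)
    rows <- txPerGene[[gid]]
    fives <- ends$five[rows]; threes <- ends$three[rows]
    us <- abund[rows, , drop = FALSE]
    siteUsage <- function(pos) {
      sites <- sort(unique(pos))
      m <- t(vapply(sites, function(s)
        colSums(us[pos == s, , drop = FALSE]), numeric(nTissues)))
      rownames(m) <- as.character(sites)
      usageFractions(m)
    }
    tssSites[[gid]] <- sort(unique(fives))
    tesSites[[gid]] <- sort(unique(threes))
    tssUsage[[gid]] <- siteUsage(fives)
    tesUsage[[gid]] <- siteUsage(threes)
    ## 3'UTR length per termination site, from the planted CDS when known
    cds <- geneInfo[[gid]]$cds
    u3 <- vapply(sort(unique(threes)), function(s) {
      i <- rows[match(s, threes)]
      sl <- sum(BiocGenerics::width(grl[[i]]))
      if (!is.null(cds)) max(0L, sl - cds[2L]) else NA_integer_
    }, numeric(1))
    names(u3) <- as.character(sort(unique(threes)))
    utr3[[gid]] <- u3
  }
  geneExpr <- t(vapply(txPerGene, function(r)
    colSums(abund[r, , drop = FALSE]), numeric(nTissues)))
  planted <- list(
    switch = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "switch", logical(1))],
    apa = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "apa", logical(1))],
    microexon = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "microexon", logical(1))],
    hotspot = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "hotspot", logical(1))],
    polycistron = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "polycistron", logical(1))],
    tissueSpecific = names(geneInfo)[vapply(geneInfo, function(i)
      i$kind == "tissueSpecific", logical(1))],
    polycistronCds = polyCds)
  structure(list(genome = genome, transcripts = ts, abundance = abund,
                 geneExpr = geneExpr, tssSites = tssSites,
                 tesSites = tesSites, tssUsage = tssUsage,
                 tesUsage = tesUsage, utr3 = utr3, geneInfo = geneInfo,
                 planted = planted, tissues = tissues,
                 params = list(nGenes = nGenes, maxIsoforms = maxIsoforms,
                               nTissues = nTissues, seed = seed)),
            class = "isoforgeTruth")
}

#' @export
print.isoforgeTruth <- function(x, ...) {
  cat("isoforgeTruth:", x$params$nGenes, "genes,",
      length(x$transcripts), "isoforms,", x$params$nTissues, "tissues\n")
  pl <- vapply(x$planted[setdiff(names(x$planted), "polycistronCds")],
               length, integer(1))
  pl <- pl[pl > 0]
  if (length(pl))
    cat("  planted:", paste(names(pl), pl, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Simulate long reads from a truth set
#'
#' Reads are sampled per isoform proportional to pooled abundance. Error
#' processes (per-read probabilities): boundary jitter shifts one
#' junction edge by 1-10 nt; a bubble inserts a spurious 20-60 nt intron
#' inside an exon; 5' truncation removes a spliced prefix ending inside
#' an exon.
#'
#' @param truth from \code{\link{simulateTruth}}.
#' @param depth expected reads per average-abundance isoform (default 8).
#' @param err list(boundary_jitter_rate, bubble_rate, truncation_5p_rate).
#' @param seed RNG seed.
#' @return list(reads = GRangesList named by read id, info = per-read
#'   data.frame(read_id, tx_id, jitter, bubble, truncated)).
#' @export
simulateLongReads <- function(truth, depth = 8,
                              err = list(boundary_jitter_rate = 0,
                                         bubble_rate = 0,
                                         truncation_5p_rate = 0),
                              seed = 1) {
  set.seed(seed)
  rates <- c(err$boundary_jitter_rate %||% 0, err$bubble_rate %||% 0,
             err$truncation_5p_rate %||% 0)
  if (any(rates < 0 | rates > 1)) stop("error rates must be in [0,1]")
  grl <- exonChains(truth$transcripts)
  txStarts <- as.list(BiocGenerics::start(grl))
  txEnds_ <- as.list(BiocGenerics::end(grl))
  txStrand <- vapply(seq_along(grl), function(i)
    as.character(BiocGenerics::strand(grl[[i]]))[1L], character(1))
  pooled <- rowSums(truth$abundance)
  rel <- pooled / mean(pooled)
  n <- stats::rpois(length(grl), depth * rel)
  exRows <- list(); info <- list()
  rid <- 0L
  for (i in seq_along(grl)) {
    for (r in seq_len(n[i])) {
      es <- txStarts[[i]]; ee <- txEnds_[[i]]
      strand <- txStrand[i]
      jit <- stats::runif(1) < rates[1L] && length(es) >= 2L
      bub <- stats::runif(1) < rates[2L] && any(ee - es + 1L >= 80L)
      trunc <- stats::runif(1) < rates[3L]
      if (jit) {
        j <- sample.int(length(es) - 1L, 1L)    # intron index
        delta <- sample(1:10, 1L) * sample(c(-1L, 1L), 1L)
        if (stats::runif(1) < 0.5) {            # shift donor-side exon end
          newEnd <- ee[j] + delta
          if (newEnd > es[j] && newEnd < es[j + 1L] - 5L) ee[j] <- newEnd
        } else {                                # shift acceptor-side start
          newStart <- es[j + 1L] + delta
          if (newStart < ee[j + 1L] && newStart > ee[j] + 5L)
            es[j + 1L] <- newStart
        }
      }
      if (bub) {
        cand <- which(ee - es + 1L >= 80L)
        e <- cand[sample.int(length(cand), 1L)]
        iw <- sample(20:60, 1L)
        s0 <- es[e]; e0 <- ee[e]
        bs <- s0 + sample.int(e0 - s0 - iw - 10L, 1L) + 4L
        es <- c(es[seq_len(e - 1L)], s0, bs + iw,
                if (e < length(es)) es[seq(e + 1L, length(es))])
        ee <- c(ee[seq_len(e - 1L)], bs - 1L, e0,
                if (e < length(ee)) ee[seq(e + 1L, length(ee))])
      }
      if (trunc) {
        w <- ee - es + 1L
        L <- sum(w)
        if (L > 60L) {
          u <- sample(seq(15L, max(16L, L %/% 2L)), 1L) # spliced cut
          ord <- if (strand == "-") rev(seq_along(es)) else seq_along(es)
          cum <- cumsum(w[ord])
          cutExon <- which(cum > u)[1L]
          keepIdx <- sort(ord[seq(cutExon, length(ord))])
          into <- u - c(0L, cum)[cutExon]       # bases removed in cut exon
          es2 <- es[keepIdx]; ee2 <- ee[keepIdx]
          if (strand == "-") ee2[length(ee2)] <- ee2[length(ee2)] - into
          else es2[1L] <- es2[1L] + into
          if (all(ee2 - es2 >= 0L)) { es <- es2; ee <- ee2 }
        }
      }
      rid <- rid + 1L
      exRows[[rid]] <- data.frame(read = rid, start = es, end = ee,
                                  strand = strand)
      info[[rid]] <- data.frame(read_id = sprintf("r%06d", rid),
                                tx_id = names(grl)[i], jitter = jit,
                                bubble = bub, truncated = trunc)
    }
  }
  if (rid == 0L)
    return(list(reads = GenomicRanges::GRangesList(),
                info = data.frame(read_id = character(),
                                  tx_id = character(), jitter = logical(),
                                  bubble = logical(), truncated = logical())))
  inf <- do.call(rbind, info)
  ex <- do.call(rbind, exRows)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  out <- GenomicRanges::split(gr, factor(ex$read, levels = seq_len(rid)))
  names(out) <- inf$read_id
  list(reads = out, info = inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate tag signal and junction support from a truth set
#'
#' 5' and 3' tags are drawn around the true terminal sites of each
#' isoform, scaled by per-tissue abundance, with geometric positional
#' noise of the given spread (spread 0 places every tag exactly on the
#' site). Junction counts are proportional to the summed abundance of
#' isoforms carrying the junction. Short-read exonic coverage of
#' expressed isoforms is returned alongside.
#'
#' @param truth from \code{\link{simulateTruth}}.
#' @param tagDepth expected tags per unit abundance (default 1.2; a site
#'   at the median gene level of ~50 then receives ~60 tags per tissue).
#' @param spread geometric positional noise parameter in nt (default 0).
#' @param jxDepth junction reads per unit abundance (default 4).
#' @param seed RNG seed.
#' @return list(sig5, sig3 = TagSignal, junctions = DataFrame,
#'   coverage = GRanges).
#' @export
simulateTagsAndJunctions <- function(truth, tagDepth = 1.2, spread = 0,
                                     jxDepth = 4, seed = 1) {
  if (spread < 0) stop("spread must be >= 0")
  set.seed(seed)
  ts <- truth$transcripts
  grl <- exonChains(ts)
  ends <- txEnds(ts)
  tissues <- truth$tissues
  tagRows <- list()
  emit <- function(pos, strand, sample, count, outward) {
    if (count <= 0) return(NULL)
    if (spread == 0) {
      data.frame(chrom = "chr1", pos = pos, strand = strand,
                 sample = sample, count = count)
    } else {
      shift <- stats::rgeom(count, 1 / (1 + spread)) *
        sample(c(-1L, 1L), count, replace = TRUE)
      tb <- table(pos + shift)
      data.frame(chrom = "chr1", pos = as.integer(names(tb)),
                 strand = strand, sample = sample,
                 count = as.numeric(tb))
    }
  }
  rows5 <- list(); rows3 <- list()
  for (i in seq_along(grl)) {
    strand <- ends$strand[i]
    for (s in seq_along(tissues)) {
      a <- truth$abundance[i, s]
      c5 <- stats::rpois(1L, tagDepth * a)
      c3 <- stats::rpois(1L, tagDepth * a)
      r5 <- emit(ends$five[i], strand, tissues[s], c5)
      r3 <- emit(ends$three[i], strand, tissues[s], c3)
      if (!is.null(r5)) rows5[[length(rows5) + 1L]] <- r5
      if (!is.null(r3)) rows3[[length(rows3) + 1L]] <- r3
    }
  }
  mk <- function(rows, end) {
    tg <- if (length(rows)) do.call(rbind, rows)
          else data.frame(chrom = character(), pos = integer(),
                          strand = character(), sample = character(),
                          count = numeric())
    TagSignal(end, tg)
  }
  sig5 <- mk(rows5, "five_prime")
  sig3 <- mk(rows3, "three_prime")
  ## junctions
  jrows <- list()
  for (i in seq_along(grl)) {
    intr <- intronsOf(grl[[i]])
    if (length(intr) == 0L) next
    for (k in seq_along(intr)) {
      jrows[[length(jrows) + 1L]] <- data.frame(
        tx = i, donor = BiocGenerics::start(intr)[k],
        acceptor = BiocGenerics::end(intr)[k],
        strand = ends$strand[i])
    }
  }
  if (length(jrows)) {
    jd <- do.call(rbind, jrows)
    key <- paste(jd$donor, jd$acceptor, jd$strand)
    uk <- !duplicated(key)
    counts <- t(vapply(which(uk), function(r) {
      members <- jd$tx[key == key[r]]
      vapply(seq_along(tissues), function(s)
        stats::rpois(1L, jxDepth *
                       sum(truth$abundance[members, s])), numeric(1))
    }, numeric(length(tissues))))
    colnames(counts) <- tissues
    jx <- junctionSet(rep("chr1", sum(uk)), jd$donor[uk], jd$acceptor[uk],
                      jd$strand[uk], counts)
  } else {
    jx <- junctionSet(character(), integer(), integer(), character(),
                      matrix(numeric(), 0, length(tissues),
                             dimnames = list(NULL, tissues)))
  }
  expressed <- rowSums(truth$abundance) > 0
  coverage <- GenomicRanges::reduce(unlist(grl[expressed],
                                           use.names = FALSE))
  list(sig5 = sig5, sig3 = sig3, junctions = jx, coverage = coverage)
}

#' Simulate a gene x tissue expression matrix
#'
#' FPKM = true abundance scaled by multiplicative lognormal noise with
#' the given coefficient of variation.
#'
#' @param truth from \code{\link{simulateTruth}}.
#' @param noiseCv coefficient of variation of the noise (default 0).
#' @param seed RNG seed.
#' @return gene x tissue matrix.
#' @export
simulateExpression <- function(truth, noiseCv = 0, seed = 1) {
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  set.seed(seed)
  m <- truth$geneExpr
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    noise <- matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog),
                    nrow(m), ncol(m))
    m <- m * noise
  }
  m
}
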