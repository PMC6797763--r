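## Sequence-level feature extraction on final isoforms: ORFs, UTRs,
## microexons, distal/proximal/coding site roles, intronic-terminus
## coupling events, and the G-quadruplex / U-rich / uORF scanners.

.STOPS <- c("TAA", "TAG", "TGA")

## All ATG-initiated, stop-terminated ORFs in the three forward frames of
## a sense-strand sequence. Returns data.frame(start, end, aa): 1-based
## closed nt coordinates, stop codon included; aa excludes the stop.
.allOrfs <- function(seq) {
  s <- toupper(chartr("U", "T", as.character(seq)))
  L <- nchar(s)
  out <- list()
  for (f in 1:3) {
    if (L - f + 1 < 6) next
    starts <- seq(f, L - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stopIdx <- which(codons %in% .STOPS)
    atgIdx <- which(codons == "ATG")
    if (length(atgIdx) == 0L || length(stopIdx) == 0L) next
    nxt <- stopIdx[findInterval(atgIdx, stopIdx) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    a <- atgIdx[ok]; b <- nxt[ok]
    out[[f]] <- data.frame(start = starts[a], end = starts[b] + 2L,
                           frame = f, aa = (b - a))
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Longest open reading frame of a spliced sequence
#'
#' Longest ATG-to-stop ORF across the three forward frames of the
#' mRNA-sense sequence; ties break to the 5'-most start.
#'
#' @param seq character or DNAString/RNAString (sense strand).
#' @return list(start, end, frame, aa) in 1-based nt coordinates with the
#'   stop codon included and protein length in amino acids (stop
#'   excluded), or NULL when no complete ORF exists.
#' @export
findLongestOrf <- function(seq) {
  orfs <- .allOrfs(seq)
  if (nrow(orfs) == 0L) return(NULL)
  best <- orfs[order(-(orfs$end - orfs$start + 1L), orfs$start), ][1L, ]
  list(start = best$start, end = best$end, frame = best$frame, aa = best$aa)
}

#' Assign a CDS to every transcript by longest ORF
#'
#' @param ts TranscriptSet.
#' @param genome named DNAStringSet.
#' @param minAa minimum protein length to accept (default 1).
#' @return TranscriptSet with \code{cds_start}/\code{cds_end} (spliced)
#'   filled where an ORF was found.
#' @export
assignCds <- function(ts, genome, minAa = 1L) {
  if (length(ts) == 0L) return(ts)
  seqs <- splicedSeqs(ts, genome)
  td <- ts@txData
  for (i in seq_along(ts)) {
    orf <- findLongestOrf(seqs[[i]])
    if (!is.null(orf) && orf$aa >= minAa) {
      td$cds_start[i] <- orf$start
      td$cds_end[i] <- orf$end
    }
  }
  new("TranscriptSet", exons = ts@exons, txData = td)
}

#' Detect microexons
#'
#' Internal exons (neither first nor last of the chain) whose length is
#' at most \code{maxLen} nt.
#'
#' @param ts TranscriptSet.
#' @param maxLen microexon threshold in nt (default 51).
#' @return data.frame(tx_id, chrom, start, end, width, exon_rank).
#' @export
detectMicroexons <- function(ts, maxLen = 51) {
  ex <- exonChains(ts)
  rows <- list()
  for (i in seq_along(ex)) {
    g <- ex[[i]]
    n <- length(g)
    if (n < 3L) next
    internal <- 2:(n - 1L)
    w <- BiocGenerics::width(g)[internal]
    hit <- internal[w <= maxLen]
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        tx_id = txIds(ts)[i],
        chrom = as.character(GenomicRanges::seqnames(g))[1L],
        start = BiocGenerics::start(g)[hit], end = BiocGenerics::end(g)[hit],
        width = BiocGenerics::width(g)[hit], exon_rank = hit)
  }
  if (length(rows) == 0L)
    return(data.frame(tx_id = character(), chrom = character(),
                      start = integer(), end = integer(), width = integer(),
                      exon_rank = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify alternative sites as distal, proximal or coding
#'
#' The gene's representative CDS is the longest ORF of its longest
#' isoform. For TSS clusters: a summit inside or 3' of the start codon is
#' coding (CT); among the summits 5' of the start codon the farthest is
#' distal (DT) and the rest proximal (PT). TES clusters mirror the logic
#' around the stop codon.
#'
#' @param geneTs TranscriptSet of one gene (CDS assigned on at least the
#'   longest isoform).
#' @param cs SiteClusterSet of the gene's clusters (one kind).
#' @return data.frame(cluster, summit, role) with role in DT/PT/CT.
#' @export
classifySites <- function(geneTs, cs) {
  if (length(cs) == 0L)
    return(data.frame(cluster = integer(), summit = integer(),
                      role = character()))
  sl <- splicedLength(geneTs)
  ord <- order(-sl)
  rep <- NA_integer_
  for (i in ord) if (!is.na(geneTs@txData$cds_start[i])) { rep <- i; break }
  if (is.na(rep)) stop("gene has no representative CDS")
  chain <- exonChains(geneTs)[[rep]]
  strand <- as.character(BiocGenerics::strand(chain))[1L]
  cdsG <- splicedToGenomic(chain, geneTs@txData$cds_start[rep],
                           geneTs@txData$cds_end[rep])
  ## strand-aware genomic position of the start/stop codon boundary
  anchor <- if (clusterKind(cs) == "TSS") {
    if (strand == "-") max(BiocGenerics::end(cdsG))
    else min(BiocGenerics::start(cdsG))
  } else {
    if (strand == "-") min(BiocGenerics::start(cdsG))
    else max(BiocGenerics::end(cdsG))
  }
  summit <- clusterSummits(cs)
  ## signed distance in the "outward" direction: positive = away from the
  ## CDS on the side where alternative sites live
  outward <- if (clusterKind(cs) == "TSS") {
    if (strand == "-") summit - anchor else anchor - summit
  } else {
    if (strand == "-") anchor - summit else summit - anchor
  }
  role <- rep("CT", length(summit))
  outside <- which(outward > 0)
  if (length(outside)) {
    role[outside] <- "PT"
    role[outside[which.max(outward[outside])]] <- "DT"
  }
  data.frame(cluster = seq_along(summit), summit = summit, role = role)
}

#' Detect intronic-terminus coupling events
#'
#' For each ordered isoform pair (A, B) of a gene, A's transcript start
#' (5') or end (3') falling inside an intron of B generates an event:
#' Is when A's terminal exon lies entirely within that intron and splices
#' out through A's own junction (skipped terminal exon, junction gained);
#' Ic when A's terminal exon runs from inside the intron continuously
#' into B's adjacent exon (composite terminal exon, junction lost).
#'
#' @param geneTs TranscriptSet of one gene (>= 2 isoforms).
#' @return data.frame(end, type, isoform, partner).
#' @export
detectCouplingEvents <- function(geneTs) {
  n <- length(geneTs)
  if (n < 2L) return(data.frame(end = character(), type = character(),
                                isoform = character(), partner = character()))
  ex <- exonChains(geneTs)
  ids <- txIds(geneTs)
  rows <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    A <- ex[[a]]; B <- ex[[b]]
    strand <- as.character(BiocGenerics::strand(A))[1L]
    intB <- intronsOf(B)
    if (length(intB) == 0L) next
    nA <- length(A)
    for (endKind in c("5p", "3p")) {
      ## genomic position of A's terminus and its terminal exon
      leftEnd <- (endKind == "5p") == (strand == "+")
      termExon <- if (leftEnd) A[1L] else A[nA]
      tpos <- if (leftEnd) BiocGenerics::start(termExon)
              else BiocGenerics::end(termExon)
      hit <- which(BiocGenerics::start(intB) <= tpos &
                   BiocGenerics::end(intB) >= tpos)
      if (length(hit) != 1L) next
      intr <- intB[hit]
      within <- BiocGenerics::start(termExon) >= BiocGenerics::start(intr) &&
        BiocGenerics::end(termExon) <= BiocGenerics::end(intr)
      if (within && nA >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          end = endKind, type = "Is", isoform = ids[a], partner = ids[b])
      } else if (!within) {
        ## composite: terminal exon crosses the intron boundary away from
        ## the terminus, into B's adjacent exon
        crosses <- if (leftEnd)
          BiocGenerics::end(termExon) > BiocGenerics::end(intr)
        else BiocGenerics::start(termExon) < BiocGenerics::start(intr)
        if (crosses)
          rows[[length(rows) + 1L]] <- data.frame(
            end = endKind, type = "Ic", isoform = ids[a], partner = ids[b])
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(end = character(), type = character(),
                      isoform = character(), partner = character()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Scan for RNA G-quadruplex motifs
#'
#' Four G-tracts of at least \code{minTract} consecutive G (>= minTract
#' stacked tetrads), separated by loops of \code{minLoop} to
#' \code{maxLoop} nt. Maximal G-runs serve as tracts; overlapping hits
#' are resolved greedily to the highest-scoring (longest summed tracts,
#' then 5'-most).
#'
#' @param seq character or XString; T and U are equivalent.
#' @param minTract minimum G-run length (default 4).
#' @param minLoop,maxLoop loop length bounds (defaults 2 and 7).
#' @return data.frame(start, end, score) in 1-based nt coordinates.
#' @export
scanRg4 <- function(seq, minTract = 4, minLoop = 2, maxLoop = 7) {
  s <- toupper(chartr("U", "T", as.character(seq)))
  m <- gregexpr(sprintf("G{%d,}", minTract), s)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer(),
                                      score = integer()))
  runs <- data.frame(start = as.integer(m),
                     end = as.integer(m) + attr(m, "match.length") - 1L)
  nr <- nrow(runs)
  hits <- list()
  if (nr >= 4L) {
    for (i in seq_len(nr - 3L)) {
      idx <- i:(i + 3L)
      gaps <- runs$start[idx[-1L]] - runs$end[idx[-4L]] - 1L
      if (all(gaps >= minLoop & gaps <= maxLoop))
        hits[[length(hits) + 1L]] <- data.frame(
          start = runs$start[i], end = runs$end[i + 3L],
          score = sum(runs$end[idx] - runs$start[idx] + 1L))
    }
  }
  if (length(hits) == 0L) return(data.frame(start = integer(),
                                            end = integer(),
                                            score = integer()))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(h)) > i)
    clash <- later[h$start[later] <= h$end[i] & h$end[later] >= h$start[i]]
    keep[clash] <- FALSE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for U-rich elements
#'
#' Qualifying windows of \code{window} nt (or the whole sequence when
#' shorter, down to \code{minLen}) with a U fraction of at least
#' \code{minFrac} are merged into maximal regions; regions of at least
#' \code{minLen} nt are reported.
#'
#' @param seq character or XString; T and U are equivalent.
#' @param window sliding window in nt (default 10).
#' @param minFrac minimum U fraction per window (default 0.8).
#' @param minLen minimum reported region length (default 6).
#' @return data.frame(start, end, u_frac).
#' @export
scanUrich <- function(seq, window = 10, minFrac = 0.8, minLen = 6) {
  s <- toupper(chartr("U", "T", as.character(seq)))
  L <- nchar(s)
  w <- min(window, L)
  empty <- data.frame(start = integer(), end = integer(), u_frac = numeric())
  if (w < minLen || L < minLen) return(empty)
  isU <- as.integer(strsplit(s, "")[[1L]] == "T")
  cs <- cumsum(c(0L, isU))
  starts <- seq_len(L - w + 1L)
  frac <- (cs[starts + w] - cs[starts]) / w
  q <- which(frac >= minFrac)
  if (length(q) == 0L) return(empty)
  runs <- split(q, cumsum(c(1L, diff(q) != 1L)))
  rows <- lapply(runs, function(r) {
    a <- r[1L]; b <- r[length(r)] + w - 1L
    data.frame(start = a, end = b, u_frac = (cs[b + 1L] - cs[a]) / (b - a + 1L))
  })
  out <- do.call(rbind, rows)
  out <- out[out$end - out$start + 1L >= minLen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find upstream ORFs in a 5'UTR
#'
#' ATG-initiated ORFs whose stop codon lies within the given 5'UTR
#' sequence and with at least \code{minAa} codons before the stop
#' (initiator ATG included).
#'
#' @param utrSeq spliced 5'UTR sequence.
#' @param minAa minimum codon count before the stop (default 2).
#' @return data.frame(start, end, aa).
#' @export
findUorfs <- function(utrSeq, minAa = 2) {
  orfs <- .allOrfs(utrSeq)
  out <- orfs[orfs$aa >= minAa, c("start", "end", "aa"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare motif content between two alternative UTR sequences
#'
#' Hits present in one UTR and absent from the other (set difference on
#' the motif coordinates within each sequence).
#'
#' @param utrA,utrB the two UTR sequences.
#' @param scanner one of "rg4", "urich", "uorf".
#' @param ... passed to the scanner.
#' @return list(gained =, lost =) data.frames (hits in A not in B, and
#'   vice versa, keyed by sequence content of the hit).
#' @export
compareUtrMotifs <- function(utrA, utrB, scanner = c("rg4", "urich", "uorf"),
                             ...) {
  scanner <- match.arg(scanner)
  fn <- switch(scanner, rg4 = scanRg4, urich = scanUrich, uorf = findUorfs)
  hitSeq <- function(seq, h) {
    if (nrow(h) == 0L) return(character(0))
    s <- toupper(chartr("U", "T", as.character(seq)))
    substring(s, h$start, h$end)
  }
  ha <- fn(utrA, ...); hb <- fn(utrB, ...)
  ka <- hitSeq(utrA, ha); kb <- hitSeq(utrB, hb)
  list(gained = ha[!(ka %in% kb), , drop = FALSE],
       lost = hb[!(kb %in% ka), , drop = FALSE])
}
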