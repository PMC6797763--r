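## Core coordinate algebra. Internal convention: 1-based closed intervals
## (GRanges native). 0-based half-open appears only at BED/bedGraph/junction
## table boundaries.

#' Intersect two genomic intervals
#'
#' Strand of the result follows \code{a}; disjoint (including merely
#' touching) intervals yield \code{NULL}.
#'
#' @param a,b GRanges of length 1 on the same chromosome.
#' @return GRanges of length 1, or NULL when disjoint.
#' @export
intersectInterval <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b)))
    stop("intervals on different chromosomes")
  s <- max(BiocGenerics::start(a), BiocGenerics::start(b))
  e <- min(BiocGenerics::end(a), BiocGenerics::end(b))
  if (s > e) return(NULL)
  GenomicRanges::GRanges(GenomicRanges::seqnames(a),
                         IRanges::IRanges(s, e),
                         strand = BiocGenerics::strand(a))
}

#' Introns of an exon chain
#'
#' @param chain GRanges exon chain (sorted, disjoint, one chrom/strand).
#' @return GRanges of the gaps between consecutive exons (empty for a
#'   single-exon chain), same strand as the chain.
#' @export
intronsOf <- function(chain) {
  if (length(chain) <= 1L)
    return(GenomicRanges::GRanges())
  chain <- chain[order(BiocGenerics::start(chain))]
  s <- BiocGenerics::end(chain)[-length(chain)] + 1L
  e <- BiocGenerics::start(chain)[-1L] - 1L
  if (any(s > e)) stop("exon chain has overlapping or adjacent exons")
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(chain))[1L],
                         IRanges::IRanges(s, e),
                         strand = as.character(BiocGenerics::strand(chain))[1L])
}

#' Group isoforms into gene loci
#'
#' Two isoforms belong to the same gene iff they are connected through the
#' relation "same strand and at least 1 bp of exonic overlap" (transitive
#' closure). Purely intronic containment without exon overlap separates
#' genes.
#'
#' @param ts a TranscriptSet.
#' @param prefix gene id prefix.
#' @return the TranscriptSet with \code{gene_id} filled in; gene ids are
#'   assigned in order of leftmost transcript coordinate.
#' @export
groupIntoGenes <- function(ts, prefix = "gene") {
  n <- length(ts)
  if (n == 0L) return(ts)
  ex <- exonChains(ts)
  hits <- GenomicRanges::findOverlaps(ex, ex)  # strand-aware by default
  g <- igraph::graph_from_data_frame(
    data.frame(from = S4Vectors::queryHits(hits),
               to = S4Vectors::subjectHits(hits)),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  ## order components by leftmost coordinate for deterministic ids
  starts <- min(BiocGenerics::start(ex))
  compStart <- tapply(starts, comp, min)
  rank <- rank(compStart, ties.method = "first")
  ids <- sprintf("%s%04d", prefix, rank[as.character(comp)])
  td <- ts@txData
  td$gene_id <- as.character(ids)
  new("TranscriptSet", exons = ts@exons, txData = td)
}

#' Spliced length of exon chains
#' @param ts a TranscriptSet
#' @return integer vector of summed exon widths.
#' @export
splicedLength <- function(ts) sum(BiocGenerics::width(exonChains(ts)))

## Map a spliced (transcript 5'->3', 1-based) interval to genomic pieces.
## Returns a GRanges (possibly several pieces, one per exon crossed).
splicedToGenomic <- function(chain, from, to) {
  stopifnot(from >= 1L, to >= from)
  chain <- chain[order(BiocGenerics::start(chain))]
  strand <- as.character(BiocGenerics::strand(chain))[1L]
  w <- BiocGenerics::width(chain)
  if (to > sum(w)) stop("spliced interval outside transcript")
  ord <- if (strand == "-") rev(seq_along(chain)) else seq_along(chain)
  offs <- cumsum(c(0L, w[ord]))  # spliced offset before each exon (tx order)
  pieces <- list()
  for (k in seq_along(ord)) {
    lo <- offs[k] + 1L; hi <- offs[k + 1L]
    a <- max(from, lo); b <- min(to, hi)
    if (a > b) next
    i <- ord[k]
    if (strand == "-") {
      gEnd <- BiocGenerics::end(chain)[i] - (a - lo)
      gStart <- BiocGenerics::end(chain)[i] - (b - lo)
    } else {
      gStart <- BiocGenerics::start(chain)[i] + (a - lo)
      gEnd <- BiocGenerics::start(chain)[i] + (b - lo)
    }
    pieces[[length(pieces) + 1L]] <- c(gStart, gEnd)
  }
  m <- do.call(rbind, pieces)
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(chain))[1L],
                         IRanges::IRanges(m[, 1L], m[, 2L]), strand = strand)
}

## Map a genomic position to its spliced (transcript) coordinate, or NA if
## the position is not exonic.
genomicToSpliced <- function(chain, pos) {
  chain <- chain[order(BiocGenerics::start(chain))]
  strand <- as.character(BiocGenerics::strand(chain))[1L]
  w <- BiocGenerics::width(chain)
  ord <- if (strand == "-") rev(seq_along(chain)) else seq_along(chain)
  offs <- cumsum(c(0L, w[ord]))
  vapply(pos, function(p) {
    for (k in seq_along(ord)) {
      i <- ord[k]
      s <- BiocGenerics::start(chain)[i]; e <- BiocGenerics::end(chain)[i]
      if (p >= s && p <= e) {
        return(if (strand == "-") offs[k] + (e - p) + 1L
               else offs[k] + (p - s) + 1L)
      }
    }
    NA_integer_
  }, integer(1))
}

#' Spliced (mRNA-sense) sequences of transcripts
#'
#' Concatenates exon sequences 5' to 3'; minus-strand transcripts are
#' reverse-complemented.
#'
#' @param ts a TranscriptSet
#' @param genome a named DNAStringSet (chromosome sequences).
#' @return DNAStringSet named by transcript id.
#' @export
splicedSeqs <- function(ts, genome) {
  ex <- exonChains(ts)
  out <- Biostrings::DNAStringSet(vapply(seq_along(ex), function(i) {
    g <- ex[[i]]
    chrom <- as.character(GenomicRanges::seqnames(g))[1L]
    pieces <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(BiocGenerics::start(g),
                                        BiocGenerics::end(g))))
    s <- paste(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(g))[1L] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1)))
  names(out) <- txIds(ts)
  out
}

## transcript-level extent (one range per transcript)
txExtent <- function(ts) {
  ex <- exonChains(ts)
  unlist(range(ex), use.names = FALSE)
}

## strand-aware transcript 5' and 3' genomic terminal positions
txEnds <- function(ts) {
  ex <- exonChains(ts)
  st <- min(BiocGenerics::start(ex))
  en <- max(BiocGenerics::end(ex))
  minus <- vapply(seq_along(ex), function(i)
    as.character(BiocGenerics::strand(ex[[i]]))[1L] == "-", logical(1))
  data.frame(tx_id = txIds(ts),
             five = ifelse(minus, en, st),
             three = ifelse(minus, st, en),
             strand = ifelse(minus, "-", "+"))
}
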