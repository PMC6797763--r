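## Post-processing of externally assembled short-read transfrags into
## isoN records and integration with long-read-derived classes.

#' Filter transfrags on expression
#'
#' Single-exon transfrags must reach \code{singleExonMin} FPKM and
#' multi-exon transfrags \code{multiExonMin} (both inclusive).
#'
#' @param ts TranscriptSet of transfrags with \code{fpkm} recorded.
#' @param singleExonMin FPKM cutoff for single-exon transfrags (0.5).
#' @param multiExonMin FPKM cutoff for multi-exon transfrags (0.2).
#' @return filtered TranscriptSet.
#' @export
filterTransfrags <- function(ts, singleExonMin = 0.5, multiExonMin = 0.2) {
  if (length(ts) == 0L) return(ts)
  fp <- ts@txData$fpkm
  if (anyNA(fp)) stop("transfrag without an FPKM value")
  nEx <- lengths(exonChains(ts))
  keep <- ifelse(nEx == 1L, fp >= singleExonMin, fp >= multiExonMin)
  ts[which(keep)]
}

#' Fix transfrag boundaries with tag-cluster summits
#'
#' When a reliable TSS (TES) cluster summit lies within \code{maxDist} nt
#' of a transfrag's 5' (3') boundary, the boundary is moved to the summit
#' (nearest summit wins). A move never crosses the first (last) splice
#' junction: adjustments that would empty or invert the terminal exon are
#' discarded.
#'
#' @param ts TranscriptSet of transfrags.
#' @param tssClusters,tesClusters reliable SiteClusterSets.
#' @param maxDist search distance in nt (default 500).
#' @return TranscriptSet with adjusted terminal exons.
#' @export
fixBoundaries <- function(ts, tssClusters, tesClusters, maxDist = 500) {
  if (length(ts) == 0L) return(ts)
  ex <- as.list(exonChains(ts))
  summitsBy <- function(cs) {
    gr <- clusterRanges(cs)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               strand = as.character(BiocGenerics::strand(gr)),
               summit = S4Vectors::mcols(gr)$summit)
  }
  tssS <- summitsBy(tssClusters); tesS <- summitsBy(tesClusters)
  nearest <- function(df, chrom, strand, pos) {
    cand <- df$summit[df$chrom == chrom & df$strand == strand &
                      abs(df$summit - pos) <= maxDist]
    if (length(cand) == 0L) return(NA_integer_)
    cand[which.min(abs(cand - pos))]
  }
  for (i in seq_along(ex)) {
    g <- ex[[i]]
    chrom <- as.character(GenomicRanges::seqnames(g))[1L]
    strand <- as.character(BiocGenerics::strand(g))[1L]
    n <- length(g)
    left <- BiocGenerics::start(g)[1L]
    right <- BiocGenerics::end(g)[n]
    ## 5' boundary is the left end on +, the right end on -
    fiveSummit <- nearest(tssS, chrom, strand,
                          if (strand == "-") right else left)
    threeSummit <- nearest(tesS, chrom, strand,
                           if (strand == "-") left else right)
    newLeft <- if (strand == "-") threeSummit else fiveSummit
    newRight <- if (strand == "-") fiveSummit else threeSummit
    if (!is.na(newLeft) && newLeft < BiocGenerics::end(g)[1L] &&
        (n == 1L || newLeft < BiocGenerics::start(g)[2L]))
      BiocGenerics::start(g)[1L] <- newLeft
    if (!is.na(newRight) && newRight > BiocGenerics::start(g)[n] &&
        (n == 1L || newRight > BiocGenerics::end(g)[n - 1L]))
      BiocGenerics::end(g)[n] <- newRight
    ex[[i]] <- g
  }
  grl <- GenomicRanges::GRangesList(ex)
  names(grl) <- txIds(ts)
  new("TranscriptSet", exons = grl, txData = ts@txData)
}

#' Integrate long-read-derived records with transfrags
#'
#' Loci (exonic-overlap connected components across both inputs) with any
#' long-read-derived isoform keep only those records; loci without
#' long-read coverage take the transfrags, labelled isoN. No locus mixes
#' the two sources.
#'
#' @param longRead TranscriptSet from the long-read assembler
#'   (isoF/isoR/isoC records).
#' @param transfrags filtered, boundary-fixed TranscriptSet.
#' @return combined TranscriptSet with fresh gene ids.
#' @export
integrateAnnotation <- function(longRead, transfrags) {
  if (length(transfrags) == 0L) return(groupIntoGenes(longRead))
  tf <- transfrags@txData
  tf$cls <- "isoN"
  transfrags@txData <- tf
  if (length(longRead) == 0L) return(groupIntoGenes(transfrags))
  ## rename on collision
  if (any(txIds(transfrags) %in% txIds(longRead))) {
    ids <- paste0("isoN_", txIds(transfrags))
    names(transfrags@exons) <- ids
    transfrags@txData$tx_id <- ids
    rownames(transfrags@txData) <- ids
  }
  both <- groupIntoGenes(combineTranscriptSets(longRead, transfrags))
  src <- c(rep("lr", length(longRead)), rep("ngs", length(transfrags)))
  gid <- geneIds(both)
  lrGenes <- unique(gid[src == "lr"])
  keep <- src == "lr" | !(gid %in% lrGenes)
  groupIntoGenes(both[which(keep)])
}
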