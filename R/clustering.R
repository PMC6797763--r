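## Density-based tag clustering (paraclu-style maximal scoring segments)
## and the cluster merge / reliability / pruning rules applied to TSS and
## TES tag signal.

## --- paraclu core -------------------------------------------------------
##
## For tag positions pos (sorted, unique) with positive counts val on one
## chrom/strand, a candidate cluster is a contiguous run of positions that
## is a maximal scoring segment for some density parameter d: every
## prefix and suffix of the run has density at least d, and no larger run
## does. Densities follow the tag-clustering convention in which a prefix
## ending at position k is measured to the next tag
## (sum(i..k) / (pos[k+1] - pos[i])) and a suffix starting at k from the
## previous tag (sum(k..j) / (pos[j] - pos[k-1])); a single position has
## infinite density. Each candidate carries:
##   max_den -- the minimum prefix/suffix density of the run: the largest
##              d at which the run is still coherent;
##   min_den -- the largest coherence density of any enclosing run (0 for
##              the outermost): above this density the run stands alone.
## A run is a candidate iff max_den > min_den; the family is laminar and
## is found by recursive splitting at the weakest prefix/suffix boundary.
.paracluSegments <- function(pos, val) {
  n <- length(pos)
  out <- vector("list", 0L)
  stack <- list(list(i = 1L, j = n, minDen = 0))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j
    if (i > j) next
    if (i == j) {
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j, min_den = fr$minDen, max_den = Inf, total = val[i])
      next
    }
    v <- val[i:j]; p <- pos[i:j]; m <- j - i + 1L
    tot <- sum(v)
    preDen <- cumsum(v[-m]) / (p[-1L] - p[1L])
    sufDen <- rev(cumsum(rev(v[-1L]))) / (p[m] - p[-m])
    cohDen <- min(preDen, sufDen)
    if (cohDen > fr$minDen)
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j, min_den = fr$minDen, max_den = cohDen, total = tot)
    childMin <- max(fr$minDen, cohDen)
    k <- if (min(preDen) <= min(sufDen)) which.min(preDen)
         else which.min(sufDen)
    stack[[length(stack) + 1L]] <- list(i = i, j = i + k - 1L,
                                        minDen = childMin)
    stack[[length(stack) + 1L]] <- list(i = i + k, j = j, minDen = childMin)
  }
  do.call(rbind, out)
}

## retention rules + flattening shared by clusterTags
.retainFlatten <- function(segs, pos, minValue, maxLength, minDensityFold) {
  span <- pos[segs$j] - pos[segs$i] + 1
  fold <- ifelse(segs$min_den <= 0, Inf, segs$max_den / segs$min_den)
  keep <- segs$total >= minValue & span <= maxLength &
    fold >= minDensityFold
  segs <- segs[keep, , drop = FALSE]
  if (nrow(segs) == 0L) return(segs)
  ## flatten: drop retained segments contained in another retained one
  ord <- order(segs$i, -segs$j)
  segs <- segs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(segs))
  maxJ <- -Inf
  for (r in seq_len(nrow(segs))) {
    if (segs$j[r] <= maxJ) keep[r] <- FALSE else maxJ <- segs$j[r]
  }
  segs[keep, , drop = FALSE]
}

#' Cluster tag signal into TSS/TES site clusters
#'
#' Paraclu-style density clustering of per-base tag counts, applied per
#' chromosome and strand. Candidate clusters are runs of positions that
#' are maximal scoring segments for some density parameter; a candidate is
#' retained when its total tag count is at least \code{minValue}, its
#' genomic span is at most \code{maxLength} nt, and its density stability
#' (max density / min density) is at least \code{minDensityFold}. Retained
#' candidates nested inside another retained candidate are flattened away,
#' leaving disjoint maximal clusters.
#'
#' @param sig a \linkS4class{TagSignal}.
#' @param sample cluster this sample's signal only; NULL pools all samples.
#' @param minValue minimum summed tag count (default 20).
#' @param maxLength maximum cluster span in nt (default 200).
#' @param minDensityFold minimum density stability ratio (default 5).
#' @return A \linkS4class{SiteClusterSet} (kind TSS for five_prime signal,
#'   TES for three_prime). Per-sample counts/TPM are computed from the
#'   full signal within each cluster interval.
#' @export
clusterTags <- function(sig, sample = NULL, minValue = 20, maxLength = 200,
                        minDensityFold = 5) {
  if (minValue <= 0) stop("minValue must be positive")
  if (maxLength <= 0) stop("maxLength must be positive")
  kind <- if (sig@end == "five_prime") "TSS" else "TES"
  tg <- sig@tags
  if (!is.null(sample)) tg <- tg[tg$sample %in% sample, , drop = FALSE]
  if (nrow(tg) == 0L)
    return(.emptyClusterSet(kind, tagSamples(sig)))
  ## pool counts across (selected) samples per position
  key <- paste(tg$chrom, tg$strand)
  res <- list()
  for (ks in unique(key)) {
    sub <- tg[key == ks, , drop = FALSE]
    pooled <- rowsum(sub$count, sub$pos)
    pos <- as.integer(rownames(pooled))
    o <- order(pos)
    pos <- pos[o]; val <- as.numeric(pooled[o, 1L])
    segs <- .paracluSegments(pos, val)
    segs <- .retainFlatten(segs, pos, minValue, maxLength, minDensityFold)
    if (nrow(segs) == 0L) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = sub$chrom[1L], strand = sub$strand[1L],
      start = pos[segs$i], end = pos[segs$j])
  }
  if (length(res) == 0L)
    return(.emptyClusterSet(kind, tagSamples(sig)))
  iv <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end),
                               strand = iv$strand)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  .clusterSetFromIntervals(kind, gr, sig)
}

.emptyClusterSet <- function(kind, samples) {
  g <- GenomicRanges::GRanges()
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(summit = integer(0),
                                              total = numeric(0))
  SiteClusterSet(kind, g,
                 matrix(numeric(), 0, length(samples),
                        dimnames = list(NULL, samples)),
                 matrix(numeric(), 0, length(samples),
                        dimnames = list(NULL, samples)))
}

## Build a SiteClusterSet from bare intervals: per-sample counts, TPM and
## pooled summit are recomputed from the full tag signal.
.clusterSetFromIntervals <- function(kind, gr, sig) {
  samples <- tagSamples(sig)
  tg <- sig@tags
  n <- length(gr)
  counts <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  summit <- integer(n); total <- numeric(n)
  for (i in seq_len(n)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    st <- as.character(BiocGenerics::strand(gr))[i]
    s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
    sub <- tg[tg$chrom == ch & tg$strand == st & tg$pos >= s & tg$pos <= e, ,
              drop = FALSE]
    if (nrow(sub)) {
      cs <- tapply(sub$count, sub$sample, sum)
      counts[i, names(cs)] <- as.numeric(cs)
      pooled <- rowsum(sub$count, sub$pos)
      pv <- as.numeric(pooled[, 1L]); pp <- as.integer(rownames(pooled))
      o <- order(pp)
      pv <- pv[o]; pp <- pp[o]
      summit[i] <- pp[which.max(pv)]     # which.max: leftmost on ties
      total[i] <- sum(pv)
    } else {
      summit[i] <- s
    }
  }
  lib <- tagLibSize(sig)[samples]
  tpm <- sweep(counts, 2L, ifelse(lib > 0, lib, NA_real_), "/") * 1e6
  tpm[is.na(tpm)] <- 0
  S4Vectors::mcols(gr)$summit <- summit
  S4Vectors::mcols(gr)$total <- total
  SiteClusterSet(kind, gr, counts, tpm)
}

#' Merge clusters called per sample into a cross-sample cluster set
#'
#' Overlapping clusters (1 bp of overlap suffices; adjacency does not)
#' of the same kind and strand are unioned; per-sample counts, TPM and the
#' pooled summit are recomputed from the full tag signal within the merged
#' interval.
#'
#' @param clusterSets list of SiteClusterSet, all of one kind.
#' @param sig the TagSignal covering all samples.
#' @return merged SiteClusterSet.
#' @export
mergeAcrossSamples <- function(clusterSets, sig) {
  kinds <- unique(vapply(clusterSets, clusterKind, character(1)))
  if (length(kinds) != 1L) stop("mixed cluster kinds cannot be merged")
  gr <- do.call(c, lapply(clusterSets, function(x) {
    g <- clusterRanges(x); S4Vectors::mcols(g) <- NULL; g
  }))
  if (length(gr) == 0L) return(.emptyClusterSet(kinds, tagSamples(sig)))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  merged <- BiocGenerics::sort(merged, ignore.strand = TRUE)
  .clusterSetFromIntervals(kinds, merged, sig)
}

#' Filter clusters down to the reliable set
#'
#' A cluster is reliable when its TPM reaches \code{tpmMin} in at least
#' one sample AND its per-base maximum signal reaches \code{topSignalMin}
#' in at least \code{minSamples} samples.
#'
#' @param cs a SiteClusterSet.
#' @param sig the TagSignal (needed for per-base per-sample maxima).
#' @param tpmMin cluster-sum TPM threshold (default 0.5).
#' @param topSignalMin per-base signal threshold (default 10).
#' @param minSamples number of samples that must reach topSignalMin
#'   (default 3).
#' @return the filtered SiteClusterSet.
#' @export
filterReliable <- function(cs, sig, tpmMin = 0.5, topSignalMin = 10,
                           minSamples = 3) {
  n <- length(cs)
  if (n == 0L) return(cs)
  gr <- clusterRanges(cs)
  tg <- sig@tags
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!any(clusterTpm(cs)[i, ] >= tpmMin)) next
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    st <- as.character(BiocGenerics::strand(gr))[i]
    s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
    sub <- tg[tg$chrom == ch & tg$strand == st & tg$pos >= s & tg$pos <= e, ,
              drop = FALSE]
    if (nrow(sub) == 0L) next
    perSampleMax <- tapply(sub$count, sub$sample, max)
    keep[i] <- sum(perSampleMax >= topSignalMin) >= minSamples
  }
  cs[keep]
}

#' Summit of a cluster
#'
#' Position of the maximum pooled signal inside the cluster interval;
#' ties break to the leftmost (5'-most in genome coordinates) position.
#'
#' @param cs SiteClusterSet.
#' @param i cluster index.
#' @param sig TagSignal.
#' @return integer position.
#' @export
selectSummit <- function(cs, i, sig) {
  gr <- clusterRanges(cs)[i]
  tg <- sig@tags
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- as.character(BiocGenerics::strand(gr))
  sub <- tg[tg$chrom == ch & tg$strand == st &
            tg$pos >= BiocGenerics::start(gr) &
            tg$pos <= BiocGenerics::end(gr), , drop = FALSE]
  if (nrow(sub) == 0L || all(sub$count == 0)) stop("cluster has no signal")
  pooled <- rowsum(sub$count, sub$pos)
  pp <- as.integer(rownames(pooled)); pv <- as.numeric(pooled[, 1L])
  o <- order(pp)
  pp[o][which.max(pv[o])]
}

#' Merge nearby clusters for assembly
#'
#' Single-linkage merging of same-kind, same-strand clusters whose gap is
#' smaller than \code{cutoff} nt (gap = bases strictly between the two
#' intervals; a 400 nt gap is NOT merged at the default 400). The merged
#' summit is the position with the highest pooled signal in the merged
#' interval.
#'
#' @param cs SiteClusterSet.
#' @param sig TagSignal.
#' @param cutoff merge distance in nt (default 400).
#' @return merged SiteClusterSet.
#' @export
mergeNearbyForAssembly <- function(cs, sig, cutoff = 400) {
  if (length(cs) == 0L) return(cs)
  gr <- clusterRanges(cs)
  S4Vectors::mcols(gr) <- NULL
  merged <- GenomicRanges::reduce(gr, min.gapwidth = cutoff)
  merged <- BiocGenerics::sort(merged, ignore.strand = TRUE)
  .clusterSetFromIntervals(clusterKind(cs), merged, sig)
}

#' Prune clusters whose summits lie within a cutoff of each other
#'
#' Greedy by descending total signal (ties: leftmost summit first): a
#' cluster is kept unless an already-kept cluster on the same chrom and
#' strand has a summit within \code{cutoff} nt.
#'
#' @param cs SiteClusterSet.
#' @param cutoff summit distance in nt (default 50).
#' @return pruned SiteClusterSet.
#' @export
pruneWithin <- function(cs, cutoff = 50) {
  n <- length(cs)
  if (n <= 1L) return(cs)
  gr <- clusterRanges(cs)
  tot <- S4Vectors::mcols(gr)$total
  sm <- S4Vectors::mcols(gr)$summit
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- as.character(BiocGenerics::strand(gr))
  ord <- order(-tot, sm)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(ch[kept] == ch[i] & st[kept] == st[i] &
                 abs(sm[kept] - sm[i]) <= cutoff)
    if (!clash) kept <- c(kept, i)
  }
  cs[sort(kept)]
}
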