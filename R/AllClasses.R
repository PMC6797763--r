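#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   replaceAt width readDNAStringSet writeXStringSet
#' @importFrom stats rpois rmultinom rlnorm runif rbinom rgeom setNames
#'   wilcox.test
#' @importFrom utils read.delim write.table
NULL

## Isoform class labels, in priority order (best first) used when
## deduplicating records that share an exon chain.
.ISO_CLASSES <- c("isoF", "isoR", "isoC", "isoM", "isoP", "isoN")

#' TranscriptSet: a set of transcript isoform records
#'
#' The central container of the package: one exon chain per transcript
#' (a \linkS4class{GRangesList}, exons sorted by genomic start, pairwise
#' disjoint, single chromosome and strand per transcript) plus a
#' per-transcript metadata \code{DataFrame} with the columns
#' \code{tx_id}, \code{gene_id}, \code{cls} (one of isoF/isoC/isoM/isoR/
#' isoP/isoN or \code{NA}), \code{cds_start}/\code{cds_end} (spliced,
#' 1-based closed, stop codon included, \code{NA} when uncalled),
#' \code{fpkm}, and the evidence anchors \code{tss_summit}/\code{tes_summit}
#' (genomic positions of the supporting tag-cluster summits, \code{NA}
#' when the record is not anchored).
#'
#' @slot exons GRangesList of exon chains, names are transcript ids.
#' @slot txData DataFrame of per-transcript metadata, parallel to exons.
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

.validTranscriptSet <- function(object) {
  msg <- character()
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    msg <- c(msg, "exons and txData have different lengths")
  if (length(ex) && !identical(names(ex), as.character(td$tx_id)))
    msg <- c(msg, "names(exons) must equal txData$tx_id")
  need <- c("tx_id", "gene_id", "cls", "cds_start", "cds_end", "fpkm",
            "tss_summit", "tes_summit")
  if (!all(need %in% colnames(td)))
    msg <- c(msg, paste("txData missing columns:",
                        paste(setdiff(need, colnames(td)), collapse = ", ")))
  if (length(ex)) {
    nchrom <- lengths(unique(GenomicRanges::seqnames(ex)))
    nstr <- lengths(unique(BiocGenerics::strand(ex)))
    if (any(nchrom != 1L) || any(nstr != 1L))
      msg <- c(msg, "each exon chain must lie on a single chromosome/strand")
    if (any(unlist(BiocGenerics::strand(ex), use.names = FALSE) == "."))
      msg <- c(msg, "strand '.' is not permitted for isoforms")
    if (!all(.chainsSortedDisjoint(ex)))
      msg <- c(msg, "exon chains must be sorted by start and pairwise disjoint")
    if ("cls" %in% colnames(td)) {
      bad <- !is.na(td$cls) & !(td$cls %in% .ISO_CLASSES)
      if (any(bad))
        msg <- c(msg, paste("invalid cls label(s):",
                            paste(unique(td$cls[bad]), collapse = ", ")))
    }
    if (all(c("cds_start", "cds_end") %in% colnames(td))) {
      sl <- sum(BiocGenerics::width(ex))
      ok <- is.na(td$cds_start) |
        (td$cds_start >= 1L & td$cds_end <= sl & td$cds_start < td$cds_end)
      if (!all(ok))
        msg <- c(msg, "cds must lie within the spliced length")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

.chainsSortedDisjoint <- function(grl) {
  st <- BiocGenerics::start(grl)
  en <- BiocGenerics::end(grl)
  vapply(seq_along(grl), function(i) {
    s <- st[[i]]; e <- en[[i]]
    if (length(s) <= 1L) return(TRUE)
    all(diff(s) > 0) && all(s[-1L] > e[-length(e)])
  }, logical(1))
}

#' Construct a TranscriptSet
#'
#' @param exons GRangesList of exon chains (one element per transcript).
#'   Unsorted exons are sorted by start; names are used as transcript ids.
#' @param tx_id,gene_id,cls,cds_start,cds_end,fpkm,tss_summit,tes_summit
#'   optional per-transcript metadata vectors recycled to length(exons).
#' @return A \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, tx_id = names(exons), gene_id = NA_character_,
                          cls = NA_character_, cds_start = NA_integer_,
                          cds_end = NA_integer_, fpkm = NA_real_,
                          tss_summit = NA_integer_, tes_summit = NA_integer_) {
  if (length(exons) == 0L) {
    td <- S4Vectors::DataFrame(tx_id = character(), gene_id = character(),
                               cls = character(), cds_start = integer(),
                               cds_end = integer(), fpkm = numeric(),
                               tss_summit = integer(), tes_summit = integer())
    return(new("TranscriptSet", exons = GenomicRanges::GRangesList(),
               txData = td))
  }
  if (is.null(tx_id))
    tx_id <- paste0("tx", seq_along(exons))
  exons <- .sortChains(exons)
  names(exons) <- tx_id
  n <- length(exons)
  rcy <- function(x) rep(x, length.out = n)
  td <- S4Vectors::DataFrame(
    tx_id = as.character(tx_id),
    gene_id = rcy(as.character(gene_id)),
    cls = rcy(as.character(cls)),
    cds_start = rcy(as.integer(cds_start)),
    cds_end = rcy(as.integer(cds_end)),
    fpkm = rcy(as.numeric(fpkm)),
    tss_summit = rcy(as.integer(tss_summit)),
    tes_summit = rcy(as.integer(tes_summit)))
  rownames(td) <- td$tx_id
  new("TranscriptSet", exons = exons, txData = td)
}

.sortChains <- function(grl) {
  GenomicRanges::GRangesList(lapply(grl, function(g) {
    g <- g[order(BiocGenerics::start(g))]
    S4Vectors::mcols(g) <- NULL
    g
  }), compress = TRUE)
}

#' @describeIn TranscriptSet number of transcripts
#' @param x a TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Exon chains of a TranscriptSet
#' @param x a TranscriptSet
#' @return GRangesList of exon chains.
#' @export
exonChains <- function(x) x@exons

#' Per-transcript metadata of a TranscriptSet
#' @param x a TranscriptSet
#' @return DataFrame with one row per transcript.
#' @export
txData <- function(x) x@txData

#' Transcript ids
#' @param x a TranscriptSet
#' @export
txIds <- function(x) as.character(x@txData$tx_id)

#' Gene ids (one per transcript)
#' @param x a TranscriptSet
#' @export
geneIds <- function(x) as.character(x@txData$gene_id)

#' Isoform class labels (isoF/isoC/isoM/isoR/isoP/isoN)
#' @param x a TranscriptSet
#' @export
txClass <- function(x) as.character(x@txData$cls)

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, txIds(x))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' Combine two TranscriptSets
#' @param x,y TranscriptSets with disjoint transcript ids
#' @export
combineTranscriptSets <- function(x, y) {
  if (any(txIds(x) %in% txIds(y)))
    stop("transcript ids overlap between the two sets")
  new("TranscriptSet", exons = c(x@exons, y@exons),
      txData = rbind(x@txData, y@txData))
}

setMethod("show", "TranscriptSet", function(object) {
  cls <- table(factor(txClass(object), levels = .ISO_CLASSES))
  cat("TranscriptSet with", length(object), "transcripts,",
      length(unique(geneIds(object))), "gene(s)\n")
  if (length(object))
    cat("  classes:", paste(names(cls), as.integer(cls), sep = "=",
                            collapse = " "), "\n")
})

#' TagSignal: per-base 5' or 3' tag counts across samples
#'
#' Sparse per-base tag counts (CAGE-style cap tags or polyadenylation-site
#' tags) for a set of samples, one strand-aware position per row, plus the
#' per-sample library size (total tags) used for tags-per-million scaling.
#'
#' @slot end "five_prime" or "three_prime".
#' @slot tags data.frame with columns chrom, pos (1-based), strand,
#'   sample, count.
#' @slot libSize named numeric vector of per-sample total tag counts.
#' @export
setClass("TagSignal",
  representation(end = "character", tags = "data.frame", libSize = "numeric"))

.validTagSignal <- function(object) {
  msg <- character()
  if (!object@end %in% c("five_prime", "three_prime"))
    msg <- c(msg, "end must be 'five_prime' or 'three_prime'")
  need <- c("chrom", "pos", "strand", "sample", "count")
  if (!all(need %in% colnames(object@tags)))
    msg <- c(msg, "tags must have columns chrom, pos, strand, sample, count")
  else {
    if (any(object@tags$count < 0)) msg <- c(msg, "negative tag counts")
    if (!all(object@tags$strand %in% c("+", "-", ".")))
      msg <- c(msg, "invalid strand in tags")
  }
  for (s in unique(object@tags$sample)) {
    tot <- sum(object@tags$count[object@tags$sample == s])
    if (!isTRUE(all.equal(unname(object@libSize[s]), tot)))
      msg <- c(msg, paste0("libSize[", s, "] != sum of counts"))
  }
  if (length(msg)) msg else TRUE
}
setValidity("TagSignal", .validTagSignal)

#' Construct a TagSignal object
#'
#' @param end "five_prime" or "three_prime"
#' @param tags data.frame(chrom, pos, strand, sample, count); duplicate
#'   (chrom,pos,strand,sample) rows are summed.
#' @return A \linkS4class{TagSignal}.
#' @export
TagSignal <- function(end, tags) {
  if (nrow(tags)) {
    key <- paste(tags$chrom, tags$pos, tags$strand, tags$sample)
    if (anyDuplicated(key)) {
      agg <- rowsum(tags$count, key)
      first <- !duplicated(key)
      tags <- tags[first, , drop = FALSE]
      tags$count <- agg[match(paste(tags$chrom, tags$pos, tags$strand,
                                    tags$sample), rownames(agg)), 1L]
    }
    tags <- tags[order(tags$sample, tags$chrom, tags$strand, tags$pos), ,
                 drop = FALSE]
    rownames(tags) <- NULL
  }
  lib <- if (nrow(tags)) {
    v <- tapply(tags$count, tags$sample, sum)
    stats::setNames(as.numeric(v), names(v))
  } else stats::setNames(numeric(0), character(0))
  new("TagSignal", end = end, tags = tags, libSize = lib)
}

#' Sample names of a TagSignal
#' @param x a TagSignal
#' @export
tagSamples <- function(x) names(x@libSize)

#' Per-sample library sizes (total tag counts)
#' @param x a TagSignal
#' @export
tagLibSize <- function(x) x@libSize

setMethod("show", "TagSignal", function(object) {
  cat("TagSignal (", object@end, "): ", nrow(object@tags),
      " positions, ", length(object@libSize), " sample(s)\n", sep = "")
})

#' SiteClusterSet: TSS or TES tag clusters
#'
#' Clusters of 5' or 3' tag signal, each with a genomic interval, a summit
#' (position of maximum pooled signal), pooled total, and per-sample tag
#' counts and tags-per-million values.
#'
#' @slot kind "TSS" or "TES".
#' @slot gr GRanges of cluster intervals with metadata columns
#'   \code{summit} and \code{total}.
#' @slot counts matrix clusters x samples of tag counts.
#' @slot tpm matrix clusters x samples of tags-per-million.
#' @export
setClass("SiteClusterSet",
  representation(kind = "character", gr = "GRanges",
                 counts = "matrix", tpm = "matrix"))

.validSiteClusterSet <- function(object) {
  msg <- character()
  if (!object@kind %in% c("TSS", "TES"))
    msg <- c(msg, "kind must be 'TSS' or 'TES'")
  gr <- object@gr
  if (!all(c("summit", "total") %in% colnames(S4Vectors::mcols(gr))))
    msg <- c(msg, "gr must carry summit and total metadata columns")
  else if (length(gr)) {
    s <- S4Vectors::mcols(gr)$summit
    if (any(s < BiocGenerics::start(gr) | s > BiocGenerics::end(gr)))
      msg <- c(msg, "summit outside cluster interval")
    tot <- S4Vectors::mcols(gr)$total
    if (nrow(object@counts) != length(gr) ||
        nrow(object@tpm) != length(gr))
      msg <- c(msg, "counts/tpm rows must match cluster count")
    else if (!isTRUE(all.equal(unname(rowSums(object@counts)), unname(tot))))
      msg <- c(msg, "total must equal the row sum of per-sample counts")
    if (any(object@tpm < 0)) msg <- c(msg, "negative TPM")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SiteClusterSet", .validSiteClusterSet)

#' Construct a SiteClusterSet
#' @param kind "TSS" or "TES"
#' @param gr GRanges with mcols summit and total
#' @param counts,tpm clusters x samples matrices
#' @export
SiteClusterSet <- function(kind, gr, counts, tpm) {
  new("SiteClusterSet", kind = kind, gr = gr,
      counts = as.matrix(counts), tpm = as.matrix(tpm))
}

#' Cluster intervals of a SiteClusterSet
#' @param x a SiteClusterSet
#' @return GRanges with summit and total metadata.
#' @export
clusterRanges <- function(x) x@gr

#' Cluster summits
#' @param x a SiteClusterSet
#' @export
clusterSummits <- function(x) S4Vectors::mcols(x@gr)$summit

#' Per-sample tag counts of clusters
#' @param x a SiteClusterSet
#' @export
clusterCounts <- function(x) x@counts

#' Per-sample TPM of clusters
#' @param x a SiteClusterSet
#' @export
clusterTpm <- function(x) x@tpm

#' Kind of a SiteClusterSet ("TSS" or "TES")
#' @param x a SiteClusterSet
#' @export
clusterKind <- function(x) x@kind

setMethod("length", "SiteClusterSet", function(x) length(x@gr))

setMethod("[", "SiteClusterSet", function(x, i, j, ..., drop = FALSE) {
  new("SiteClusterSet", kind = x@kind, gr = x@gr[i],
      counts = x@counts[i, , drop = FALSE], tpm = x@tpm[i, , drop = FALSE])
})

setMethod("show", "SiteClusterSet", function(object) {
  cat("SiteClusterSet (", object@kind, "): ", length(object),
      " cluster(s), ", ncol(object@counts), " sample(s)\n", sep = "")
})

#' HotspotNull: branching-process null for distinct isoform substrings
#'
#' The null distribution of the number of distinct k-segment isoform
#' substrings in a gene when splicing decisions are independent: starting
#' from a single path, every distinct path duplicates independently with
#' probability p at each of the K segments, so the path count follows
#' xi_{k+1} = xi_k + Binomial(xi_k, p) with xi_1 = 1 + Bernoulli(p), and
#' E(X) = (1+p)^K.
#'
#' @slot p per-segment branch probability.
#' @slot K substring length.
#' @slot pmf numeric vector; pmf[n] = P(X = n), support 1..2^K.
#' @export
setClass("HotspotNull",
  representation(p = "numeric", K = "integer", pmf = "numeric"))

.validHotspotNull <- function(object) {
  msg <- character()
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0,1]")
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (abs(sum(object@pmf) - 1) > 1e-12) msg <- c(msg, "pmf must sum to 1")
  if (length(object@pmf) > 2^object@K) msg <- c(msg, "support exceeds 2^K")
  ev <- sum(seq_along(object@pmf) * object@pmf)
  if (abs(ev - (1 + object@p)^object@K) > 1e-9)
    msg <- c(msg, "E(X) must equal (1+p)^K")
  if (length(msg)) msg else TRUE
}
setValidity("HotspotNull", .validHotspotNull)

#' Expected number of distinct substrings under the null
#' @param x a HotspotNull
#' @export
nullExpectation <- function(x) (1 + x@p)^x@K

#' Probability mass function of a HotspotNull
#' @param x a HotspotNull
#' @return numeric vector indexed by n = 1..2^K.
#' @export
nullProb <- function(x) x@pmf

setMethod("show", "HotspotNull", function(object) {
  cat("HotspotNull: p =", signif(object@p, 4), ", K =", object@K,
      ", E(X) =", signif(nullExpectation(object), 5), "\n")
})
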