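## The alternative-splicing hotspot model: binary isoform strings over
## exon-boundary segments, distinct k-substring counts, the
## branching-process null, and the genome scan with its three-fold rule.

#' Encode a gene's isoforms as binary segment strings
#'
#' The gene span is divided at the union of all isoforms' exon boundaries;
#' each isoform becomes a string with "1" where it covers the segment and
#' "0" where it does not. Only segments within the union of exonic and
#' intronic extent are used; all strings of a gene have equal length.
#'
#' @param geneTs TranscriptSet of one gene (>= 2 isoforms).
#' @return list(strings = character vector named by tx id,
#'   segments = GRanges of the segmentation).
#' @export
encodeIsoformStrings <- function(geneTs) {
  if (length(geneTs) < 2L) stop("need at least 2 isoforms to encode")
  ex <- exonChains(geneTs)
  u <- unlist(ex, use.names = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(u))[1L]
  strand <- as.character(BiocGenerics::strand(u))[1L]
  bounds <- sort(unique(c(BiocGenerics::start(u),
                          BiocGenerics::end(u) + 1L)))
  segStart <- bounds[-length(bounds)]
  segEnd <- bounds[-1L] - 1L
  segs <- GenomicRanges::GRanges(chrom, IRanges::IRanges(segStart, segEnd),
                                 strand = strand)
  strings <- vapply(seq_along(ex), function(i) {
    hit <- IRanges::overlapsAny(segs, ex[[i]])
    paste(as.integer(hit), collapse = "")
  }, character(1))
  names(strings) <- txIds(geneTs)
  list(strings = strings, segments = segs)
}

#' Count distinct k-length substring patterns per window
#'
#' @param strings equal-length binary strings (one per isoform).
#' @param k substring length (>= 1).
#' @return integer vector: for each window of k consecutive segments, the
#'   number of distinct patterns across the strings.
#' @export
countSubstringTypes <- function(strings, k) {
  if (k < 1) stop("k must be >= 1")
  L <- unique(nchar(strings))
  if (length(L) != 1L) stop("strings must have equal length")
  if (k > L) stop("k exceeds string length")
  vapply(seq_len(L - k + 1L), function(i)
    length(unique(substring(strings, i, i + k - 1L))), integer(1))
}

#' Branching-process null distribution of distinct substring counts
#'
#' Under independence of splicing decisions the number of distinct
#' k-segment substrings follows the branching process
#' P(xi = 2 | K = 1) = p, P(xi = 1 | K = 1) = 1 - p, and
#' P(xi = n | K = k+1) = sum_{i = ceil(n/2)}^{n} C(i, n-i) p^(n-i)
#' (1-p)^(2i-n) P(xi = i | K = k): each of i distinct paths branches
#' independently with probability p. E(X) = (1+p)^K.
#'
#' @param p per-segment branch probability in [0, 1].
#' @param K substring length (>= 1).
#' @return A \linkS4class{HotspotNull}.
#' @export
nullPmf <- function(p, K) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  pmf <- c(1 - p, p)                       # K = 1, support {1, 2}
  ## binomial term C(i, n-i) p^(n-i) (1-p)^(2i-n), in log space so that
  ## huge coefficients cannot overflow against tiny probabilities
  term <- function(i, n) {
    if (p == 0) return(as.numeric(n == i))
    if (p == 1) return(as.numeric(n == 2 * i))
    exp(lchoose(i, n - i) + (n - i) * log(p) + (2 * i - n) * log1p(-p))
  }
  if (K > 1L) for (step in seq_len(K - 1L)) {
    nmax <- 2L * length(pmf)
    nxt <- numeric(nmax)
    for (n in seq_len(nmax)) {
      lo <- ceiling(n / 2)
      hi <- min(n, length(pmf))
      if (lo > hi) next
      i <- lo:hi
      nxt[n] <- sum(term(i, n) * pmf[i])
    }
    pmf <- nxt
  }
  new("HotspotNull", p = p, K = K, pmf = pmf)
}

#' Estimate the branch probability from observed counts
#'
#' From E(X) = (1+p)^K: p = mean(counts)^(1/K) - 1, clamped to [0, 1].
#'
#' @param counts observed distinct-substring counts (>= 1 each).
#' @param K the substring length the counts were taken at.
#' @return the estimate p-hat.
#' @export
estimateP <- function(counts, K) {
  if (length(counts) == 0L) stop("no counts")
  min(1, max(0, mean(counts)^(1 / K) - 1))
}

#' Simulate distinct-substring counts from the null
#'
#' Direct simulation of the branching chain xi_{k+1} = xi_k +
#' Binomial(xi_k, p), xi_1 = 1 + Bernoulli(p).
#'
#' @param n number of draws.
#' @param p branch probability.
#' @param K substring length.
#' @return integer vector of counts.
#' @export
simulateNullCounts <- function(n, p, K) {
  xi <- 1L + stats::rbinom(n, 1L, p)
  if (K > 1L) for (step in seq_len(K - 1L))
    xi <- xi + stats::rbinom(n, xi, p)
  xi
}

#' Hotspot cutoff from the three-fold rule
#'
#' The smallest count n whose observed frequency is at least \code{fold}
#' times the null probability at n (and is positive); NA when no such n
#' exists, in which case the genome is called hotspot-free at this k.
#'
#' @param null a HotspotNull.
#' @param counts observed distinct-substring counts.
#' @param fold excess factor (default 3).
#' @return integer cutoff or NA.
#' @export
hotspotCutoff <- function(null, counts, fold = 3) {
  pmf <- nullProb(null)
  tab <- tabulate(counts, nbins = max(length(pmf), max(counts)))
  obs <- tab / length(counts)
  nullP <- c(pmf, rep(0, length(obs) - length(pmf)))
  hit <- which(obs > 0 & obs >= fold * nullP)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Scan a genome's isoform strings for alternative-splicing hotspots
#'
#' For each substring length k the branch probability is estimated from
#' all windows genome-wide, the null computed, and the three-fold cutoff
#' derived; windows at or above the cutoff are hotspot evidence. Evidence
#' windows of one gene that share segments are merged into regions, and
#' genes with strictly more than \code{minEvidence} supporting
#' (gene, k, window) triples are reported.
#'
#' @param x a TranscriptSet (gene ids assigned) or a named list of
#'   equal-length binary string vectors, one per gene.
#' @param kRange substring lengths to scan (default 3:10).
#' @param fold excess factor (default 3).
#' @param minEvidence evidence triples required, strict (default 3).
#' @return list(genes = data.frame(gene_id, n_evidence, seg_lo, seg_hi),
#'   cutoffs = data.frame(k, p_hat, cutoff)).
#' @export
scanHotspots <- function(x, kRange = 3:10, fold = 3, minEvidence = 3) {
  stringsByGene <- if (methods::is(x, "TranscriptSet")) {
    gs <- split(seq_along(x), geneIds(x))
    gs <- gs[lengths(gs) >= 2L]
    lapply(gs, function(i) encodeIsoformStrings(x[i])$strings)
  } else x
  stringsByGene <- stringsByGene[lengths(stringsByGene) >= 2L]
  empty <- list(genes = data.frame(gene_id = character(),
                                   n_evidence = integer(),
                                   seg_lo = integer(), seg_hi = integer()),
                cutoffs = data.frame(k = integer(), p_hat = numeric(),
                                     cutoff = integer()))
  if (length(stringsByGene) == 0L) return(empty)
  evid <- list()
  cuts <- list()
  for (k in kRange) {
    long <- names(stringsByGene)[
      vapply(stringsByGene, function(s) nchar(s[1L]) >= k, logical(1))]
    if (length(long) == 0L) next
    counts <- lapply(stringsByGene[long], countSubstringTypes, k = k)
    allCounts <- unlist(counts, use.names = FALSE)
    pHat <- estimateP(allCounts, k)
    cutoff <- hotspotCutoff(nullPmf(pHat, k), allCounts, fold = fold)
    cuts[[length(cuts) + 1L]] <- data.frame(k = k, p_hat = pHat,
                                            cutoff = cutoff)
    if (is.na(cutoff)) next
    for (g in long) {
      w <- which(counts[[g]] >= cutoff)
      if (length(w))
        evid[[length(evid) + 1L]] <- data.frame(
          gene_id = g, k = k, seg_lo = w, seg_hi = w + k - 1L)
    }
  }
  cutoffs <- if (length(cuts)) do.call(rbind, cuts) else empty$cutoffs
  if (length(evid) == 0L) return(list(genes = empty$genes,
                                      cutoffs = cutoffs))
  ev <- do.call(rbind, evid)
  genes <- lapply(split(ev, ev$gene_id), function(sub) {
    ## merge evidence windows sharing >= 1 segment into regions
    sub <- sub[order(sub$seg_lo, sub$seg_hi), , drop = FALSE]
    regId <- integer(nrow(sub))
    cur <- 0L; hi <- -1L
    for (r in seq_len(nrow(sub))) {
      if (sub$seg_lo[r] > hi) { cur <- cur + 1L; hi <- sub$seg_hi[r] }
      else hi <- max(hi, sub$seg_hi[r])
      regId[r] <- cur
    }
    do.call(rbind, lapply(split(sub, regId), function(rg)
      data.frame(gene_id = rg$gene_id[1L], n_evidence = nrow(rg),
                 seg_lo = min(rg$seg_lo), seg_hi = max(rg$seg_hi))))
  })
  genes <- do.call(rbind, genes)
  genes <- genes[genes$n_evidence > minEvidence, , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, cutoffs = cutoffs)
}

#' Simulate a string genome under the null, with optional planted hotspots
#'
#' Null genes grow their isoform set by the branching process: scanning
#' segments left to right, every distinct path duplicates with
#' probability p, the duplicate toggling its bit at that segment. Planted
#' hotspot genes additionally diversify a window of \code{hotWindow}
#' segments so that \code{hotIso} distinct local patterns occur.
#'
#' @param nGenes gene count.
#' @param L segments per gene.
#' @param p branch probability.
#' @param planted number of hotspot genes (first \code{planted} genes).
#' @param hotIso distinct local patterns per planted gene (default 8).
#' @param hotWindow planted window width in segments (default 4).
#' @param maxIso cap on isoforms per gene (default 32).
#' @return named list of string vectors; planted genes are named
#'   "hot<i>", null genes "null<i>".
#' @export
simulateStringGenome <- function(nGenes, L, p, planted = 0, hotIso = 8,
                                 hotWindow = 4, maxIso = 32) {
  out <- vector("list", nGenes)
  nm <- character(nGenes)
  for (g in seq_len(nGenes)) {
    paths <- matrix(1L, nrow = 1L, ncol = L)
    for (s in seq_len(L)) {
      nP <- nrow(paths)
      branch <- stats::rbinom(nP, 1L, p) == 1L
      if (any(branch) && nP + sum(branch) <= maxIso) {
        dup <- paths[branch, , drop = FALSE]
        dup[, s] <- 1L - dup[, s]
        paths <- rbind(paths, dup)
        paths <- paths[!duplicated(paths), , drop = FALSE]
      }
    }
    if (g <= planted) {
      lo <- sample.int(L - hotWindow + 1L, 1L)
      idx <- lo:(lo + hotWindow - 1L)
      base <- paths[rep_len(seq_len(nrow(paths)), hotIso), , drop = FALSE]
      patterns <- t(vapply(seq_len(hotIso) - 1L, function(m)
        as.integer(intToBits(m)[seq_len(hotWindow)]), integer(hotWindow)))
      base[, idx] <- patterns
      paths <- rbind(paths, base)
      paths <- paths[!duplicated(paths), , drop = FALSE]
      nm[g] <- paste0("hot", g)
    } else nm[g] <- paste0("null", g)
    if (nrow(paths) < 2L) {
      extra <- paths[1L, ]
      flip <- sample.int(L, 1L)
      extra[flip] <- 1L - extra[flip]
      paths <- rbind(paths, extra)
    }
    out[[g]] <- apply(paths, 1L, paste, collapse = "")
  }
  names(out) <- nm
  out
}
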