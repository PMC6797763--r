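## The assembler core: linkage groups, credible junctions, indivisible
## segments, binary read paths, and the isoF/isoC/isoM/isoR/isoP
## classification-and-correction ladder.
##
## A "path" is a list:
##   bits     integer 0/1 vector over the segments of one linkage group
##   jx       data.frame(donor, acceptor, supported) of implied junctions
##   five_ok  TRUE when the 5'-terminal covered segment is a TSS segment
##   three_ok TRUE when the 3'-terminal covered segment is a TES segment
##   range    genomic c(start, end) of the underlying read
##   read_ids provenance

#' Partition the genome into linkage groups
#'
#' The genome is scanned in fixed windows; consecutive windows touched by
#' any signal (short-read coverage or long-read exons) merge into maximal
#' groups, and a long read whose extent spans two groups forces them to
#' merge (its introns bridge the signal gap).
#'
#' @param reads GRangesList of long-read exon chains.
#' @param coverage optional GRanges of short-read covered intervals
#'   (stranded).
#' @param window scan window in bp (default 100).
#' @return GRanges of linkage groups (stranded).
#' @export
findLinkageGroups <- function(reads, coverage = NULL, window = 100) {
  sigs <- GenomicRanges::GRanges()
  if (length(reads)) {
    u <- unlist(reads, use.names = FALSE)
    S4Vectors::mcols(u) <- NULL
    sigs <- c(sigs, u)
  }
  if (!is.null(coverage) && length(coverage)) {
    cv <- coverage
    S4Vectors::mcols(cv) <- NULL
    sigs <- c(sigs, cv)
  }
  if (length(sigs) == 0L) return(GenomicRanges::GRanges())
  ## snap signal to window grid: window k covers [(k-1)*w+1, k*w]
  ws <- ((BiocGenerics::start(sigs) - 1L) %/% window) * window + 1L
  we <- ((BiocGenerics::end(sigs) - 1L) %/% window + 1L) * window
  grid <- GenomicRanges::GRanges(GenomicRanges::seqnames(sigs),
                                 IRanges::IRanges(ws, we),
                                 strand = BiocGenerics::strand(sigs))
  groups <- GenomicRanges::reduce(grid)   # adjacent windows merge
  if (length(reads)) {
    ext <- unlist(range(reads), use.names = FALSE)
    groups <- GenomicRanges::reduce(c(groups, ext))
  }
  BiocGenerics::sort(groups, ignore.strand = TRUE)
}

#' Call credible splice junctions
#'
#' Junctions with at least \code{minReads} supporting reads in at least
#' \code{minSamples} samples.
#'
#' @param jx junction DataFrame (see \code{\link{readJunctionTable}}).
#' @param minReads read threshold per sample (default 3).
#' @param minSamples number of samples required to pass it (default 1).
#' @return the credible subset of \code{jx}.
#' @export
callCredibleJunctions <- function(jx, minReads = 3, minSamples = 1) {
  if (nrow(jx) == 0L) return(jx)
  keep <- rowSums(jx$counts >= minReads) >= minSamples
  jx[keep, ]
}

#' Divide a linkage group into indivisible segments
#'
#' Segment boundaries are the group ends, credible junction donor and
#' acceptor sites, and TSS/TES cluster summits. Summits anchor the
#' transcript terminus they represent: a segment boundary is placed so
#' that the summit is the first base of its segment when it is a
#' transcript 5' start in genome coordinates (TSS on +, TES on -) and the
#' last base when it is a 3' end (TES on +, TSS on -). A segment
#' containing a TSS (TES) summit is labelled a TSS (TES) segment.
#'
#' @param group GRanges of length 1 (stranded linkage group).
#' @param tssClusters,tesClusters SiteClusterSets (assembly-merged).
#' @param jx credible junction DataFrame.
#' @return data.frame(start, end, is_tss, is_tes, tss_summit, tes_summit)
#'   with attributes \code{chrom} and \code{strand}; segments tile the
#'   group without overlap, in coordinate order.
#' @export
segmentLocus <- function(group, tssClusters, tesClusters, jx) {
  stopifnot(length(group) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(group))
  strand <- as.character(BiocGenerics::strand(group))
  gs <- BiocGenerics::start(group); ge <- BiocGenerics::end(group)
  jsub <- jx[jx$chrom == chrom & jx$strand == strand, , drop = FALSE]
  touching <- jsub$donor <= ge & jsub$acceptor >= gs
  inside <- jsub$donor > gs & jsub$acceptor < ge
  if (any(touching & !inside))
    stop("junction boundary outside linkage group")
  jsub <- jsub[inside, , drop = FALSE]
  summitsOf <- function(cs) {
    if (is.null(cs) || length(cs) == 0L) return(data.frame(summit = integer(),
                                                           total = numeric()))
    gr <- clusterRanges(cs)
    sel <- as.character(GenomicRanges::seqnames(gr)) == chrom &
      as.character(BiocGenerics::strand(gr)) == strand &
      S4Vectors::mcols(gr)$summit >= gs & S4Vectors::mcols(gr)$summit <= ge
    data.frame(summit = S4Vectors::mcols(gr)$summit[sel],
               total = S4Vectors::mcols(gr)$total[sel])
  }
  tss <- summitsOf(tssClusters)
  tes <- summitsOf(tesClusters)
  ## genomic-left ("start-like") anchors open a segment at the summit;
  ## genomic-right anchors close one after it
  startAnchors <- if (strand == "-") tes$summit else tss$summit
  endAnchors <- if (strand == "-") tss$summit else tes$summit
  breaks <- sort(unique(c(gs, jsub$donor, jsub$acceptor + 1L,
                          startAnchors, endAnchors + 1L)))
  breaks <- breaks[breaks >= gs & breaks <= ge]
  segStart <- breaks
  segEnd <- c(breaks[-1L] - 1L, ge)
  seg <- data.frame(start = segStart, end = segEnd)
  pick <- function(df, s, e) {
    hit <- df$summit >= s & df$summit <= e
    if (!any(hit)) return(NA_integer_)
    df$summit[hit][which.max(df$total[hit])]
  }
  seg$tss_summit <- mapply(pick, s = seg$start, e = seg$end,
                           MoreArgs = list(df = tss))
  seg$tes_summit <- mapply(pick, s = seg$start, e = seg$end,
                           MoreArgs = list(df = tes))
  seg$is_tss <- !is.na(seg$tss_summit)
  seg$is_tes <- !is.na(seg$tes_summit)
  attr(seg, "chrom") <- chrom
  attr(seg, "strand") <- strand
  seg
}

## lean projection core on plain exon start/end vectors; jkey is the
## pre-pasted "donor acceptor" key set of credible junctions on the
## segment table's chrom/strand
.projectCore <- function(es, ee, segments, jkey, strand, read_id) {
  n <- nrow(segments)
  ss <- segments$start; se <- segments$end
  ov <- numeric(n)
  for (k in seq_along(es)) {
    o <- pmin(ee[k], se) - pmax(es[k], ss) + 1L
    o[o < 0L] <- 0L
    ov <- ov + o
  }
  bits <- as.integer(ov >= (se - ss + 1) / 2)
  if (!any(bits == 1L)) stop("read overlaps no segment")
  ones <- which(bits == 1L)
  first1 <- ones[1L]; last1 <- ones[length(ones)]
  ## implied junctions: 0-runs strictly between covered segments
  gaps <- which(diff(ones) > 1L)
  jdf <- if (length(gaps)) {
    donor <- ss[ones[gaps] + 1L]
    acceptor <- se[ones[gaps + 1L] - 1L]
    ri <- if (length(es) > 1L)
      paste(ee[-length(ee)] + 1L, es[-1L] - 1L) else character(0)
    key <- paste(donor, acceptor)
    data.frame(donor = donor, acceptor = acceptor,
               supported = key %in% jkey & key %in% ri)
  } else data.frame(donor = integer(), acceptor = integer(),
                    supported = logical())
  fiveSeg <- if (strand == "-") last1 else first1
  threeSeg <- if (strand == "-") first1 else last1
  list(bits = bits, jx = jdf,
       five_ok = segments$is_tss[fiveSeg],
       three_ok = segments$is_tes[threeSeg],
       range = c(min(es), max(ee)),
       read_ids = read_id)
}

#' Project a long read onto the segments of its linkage group
#'
#' A segment bit is set when the read's exonic overlap with the segment is
#' at least half the segment length (terminal-jitter tolerance). Implied
#' junctions are the gaps between consecutive covered runs; an implied
#' junction is supported when it is in the credible set AND the read
#' itself carries an intron with exactly those boundaries.
#'
#' @param read GRanges exon chain.
#' @param segments segment table from \code{\link{segmentLocus}}.
#' @param jx credible junction DataFrame.
#' @param read_id provenance id.
#' @return a path list (see file header).
#' @export
projectRead <- function(read, segments, jx, read_id = "read") {
  strand <- attr(segments, "strand")
  chrom <- attr(segments, "chrom")
  jkey <- paste(jx$donor, jx$acceptor)[jx$chrom == chrom &
                                       jx$strand == strand]
  read <- read[order(BiocGenerics::start(read))]
  .projectCore(BiocGenerics::start(read), BiocGenerics::end(read),
               segments, jkey, strand, read_id)
}

#' Classify projected paths
#'
#' isoF: starts at a TSS segment, ends at a TES segment, all implied
#' junctions supported. Candidate (for completion): all junctions
#' supported but a terminal anchor missing. Conflicted: any unsupported
#' junction.
#'
#' @param paths list of paths.
#' @return list(isoF =, candidate =, conflicted =) of paths.
#' @export
classifyPaths <- function(paths) {
  lab <- vapply(paths, function(p) {
    if (nrow(p$jx) && !all(p$jx$supported)) "conflicted"
    else if (p$five_ok && p$three_ok) "isoF"
    else "candidate"
  }, character(1))
  list(isoF = paths[lab == "isoF"],
       candidate = paths[lab == "candidate"],
       conflicted = paths[lab == "conflicted"])
}

.coveredRange <- function(bits) {
  ones <- which(bits == 1L)
  c(ones[1L], ones[length(ones)])
}

#' Complete a partial path against the full-length set
#'
#' A candidate with all junctions supported but a missing terminal anchor
#' is extended with the terminal structure of full-length paths that match
#' it over the shared covered range at the incomplete end. The completion
#' must be unique: if matching full-length paths offer different
#' extensions, no completed isoform is produced.
#'
#' @param cand a candidate path.
#' @param isoFbits list of isoF bit vectors.
#' @param strand "+" or "-".
#' @return completed bit vector, or NULL.
#' @export
completePartial <- function(cand, isoFbits, strand) {
  cr <- .coveredRange(cand$bits)
  missLeft <- if (strand == "-") !cand$three_ok else !cand$five_ok
  missRight <- if (strand == "-") !cand$five_ok else !cand$three_ok
  prefixes <- list(); suffixes <- list()
  for (fb in isoFbits) {
    fr <- .coveredRange(fb)
    if (missLeft && fr[1L] < cr[1L]) {
      hi <- min(cr[2L], fr[2L])
      if (hi >= cr[1L] && all(fb[cr[1L]:hi] == cand$bits[cr[1L]:hi]))
        prefixes[[length(prefixes) + 1L]] <- fb[seq_len(cr[1L] - 1L)]
    }
    if (missRight && fr[2L] > cr[2L]) {
      lo <- max(cr[1L], fr[1L])
      if (lo <= cr[2L] && all(fb[lo:cr[2L]] == cand$bits[lo:cr[2L]]))
        suffixes[[length(suffixes) + 1L]] <-
          fb[seq(cr[2L] + 1L, length(fb))]
    }
  }
  uniq <- function(lst) unique(lapply(lst, as.integer))
  out <- cand$bits
  if (missLeft) {
    u <- uniq(prefixes)
    if (length(u) != 1L) return(NULL)
    out[seq_len(cr[1L] - 1L)] <- u[[1L]]
  }
  if (missRight) {
    u <- uniq(suffixes)
    if (length(u) != 1L) return(NULL)
    out[seq(cr[2L] + 1L, length(out))] <- u[[1L]]
  }
  out
}

#' Merge complementary uncompleted candidates
#'
#' Pairs of candidates -- one anchored only at the 5' end, the other only
#' at the 3' end -- whose covered ranges overlap with identical bits on
#' the overlap are merged into a single full path.
#'
#' @param cands list of candidate paths (not completed by isoF).
#' @param strand "+" or "-".
#' @return list of merged bit vectors (deduplicated).
#' @export
mergeComplementary <- function(cands, strand) {
  fiveOnly <- Filter(function(p) p$five_ok && !p$three_ok, cands)
  threeOnly <- Filter(function(p) !p$five_ok && p$three_ok, cands)
  out <- list()
  for (a in fiveOnly) for (b in threeOnly) {
    ra <- .coveredRange(a$bits); rb <- .coveredRange(b$bits)
    lo <- max(ra[1L], rb[1L]); hi <- min(ra[2L], rb[2L])
    if (lo > hi) next
    if (!all(a$bits[lo:hi] == b$bits[lo:hi])) next
    merged <- as.integer(a$bits | b$bits)
    mr <- .coveredRange(merged)
    ## merged path must span both anchors contiguously in coverage sense
    if (mr[1L] != min(ra[1L], rb[1L]) || mr[2L] != max(ra[2L], rb[2L])) next
    out[[length(out) + 1L]] <- merged
  }
  unique(out)
}

#' Rescue a conflicted path against the full-length set
#'
#' Each unsupported implied junction defines a local window: the run of
#' absent segments plus its flanking covered segments (the supported
#' anchors). The window interior is replaced with the structure of
#' full-length paths that agree with the conflicted path everywhere
#' outside the window interiors; the replacement must be unique.
#'
#' @param p conflicted path.
#' @param isoFbits list of isoF bit vectors.
#' @param segments segment table (for window localisation).
#' @return corrected bit vector, or NULL when no unique correction exists
#'   or the path lacks terminal anchors.
#' @export
rescueConflict <- function(p, isoFbits, segments) {
  if (!(p$five_ok && p$three_ok)) return(NULL)
  cr <- .coveredRange(p$bits)
  free <- integer(0)
  for (k in which(!p$jx$supported)) {
    idx <- which(segments$start >= p$jx$donor[k] &
                 segments$end <= p$jx$acceptor[k])
    free <- union(free, idx)
  }
  if (length(free) == 0L) return(NULL)
  fixed <- setdiff(seq(cr[1L], cr[2L]), free)
  patts <- list()
  for (fb in isoFbits) {
    if (all(fb[fixed] == p$bits[fixed]))
      patts[[length(patts) + 1L]] <- fb[free]
  }
  u <- unique(lapply(patts, as.integer))
  if (length(u) != 1L) return(NULL)
  out <- p$bits
  out[free] <- u[[1L]]
  out
}

#' Fill a conflicted path from short-read exon structure
#'
#' Unsupported junctions are removed and each gap is re-filled with the
#' segment pattern whose implied junctions are all credible; when several
#' patterns are consistent the one agreeing best with short-read exonic
#' coverage is chosen (coverage-weighted agreement, ties to the pattern
#' with fewer exonic segments, then lexicographically).
#'
#' @param p conflicted path (rescue failed).
#' @param jx credible junction DataFrame.
#' @param segments segment table.
#' @param coverage optional GRanges of short-read covered intervals; when
#'   NULL the filling must be unique or the path is dropped.
#' @param covWidths optional precomputed per-segment covered widths
#'   (overrides coverage).
#' @return filled bit vector, or NULL.
#' @export
fillPartial <- function(p, jx, segments, coverage = NULL, covWidths = NULL) {
  chrom <- attr(segments, "chrom"); strand <- attr(segments, "strand")
  jkey <- paste(jx$donor, jx$acceptor)[jx$chrom == chrom & jx$strand == strand]
  covW <- if (!is.null(covWidths)) covWidths
          else if (!is.null(coverage)) .segmentCoverage(segments, coverage)
          else NULL
  out <- p$bits
  for (k in which(!p$jx$supported)) {
    idx <- which(segments$start >= p$jx$donor[k] &
                 segments$end <= p$jx$acceptor[k])
    if (length(idx) == 0L || length(idx) > 12L) return(NULL)
    f1 <- min(idx) - 1L; f2 <- max(idx) + 1L
    consistent <- list()
    for (mask in seq_len(2^length(idx)) - 1L) {
      patt <- as.integer(intToBits(mask)[seq_along(idx)])
      local <- c(1L, patt, 1L)
      ## implied junctions of the local pattern, in genomic coordinates
      segIdx <- c(f1, idx, f2)
      ok <- TRUE
      i <- 1L
      while (i < length(local)) {
        if (local[i] == 1L && local[i + 1L] == 0L) {
          j <- i + 1L
          while (j < length(local) && local[j + 1L] == 0L) j <- j + 1L
          dn <- segments$start[segIdx[i + 1L]]
          ac <- segments$end[segIdx[j]]
          if (!(paste(dn, ac) %in% jkey)) { ok <- FALSE; break }
          i <- j + 1L
        } else i <- i + 1L
      }
      if (ok) consistent[[length(consistent) + 1L]] <- patt
    }
    if (length(consistent) == 0L) return(NULL)
    if (length(consistent) > 1L) {
      if (is.null(covW)) return(NULL)
      w <- segments$end[idx] - segments$start[idx] + 1
      score <- vapply(consistent, function(patt)
        sum(ifelse(patt == 1L, covW[idx], w - covW[idx])), numeric(1))
      nex <- vapply(consistent, sum, numeric(1))
      key <- vapply(consistent, paste, character(1), collapse = "")
      best <- order(-score, nex, key)[1L]
      consistent <- consistent[best]
    }
    out[idx] <- consistent[[1L]]
  }
  out
}

## per-segment width covered by (reduced) short-read coverage intervals,
## plain arithmetic to keep the per-locus hot path S4-free
.segmentCoverage <- function(segments, coverage) {
  chrom <- attr(segments, "chrom"); strand <- attr(segments, "strand")
  cv <- GenomicRanges::reduce(coverage)
  sel <- as.character(GenomicRanges::seqnames(cv)) == chrom &
    as.character(BiocGenerics::strand(cv)) %in% c(strand, "*", ".")
  cs <- BiocGenerics::start(cv)[sel]; ce <- BiocGenerics::end(cv)[sel]
  vapply(seq_len(nrow(segments)), function(i) {
    o <- pmin(ce, segments$end[i]) - pmax(cs, segments$start[i]) + 1L
    sum(o[o > 0L])
  }, numeric(1))
}

## Convert a bit path to a genomic exon chain. Terminal coordinates snap
## to the summit recorded on an anchoring terminal segment; unanchored
## ends keep the read's own terminal coordinate (clipped into the
## terminal segment's run).
.pathToChain <- function(bits, segments, strand, readRange = NULL) {
  chrom <- attr(segments, "chrom")
  ones <- which(bits == 1L)
  runs <- split(ones, cumsum(c(1L, diff(ones) != 1L)))
  ex <- do.call(rbind, lapply(runs, function(r)
    c(segments$start[r[1L]], segments$end[r[length(r)]])))
  first1 <- ones[1L]; last1 <- ones[length(ones)]
  leftSeg <- first1; rightSeg <- last1
  ## left genomic terminus
  leftAnchor <- if (strand == "-") segments$tes_summit[leftSeg]
                else segments$tss_summit[leftSeg]
  if (!is.na(leftAnchor)) ex[1L, 1L] <- leftAnchor
  else if (!is.null(readRange)) ex[1L, 1L] <- max(ex[1L, 1L], readRange[1L])
  rightAnchor <- if (strand == "-") segments$tss_summit[rightSeg]
                 else segments$tes_summit[rightSeg]
  if (!is.na(rightAnchor)) ex[nrow(ex), 2L] <- rightAnchor
  else if (!is.null(readRange))
    ex[nrow(ex), 2L] <- min(ex[nrow(ex), 2L], readRange[2L])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(ex[, 1L], ex[, 2L]),
                         strand = strand)
}

#' Assemble one linkage group
#'
#' Orchestrates segmentation, read projection, classification, completion,
#' merging, rescue and gap filling, then deduplicates records (identical
#' exon chains collapse to one record keeping the best class, priority
#' isoF > isoR > isoC > isoM > isoP).
#'
#' @param group GRanges of length 1.
#' @param tssClusters,tesClusters assembly-merged SiteClusterSets.
#' @param jx credible junction DataFrame.
#' @param reads GRangesList of long-read exon chains within the group.
#' @param coverage optional short-read coverage GRanges (for gap filling).
#' @param prefix transcript id prefix.
#' @return A TranscriptSet (possibly empty).
#' @export
assembleLocus <- function(group, tssClusters, tesClusters, jx, reads,
                          coverage = NULL, prefix = "tx") {
  strand <- as.character(BiocGenerics::strand(group))
  chrom <- as.character(GenomicRanges::seqnames(group))
  segments <- segmentLocus(group, tssClusters, tesClusters, jx)
  if (length(reads) == 0L) return(TranscriptSet(GenomicRanges::GRangesList()))
  jkey <- paste(jx$donor, jx$acceptor)[jx$chrom == chrom &
                                       jx$strand == strand]
  readStarts <- as.list(BiocGenerics::start(reads))
  readEnds <- as.list(BiocGenerics::end(reads))
  readNames <- if (is.null(names(reads)))
    sprintf("read%d", seq_along(reads)) else names(reads)
  paths <- list()
  for (i in seq_along(reads)) {
    es <- readStarts[[i]]; ee <- readEnds[[i]]
    o <- order(es)
    p <- tryCatch(.projectCore(es[o], ee[o], segments, jkey, strand,
                               readNames[i]),
                  error = function(e) NULL)
    if (is.null(p)) next
    sig <- paste(paste(p$bits, collapse = ""),
                 paste(p$jx$supported, collapse = ""),
                 p$five_ok, p$three_ok)
    if (!is.null(paths[[sig]])) {
      paths[[sig]]$read_ids <- c(paths[[sig]]$read_ids, p$read_ids)
      paths[[sig]]$range <- c(min(paths[[sig]]$range[1L], p$range[1L]),
                              max(paths[[sig]]$range[2L], p$range[2L]))
    } else paths[[sig]] <- p
  }
  if (length(paths) == 0L) return(TranscriptSet(GenomicRanges::GRangesList()))
  cl <- classifyPaths(unname(paths))
  isoFbits <- unique(lapply(cl$isoF, function(p) p$bits))
  recs <- list()
  addRec <- function(bits, cls, range = NULL) {
    recs[[length(recs) + 1L]] <<- list(bits = bits, cls = cls, range = range)
  }
  for (p in cl$isoF) addRec(p$bits, "isoF", p$range)
  uncompleted <- list()
  for (p in cl$candidate) {
    comp <- completePartial(p, isoFbits, strand)
    if (!is.null(comp)) addRec(comp, "isoC", p$range)
    else uncompleted[[length(uncompleted) + 1L]] <- p
  }
  for (bits in mergeComplementary(uncompleted, strand))
    addRec(bits, "isoM")
  covW <- if (!is.null(coverage) && length(cl$conflicted))
    .segmentCoverage(segments, coverage) else NULL
  for (p in cl$conflicted) {
    fixedBits <- rescueConflict(p, isoFbits, segments)
    if (!is.null(fixedBits)) { addRec(fixedBits, "isoR", p$range); next }
    filled <- fillPartial(p, jx, segments, covWidths = covW)
    if (!is.null(filled)) addRec(filled, "isoP", p$range)
  }
  if (length(recs) == 0L) return(TranscriptSet(GenomicRanges::GRangesList()))
  chains <- lapply(recs, function(r)
    .pathToChain(r$bits, segments, strand, r$range))
  keys <- vapply(chains, function(g)
    paste(BiocGenerics::start(g), BiocGenerics::end(g), collapse = ";"),
    character(1))
  prio <- match(vapply(recs, `[[`, character(1), "cls"), .ISO_CLASSES)
  ord <- order(keys, prio)
  keep <- ord[!duplicated(keys[ord])]
  keep <- keep[order(vapply(chains[keep], function(g)
    min(BiocGenerics::start(g)), numeric(1)))]
  tssSm <- as.integer(vapply(keep, function(k) {
    b <- .coveredRange(recs[[k]]$bits)
    seg5 <- if (strand == "-") b[2L] else b[1L]
    as.numeric(segments$tss_summit[seg5])
  }, numeric(1)))
  tesSm <- as.integer(vapply(keep, function(k) {
    b <- .coveredRange(recs[[k]]$bits)
    seg3 <- if (strand == "-") b[1L] else b[2L]
    as.numeric(segments$tes_summit[seg3])
  }, numeric(1)))
  grl <- GenomicRanges::GRangesList(chains[keep])
  names(grl) <- sprintf("%s.%d", prefix, seq_along(keep))
  TranscriptSet(grl,
                cls = vapply(recs[keep], `[[`, character(1), "cls"),
                tss_summit = tssSm, tes_summit = tesSm)
}

#' Assemble transcripts genome-wide
#'
#' Convenience driver: finds linkage groups, merges clusters at the
#' assembly cutoff, calls credible junctions, assembles every group and
#' groups the result into gene loci.
#'
#' @param reads GRangesList of long-read exon chains.
#' @param tssClusters,tesClusters reliable SiteClusterSets (pre-merge).
#' @param jx junction DataFrame (unfiltered).
#' @param sig5,sig3 TagSignals (for summit recomputation during merging).
#' @param coverage optional short-read coverage GRanges.
#' @param config list from \code{\link{isoforgeConfig}}.
#' @return A TranscriptSet with gene ids assigned.
#' @export
assembleTranscripts <- function(reads, tssClusters, tesClusters, jx,
                                sig5, sig3, coverage = NULL,
                                config = isoforgeConfig()) {
  tssA <- mergeNearbyForAssembly(tssClusters, sig5,
                                 cutoff = config$clustering$assembly_merge_nt)
  tesA <- mergeNearbyForAssembly(tesClusters, sig3,
                                 cutoff = config$clustering$assembly_merge_nt)
  cred <- callCredibleJunctions(jx, config$assembler$junction_min_reads,
                                config$assembler$junction_min_samples)
  groups <- findLinkageGroups(reads, coverage,
                              window = config$assembler$window)
  ext <- unlist(range(reads), use.names = FALSE)
  hits <- GenomicRanges::findOverlaps(ext, groups)
  byGroup <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  parts <- list()
  for (gname in names(byGroup)) {
    g <- as.integer(gname)
    sub <- assembleLocus(groups[g], tssA, tesA, cred,
                         reads[byGroup[[gname]]],
                         coverage = coverage, prefix = sprintf("tx%04d", g))
    if (length(sub)) parts[[length(parts) + 1L]] <- sub
  }
  if (length(parts) == 0L) return(TranscriptSet(GenomicRanges::GRangesList()))
  out <- new("TranscriptSet",
             exons = do.call(c, lapply(parts, exonChains)),
             txData = do.call(rbind, lapply(parts, txData)))
  groupIntoGenes(out)
}
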