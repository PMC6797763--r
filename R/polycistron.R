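## Polycistron detection: transcripts carrying two or more major,
## non-overlapping ORFs, inter-CDS spacing, co-expression contrast, and
## the cross-species co-linearity rule.

#' Detect polycistronic transcripts
#'
#' A transcript is polycistronic when its spliced sequence contains two
#' or more non-overlapping ATG-to-stop ORFs of at least \code{minAa}
#' codons ("major" ORFs). ORFs are selected greedily by descending
#' length (ties 5'-most) with overlap exclusion.
#'
#' @param ts TranscriptSet.
#' @param genome named DNAStringSet.
#' @param minAa major-ORF threshold in codons (default 100).
#' @return list of calls: each
#'   list(tx_id, arity, cds = data.frame(start, end, aa)) with CDSs in
#'   spliced coordinates ordered 5' to 3'.
#' @export
detectPolycistrons <- function(ts, genome, minAa = 100) {
  if (length(ts) == 0L) return(list())
  seqs <- splicedSeqs(ts, genome)
  calls <- list()
  for (i in seq_along(ts)) {
    orfs <- .allOrfs(seqs[[i]])
    orfs <- orfs[orfs$aa >= minAa, , drop = FALSE]
    if (nrow(orfs) < 2L) next
    orfs <- orfs[order(-(orfs$end - orfs$start + 1L), orfs$start), ,
                 drop = FALSE]
    sel <- integer(0)
    for (r in seq_len(nrow(orfs))) {
      clash <- any(orfs$start[r] <= orfs$end[sel] &
                   orfs$end[r] >= orfs$start[sel])
      if (!clash) sel <- c(sel, r)
    }
    if (length(sel) < 2L) next
    cds <- orfs[sel, c("start", "end", "aa"), drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    calls[[length(calls) + 1L]] <- list(tx_id = txIds(ts)[i],
                                        arity = nrow(cds), cds = cds)
  }
  calls
}

#' Inter-CDS distances of a polycistron call
#'
#' Spliced-coordinate gap between the stop codon of each ORF and the
#' start codon of the next (0 when adjacent).
#'
#' @param call one element of \code{\link{detectPolycistrons}} output.
#' @return integer vector of length arity - 1.
#' @export
intercdsDistance <- function(call) {
  cds <- call$cds
  if (any(cds$start[-1L] <= cds$end[-nrow(cds)]))
    stop("overlapping CDS regions")
  cds$start[-1L] - cds$end[-nrow(cds)] - 1L
}

#' Co-expression contrast of polycistron member genes vs random pairs
#'
#' Pearson correlation across tissues for each within-polycistron gene
#' pair, against \code{nRandom} random same-chromosome gene pairs, with a
#' one-sided rank-sum comparison (paired greater).
#'
#' @param memberPairs data.frame(gene_a, gene_b) of member-gene pairs.
#' @param expr gene x tissue expression matrix (rownames = gene ids).
#' @param geneChrom named character: chromosome of each gene.
#' @param nRandom number of random control pairs (default 1000).
#' @return list(paired, random, test) -- the two correlation samples and
#'   the \code{wilcox.test} result.
#' @export
coexpressionContrast <- function(memberPairs, expr, geneChrom,
                                 nRandom = 1000) {
  corOf <- function(a, b) {
    if (!(a %in% rownames(expr)) || !(b %in% rownames(expr)))
      return(NA_real_)
    suppressWarnings(stats::cor(expr[a, ], expr[b, ]))
  }
  paired <- mapply(corOf, memberPairs$gene_a, memberPairs$gene_b)
  paired <- paired[!is.na(paired)]
  if (length(paired) == 0L) stop("no quantifiable member pairs")
  genes <- intersect(rownames(expr), names(geneChrom))
  byChrom <- split(genes, geneChrom[genes])
  byChrom <- byChrom[lengths(byChrom) >= 2L]
  rnd <- numeric(0)
  while (length(rnd) < nRandom) {
    ch <- sample(names(byChrom), 1L)
    pair <- sample(byChrom[[ch]], 2L)
    r <- corOf(pair[1L], pair[2L])
    if (!is.na(r)) rnd <- c(rnd, r)
  }
  test <- stats::wilcox.test(paired, rnd, alternative = "greater",
                             exact = FALSE)
  list(paired = unname(paired), random = rnd, test = test)
}

#' Check co-linearity of a member-gene pair in other species
#'
#' A pair is co-linear in a species when both orthologs lie on the same
#' strand of the same chromosome with a gap below \code{maxDist} nt;
#' missing orthologs yield FALSE.
#'
#' @param geneA,geneB member gene ids.
#' @param orthologs data.frame(gene_id, species, chrom, start, end,
#'   strand).
#' @param maxDist co-linearity distance in nt (default 20000).
#' @return named logical vector over the species present in the map.
#' @export
checkColinearity <- function(geneA, geneB, orthologs, maxDist = 20000) {
  species <- sort(unique(orthologs$species))
  vapply(species, function(sp) {
    a <- orthologs[orthologs$gene_id == geneA & orthologs$species == sp, ,
                   drop = FALSE]
    b <- orthologs[orthologs$gene_id == geneB & orthologs$species == sp, ,
                   drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
    a <- a[1L, ]; b <- b[1L, ]
    if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
    gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
    gap < maxDist
  }, logical(1))
}
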