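## shared fixture builders

mkChain <- function(starts, ends, strand = "+", chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand)
}

mkTs <- function(chains, ...) {
  if (length(chains) == 0)
    return(TranscriptSet(GenomicRanges::GRangesList()))
  grl <- GenomicRanges::GRangesList(chains)
  if (is.null(names(grl))) names(grl) <- paste0("tx", seq_along(grl))
  TranscriptSet(grl, ...)
}

chainKey <- function(g) {
  paste(as.character(GenomicRanges::seqnames(g))[1],
        as.character(BiocGenerics::strand(g))[1],
        paste(BiocGenerics::start(g), BiocGenerics::end(g), collapse = ";"))
}

## a TagSignal from a compact spec: list(sample = list(strand, pos, count))
mkSignal <- function(end, ...) {
  specs <- list(...)
  rows <- lapply(names(specs), function(s) {
    sp <- specs[[s]]
    data.frame(chrom = "chr1", pos = sp$pos,
               strand = sp$strand %||% "+",
               sample = s, count = sp$count)
  })
  TagSignal(end, do.call(rbind, rows))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mkJx <- function(donor, acceptor, strand = "+", counts = NULL,
                 samples = c("s1")) {
  n <- length(donor)
  if (is.null(counts)) counts <- matrix(10, n, length(samples),
                                        dimnames = list(NULL, samples))
  isoforge:::junctionSet(rep("chr1", n), donor, acceptor,
                         rep(strand, length.out = n), counts)
}

randomTranscriptSet <- function(n, seed = 1) {
  set.seed(seed)
  chains <- lapply(seq_len(n), function(i) {
    nEx <- sample(1:6, 1)
    w <- sample(50:300, nEx, replace = TRUE)
    gaps <- sample(60:400, nEx, replace = TRUE)
    start0 <- sample(1:100000, 1)
    starts <- start0 + cumsum(c(0, (w + gaps)[-nEx]))
    mkChain(starts, starts + w - 1,
            strand = sample(c("+", "-"), 1),
            chrom = sample(c("chr1", "chr2"), 1))
  })
  sl <- vapply(chains, function(g) sum(BiocGenerics::width(g)), numeric(1))
  cdsOn <- sl >= 60 & stats::runif(n) < 0.5
  cs <- ifelse(cdsOn, 10L, NA_integer_)
  ce <- ifelse(cdsOn, pmin(sl, 10L + 3L * ((sl - 20L) %/% 3L)), NA_integer_)
  grl <- GenomicRanges::GRangesList(chains)
  names(grl) <- sprintf("t%04d", seq_len(n))
  TranscriptSet(grl, gene_id = sprintf("g%04d", seq_len(n)),
                cls = sample(c("isoF", "isoC", "isoN", NA), n, replace = TRUE),
                cds_start = cs, cds_end = as.integer(ce),
                fpkm = round(stats::runif(n, 0, 50), 3))
}

randomSeq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
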