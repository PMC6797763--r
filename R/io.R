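## Readers and writers for the standard formats touched by the pipeline.
## GTF and GFF3 are both accepted on input; GFF3 is the only output dialect.

#' Read transcript models from GTF or GFF3
#'
#' Uses rtracklayer to parse; exon children are collected per transcript,
#' sorted by start. An \code{FPKM} attribute (common assembler dialect) is
#' retained when present, as is a \code{cls} attribute written by
#' \code{\link{writeTranscripts}}. CDS features, when present, are mapped
#' back to spliced coordinates.
#'
#' @param path GTF or GFF3 file.
#' @return A \linkS4class{TranscriptSet}.
#' @export
readTranscripts <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  isExon <- type == "exon"
  isCds <- type == "CDS"
  if (!any(isExon)) {
    return(TranscriptSet(GenomicRanges::GRangesList()))
  }
  parentOf <- function(sub) {
    if (!is.null(mc$transcript_id)) {
      as.character(mc$transcript_id[sub])
    } else if (!is.null(mc$Parent)) {
      p <- mc$Parent[sub]
      vapply(as.list(p), function(z) if (length(z)) z[[1L]] else NA_character_,
             character(1))
    } else stop("cannot determine exon parents (no transcript_id/Parent)")
  }
  exParent <- parentOf(isExon)
  if (anyNA(exParent)) stop("exon feature without a parent transcript")
  exGr <- gr[isExon]
  S4Vectors::mcols(exGr) <- NULL
  grl <- GenomicRanges::split(exGr, factor(exParent, levels = unique(exParent)))
  txids <- names(grl)
  ## transcript-level rows for metadata
  isTx <- type %in% c("transcript", "mRNA")
  txMeta <- if (any(isTx)) {
    id <- if (!is.null(mc$ID)) as.character(mc$ID[isTx]) else
      as.character(mc$transcript_id[isTx])
    fp <- if (!is.null(mc$FPKM)) suppressWarnings(as.numeric(mc$FPKM[isTx]))
          else rep(NA_real_, sum(isTx))
    cls <- if (!is.null(mc$cls)) as.character(mc$cls[isTx])
           else rep(NA_character_, sum(isTx))
    gid <- if (!is.null(mc$gene_id)) as.character(mc$gene_id[isTx])
           else if (!is.null(mc$Parent))
             vapply(as.list(mc$Parent[isTx]),
                    function(z) if (length(z)) z[[1L]] else NA_character_,
                    character(1))
           else rep(NA_character_, sum(isTx))
    ## check exon containment in the transcript bounds
    txGr <- gr[isTx]
    m <- match(txids, id)
    for (k in seq_along(txids)) {
      if (is.na(m[k])) next
      tx <- txGr[m[k]]
      e <- grl[[k]]
      if (any(BiocGenerics::start(e) < BiocGenerics::start(tx)) ||
          any(BiocGenerics::end(e) > BiocGenerics::end(tx)))
        stop("exon outside transcript bounds for ", txids[k])
    }
    data.frame(id = id, fpkm = fp, cls = cls, gid = gid,
               stringsAsFactors = FALSE)
  } else NULL
  m <- if (is.null(txMeta)) rep(NA_integer_, length(txids)) else
    match(txids, txMeta$id)
  ts <- TranscriptSet(
    grl, tx_id = txids,
    gene_id = if (is.null(txMeta)) NA_character_ else txMeta$gid[m],
    cls = if (is.null(txMeta)) NA_character_ else txMeta$cls[m],
    fpkm = if (is.null(txMeta)) NA_real_ else txMeta$fpkm[m])
  ## CDS back-mapping to spliced coordinates
  if (any(isCds)) {
    cdsParent <- parentOf(isCds)
    cdsGr <- gr[isCds]
    td <- ts@txData
    for (id in unique(cdsParent)) {
      k <- match(id, txIds(ts))
      if (is.na(k)) next
      cg <- cdsGr[cdsParent == id]
      chain <- exonChains(ts)[[k]]
      sp <- genomicToSpliced(chain, c(BiocGenerics::start(cg),
                                      BiocGenerics::end(cg)))
      td$cds_start[k] <- min(sp)
      td$cds_end[k] <- max(sp)
    }
    ts@txData <- td
  }
  methods::validObject(ts)
  ts
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA, exon and (when spliced CDS coordinates are recorded)
#' CDS features, in deterministic order (chrom, start, transcript id).
#' The isoform class label is written as a \code{cls} attribute; FPKM is
#' written when present.
#'
#' @param ts a TranscriptSet.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTranscripts <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(ts) == 0L) return(invisible(path))
  ex <- exonChains(ts)
  td <- ts@txData
  gid <- geneIds(ts)
  if (anyNA(gid)) gid[is.na(gid)] <- paste0("g_", txIds(ts)[is.na(gid)])
  ext <- txExtent(ts)
  ord <- order(as.character(GenomicRanges::seqnames(ext)),
               BiocGenerics::start(ext), txIds(ts))
  esc <- function(x) gsub("[;=,\t\n]", "_", x)
  ## gene features: union extent per gene id
  geneRows <- split(seq_along(ts), gid)
  geneLines <- vapply(names(geneRows), function(g) {
    idx <- geneRows[[g]]
    sub <- ext[idx]
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
            as.character(GenomicRanges::seqnames(sub))[1L], "isoforge", "gene",
            min(BiocGenerics::start(sub)), max(BiocGenerics::end(sub)),
            as.character(BiocGenerics::strand(sub))[1L], esc(g))
  }, character(1))
  gstart <- vapply(names(geneRows), function(g)
    min(BiocGenerics::start(ext[geneRows[[g]]])), numeric(1))
  gchr <- vapply(names(geneRows), function(g)
    as.character(GenomicRanges::seqnames(ext[geneRows[[g]]]))[1L], character(1))
  writeLines(geneLines[order(gchr, gstart, names(geneRows))], con)
  for (i in ord) {
    id <- txIds(ts)[i]
    chain <- ex[[i]]
    chrom <- as.character(GenomicRanges::seqnames(chain))[1L]
    strand <- as.character(BiocGenerics::strand(chain))[1L]
    attrs <- sprintf("ID=%s;Parent=%s", esc(id), esc(gid[i]))
    if (!is.na(td$cls[i])) attrs <- paste0(attrs, ";cls=", td$cls[i])
    if (!is.na(td$fpkm[i]))
      attrs <- paste0(attrs, ";FPKM=", format(td$fpkm[i], digits = 10))
    writeLines(sprintf("%s\tisoforge\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                       chrom, min(BiocGenerics::start(chain)),
                       max(BiocGenerics::end(chain)), strand, attrs), con)
    writeLines(sprintf("%s\tisoforge\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       chrom, BiocGenerics::start(chain),
                       BiocGenerics::end(chain), strand, esc(id)), con)
    if (!is.na(td$cds_start[i])) {
      cg <- splicedToGenomic(chain, td$cds_start[i], td$cds_end[i])
      writeLines(sprintf("%s\tisoforge\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                         chrom, BiocGenerics::start(cg),
                         BiocGenerics::end(cg), strand, esc(id)), con)
    }
  }
  invisible(path)
}

#' Read per-base tag signal from bedGraph files
#'
#' bedGraph intervals (0-based half-open) are expanded to per-base
#' 1-based positions. Values must be non-negative; overlapping intervals
#' within one file are an error. Library size per sample is the total tag
#' count read.
#'
#' @param paths character vector of bedGraph files.
#' @param samples sample id for each file.
#' @param strands strand ("+"/"-"/".") of the signal in each file.
#' @param end "five_prime" or "three_prime".
#' @return A \linkS4class{TagSignal}.
#' @export
readTagSignal <- function(paths, samples, strands, end) {
  stopifnot(length(paths) == length(samples), length(paths) == length(strands))
  rows <- list()
  for (k in seq_along(paths)) {
    nonEmpty <- file.exists(paths[k]) && file.size(paths[k]) > 0
    df <- if (nonEmpty)
      utils::read.delim(paths[k], header = FALSE, sep = "",
                        comment.char = "#",
                        col.names = c("chrom", "start", "end", "value"),
                        colClasses = c("character", "integer", "integer",
                                       "numeric"))
    else data.frame(chrom = character(), start = integer(),
                    end = integer(), value = numeric())
    df <- df[!grepl("^track", df$chrom), , drop = FALSE]
    if (nrow(df)) {
      if (any(df$value < 0)) stop("negative value in ", paths[k])
      ## overlap check per chrom
      for (ch in unique(df$chrom)) {
        sub <- df[df$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
          stop("overlapping bedGraph intervals in ", paths[k])
      }
      n <- df$end - df$start
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = rep(df$chrom, n),
        pos = unlist(lapply(seq_len(nrow(df)),
                            function(i) seq(df$start[i] + 1L, df$end[i]))),
        strand = strands[k], sample = samples[k],
        count = rep(df$value, n), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = character(), pos = integer(), strand = character(),
        sample = character(), count = numeric())
    }
  }
  tg <- do.call(rbind, rows)
  sig <- TagSignal(end, tg)
  ## samples with no tags still need a (zero) library size entry
  missing <- setdiff(unique(samples), names(sig@libSize))
  if (length(missing))
    sig@libSize <- c(sig@libSize, stats::setNames(rep(0, length(missing)),
                                                  missing))
  sig
}

#' Write a TagSignal as one bedGraph per sample
#'
#' @param sig a TagSignal.
#' @param dir output directory.
#' @param prefix file name prefix; files are
#'   \code{<prefix>.<sample>.<plus|minus>.bedGraph}.
#' @return data.frame(sample, strand, path) manifest.
#' @export
writeTagSignal <- function(sig, dir, prefix = sig@end) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  combos <- unique(sig@tags[, c("sample", "strand")])
  if (nrow(combos) == 0L)
    combos <- data.frame(sample = tagSamples(sig), strand = "+")
  for (k in seq_len(nrow(combos))) {
    s <- combos$sample[k]; st <- combos$strand[k]
    sub <- sig@tags[sig@tags$sample == s & sig@tags$strand == st, ,
                    drop = FALSE]
    sub <- sub[order(sub$chrom, sub$pos), , drop = FALSE]
    path <- file.path(dir, sprintf("%s.%s.%s.bedGraph", prefix, s,
                                   if (st == "-") "minus" else "plus"))
    lines <- sprintf("%s\t%d\t%d\t%s", sub$chrom, sub$pos - 1L, sub$pos,
                     format(sub$count, trim = TRUE, scientific = FALSE))
    writeLines(lines, path)
    man[[length(man) + 1L]] <- data.frame(sample = s, strand = st,
                                          path = path)
  }
  do.call(rbind, man)
}

#' Read a splice-junction support table
#'
#' Tab-separated with columns chrom, donor, acceptor, strand, then one
#' count column per sample. Donor is the 0-based intron start; acceptor
#' is the exclusive intron end (both converted to the internal 1-based
#' closed intron interval). Duplicate junction rows are summed.
#'
#' @param path TSV file (header line with sample names).
#' @return DataFrame with columns chrom, donor, acceptor, strand and a
#'   counts matrix column (one column per sample).
#' @export
readJunctionTable <- function(path) {
  nonEmpty <- file.exists(path) && file.size(path) > 0
  df <- if (nonEmpty) utils::read.delim(path, header = TRUE,
                                        stringsAsFactors = FALSE)
        else data.frame(chrom = character(), donor = integer(),
                        acceptor = integer(), strand = character())
  fixed <- c("chrom", "donor", "acceptor", "strand")
  if (!all(fixed %in% colnames(df)))
    stop("junction table must have columns chrom, donor, acceptor, strand")
  sampleCols <- setdiff(colnames(df), fixed)
  if (nrow(df) && any(df$donor >= df$acceptor))
    stop("junction with donor >= acceptor")
  donor <- df$donor + 1L     # first intron base, 1-based
  acceptor <- df$acceptor    # last intron base, 1-based
  counts <- as.matrix(df[, sampleCols, drop = FALSE])
  junctionSet(df$chrom, donor, acceptor, df$strand, counts)
}

## canonical junction container: DataFrame with a counts matrix column,
## duplicates merged by summation, sorted by (chrom, donor, acceptor, strand)
junctionSet <- function(chrom, donor, acceptor, strand, counts) {
  if (length(chrom) == 0L) {
    return(S4Vectors::DataFrame(chrom = character(), donor = integer(),
                                acceptor = integer(), strand = character(),
                                counts = I(matrix(numeric(), 0, ncol(counts),
                                  dimnames = list(NULL, colnames(counts))))))
  }
  key <- paste(chrom, donor, acceptor, strand)
  agg <- rowsum(counts, key)
  first <- !duplicated(key)
  out <- S4Vectors::DataFrame(chrom = chrom[first], donor = donor[first],
                              acceptor = acceptor[first],
                              strand = strand[first])
  out$counts <- agg[match(paste(out$chrom, out$donor, out$acceptor,
                                out$strand), rownames(agg)), , drop = FALSE]
  out <- out[order(out$chrom, out$donor, out$acceptor, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write a junction table (inverse of readJunctionTable)
#' @param jx junction DataFrame with counts matrix column.
#' @param path output TSV.
#' @export
writeJunctionTable <- function(jx, path) {
  df <- data.frame(chrom = jx$chrom, donor = jx$donor - 1L,
                   acceptor = jx$acceptor, strand = jx$strand,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(jx$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-read alignments from BED12
#'
#' Each BED12 record becomes an exon chain (blocks = exons).
#'
#' @param path BED12 file.
#' @return GRangesList of exon chains, names from the BED name column.
#' @export
readBed12 <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(GenomicRanges::GRangesList())
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  names(bl) <- make.unique(as.character(S4Vectors::mcols(gr)$name))
  ## blocks() drops strand on some paths; restore from parent record
  GenomicRanges::GRangesList(lapply(seq_along(bl), function(i) {
    g <- bl[[i]]
    BiocGenerics::strand(g) <- as.character(BiocGenerics::strand(gr[i]))
    S4Vectors::mcols(g) <- NULL
    g
  })) -> out
  names(out) <- names(bl)
  out
}

#' Write exon chains as BED12
#' @param grl GRangesList of exon chains.
#' @param path output file.
#' @export
writeBed12 <- function(grl, path) {
  if (length(grl) == 0L) { writeLines(character(), path); return(invisible(path)) }
  lines <- vapply(seq_along(grl), function(i) {
    g <- grl[[i]]
    g <- g[order(BiocGenerics::start(g))]
    chrom <- as.character(GenomicRanges::seqnames(g))[1L]
    strand <- as.character(BiocGenerics::strand(g))[1L]
    cs <- BiocGenerics::start(g) - 1L
    ce <- BiocGenerics::end(g)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom, cs[1L], ce[length(ce)],
            if (is.null(names(grl))) paste0("read", i) else names(grl)[i],
            strand, cs[1L], ce[length(ce)], length(g),
            paste0(paste(ce - cs, collapse = ","), ","),
            paste0(paste(cs - cs[1L], collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export site clusters as BED6
#'
#' name = cluster id, score = summit pooled signal (capped at 1000 for
#' BED compliance is deliberately NOT applied; consumers are internal).
#'
#' @param cs a SiteClusterSet
#' @param path output file
#' @export
writeClustersBed <- function(cs, path) {
  gr <- clusterRanges(cs)
  if (length(gr) == 0L) { writeLines(character(), path); return(invisible(path)) }
  sig <- vapply(seq_along(gr), function(i) {
    S4Vectors::mcols(gr)$total[i]
  }, numeric(1))
  lines <- sprintf("%s\t%d\t%d\t%s_%05d\t%s\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   clusterKind(cs), seq_along(gr),
                   format(sig, trim = TRUE),
                   as.character(BiocGenerics::strand(gr)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#' @param path TSV with a gene id first column and one column per sample.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an expression matrix to TSV
#' @param m numeric matrix, gene rownames.
#' @param path output TSV.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable thresholds of the pipeline, named per module, with defaults
#' equal to the published operating point of the method (tag clustering
#' minValue 20 / max length 200 / density fold 5; reliable-cluster TPM 0.5
#' and top signal 10 in >= 3 samples; 400 nt assembly merge; 50 nt summit
#' pruning; credible junctions >= 3 reads in >= 1 sample; transfrag FPKM
#' 0.5 single-exon / 0.2 multi-exon and 500 nt boundary fixing; microexon
#' <= 51 nt; switch score > 0.3 with dominant usage > 0.5; APA deltaL >
#' 100 nt at TPM > 5; hotspot k 3..10, fold 3, > 3 evidences; polycistron
#' major CDS >= 100 codons, co-linearity < 20 kb).
#'
#' @param ... named overrides of the form \code{section$name}, e.g.
#'   \code{clustering = list(min_value = 10)} (partial lists are merged).
#' @return nested list of settings.
#' @export
isoforgeConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    clustering = list(min_value = 20, max_length = 200, min_density_fold = 5,
                      tpm_min = 0.5, top_signal_min = 10, min_samples = 3,
                      assembly_merge_nt = 400, prune_nt = 50),
    assembler = list(window = 100, junction_min_reads = 3,
                     junction_min_samples = 1),
    ngs = list(single_exon_min_fpkm = 0.5, multi_exon_min_fpkm = 0.2,
               boundary_max_dist = 500),
    features = list(microexon_max_nt = 51, rg4_min_tract = 4,
                    rg4_min_loop = 2, rg4_max_loop = 7,
                    urich_window = 10, urich_min_frac = 0.8,
                    urich_min_len = 6, uorf_min_aa = 2),
    dynamics = list(expressed_frac = 0.2, dominant_min = 0.5,
                    switch_w_min = 0.3, apa_delta_min = 100, apa_tpm_min = 5,
                    cluster_tpm_min = 0.5, cluster_min_tissues = 2),
    hotspot = list(k_min = 3, k_max = 10, fold = 3, min_evidence = 3),
    polycistron = list(min_aa = 100, colinear_max_dist = 20000,
                       n_random = 1000),
    samples = list())
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read / write a run configuration (YAML)
#' @param path YAML file.
#' @return for \code{readConfig}, the config list merged over defaults.
#' @export
readConfig <- function(path) {
  do.call(isoforgeConfig, yaml::read_yaml(path))
}

#' @rdname readConfig
#' @param cfg config list from \code{\link{isoforgeConfig}}.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
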