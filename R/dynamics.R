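## Expression quantification contracts and the transcriptome-dynamics
## statistics: entropy-based tissue specificity, dominant-site usage,
## switch scores, weighted 3'UTR length, and APA switch calls.

#' Fragments per kilobase per million
#' @param count mapped reads/fragments for the feature.
#' @param length feature length in nt.
#' @param library total mapped fragments.
#' @return FPKM = count * 1e9 / (length * library).
#' @export
computeFpkm <- function(count, length, library) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(library <= 0)) stop("library must be positive")
  count * 1e9 / (length * library)
}

#' Entropy-based tissue specificity score
#'
#' S = Hmax - Hobs = log2(N) + sum_i P_i log2 P_i, where P_i is the
#' row-normalised expression in tissue i and 0*log2(0) is taken as 0.
#' S is 0 for perfectly uniform expression and log2(N) for expression
#' confined to a single tissue.
#'
#' @param exprRow non-negative expression values across N tissues (vector
#'   or matrix with tissues in columns).
#' @return specificity score(s) S.
#' @export
tissueSpecificity <- function(exprRow) {
  f <- function(x) {
    if (any(x < 0)) stop("negative expression")
    tot <- sum(x)
    if (tot == 0) stop("all-zero expression row")
    p <- x / tot
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    log2(length(x)) - h
  }
  if (is.matrix(exprRow)) apply(exprRow, 1L, f) else f(exprRow)
}

#' Tissues in which a gene counts as expressed
#'
#' Expressed in tissue i when its level is strictly above \code{frac}
#' times the maximum across tissues.
#'
#' @param exprRow non-negative expression values.
#' @param frac fraction of the maximum (default 0.2).
#' @return indices (or names, when present) of expressed tissues.
#' @export
expressedTissues <- function(exprRow, frac = 0.2) {
  if (any(exprRow < 0)) stop("negative expression")
  hit <- exprRow > frac * max(exprRow)
  if (!is.null(names(exprRow))) names(exprRow)[hit] else which(hit)
}

#' Dominant site of a usage row
#'
#' The site carrying strictly more than half of the signal, when one
#' exists.
#'
#' @param usageRow usage fractions over the sites of one gene in one
#'   tissue (sums to 1, or all zero).
#' @return site index (or name), or NA when no site dominates.
#' @export
dominantSite <- function(usageRow) {
  hit <- which(usageRow > 0.5)
  if (length(hit) != 1L)
    return(if (!is.null(names(usageRow))) NA_character_ else NA_integer_)
  if (!is.null(names(usageRow))) names(usageRow)[hit] else hit
}

#' Switch score between two tissues
#'
#' W = P_{i,d(i)} + P_{j,d(j)} - 1 when the dominant sites differ, else 0.
#' W lies in [0, 1] and is symmetric.
#'
#' @param usageI,usageJ usage rows of the same gene in two tissues; both
#'   must have a dominant site.
#' @return the switch score W.
#' @export
switchScore <- function(usageI, usageJ) {
  di <- dominantSite(usageI); dj <- dominantSite(usageJ)
  if (is.na(di) || is.na(dj)) stop("both tissues must have a dominant site")
  if (identical(di, dj)) return(0)
  unname(usageI[di] + usageJ[dj] - 1)
}

#' Usage fractions from a site x tissue signal matrix
#' @param signal non-negative matrix, sites in rows, tissues in columns.
#' @return matrix of per-tissue usage fractions (columns sum to 1, or 0
#'   for all-zero tissues).
#' @export
usageFractions <- function(signal) {
  tot <- colSums(signal)
  sweep(signal, 2L, ifelse(tot > 0, tot, NA_real_), "/") -> u
  u[is.na(u)] <- 0
  u
}

#' Call dynamic switch genes
#'
#' A gene switches when the set of per-tissue dominant sites has at least
#' two members and the maximum pairwise switch score is strictly above
#' \code{wMin}.
#'
#' @param usageList named list; per gene a sites x tissues usage-fraction
#'   matrix (on clusters surviving the 50 nt summit pruning).
#' @param wMin switch-score threshold (default 0.3, strict).
#' @return data.frame(gene_id, n_dominant, max_w, called).
#' @export
callSwitchGenes <- function(usageList, wMin = 0.3) {
  rows <- lapply(names(usageList), function(g) {
    u <- usageList[[g]]
    doms <- vapply(seq_len(ncol(u)), function(j) {
      d <- dominantSite(u[, j])
      if (is.na(d)) NA_character_ else as.character(d)
    }, character(1))
    have <- which(!is.na(doms))
    nd <- length(unique(doms[have]))
    maxW <- 0
    if (nd >= 2L) {
      for (a in have) for (b in have) {
        if (a < b && doms[a] != doms[b]) {
          w <- switchScore(u[, a], u[, b])
          if (w > maxW) maxW <- w
        }
      }
    }
    data.frame(gene_id = g, n_dominant = nd, max_w = maxW,
               called = nd >= 2L && maxW > wMin)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighted 3'UTR length
#'
#' L_w = sum_s P_s * length_s over the gene's termination sites.
#'
#' @param usageRow usage fractions over sites (one tissue).
#' @param utrLengths 3'UTR length of each site, same order.
#' @return the usage-weighted mean 3'UTR length.
#' @export
weightedUtrLength <- function(usageRow, utrLengths) {
  if (length(usageRow) != length(utrLengths))
    stop("usage and length vectors differ in length")
  if (any(utrLengths < 0)) stop("negative UTR length")
  sum(usageRow * utrLengths)
}

#' Call an APA switch between two samples
#'
#' TRUE when the weighted 3'UTR length changes by strictly more than
#' \code{deltaMin} nt and the total termination-site signal is strictly
#' above \code{tpmMin} TPM in both samples.
#'
#' @param usage sites x samples usage-fraction matrix of one gene.
#' @param utrLengths per-site 3'UTR lengths.
#' @param tpm sites x samples TPM matrix (same sites).
#' @param a,b the two sample columns to compare.
#' @param deltaMin length-change threshold in nt (default 100).
#' @param tpmMin total TPM threshold (default 5).
#' @return logical.
#' @export
callApaSwitch <- function(usage, utrLengths, tpm, a, b,
                          deltaMin = 100, tpmMin = 5) {
  la <- weightedUtrLength(usage[, a], utrLengths)
  lb <- weightedUtrLength(usage[, b], utrLengths)
  abs(la - lb) > deltaMin &&
    sum(tpm[, a]) > tpmMin && sum(tpm[, b]) > tpmMin
}

#' Prefilter site clusters for dynamics analyses
#'
#' Keeps clusters with TPM above \code{tpmMin} in at least
#' \code{minTissues} tissues AND average TPM above \code{tpmMin} across
#' all samples, then prunes summits within \code{pruneNt} of each other
#' (larger total signal wins).
#'
#' @param cs SiteClusterSet.
#' @param tpmMin TPM threshold (default 0.5, strict).
#' @param minTissues tissue count for the per-tissue rule (default 2).
#' @param pruneNt summit pruning distance (default 50).
#' @return filtered SiteClusterSet.
#' @export
dynamicsClusterFilter <- function(cs, tpmMin = 0.5, minTissues = 2,
                                  pruneNt = 50) {
  if (length(cs) == 0L) return(cs)
  tpm <- clusterTpm(cs)
  keep <- rowSums(tpm > tpmMin) >= minTissues & rowMeans(tpm) > tpmMin
  pruneWithin(cs[which(keep)], cutoff = pruneNt)
}
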