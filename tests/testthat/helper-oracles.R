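## independent brute-force oracles used by the property tests

## exhaustive maximal-scoring-segment oracle for the tag clustering:
## enumerates all O(n^2) runs, computes each run's coherence density
## directly, and keeps runs denser than every enclosing run, then applies
## the same retention and flattening rules as the implementation
oracleClusterRuns <- function(pos, val, minValue, maxLength, fold) {
  n <- length(pos)
  M <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) next
    pre <- sapply(i:(j - 1), function(k) sum(val[i:k]) / (pos[k + 1] - pos[i]))
    suf <- sapply((i + 1):j, function(k) sum(val[k:j]) / (pos[j] - pos[k - 1]))
    M[i, j] <- min(pre, suf)
  }
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    sup <- 0
    for (a in 1:i) for (b in j:n)
      if (!(a == i && b == j)) sup <- max(sup, M[a, b])
    if (M[i, j] > sup) {
      tot <- sum(val[i:j]); span <- pos[j] - pos[i] + 1
      fl <- if (sup <= 0) Inf else M[i, j] / sup
      if (tot >= minValue && span <= maxLength && fl >= fold)
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  keep <- rep(TRUE, nrow(m))
  for (r in seq_len(nrow(m))) for (q in seq_len(nrow(m)))
    if (r != q && m[q, 1] <= m[r, 1] && m[q, 2] >= m[r, 2] &&
        !(m[q, 1] == m[r, 1] && m[q, 2] == m[r, 2]))
      keep[r] <- FALSE
  out <- data.frame(i = m[keep, 1], j = m[keep, 2])
  out[order(out$i), , drop = FALSE]
}

## brute-force longest ORF: walk codons from every ATG position
oracleLongestOrf <- function(seq) {
  s <- toupper(chartr("U", "T", seq))
  L <- nchar(s)
  best <- NULL
  for (i in seq_len(max(L - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i
    while (j + 2 <= L) {
      cod <- substr(s, j, j + 2)
      if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2 - i + 1
        if (is.null(best) || len > best$len) best <- list(start = i,
                                                          end = j + 2,
                                                          len = len)
        break
      }
      j <- j + 3
    }
  }
  best
}

oracleUorfs <- function(seq, minAa = 2) {
  s <- toupper(chartr("U", "T", seq))
  L <- nchar(s)
  hits <- list()
  for (i in seq_len(max(L - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= L) {
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        if ((j - i) / 3 >= minAa)
          hits[[length(hits) + 1L]] <- c(i, j + 2)
        break
      }
      j <- j + 3
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], end = m[, 2])
}

## naive G-quadruplex scan: same motif definition, regex-free enumeration
oracleRg4 <- function(seq, minTract = 4, minLoop = 2, maxLoop = 7) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ## maximal G runs
  runs <- list(); i <- 1
  while (i <= length(s)) {
    if (s[i] == "G") {
      j <- i
      while (j < length(s) && s[j + 1] == "G") j <- j + 1
      if (j - i + 1 >= minTract) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) < 4) return(data.frame(start = integer(), end = integer()))
  hits <- list()
  for (a in seq_len(length(runs) - 3)) {
    ok <- TRUE
    for (q in 0:2) {
      gap <- runs[[a + q + 1]][1] - runs[[a + q]][2] - 1
      if (gap < minLoop || gap > maxLoop) { ok <- FALSE; break }
    }
    if (ok) {
      sc <- sum(sapply(a:(a + 3), function(q) runs[[q]][2] - runs[[q]][1] + 1))
      hits[[length(hits) + 1]] <- c(runs[[a]][1], runs[[a + 3]][2], sc)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, hits)
  h <- data.frame(start = m[, 1], end = m[, 2], score = m[, 3])
  h <- h[order(-h$score, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (r in seq_len(nrow(h))) {
    if (!keep[r]) next
    for (q in seq_len(nrow(h))) {
      if (q <= r || !keep[q]) next
      if (h$start[q] <= h$end[r] && h$end[q] >= h$start[r]) keep[q] <- FALSE
    }
  }
  h <- h[keep, c("start", "end")]
  h[order(h$start), , drop = FALSE]
}

## naive U-rich scan: test every window position directly
oracleUrich <- function(seq, window = 10, minFrac = 0.8, minLen = 6) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  L <- length(s)
  w <- min(window, L)
  if (w < minLen || L < minLen)
    return(data.frame(start = integer(), end = integer()))
  qual <- logical(L - w + 1)
  for (i in seq_len(L - w + 1))
    qual[i] <- mean(s[i:(i + w - 1)] == "T") >= minFrac
  covered <- logical(L)
  for (i in which(qual)) covered[i:(i + w - 1)] <- TRUE
  ## runs of covered positions that start at a qualifying window
  out <- list()
  i <- 1
  while (i <= L - w + 1) {
    if (qual[i]) {
      j <- i
      while (j < L - w + 1 && qual[j + 1]) j <- j + 1
      out[[length(out) + 1]] <- c(i, j + w - 1)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  h <- data.frame(start = m[, 1], end = m[, 2])
  h[h$end - h$start + 1 >= minLen, , drop = FALSE]
}

## branching-process pmf via stats::dbinom convolution (independent of
## the package's explicit-binomial-coefficient recursion)
oraclePmf <- function(p, K) {
  pmf <- c(dbinom(0, 1, p), dbinom(1, 1, p))   # X_1 = 1 + Bern(p)
  if (K > 1) for (s in seq_len(K - 1)) {
    nxt <- numeric(2 * length(pmf))
    for (i in seq_along(pmf)) {
      if (pmf[i] == 0) next
      add <- dbinom(0:i, i, p)
      nxt[i + 0:i] <- nxt[i + 0:i] + pmf[i] * add
    }
    pmf <- nxt
  }
  pmf
}
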