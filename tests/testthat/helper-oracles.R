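# Shared fixtures and independent brute-force oracles used across tests.

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# least rotation of a motif, written independently of the package
leastRotation <- function(motif) {
  m <- nchar(motif)
  min(vapply(seq_len(m), function(i)
    paste0(substr(motif, i, m), substr(motif, 1, i - 1)), ""))
}

# Exhaustive SSR oracle: walks every (position, motif length) pair,
# counts whole tandem units by direct string comparison, keeps
# left-maximal runs meeting the threshold whose motif is primitive.
ssrOracle <- function(seq, thresholds = defaultSsrThresholds()) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (n < m * thr) next
    # necessary condition s[i] == s[i+m] prunes hopeless starts; the
    # counting itself stays naive
    candidate <- which(chars[seq_len(n - m)] == chars[(m + 1):n])
    for (i in candidate) {
      if (i + 2L * m - 1L > n) next
      motif <- substr(seq, i, i + m - 1L)
      if (grepl("[^ACGT]", motif)) next
      primitive <- TRUE
      for (p in seq_len(m - 1L))
        if (m %% p == 0L &&
            strrep(substr(motif, 1, p), m / p) == motif) {
          primitive <- FALSE
          break
        }
      if (!primitive) next
      if (i > 1L && substr(seq, i - 1L, i - 1L) ==
            substr(seq, i + m - 1L, i + m - 1L)) next   # not left-maximal
      k <- 1L
      while (i + (k + 1L) * m - 1L <= n &&
             substr(seq, i + k * m, i + (k + 1L) * m - 1L) == motif)
        k <- k + 1L
      if (k < thr) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = leastRotation(motif), unitCount = k,
        start = i - 1L, end = i - 1L + m * k, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
  else data.frame(motif = character(0), unitCount = integer(0),
                  start = integer(0), end = integer(0),
                  stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs repeat oracle by diagonal (forward) and antidiagonal
# (palindromic) scans; maximal runs only. The same tandem-collapse
# definition as the package (overlapping copies sharing a merged span
# keep the smallest offset) is applied to the enumerated pairs.
repeatOracle <- function(seq, minLen = 30L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  rows <- list()
  addRuns <- function(eq, toHit) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (j in which(r$values & r$lengths >= minLen)) {
      i0 <- ends[j] - r$lengths[j] + 1L
      rows[[length(rows) + 1L]] <<- toHit(i0, r$lengths[j])
    }
  }
  for (d in 1:(n - minLen)) {
    eq <- chars[1:(n - d)] == chars[(1 + d):n] &
      chars[1:(n - d)] %in% c("A", "C", "G", "T")
    addRuns(eq, function(i0, len) data.frame(
      kind = "forward", start1 = i0 - 1L, end1 = i0 - 1L + len,
      start2 = i0 + d - 1L, end2 = i0 + d - 1L + len, length = len,
      stringsAsFactors = FALSE))
  }
  cc <- comp[chars]
  for (a in 2:(2L * n)) {
    lo <- max(1L, a - n)
    hi <- min(n, a - 1L)
    if (hi - lo + 1L < minLen) next
    u <- lo:hi
    eq <- chars[u] == cc[a - u]
    addRuns(eq, function(i0, len) {
      s1 <- u[i0]
      s2 <- a - s1 - len + 1L
      data.frame(kind = "palindromic",
                 start1 = min(s1, s2) - 1L, end1 = min(s1, s2) - 1L + len,
                 start2 = max(s1, s2) - 1L, end2 = max(s1, s2) - 1L + len,
                 length = len, stringsAsFactors = FALSE)
    })
  }
  out <- if (length(rows)) unique(do.call(rbind, rows))
  else data.frame(kind = character(0), start1 = integer(0),
                  end1 = integer(0), start2 = integer(0),
                  end2 = integer(0), length = integer(0),
                  stringsAsFactors = FALSE)
  # shared tandem-collapse definition
  overl <- out$start2 < out$end1
  if (any(overl)) {
    ov <- out[overl, , drop = FALSE]
    key <- paste(ov$kind, pmin(ov$start1, ov$start2),
                 pmax(ov$end1, ov$end2))
    pick <- unlist(lapply(split(seq_len(nrow(ov)), key), function(ix)
      ix[which.min(ov$start2[ix] - ov$start1[ix])]))
    out <- rbind(out[!overl, , drop = FALSE], ov[sort(pick), , drop = FALSE])
  }
  out <- out[order(out$kind, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force intraspecific-pi oracle: expands a pileup column into an
# explicit list of observations and counts mismatching unordered read
# pairs directly.
piIntraOracle <- function(counts, deletions, minCov = 10L) {
  L <- ncol(counts)
  h <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    obs <- c(rep("A", counts["A", i]), rep("C", counts["C", i]),
             rep("G", counts["G", i]), rep("T", counts["T", i]))
    cov <- length(obs) + deletions[i]
    if (cov < minCov || deletions[i] / max(cov, 1) > 0.5 || cov < 2) next
    mm <- 0L
    for (aI in seq_along(obs)[-1])
      for (bI in seq_len(aI - 1L))
        if (obs[aI] != obs[bI]) mm <- mm + 1L
    h[i] <- mm / (cov * (cov - 1) / 2)
  }
  h
}

# Affine local-alignment best score by dynamic programming
# (match 1 / mismatch -1 / gap open 4 / gap extend 1), independent of
# Biostrings; used to check recruitment decisions.
swScoreOracle <- function(a, b, match = 1, mismatch = -1,
                          gapOpen = 4, gapExt = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in y (x consumed)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, X[i - 1, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Y[i, j - 1] - gapExt)
      best <- max(best, M[i, j])
    }
  }
  best
}

# tiny in-memory SAM writer for two-path pileup tests
writeSamFixture <- function(path, refId, refLen, ids, starts, seqs,
                            cigars = paste0(nchar(seqs), "M")) {
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", refId, refLen),
               sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       ids, refId, starts, cigars, seqs)), path)
  path
}
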