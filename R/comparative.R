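# Comparative plastome statistics: GC content by partition, perfect
# microsatellites (SSRs) at MISA-style unit-count thresholds, exact long
# forward/palindromic repeats, indel/SNP catalogues from a multiple
# alignment, and codon usage with RSCU.

#' GC content of a DNA string
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq character DNA string.
#' @return fraction (G + C) / (A + C + G + T) in `[0, 1]`.
#' @export
gcContent <- function(seq) {
  tab <- table(strsplit(toupper(seq), "")[[1]])
  acgt <- sum(tab[intersect(names(tab), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("GC content undefined: no unambiguous bases")
  gc <- sum(tab[intersect(names(tab), c("G", "C"))])
  gc / acgt
}

#' Length and GC summary of a genome, by quadripartite partition
#'
#' @param genome a [GenomeRecord-class] (partitioned or not).
#' @return data.frame with one row per region (`total`, and `lsc`, `ira`,
#'   `ssc`, `irb` when partitioned) giving `length` and `gc`.
#' @export
plastomeSummary <- function(genome) {
  seq <- genomeSeq(genome)
  out <- data.frame(region = "total", length = nchar(seq),
                    gc = gcContent(seq), stringsAsFactors = FALSE)
  part <- genomePartition(genome)
  for (r in intersect(c("lsc", "ira", "ssc", "irb"), names(part))) {
    iv <- part[[r]]
    sub <- substr(seq, iv[1] + 1L, iv[2])
    out <- rbind(out, data.frame(region = r, length = nchar(sub),
                                 gc = gcContent(sub)))
  }
  out
}

# default MISA-style unit-count thresholds by motif length
#' @export
defaultSsrThresholds <- function()
  c(`1` = 8L, `2` = 4L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

# lexicographically least rotation of a motif
canonicalMotif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(motif)
  rots <- vapply(seq_len(m), function(i)
    paste0(substr(motif, i, m), substr(motif, 1, i - 1L)), "")
  min(rots)
}

# smallest period of a string (== nchar when the string is primitive)
smallestPeriod <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        identical(strrep(substr(s, 1, p), n %/% p), s)) return(p)
  }
  n
}

#' Find perfect microsatellites (SSRs)
#'
#' Scans for maximal perfect tandem runs of 1-6 bp motifs meeting
#' per-motif-length unit-count thresholds (MISA-style defaults: 8 units
#' for mononucleotides, 4 for di- and tri-, 3 for tetra- to
#' hexanucleotides). A single mismatch terminates a run. Motifs are
#' reported as their lexicographically least rotation; runs whose motif is
#' itself periodic (e.g. `AA` as a dinucleotide) are reported at the
#' smallest period only. Runs containing `N` are not extended through it.
#'
#' @param seq character DNA string.
#' @param thresholds named integer vector, names `"1"`..`"6"`, minimum
#'   unit counts per motif length.
#' @param features optional feature table (as in a GenomeRecord) used to
#'   classify each hit's context as CDS / intron / IGS.
#' @return data.frame with columns `motif`, `unitCount`, `start`, `end`
#'   (0-based half-open, length = motif length x unit count), `context`.
#' @export
findSSRs <- function(seq, thresholds = defaultSsrThresholds(),
                     features = NULL) {
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  hits <- list()
  for (m in 1:6) {
    if (n < 2L * m) next
    thr <- thresholds[[as.character(m)]]
    eq <- chars[seq_len(n - m)] == chars[(m + 1L):n] &
      valid[seq_len(n - m)] & valid[(m + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + m          # total matched region length
      units <- span %/% m
      if (units < thr) next
      i <- starts[j]                    # 1-based start of the run
      motif <- substr(seq, i, i + m - 1L)
      if (smallestPeriod(motif) < m) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = canonicalMotif(motif), unitCount = units,
        start = i - 1L, end = i - 1L + m * units,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
  else data.frame(motif = character(0), unitCount = integer(0),
                  start = integer(0), end = integer(0),
                  stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$context <- classifyContext(out$start, out$end, features)
  out
}

# CDS / intron / IGS / unknown context from a feature table
classifyContext <- function(start, end, features) {
  if (is.null(features) || !nrow(features))
    return(rep("unknown", length(start)))
  vapply(seq_along(start), function(i) {
    inCds <- any(features$kind == "CDS" &
                   features$start < end[i] & features$end > start[i])
    if (inCds) return("CDS")
    # intron: between two intervals of the same (multi-exon) feature
    for (f in unique(features$feature)) {
      fx <- features[features$feature == f, , drop = FALSE]
      if (nrow(fx) < 2L) next
      fx <- fx[order(fx$start), ]
      for (k in seq_len(nrow(fx) - 1L))
        if (start[i] >= fx$end[k] && end[i] <= fx$start[k + 1L])
          return("intron")
    }
    "IGS"
  }, "")
}

#' Find exact long repeats (forward and palindromic)
#'
#' Reports all maximal exact repeat pairs of length >= `minLen`: forward
#' (both copies on the same strand) and palindromic (second copy is the
#' exact reverse complement). Maximality means the match cannot be
#' extended on either side. Pairs of a tandem array whose copies overlap
#' and share a merged span are collapsed to the pair with the smallest
#' offset (the fundamental period).
#'
#' @param seq character DNA string.
#' @param minLen minimum repeat length in bp (default 30, must be >= 8).
#' @return data.frame with columns `kind` (`forward`/`palindromic`),
#'   `start1`, `end1`, `start2`, `end2` (0-based half-open; copy 1 starts
#'   first), `length`.
#' @export
findRepeats <- function(seq, minLen = 30L) {
  stopifnot(minLen >= 8L)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (n < minLen) return(empty)
  k <- as.integer(minLen)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  ok <- !grepl("N", kmers, fixed = TRUE)

  # forward: anchor pairs grouped by diagonal, consecutive runs merged
  grp <- split(which(ok), kmers[ok])
  grp <- grp[lengths(grp) > 1L]
  fwd <- list()
  if (length(grp)) {
    pairs <- do.call(rbind, lapply(grp, function(p) {
      cmb <- utils::combn(p, 2L)
      cbind(p1 = cmb[1, ], p2 = cmb[2, ])
    }))
    d <- pairs[, "p2"] - pairs[, "p1"]
    for (dd in unique(d)) {
      p1s <- sort(pairs[d == dd, "p1"])
      runs <- split(p1s, cumsum(c(1L, diff(p1s) != 1L)))
      for (r in runs) {
        len <- length(r) + k - 1L
        s1 <- r[1]
        fwd[[length(fwd) + 1L]] <- c(s1, dd, len)
      }
    }
  }
  out <- empty
  if (length(fwd)) {
    fm <- do.call(rbind, fwd)
    out <- rbind(out, data.frame(
      kind = "forward", start1 = fm[, 1] - 1L, end1 = fm[, 1] - 1L + fm[, 3],
      start2 = fm[, 1] + fm[, 2] - 1L, end2 = fm[, 1] + fm[, 2] - 1L + fm[, 3],
      length = fm[, 3], stringsAsFactors = FALSE))
  }

  # palindromic: match k-mers against reverse-complement k-mers,
  # anchors grouped by antidiagonal p1 + p2
  rcseq <- revComp(seq)
  rckmers <- substring(rcseq, 1:(n - k + 1L), k:n)
  # rc k-mer at rcseq position j covers seq positions (n-j-k+2)..(n-j+1)
  rcstart <- n - seq_along(rckmers) - k + 2L
  both <- split(
    data.frame(pos = c(which(ok), rcstart[!grepl("N", rckmers, fixed = TRUE)]),
               src = rep(c(1L, 2L), c(sum(ok), sum(!grepl("N", rckmers, fixed = TRUE)))),
               stringsAsFactors = FALSE),
    c(kmers[ok], rckmers[!grepl("N", rckmers, fixed = TRUE)]))
  pal <- list()
  for (g in both) {
    p1 <- g$pos[g$src == 1L]
    p2 <- g$pos[g$src == 2L]
    if (!length(p1) || !length(p2)) next
    # all anchors, including p1 > p2: chains crossing the palindrome
    # centre must stay unbroken; mirror duplicates are dropped later
    pal[[length(pal) + 1L]] <- cbind(rep(p1, each = length(p2)),
                                     rep(p2, times = length(p1)))
  }
  if (length(pal)) {
    pm <- unique(do.call(rbind, pal))
    anti <- pm[, 1] + pm[, 2]
    rows <- list()
    for (aa in unique(anti)) {
      p1s <- sort(pm[anti == aa, 1])
      # consecutive anchors (p1+1 pairs with p2-1) extend the same match
      runs <- split(p1s, cumsum(c(1L, diff(p1s) != 1L)))
      for (r in runs) {
        q <- r[1]
        rlen <- length(r)
        len <- rlen + k - 1L
        rows[[length(rows) + 1L]] <- c(q, aa - q - rlen + 1L, len)
      }
    }
    pmat <- do.call(rbind, rows)
    df <- data.frame(kind = "palindromic",
                     start1 = pmat[, 1] - 1L, end1 = pmat[, 1] - 1L + pmat[, 3],
                     start2 = pmat[, 2] - 1L, end2 = pmat[, 2] - 1L + pmat[, 3],
                     length = pmat[, 3], stringsAsFactors = FALSE)
    # each disjoint pair appears twice (copies swapped); keep copy1 first
    df <- df[df$start1 <= df$start2, , drop = FALSE]
    out <- rbind(out, unique(df))
  }
  out <- collapseTandem(out)
  out <- out[order(out$kind, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# among hits whose copies overlap and share a merged span, keep the pair
# with the smallest offset (the fundamental period of the tandem array)
collapseTandem <- function(hits) {
  if (!nrow(hits)) return(hits)
  overl <- hits$start2 < hits$end1
  if (!any(overl)) return(hits)
  ov <- hits[overl, , drop = FALSE]
  key <- paste(ov$kind, pmin(ov$start1, ov$start2),
               pmax(ov$end1, ov$end2))
  pick <- unlist(lapply(split(seq_len(nrow(ov)), key), function(ix) {
    ix[which.min(ov$start2[ix] - ov$start1[ix])]
  }))
  rbind(hits[!overl, , drop = FALSE], ov[sort(pick), , drop = FALSE])
}

#' Catalogue SNP sites and indel events in a multiple alignment
#'
#' A SNP site is a gap-free, `N`-free column with >= 2 distinct bases. An
#' indel event is a maximal run of consecutive gap-containing columns
#' sharing one gap/non-gap row pattern (so a 5-column gap is one 5 bp
#' event). Columns whose pattern changes start a new event.
#'
#' @param aln a [GenomeAlignment-class].
#' @param features optional feature table in coordinates of the reference
#'   row (ungapped); a site is assigned to a feature when its ungapped
#'   reference coordinate falls inside the feature.
#' @param refRow which alignment row anchors feature coordinates.
#' @return list with `snps` (data.frame: `column` 0-based, `refPos`
#'   0-based on the reference row, one base column per row), `indels`
#'   (data.frame: `start`, `end` alignment columns 0-based half-open,
#'   `length`, `pattern` of `-`/`*` per row), and `featureTallies`.
#' @export
callVariants <- function(aln, features = NULL, refRow = 1L) {
  m <- alignmentMatrix(aln)
  nr <- nrow(m)
  nc <- ncol(m)
  isGap <- m == "-"
  hasGap <- colSums(isGap) > 0L
  hasN <- colSums(m == "N") > 0L

  # map alignment column -> 0-based ungapped position on the reference row
  refUngapped <- cumsum(!isGap[refRow, ]) - 1L

  snpCol <- which(!hasGap & !hasN &
                    apply(m, 2, function(col) length(unique(col)) > 1L))
  snps <- data.frame(column = snpCol - 1L, refPos = refUngapped[snpCol])
  for (r in seq_len(nr))
    snps[[rownames(m)[r]]] <- m[r, snpCol]

  gcols <- which(hasGap)
  indels <- data.frame(start = integer(0), end = integer(0),
                       length = integer(0), pattern = character(0),
                       stringsAsFactors = FALSE)
  if (length(gcols)) {
    pat <- apply(isGap[, gcols, drop = FALSE], 2, function(g)
      paste(ifelse(g, "-", "*"), collapse = ""))
    newRun <- c(TRUE, diff(gcols) != 1L | pat[-1L] != pat[-length(pat)])
    runId <- cumsum(newRun)
    indels <- do.call(rbind, lapply(split(seq_along(gcols), runId),
      function(ix) {
        data.frame(start = gcols[ix[1]] - 1L,
                   end = gcols[ix[length(ix)]],
                   length = length(ix), pattern = pat[ix[1]],
                   stringsAsFactors = FALSE)
      }))
    rownames(indels) <- NULL
  }

  tallies <- NULL
  if (!is.null(features) && nrow(features)) {
    featOf <- function(refPos) {
      hit <- features$start <= refPos & features$end > refPos
      if (any(hit)) features$name[which(hit)[1]] else NA_character_
    }
    snpFeat <- vapply(snps$refPos, featOf, "")
    indelFeat <- if (nrow(indels))
      vapply(refUngapped[indels$start + 1L], featOf, "") else character(0)
    nm <- unique(features$name)
    tallies <- data.frame(
      name = nm,
      snps = vapply(nm, function(x) sum(snpFeat == x, na.rm = TRUE), 0L),
      indels = vapply(nm, function(x) sum(indelFeat == x, na.rm = TRUE), 0L),
      stringsAsFactors = FALSE)
    rownames(tallies) <- NULL
  }
  list(snps = snps, indels = indels, featureTallies = tallies)
}

#' Codon usage and relative synonymous codon usage (RSCU)
#'
#' Counts codons across in-frame coding sequences and computes
#' `RSCU(c) = count(c) * k / sum(counts of c's synonymous codons)` where
#' `k` is the size of the synonymous group. Amino-acid grouping follows
#' the bacterial/plastid codon table (identical codon-to-amino-acid map
#' as the standard table); stop codons form their own group. Sequences
#' whose length is not divisible by 3 are rejected with a warning; codons
#' containing `N` are skipped.
#'
#' @param cdsSeqs character vector of in-frame CDS sequences.
#' @return list with `codons` (data.frame: `codon`, `aa`, `count`,
#'   `rscu`; `rscu` is `NA` when the amino acid is unobserved) and
#'   `totalCodons`.
#' @export
codonUsage <- function(cdsSeqs) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  counts <- setNames(integer(64), codons)
  for (i in seq_along(cdsSeqs)) {
    s <- toupper(cdsSeqs[[i]])
    if (nchar(s) %% 3L != 0L) {
      warning("CDS ", i, " length not divisible by 3; skipped")
      next
    }
    cs <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cs <- cs[cs %in% codons]
    tab <- table(cs)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa <- unname(code[codons])
  rscu <- rep(NA_real_, 64)
  for (a in unique(aa)) {
    ix <- which(aa == a)
    tot <- sum(counts[ix])
    if (tot > 0) rscu[ix] <- counts[ix] * length(ix) / tot
  }
  list(codons = data.frame(codon = codons, aa = aa,
                           count = unname(counts), rscu = rscu,
                           stringsAsFactors = FALSE),
       totalCodons = sum(counts))
}
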