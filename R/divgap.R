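# Diversity-Gap scoring: interspecific nucleotide diversity from a genome
# alignment, intraspecific diversity per species from read pileups, the
# gap score G = pi_inter - max_s pi_intra[s], homopolymer screening and
# ranked candidate-marker windows.
#
# pi is the average pairwise difference per site (Nei-Li) at both levels:
# between alignment rows for pi_inter, between reads within a pileup
# column for pi_intra.

.baseToInt <- local({
  v <- integer(256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
})

emptyPileup <- function(refId, L) {
  new("Pileup", refId = refId, refLength = as.integer(L),
      counts = matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL)),
      deletions = integer(L), insertions = integer(L),
      nReadsMapped = 0L, nReadsDiscarded = 0L)
}

#' Build a read pileup by mapping reads to a reference genome
#'
#' Each read is placed at its best position on either strand by k-mer
#' seeding; an ungapped placement is used when its identity clears
#' `minIdentity`, otherwise a gapped alignment
#' ([Biostrings::pairwiseAlignment]) against the seeded region decides.
#' Reads below `minIdentity` over their aligned span are discarded.
#' Aligned bases accumulate into per-position base counts, deleted
#' reference positions into deletion counts; read insertions relative to
#' the reference are tallied per position but excluded from diversity
#' statistics. On circular references reads may wrap through the origin.
#'
#' @param reads a [ReadSet-class].
#' @param reference a [GenomeRecord-class].
#' @param minIdentity minimum aligned identity to keep a read.
#' @param seedLength k-mer length used for seeding placements.
#' @return a [Pileup-class].
#' @export
pileupFromReads <- function(reads, reference, minIdentity = 0.9,
                            seedLength = 15L) {
  L <- length(reference)
  refSeq <- genomeSeq(reference)
  if (length(reads) == 0L) {
    warning("empty ReadSet '", speciesLabel(reads), "': empty pileup")
    return(emptyPileup(genomeId(reference), L))
  }
  w <- Biostrings::width(reads@reads)
  if (L < max(w)) stop("reference shorter than the longest read")
  ext <- if (isCircular(reference)) max(w) + 16L else 0L
  refExt <- if (ext > 0L) paste0(refSeq, substr(refSeq, 1L, ext)) else refSeq
  nExt <- nchar(refExt)
  k <- as.integer(seedLength)
  kmers <- substring(refExt, 1:(nExt - k + 1L), k:nExt)
  index <- split(seq_len(nExt - k + 1L), kmers)
  refInt <- .baseToInt[utf8ToInt(refExt)]

  seqs <- as.character(reads@reads)
  posAll <- integer(0); baseAll <- integer(0)
  delPos <- integer(0); insPos <- integer(0)
  nMapped <- 0L; nDrop <- 0L

  placeUngapped <- function(rd, rw) {
    offs <- unique(pmax(1L, c(1L, (rw - k) %/% 2L + 1L, rw - k + 1L)))
    cand <- integer(0)
    for (o in offs) {
      hit <- index[[substr(rd, o, o + k - 1L)]]
      if (!is.null(hit)) cand <- c(cand, hit - o + 1L)
    }
    cand <- cand[cand >= 1L & cand + rw - 1L <= nExt]
    if (!length(cand)) return(NULL)
    tab <- sort(table(cand), decreasing = TRUE)
    starts <- as.integer(names(tab))[seq_len(min(3L, length(tab)))]
    rdInt <- .baseToInt[utf8ToInt(rd)]
    best <- NULL; bestId <- -1
    for (s in starts) {
      m <- sum(rdInt == refInt[s:(s + rw - 1L)] & rdInt > 0L)
      if (m / rw > bestId) { bestId <- m / rw; best <- s }
    }
    list(start = best, identity = bestId)
  }

  for (i in seq_along(seqs)) {
    rw <- w[i]
    placed <- FALSE
    bestOverall <- NULL
    for (orient in 1:2) {
      rd <- if (orient == 1L) seqs[i] else revComp(seqs[i])
      p <- placeUngapped(rd, rw)
      if (is.null(p)) next
      if (is.null(bestOverall) || p$identity > bestOverall$identity)
        bestOverall <- c(p, list(rd = rd))
    }
    if (!is.null(bestOverall) && bestOverall$identity >= minIdentity) {
      s <- bestOverall$start
      posAll <- c(posAll, s:(s + rw - 1L))
      baseAll <- c(baseAll, .baseToInt[utf8ToInt(bestOverall$rd)])
      nMapped <- nMapped + 1L
      placed <- TRUE
    } else if (!is.null(bestOverall)) {
      # gapped fallback around the seeded region
      s <- bestOverall$start
      lo <- max(1L, s - 16L); hi <- min(nExt, s + rw + 15L)
      pa <- Biostrings::pairwiseAlignment(
        bestOverall$rd, substr(refExt, lo, hi), type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 4, gapExtension = 1)
      pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      ident <- sum(pat == sub & pat != "-") / length(pat)
      if (ident >= minIdentity) {
        refPos <- lo + Biostrings::start(Biostrings::subject(pa)) - 1L
        prev <- refPos - 1L
        for (j in seq_along(pat)) {
          if (sub[j] != "-") {
            if (pat[j] != "-") {
              posAll <- c(posAll, refPos)
              baseAll <- c(baseAll, .baseToInt[utf8ToInt(pat[j])])
            } else delPos <- c(delPos, refPos)
            prev <- refPos
            refPos <- refPos + 1L
          } else if (pat[j] != "-") {
            insPos <- c(insPos, prev)
          }
        }
        nMapped <- nMapped + 1L
        placed <- TRUE
      }
    }
    if (!placed) nDrop <- nDrop + 1L
  }

  keep <- baseAll > 0L
  posAll <- posAll[keep]; baseAll <- baseAll[keep]
  posMod <- (posAll - 1L) %% L
  counts <- matrix(tabulate(baseAll + 4L * posMod, nbins = 4L * L), nrow = 4L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  storage.mode(counts) <- "integer"
  dels <- tabulate((delPos - 1L) %% L + 1L, nbins = L)
  inss <- tabulate((pmax(insPos, 1L) - 1L) %% L + 1L, nbins = L)
  new("Pileup", refId = genomeId(reference), refLength = as.integer(L),
      counts = counts, deletions = as.integer(dels),
      insertions = as.integer(inss),
      nReadsMapped = nMapped, nReadsDiscarded = nDrop)
}

#' Build a pileup from a pre-mapped SAM file
#'
#' Consumes QNAME/FLAG/RNAME/POS/CIGAR/SEQ only, honouring M/=/X/I/D/S
#' (and N/H) CIGAR operations. Unmapped records (flag 0x4) are skipped.
#'
#' @param path SAM text file (with `@SQ` header, as required for
#'   conversion).
#' @param reference a [GenomeRecord-class] the reads were mapped to.
#' @return a [Pileup-class].
#' @export
pileupFromSam <- function(path, reference) {
  L <- length(reference)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("flag", "pos", "cigar", "seq")))[[1]]
  posAll <- integer(0); baseAll <- integer(0)
  delPos <- integer(0); insPos <- integer(0)
  nMapped <- 0L
  for (i in seq_along(res$pos)) {
    if (bitwAnd(res$flag[i], 4L) != 0L || is.na(res$pos[i])) next
    ops <- regmatches(res$cigar[i],
                      gregexpr("\\d+[MIDNSHP=X]", res$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    kinds <- sub("\\d+", "", ops)
    rd <- as.character(res$seq[i])
    qpos <- 1L
    rpos <- res$pos[i]
    for (j in seq_along(ops)) {
      n <- lens[j]
      switch(kinds[j],
        "M" = , "=" = , "X" = {
          posAll <- c(posAll, rpos:(rpos + n - 1L))
          baseAll <- c(baseAll,
                       .baseToInt[utf8ToInt(substr(rd, qpos, qpos + n - 1L))])
          qpos <- qpos + n; rpos <- rpos + n
        },
        "I" = { insPos <- c(insPos, rpos - 1L); qpos <- qpos + n },
        "D" = { delPos <- c(delPos, rpos:(rpos + n - 1L)); rpos <- rpos + n },
        "N" = { rpos <- rpos + n },
        "S" = { qpos <- qpos + n },
        NULL)
    }
    nMapped <- nMapped + 1L
  }
  keep <- baseAll > 0L
  posAll <- posAll[keep]; baseAll <- baseAll[keep]
  counts <- matrix(tabulate(baseAll + 4L * ((posAll - 1L) %% L),
                            nbins = 4L * L), nrow = 4L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  storage.mode(counts) <- "integer"
  new("Pileup", refId = genomeId(reference), refLength = as.integer(L),
      counts = counts,
      deletions = as.integer(tabulate((delPos - 1L) %% L + 1L, nbins = L)),
      insertions = as.integer(tabulate((pmax(insPos, 1L) - 1L) %% L + 1L,
                                       nbins = L)),
      nReadsMapped = nMapped, nReadsDiscarded = 0L)
}

#' Interspecific nucleotide diversity over an alignment window
#'
#' Over gap-free, `N`-free columns in the window, averages the per-site
#' mismatch fraction over all row pairs (Nei-Li pairwise diversity).
#'
#' @param aln a [GenomeAlignment-class].
#' @param start,end window in alignment columns, 0-based half-open.
#' @param minSites minimum usable columns; below it `piInter` is `NA`.
#' @return list with `piInter` and `usableSites`.
#' @export
interspecificDiversity <- function(aln, start, end, minSites = 20L) {
  m <- alignmentMatrix(aln)
  stopifnot(start >= 0, end <= ncol(m), start < end)
  mw <- m[, (start + 1L):end, drop = FALSE]
  usable <- colSums(mw == "-" | mw == "N") == 0L
  u <- sum(usable)
  if (u < minSites) return(list(piInter = NA_real_, usableSites = u))
  mw <- mw[, usable, drop = FALSE]
  nr <- nrow(mw)
  total <- 0L
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr)
    total <- total + sum(mw[i, ] != mw[j, ])
  npairs <- nr * (nr - 1L) / 2L
  list(piInter = total / npairs / u, usableSites = u)
}

# per-site read-pair heterozygosity h for every reference position:
# h = sum_{b<b'} c_b c_b' / (c(c-1)/2) with c = coverage incl. deletions.
# Returns list(h, qualifying) over the whole reference.
siteHeterozygosity <- function(pileup, minCov = 10L) {
  cnt <- pileup@counts
  tBase <- colSums(cnt)
  cov <- tBase + pileup@deletions
  qual <- cov >= minCov & (pileup@deletions / pmax(cov, 1L)) <= 0.5
  hetPairs <- (tBase^2 - colSums(cnt^2)) / 2
  h <- ifelse(cov >= 2L, hetPairs / (cov * (cov - 1) / 2), NA_real_)
  list(h = h, qualifying = qual & !is.na(h))
}

#' Intraspecific nucleotide diversity from a read pileup
#'
#' Per qualifying site (coverage >= `minCov`, deletion fraction <= 0.5)
#' the site heterozygosity is the fraction of mismatching unordered read
#' pairs, `h = sum_{b<b'} c_b c_b' / (c(c-1)/2)`; `piIntra` is the mean
#' `h` over qualifying sites in the window. Within-sample read-pair
#' diversity estimates heteroplasmic variation plus sequencing error.
#'
#' @param pileup a [Pileup-class].
#' @param start,end window on the reference, 0-based half-open.
#' @param minCov coverage floor for a site to qualify.
#' @param minSites minimum qualifying sites; below it `piIntra` is `NA`.
#' @return list with `piIntra` and `usableSites`.
#' @export
intraspecificDiversity <- function(pileup, start, end, minCov = 10L,
                                   minSites = 20L) {
  stopifnot(start >= 0, end <= pileup@refLength, start < end)
  sh <- siteHeterozygosity(pileup, minCov)
  ix <- (start + 1L):end
  q <- sh$qualifying[ix]
  u <- sum(q)
  if (u < minSites) return(list(piIntra = NA_real_, usableSites = u))
  list(piIntra = mean(sh$h[ix][q]), usableSites = u)
}

#' The Diversity Gap
#'
#' `G = pi_inter - max_s pi_intra[s]` (conservative aggregation over
#' species; `aggregate = "mean"` uses the mean instead). `NA` inputs
#' yield `NA` (the window is excluded downstream).
#'
#' @param piInter interspecific diversity of the region.
#' @param piIntraBySpecies numeric vector (or list) of per-species
#'   intraspecific diversities.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return the gap score G.
#' @export
diversityGap <- function(piInter, piIntraBySpecies,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  v <- unlist(piIntraBySpecies)
  if (is.na(piInter) || any(is.na(v))) return(NA_real_)
  piInter - if (aggregate == "max") max(v) else mean(v)
}

# longest single-base run in a character DNA string
maxHomopolymerRun <- function(s) {
  if (!nchar(s)) return(0L)
  r <- rle(strsplit(s, "")[[1]])
  max(r$lengths)
}

#' Slide windows over an aligned genome trio and rank by Diversity Gap
#'
#' For each window of `windowLen` alignment columns (stepped by `step`),
#' computes `pi_inter` from the alignment, `pi_intra` per species from
#' that species' read pileup over the window's image in its own genome
#' coordinates, and the gap score G. Windows are screened for
#' homopolymer stretches (any row carrying a single-base run >=
#' `homopolymerMax` within the window or its flanks fails) and for
#' conserved flanks (`flankLen` columns each side with no gaps and
#' `pi_inter <= flankMaxPi`), mirroring the requirement that primers land
#' on conserved sequence and that polynucleotide stretches sequence
#' poorly. Qualifying windows (G > 0) are sorted by G descending (ties:
#' smaller start), overlapping candidates are merged keeping the
#' higher-G window, and ranks run consecutively from 1.
#'
#' @param aln a [GenomeAlignment-class] of the species' genomes.
#' @param pileups named list of [Pileup-class], one per alignment row
#'   (names must match row names).
#' @param windowLen,step window length and step in alignment columns.
#' @param homopolymerMax single-base run length that disqualifies.
#' @param flankLen,flankMaxPi flank width and its maximum `pi_inter`.
#' @param minCov,minSites pileup coverage floor and minimum usable sites.
#' @param aggregate how G aggregates intraspecific diversity.
#' @param topK keep at most this many candidates.
#' @return list with `windows` (every window with its statistics and
#'   flags) and `candidates` (ranked data.frame; columns `rank`, `start`,
#'   `end` in 0-based half-open alignment columns, `G`, `piInter`,
#'   `piIntra.<species>`, flank intervals).
#' @export
rankWindows <- function(aln, pileups, windowLen = 200L, step = 50L,
                        homopolymerMax = 8L, flankLen = 20L,
                        flankMaxPi = 0, minCov = 10L, minSites = 20L,
                        aggregate = "max", topK = Inf) {
  m <- alignmentMatrix(aln)
  species <- rownames(m)
  if (!all(species %in% names(pileups)))
    stop("pileups must be named for every alignment row")
  nc <- ncol(m)
  isGap <- m == "-"
  # cumulative non-gap counts: ngBefore[r, c+1] = bases of row r in
  # columns 1..c -> 0-based species coordinates of column ranges
  ngBefore <- cbind(0L, t(apply(!isGap, 1, cumsum)))
  rownames(ngBefore) <- rownames(m)

  # per-pair mismatch and usable-column cumsums for O(1) window pi_inter
  usable <- colSums(isGap | m == "N") == 0L
  nr <- nrow(m)
  pairIdx <- utils::combn(nr, 2L)
  mmCum <- matrix(0, ncol(pairIdx), nc + 1L)
  for (p in seq_len(ncol(pairIdx))) {
    d <- m[pairIdx[1, p], ] != m[pairIdx[2, p], ] & usable
    mmCum[p, ] <- c(0, cumsum(d))
  }
  usCum <- c(0, cumsum(usable))
  gapCum <- c(0, cumsum(colSums(isGap) > 0L))

  sh <- lapply(pileups[species], siteHeterozygosity, minCov = minCov)

  starts <- seq(0L, nc - windowLen, by = step)  # 0-based col starts
  rows <- lapply(starts, function(s0) {
    e0 <- s0 + windowLen
    u <- usCum[e0 + 1L] - usCum[s0 + 1L]
    piInter <- if (u >= minSites)
      sum(mmCum[, e0 + 1L] - mmCum[, s0 + 1L]) / ncol(pairIdx) / u
    else NA_real_

    piIntra <- vapply(species, function(sp) {
      rs <- ngBefore[sp, s0 + 1L]; re <- ngBefore[sp, e0 + 1L]
      if (re - rs < 1L) return(NA_real_)
      ix <- (rs + 1L):re
      q <- sh[[sp]]$qualifying[ix]
      if (sum(q) < minSites) NA_real_ else mean(sh[[sp]]$h[ix][q])
    }, 0)

    G <- diversityGap(piInter, piIntra, aggregate)

    hs0 <- max(0L, s0 - flankLen); he0 <- min(nc, e0 + flankLen)
    homop <- any(vapply(species, function(sp) {
      sub <- paste(m[sp, (hs0 + 1L):he0], collapse = "")
      maxHomopolymerRun(gsub("-", "", sub)) >= homopolymerMax
    }, TRUE))

    flankOk <- FALSE
    if (s0 - flankLen >= 0L && e0 + flankLen <= nc) {
      lGaps <- gapCum[s0 + 1L] - gapCum[s0 - flankLen + 1L]
      rGaps <- gapCum[e0 + flankLen + 1L] - gapCum[e0 + 1L]
      lu <- usCum[s0 + 1L] - usCum[s0 - flankLen + 1L]
      ru <- usCum[e0 + flankLen + 1L] - usCum[e0 + 1L]
      lmm <- sum(mmCum[, s0 + 1L] - mmCum[, s0 - flankLen + 1L])
      rmm <- sum(mmCum[, e0 + flankLen + 1L] - mmCum[, e0 + 1L])
      lPi <- if (lu > 0) lmm / ncol(pairIdx) / lu else NA
      rPi <- if (ru > 0) rmm / ncol(pairIdx) / ru else NA
      flankOk <- lGaps == 0L && rGaps == 0L && !is.na(lPi) && !is.na(rPi) &&
        lPi <= flankMaxPi && rPi <= flankMaxPi
    }

    c(list(start = s0, end = e0, piInter = piInter),
      as.list(setNames(piIntra, paste0("piIntra.", species))),
      list(G = G, usableSites = u, homopolymer = homop, flankOk = flankOk))
  })
  windows <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  cand <- windows[!windows$homopolymer & windows$flankOk &
                    !is.na(windows$G) & windows$G > 0, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no window qualifies as a marker candidate")
    return(list(windows = windows,
                candidates = cbind(rank = integer(0), cand)))
  }
  cand <- cand[order(-cand$G, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$start < cand$end[i] & cand$end > cand$start[i]
    keep[i] <- !any(ov)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- utils::head(cand, if (is.finite(topK)) topK else nrow(cand))
  cand <- cbind(rank = seq_len(nrow(cand)), cand)
  rownames(cand) <- NULL
  list(windows = windows, candidates = cand)
}

#' Map an alignment-column interval to one row's ungapped coordinates
#'
#' @param aln a [GenomeAlignment-class].
#' @param row row name or index.
#' @param start,end 0-based half-open alignment-column interval.
#' @return integer `c(start, end)`, 0-based half-open in the row's
#'   ungapped sequence.
#' @export
alignmentToSeqCoords <- function(aln, row, start, end) {
  g <- strsplit(alignmentRows(aln)[[row]], "")[[1]] != "-"
  ng <- c(0L, cumsum(g))
  c(ng[start + 1L], ng[end + 1L])
}
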