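# Target-centred allele profiling: extract a fragment with the target
# region in the middle, recruit reads by local alignment, and tabulate
# allele types and frequencies among reads fully spanning the target.

#' Extract a fragment centred on a target region
#'
#' The fragment has `fragmentLen` bp with the target in the middle
#' (left pad = `floor((fragmentLen - targetLen)/2)`). On circular
#' genomes the fragment wraps through the origin; on linear genomes it
#' is clipped at the ends with a warning.
#'
#' @param genome a [GenomeRecord-class].
#' @param targetStart,targetEnd target interval, 0-based half-open.
#' @param fragmentLen total fragment length (default 600 bp).
#' @return object of class `TargetFragment`: list with `genomeId`,
#'   `fragmentStart`, `fragmentEnd` (genome coords; `end` may exceed the
#'   genome length when wrapped), `targetStart`, `targetEnd`,
#'   `targetOffset` (0-based offset of the target inside the fragment)
#'   and `fragmentSeq`.
#' @export
extractTargetFragment <- function(genome, targetStart, targetEnd,
                                  fragmentLen = 600L) {
  L <- length(genome)
  tlen <- targetEnd - targetStart
  if (tlen >= fragmentLen)
    stop("target (", tlen, " bp) longer than fragment (", fragmentLen, ")")
  stopifnot(targetStart >= 0, targetEnd <= L)
  leftPad <- (fragmentLen - tlen) %/% 2L
  fragStart <- targetStart - leftPad
  fragEnd <- fragStart + fragmentLen
  if (isCircular(genome)) {
    normStart <- ((fragStart %% L) + L) %% L
    seq <- sliceRegion(genome, normStart, normStart + fragmentLen,
                       allowWrap = TRUE)
    offset <- leftPad
  } else {
    clipStart <- max(0L, fragStart)
    clipEnd <- min(L, fragEnd)
    if (clipStart > fragStart || clipEnd < fragEnd)
      warning("fragment clipped at linear genome end: [",
              clipStart, ",", clipEnd, ")")
    seq <- substr(genomeSeq(genome), clipStart + 1L, clipEnd)
    fragStart <- clipStart; fragEnd <- clipEnd
    offset <- targetStart - clipStart
  }
  structure(list(genomeId = genomeId(genome),
                 fragmentStart = fragStart, fragmentEnd = fragEnd,
                 targetStart = targetStart, targetEnd = targetEnd,
                 targetOffset = offset, fragmentSeq = seq),
            class = "TargetFragment")
}

#' @export
print.TargetFragment <- function(x, ...) {
  cat(sprintf(
    "TargetFragment on '%s': fragment %d bp, target [%d,%d) at offset %d\n",
    x$genomeId, nchar(x$fragmentSeq), x$targetStart, x$targetEnd,
    x$targetOffset))
  invisible(x)
}

.alnScoring <- function() Biostrings::nucleotideSubstitutionMatrix(
  match = 1, mismatch = -1, baseOnly = FALSE)

# k-mer prefilter: does any read k-mer (stride `by`) occur in the
# fragment or its reverse complement?
sharesKmer <- function(readSeqs, fragSeq, k = 11L) {
  n <- nchar(fragSeq)
  fk <- unique(c(substring(fragSeq, 1:(n - k + 1L), k:n),
                 substring(revComp(fragSeq), 1:(n - k + 1L), k:n)))
  vapply(readSeqs, function(rd) {
    w <- nchar(rd)
    if (w < k) return(FALSE)
    any(substring(rd, 1:(w - k + 1L), k:w) %in% fk)
  }, TRUE, USE.NAMES = FALSE)
}

#' Recruit reads matching a target fragment
#'
#' A read is recruited when its best local gapped alignment to the
#' fragment, on either strand, spans at least `minHitLen` aligned
#' columns with identity at least `minIdentity` (an explicit,
#' database-free replacement for a BLAST e-value cutoff). Recruited
#' reads are orientation-normalised to the fragment strand. A cheap
#' shared-k-mer screen rejects clearly unrelated reads before aligning.
#'
#' @param fragment a `TargetFragment`.
#' @param reads a [ReadSet-class].
#' @param minIdentity minimum aligned identity (default 0.8, so a 250 bp
#'   read with up to 20 percent divergence is recruited).
#' @param minHitLen minimum aligned length in columns.
#' @return a [ReadSet-class] of recruited, orientation-normalised reads.
#' @export
recruitReads <- function(fragment, reads, minIdentity = 0.8,
                         minHitLen = 50L) {
  seqs <- readSequences(reads)
  if (!length(seqs))
    return(ReadSet(speciesLabel(reads), character(0)))
  keepPre <- sharesKmer(seqs, fragment$fragmentSeq)
  cand <- seqs[keepPre]
  if (!length(cand)) {
    message("no reads recruited for '", speciesLabel(reads), "'")
    return(ReadSet(speciesLabel(reads), character(0)))
  }
  uniq <- unique(unname(cand))
  sc <- .alnScoring()
  alnStat <- function(patterns) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), fragment$fragmentSeq,
      type = "local", substitutionMatrix = sc,
      gapOpening = 4, gapExtension = 1)
    cbind(len = Biostrings::nchar(pa), ident = Biostrings::nmatch(pa) /
            pmax(Biostrings::nchar(pa), 1L))
  }
  fwd <- alnStat(uniq)
  rev <- alnStat(vapply(uniq, revComp, ""))
  useRev <- rev[, "ident"] * rev[, "len"] > fwd[, "ident"] * fwd[, "len"]
  best <- fwd; best[useRev, ] <- rev[useRev, ]
  ok <- best[, "len"] >= minHitLen & best[, "ident"] >= minIdentity
  oriented <- ifelse(useRev, vapply(uniq, revComp, ""), uniq)
  lut <- setNames(ifelse(ok, oriented, NA_character_), uniq)
  out <- lut[unname(cand)]
  keep <- !is.na(out)
  if (!any(keep))
    message("no reads recruited for '", speciesLabel(reads), "'")
  ReadSet(speciesLabel(reads),
          setNames(unname(out[keep]), names(cand)[keep]))
}

# Align one read to the fragment and return its characters over
# fragment positions: list(fragFrom, fragTo 1-based, chars vector with
# '-' for deletions, insertions = named list pos -> inserted string).
alignReadToFragment <- function(read, fragSeq) {
  pa <- Biostrings::pairwiseAlignment(
    read, fragSeq, type = "local", substitutionMatrix = .alnScoring(),
    gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  from <- Biostrings::start(Biostrings::subject(pa))
  chars <- character(0)
  ins <- list()
  fpos <- from - 1L
  for (j in seq_along(pat)) {
    if (sub[j] != "-") {
      fpos <- fpos + 1L
      chars[fpos - from + 1L] <- pat[j]
    } else if (fpos >= from - 1L) {
      key <- as.character(fpos)
      ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]],
                           pat[j])
    }
  }
  list(fragFrom = from, fragTo = fpos, chars = chars, insertions = ins)
}

#' Tabulate allele types among reads spanning the target window
#'
#' Each recruited read is gap-aligned to the fragment; reads fully
#' spanning the target window contribute one allele string: their
#' aligned characters over the target columns, with deletions as `-`
#' and insertions spliced in after the column they follow. Counts are
#' aggregated per distinct allele string; `totalMapped` is fixed before
#' the `minCount` filter so shares always refer to all spanning reads.
#'
#' @param recruited a [ReadSet-class] of orientation-normalised reads
#'   (see [recruitReads]).
#' @param fragment the `TargetFragment` they were recruited against.
#' @param minCount records with fewer reads are dropped (after
#'   `totalMapped` is fixed).
#' @return an [AlleleTable-class].
#' @export
tabulateAlleles <- function(recruited, fragment, minCount = 1L) {
  seqs <- unname(readSequences(recruited))
  t1 <- fragment$targetOffset + 1L                 # 1-based target cols
  t2 <- fragment$targetOffset + (fragment$targetEnd - fragment$targetStart)
  alleles <- character(0)
  if (length(seqs)) {
    uniq <- table(seqs)
    per <- lapply(names(uniq), function(rd) {
      a <- alignReadToFragment(rd, fragment$fragmentSeq)
      if (a$fragFrom > t1 || a$fragTo < t2) return(NULL)  # not spanning
      cols <- vapply(t1:t2, function(p) {
        ch <- a$chars[p - a$fragFrom + 1L]
        if (is.na(ch)) ch <- "-"
        insAfter <- if (p < t2) a$insertions[[as.character(p)]] else NULL
        paste0(ch, if (is.null(insAfter)) "" else insAfter)
      }, "")
      paste(cols, collapse = "")
    })
    n <- as.integer(uniq)
    keep <- !vapply(per, is.null, TRUE)
    alleles <- rep(unlist(per[keep]), n[keep])
  }
  total <- length(alleles)
  if (total) {
    tab <- table(alleles)
    rec <- data.frame(allele = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    rec <- rec[order(-rec$count, rec$allele), , drop = FALSE]
    rec$share <- rec$count / total
    rec <- rec[rec$count >= minCount, , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec <- data.frame(allele = character(0), count = integer(0),
                      share = numeric(0), stringsAsFactors = FALSE)
  }
  new("AlleleTable", speciesLabel = speciesLabel(recruited),
      totalMapped = as.integer(total), records = rec)
}

#' Shares of the top-k alleles
#'
#' @param table an [AlleleTable-class].
#' @param k how many top records.
#' @return numeric vector of `count / totalMapped` for the top `k`
#'   records.
#' @export
dominantShare <- function(table, k = 1L) {
  if (totalMapped(table) == 0L || !nrow(alleleRecords(table)))
    stop("dominant share undefined: no mapped reads")
  rec <- utils::head(alleleRecords(table), k)
  rec$count / totalMapped(table)
}
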