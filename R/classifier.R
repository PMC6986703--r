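# Diagnostic-indel rules: derive the column ranges whose gap/non-gap
# pattern separates species from a star alignment of their dominant
# alleles, and classify query amplicons by those indel patterns,
# tolerating substitutions outside the diagnostic regions.

# Right-normalise gaps in a pairwise alignment: shift every gap run as
# far right as possible while the alignment score is preserved (the
# character entering the gap's left edge must equal the one leaving its
# right edge). Makes indel placement in repeats deterministic and
# end-anchored, matching the conventional rendering of tail insertions.
shiftGapsRight <- function(rowWithGaps, otherRow) {
  a <- strsplit(rowWithGaps, "")[[1]]
  b <- strsplit(otherRow, "")[[1]]
  n <- length(a)
  repeat {
    moved <- FALSE
    i <- 1L
    while (i <= n) {
      if (a[i] == "-") {
        j <- i
        while (j < n && a[j + 1L] == "-") j <- j + 1L
        if (j < n && a[j + 1L] != "-" && b[i] != "-" &&
            b[i] == b[j + 1L]) {
          a[i] <- a[j + 1L]
          a[j + 1L] <- "-"
          moved <- TRUE
          i <- i + 1L
        } else i <- j + 1L
      } else i <- i + 1L
    }
    if (!moved) break
  }
  paste(a, collapse = "")
}

# Global pairwise alignment of two ungapped sequences with affine gaps
# (open > extend so short insertions align as single events) and a
# strong mismatch penalty so indel structure is preferred over runs of
# mismatches; gap runs right-normalised in both rows. Returns
# c(row1, row2).
alignPair <- function(s1, s2, gapOpening = 4, gapExtension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3, baseOnly = FALSE),
    gapOpening = gapOpening, gapExtension = gapExtension)
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  p2 <- shiftGapsRight(p, s)
  s2r <- shiftGapsRight(s, p2)
  c(p2, s2r)
}

#' Star alignment of short allele sequences
#'
#' Aligns every sequence globally to a centre sequence (the shortest, so
#' that diagnostic insertions appear as insertions relative to it) and
#' merges the pairwise alignments into one set of columns. Insertions at
#' the same junction from different sequences are left-aligned against
#' each other and padded with gaps.
#'
#' @param seqs named character vector of >= 2 ungapped DNA sequences.
#' @return character matrix, one row per sequence, `-` for gaps.
#' @export
alignAlleles <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (length(seqs) == 2L) {
    rows <- alignPair(seqs[[1]], seqs[[2]])
    m <- rbind(strsplit(rows[1], "")[[1]], strsplit(rows[2], "")[[1]])
    rownames(m) <- names(seqs)
    return(m)
  }
  ord <- order(nchar(seqs), names(seqs))
  centerName <- names(seqs)[ord[1]]
  center <- seqs[[centerName]]
  nC <- nchar(center)
  others <- setdiff(names(seqs), centerName)
  # per other sequence: aligned char at each centre position, plus the
  # insertion string after each centre position (0 = before the first)
  perSeq <- lapply(others, function(nm) {
    rows <- alignPair(seqs[[nm]], center)
    p <- strsplit(rows[1], "")[[1]]
    s <- strsplit(rows[2], "")[[1]]
    at <- character(nC)
    ins <- vector("list", nC + 1L)
    cpos <- 0L
    for (j in seq_along(s)) {
      if (s[j] != "-") {
        cpos <- cpos + 1L
        at[cpos] <- p[j]
      } else {
        ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], p[j])
      }
    }
    list(at = at, ins = ins)
  })
  names(perSeq) <- others
  insWidth <- vapply(seq_len(nC + 1L), function(c0)
    max(0L, vapply(perSeq, function(x) length(x$ins[[c0]]), 0L)), 0L)
  buildRow <- function(at, ins) {
    out <- character(0)
    for (c0 in seq_len(nC + 1L)) {
      if (insWidth[c0] > 0L) {
        block <- rep("-", insWidth[c0])
        if (!is.null(ins[[c0]]))
          block[seq_along(ins[[c0]])] <- ins[[c0]]
        out <- c(out, block)
      }
      if (c0 <= nC) out <- c(out, at[c0])
    }
    out
  }
  centerChars <- strsplit(center, "")[[1]]
  m <- rbind(buildRow(centerChars, vector("list", nC + 1L)))
  for (nm in others)
    m <- rbind(m, buildRow(perSeq[[nm]]$at, perSeq[[nm]]$ins))
  rownames(m) <- c(centerName, others)
  m[names(seqs), , drop = FALSE]
}

#' Derive diagnostic-indel rules from per-species dominant alleles
#'
#' Star-aligns the dominant alleles and turns every maximal column range
#' whose gap/non-gap pattern differs between species into a diagnostic
#' region (presence/absence of the inserted motif per species). Regions
#' narrower than `minRegionWidth` columns are ignored as too fragile.
#' Errors when some species pair is not distinguished by any region.
#'
#' @param dominantAlleles named character vector (>= 2 species) of
#'   ungapped dominant allele sequences.
#' @param minRegionWidth minimum diagnostic region width (default 3 bp).
#' @return a [MarkerRuleSet-class].
#' @export
deriveRules <- function(dominantAlleles, minRegionWidth = 3L) {
  stopifnot(length(dominantAlleles) >= 2L)
  species <- names(dominantAlleles)
  msa <- alignAlleles(dominantAlleles)
  isGap <- msa == "-"
  mixed <- colSums(isGap) > 0L   # all-gap columns cannot occur
  pat <- apply(isGap, 2, function(g) paste(as.integer(g), collapse = ""))
  regions <- data.frame(region = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  if (any(mixed)) {
    cols <- which(mixed)
    newRun <- c(TRUE, diff(cols) != 1L |
                  pat[cols][-1L] != pat[cols][-length(cols)])
    runId <- cumsum(newRun)
    rg <- lapply(split(cols, runId), function(cc)
      c(start = cc[1] - 1L, end = cc[length(cc)]))
    rg <- Filter(function(x) x["end"] - x["start"] >= minRegionWidth, rg)
    if (length(rg)) {
      regions <- data.frame(
        region = LETTERS[seq_along(rg)],
        start = vapply(rg, `[[`, 0L, "start"),
        end = vapply(rg, `[[`, 0L, "end"), stringsAsFactors = FALSE)
    }
  }
  # ngBefore[c0+1, sp] = non-gap chars of species sp in columns 1..c0
  ngBefore <- vapply(species, function(sp)
    c(0L, cumsum(!isGap[sp, ])), integer(ncol(msa) + 1L))
  for (sp in species) {
    regions[[paste0("motif.", sp)]] <- vapply(seq_len(nrow(regions)),
      function(i) {
        cc <- (regions$start[i] + 1L):regions$end[i]
        if (any(isGap[sp, cc])) "" else paste(msa[sp, cc], collapse = "")
      }, "")
    regions[[paste0("pos.", sp)]] <- vapply(seq_len(nrow(regions)),
      function(i) ngBefore[regions$start[i] + 1L, sp], 0L)
  }
  # every species pair must be separated by at least one region
  for (i in seq_along(species)[-length(species)])
    for (j in (i + 1L):length(species)) {
      a <- species[i]; b <- species[j]
      sep <- nrow(regions) > 0L &&
        any(nzchar(regions[[paste0("motif.", a)]]) !=
              nzchar(regions[[paste0("motif.", b)]]))
      if (!sep)
        stop("no diagnostic region between ", a, " and ", b)
    }
  rownames(regions) <- NULL
  new("MarkerRuleSet", species = species,
      alleles = unlist(dominantAlleles[species]), msa = msa,
      regions = regions)
}

# does the query-vs-allele alignment contain an insertion (subject-gap
# run) of >= minLen with its junction near subject offset `pos`?
hasInsertionAt <- function(pat, sub, pos, minLen = 3L, tol = 2L) {
  consumed <- 0L
  j <- 1L
  n <- length(sub)
  while (j <= n) {
    if (sub[j] == "-") {
      k <- j
      while (k < n && sub[k + 1L] == "-") k <- k + 1L
      if (k - j + 1L >= minLen && abs(consumed - pos) <= tol) return(TRUE)
      j <- k + 1L
    } else {
      consumed <- consumed + 1L
      j <- j + 1L
    }
  }
  FALSE
}

#' Classify a query amplicon against diagnostic-indel rules
#'
#' The query is globally aligned to each species' dominant allele.
#' A species matches a diagnostic region when the query carries the
#' region's motif where the species has it (no gap across the region)
#' and carries no comparable insertion at the junction where the species
#' lacks it. Substitutions never decide identity: they only count
#' toward a background-divergence sanity check outside the diagnostic
#' regions. Species matching every region are candidates; exactly one
#' candidate (within the divergence bound) gives the label, several give
#' `"ambiguous"`. When no species matches every region, species whose
#' own motifs are all present in the query are reconsidered (a query
#' carrying the insertions of two species is therefore `"ambiguous"`,
#' not forced to a nearest label); failing that the query is
#' `"unclassified"`.
#'
#' @param query ungapped DNA string (an amplicon/allele sequence).
#' @param rules a [MarkerRuleSet-class] from [deriveRules].
#' @param maxBackgroundDivergence maximum mismatch fraction outside the
#'   diagnostic regions for a positive call (default 0.15, sized so the
#'   substitution variants seen in field amplicons do not block
#'   identification).
#' @return list of class `classificationResult`: `label` (a species,
#'   `"ambiguous"` or `"unclassified"`), `matchedRegions` (per species,
#'   the region ids that matched), `divergence` (per species, mismatch
#'   fraction outside diagnostic regions).
#' @export
classifyQuery <- function(query, rules, maxBackgroundDivergence = 0.15) {
  query <- normalizeDnaString(query, what = "query")
  maxAllele <- max(nchar(rules@alleles))
  if (nchar(query) < maxAllele / 2)
    stop("query shorter than half the rule allele length")
  species <- rules@species
  regions <- rules@regions
  matched <- setNames(vector("list", length(species)), species)
  diverg <- setNames(rep(NA_real_, length(species)), species)
  allMatch <- setNames(logical(length(species)), species)
  presMatch <- setNames(logical(length(species)), species)
  for (sp in species) {
    allele <- rules@alleles[[sp]]
    rows <- alignPair(query, allele)
    pat <- strsplit(rows[1], "")[[1]]
    sub <- strsplit(rows[2], "")[[1]]
    subPos <- cumsum(sub != "-")          # 1-based allele position per col
    inRegion <- rep(FALSE, length(sub))
    okPerRegion <- logical(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      motif <- regions[[paste0("motif.", sp)]][i]
      pos <- regions[[paste0("pos.", sp)]][i]
      if (nzchar(motif)) {
        cols <- which(subPos > pos & subPos <= pos + nchar(motif) &
                        sub != "-")
        inRegion[cols] <- TRUE
        okPerRegion[i] <- length(cols) == nchar(motif) &&
          all(pat[cols] != "-")
      } else {
        okPerRegion[i] <- !hasInsertionAt(pat, sub, pos,
                                          minLen = 3L)
      }
    }
    comp <- pat != "-" & sub != "-" & !inRegion
    diverg[sp] <- if (any(comp)) mean(pat[comp] != sub[comp]) else 0
    matched[[sp]] <- regions$region[okPerRegion]
    allMatch[sp] <- all(okPerRegion)
    presIx <- nzchar(regions[[paste0("motif.", sp)]])
    presMatch[sp] <- any(presIx) && all(okPerRegion[presIx])
  }
  okDiv <- diverg <= maxBackgroundDivergence
  strict <- species[allMatch & okDiv]
  label <- if (length(strict) == 1L) strict
  else if (length(strict) > 1L) "ambiguous"
  else {
    fallback <- species[presMatch & okDiv]
    if (length(fallback) == 1L) fallback
    else if (length(fallback) > 1L) "ambiguous"
    else "unclassified"
  }
  structure(list(label = label, matchedRegions = matched,
                 divergence = diverg),
            class = "classificationResult")
}

#' @export
print.classificationResult <- function(x, ...) {
  cat("classification:", x$label, "\n")
  for (sp in names(x$matchedRegions))
    cat(sprintf("  %s: regions [%s], background divergence %.3f\n", sp,
                paste(x$matchedRegions[[sp]], collapse = ","),
                x$divergence[[sp]]))
  invisible(x)
}

#' Serialize a MarkerRuleSet to JSON
#' @param rules a [MarkerRuleSet-class].
#' @param path output file.
#' @export
writeRules <- function(rules, path) {
  jsonlite::write_json(
    list(species = rules@species, alleles = as.list(rules@alleles),
         msa = apply(rules@msa, 1, paste, collapse = ""),
         regions = rules@regions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a MarkerRuleSet from JSON
#' @param path JSON file written by [writeRules].
#' @return a [MarkerRuleSet-class].
#' @export
readRules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  msa <- do.call(rbind, strsplit(x$msa, ""))
  rownames(msa) <- names(x$msa)
  new("MarkerRuleSet", species = x$species,
      alleles = unlist(x$alleles), msa = msa,
      regions = as.data.frame(x$regions, stringsAsFactors = FALSE))
}
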