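# Sequence I/O: FASTA/FASTQ/aligned FASTA readers, a GenBank flat-file
# parser, and coordinate-safe slicing on circular genomes.
#
# Convention: all internal coordinates are 0-based half-open intervals;
# GenBank's 1-based inclusive coordinates are converted on read and
# restored by gbCoords() for user-facing reports.

#' Read a (multi-)FASTA file of genome sequences
#'
#' Sequences are upper-cased, `U` is mapped to `T`, and IUPAC ambiguity
#' codes other than `N` are collapsed to `N` with a warning.
#'
#' @param path FASTA file.
#' @param circular logical; mark the records circular?
#' @return list of [GenomeRecord-class] objects, one per header.
#' @export
readFasta <- function(path, circular = FALSE) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(raw), function(i) {
    GenomeRecord(ids[i], as.character(raw[[i]]), circular = circular)
  })
}

#' Write GenomeRecords (or named sequences) as wrapped FASTA
#'
#' @param records list of GenomeRecords, or a named character vector.
#' @param path output path.
#' @param width line width (default 60 columns).
#' @export
writeFasta <- function(records, path, width = 60L) {
  if (is.list(records)) {
    seqs <- vapply(records, genomeSeq, "")
    names(seqs) <- vapply(records, genomeId, "")
  } else seqs <- records
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = as.integer(width))
  invisible(path)
}

#' Read reads as a ReadSet (FASTA or FASTQ, auto-detected)
#'
#' FASTQ qualities are parsed but unused downstream.
#'
#' @param path reads file.
#' @param speciesLabel label to attach to the set.
#' @return a [ReadSet-class].
#' @export
readReads <- function(path, speciesLabel) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, "@")) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("FASTQ format error: line count not a multiple of 4 in ", path)
    ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
    seqs <- lines[seq(2, length(lines), 4)]
    quals <- lines[seq(4, length(lines), 4)]
    ReadSet(speciesLabel, setNames(seqs, ids), qualities = quals)
  } else {
    raw <- Biostrings::readBStringSet(path)
    ReadSet(speciesLabel,
            setNames(as.character(raw), sub("\\s.*$", "", names(raw))))
  }
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA with >= 2 equal-length gapped rows.
#' @return a [GenomeAlignment-class].
#' @export
readAlignmentFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) < 2L)
    stop("alignment format error: need >= 2 rows in ", path)
  w <- Biostrings::width(raw)
  if (length(unique(w)) > 1L)
    stop("alignment format error: unequal row lengths: ",
         paste(sub("\\s.*$", "", names(raw)), w, sep = "=", collapse = ", "))
  GenomeAlignment(setNames(as.character(raw), sub("\\s.*$", "", names(raw))))
}

#' Write a GenomeAlignment as aligned FASTA
#' @param aln a GenomeAlignment.
#' @param path output path.
#' @export
writeAlignmentFasta <- function(aln, path) {
  rows <- alignmentRows(aln)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(rows), path,
                              width = 60L)
  invisible(path)
}

#' Convert a 0-based half-open interval to GenBank 1-based inclusive
#' @param start,end 0-based half-open bounds.
#' @return integer vector c(first, last), 1-based inclusive.
#' @export
gbCoords <- function(start, end) c(start + 1L, end)

#' Convert GenBank 1-based inclusive coordinates to 0-based half-open
#' @param first,last 1-based inclusive bounds.
#' @return integer vector c(start, end), 0-based half-open.
#' @export
fromGbCoords <- function(first, last) c(first - 1L, last)

# ---- GenBank flat file -----------------------------------------------------

# Parse a GenBank location string into a list(strand, intervals) where
# intervals is an n x 2 matrix of 0-based half-open exon intervals in
# reading order along the strand.
parseGbLocation <- function(loc, featureName = "?") {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  iv <- t(vapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2)
    } else {
      stop("GenBank format error: unparseable location for feature '",
           featureName, "': ", p)
    }
    fromGbCoords(ab[1], ab[2])
  }, integer(2)))
  dimnames(iv) <- NULL
  list(strand = strand, intervals = iv)
}

#' Read a GenBank flat file into a GenomeRecord
#'
#' Parses LOCUS (length, circular flag), the FEATURES table (CDS, tRNA,
#' rRNA and gene features; `join()` locations become multi-interval
#' features, `complement()` sets strand `-`) and ORIGIN. GenBank's
#' 1-based inclusive coordinates become 0-based half-open.
#'
#' @param path GenBank flat file.
#' @return a [GenomeRecord-class] with populated features.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank format error: no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(tolower(toks) == "circular")

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank format error: missing ORIGIN in ", path)
  endi <- grep("^//", lines)
  endi <- if (length(endi)) endi[endi > oi[1]][1] else length(lines) + 1L
  seqlines <- lines[(oi[1] + 1L):(endi - 1L)]
  seq <- gsub("[0-9 ]", "", paste(seqlines, collapse = ""))

  fi <- grep("^FEATURES", lines)
  feats <- emptyFeatures()
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # feature header lines have a key in columns 6-20; continuation and
    # qualifier lines are blank there
    isKey <- grepl("^ {5}\\S", block)
    starts <- which(isKey)
    rows <- list()
    fid <- 0L
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
      if (key == "source") next
      # location may continue over lines until the first qualifier
      qual1 <- grep("^\\s+/", chunk)
      locEnd <- if (length(qual1)) qual1[1] - 1L else length(chunk)
      loc <- paste(trimws(sub("^\\s*\\S+\\s*", "", chunk[1])),
                   paste(trimws(chunk[seq_len(locEnd)][-1]), collapse = ""),
                   sep = "")
      name <- NA_character_
      gm <- regmatches(chunk, regexec("/(?:gene|product|label)=\"?([^\"]+)\"?",
                                      chunk))
      hits <- vapply(gm, length, 0L) == 2L
      if (any(hits)) name <- gm[[which(hits)[1]]][2]
      parsed <- parseGbLocation(loc, featureName =
                                  if (is.na(name)) key else name)
      fid <- fid + 1L
      kind <- if (key %in% c("CDS", "tRNA", "rRNA")) key else "other"
      rows[[fid]] <- data.frame(
        feature = fid,
        name = if (is.na(name)) sprintf("%s_%d", key, fid) else name,
        kind = kind, strand = parsed$strand,
        start = parsed$intervals[, 1], end = parsed$intervals[, 2],
        stringsAsFactors = FALSE)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  GenomeRecord(id, seq, circular = circular, features = feats)
}

#' Spliced sequence of an annotated feature
#'
#' Concatenates the feature's exon intervals (in genome order) and
#' reverse-complements the result for minus-strand features.
#'
#' @param genome a GenomeRecord.
#' @param name feature name (as in `genomeFeatures(genome)$name`).
#' @return character DNA string of the spliced feature.
#' @export
featureSequence <- function(genome, name) {
  f <- genomeFeatures(genome)
  f <- f[f$name == name, , drop = FALSE]
  if (!nrow(f)) stop("no feature named '", name, "'")
  f <- f[order(f$start), , drop = FALSE]
  seq <- genomeSeq(genome)
  parts <- substring(seq, f$start + 1L, f$end)
  out <- paste(parts, collapse = "")
  if (f$strand[1] == "-")
    out <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(out)))
  out
}

#' Extract a subsequence, optionally wrapping around a circular origin
#'
#' @param genome a GenomeRecord.
#' @param start,end 0-based half-open interval; `end` may exceed the
#'   genome length when wrapping.
#' @param allowWrap continue through the origin when `end` passes the end
#'   of a circular genome. Requesting a wrap (`end` > length with
#'   `allowWrap = TRUE`) on a linear genome is an error; without
#'   `allowWrap` the slice is clipped with a warning.
#' @return character DNA string.
#' @export
sliceRegion <- function(genome, start, end, allowWrap = FALSE) {
  L <- length(genome)
  if (start < 0L || start >= L) stop("start out of range [0, ", L, ")")
  if (end - start > L) stop("slice longer than the genome")
  seq <- genomeSeq(genome)
  if (end <= L) return(substr(seq, start + 1L, end))
  if (allowWrap) {
    if (!isCircular(genome))
      stop("wrap requested on non-circular genome '", genomeId(genome), "'")
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
  } else {
    warning("slice [", start, ",", end, ") clipped at genome end ", L)
    substr(seq, start + 1L, L)
  }
}

# reverse complement of a plain character string
revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
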