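# Constructors, accessors and show methods for the core classes.

#' Construct a GenomeRecord
#'
#' @param id genome identifier.
#' @param sequence character or DNAString; upper-cased, `U` mapped to `T`,
#'   other IUPAC ambiguity codes collapsed to `N` (with a warning).
#' @param circular logical; circular molecule?
#' @param features optional feature data.frame (see [GenomeRecord-class]).
#' @param partition optional quadripartite partition list.
#' @return a [GenomeRecord-class] object.
#' @export
GenomeRecord <- function(id, sequence, circular = FALSE,
                         features = emptyFeatures(), partition = list()) {
  seq <- normalizeDnaString(as.character(sequence), what = id)
  new("GenomeRecord", id = as.character(id),
      sequence = Biostrings::DNAString(seq),
      circular = isTRUE(circular),
      features = features, partition = partition)
}

#' Empty feature table
#' @return zero-row data.frame with the feature-annotation columns.
#' @export
emptyFeatures <- function() {
  data.frame(feature = integer(0), name = character(0), kind = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

# Upper-case, U->T, anything outside {A,C,G,T,N,-} -> N (warn).
# Gaps are only legal when allowGaps = TRUE (alignment rows).
normalizeDnaString <- function(x, what = "sequence", allowGaps = FALSE) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  allowed <- if (allowGaps) "ACGTN-" else "ACGTN"
  bad <- unique(strsplit(gsub(sprintf("[%s]", allowed), "", x), "")[[1]])
  if (length(bad)) {
    if (any(grepl("[^A-Z.-]", bad)))
      stop("non-sequence characters in ", what, ": ",
           paste(bad, collapse = ","))
    warning("ambiguity codes in ", what, " mapped to N: ",
            paste(bad, collapse = ","))
    for (b in bad) x <- gsub(b, "N", x, fixed = TRUE)
  }
  x
}

#' @describeIn GenomeRecord-class genome identifier.
#' @param object,x a GenomeRecord.
#' @export
genomeId <- function(x) x@id

#' @describeIn GenomeRecord-class genome sequence as a character string.
#' @export
genomeSeq <- function(x) as.character(x@sequence)

#' @describeIn GenomeRecord-class is the molecule circular?
#' @export
isCircular <- function(x) x@circular

#' @describeIn GenomeRecord-class feature annotation table.
#' @export
genomeFeatures <- function(x) x@features

#' @describeIn GenomeRecord-class quadripartite partition (possibly empty).
#' @export
genomePartition <- function(x) x@partition

#' @export
setMethod("length", "GenomeRecord", function(x) length(x@sequence))

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s\n", object@id,
              length(object@sequence),
              if (object@circular) "circular" else "linear"))
  if (nrow(object@features))
    cat(sprintf("  %d feature interval(s) on %d feature(s)\n",
                nrow(object@features),
                length(unique(object@features$feature))))
  if (length(object@partition))
    cat("  partitioned: LSC/IRa/SSC/IRb\n")
})

#' Construct a GenomeAlignment from gapped rows
#'
#' @param rows named character vector or DNAStringSet of equal-length
#'   gapped rows.
#' @return a [GenomeAlignment-class].
#' @export
GenomeAlignment <- function(rows) {
  if (is.character(rows)) {
    rows <- vapply(rows, normalizeDnaString, "", what = "alignment row",
                   allowGaps = TRUE)
    rows <- Biostrings::DNAStringSet(rows)
  }
  new("GenomeAlignment", rows = rows)
}

#' @describeIn GenomeAlignment-class rows as a named character vector.
#' @param x a GenomeAlignment.
#' @export
alignmentRows <- function(x) setNames(as.character(x@rows), names(x@rows))

#' @describeIn GenomeAlignment-class number of alignment columns.
#' @export
alignmentNcol <- function(x) Biostrings::width(x@rows)[1]

#' @describeIn GenomeAlignment-class alignment as a character matrix
#'   (rows = sequences, columns = alignment columns).
#' @export
alignmentMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x@rows), ""))
  rownames(m) <- names(x@rows)
  m
}

setMethod("show", "GenomeAlignment", function(object) {
  cat(sprintf("GenomeAlignment: %d rows x %d columns (%s)\n",
              length(object@rows), Biostrings::width(object@rows)[1],
              paste(names(object@rows), collapse = ", ")))
})

#' Construct a ReadSet
#'
#' @param speciesLabel species/sample label.
#' @param reads named character vector or DNAStringSet of read sequences.
#' @param qualities optional per-read quality strings.
#' @return a [ReadSet-class].
#' @export
ReadSet <- function(speciesLabel, reads, qualities = character(0)) {
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%06d", seq_along(reads))
    reads <- Biostrings::DNAStringSet(
      vapply(reads, normalizeDnaString, "", what = "read"))
  }
  new("ReadSet", speciesLabel = speciesLabel, reads = reads,
      qualities = qualities)
}

#' @describeIn ReadSet-class species label.
#' @param x a ReadSet.
#' @export
speciesLabel <- function(x) x@speciesLabel

#' @describeIn ReadSet-class read sequences as a named character vector.
#' @export
readSequences <- function(x) setNames(as.character(x@reads), names(x@reads))

#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

setMethod("show", "ReadSet", function(object) {
  w <- Biostrings::width(object@reads)
  cat(sprintf("ReadSet '%s': %d reads%s\n", object@speciesLabel,
              length(object@reads),
              if (length(w)) sprintf(", length %d-%d bp", min(w), max(w))
              else ""))
})

#' @describeIn Pileup-class per-site coverage (bases + deletions).
#' @param x a Pileup.
#' @export
pileupCoverage <- function(x) colSums(x@counts) + x@deletions

#' @describeIn Pileup-class the 4 x L base-count matrix.
#' @export
pileupCounts <- function(x) x@counts

#' @describeIn Pileup-class per-position deletion counts.
#' @export
pileupDeletions <- function(x) x@deletions

setMethod("show", "Pileup", function(object) {
  cov <- colSums(object@counts) + object@deletions
  cat(sprintf(
    "Pileup on '%s' (%d bp): %d reads mapped, %d discarded, mean coverage %.1f\n",
    object@refId, object@refLength, object@nReadsMapped,
    object@nReadsDiscarded, mean(cov)))
})

#' @describeIn AlleleTable-class the allele record data.frame.
#' @param x an AlleleTable.
#' @export
alleleRecords <- function(x) x@records

#' @describeIn AlleleTable-class total reads spanning the target window
#'   (pre-filter).
#' @export
totalMapped <- function(x) x@totalMapped

setMethod("show", "AlleleTable", function(object) {
  cat(sprintf("AlleleTable '%s': %d spanning reads, %d allele type(s)\n",
              object@speciesLabel, object@totalMapped,
              nrow(object@records)))
  if (nrow(object@records)) {
    top <- utils::head(object@records, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s  n=%d (%.2f%%)\n", top$allele[i], top$count[i],
                  100 * top$share[i]))
    if (nrow(object@records) > 3) cat("  ...\n")
  }
})

#' @describeIn MarkerRuleSet-class diagnostic region table.
#' @param x a MarkerRuleSet.
#' @export
ruleRegions <- function(x) x@regions

#' @describeIn MarkerRuleSet-class source dominant alleles.
#' @export
ruleAlleles <- function(x) x@alleles

setMethod("show", "MarkerRuleSet", function(object) {
  cat(sprintf("MarkerRuleSet: %d species, %d diagnostic region(s)\n",
              length(object@species), nrow(object@regions)))
  for (i in seq_len(nrow(object@regions))) {
    r <- object@regions[i, ]
    motifs <- vapply(object@species, function(s) {
      m <- r[[paste0("motif.", s)]]
      if (nzchar(m)) sprintf("%s:%s", s, m) else sprintf("%s:-", s)
    }, "")
    cat(sprintf("  region %s [cols %d-%d]: %s\n", r$region, r$start + 1L,
                r$end, paste(motifs, collapse = " ")))
  }
})
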