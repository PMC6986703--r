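#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet BStringSet width
#'   readDNAStringSet writeXStringSet reverseComplement pairwiseAlignment
#'   alignedPattern alignedSubject subseq
#' @importFrom stats rpois runif setNames
#' @importFrom utils head tail write.table
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' A single (possibly circular) genome sequence
#'
#' Container for one genome: its sequence, circularity flag, optional
#' feature annotations and optional quadripartite partition
#' (LSC / IRa / SSC / IRb). All internal coordinates are 0-based half-open;
#' user-facing reports are 1-based inclusive.
#'
#' @slot id single character identifier.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T/N.
#' @slot circular logical scalar; whether the molecule is circular.
#' @slot features data.frame with one row per exon interval: columns
#'   `feature` (integer id grouping exons), `name`, `kind`
#'   (CDS/tRNA/rRNA/other), `strand` (`+`/`-`), `start`, `end`
#'   (0-based half-open).
#' @slot partition named list with elements `lsc`, `ira`, `ssc`, `irb`,
#'   each an integer pair `c(start, end)` (0-based half-open), or an empty
#'   list when unpartitioned.
#' @export
setClass("GenomeRecord",
  representation(
    id = "character",
    sequence = "DNAString",
    circular = "logical",
    features = "data.frame",
    partition = "list"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@sequence) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 .DNA_ALPHABET)
  if (length(bad))
    msg <- c(msg, paste0("sequence contains characters outside {A,C,G,T,N}: ",
                         paste(bad, collapse = ",")))
  if (nrow(object@features)) {
    need <- c("feature", "name", "kind", "strand", "start", "end")
    if (!all(need %in% names(object@features))) {
      msg <- c(msg, "features must have columns feature,name,kind,strand,start,end")
    } else {
      L <- length(object@sequence)
      if (any(object@features$start < 0L) || any(object@features$end > L) ||
          any(object@features$start >= object@features$end))
        msg <- c(msg, "feature intervals must lie within [0, genome length)")
    }
  }
  if (length(object@partition)) {
    if (!setequal(names(object@partition), c("lsc", "ira", "ssc", "irb"))) {
      msg <- c(msg, "partition must have elements lsc, ira, ssc, irb")
    } else {
      iv <- do.call(rbind, object@partition[c("lsc", "ira", "ssc", "irb")])
      lens <- iv[, 2] - iv[, 1]
      if (sum(lens) != length(object@sequence))
        msg <- c(msg, "partition intervals must tile the genome exactly")
      if (lens["ira"] != lens["irb"])
        msg <- c(msg, "|IRa| must equal |IRb|")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Gapped multiple alignment over a common coordinate system
#'
#' Thin wrapper around a named [Biostrings::DNAStringSet] of equal-width
#' gapped rows (`-` for gaps). Removing the gaps from a row reconstructs
#' the source sequence.
#'
#' @slot rows named DNAStringSet, >= 2 rows, all the same width.
#' @export
setClass("GenomeAlignment", representation(rows = "DNAStringSet"))

setValidity("GenomeAlignment", function(object) {
  msg <- character(0)
  if (length(object@rows) < 2L)
    msg <- c(msg, "an alignment needs at least 2 rows")
  w <- Biostrings::width(object@rows)
  if (length(unique(w)) > 1L)
    msg <- c(msg, paste0("rows have unequal lengths: ",
                         paste(names(object@rows), w, sep = "=", collapse = ", ")))
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    msg <- c(msg, "rows must carry unique names")
  if (length(msg)) msg else TRUE
})

#' A set of reads from one species
#'
#' @slot speciesLabel single character label for the species/sample.
#' @slot reads named DNAStringSet of read sequences (single-end; pairing,
#'   if any, is ignored).
#' @slot qualities character vector of per-read quality strings (parsed
#'   from FASTQ but unused), or length 0.
#' @export
setClass("ReadSet",
  representation(
    speciesLabel = "character",
    reads = "DNAStringSet",
    qualities = "character"
  )
)

setValidity("ReadSet", function(object) {
  msg <- character(0)
  if (length(object@speciesLabel) != 1L)
    msg <- c(msg, "speciesLabel must be a single string")
  if (length(object@reads) && any(Biostrings::width(object@reads) == 0L))
    msg <- c(msg, "read sequences must be non-empty")
  if (length(object@qualities) &&
      length(object@qualities) != length(object@reads))
    msg <- c(msg, "qualities must be empty or one per read")
  if (length(msg)) msg else TRUE
})

#' Per-site base counts from reads mapped to a reference
#'
#' Column-oriented pileup: a 4 x L count matrix (rows A,C,G,T) plus
#' per-position deletion and insertion tallies. Coverage at a site is
#' `colSums(counts) + deletions`; insertions are recorded but excluded
#' from diversity statistics.
#'
#' @slot refId reference genome id.
#' @slot refLength reference length in bp.
#' @slot counts integer matrix 4 x refLength, rownames A,C,G,T.
#' @slot deletions integer vector of deleted-base counts per position.
#' @slot insertions integer vector counting reads with an insertion
#'   immediately after each position.
#' @slot nReadsMapped number of reads contributing to the pileup.
#' @slot nReadsDiscarded number of reads rejected (identity below
#'   threshold or unplaceable).
#' @export
setClass("Pileup",
  representation(
    refId = "character",
    refLength = "integer",
    counts = "matrix",
    deletions = "integer",
    insertions = "integer",
    nReadsMapped = "integer",
    nReadsDiscarded = "integer"
  )
)

setValidity("Pileup", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
    msg <- c(msg, "counts must have rownames A,C,G,T")
  if (ncol(object@counts) != object@refLength)
    msg <- c(msg, "counts must have one column per reference position")
  if (length(object@deletions) != object@refLength ||
      length(object@insertions) != object@refLength)
    msg <- c(msg, "deletions/insertions must have one entry per position")
  if (any(object@counts < 0) || any(object@deletions < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Allele types and frequencies at a target locus
#'
#' One table per species: every distinct allele string observed among
#' reads fully spanning the target window, its read count and its share of
#' `totalMapped` (the pre-filter number of spanning reads).
#'
#' @slot speciesLabel species/sample label.
#' @slot totalMapped integer; number of recruited reads fully spanning the
#'   target window, fixed before any `minCount` filtering.
#' @slot records data.frame with columns `allele`, `count`, `share`,
#'   sorted by count descending (ties lexicographic by allele).
#' @export
setClass("AlleleTable",
  representation(
    speciesLabel = "character",
    totalMapped = "integer",
    records = "data.frame"
  )
)

setValidity("AlleleTable", function(object) {
  msg <- character(0)
  need <- c("allele", "count", "share")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, "records must have columns allele,count,share")
  else if (nrow(object@records)) {
    if (is.unsorted(rev(object@records$count)))
      msg <- c(msg, "records must be sorted by count descending")
    if (any(object@records$count < 1L))
      msg <- c(msg, "record counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Diagnostic-indel rules distinguishing species
#'
#' Derived from per-species dominant alleles: a star alignment of the
#' alleles and the maximal column ranges whose gap/non-gap pattern differs
#' between species. Each region carries, per species, the motif it inserts
#' there (or `""` when the species lacks it) and the position of the
#' region in that species' ungapped allele coordinates.
#'
#' @slot species character vector of species labels.
#' @slot alleles named character vector of the source dominant alleles
#'   (ungapped).
#' @slot msa character matrix, one row per species, of the gapped star
#'   alignment the regions were read from.
#' @slot regions data.frame with columns `region`, `start`, `end`
#'   (alignment columns, 0-based half-open), plus per-species columns
#'   `motif.<sp>` and `pos.<sp>` (0-based offset of the region start in
#'   the species' ungapped allele).
#' @export
setClass("MarkerRuleSet",
  representation(
    species = "character",
    alleles = "character",
    msa = "matrix",
    regions = "data.frame"
  )
)

setValidity("MarkerRuleSet", function(object) {
  msg <- character(0)
  if (length(object@species) < 2L)
    msg <- c(msg, "need at least 2 species")
  if (!all(object@species %in% names(object@alleles)))
    msg <- c(msg, "every species needs a source allele")
  if (length(msg)) msg else TRUE
})
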