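# Seeded synthetic data: a trio of closely related circular genomes with
# implanted divergent windows, species-diagnostic short insertions and
# homopolymer decoys; heteroplasmic read pools with a configurable allele
# pool and substitution errors; and a read fixture reconstructing the
# published cz11 allele survey. Every generator returns a machine-readable
# truth log alongside its sequences.

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# substitute position pos (0-based) to a uniformly drawn different base
.mutateBase <- function(chars, pos) {
  old <- chars[pos + 1L]
  chars[pos + 1L] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  chars
}

#' Default implant window for the trio simulator
#'
#' One divergent window with a 5 bp tail insertion in the first species
#' and a 6 bp head insertion in the second (the shape of the published
#' cz11 diagnostic indels), placed mid-genome.
#'
#' @param genomeLength genome length the window is scaled to.
#' @return list with one implant specification.
#' @export
defaultImplant <- function(genomeLength) {
  s <- as.integer(genomeLength %/% 2)
  list(list(start = s, end = s + 200L, divergence = 0.05,
            motifs = c("TATAT", "TCTTAC", ""),
            motifAt = c("tail", "head", "")))
}

#' Simulate a trio of closely related circular genomes
#'
#' Draws a uniform-random ancestor and gives each species copy
#' independent Poisson substitutions such that each species pair
#' diverges at about `mu` substitutions/site outside the implants.
#' Implant windows receive their configured (pairwise) divergence in
#' their core and species-specific motif insertions at their head or
#' tail; homopolymer decoys are written verbatim into all three genomes.
#' Background substitutions are kept out of the implant windows and a
#' protective pad around them so implanted flanks stay conserved. The
#' true multiple alignment is built from the edit log, and every edit is
#' recorded in the truth log.
#'
#' @param genomeLength ancestor length in bp (study-scale plastomes are
#'   ~150 kb; tests run at 5-20 kb).
#' @param mu background pairwise substitution rate per site (0-0.2).
#' @param implants list of implant windows: each a list with `start`,
#'   `end` (ancestor coordinates, 0-based half-open), `divergence`
#'   (pairwise, within the window core), `motifs` (one DNA string per
#'   species, `""` for none) and `motifAt` (`"head"`/`"tail"`).
#' @param decoys list of homopolymer decoys: each `list(pos, base, len)`.
#'   Default: one A-run of 12 at a quarter of the genome.
#' @param speciesNames three labels.
#' @param seed integer seed; runs are byte-identical given a seed.
#' @param protectPad background-substitution-free margin around implants.
#' @return list with `genomes` (named list of [GenomeRecord-class]),
#'   `alignment` (the true [GenomeAlignment-class]) and `truth` (edit
#'   log: ancestor, substitutions, insertions, decoys, implants).
#' @export
simulateGenomeTrio <- function(genomeLength = 20000L, mu = 0.005,
                               implants = defaultImplant(genomeLength),
                               decoys = list(list(pos = genomeLength %/% 4,
                                                  base = "A", len = 12L)),
                               speciesNames = c("speciesA", "speciesB",
                                                "speciesC"),
                               seed = 1L, protectPad = 60L) {
  stopifnot(mu >= 0, mu <= 0.2, length(speciesNames) == 3L)
  for (im in implants)
    for (im2 in implants)
      if (!identical(im, im2) && im$start < im2$end && im$end > im2$start)
        stop("implant windows must be disjoint")
  withSeed(seed, {
    L <- as.integer(genomeLength)
    anc <- strsplit(randomDna(L), "")[[1]]
    # write decoys into the ancestor so all species share them
    for (d in decoys) {
      ix <- (d$pos + 1L):(d$pos + d$len)
      stopifnot(max(ix) <= L)
      anc[ix] <- d$base
    }
    protected <- rep(FALSE, L)
    for (im in implants) {
      lo <- max(1L, im$start - protectPad + 1L)
      hi <- min(L, im$end + protectPad)
      protected[lo:hi] <- TRUE
    }
    subs <- list()
    species <- lapply(seq_len(3L), function(s) anc)
    names(species) <- speciesNames
    bgPool <- which(!protected)
    for (s in seq_len(3L)) {
      n <- stats::rpois(1L, mu * L / 2)
      pos <- sample(bgPool, min(n, length(bgPool)))
      for (p in pos) {
        old <- species[[s]][p]
        species[[s]] <- .mutateBase(species[[s]], p - 1L)
        subs[[length(subs) + 1L]] <- data.frame(
          species = speciesNames[s], pos = p - 1L, from = old,
          to = species[[s]][p], class = "background",
          stringsAsFactors = FALSE)
      }
    }
    coreMargin <- 30L
    for (im in implants) {
      core <- (im$start + coreMargin + 1L):(im$end - coreMargin)
      for (s in seq_len(3L)) {
        # implants receive their configured pairwise divergence exactly
        # (count scaled to the full window), placed in the window core
        n <- round(im$divergence * (im$end - im$start) / 2)
        pos <- sample(core, min(n, length(core)))
        for (p in pos) {
          old <- species[[s]][p]
          species[[s]] <- .mutateBase(species[[s]], p - 1L)
          subs[[length(subs) + 1L]] <- data.frame(
            species = speciesNames[s], pos = p - 1L, from = old,
            to = species[[s]][p], class = "implant",
            stringsAsFactors = FALSE)
        }
      }
    }
    # species-specific motif insertions at implant head/tail junctions
    ins <- list()
    for (im in implants) {
      for (s in seq_len(3L)) {
        motif <- im$motifs[s]
        if (!nzchar(motif)) next
        # junctions sit close to the window centre so any
        # window-length region overlapping the implant core carries
        # every species' diagnostic insertion
        centre <- (im$start + im$end) %/% 2L
        junction <- if (im$motifAt[s] == "head") centre - 20L
        else centre + 20L
        ins[[length(ins) + 1L]] <- data.frame(
          species = speciesNames[s], junction = junction, motif = motif,
          stringsAsFactors = FALSE)
      }
    }
    insDf <- if (length(ins)) do.call(rbind, ins)
    else data.frame(species = character(0), junction = integer(0),
                    motif = character(0), stringsAsFactors = FALSE)
    insDf <- insDf[order(insDf$junction, insDf$species), , drop = FALSE]

    # assemble genomes and the true alignment from the edit log
    rows <- list()
    seqs <- list()
    for (s in seq_len(3L)) {
      sp <- speciesNames[s]
      segs <- character(0)
      alnSegs <- character(0)
      prev <- 0L
      for (i in seq_len(nrow(insDf))) {
        j <- insDf$junction[i]
        seg <- paste(species[[s]][(prev + 1L):j], collapse = "")
        segs <- c(segs, seg)
        alnSegs <- c(alnSegs, seg)
        w <- nchar(insDf$motif[i])
        if (insDf$species[i] == sp) {
          segs <- c(segs, insDf$motif[i])
          alnSegs <- c(alnSegs, insDf$motif[i])
        } else alnSegs <- c(alnSegs, strrep("-", w))
        prev <- j
      }
      tailSeg <- paste(species[[s]][(prev + 1L):L], collapse = "")
      seqs[[sp]] <- paste(c(segs, tailSeg), collapse = "")
      rows[[sp]] <- paste(c(alnSegs, tailSeg), collapse = "")
    }
    genomes <- lapply(speciesNames, function(sp)
      GenomeRecord(sp, seqs[[sp]], circular = TRUE))
    names(genomes) <- speciesNames
    truth <- list(
      ancestor = paste(anc, collapse = ""),
      substitutions = if (length(subs)) do.call(rbind, subs)
      else data.frame(species = character(0), pos = integer(0),
                      from = character(0), to = character(0),
                      class = character(0), stringsAsFactors = FALSE),
      insertions = insDf, decoys = decoys, implants = implants,
      seed = seed)
    list(genomes = genomes,
         alignment = GenomeAlignment(unlist(rows)),
         truth = truth)
  })
}

# apply an allele edit list to a genome string; edits are applied in
# descending position order so coordinates stay valid
applyEdits <- function(seq, edits) {
  if (!length(edits)) return(seq)
  ord <- order(-vapply(edits, `[[`, 0, "pos"))
  for (e in edits[ord]) {
    p <- e$pos  # 0-based
    seq <- switch(e$type,
      sub = paste0(substr(seq, 1, p), e$bases,
                   substr(seq, p + nchar(e$bases) + 1L, nchar(seq))),
      ins = paste0(substr(seq, 1, p), e$bases,
                   substr(seq, p + 1L, nchar(seq))),
      del = paste0(substr(seq, 1, p),
                   substr(seq, p + e$len + 1L, nchar(seq))),
      stop("unknown edit type: ", e$type))
  }
  seq
}

#' Simulate a heteroplasmic read pool from one genome
#'
#' Reads are drawn uniformly along the (circular) genome at the
#' configured mean depth; each read's template is chosen from the allele
#' pool by its frequency, the strand is random, and per-base
#' substitution errors are i.i.d. at `errorRate`. The truth log stores
#' every read's source allele, start and strand.
#'
#' @param genome a [GenomeRecord-class].
#' @param depth mean coverage.
#' @param readLength read length in bp (study reads are 250 bp;
#'   single-end).
#' @param errorRate per-base substitution probability (<= 0.05).
#' @param allelePool named list of alleles: each
#'   `list(edits = list(...), freq = f)` with edits as
#'   `list(type = "sub"/"ins"/"del", pos, bases/len)` on the genome;
#'   frequencies must sum to 1.
#' @param seed integer seed.
#' @return list with `reads` (a [ReadSet-class]) and `truth`
#'   (data.frame: read, allele, start, strand; plus `alleleSeqs`).
#' @export
simulateHeteroplasmicReads <- function(genome, depth = 100, readLength = 250L,
                                       errorRate = 0.01,
                                       allelePool = list(
                                         main = list(edits = list(),
                                                     freq = 1)),
                                       seed = 1L) {
  stopifnot(errorRate >= 0, errorRate <= 0.05)
  f <- vapply(allelePool, `[[`, 0, "freq")
  stopifnot(abs(sum(f) - 1) < 1e-9)
  L <- length(genome)
  if (readLength > L) stop("read length exceeds genome length")
  withSeed(seed, {
    alleleSeqs <- lapply(allelePool, function(a)
      applyEdits(genomeSeq(genome), a$edits))
    templates <- lapply(alleleSeqs, function(s) {
      if (isCircular(genome)) paste0(s, substr(s, 1L, readLength - 1L))
      else s
    })
    nReads <- round(depth * L / readLength)
    whichAllele <- sample(names(allelePool), nReads, replace = TRUE,
                          prob = f)
    seqs <- character(nReads)
    starts <- integer(nReads)
    strands <- character(nReads)
    for (i in seq_len(nReads)) {
      tpl <- templates[[whichAllele[i]]]
      maxStart <- if (isCircular(genome)) nchar(alleleSeqs[[whichAllele[i]]])
      else nchar(tpl) - readLength + 1L
      s <- sample.int(maxStart, 1L)
      rd <- substr(tpl, s, s + readLength - 1L)
      if (errorRate > 0) {
        nerr <- stats::rbinom(1L, readLength, errorRate)
        if (nerr > 0) {
          chars <- strsplit(rd, "")[[1]]
          for (p in sample.int(readLength, nerr))
            chars <- .mutateBase(chars, p - 1L)
          rd <- paste(chars, collapse = "")
        }
      }
      strands[i] <- sample(c("+", "-"), 1L)
      if (strands[i] == "-") rd <- revComp(rd)
      seqs[i] <- rd
      starts[i] <- s - 1L
    }
    ids <- sprintf("%s_r%06d", genomeId(genome), seq_len(nReads))
    reads <- ReadSet(genomeId(genome), setNames(seqs, ids),
                     qualities = rep(strrep("I", readLength), nReads))
    list(reads = reads,
         truth = list(reads = data.frame(read = ids, allele = whichAllele,
                                         start = starts, strand = strands,
                                         stringsAsFactors = FALSE),
                      alleleSeqs = alleleSeqs, seed = seed))
  })
}

#' Write a ReadSet as FASTQ (constant qualities when none are stored)
#' @param reads a [ReadSet-class].
#' @param path output path.
#' @export
writeFastq <- function(reads, path) {
  seqs <- readSequences(reads)
  quals <- if (length(reads@qualities)) reads@qualities
  else strrep("I", nchar(seqs))
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}

# The published cz11 allele survey: gapped allele strings (38 alignment
# columns; head columns carry the 6 bp TCTTAC insertion, tail columns
# the 5 bp TATAT insertion) and read counts per species, with the
# per-species totals of mapped reads (the visible rows sum to less than
# the totals; the remainder are singleton alleles).
.cz11Rows <- function() {
  rows <- c(
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATATTATAT|356",
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATAT-----|8",
    "A_lancea|------AAGGAAAAGGAAAAAATGACATTATATTATAT|3",
    "A_lancea|------AAGGAAAGAGAAAAAATGACATTATATTATAT|3",
    "A_lancea|------AAGGAAAGGGAAAAAAAGACATTATATTATAT|3",
    "A_lancea|------AAAGAAAGGGAAAAAATGACATTATATTATAT|2",
    "A_lancea|------AAGGAAAGGAAAAAAATGACATTATATTATAT|2",
    "A_lancea|------AAGGAAAGGGAAAAAAGGACATTATATTATAT|2",
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATAATATAT|2",
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATA-----T|2",
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATATTAT--|2",
    "A_lancea|------AAGGAAAGGGAAAAAATGACATTATATTATCT|2",
    "A_lancea|------AAGGAAAGGGAAAAAATGACCTTATATTATAT|2",
    "A_lancea|------AAGGAAAGGGAAACAATGACATTATATTATAT|2",
    "A_lancea|------AAGGCAAGGGAAAAAATGACATTATATTATAT|2",
    "A_lancea|------AAGGTAAGGGAAAAAATGACATTATATTATAT|2",
    "A_lancea|------AATGAAAGGGAAAAAATGACATTATATTATAT|2",
    "A_lancea|------CAGGAAAGGGAAAAAATGACATTATATTATAT|2",
    "A_macrocephala|TCTTACAAGGAAAGGGAAAAAATGACATTATAT-----|588",
    "A_macrocephala|TCTTAAAAGGAAAGGGAAAAAATGACATTATAT-----|2",
    "A_macrocephala|TCTTACAAGGAAAGAGAAAAAATGACATTATAT-----|2",
    "A_macrocephala|TCTTACAAGGAAAGGGAAAAAATTACATTATAT-----|2",
    "A_chinensis|------AAGGAAAGGTAAAAAATGACATTATAT-----|420",
    "A_chinensis|------AAGGAAAGGGAAAAAATGACATTATAT-----|309",
    "A_chinensis|------AAGGAAAGGGAAAAAAAGACATTATAT-----|3",
    "A_chinensis|------AAGGAAAGGGAAAAA-TGACATTATAT-----|3",
    "A_chinensis|------AAGGAAAGAGAAAAAATGACATTATAT-----|2",
    "A_chinensis|------AAGGAAAGATAAAAAATGACATTATAT-----|2")
  parts <- strsplit(rows, "|", fixed = TRUE)
  data.frame(species = vapply(parts, `[[`, "", 1),
             allele = vapply(parts, `[[`, "", 2),
             count = as.integer(vapply(parts, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' The published cz11 allele survey
#'
#' Allele strings (38 gapped alignment columns) and read counts of the
#' cz11 marker locus for the three Atractylodes species, with the total
#' number of reads mapped per species. The visible rows sum to less than
#' the totals; the remainder are modelled as singleton alleles by
#' [makeCz11Fixture].
#'
#' @return list with `rows` (species/allele/count data.frame) and
#'   `totals` (named integer vector of mapped reads per species).
#' @export
cz11AlleleSurvey <- function() {
  list(rows = .cz11Rows(),
       totals = c(A_lancea = 445L, A_macrocephala = 620L,
                  A_chinensis = 762L))
}

#' Build the cz11 allele-survey read fixture
#'
#' Embeds the published cz11 allele strings into a conserved 600 bp
#' synthetic flank context and emits error-free reads with exactly the
#' published per-allele counts, topped up with distinct singleton
#' variants so species totals reach 445 / 620 / 762 reads. Profiling
#' this fixture with [recruitReads] + [tabulateAlleles] reproduces the
#' published counts and dominant shares. Deterministic: repeated calls
#' are identical.
#'
#' @param readLength read length of the emitted reads.
#' @return list with per-species `genomes` (locus context as a
#'   [GenomeRecord-class]), `targets` (0-based half-open target interval
#'   in the context), `fragments` (a `TargetFragment` per species),
#'   `readSets` (a [ReadSet-class] per species), `dominant` (named
#'   ungapped dominant alleles) and `expected` (the per-species count
#'   tables the profiler should reproduce, singletons included).
#' @export
makeCz11Fixture <- function(readLength = 250L) {
  tab <- .cz11Rows()
  totals <- cz11AlleleSurvey()$totals
  flankLen <- 300L
  flanks <- withSeed(20200128L, {
    list(left = randomDna(flankLen), right = randomDna(flankLen))
  })
  out <- list(genomes = list(), targets = list(), fragments = list(),
              readSets = list(), dominant = character(0), expected = list())
  for (sp in unique(tab$species)) {
    rows <- tab[tab$species == sp, , drop = FALSE]
    variants <- gsub("-", "", rows$allele)
    counts <- rows$count
    dominant <- variants[1]
    # top up with distinct novel single-substitution singleton variants
    need <- totals[[sp]] - sum(counts)
    seen <- variants
    p <- 0L
    while (need > 0L) {
      pos <- (p %% nchar(dominant)) + 1L
      shift <- p %/% nchar(dominant) + 1L
      old <- substr(dominant, pos, pos)
      newBase <- c("A", "C", "G", "T")[
        (match(old, c("A", "C", "G", "T")) + shift - 1L) %% 4L + 1L]
      cand <- dominant
      substr(cand, pos, pos) <- newBase
      p <- p + 1L
      if (newBase == old || cand %in% seen) next
      seen <- c(seen, cand)
      variants <- c(variants, cand)
      counts <- c(counts, 1L)
      need <- need - 1L
    }
    context <- paste0(flanks$left, dominant, flanks$right)
    genome <- GenomeRecord(paste0(sp, "_cz11_locus"), context,
                           circular = FALSE)
    tStart <- flankLen
    tEnd <- flankLen + nchar(dominant)
    frag <- extractTargetFragment(genome, tStart, tEnd, fragmentLen = 600L)
    # error-free reads spanning the target, start offsets cycling over a
    # fixed grid well inside the flanks
    starts <- seq(140L, 260L, by = 20L)
    seqs <- character(0)
    for (v in seq_along(variants)) {
      tpl <- paste0(flanks$left, variants[v], flanks$right)
      for (r in seq_len(counts[v])) {
        s <- starts[(r - 1L) %% length(starts) + 1L]
        seqs <- c(seqs, substr(tpl, s, s + readLength - 1L))
      }
    }
    ids <- sprintf("%s_read%04d", sp, seq_along(seqs))
    out$genomes[[sp]] <- genome
    out$targets[[sp]] <- c(tStart, tEnd)
    out$fragments[[sp]] <- frag
    out$readSets[[sp]] <- ReadSet(sp, setNames(seqs, ids))
    out$dominant[[sp]] <- dominant
    out$expected[[sp]] <- data.frame(variant = variants, count = counts,
                                     stringsAsFactors = FALSE)
  }
  out
}
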