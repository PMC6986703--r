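test_that("trio simulation is deterministic and respects mu = 0", {
  flat <- simulateGenomeTrio(genomeLength = 2000L, mu = 0, seed = 3L,
                             implants = list(), decoys = list())
  seqs <- vapply(flat$genomes, genomeSeq, "")
  expect_true(all(seqs == seqs[1]))

  a <- simulateGenomeTrio(genomeLength = 3000L, seed = 9L)
  b <- simulateGenomeTrio(genomeLength = 3000L, seed = 9L)
  expect_identical(vapply(a$genomes, genomeSeq, ""),
                   vapply(b$genomes, genomeSeq, ""))
  expect_identical(a$truth$substitutions, b$truth$substitutions)
  c2 <- simulateGenomeTrio(genomeLength = 3000L, seed = 10L)
  expect_false(identical(vapply(a$genomes, genomeSeq, ""),
                         vapply(c2$genomes, genomeSeq, "")))
})

test_that("pairwise background divergence follows the Poisson expectation", {
  mu <- 0.005
  L <- 20000L
  trio <- simulateGenomeTrio(genomeLength = L, mu = mu,
                             implants = list(), decoys = list(),
                             seed = 21L)
  m <- alignmentMatrix(trio$alignment)
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    d <- sum(m[p[1], ] != m[p[2], ])
    expect_lt(abs(d - mu * L), 3 * sqrt(mu * L) + 1e-9)
  }
})

test_that("every truth-log edit is verifiable against the emitted genomes", {
  trio <- simulateGenomeTrio(genomeLength = 4000L, seed = 5L)
  anc <- strsplit(trio$truth$ancestor, "")[[1]]
  m <- alignmentMatrix(trio$alignment)
  # alignment rows with gap columns removed reconstruct the genomes
  for (sp in names(trio$genomes)) {
    row <- paste(m[sp, m[sp, ] != "-"], collapse = "")
    expect_identical(row, genomeSeq(trio$genomes[[sp]]))
  }
  # ancestor-coordinate columns (non-insertion) differ from the
  # ancestor exactly at the logged substitutions
  insCols <- colSums(m == "-") > 0L
  for (sp in names(trio$genomes)) {
    anchored <- m[sp, !insCols]
    subsSp <- trio$truth$substitutions[
      trio$truth$substitutions$species == sp, ]
    diffs <- which(anchored != anc)
    expect_setequal(diffs - 1L, subsSp$pos)
    expect_identical(unname(anchored[subsSp$pos + 1L]), subsSp$to)
  }
  # logged insertions appear verbatim in their own species only
  ins <- trio$truth$insertions
  for (i in seq_len(nrow(ins))) {
    sp <- ins$species[i]
    expect_true(grepl(ins$motif[i], genomeSeq(trio$genomes[[sp]]),
                      fixed = TRUE))
  }
  # homopolymer decoys present in all genomes
  for (d in trio$truth$decoys)
    for (sp in names(trio$genomes))
      expect_true(grepl(strrep(d$base, d$len), genomeSeq(trio$genomes[[sp]]),
                        fixed = TRUE))
})

test_that("overlapping implants are rejected", {
  bad <- list(list(start = 100L, end = 300L, divergence = 0.05,
                   motifs = c("", "", ""), motifAt = c("", "", "")),
              list(start = 250L, end = 450L, divergence = 0.05,
                   motifs = c("", "", ""), motifAt = c("", "", "")))
  expect_error(simulateGenomeTrio(genomeLength = 2000L, implants = bad),
               "disjoint")
})

test_that("error-free single-allele reads are exact genome substrings", {
  g <- GenomeRecord("g", randomSeq(1200, seed = 31), circular = TRUE)
  sim <- simulateHeteroplasmicReads(g, depth = 10, readLength = 100,
                                    errorRate = 0, seed = 32L)
  doubled <- paste0(genomeSeq(g), genomeSeq(g))
  for (i in seq_len(length(sim$reads))) {
    rd <- readSequences(sim$reads)[[i]]
    info <- sim$truth$reads[i, ]
    tpl <- substr(doubled, info$start + 1, info$start + 100)
    expect_identical(if (info$strand == "-") rcOracle(rd) else rd, tpl)
  }
  # truth-log allele counts sum to the number of emitted reads
  expect_equal(sum(table(sim$truth$reads$allele)), length(sim$reads))
  expect_error(simulateHeteroplasmicReads(g, readLength = 2000L),
               "exceeds")
})

test_that("heteroplasmic pool frequencies are recovered by profiling", {
  g <- GenomeRecord("g", randomSeq(1200, seed = 41), circular = TRUE)
  base <- substr(genomeSeq(g), 601, 601)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  pool <- list(X = list(edits = list(), freq = 0.8),
               Y = list(edits = list(list(type = "sub", pos = 600L,
                                          bases = alt)), freq = 0.2))
  sim <- simulateHeteroplasmicReads(g, depth = 200, readLength = 150,
                                    errorRate = 0, allelePool = pool,
                                    seed = 43L)
  fr <- extractTargetFragment(g, 590, 610, 400)
  tab <- tabulateAlleles(recruitReads(fr, sim$reads), fr)
  n <- totalMapped(tab)
  shares <- dominantShare(tab, 2)
  # 99% binomial interval around the configured 0.8 / 0.2
  expect_lt(abs(shares[1] - 0.8), 2.58 * sqrt(0.8 * 0.2 / n))
  expect_lt(abs(shares[2] - 0.2), 2.58 * sqrt(0.8 * 0.2 / n))
  # truth log agrees with the tabulated dominant allele
  expect_equal(names(which.max(table(sim$truth$reads$allele))), "X")
})

test_that("the cz11 fixture carries the published counts and structure", {
  fx <- makeCz11Fixture()
  totals <- cz11AlleleSurvey()$totals
  for (sp in names(totals)) {
    expect_equal(length(fx$readSets[[sp]]), unname(totals[[sp]]))
    expect_equal(sum(fx$expected[[sp]]$count), unname(totals[[sp]]))
    # singleton padding variants are distinct from every listed variant
    # and from each other (two published rows may share an ungapped
    # sequence; they merge when profiled)
    singles <- fx$expected[[sp]]$variant[fx$expected[[sp]]$count == 1L]
    listed <- fx$expected[[sp]]$variant[fx$expected[[sp]]$count > 1L]
    expect_false(anyDuplicated(singles) > 0)
    expect_length(intersect(singles, listed), 0)
    # dominant allele is embedded at the fragment centre
    frag <- fx$fragments[[sp]]
    t1 <- frag$targetOffset + 1
    expect_identical(substr(frag$fragmentSeq, t1,
                            t1 + nchar(fx$dominant[[sp]]) - 1),
                     fx$dominant[[sp]])
  }
  # deterministic
  fx2 <- makeCz11Fixture()
  expect_identical(readSequences(fx$readSets[[1]]),
                   readSequences(fx2$readSets[[1]]))
})
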